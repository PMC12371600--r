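# Shared lexical resources: template sentence pools for the synthetic
# generator, emotion/bucket cue vocabularies, and the spell-check dictionary
# assembled from them. The generator and the default classifiers are
# co-designed around these lists so planted labels are recoverable exactly.

.kin_nouns <- c("husband", "wife", "mother", "father", "mom", "dad",
                "son", "daughter", "brother", "sister", "partner")

.patient_role_phrases <- c(
  "I have MDS", "I was diagnosed with MDS", "I am living with MDS",
  "I suffer from MDS"
)

# Cue vocabularies. The seven emotion classes, the two finer labels, and the
# high-risk sub-sentiment buckets use pairwise disjoint cue words so that a
# planted label never fires a sibling class.
.emotion_cues <- list(
  sadness  = c("heartbroken", "tearful", "grieving", "devastated"),
  joy      = c("overjoyed", "delighted", "grateful", "wonderful"),
  surprise = c("astonished", "stunned", "unexpected"),
  fear     = c("terrified", "frightened", "dreading"),
  disgust  = c("disgusted", "repulsed"),
  anger    = c("furious", "outraged", "infuriating")
)

.finer_cues <- list(
  worry       = c("worried", "worrying"),
  hopefulness = c("hopeful", "hoping")
)

.bucket_cues <- list(
  concern             = c("concerned", "concern", "concerns"),
  anxiety             = c("anxious", "anxiety"),
  frustration         = c("frustrated", "frustrating"),
  fear                = c("fearful"),
  confusion           = c("confused", "confusing"),
  information_seeking = c("does anyone know", "any advice",
                          "where can i find", "has anyone tried")
)

.filler_sentences <- c(
  "The last few weeks have been busy with appointments.",
  "We are taking things one day at a time.",
  "Thanks to everyone on this forum for the kind words.",
  "The nurses at the clinic have been very helpful.",
  "I will post an update after the next visit.",
  "It helps so much to read about other experiences here.",
  "The drive to the hospital was easier this week.",
  "We finally got the paperwork sorted out.",
  "My energy comes and goes from day to day.",
  "The care team answered most of our questions."
)

# Role-marker sentences; patient phrases are completed into sentences, the
# caregiver pool realizes kin + diagnosis patterns (KIN is slot-filled).
.role_sentence_templates <- list(
  patient = c(
    "PHRASE and wanted to share an update.",
    "PHRASE and this forum has helped a lot.",
    "PHRASE so I know how this feels."
  ),
  caregiver = c(
    "My KIN was diagnosed with MDS and I care for him every day.",
    "My KIN has MDS and I am the main caregiver now.",
    "My KIN is living with MDS and we manage it together.",
    "My KIN suffers from MDS and I go to every visit."
  ),
  other = c(
    "MDS is a rare disease.",
    "What does this diagnosis mean in practice?",
    "Is there a good overview of MDS somewhere?"
  )
)

# High-risk surrogate marker sentences, one pool per marker category. A
# fraction of drug mentions use the brand name so the brand-to-INN mapping is
# exercised before risk tagging.
.risk_sentences <- list(
  hypomethylating_agent = c(
    "My doctor started me on azacitidine last month.",
    "We are starting decitabine next week."
  ),
  venetoclax = c(
    "The team added venetoclax to the plan.",
    "My doctor started me on Venclexta."
  ),
  aml_progression = c(
    "They said it has progressed to AML."
  ),
  transplant = c(
    "The team is planning an allogeneic stem cell transplant.",
    "A haploidentical transplant is on the table."
  ),
  dli = c(
    "I had a donor lymphocyte infusion in the spring."
  ),
  epo_failure = c(
    "Erythropoietin failed to improve my anemia."
  ),
  multiple_transfusions = c(
    "I am getting weekly transfusions now."
  ),
  stem_cell_transplantation = c(
    "A stem cell transplantation was recommended."
  ),
  intensive_chemotherapy = c(
    "We are considering intensive chemotherapy."
  ),
  explicit_high_risk = c(
    "They told us this is high-risk MDS."
  ),
  blast_threshold = c(
    "My blasts were at BLAST% on the last biopsy."
  )
)

.low_risk_sentence <- "I have low risk MDS according to my doctor."
.low_blast_sentence <- "My blasts were at BLAST% on the last biopsy."

# Broad-category seed sentences; each sentence only contains seed keywords of
# its own category so planted category labels stay recoverable.
.theme_sentences <- list(
  clinical = c(
    "The hemoglobin and platelets were low again.",
    "Blood counts are checked every two weeks.",
    "The biopsy confirmed the diagnosis."
  ),
  diet_lifestyle = c(
    "I changed my diet and added light exercise.",
    "Nutrition and daily routine matter a lot."
  ),
  education_logistics = c(
    "The insurance forms for the appointment took hours.",
    "We asked for a second opinion about the care options."
  ),
  emotional = c(
    "Sending support and encouragement to everyone here.",
    "Stay strong and know you are not alone."
  ),
  physical = c(
    "The fatigue and nausea have been hard.",
    "Pain and side effects come and go."
  ),
  transplants = c(
    "The donor search for the transplant continues.",
    "Conditioning before the graft starts soon."
  ),
  treatments = c(
    "The treatment cycle and regimen were adjusted.",
    "A transfusion was scheduled for Friday."
  )
)

# Emotion / finer / bucket cue sentence templates (WORD is slot-filled).
.cue_sentence_templates <- c(
  "I feel WORD about all of it.",
  "It has been WORD lately.",
  "Honestly I am WORD about the next steps."
)
.info_seeking_sentences <- c(
  "Does anyone know what to expect?",
  "Any advice on what to ask the team?",
  "Has anyone tried something similar?"
)

.trial_sentence <- paste(
  "I decided to enroll in a clinical trial with a new drug called",
  "sabatolimab.")

# PII sentence templates; slots GIVEN/SURNAME/LOCAL/PHONE are filled from the
# synthetic name lists. LOCAL is uppercase-plus-digits so the spell corrector
# (which only touches lowercase tokens) can never alter an injected handle.
.pii_templates <- list(
  NAME = "My name is GIVEN SURNAME.",
  EMAIL = "You can email me at LOCAL@example.com.",
  PHONE = "Call me at PHONE.",
  PROVIDER_NAME = "Dr SURNAME is my hematologist.",
  URL = "I write about it at http://blog.example.com/LOCAL",
  MANUFACTURER = "The pills come from Celgene."
)

# Length-preserving corruptions (substitution or adjacent transposition) with
# a unique dictionary word at edit distance 1, so autocorrection is exact.
.misspell_map <- c(
  doctor = "docter", treatment = "treatmnet", transfusion = "transfusoin",
  hospital = "hosptial", fatigue = "fatigeu", insurance = "insuranec"
)

.inn_names <- c("venetoclax", "ivosidenib", "gilteritinib", "bortezomib",
                "glasdegib", "enasidenib", "gemtuzumab", "ozogamicin",
                "clofarabine", "azacitidine", "decitabine", "sabatolimab",
                "magrolimab", "tamibarotene", "erythropoietin")

.extra_dictionary_words <- c(
  "receive", "received", "definitely", "tomorrow", "morning", "because",
  "through", "a", "an", "and", "at", "be", "but", "by", "for", "from",
  "had", "has", "have", "he", "her", "him", "his", "i", "in", "is", "it",
  "me", "my", "not", "of", "on", "or", "our", "she", "so", "that", "the",
  "their", "them", "they", "this", "to", "us", "was", "we", "were",
  "with", "you"
)

.collect_words <- function(x) {
  toks <- unlist(stringr::str_extract_all(tolower(unlist(x)), "[a-z']+"))
  sort(unique(toks))
}

#' Default spell-check dictionary
#'
#' The bundled word list used by [correct_spelling()]. It is assembled from
#' the package's own template and cue vocabularies (so cleaning can never
#' mangle a planted marker) plus drug nonproprietary names and a core of
#' common English words. Frequencies are coarse: common function words rank
#' above content words for tie-breaking.
#'
#' @return Tibble with columns `word` and `freq`.
#' @export
default_dictionary <- function() {
  vocab <- .collect_words(list(
    .filler_sentences, .patient_role_phrases, .kin_nouns,
    unlist(.emotion_cues), unlist(.finer_cues), unlist(.bucket_cues),
    unlist(.role_sentence_templates), unlist(.risk_sentences),
    .low_risk_sentence, unlist(.theme_sentences),
    .cue_sentence_templates, .info_seeking_sentences,
    .trial_sentence, unlist(.pii_templates),
    names(.misspell_map)
  ))
  vocab <- union(vocab, .inn_names)
  vocab <- union(vocab, .extra_dictionary_words)
  vocab <- setdiff(vocab, c("word", "kin", "phrase", "blast", "given",
                            "surname", "local", "phone"))
  tibble::tibble(
    word = vocab,
    freq = ifelse(vocab %in% .extra_dictionary_words, 10L, 1L)
  )
}

# Synthetic name lists for PII injection; disjoint from the institution
# allowlist used by the scrubber.
.synth_given_names <- c("Alice", "Brian", "Clara", "Daniel", "Elena",
                        "Frank", "Grace", "Henry", "Irene", "Jacob",
                        "Karen", "Louis", "Maria", "Nolan", "Olive")
.synth_surnames <- c("Abbott", "Bennett", "Carver", "Dalton", "Ellison",
                     "Foster", "Granger", "Holloway", "Ingram", "Jennings",
                     "Keller", "Lawson", "Mercer", "Norwood", "Osborne")
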