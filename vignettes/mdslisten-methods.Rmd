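---
title: "Methods: mining patient and caregiver experience from MDS forums"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mining patient and caregiver experience from MDS forums}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mdslisten)
```

## The problem

Myelodysplastic syndromes (MDS) are clonal hematologic malignancies with
variable prognosis and a risk of progression to acute myeloid leukemia
(AML). Patients and their caregivers discuss diagnosis, treatment decisions,
and day-to-day burden on public forums, and those unprompted narratives are
a useful complement to structured patient-reported-outcome research —
especially for the higher-risk (HR-MDS) subgroup, whose experiences are
rarely isolated in the literature. `mdslisten` implements a full
social-media-listening pipeline over such forum corpora: cleaning and
de-identification, patient-versus-caregiver attribution, HR-MDS cohort
extraction from textual treatment surrogates, theme and sentiment analysis,
engagement and thematic-saturation analysis, and a pre/post-COVID temporal
split.

Because real forum data cannot be redistributed, the package ships a
synthetic corpus generator (`generate_corpus()`) that emits forum-shaped
data with exact ground-truth labels. Every downstream stage is exercised and
tested against that ground truth.

## Pipeline stages and their assumptions

`run_pipeline()` runs the stages in a fixed order: load, clean/dedup/
exclude, anonymize, role, risk, themes, sentiment, engagement/saturation/
temporal, report. Each stage reports input/output/removed counts so record
conservation is checkable from the run report.

### Cleaning

Posts failing UTF-8 validation are excluded. Spell autocorrection replaces
an out-of-dictionary lowercase token with its unique best in-dictionary
candidate at edit distance at most 1, where an adjacent transposition
("recieve" for "receive") also counts as a single edit; ties break by
dictionary frequency and then lexicographically. Capitalized and
non-alphabetic tokens are never touched, so names, handles, emails, and
numeric values cannot be corrupted by cleaning. Duplicates are keyed on
(user, whitespace/case-normalized text) — cross-posting by the same user is
the dominant duplication mode on forums — and the earliest copy is kept.
The study window filter is inclusive of both endpoints; the default window
is 2008-01-01 to 2022-12-31, kept configurable because different parts of a
study protocol often state slightly different windows.

### De-identification

Name scrubbing is lexicon-and-title driven rather than model driven: person
names become `NAME`, title+name provider mentions (`Dr Smith`) become
`PROVIDER NAME`, manufacturer names become `PRODUCT MANUFACTURER`, and
emails, phone numbers and personal links are removed outright (the audit
table records each span, and replaying the audit over the original text
reproduces the scrubbed text). Institutions on an allowlist (NCI, Dana
Farber, ...) are retained verbatim and take precedence over overlapping
name matches. Brand drug names are mapped to lowercase International
Nonproprietary Names (Venclexta to venetoclax, and so on) by
case-insensitive whole-word replacement; because no INN is itself a key,
the mapping is idempotent, and misspelled brands are expected to have been
repaired by the spell corrector that runs earlier.

Usernames are replaced by 12-hex-digit tokens from a salted keyed hash so
that one user's posts stay linkable over time. The token generator re-hashes
with an internal counter until the token shares no 3-character substring
with the raw handle, and a corpus-level collision between distinct users is
treated as fatal. The hash concatenates three polynomial hashes with
independent multipliers; variants differing only in an additive seed have
perfectly correlated collisions and were rejected for exactly that reason.

Posts naming an investigational agent, or asserting first-person trial
participation ("I enrolled in the trial"), are dropped; passing references
("my oncologist recommended I look at clinical trials") are kept. Where a
strict reading of exclusion rules conflicts with that worked example, the
worked example wins, since it pins down intended behaviour on a concrete
sentence.

### Role attribution

Posts are labeled by key phrases: first-person diagnosis phrases ("I have
MDS", "I was diagnosed with MDS", "I am living with MDS", "I suffer from
MDS", with "myelodysplastic syndrome" also accepted for the disease term)
mark a patient; third-person kin+diagnosis and caregiving patterns mark a
caregiver. If both match, the earlier match position decides. A user takes
a role when at least 80% of their labeled posts agree — the boundary is
inclusive, so 4 of 5 posts suffices — otherwise the posts are scanned
chronologically and the first label with confidence at or above 0.9
decides. Posts with no role evidence are excluded from the 80% denominator:
an ambiguous post carries no information about who is writing. The
confidence threshold matters only for pluggable fallback classifiers; the
bundled reference fallback is a transparent term-frequency nearest-centroid
scorer trained on synthetic posts, standing in for the supervised models a
production deployment would plug in.

### HR-MDS extraction

A post is high-risk evidence when it mentions a treatment surrogate drawn
from guideline-aligned markers: hypomethylating agents (azacitidine,
decitabine), venetoclax, progression to AML, allogeneic or haploidentical
transplantation, donor lymphocyte infusion, erythropoietin failure,
multiple transfusions, stem cell transplantation, intensive chemotherapy,
an explicit "high-risk" self-report, or a blast percentage at or above 20.
Blast parsing ties a percentage to a blast mention within a 6-token window
— wide enough for "blasts were at 22%", narrow enough to avoid
cross-sentence leakage. "Multiple transfusions" is operationalized as a
transfusion mention with a plural or frequency cue, since no count
threshold is given anywhere. A single marker anywhere in a user's history
labels the user high risk; explicit self-reports of low/intermediate/very
high risk are emitted only in the absence of surrogate markers, and an
explicit "low risk" statement never vetoes surrogate-derived high risk —
disease can progress between posts, so the surrogate evidence dominates.

### Themes

Two parallel label systems are kept deliberately: seven broad categories
(clinical, diet and lifestyle, education and logistics, emotional,
physical, transplants, treatments) and a five-root theme hierarchy (disease
burden, treatment decision, unmet needs, life milestones, logistic burden)
with keyword-seeded subthemes. Their relationship is not formally defined
in the source protocol, so no mapping between them is invented. The
reference top-down classifier is seeded-keyword scoring (a node fires on
any seed; its score is the matched-seed fraction), which is fully auditable;
a supervised classifier can be plugged in behind the same interface.

Bottom-up discovery (`fit_latent_topics()`) supports LDA (collapsed Gibbs),
LSA (truncated SVD plus k-means), k-means, spectral, agglomerative, DBSCAN,
and OPTICS over tf-idf vectors (lowercase, stopword removal, minimum
document frequency 2, L2-normalized rows). All methods are seeded and
deterministic. OPTICS clusters are extracted from the reachability profile
at a fixed eps (the DBSCAN-equivalent cut). Discovered topics are merged
into the hierarchy by an explicit reviewer mapping (map to a node, create a
subtheme, or discard); merging never removes existing nodes.

Theme prevalence counts unique discussions (threads) mentioning a theme —
not posts — and the co-mention network connects two themes with the number
of discussions containing both. A theme is major when its prevalence
reaches the threshold, inclusive at the boundary; the default threshold is
5% of discussions, a configuration choice since only the existence of a
threshold is specified. Actionability is a per-node flag: emotional-support
themes are nonactionable, gap-identifying themes actionable.

### Sentiment

The default emotion classifier is a cue-word lexicon over seven classes
(neutral, sadness, joy, surprise, fear, disgust, anger) plus finer worry/
hopefulness labels; a class fires when any of its cues occurs, and neutral
fires exactly when nothing else does. This replaces a fine-tuned
transformer whose training corpus and weights are proprietary and therefore
out of reach; the scorer interface accepts any function returning per-class
scores, so a transformer can be substituted without touching aggregation.
High-risk discussions are additionally bucketed into concern, anxiety,
frustration, fear, confusion, and information-seeking, each bucket carrying
the subset of its attribution topics found in the post's theme assignment.

Cohort prevalence tables are user-denominated: a user carries a label if at
least one of their posts does (union aggregation — the weakest assumption
consistent with user-level reporting), counts once regardless of volume,
and percentages are rounded half away from zero to integers.

### Engagement, saturation, temporal

Superusers are the top 1% of users by post count (ties at the cut
included); for discussion-level aggregation each superuser contributes at
most 1 post per discussion (capping matches the discussion-level prevalence
unit better than winsorizing scores would). Thematic saturation processes
posts chronologically in batches (default 100 posts) and declares
saturation at the first batch followed by a lookahead window (default 3
batches) in which no significant theme — one that is major on the full
corpus — first appears; the final batch can never qualify, so a schedule
that keeps introducing themes yields no saturation point. The COVID split
uses the fixed boundaries 2018-01-01..2020-02-29 (pre) and 2020-03-01
onward (post); earlier posts are excluded from that comparison.

## The synthetic generator

`generate_corpus()` emulates the population structure the analysis assumes:
a role mix of roughly 49% patients / 42% caregivers / 9% others, about a
third of clinical users in the high-risk cohort, ~1% superusers whose post
counts come from a shifted negative binomial far above the regular-user
mean, regular activity spans log-normal around a 10-day median with a tail
beyond 1000 days, timestamps across 2008–2022 over three forum-shaped
sources, and per-post injection of PII (5%), length-preserving misspellings
(10%), duplicates (2%), and trial mentions (1%).

Post text is template-based, not free generation: role phrases, marker
sentences, theme seed sentences and emotion cue words are slotted into
fixed sentence frames, so every planted label is recoverable by
construction and PII spans are exact character ranges. The cue lexicons of
the generator and of the default classifiers are co-designed and pairwise
disjoint across labels. Two deliberate couplings keep the planted truth
recoverable end to end: trial-mention sentences are never attached to a
post that carries a user's risk marker (trial posts are dropped by the
anonymizer, which would otherwise silently destroy planted evidence), and
misspellings are length-preserving substitutions/transpositions outside
PII spans with a unique dictionary repair.

What the generator does *not* emulate: free-text style variation,
misspelled role/marker phrases, sarcasm or negation ("never started
azacitidine" still matches), multilingual content, PII forms outside its
templates, and users whose role changes over time. Passing tests therefore
show that the rules are implemented correctly and are internally
consistent, not that they would achieve the same accuracy on real forum
text — on real data the phrase lexicons and the pluggable classifiers
carry that burden.

## Numerical choices

- Percentages: rounded half away from zero to integers (`pct_of()`);
  reported values keep the printed scale (47 means 47%).
- Spell correction: maximum edit distance 1 including adjacent
  transpositions; ties by frequency then lexicographic order.
- Duplicate tie-break: earliest timestamp, then post id.
- Blast window: 6 tokens; threshold inclusive (`>= 20`).
- Majority rule: inclusive at 0.8; denominator excludes unlabeled posts.
- Major themes: inclusive at the prevalence threshold; default threshold
  `ceiling(0.05 * discussions)`, floored at 1.
- Username tokens: 12 hex characters; three 16-bit polynomial hashes with
  multipliers 31/257/8191 modulo 2^31-1; deterministic substring-leak
  rejection loop; collisions fatal.
- Degenerate inputs: empty corpora flow through every stage with zero
  counts; an empty prevalence cohort is a hard error (a silent 0/0 would
  fabricate percentages); k larger than the corpus is fatal for
  partitional topic models.

## Problem sizes

The test-suite defaults are sized for routine runs: unit fixtures use a
120-user corpus and the end-to-end acceptance properties a 2000-user corpus
(roughly 23,000 posts), which the full pipeline processes in about two
minutes on one core. `scripts/acceptance.R` regenerates the 2000-user
corpus from the command-line seed and recomputes every reported quantity
from scratch.

## Known limitations

- Lexicon-driven name scrubbing misses names absent from the bundled lists;
  the lists are an artifact choice, not a clinical registry.
- Single-role user decisions: a genuinely dual-role user (patient *and*
  caregiver) is resolved to whichever role dominates their posts.
- Only the high-risk label is operationalized from surrogates; low /
  intermediate / very-high labels require explicit self-report.
- The emotion lexicon is intentionally transparent and therefore shallow;
  it does not model negation, intensity, or context.
- Saturation depends on batch size and lookahead; both are configuration
  with documented defaults, as no canonical values exist.
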