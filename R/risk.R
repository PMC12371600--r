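#' Default high-risk MDS marker lexicon
#'
#' Surface-form lists per surrogate-marker category, plus the blast-count
#' threshold rule (a percentage at or above `blast_threshold` within
#' `blast_window` tokens of a blast mention). Texts are expected to be
#' INN-normalized first so brand mentions hit the nonproprietary-name lists.
#'
#' @param blast_threshold Blast percentage at or above which the blast rule
#'   fires (default 20).
#' @param blast_window Token window linking a number to a blast mention
#'   (default 6).
#' @return List of class `risk_marker_lexicon`.
#' @export
risk_marker_lexicon <- function(blast_threshold = 20, blast_window = 6L) {
  stopifnot(blast_threshold > 0, blast_threshold <= 100, blast_window >= 1)
  categories <- list(
    explicit_high_risk = c("(?<!very )high[- ]?risk", "\\bhr-mds\\b"),
    hypomethylating_agent = c("\\bazacitidine\\b", "\\bdecitabine\\b",
                              "\\bhypomethylating\\b"),
    venetoclax = c("\\bvenetoclax\\b"),
    aml_progression = c(
      "progress(ed|ing|ion) to aml", "transform(ed|ation)? (to|into) aml",
      "developed aml", "turned into aml"),
    transplant = c("\\ballogeneic\\b", "\\bhaploidentical\\b",
                   "bone marrow transplant", "stem cell transplant\\b"),
    dli = c("donor lymphocyte infusion", "\\bdli\\b"),
    epo_failure = c(
      "(erythropoietin|\\bepo\\b) (failed|did ?n[o']t work|stopped working)",
      "fail(ed|ure) of (recombinant )?erythropoietin"),
    multiple_transfusions = c(
      "\\btransfusions\\b", "another transfusion",
      "(weekly|monthly|regular|frequent) transfusions?",
      "transfusion dependent"),
    stem_cell_transplantation = c("stem cell transplantation"),
    intensive_chemotherapy = c("intensive chemotherapy",
                               "induction chemotherapy", "\\b7\\+3\\b")
  )
  if (any(lengths(categories) == 0)) abort("every marker category needs terms")
  structure(list(categories = categories,
                 blast_threshold = blast_threshold,
                 blast_window = as.integer(blast_window)),
            class = "risk_marker_lexicon")
}

#' Parse blast percentages from text
#'
#' Returns, in order of appearance, every numeric percentage ("N%" or
#' "N percent") within `window` tokens of a blast mention ("blast", "blasts",
#' "blast count(s)").
#'
#' @param text Character scalar.
#' @param window Token distance linking number to blast word (default 6).
#' @return Numeric vector of percentages (possibly empty).
#' @export
parse_blast_percentages <- function(text, window = 6L) {
  toks <- tokenize_words(text)[[1]]
  if (length(toks) == 0) return(numeric(0))
  blast_idx <- which(toks %in% c("blast", "blasts"))
  if (length(blast_idx) == 0) return(numeric(0))
  pct_idx <- which(grepl("^\\d+(\\.\\d+)?%$", toks))
  # "N percent" form: number token followed by the word "percent"
  num_idx <- which(grepl("^\\d+(\\.\\d+)?$", toks))
  num_idx <- num_idx[num_idx < length(toks) & toks[num_idx + 1L] == "percent"]
  cand <- sort(unique(c(pct_idx, num_idx)))
  if (length(cand) == 0) return(numeric(0))
  near <- vapply(cand, function(i) min(abs(i - blast_idx)) <= window,
                 logical(1))
  vals <- as.numeric(sub("%$", "", toks[cand[near]]))
  vals[vals >= 0 & vals <= 100]
}

#' Detect high-risk surrogate markers in a post
#'
#' Matches every marker category of the lexicon against the (already
#' INN-normalized) text; the blast category fires iff some parsed blast
#' percentage reaches the threshold.
#'
#' @param text Character scalar.
#' @param lexicon A [risk_marker_lexicon()].
#' @return Tibble of matched categories with the matched surface evidence
#'   and, for the blast rule, the qualifying values.
#' @export
detect_hr_markers <- function(text, lexicon = risk_marker_lexicon()) {
  lower <- tolower(text)
  rows <- list()
  for (cat in names(lexicon$categories)) {
    for (p in lexicon$categories[[cat]]) {
      m <- regexpr(p, lower, perl = TRUE)
      if (m > 0) {
        rows[[length(rows) + 1]] <- tibble::tibble(
          category = cat,
          evidence = substring(lower, m, m + attr(m, "match.length") - 1L)
        )
        break
      }
    }
  }
  blasts <- parse_blast_percentages(text, lexicon$blast_window)
  qualifying <- blasts[blasts >= lexicon$blast_threshold]
  if (length(qualifying) > 0) {
    rows[[length(rows) + 1]] <- tibble::tibble(
      category = "blast_threshold",
      evidence = paste0(qualifying, "%", collapse = ", ")
    )
  }
  if (length(rows) == 0) {
    return(tibble::tibble(category = character(0), evidence = character(0)))
  }
  dplyr::bind_rows(rows)
}

.explicit_risk_patterns <- c(
  low = "\\blow[- ]?risk (mds|myelodysplastic)|\\b(i have|diagnosed with) low risk\\b",
  intermediate = "\\bintermediate[- ]?risk\\b",
  very_high = "\\bvery high[- ]?risk\\b"
)

#' Classify a user's risk from their posts' evidence
#'
#' A user is `high` risk if any post carries at least one surrogate marker.
#' The reserved labels `low`, `intermediate` and `very_high` are emitted only
#' on an explicit textual self-report and only in the absence of surrogate
#' markers (an explicit low-risk statement never vetoes surrogate-derived
#' high risk, since disease may progress). Otherwise `unknown`.
#'
#' @param texts All of one user's post texts.
#' @param lexicon A [risk_marker_lexicon()].
#' @return Character scalar risk label.
#' @export
classify_user_risk <- function(texts, lexicon = risk_marker_lexicon()) {
  any_marker <- FALSE
  for (t in texts) {
    if (nrow(detect_hr_markers(t, lexicon)) > 0) {
      any_marker <- TRUE
      break
    }
  }
  if (any_marker) return("high")
  lower <- tolower(paste(texts, collapse = " \n "))
  for (lbl in names(.explicit_risk_patterns)) {
    if (grepl(.explicit_risk_patterns[[lbl]], lower, perl = TRUE)) {
      return(lbl)
    }
  }
  "unknown"
}

#' Classify risk for every user in a corpus
#'
#' Runs [detect_hr_markers()] over all posts (vectorized per category) and
#' aggregates to per-user risk labels; the corpus user table's `risk` column
#' is updated.
#'
#' @param corpus A `forum_corpus` whose texts are INN-normalized.
#' @param lexicon A [risk_marker_lexicon()].
#' @return List with `corpus`, `evidence` (per-post marker tibble) and
#'   `user_risk` (per-user tibble).
#' @export
classify_corpus_risk <- function(corpus, lexicon = risk_marker_lexicon()) {
  posts <- corpus$posts
  lower <- tolower(posts$text)
  marker_any <- rep(FALSE, nrow(posts))
  ev <- list()
  for (cat in names(lexicon$categories)) {
    hit <- rep(FALSE, nrow(posts))
    for (p in lexicon$categories[[cat]]) {
      hit <- hit | stringr::str_detect(lower, stringr::regex(p))
    }
    if (any(hit)) {
      ev[[cat]] <- tibble::tibble(post_id = posts$post_id[hit],
                                  category = cat)
      marker_any <- marker_any | hit
    }
  }
  # blast rule only needs evaluating where a blast word occurs
  blast_posts <- which(stringr::str_detect(lower, "\\bblasts?\\b"))
  blast_hit <- vapply(blast_posts, function(i) {
    any(parse_blast_percentages(posts$text[i], lexicon$blast_window) >=
          lexicon$blast_threshold)
  }, logical(1))
  if (any(blast_hit)) {
    idx <- blast_posts[blast_hit]
    ev[["blast_threshold"]] <- tibble::tibble(
      post_id = posts$post_id[idx], category = "blast_threshold")
    marker_any[idx] <- TRUE
  }
  evidence <- if (length(ev) > 0) dplyr::bind_rows(ev) else
    tibble::tibble(post_id = character(0), category = character(0))

  high_users <- unique(posts$user_ref[marker_any])
  user_risk <- tibble::tibble(user_ref = unique(posts$user_ref))
  user_risk$risk <- ifelse(user_risk$user_ref %in% high_users, "high", NA)
  # explicit self-reports for the users without surrogate markers
  rest <- which(is.na(user_risk$risk))
  if (length(rest) > 0) {
    joined <- split(lower, posts$user_ref)
    for (i in rest) {
      txt <- paste(joined[[user_risk$user_ref[i]]], collapse = " \n ")
      lbl <- "unknown"
      for (cand in names(.explicit_risk_patterns)) {
        if (grepl(.explicit_risk_patterns[[cand]], txt, perl = TRUE)) {
          lbl <- cand
          break
        }
      }
      user_risk$risk[i] <- lbl
    }
  }
  if (nrow(user_risk) > 0) {
    corpus$users$risk <- as.character(user_risk$risk[
      match(corpus$users$user_ref, user_risk$user_ref)])
    corpus$users$risk[is.na(corpus$users$risk)] <- "unknown"
  }
  list(corpus = corpus, evidence = evidence, user_risk = user_risk)
}
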