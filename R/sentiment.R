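#' Default emotion cue lexicon scorer
#'
#' The bundled multilabel emotion classifier: a transparent cue-word lexicon
#' over the seven emotion classes (neutral, sadness, joy, surprise, fear,
#' disgust, anger) plus the finer labels worry and hopefulness. A class
#' scores 1 when any of its cue words occurs, else 0. The interface admits
#' any external scorer returning per-class scores, so a supervised model can
#' be plugged in without touching downstream aggregation.
#'
#' @return A function `text -> named numeric scores` over the emotion
#'   classes and finer labels.
#' @export
emotion_lexicon_scorer <- function() {
  cues <- c(.emotion_cues, .finer_cues)
  patterns <- lapply(cues, function(w) {
    paste0("\\b(", paste(stringr::str_escape(w), collapse = "|"), ")\\b")
  })
  function(text) {
    lower <- tolower(text)
    vapply(patterns, function(p) {
      as.numeric(stringr::str_detect(lower, p))
    }, numeric(length(text)))
  }
}

.emotion_classes <- c("neutral", "sadness", "joy", "surprise", "fear",
                      "disgust", "anger")

#' Classify post emotions (multilabel)
#'
#' Classes whose score reaches the cutoff are set; `neutral` is set iff no
#' other class fires. Finer labels (worry, hopefulness) are reported
#' alongside and never suppress `neutral`.
#'
#' @param texts Character vector of post texts.
#' @param post_id Matching ids.
#' @param scorer Pluggable scorer from [emotion_lexicon_scorer()] (default)
#'   or any function returning per-class scores.
#' @param cutoff Score cutoff for a class to fire (default 0.5).
#' @return Tibble (`post_id`, `labels` list-column of emotion classes,
#'   `finer` list-column).
#' @export
classify_emotions <- function(texts, post_id = seq_along(texts),
                              scorer = emotion_lexicon_scorer(),
                              cutoff = 0.5) {
  scores <- scorer(texts)
  if (is.null(dim(scores))) scores <- matrix(scores, nrow = 1,
                                             dimnames = list(NULL,
                                                             names(scores)))
  main <- intersect(colnames(scores), setdiff(.emotion_classes, "neutral"))
  finer_cols <- intersect(colnames(scores), names(.finer_cues))
  labels <- lapply(seq_along(texts), function(i) {
    fired <- main[scores[i, main] >= cutoff]
    if (length(fired) == 0) "neutral" else fired
  })
  finer <- lapply(seq_along(texts), function(i) {
    finer_cols[scores[i, finer_cols] >= cutoff]
  })
  tibble::tibble(post_id = post_id, labels = labels, finer = finer)
}

#' Default sub-sentiment map for the high-risk cohort
#'
#' The high-risk discussion buckets (concern, anxiety, frustration, fear,
#' confusion, information-seeking) with their bucket cue words and the theme
#' topics attributable to each bucket. In the default map every attribution
#' topic belongs to exactly one bucket.
#'
#' @return List of class `sub_sentiment_map`: per-bucket `cues` and
#'   `topics`.
#' @export
sub_sentiment_map <- function() {
  map <- list(
    concern = list(
      cues = .bucket_cues$concern,
      topics = c("blood counts", "disease burden", "quality of life",
                 "treatment options", "disease progression")),
    anxiety = list(
      cues = .bucket_cues$anxiety,
      topics = c("health and disease", "treatment", "diagnostic process")),
    frustration = list(
      cues = .bucket_cues$frustration,
      topics = c("treatment modalities", "hematological management",
                 "navigating the health care system",
                 "knowledge constraints")),
    fear = list(
      cues = .bucket_cues$fear,
      topics = c("complications", "disease exacerbation")),
    confusion = list(
      cues = .bucket_cues$confusion,
      topics = c("disease understanding")),
    information_seeking = list(
      cues = .bucket_cues$information_seeking,
      topics = c("therapeutic intervention", "ongoing research"))
  )
  topics <- unlist(lapply(map, `[[`, "topics"))
  if (anyDuplicated(topics) > 0) {
    abort("sub-sentiment attribution topics must belong to exactly one bucket")
  }
  structure(map, class = "sub_sentiment_map")
}

#' Map posts to sub-sentiment buckets with topic attribution
#'
#' A bucket fires when one of its cue phrases occurs in the post; the fired
#' bucket carries the subset of its attribution topics present in the post's
#' theme assignment (possibly empty). Posts may hit several buckets;
#' unlabeled posts hit none.
#'
#' @param texts Post texts.
#' @param post_id Matching ids.
#' @param theme_nodes List-column (or list) of theme nodes assigned to each
#'   post.
#' @param map A [sub_sentiment_map()].
#' @return Tibble (`post_id`, `bucket`, `topics` list-column).
#' @export
map_subsentiments <- function(texts, post_id = seq_along(texts),
                              theme_nodes = vector("list", length(texts)),
                              map = sub_sentiment_map()) {
  if (!inherits(map, "sub_sentiment_map")) {
    abort("map must be a sub_sentiment_map")
  }
  lower <- tolower(texts)
  rows <- list()
  for (b in names(map)) {
    pat <- paste0("\\b(",
                  paste(stringr::str_escape(map[[b]]$cues), collapse = "|"),
                  ")\\b")
    hit <- which(stringr::str_detect(lower, pat))
    if (length(hit) == 0) next
    rows[[b]] <- tibble::tibble(
      post_id = post_id[hit], bucket = b,
      topics = lapply(hit, function(i) {
        intersect(map[[b]]$topics, theme_nodes[[i]] %||% character(0))
      })
    )
  }
  if (length(rows) == 0) {
    return(tibble::tibble(post_id = post_id[0], bucket = character(0),
                          topics = list()))
  }
  dplyr::bind_rows(rows) |> dplyr::arrange(.data$post_id, .data$bucket)
}

#' Aggregate user-level label prevalence for a cohort
#'
#' Counts, for each label, the users in the cohort carrying it (a user
#' counts once per label regardless of posting volume: the user-level label
#' is the union of their post-level labels) and reports the integer
#' percentage of the cohort denominator, rounded half away from zero. Rows
#' are sorted by count descending.
#'
#' @param user_labels Tibble with `user_ref` and `label` columns (one row
#'   per user-label pair, duplicates tolerated).
#' @param cohort Character vector of user refs defining the cohort
#'   (denominator).
#' @param cohort_name Name recorded in the output.
#' @return Tibble (`cohort`, `label`, `n`, `denominator`, `pct`).
#' @export
aggregate_prevalence <- function(user_labels, cohort,
                                 cohort_name = "cohort") {
  if (length(cohort) == 0) {
    abort("empty cohort: prevalence denominator would be zero")
  }
  denom <- length(unique(cohort))
  inside <- user_labels[user_labels$user_ref %in% cohort, , drop = FALSE]
  out <- inside |>
    dplyr::distinct(.data$user_ref, .data$label) |>
    dplyr::count(.data$label, name = "n") |>
    dplyr::arrange(dplyr::desc(.data$n), .data$label)
  out$cohort <- cohort_name
  out$denominator <- denom
  out$pct <- pct_of(out$n, denom)
  out[, c("cohort", "label", "n", "denominator", "pct")]
}
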