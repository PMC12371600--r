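#' Default role-phrase lexicon
#'
#' Key phrases labeling a post as authored by a patient (first-person
#' diagnosis phrases) or a caregiver (third-person kin + diagnosis/caregiving
#' patterns). Matching is case-insensitive and whole-phrase, and the disease
#' term `MDS` also matches spelled-out "myelodysplastic syndrome(s)".
#'
#' @return List with `patient` and `caregiver` regular-expression vectors
#'   (already disease-term expanded) and the raw phrase lists.
#' @export
role_phrase_lexicon <- function() {
  disease <- "(mds|myelodysplastic syndromes?)"
  expand <- function(phrases) {
    vapply(phrases, function(p) {
      gsub("mds", disease, stringr::str_escape(tolower(p)), fixed = TRUE)
    }, character(1), USE.NAMES = FALSE)
  }
  patient_phrases <- .patient_role_phrases
  kin <- paste0("(", paste(.kin_nouns, collapse = "|"), ")")
  caregiver_patterns <- c(
    paste0("\\b(my|our) ", kin,
           " (was diagnosed with|has|is living with|suffers from|",
           "is battling) ", disease),
    "\\bi (care|am caring|have been caring) for (my|our|him|her)\\b",
    "\\bi am (his|her|the) (main )?caregiver\\b",
    "\\bas (his|her) caregiver\\b"
  )
  if (length(intersect(tolower(patient_phrases), caregiver_patterns)) > 0) {
    abort("role phrase sets must be disjoint")
  }
  list(
    patient = paste0("\\b", expand(tolower(patient_phrases)), "\\b"),
    caregiver = caregiver_patterns,
    patient_phrases = patient_phrases
  )
}

.first_match_pos <- function(text, patterns) {
  pos <- Inf
  hits <- character(0)
  for (p in patterns) {
    m <- regexpr(p, text, perl = TRUE)
    if (m > 0) {
      hits <- c(hits, substring(text, m, m + attr(m, "match.length") - 1L))
      pos <- min(pos, as.integer(m))
    }
  }
  list(pos = pos, evidence = hits)
}

#' Label a single post as patient or caregiver
#'
#' A lexicon phrase match wins with confidence 1.0; if both phrase sets
#' match, the earlier match position decides. With no phrase match the post
#' is delegated to the optional fallback classifier (a function of the text
#' returning `list(label=, confidence=)`), else labeled `none`.
#'
#' @param text Post text (scalar).
#' @param lexicon A [role_phrase_lexicon()].
#' @param fallback Optional pluggable classifier function.
#' @return Tibble row: `label` (patient/caregiver/none), `confidence`,
#'   `evidence` (matched phrases, collapsed).
#' @export
label_post_role <- function(text, lexicon = role_phrase_lexicon(),
                            fallback = NULL) {
  lower <- tolower(text)
  pat <- .first_match_pos(lower, lexicon$patient)
  care <- .first_match_pos(lower, lexicon$caregiver)
  if (is.finite(pat$pos) || is.finite(care$pos)) {
    label <- if (pat$pos <= care$pos) "patient" else "caregiver"
    evidence <- if (label == "patient") pat$evidence else care$evidence
    return(tibble::tibble(label = label, confidence = 1,
                          evidence = paste(evidence, collapse = "; ")))
  }
  if (!is.null(fallback)) {
    res <- fallback(text)
    if (!is.null(res$label) && res$label %in% c("patient", "caregiver")) {
      return(tibble::tibble(label = res$label,
                            confidence = as.numeric(res$confidence),
                            evidence = "fallback classifier"))
    }
  }
  tibble::tibble(label = "none", confidence = 0, evidence = "")
}

#' Classify a user from their ordered post labels
#'
#' Implements the 80% majority rule with chronological fallback: posts with a
#' non-`none` label form the denominator; if one role accounts for at least
#' `majority_threshold` of them the user takes that role (`rule_used =
#' "majority_80"`). Otherwise labeled posts are scanned in chronological
#' order and the first label with confidence at or above
#' `confidence_threshold` decides (`"chronological"`). An empty or exhausted
#' scan yields `unknown`.
#'
#' @param labels Tibble of per-post labels (`label`, `confidence`), sorted by
#'   post timestamp ascending.
#' @param majority_threshold Majority share required (default 0.8,
#'   inclusive).
#' @param confidence_threshold Minimum confidence for the chronological rule
#'   (default 0.9).
#' @return One-row tibble: `role`, `rule_used`, `majority_share`.
#' @export
classify_user <- function(labels, majority_threshold = 0.8,
                          confidence_threshold = 0.9) {
  labeled <- labels[labels$label %in% c("patient", "caregiver"), ,
                    drop = FALSE]
  if (nrow(labeled) == 0) {
    return(tibble::tibble(role = "unknown", rule_used = "none",
                          majority_share = NA_real_))
  }
  counts <- table(factor(labeled$label, c("patient", "caregiver")))
  share <- max(counts) / nrow(labeled)
  if (share >= majority_threshold) {
    return(tibble::tibble(role = names(counts)[which.max(counts)],
                          rule_used = "majority_80",
                          majority_share = share))
  }
  for (i in seq_len(nrow(labeled))) {
    if (labeled$confidence[i] >= confidence_threshold) {
      return(tibble::tibble(role = labeled$label[i],
                            rule_used = "chronological",
                            majority_share = share))
    }
  }
  tibble::tibble(role = "unknown", rule_used = "none",
                 majority_share = share)
}

#' Classify every user in a corpus
#'
#' Labels each post with [label_post_role()] and aggregates per user with
#' [classify_user()]; the corpus user table's `role` column is updated.
#'
#' @param corpus A `forum_corpus`.
#' @inheritParams label_post_role
#' @inheritParams classify_user
#' @return List with `corpus` (roles filled in), `post_labels` (per-post
#'   tibble) and `decisions` (per-user tibble with `rule_used`, etc.).
#' @export
classify_corpus_roles <- function(corpus, lexicon = role_phrase_lexicon(),
                                  fallback = NULL,
                                  majority_threshold = 0.8,
                                  confidence_threshold = 0.9) {
  posts <- corpus$posts
  lower <- tolower(posts$text)

  # Vectorized phrase matching: earliest match position per role set.
  pos_for <- function(patterns) {
    pos <- rep(Inf, length(lower))
    for (p in patterns) {
      m <- regexpr(p, lower, perl = TRUE)
      hit <- m > 0
      pos[hit] <- pmin(pos[hit], as.integer(m[hit]))
    }
    pos
  }
  p_pos <- pos_for(lexicon$patient)
  c_pos <- pos_for(lexicon$caregiver)
  label <- rep("none", length(lower))
  confidence <- rep(0, length(lower))
  hit <- is.finite(p_pos) | is.finite(c_pos)
  label[hit] <- ifelse(p_pos[hit] <= c_pos[hit], "patient", "caregiver")
  confidence[hit] <- 1
  if (!is.null(fallback) && any(!hit)) {
    for (i in which(!hit)) {
      res <- fallback(posts$text[i])
      if (!is.null(res$label) && res$label %in% c("patient", "caregiver")) {
        label[i] <- res$label
        confidence[i] <- as.numeric(res$confidence)
      }
    }
  }
  post_labels <- tibble::tibble(
    post_id = posts$post_id, user_ref = posts$user_ref,
    timestamp = posts$timestamp, label = label, confidence = confidence
  )

  decisions <- post_labels |>
    dplyr::arrange(.data$timestamp, .data$post_id) |>
    dplyr::group_by(.data$user_ref) |>
    dplyr::group_modify(function(df, key) {
      classify_user(df, majority_threshold, confidence_threshold)
    }) |>
    dplyr::ungroup()

  if (nrow(decisions) > 0) {
    corpus$users$role <- decisions$role[
      match(corpus$users$user_ref, decisions$user_ref)]
    corpus$users$role[is.na(corpus$users$role)] <- "unknown"
  }
  list(corpus = corpus, post_labels = post_labels, decisions = decisions)
}

#' Train the reference fallback role classifier
#'
#' A transparent term-frequency nearest-centroid scorer: token frequency
#' profiles are averaged per role over a labeled training set (typically
#' synthetic posts with ground-truth roles), and a new post is scored by
#' cosine similarity to each centroid. Confidence is the normalized margin
#' between the two similarities.
#'
#' @param texts Training post texts.
#' @param roles Matching role labels (`patient`/`caregiver`).
#' @return A function `(text) -> list(label, confidence)` usable as the
#'   `fallback` argument of [label_post_role()].
#' @export
train_role_fallback <- function(texts, roles) {
  stopifnot(length(texts) == length(roles),
            all(roles %in% c("patient", "caregiver")))
  toks <- tokenize_words(texts)
  vocab <- sort(unique(unlist(toks)))
  profile <- function(which_role) {
    tt <- table(factor(unlist(toks[roles == which_role]), vocab))
    v <- as.numeric(tt)
    v / max(1, sqrt(sum(v^2)))
  }
  cp <- profile("patient")
  cc <- profile("caregiver")
  function(text) {
    tv <- table(factor(unlist(tokenize_words(text)), vocab))
    v <- as.numeric(tv)
    nrm <- sqrt(sum(v^2))
    if (nrm == 0) return(list(label = "none", confidence = 0))
    v <- v / nrm
    sp <- sum(v * cp)
    sc <- sum(v * cc)
    if (sp == sc) return(list(label = "none", confidence = 0))
    list(label = if (sp > sc) "patient" else "caregiver",
         confidence = abs(sp - sc) / max(sp, sc))
  }
}
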