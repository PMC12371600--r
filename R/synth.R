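#' Configuration for the synthetic forum-corpus generator
#'
#' Defaults emulate the population structure of the public MDS forums the
#' pipeline targets: roughly half patients and two-fifths caregivers, about a
#' third of users in the high-risk cohort, ~1% superusers with heavy-tailed
#' post counts, timestamps spanning 2008--2022, and per-post injection rates
#' for PII, misspellings, duplicates, and clinical-trial mentions.
#'
#' @param n_users Number of users to generate.
#' @param role_mix Named probabilities over `patient`, `caregiver`, `other`;
#'   must sum to 1.
#' @param hr_fraction Probability a patient/caregiver user is high-risk.
#' @param low_risk_fraction Probability a non-high-risk patient/caregiver user
#'   explicitly self-reports low-risk disease.
#' @param superuser_fraction Probability a user is a heavy-tail poster.
#' @param posts_per_user List of negative-binomial parameters for regular
#'   (`regular_mu`, `regular_size`) and superuser (`superuser_min`,
#'   `superuser_mu`, `superuser_size`) post counts.
#' @param date_range Inclusive Date interval posts fall in.
#' @param pii_rate,misspell_rate,duplicate_rate,trial_mention_rate Per-post
#'   injection probabilities.
#' @param emotion_mix Named probabilities over the 7 emotion classes.
#' @param bucket_rate Probability a high-risk user's post carries a
#'   sub-sentiment bucket cue.
#' @param finer_rate Probability a post carries a worry/hopefulness cue.
#' @param seed Integer seed; the full generation is deterministic given it.
#' @return A validated list of class `synth_config`.
#' @export
synth_config <- function(n_users = 2000,
                         role_mix = c(patient = 0.49, caregiver = 0.42,
                                      other = 0.09),
                         hr_fraction = 0.36,
                         low_risk_fraction = 0.08,
                         superuser_fraction = 0.01,
                         posts_per_user = list(regular_mu = 7,
                                               regular_size = 1.2,
                                               superuser_min = 100,
                                               superuser_mu = 250,
                                               superuser_size = 2),
                         date_range = as.Date(c("2008-01-01", "2022-12-31")),
                         pii_rate = 0.05,
                         misspell_rate = 0.10,
                         duplicate_rate = 0.02,
                         trial_mention_rate = 0.01,
                         emotion_mix = c(neutral = 0.37, sadness = 0.22,
                                         joy = 0.20, surprise = 0.13,
                                         fear = 0.04, disgust = 0.02,
                                         anger = 0.02),
                         bucket_rate = 0.5,
                         finer_rate = 0.10,
                         seed = 20080801L) {
  cfg <- list(
    n_users = n_users, role_mix = role_mix, hr_fraction = hr_fraction,
    low_risk_fraction = low_risk_fraction,
    superuser_fraction = superuser_fraction,
    posts_per_user = posts_per_user, date_range = as.Date(date_range),
    pii_rate = pii_rate, misspell_rate = misspell_rate,
    duplicate_rate = duplicate_rate,
    trial_mention_rate = trial_mention_rate, emotion_mix = emotion_mix,
    bucket_rate = bucket_rate, finer_rate = finer_rate,
    seed = as.integer(seed)
  )
  validate_synth_config(cfg)
  structure(cfg, class = "synth_config")
}

#' @rdname synth_config
#' @param config A configuration list to validate.
#' @export
validate_synth_config <- function(config) {
  problems <- character(0)
  chk_prob <- function(field) {
    v <- config[[field]]
    if (!is.numeric(v) || any(v < 0) || any(v > 1)) {
      problems <<- c(problems, paste0(field, ": must be a probability in [0,1]"))
    }
  }
  if (!is.numeric(config$n_users) || config$n_users < 0) {
    problems <- c(problems, "n_users: must be a non-negative count")
  }
  for (f in c("hr_fraction", "low_risk_fraction", "superuser_fraction",
              "pii_rate", "misspell_rate", "duplicate_rate",
              "trial_mention_rate", "bucket_rate", "finer_rate")) {
    chk_prob(f)
  }
  if (!setequal(names(config$role_mix), c("patient", "caregiver", "other")) ||
      abs(sum(config$role_mix) - 1) > 1e-9) {
    problems <- c(problems,
                  "role_mix: must cover patient/caregiver/other and sum to 1")
  }
  if (abs(sum(config$emotion_mix) - 1) > 1e-9 ||
      !"neutral" %in% names(config$emotion_mix)) {
    problems <- c(problems,
                  "emotion_mix: must include neutral and sum to 1")
  }
  if (length(config$date_range) != 2 ||
      config$date_range[1] > config$date_range[2]) {
    problems <- c(problems, "date_range: must be an ordered Date interval")
  }
  if (length(problems) > 0) {
    abort(paste0("invalid synth_config:\n  ",
                 paste(problems, collapse = "\n  ")))
  }
  invisible(config)
}

#' Render one post from a template
#'
#' Deterministically composes a post text from a marker set and a
#' template-specific filler sentence: every requested marker appears verbatim
#' exactly once, and the filler is drawn reproducibly from `rng_state`.
#'
#' @param template_id Template name (currently `"generic"`).
#' @param markers Character vector of marker phrases/sentences to embed.
#' @param rng_state Integer driving the filler draw.
#' @return A single text string.
#' @export
render_post <- function(template_id = "generic", markers = character(0),
                        rng_state = 1L) {
  pools <- list(generic = .filler_sentences)
  if (!template_id %in% names(pools)) {
    abort(paste0("unknown template: ", template_id))
  }
  filler <- withr::with_seed(rng_state,
                             sample(pools[[template_id]], 1))
  paste(c(markers, filler), collapse = " ")
}

.synth_sources <- c("mds_foundation_forum", "marrowforums",
                    "mds_patient_support")

.empty_ground_truth <- function() {
  structure(list(
    users = tibble::tibble(user_ref = character(0), role = character(0),
                           risk = character(0), superuser = logical(0)),
    posts = tibble::tibble(post_id = character(0), user_ref = character(0),
                           emotions = list(), finer = list(),
                           buckets = list(), themes = list(),
                           risk_markers = list(),
                           trial_mention = logical(0),
                           misspelled = logical(0),
                           duplicate_of = character(0)),
    pii = tibble::tibble(post_id = character(0), start = integer(0),
                         end = integer(0), surface = character(0),
                         category = character(0))
  ), class = "synth_ground_truth")
}

#' Generate a synthetic forum corpus with ground truth
#'
#' Produces a [new_corpus()] whose posts are template-assembled sentences
#' carrying exactly known labels: every patient (caregiver) post contains a
#' first-person (third-person kin) role marker, every high-risk user carries
#' at least one treatment-surrogate marker across their posts, and emotion
#' cues, PII spans, misspellings, duplicates and trial mentions are injected
#' at the configured per-post rates. Deterministic for a fixed seed.
#'
#' @param config A [synth_config()].
#' @return List with elements `corpus` (a `forum_corpus`) and `ground_truth`
#'   (tables `users`, `posts`, `pii`).
#' @export
generate_corpus <- function(config = synth_config()) {
  validate_synth_config(config)
  withr::with_seed(config$seed, .generate_impl(config))
}

.generate_impl <- function(config) {
  n <- as.integer(config$n_users)
  if (n == 0) {
    empty <- tibble::tibble(
      post_id = character(0), thread_id = character(0),
      user_ref = character(0), timestamp = as.Date(character(0)),
      source = character(0), url = character(0), text = character(0),
      reply_to = character(0)
    )
    return(list(corpus = new_corpus(empty, study_window = config$date_range),
                ground_truth = .empty_ground_truth()))
  }

  stems <- c("bluejay", "mapleleaf", "riverstone", "quietowl", "sunfield",
             "graywolf", "meadowlark", "pinecrest", "foxglove", "harborlight")
  user_ref <- paste0(sample(stems, n, replace = TRUE), seq_len(n))
  role <- sample(names(config$role_mix), n, replace = TRUE,
                 prob = config$role_mix)
  clinical_user <- role %in% c("patient", "caregiver")
  risk <- rep("unknown", n)
  hr <- clinical_user & runif(n) < config$hr_fraction
  risk[hr] <- "high"
  low <- clinical_user & !hr & runif(n) < config$low_risk_fraction
  risk[low] <- "low"
  superuser <- runif(n) < config$superuser_fraction
  source <- sample(.synth_sources, n, replace = TRUE,
                   prob = c(0.20, 0.60, 0.20))

  pp <- config$posts_per_user
  n_posts <- ifelse(
    superuser,
    pp$superuser_min + stats::rnbinom(n, size = pp$superuser_size,
                                      mu = pp$superuser_mu),
    1L + stats::rnbinom(n, size = pp$regular_size, mu = pp$regular_mu)
  )

  range_days <- as.integer(config$date_range[2] - config$date_range[1])
  span <- ifelse(superuser,
                 runif(n, 500, min(3000, range_days)),
                 pmin(stats::rlnorm(n, log(10), 1.3), range_days))
  first_day <- floor(runif(n, 0, pmax(1, range_days - span)))

  # Thread pools per source, sized to ~7.5 posts per thread.
  posts_by_source <- tapply(n_posts, source, sum)
  thread_pool <- lapply(.synth_sources, function(s) {
    np <- posts_by_source[s]
    if (is.na(np)) np <- 0
    k <- max(1L, ceiling(np / 7.5))
    sprintf("t_%s_%04d", abbreviate(s, 6), seq_len(k))
  })
  names(thread_pool) <- .synth_sources

  kin_map <- sample(.kin_nouns, n, replace = TRUE)

  total <- sum(n_posts)
  post_user <- rep(seq_len(n), n_posts)
  ts_list <- lapply(seq_len(n), function(i) {
    config$date_range[1] +
      sort(floor(runif(n_posts[i], first_day[i],
                       pmin(first_day[i] + span[i] + 1, range_days + 1))))
  })
  timestamp <- as.Date(unlist(lapply(ts_list, as.character)))
  thread_id <- vapply(post_user, function(i) {
    pool <- thread_pool[[source[i]]]
    pool[sample.int(length(pool), 1)]
  }, character(1))
  post_id <- sprintf("p%06d", seq_len(total))

  # Pick marker posts for high-risk users: each post w.p. 0.25, at least one.
  marker_flag <- logical(total)
  for (i in which(hr)) {
    idx <- which(post_user == i)
    f <- runif(length(idx)) < 0.25
    if (!any(f)) f[sample.int(length(idx), 1)] <- TRUE
    marker_flag[idx] <- f
  }
  low_flag <- logical(total)
  for (i in which(low)) {
    idx <- which(post_user == i)
    low_flag[idx[sample.int(length(idx), 1)]] <- TRUE
  }
  # trial-mention posts are dropped by the anonymizer, so they must never be
  # the carrier of a planted risk marker or self-report
  trial_block <- marker_flag | low_flag

  emo_classes <- names(config$emotion_mix)
  cat_names <- names(.theme_sentences)
  bucket_names <- names(.bucket_cues)

  text <- character(total)
  gt_emotions <- vector("list", total)
  gt_finer <- vector("list", total)
  gt_buckets <- vector("list", total)
  gt_themes <- vector("list", total)
  gt_markers <- vector("list", total)
  trial_mention <- runif(total) < config$trial_mention_rate & !trial_block
  misspelled <- logical(total)
  pii_rows <- vector("list", total)

  cue_sentence <- function(word) {
    tpl <- sample(.cue_sentence_templates, 1)
    sub("WORD", word, tpl, fixed = TRUE)
  }

  for (p in seq_len(total)) {
    u <- post_user[p]
    sentences <- character(0)

    # role marker
    if (role[u] == "patient") {
      phrase <- sample(.patient_role_phrases, 1)
      if (runif(1) < 0.2) {
        phrase <- sub("MDS", "myelodysplastic syndrome", phrase, fixed = TRUE)
      }
      tpl <- sample(.role_sentence_templates$patient, 1)
      sentences <- c(sentences, sub("PHRASE", phrase, tpl, fixed = TRUE))
    } else if (role[u] == "caregiver") {
      tpl <- sample(.role_sentence_templates$caregiver, 1)
      sentences <- c(sentences, sub("KIN", kin_map[u], tpl, fixed = TRUE))
    } else {
      sentences <- c(sentences, sample(.role_sentence_templates$other, 1))
    }

    # themes
    k_cat <- if (runif(1) < 0.7) 1L else 2L
    cats <- sample(cat_names, k_cat)
    for (cc in cats) {
      sentences <- c(sentences, sample(.theme_sentences[[cc]], 1))
    }
    gt_themes[[p]] <- cats

    # emotions
    first <- sample(emo_classes, 1, prob = config$emotion_mix)
    if (first == "neutral") {
      emos <- "neutral"
    } else if (runif(1) < 0.15) {
      other_cls <- setdiff(emo_classes, c("neutral", first))
      emos <- c(first, sample(other_cls, 1))
    } else {
      emos <- first
    }
    for (e in setdiff(emos, "neutral")) {
      sentences <- c(sentences, cue_sentence(sample(.emotion_cues[[e]], 1)))
    }
    gt_emotions[[p]] <- emos

    # finer labels
    if (runif(1) < config$finer_rate) {
      fl <- sample(names(.finer_cues), 1)
      sentences <- c(sentences, cue_sentence(sample(.finer_cues[[fl]], 1)))
      gt_finer[[p]] <- fl
    } else gt_finer[[p]] <- character(0)

    # sub-sentiment buckets (high-risk users only)
    if (risk[u] == "high" && runif(1) < config$bucket_rate) {
      b <- sample(bucket_names, 1)
      if (b == "information_seeking") {
        sentences <- c(sentences, sample(.info_seeking_sentences, 1))
      } else {
        sentences <- c(sentences, cue_sentence(sample(.bucket_cues[[b]], 1)))
      }
      gt_buckets[[p]] <- b
    } else gt_buckets[[p]] <- character(0)

    # risk markers
    if (marker_flag[p]) {
      cat_r <- sample(names(.risk_sentences), 1)
      s <- sample(.risk_sentences[[cat_r]], 1)
      if (cat_r == "blast_threshold") {
        s <- sub("BLAST", sample(20:35, 1), s, fixed = TRUE)
      }
      sentences <- c(sentences, s)
      gt_markers[[p]] <- cat_r
    } else if (low_flag[p]) {
      sentences <- c(sentences, .low_risk_sentence)
      gt_markers[[p]] <- character(0)
    } else {
      if (clinical_user[u] && runif(1) < 0.02) {
        sentences <- c(sentences,
                       sub("BLAST", sample(3:19, 1), .low_blast_sentence,
                           fixed = TRUE))
      }
      gt_markers[[p]] <- character(0)
    }

    if (trial_mention[p]) sentences <- c(sentences, .trial_sentence)

    # filler
    sentences <- c(sentences, sample(.filler_sentences, 1))

    txt <- paste(sentences, collapse = " ")

    # PII injection with exact character spans
    if (runif(1) < config$pii_rate) {
      categ <- sample(names(.pii_templates), 1)
      tpl <- .pii_templates[[categ]]
      given <- sample(.synth_given_names, 1)
      surname <- sample(.synth_surnames, 1)
      local <- paste0(paste(sample(LETTERS, 2), collapse = ""),
                      sample(100:999, 1))
      phone <- sprintf("555-%04d", sample(100:9999, 1))
      sent <- tpl
      sent <- sub("GIVEN", given, sent, fixed = TRUE)
      sent <- sub("SURNAME", surname, sent, fixed = TRUE)
      sent <- sub("LOCAL", local, sent, fixed = TRUE)
      sent <- sub("PHONE", phone, sent, fixed = TRUE)
      surface <- switch(categ,
        NAME = paste(given, surname),
        EMAIL = paste0(local, "@example.com"),
        PHONE = phone,
        PROVIDER_NAME = surname,
        URL = paste0("http://blog.example.com/", local),
        MANUFACTURER = "Celgene"
      )
      offset <- nchar(txt) + 1L # the " " separator
      start <- offset + 1L + as.integer(regexpr(surface, sent, fixed = TRUE)) - 1L
      txt <- paste(txt, sent)
      pii_rows[[p]] <- tibble::tibble(
        post_id = post_id[p], start = start,
        end = start + nchar(surface) - 1L,
        surface = surface, category = categ
      )
    }

    # length-preserving misspelling outside any PII span
    if (runif(1) < config$misspell_rate) {
      for (w in sample(names(.misspell_map))) {
        m <- regexpr(paste0("\\b", w, "\\b"), txt)
        if (m > 0) {
          pii_start <- if (is.null(pii_rows[[p]])) Inf else pii_rows[[p]]$start
          if (m + attr(m, "match.length") <= pii_start) {
            substr(txt, m, m + nchar(w) - 1L) <- .misspell_map[[w]]
            misspelled[p] <- TRUE
          }
          break
        }
      }
    }
    text[p] <- txt
  }

  # duplicates: re-post of an earlier post by the same user, later timestamp
  dup_src <- which(runif(total) < config$duplicate_rate)
  dup_rows <- NULL
  if (length(dup_src) > 0) {
    dup_id <- sprintf("d%06d", seq_along(dup_src))
    dup_ts <- pmin(timestamp[dup_src] + sample(1:30, length(dup_src),
                                               replace = TRUE),
                   config$date_range[2])
    dup_rows <- tibble::tibble(
      post_id = dup_id, thread_id = thread_id[dup_src],
      user_ref = user_ref[post_user[dup_src]], timestamp = dup_ts,
      source = source[post_user[dup_src]], url = NA_character_,
      text = text[dup_src], reply_to = NA_character_
    )
  }

  posts <- tibble::tibble(
    post_id = post_id, thread_id = thread_id,
    user_ref = user_ref[post_user], timestamp = timestamp,
    source = source[post_user], url = NA_character_, text = text,
    reply_to = NA_character_
  )
  if (!is.null(dup_rows)) posts <- dplyr::bind_rows(posts, dup_rows)

  users <- tibble::tibble(
    user_ref = user_ref,
    join_date = config$date_range[1] + first_day -
      sample(0:30, n, replace = TRUE),
    location = sample(c("US", "UK", "Canada"), n, replace = TRUE,
                      prob = c(0.6, 0.25, 0.15)),
    role = "unknown", risk = "unknown"
  )

  corpus <- new_corpus(posts, users = users,
                       study_window = config$date_range)
  corpus <- log_event(corpus, "synth: posts generated", nrow(posts))

  gt_posts <- tibble::tibble(
    post_id = post_id, user_ref = user_ref[post_user],
    emotions = gt_emotions, finer = gt_finer, buckets = gt_buckets,
    themes = gt_themes, risk_markers = gt_markers,
    trial_mention = trial_mention, misspelled = misspelled,
    duplicate_of = NA_character_
  )
  if (length(dup_src) > 0) {
    dup_gt <- gt_posts[dup_src, , drop = FALSE]
    dup_gt$post_id <- dup_rows$post_id
    dup_gt$duplicate_of <- post_id[dup_src]
    gt_posts <- dplyr::bind_rows(gt_posts, dup_gt)
  }
  pii <- dplyr::bind_rows(pii_rows[!vapply(pii_rows, is.null, logical(1))])
  if (length(dup_src) > 0 && nrow(pii) > 0) {
    dup_pii <- pii[pii$post_id %in% post_id[dup_src], , drop = FALSE]
    if (nrow(dup_pii) > 0) {
      dup_pii$post_id <- dup_rows$post_id[match(dup_pii$post_id,
                                                post_id[dup_src])]
      pii <- dplyr::bind_rows(pii, dup_pii)
    }
  }
  if (nrow(pii) == 0) pii <- .empty_ground_truth()$pii

  ground_truth <- structure(list(
    users = tibble::tibble(user_ref = user_ref, role = role, risk = risk,
                           superuser = superuser),
    posts = gt_posts,
    pii = pii
  ), class = "synth_ground_truth")

  list(corpus = corpus, ground_truth = ground_truth)
}

#' Write ground-truth tables as a sidecar
#'
#' Serializes the ground truth emitted by [generate_corpus()] to three
#' delimited tables (`users.csv`, `posts.csv` with list columns collapsed by
#' `;`, and `pii.csv`) next to a generated corpus.
#'
#' @param ground_truth A `synth_ground_truth` object.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_ground_truth <- function(ground_truth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  collapse <- function(col) vapply(col, paste, character(1), collapse = ";")
  posts <- ground_truth$posts
  posts$emotions <- collapse(posts$emotions)
  posts$finer <- collapse(posts$finer)
  posts$buckets <- collapse(posts$buckets)
  posts$themes <- collapse(posts$themes)
  posts$risk_markers <- collapse(posts$risk_markers)
  readr::write_csv(ground_truth$users, file.path(dir, "users.csv"),
                   progress = FALSE)
  readr::write_csv(posts, file.path(dir, "posts.csv"), progress = FALSE)
  readr::write_csv(ground_truth$pii, file.path(dir, "pii.csv"),
                   progress = FALSE)
  invisible(dir)
}
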