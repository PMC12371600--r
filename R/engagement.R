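#' Per-user engagement profiles
#'
#' Computes each user's first/last post dates, active span in days, and post
#' count, with a summary (min, median, max span) over users with at least
#' one post. The retention fraction (users with active span of at most 2
#' days) is reported alongside.
#'
#' @param corpus A `forum_corpus`.
#' @return List with `profiles` (tibble `user_ref`, `first_post`,
#'   `last_post`, `active_span_days`, `post_count`, `is_superuser`,
#'   `weight`) and `summary` (min/median/max span, retention fraction).
#' @export
engagement_metrics <- function(corpus) {
  if (nrow(corpus$posts) == 0) {
    return(list(
      profiles = tibble::tibble(
        user_ref = character(0), first_post = as.Date(character(0)),
        last_post = as.Date(character(0)), post_count = integer(0),
        active_span_days = integer(0), is_superuser = logical(0),
        weight = numeric(0)),
      summary = tibble::tibble(min_span = NA_integer_,
                               median_span = NA_real_,
                               max_span = NA_integer_,
                               retention_2d = NA_real_)))
  }
  profiles <- corpus$posts |>
    dplyr::group_by(.data$user_ref) |>
    dplyr::summarise(
      first_post = min(.data$timestamp),
      last_post = max(.data$timestamp),
      post_count = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      active_span_days = as.integer(.data$last_post - .data$first_post),
      is_superuser = FALSE,
      weight = 1
    )
  summary <- if (nrow(profiles) == 0) {
    tibble::tibble(min_span = NA_integer_, median_span = NA_real_,
                   max_span = NA_integer_, retention_2d = NA_real_)
  } else {
    tibble::tibble(
      min_span = min(profiles$active_span_days),
      median_span = median(profiles$active_span_days),
      max_span = max(profiles$active_span_days),
      retention_2d = mean(profiles$active_span_days <= 2)
    )
  }
  list(profiles = profiles, summary = summary)
}

#' Flag superusers
#'
#' Flags the top `ceiling(fraction * N)` users by post count; ties at the
#' cut are included in full.
#'
#' @param profiles Profile tibble from [engagement_metrics()].
#' @param fraction Fraction of users to flag (default 0.01).
#' @return The profile tibble with `is_superuser` set.
#' @export
detect_superusers <- function(profiles, fraction = 0.01) {
  stopifnot(fraction > 0, fraction < 1)
  n <- nrow(profiles)
  if (n == 0) return(profiles)
  k <- ceiling(fraction * n)
  cut_count <- sort(profiles$post_count, decreasing = TRUE)[k]
  profiles$is_superuser <- profiles$post_count >= cut_count
  profiles
}

#' Cap superuser influence per discussion
#'
#' For prevalence and sentiment aggregation, a superuser contributes at most
#' `cap` posts per discussion (thread): their earliest `cap` posts in each
#' thread keep weight 1, the rest get weight 0. Non-superusers are
#' untouched. Capping can only reduce aggregate counts.
#'
#' @param posts Post table (needs `post_id`, `user_ref`, `thread_id`,
#'   `timestamp`).
#' @param profiles Profile tibble with `is_superuser` flags.
#' @param cap Maximum posts per superuser per discussion (default 1).
#' @return Tibble (`post_id`, `weight`).
#' @export
normalize_superuser_influence <- function(posts, profiles, cap = 1L) {
  stopifnot(cap >= 1)
  super <- profiles$user_ref[profiles$is_superuser]
  weights <- posts |>
    dplyr::arrange(.data$timestamp, .data$post_id) |>
    dplyr::group_by(.data$user_ref, .data$thread_id) |>
    dplyr::mutate(.rank = dplyr::row_number()) |>
    dplyr::ungroup() |>
    dplyr::mutate(weight = ifelse(
      .data$user_ref %in% super & .data$.rank > cap, 0, 1))
  weights[match(posts$post_id, weights$post_id), c("post_id", "weight")]
}

#' Thematic saturation analysis
#'
#' Processes posts in chronological order in batches, tracking the first
#' batch in which each significant theme appears. A theme is significant
#' when it reaches major status (prevalence at or above the threshold) on
#' the full corpus. The saturation index is the smallest batch `b` such
#' that no significant theme first appears in batches `(b, b + lookahead]`;
#' `NA` when new themes keep arriving to the end.
#'
#' @param posts Post table sorted however; sorted internally by timestamp.
#' @param assignments Theme assignment tibble (`post_id`, `node`).
#' @param discussion_map `post_id` -> `thread_id` map.
#' @param batch_size Posts per batch.
#' @param lookahead Batches that must stay quiet after `b` (default 3).
#' @param threshold Prevalence threshold defining significance; defaults to
#'   5% of discussions.
#' @return List of class `saturation_curve`: `curve` (tibble `batch`,
#'   `cumulative_themes`), `saturation_index`, `significant_themes`.
#' @export
saturation_analysis <- function(posts, assignments, discussion_map,
                                batch_size = 100L, lookahead = 3L,
                                threshold = NULL) {
  stopifnot(batch_size >= 1)
  n_disc <- length(unique(discussion_map$thread_id))
  if (is.null(threshold)) threshold <- max(1, ceiling(0.05 * n_disc))
  prev <- score_prevalence(assignments, discussion_map)
  significant <- prev$node[prev$prevalence >= threshold]

  ord <- order(posts$timestamp, posts$post_id)
  post_seq <- posts$post_id[ord]
  n_batches <- max(1L, ceiling(length(post_seq) / batch_size))
  batch_of_post <- setNames(
    rep(seq_len(n_batches), each = batch_size)[seq_along(post_seq)],
    post_seq)

  sig_assign <- assignments[assignments$node %in% significant, ,
                            drop = FALSE]
  first_batch <- tapply(
    batch_of_post[sig_assign$post_id], sig_assign$node, min)

  cumulative <- vapply(seq_len(n_batches), function(b) {
    sum(first_batch <= b)
  }, numeric(1))
  curve <- tibble::tibble(batch = seq_len(n_batches),
                          cumulative_themes = as.integer(cumulative))

  # A saturation point needs an observable quiet window after it, so the
  # final batch can never qualify (a schedule that keeps introducing themes
  # to the end yields NA). A single-batch corpus saturates trivially.
  sat <- NA_integer_
  if (n_batches == 1L) {
    if (length(first_batch) > 0) sat <- 1L
  } else {
    for (b in seq_len(n_batches - 1L)) {
      upper <- min(n_batches, b + lookahead)
      if (!any(first_batch > b & first_batch <= upper)) {
        sat <- b
        break
      }
    }
  }
  structure(list(curve = curve, saturation_index = sat,
                 significant_themes = sort(names(first_batch)),
                 threshold = threshold),
            class = "saturation_curve")
}

#' Split posts into pre/post-COVID periods
#'
#' The matched pre-COVID period covers January 2018 through February 2020;
#' everything from March 2020 onward is post-COVID; earlier posts land in
#' the excluded bucket. The three buckets partition the corpus.
#'
#' @param posts Post table with a `timestamp` column.
#' @return List with `pre`, `post`, `excluded` post tables and `counts`.
#' @export
covid_split <- function(posts) {
  pre_lo <- as.Date("2018-01-01")
  pre_hi <- as.Date("2020-02-29")
  post_lo <- as.Date("2020-03-01")
  pre <- posts[posts$timestamp >= pre_lo & posts$timestamp <= pre_hi, ,
               drop = FALSE]
  post <- posts[posts$timestamp >= post_lo, , drop = FALSE]
  excluded <- posts[posts$timestamp < pre_lo, , drop = FALSE]
  list(pre = pre, post = post, excluded = excluded,
       counts = tibble::tibble(period = c("pre", "post", "excluded"),
                               n = c(nrow(pre), nrow(post),
                                     nrow(excluded))))
}
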