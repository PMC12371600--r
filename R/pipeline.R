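#' Pipeline configuration
#'
#' Houses every tunable constant of the analysis in one validated object:
#' the study window, the role majority threshold (0.8), the blast-count
#' threshold (20%), the major-theme prevalence threshold (fraction of
#' discussions), the emotion cutoff, superuser fraction and per-discussion
#' cap, and the saturation batch parameters.
#'
#' @param study_window Inclusive Date interval.
#' @param role_majority Majority share for user role assignment
#'   (default 0.8).
#' @param role_confidence Chronological-fallback confidence threshold.
#' @param blast_threshold Blast percentage threshold (default 20).
#' @param blast_window Token window for blast parsing.
#' @param prevalence_threshold_frac Major-theme threshold as a fraction of
#'   discussions (default 0.05).
#' @param emotion_cutoff Score cutoff for emotion classes.
#' @param superuser_fraction Fraction of users flagged as superusers.
#' @param superuser_cap Posts a superuser may contribute per discussion.
#' @param saturation_batch_size,saturation_lookahead Saturation parameters.
#' @param salt Username tokenization salt (never logged).
#' @param seed Integer seed for any stochastic stage.
#' @param out_dir Optional output directory for [export_summary()].
#' @return Validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(study_window = as.Date(c("2008-01-01",
                                                     "2022-12-31")),
                            role_majority = 0.8,
                            role_confidence = 0.9,
                            blast_threshold = 20,
                            blast_window = 6L,
                            prevalence_threshold_frac = 0.05,
                            emotion_cutoff = 0.5,
                            superuser_fraction = 0.01,
                            superuser_cap = 1L,
                            saturation_batch_size = 100L,
                            saturation_lookahead = 3L,
                            salt = "mdslisten",
                            seed = 1L,
                            out_dir = NULL) {
  cfg <- list(
    study_window = as.Date(study_window), role_majority = role_majority,
    role_confidence = role_confidence, blast_threshold = blast_threshold,
    blast_window = as.integer(blast_window),
    prevalence_threshold_frac = prevalence_threshold_frac,
    emotion_cutoff = emotion_cutoff,
    superuser_fraction = superuser_fraction,
    superuser_cap = as.integer(superuser_cap),
    saturation_batch_size = as.integer(saturation_batch_size),
    saturation_lookahead = as.integer(saturation_lookahead),
    salt = salt, seed = as.integer(seed), out_dir = out_dir
  )
  problems <- character(0)
  in01 <- function(f) {
    if (!is.numeric(cfg[[f]]) || cfg[[f]] < 0 || cfg[[f]] > 1) {
      problems <<- c(problems, paste0(f, ": must be in [0,1]"))
    }
  }
  for (f in c("role_majority", "role_confidence",
              "prevalence_threshold_frac", "emotion_cutoff",
              "superuser_fraction")) in01(f)
  if (cfg$blast_threshold <= 0 || cfg$blast_threshold > 100) {
    problems <- c(problems, "blast_threshold: must lie in (0,100]")
  }
  if (cfg$superuser_cap < 1) {
    problems <- c(problems, "superuser_cap: must be >= 1")
  }
  if (cfg$saturation_batch_size < 1) {
    problems <- c(problems, "saturation_batch_size: must be >= 1")
  }
  if (length(cfg$study_window) != 2 ||
      cfg$study_window[1] > cfg$study_window[2]) {
    problems <- c(problems, "study_window: must be an ordered interval")
  }
  if (length(problems) > 0) {
    abort(paste0("invalid pipeline_config:\n  ",
                 paste(problems, collapse = "\n  ")))
  }
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose keys match [pipeline_config()] arguments.
#' @return A validated `pipeline_config`.
#' @export
load_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$study_window)) raw$study_window <- as.Date(unlist(raw$study_window))
  do.call(pipeline_config, raw)
}

.stage_row <- function(stage, n_in, n_out) {
  tibble::tibble(stage = stage, n_in = as.integer(n_in),
                 n_out = as.integer(n_out),
                 n_removed = as.integer(n_in - n_out))
}

#' Run the full listening pipeline
#'
#' Stage order: load -> clean/dedup/exclude -> anonymize -> role -> risk ->
#' themes -> sentiment -> engagement/saturation/temporal -> report. Fully
#' deterministic for a fixed config and seed. Artifacts are written to
#' `config$out_dir` when set.
#'
#' @param corpus A `forum_corpus`, or a path loadable by [load_corpus()].
#' @param config A [pipeline_config()].
#' @param format Passed to [load_corpus()] when `corpus` is a path.
#' @return A `run_report` list: stage counts, per-source corpus summary,
#'   cohort sizes, sentiment and theme prevalence tables, theme network,
#'   saturation and engagement summaries, COVID split counts.
#' @export
run_pipeline <- function(corpus, config = pipeline_config(),
                         format = "jsonl") {
  if (is.character(corpus)) {
    corpus <- load_corpus(corpus, format = format,
                          study_window = config$study_window)
  }
  stages <- list()

  # clean / dedup / exclude
  n0 <- nrow(corpus$posts)
  corpus <- clean_corpus(corpus)
  corpus <- deduplicate(corpus)
  corpus <- apply_exclusion_filters(
    corpus, exclusion_rules(window = config$study_window))
  stages[[1]] <- .stage_row("clean_dedup_exclude", n0, nrow(corpus$posts))

  # anonymize
  n1 <- nrow(corpus$posts)
  anon <- anonymize_corpus(corpus, salt = config$salt)
  corpus <- anon$corpus
  stages[[2]] <- .stage_row("anonymize", n1, nrow(corpus$posts))

  # roles
  roles <- classify_corpus_roles(
    corpus, majority_threshold = config$role_majority,
    confidence_threshold = config$role_confidence)
  corpus <- roles$corpus
  stages[[3]] <- .stage_row("role", nrow(corpus$posts), nrow(corpus$posts))

  # risk
  risk <- classify_corpus_risk(
    corpus, risk_marker_lexicon(config$blast_threshold,
                                config$blast_window))
  corpus <- risk$corpus
  stages[[4]] <- .stage_row("risk", nrow(corpus$posts), nrow(corpus$posts))

  posts <- corpus$posts
  discussion_map <- posts[, c("post_id", "thread_id")]
  n_disc <- length(unique(discussion_map$thread_id))

  # engagement first so superuser weights can cap theme prevalence
  eng <- engagement_metrics(corpus)
  profiles <- detect_superusers(eng$profiles, config$superuser_fraction)
  weights <- normalize_superuser_influence(posts, profiles,
                                           config$superuser_cap)
  capped_ids <- weights$post_id[weights$weight > 0]

  # themes
  hierarchy <- theme_hierarchy()
  assignments <- assign_categories(posts$text, posts$post_id, hierarchy)
  capped_assignments <- assignments[assignments$post_id %in% capped_ids, ,
                                    drop = FALSE]
  prevalence_threshold <- max(1, ceiling(
    config$prevalence_threshold_frac * n_disc))
  theme_prevalence <- categorize_theme(
    score_prevalence(capped_assignments, discussion_map),
    prevalence_threshold, hierarchy)
  network <- build_theme_network(capped_assignments, discussion_map)
  stages[[5]] <- .stage_row("themes", nrow(posts), nrow(posts))

  # sentiment
  emotions <- classify_emotions(posts$text, posts$post_id,
                                cutoff = config$emotion_cutoff)
  theme_nodes <- split(assignments$node, assignments$post_id)
  buckets <- map_subsentiments(
    posts$text, posts$post_id,
    theme_nodes = theme_nodes[as.character(posts$post_id)] |>
      lapply(function(x) x %||% character(0)))
  stages[[6]] <- .stage_row("sentiment", nrow(posts), nrow(posts))

  # cohorts and prevalence tables
  users <- corpus$users
  hr_users <- users$user_ref[users$risk == "high"]
  hr_patients <- users$user_ref[users$risk == "high" &
                                  users$role == "patient"]
  hr_caregivers <- users$user_ref[users$risk == "high" &
                                    users$role == "caregiver"]
  cohort_sizes <- tibble::tibble(
    cohort = c("hr_users", "hr_patients", "hr_caregivers"),
    n = c(length(hr_users), length(hr_patients), length(hr_caregivers))
  )

  bucket_user_labels <- dplyr::distinct(
    dplyr::inner_join(buckets, posts[, c("post_id", "user_ref")],
                      by = "post_id")[, c("user_ref", "bucket")] |>
      dplyr::rename(label = "bucket"))
  emo_long <- tidyr::unnest(emotions[, c("post_id", "labels")],
                            cols = "labels")
  emotion_user_labels <- dplyr::distinct(
    dplyr::inner_join(emo_long, posts[, c("post_id", "user_ref")],
                      by = "post_id")[, c("user_ref", "labels")] |>
      dplyr::rename(label = "labels"))

  prev_tbl <- function(labels, cohort, name) {
    if (length(cohort) == 0) {
      return(tibble::tibble(cohort = character(0), label = character(0),
                            n = integer(0), denominator = integer(0),
                            pct = integer(0)))
    }
    aggregate_prevalence(labels, cohort, name)
  }
  sentiment_tables <- dplyr::bind_rows(
    prev_tbl(bucket_user_labels, hr_users, "hr_users"),
    prev_tbl(bucket_user_labels, hr_patients, "hr_patients"),
    prev_tbl(bucket_user_labels, hr_caregivers, "hr_caregivers")
  )
  emotion_tables <- prev_tbl(emotion_user_labels, users$user_ref,
                             "all_users")

  # saturation / temporal
  saturation <- saturation_analysis(
    posts, assignments, discussion_map,
    batch_size = config$saturation_batch_size,
    lookahead = config$saturation_lookahead,
    threshold = prevalence_threshold)
  covid <- covid_split(posts)
  stages[[7]] <- .stage_row("temporal", nrow(posts), nrow(posts))

  source_summary <- posts |>
    dplyr::group_by(source = .data$source) |>
    dplyr::summarise(posts = dplyr::n(),
                     threads = dplyr::n_distinct(.data$thread_id),
                     users = dplyr::n_distinct(.data$user_ref),
                     .groups = "drop")

  report <- structure(list(
    stage_counts = dplyr::bind_rows(stages),
    source_summary = source_summary,
    cohort_sizes = cohort_sizes,
    role_decisions = roles$decisions,
    risk_users = risk$user_risk,
    theme_prevalence = theme_prevalence,
    theme_network = network,
    sentiment_prevalence = sentiment_tables,
    emotion_prevalence = emotion_tables,
    engagement_summary = dplyr::mutate(
      eng$summary, n_superusers = sum(profiles$is_superuser)),
    saturation = list(curve = saturation$curve,
                      saturation_index = saturation$saturation_index,
                      threshold = saturation$threshold),
    covid_counts = covid$counts,
    corpus = corpus
  ), class = "run_report")

  if (!is.null(config$out_dir)) export_summary(report, config$out_dir)
  report
}

#' @exportS3Method base::print
print.run_report <- function(x, ...) {
  tot <- colSums(x$source_summary[, c("posts", "threads", "users")])
  cat("<run_report>\n")
  cat(sprintf("  corpus: %d posts / %d threads / %d users\n",
              tot["posts"], tot["threads"], tot["users"]))
  cat("  cohorts:",
      paste(sprintf("%s=%d", x$cohort_sizes$cohort, x$cohort_sizes$n),
            collapse = ", "), "\n")
  cat("  saturation index:", x$saturation$saturation_index, "\n")
  invisible(x)
}

#' Export run-report tables to disk
#'
#' Writes the per-source volume table (with a Total row equal to the column
#' sums), the cohort-stratified sentiment and emotion prevalence tables,
#' theme prevalence, the co-mention edge list (CSV + GraphML), the
#' saturation curve, COVID split counts, stage counts, and a single JSON
#' run report.
#'
#' @param report A `run_report` from [run_pipeline()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
export_summary <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  src <- summarise_sources(report$source_summary)
  readr::write_csv(src, file.path(dir, "source_summary.csv"),
                   progress = FALSE)
  readr::write_csv(report$sentiment_prevalence,
                   file.path(dir, "sentiment_prevalence.csv"),
                   progress = FALSE)
  readr::write_csv(report$emotion_prevalence,
                   file.path(dir, "emotion_prevalence.csv"),
                   progress = FALSE)
  readr::write_csv(report$theme_prevalence,
                   file.path(dir, "theme_prevalence.csv"), progress = FALSE)
  write_theme_network(report$theme_network,
                      file.path(dir, "theme_network.csv"),
                      file.path(dir, "theme_network.graphml"))
  readr::write_csv(report$saturation$curve,
                   file.path(dir, "saturation_curve.csv"), progress = FALSE)
  readr::write_csv(report$covid_counts,
                   file.path(dir, "covid_split.csv"), progress = FALSE)
  readr::write_csv(report$stage_counts,
                   file.path(dir, "stage_counts.csv"), progress = FALSE)
  json <- report[setdiff(names(report), "corpus")]
  jsonlite::write_json(json, file.path(dir, "run_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(dir)
}

#' Per-source volume summary with a Total row
#'
#' @param source_summary Tibble (`source`, `posts`, `threads`, `users`).
#' @return The same tibble with a `Total` row appended whose entries equal
#'   the column sums.
#' @export
summarise_sources <- function(source_summary) {
  totals <- tibble::tibble(
    source = "Total",
    posts = sum(source_summary$posts),
    threads = sum(source_summary$threads),
    users = sum(source_summary$users)
  )
  dplyr::bind_rows(source_summary, totals)
}
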