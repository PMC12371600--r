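#' Forum corpus container
#'
#' A `forum_corpus` bundles the three record tables of a scraped (or synthetic)
#' forum dataset — posts, threads, users — together with the study window and a
#' provenance log. Referential integrity is enforced at construction: every
#' post must reference an existing thread and user (missing ones are created
#' as stubs), and each thread's `n_posts` is recomputed from the post table.
#'
#' @param posts Tibble with columns `post_id`, `thread_id`, `user_ref`,
#'   `timestamp` (Date), `source`, `url`, `text`, `reply_to`.
#' @param threads Optional tibble (`thread_id`, `title`, `source`, `n_posts`,
#'   `n_views`); derived from `posts` when absent.
#' @param users Optional tibble (`user_ref`, `join_date`, `location`, `role`,
#'   `risk`); derived from `posts` when absent. Role and risk default to
#'   `"unknown"` before classification.
#' @param study_window Length-2 Date vector (inclusive interval).
#' @param provenance List with at least a `log` tibble (`event`, `n`).
#' @return An object of class `forum_corpus`.
#' @export
new_corpus <- function(posts,
                       threads = NULL,
                       users = NULL,
                       study_window = as.Date(c("2008-01-01", "2022-12-31")),
                       provenance = list()) {
  required <- c("post_id", "thread_id", "user_ref", "timestamp", "source", "text")
  missing_cols <- setdiff(required, names(posts))
  if (length(missing_cols) > 0) {
    abort(paste0("posts table lacks required columns: ",
                 paste(missing_cols, collapse = ", ")))
  }
  posts <- tibble::as_tibble(posts)
  if (!"url" %in% names(posts)) posts$url <- NA_character_
  if (!"reply_to" %in% names(posts)) posts$reply_to <- NA_character_
  posts$timestamp <- parse_post_date(posts$timestamp)
  if (anyNA(posts$timestamp)) abort("posts contain unparseable timestamps")
  if (anyDuplicated(posts$post_id) > 0) abort("post_id values are not unique")

  if (is.null(threads)) {
    threads <- posts |>
      dplyr::group_by(.data$thread_id) |>
      dplyr::summarise(
        title = paste("Thread", dplyr::first(.data$thread_id)),
        source = dplyr::first(.data$source),
        n_posts = dplyr::n(),
        n_views = NA_integer_,
        .groups = "drop"
      )
  } else {
    threads <- tibble::as_tibble(threads)
    stub <- setdiff(unique(posts$thread_id), threads$thread_id)
    if (length(stub) > 0) {
      threads <- dplyr::bind_rows(threads, tibble::tibble(
        thread_id = stub, title = paste("Thread", stub),
        source = NA_character_, n_posts = 0L, n_views = NA_integer_
      ))
    }
    counts <- table(posts$thread_id)
    threads$n_posts <- as.integer(counts[threads$thread_id])
    threads$n_posts[is.na(threads$n_posts)] <- 0L
  }

  if (is.null(users)) {
    users <- tibble::tibble(
      user_ref = unique(posts$user_ref),
      join_date = as.Date(NA), location = NA_character_,
      role = "unknown", risk = "unknown"
    )
  } else {
    users <- tibble::as_tibble(users)
    if (!"role" %in% names(users)) users$role <- "unknown"
    if (!"risk" %in% names(users)) users$risk <- "unknown"
    stub <- setdiff(unique(posts$user_ref), users$user_ref)
    if (length(stub) > 0) {
      users <- dplyr::bind_rows(users, tibble::tibble(
        user_ref = stub, join_date = as.Date(NA), location = NA_character_,
        role = "unknown", risk = "unknown"
      ))
    }
  }

  if (is.null(provenance$log)) {
    provenance$log <- tibble::tibble(event = character(0), n = integer(0))
  }
  provenance$sources <- sort(unique(posts$source))

  structure(
    list(posts = posts, threads = threads, users = users,
         study_window = as.Date(study_window), provenance = provenance),
    class = "forum_corpus"
  )
}

#' @exportS3Method base::print
print.forum_corpus <- function(x, ...) {
  cat("<forum_corpus> ", nrow(x$posts), " posts, ", nrow(x$threads),
      " threads, ", nrow(x$users), " users\n", sep = "")
  cat("  window: ", format(x$study_window[1]), " .. ",
      format(x$study_window[2]), "\n", sep = "")
  cat("  sources: ", paste(x$provenance$sources, collapse = ", "), "\n", sep = "")
  invisible(x)
}

log_event <- function(corpus, event, n) {
  corpus$provenance$log <- dplyr::bind_rows(
    corpus$provenance$log,
    tibble::tibble(event = event, n = as.integer(n))
  )
  corpus
}

.required_post_fields <- c("post_id", "thread_id", "user_ref", "timestamp",
                           "source", "text")

#' Load a forum corpus from disk
#'
#' Reads one post per record from a line-delimited JSON file (one object per
#' line) or a comma-separated table with a header row. Records missing a
#' required field or carrying an unparseable timestamp are skipped and counted
#' in the provenance log; if more than half the records are malformed the load
#' aborts with a diagnostic.
#'
#' @param path Path to the posts file.
#' @param format `"jsonl"` or `"csv"`.
#' @param threads,users Optional paths to companion thread/user tables (same
#'   format family: JSONL for `"jsonl"`, CSV for `"csv"`). Derived from the
#'   posts when absent.
#' @param study_window Inclusive Date interval stored on the corpus.
#' @return A [new_corpus()] object.
#' @export
load_corpus <- function(path, format = c("jsonl", "csv"),
                        threads = NULL, users = NULL,
                        study_window = as.Date(c("2008-01-01", "2022-12-31"))) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(paste0("corpus file not found: ", path))

  read_table <- function(p) {
    if (format == "jsonl") {
      lines <- readLines(p, warn = FALSE, encoding = "UTF-8")
      lines <- lines[nzchar(trimws(lines))]
      if (length(lines) == 0) return(tibble::tibble())
      rows <- lapply(lines, function(l) {
        tryCatch(jsonlite::fromJSON(l), error = function(e) NULL)
      })
      bad <- vapply(rows, is.null, logical(1))
      out <- dplyr::bind_rows(lapply(rows[!bad], function(r) {
        tibble::as_tibble(lapply(r, function(v) if (is.null(v)) NA else v))
      }))
      attr(out, "n_unparseable") <- sum(bad)
      out
    } else {
      readr::read_csv(p, show_col_types = FALSE, progress = FALSE,
                      col_types = readr::cols(.default = readr::col_character()))
    }
  }

  raw <- read_table(path)
  n_unparseable <- attr(raw, "n_unparseable") %||% 0L
  if (nrow(raw) == 0 && n_unparseable == 0) {
    empty <- tibble::tibble(
      post_id = character(0), thread_id = character(0),
      user_ref = character(0), timestamp = as.Date(character(0)),
      source = character(0), url = character(0), text = character(0),
      reply_to = character(0)
    )
    corp <- new_corpus(empty, study_window = study_window)
    return(log_event(corp, "load: records read", 0L))
  }

  for (f in .required_post_fields) {
    if (!f %in% names(raw)) raw[[f]] <- NA_character_
  }
  ts <- parse_post_date(raw$timestamp)
  field_ok <- !Reduce(`|`, lapply(
    .required_post_fields[.required_post_fields != "timestamp"],
    function(f) is.na(raw[[f]]) | raw[[f]] == ""
  ))
  ok <- field_ok & !is.na(ts) & !duplicated(raw$post_id)
  n_total <- nrow(raw) + n_unparseable
  n_bad <- sum(!ok) + n_unparseable
  if (n_total > 0 && n_bad > n_total / 2) {
    abort(sprintf(
      "more than half of the records are malformed (%d of %d): wrong format or schema?",
      n_bad, n_total))
  }
  posts <- raw[ok, , drop = FALSE]
  posts$timestamp <- ts[ok]

  thr <- if (!is.null(threads) && file.exists(threads)) read_table(threads) else NULL
  usr <- if (!is.null(users) && file.exists(users)) read_table(users) else NULL
  if (!is.null(thr) && nrow(thr) > 0) {
    thr$n_posts <- suppressWarnings(as.integer(thr$n_posts))
    thr$n_views <- suppressWarnings(as.integer(thr$n_views %||% NA))
  } else thr <- NULL
  if (!is.null(usr) && nrow(usr) > 0) {
    usr$join_date <- parse_post_date(usr$join_date %||% NA)
  } else usr <- NULL

  corp <- new_corpus(posts, threads = thr, users = usr,
                     study_window = study_window)
  corp <- log_event(corp, "load: records read", n_total)
  log_event(corp, "load: malformed records skipped", n_bad)
}

#' Write a forum corpus to disk
#'
#' Inverse of [load_corpus()]; `load -> write -> load` round-trips well-formed
#' corpora exactly. Dates are serialized as ISO `YYYY-MM-DD` strings.
#'
#' @param corpus A `forum_corpus`.
#' @param path Output path for the posts file.
#' @param format `"jsonl"` or `"csv"`.
#' @param threads,users Optional output paths for the companion tables.
#' @return `path`, invisibly.
#' @export
write_corpus <- function(corpus, path, format = c("jsonl", "csv"),
                         threads = NULL, users = NULL) {
  format <- match.arg(format)
  write_table <- function(df, p) {
    df <- dplyr::mutate(df, dplyr::across(
      dplyr::where(function(x) inherits(x, "Date")),
      function(x) format(x, "%Y-%m-%d")))
    if (format == "jsonl") {
      lines <- vapply(seq_len(nrow(df)), function(i) {
        as.character(jsonlite::toJSON(as.list(df[i, , drop = FALSE]),
                                      auto_unbox = TRUE, na = "null"))
      }, character(1))
      writeLines(lines, p, useBytes = TRUE)
    } else {
      readr::write_csv(df, p, progress = FALSE)
    }
  }
  write_table(corpus$posts, path)
  if (!is.null(threads)) write_table(corpus$threads, threads)
  if (!is.null(users)) write_table(corpus$users, users)
  invisible(path)
}

#' Remove duplicate posts
#'
#' Two posts are duplicates when they share the same user and the same text
#' after whitespace and case normalization (cross-posting by one user is the
#' dominant duplication mode on forums). The earliest-timestamped copy is
#' retained; ties break on post id order. Idempotent.
#'
#' @param corpus A `forum_corpus`.
#' @return The corpus with duplicates removed and the removal count logged.
#' @export
deduplicate <- function(corpus) {
  posts <- corpus$posts
  if (nrow(posts) == 0) return(log_event(corpus, "dedup: duplicates removed", 0L))
  key <- paste(posts$user_ref,
               stringr::str_squish(tolower(posts$text)), sep = "\r")
  ord <- order(posts$timestamp, posts$post_id)
  keep_ids <- posts$post_id[ord][!duplicated(key[ord])]
  n_removed <- nrow(posts) - length(keep_ids)
  corpus$posts <- posts[posts$post_id %in% keep_ids, , drop = FALSE]
  corpus <- .sync_corpus(corpus)
  log_event(corpus, "dedup: duplicates removed", n_removed)
}

# Recompute thread post counts and drop orphan thread/user rows after filtering.
.sync_corpus <- function(corpus) {
  counts <- table(corpus$posts$thread_id)
  corpus$threads <- corpus$threads[corpus$threads$thread_id %in% names(counts), ,
                                   drop = FALSE]
  corpus$threads$n_posts <- as.integer(counts[corpus$threads$thread_id])
  corpus$users <- corpus$users[corpus$users$user_ref %in% corpus$posts$user_ref, ,
                               drop = FALSE]
  corpus$provenance$sources <- sort(unique(corpus$posts$source))
  corpus
}

#' Spell-correct a text against a dictionary
#'
#' Out-of-dictionary tokens are replaced by their single best in-dictionary
#' correction at edit distance at most `max_dist` (default 1); ties break by
#' dictionary frequency, then lexicographically. Tokens with no candidate are
#' left untouched, as are all in-dictionary tokens. Capitalized and
#' non-alphabetic tokens are never corrected (names, ids, numbers).
#'
#' @param text Character vector.
#' @param dictionary Tibble with columns `word`, `freq` (see
#'   [default_dictionary()]) or a plain character vector.
#' @param max_dist Maximum edit distance for a correction (default 1).
#' @return List with `text` (corrected) and `log` (tibble `token`,
#'   `replacement`, `n`).
#' @export
correct_spelling <- function(text, dictionary = default_dictionary(),
                             max_dist = 1L) {
  if (is.character(dictionary)) {
    dictionary <- tibble::tibble(word = dictionary, freq = 1L)
  }
  stopifnot(nrow(dictionary) > 0)
  words <- dictionary$word
  tokens <- stringr::str_extract_all(text, "[A-Za-z']+")
  flat <- unique(unlist(tokens))
  flat <- flat[grepl("^[a-z']+$", flat)]
  ood <- setdiff(flat, words)
  if (length(ood) == 0) {
    return(list(text = text,
                log = tibble::tibble(token = character(0),
                                     replacement = character(0),
                                     n = integer(0))))
  }
  d <- adist(ood, words)
  # Adjacent transpositions ("recieve" -> "receive") count as one edit even
  # though plain Levenshtein scores them 2.
  transposed <- function(tok) {
    n <- nchar(tok)
    if (n < 2) return(character(0))
    unique(vapply(seq_len(n - 1), function(j) {
      paste0(substr(tok, 1, j - 1), substr(tok, j + 1, j + 1),
             substr(tok, j, j), substr(tok, j + 2, n))
    }, character(1)))
  }
  repl <- vapply(seq_along(ood), function(i) {
    di <- d[i, ]
    hit <- match(transposed(ood[i]), words)
    di[hit[!is.na(hit)]] <- pmin(di[hit[!is.na(hit)]], 1L)
    cand <- which(di <= max_dist)
    if (length(cand) == 0) return(NA_character_)
    cand <- cand[order(di[cand], -dictionary$freq[cand], words[cand])]
    words[cand[1]]
  }, character(1))
  names(repl) <- ood
  repl <- repl[!is.na(repl)]
  if (length(repl) == 0) {
    return(list(text = text,
                log = tibble::tibble(token = character(0),
                                     replacement = character(0),
                                     n = integer(0))))
  }
  pat <- stringr::str_c("\\b(", paste(names(repl), collapse = "|"), ")\\b")
  counts <- integer(length(repl))
  names(counts) <- names(repl)
  for (tok in names(repl)) {
    counts[tok] <- sum(stringr::str_count(text, stringr::str_c("\\b", tok, "\\b")))
  }
  fixed <- stringr::str_replace_all(text, pat, function(m) repl[m])
  list(
    text = fixed,
    log = tibble::tibble(token = names(repl), replacement = unname(repl),
                         n = unname(counts))[counts > 0, , drop = FALSE]
  )
}

#' Clean a single post
#'
#' Validates the text as well-formed UTF-8 (posts failing validation are
#' flagged for exclusion) and applies [correct_spelling()]. The correction log
#' is attached as the `"corrections"` attribute and the exclusion flag as
#' `"exclude"`.
#'
#' @param post One-row tibble from a corpus post table.
#' @param dictionary See [correct_spelling()].
#' @param max_dist Maximum edit distance for corrections.
#' @return The post row, possibly with corrected text.
#' @export
clean_text <- function(post, dictionary = default_dictionary(), max_dist = 1L) {
  stopifnot(nrow(post) == 1)
  if (!validUTF8(post$text)) {
    attr(post, "exclude") <- TRUE
    attr(post, "corrections") <- tibble::tibble(
      token = character(0), replacement = character(0), n = integer(0))
    return(post)
  }
  fixed <- correct_spelling(post$text, dictionary, max_dist)
  post$text <- fixed$text
  attr(post, "exclude") <- FALSE
  attr(post, "corrections") <- fixed$log
  post
}

#' Clean every post in a corpus
#'
#' Applies UTF-8 validation (invalid posts are excluded and counted) and spell
#' autocorrection to the whole post table in one pass.
#'
#' @inheritParams deduplicate
#' @inheritParams correct_spelling
#' @return The cleaned corpus; counts appear in the provenance log.
#' @export
clean_corpus <- function(corpus, dictionary = default_dictionary(),
                         max_dist = 1L) {
  posts <- corpus$posts
  if (nrow(posts) == 0) return(log_event(corpus, "clean: invalid encoding excluded", 0L))
  valid <- validUTF8(posts$text)
  n_invalid <- sum(!valid)
  posts <- posts[valid, , drop = FALSE]
  fixed <- correct_spelling(posts$text, dictionary, max_dist)
  posts$text <- fixed$text
  corpus$posts <- posts
  corpus <- .sync_corpus(corpus)
  corpus <- log_event(corpus, "clean: invalid encoding excluded", n_invalid)
  log_event(corpus, "clean: tokens autocorrected", sum(fixed$log$n))
}

#' Default exclusion rules
#'
#' Textual cues marking posts with no personal patient/caregiver experience:
#' news and research articles, drug-approval announcements, and promotional
#' content. The study window filter is inclusive of both endpoints.
#'
#' @param window Inclusive Date interval.
#' @param cue_phrases Character vector of case-insensitive cue phrases.
#' @return A list understood by [apply_exclusion_filters()].
#' @export
exclusion_rules <- function(window = as.Date(c("2008-01-01", "2022-12-31")),
                            cue_phrases = c(
                              "press release", "news article",
                              "fda approves", "fda approval",
                              "drug approval", "approval announced",
                              "researchers report", "study published",
                              "journal article", "sponsored content",
                              "subscribe to our newsletter"
                            )) {
  list(window = as.Date(window), cue_phrases = cue_phrases)
}

#' Apply exclusion filters to a corpus
#'
#' Removes posts outside the study window (inclusive of both endpoints) and
#' posts matching any of the configured no-personal-experience cue phrases.
#' Per-rule removal counts are recorded in the provenance log.
#'
#' @param corpus A `forum_corpus`.
#' @param rules A list from [exclusion_rules()].
#' @return The filtered corpus with `study_window` set from the rules.
#' @export
apply_exclusion_filters <- function(corpus, rules = exclusion_rules()) {
  posts <- corpus$posts
  in_window <- posts$timestamp >= rules$window[1] &
    posts$timestamp <= rules$window[2]
  n_window <- sum(!in_window)
  posts <- posts[in_window, , drop = FALSE]
  cue_hit <- rep(FALSE, nrow(posts))
  if (length(rules$cue_phrases) > 0 && nrow(posts) > 0) {
    pat <- paste(stringr::str_escape(rules$cue_phrases), collapse = "|")
    cue_hit <- stringr::str_detect(tolower(posts$text), pat)
  }
  n_cue <- sum(cue_hit)
  corpus$posts <- posts[!cue_hit, , drop = FALSE]
  corpus$study_window <- rules$window
  corpus <- .sync_corpus(corpus)
  corpus <- log_event(corpus, "exclude: outside study window", n_window)
  log_event(corpus, "exclude: no-experience cue matched", n_cue)
}
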