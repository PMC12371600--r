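#' Default brand-to-INN map
#'
#' The bundled mapping from drug brand names to their International
#' Nonproprietary Names. Keys are matched case-insensitively as whole words;
#' INN values are lowercase, and no INN is itself a key, which makes
#' [map_brand_to_inn()] idempotent.
#'
#' @param extra Optional named character vector of additional brand -> INN
#'   entries.
#' @return Named character vector (brand -> INN).
#' @export
default_brand_map <- function(extra = NULL) {
  map <- c(
    Venclexta = "venetoclax",
    Tibsovo   = "ivosidenib",
    Xospata   = "gilteritinib",
    Velcade   = "bortezomib",
    Daurismo  = "glasdegib",
    Idhifa    = "enasidenib",
    Mylotarg  = "gemtuzumab ozogamicin",
    Clolar    = "clofarabine"
  )
  if (!is.null(extra)) map <- c(map, extra)
  if (anyDuplicated(tolower(names(map))) > 0) {
    abort("brand map keys must be unique case-insensitively")
  }
  setNames(tolower(map), names(map))
}

#' Default PII lexicon
#'
#' Name lists, provider titles, product manufacturers, and the institution
#' allowlist driving [scrub_pii()]. The name lists are a bundled artifact
#' choice (no named-entity model is used); the institution allowlist is
#' retained verbatim in scrubbed text.
#'
#' @return List with `given_names`, `surnames`, `provider_titles`,
#'   `manufacturers`, `institutions`.
#' @export
default_pii_lexicon <- function() {
  lex <- list(
    given_names = .synth_given_names,
    surnames = .synth_surnames,
    provider_titles = c("Dr", "Doctor", "Prof", "Professor", "Nurse"),
    manufacturers = c("Celgene", "Novartis", "Pfizer", "Genentech",
                      "Bristol Myers Squibb", "Jazz Pharmaceuticals",
                      "AbbVie"),
    institutions = c("NCI", "National Cancer Institute", "Dana Farber",
                     "Dana-Farber", "Mayo Clinic", "MD Anderson",
                     "Memorial Sloan Kettering", "Cleveland Clinic")
  )
  overlap <- intersect(c(lex$given_names, lex$surnames),
                       unlist(strsplit(lex$institutions, " ")))
  if (length(overlap) > 0) {
    abort(paste0("PII name lists overlap the institution allowlist: ",
                 paste(overlap, collapse = ", ")))
  }
  lex
}

.regex_or <- function(x) paste0(stringr::str_escape(x), collapse = "|")

# Collect candidate scrub spans (start, end, category, replacement) in text.
.pii_matches <- function(text, lexicon) {
  spans <- list()
  grab <- function(pattern, category, replacement, perl = FALSE) {
    m <- gregexpr(pattern, text, perl = perl)[[1]]
    if (m[1] == -1) return()
    len <- attr(m, "match.length")
    spans[[length(spans) + 1]] <<- tibble::tibble(
      start = as.integer(m), end = as.integer(m) + len - 1L,
      category = category, replacement = replacement
    )
  }

  # Contact details: removed outright, together with one leading space.
  grab(" ?[A-Za-z0-9._%+-]+@[A-Za-z0-9.-]+\\.[A-Za-z]{2,}", "EMAIL", "")
  grab(" ?\\bhttps?://[A-Za-z0-9./_%-]*[A-Za-z0-9/_%-]", "URL", "")
  grab(" ?\\bwww\\.[A-Za-z0-9./_%-]*[A-Za-z0-9/_%-]", "URL", "")
  grab(" ?\\b(\\(\\d{3}\\)[ -]?|\\d{3}[ .-])?\\d{3,4}[ .-]\\d{4}\\b", "PHONE", "")

  # Provider: title + capitalized name(s).
  grab(paste0("\\b(", .regex_or(lexicon$provider_titles),
              ")\\.? [A-Z][a-z]+( [A-Z][a-z]+)?"),
       "PROVIDER NAME", "PROVIDER NAME")

  if (length(lexicon$manufacturers) > 0) {
    grab(paste0("\\b(", .regex_or(lexicon$manufacturers), ")\\b"),
         "PRODUCT MANUFACTURER", "PRODUCT MANUFACTURER")
  }

  # Person names: given+surname pairs, then single given names / surnames.
  names_all <- unique(c(lexicon$given_names, lexicon$surnames))
  if (length(names_all) > 0) {
    pat1 <- paste0("\\b(", .regex_or(lexicon$given_names), ") (",
                   .regex_or(lexicon$surnames), ")\\b")
    grab(pat1, "NAME", "NAME")
    grab(paste0("\\b(", .regex_or(names_all), ")\\b"), "NAME", "NAME")
  }

  if (length(spans) == 0) {
    return(tibble::tibble(start = integer(0), end = integer(0),
                          category = character(0),
                          replacement = character(0)))
  }
  out <- dplyr::bind_rows(spans)

  # Allowlisted institutions win: drop any span overlapping one.
  if (length(lexicon$institutions) > 0) {
    m <- gregexpr(paste0("\\b(", .regex_or(lexicon$institutions), ")\\b"),
                  text)[[1]]
    if (m[1] != -1) {
      a_start <- as.integer(m)
      a_end <- a_start + attr(m, "match.length") - 1L
      keep <- vapply(seq_len(nrow(out)), function(i) {
        !any(out$start[i] <= a_end & out$end[i] >= a_start)
      }, logical(1))
      out <- out[keep, , drop = FALSE]
    }
  }

  # Resolve overlaps among the remaining spans: earlier start, then longer
  # match wins (so "Dr Alice Abbott" scrubs as one provider mention).
  out <- out[order(out$start, -(out$end - out$start)), , drop = FALSE]
  keep <- logical(nrow(out))
  last_end <- 0L
  for (i in seq_len(nrow(out))) {
    if (out$start[i] > last_end) {
      keep[i] <- TRUE
      last_end <- out$end[i]
    }
  }
  out[keep, , drop = FALSE]
}

#' Scrub personally identifying information from text
#'
#' Person names become `NAME`, title+name provider mentions become
#' `PROVIDER NAME`, manufacturer names become `PRODUCT MANUFACTURER`, and
#' email addresses, phone numbers and personal links are removed. Allowlisted
#' institutions are left untouched. The operation is idempotent: replacement
#' labels never match the lexicons.
#'
#' @param text Character scalar.
#' @param lexicon A [default_pii_lexicon()]-shaped list.
#' @return List with `text` (scrubbed) and `audit`, a tibble of
#'   (`start`, `end`, `surface`, `category`, `replacement`) spans in the
#'   original text; applying the replacements to the original reproduces the
#'   scrubbed text.
#' @export
scrub_pii <- function(text, lexicon = default_pii_lexicon()) {
  stopifnot(length(text) == 1)
  spans <- .pii_matches(text, lexicon)
  if (nrow(spans) == 0) {
    return(list(text = text,
                audit = tibble::tibble(start = integer(0), end = integer(0),
                                       surface = character(0),
                                       category = character(0),
                                       replacement = character(0))))
  }
  spans$surface <- substring(text, spans$start, spans$end)
  out <- text
  for (i in rev(seq_len(nrow(spans)))) {
    out <- paste0(substring(out, 1, spans$start[i] - 1L),
                  spans$replacement[i],
                  substring(out, spans$end[i] + 1L))
  }
  list(text = out,
       audit = spans[, c("start", "end", "surface", "category",
                         "replacement")])
}

#' Replace brand names with International Nonproprietary Names
#'
#' Every case-insensitive whole-word occurrence of a brand key is replaced by
#' its lowercase INN; all other text is untouched. Idempotent because INNs
#' are never keys.
#'
#' @param text Character vector.
#' @param map Named character vector from [default_brand_map()].
#' @return Character vector with brands normalized.
#' @export
map_brand_to_inn <- function(text, map = default_brand_map()) {
  stopifnot(length(map) > 0)
  lookup <- setNames(unname(map), tolower(names(map)))
  pat <- stringr::regex(
    paste0("\\b(", .regex_or(names(map)), ")\\b"), ignore_case = TRUE)
  stringr::str_replace_all(text, pat, function(m) lookup[tolower(m)])
}

#' Tokenize a username
#'
#' Maps a raw username to a fixed-length 12-hex-character token via a salted
#' keyed hash, so posts by one user remain linkable while the handle itself
#' is unrecoverable. Deterministic for a fixed salt; the token is re-derived
#' (with an internal counter) until it shares no 3-character substring with
#' the original handle.
#'
#' @param user_ref Non-empty username string (vectorized).
#' @param salt Secret salt string; never logged.
#' @return Character vector of 12-hex-digit tokens.
#' @export
tokenize_username <- function(user_ref, salt) {
  if (any(is.na(user_ref) | !nzchar(user_ref))) {
    abort("user_ref must be non-empty")
  }
  vapply(user_ref, function(u) {
    leak <- .substrings_k(u, 3)
    counter <- 0L
    repeat {
      tok <- .hash_token(paste0(u, "\r", counter), salt)
      if (length(leak) == 0 ||
          !any(vapply(leak, function(s) grepl(s, tok, fixed = TRUE),
                      logical(1)))) {
        return(tok)
      }
      counter <- counter + 1L
    }
  }, character(1), USE.NAMES = FALSE)
}

#' Flag clinical-trial / investigational-drug posts
#'
#' A post is dropped when it names an investigational agent or asserts trial
#' participation in the first person; passing references to trials as an
#' option ("my oncologist recommended I look at clinical trials") are kept.
#'
#' @param text Character vector of post texts.
#' @param investigational_lexicon Investigational drug names.
#' @return Tibble with `keep` (logical) and `reason` (`NA` when kept).
#' @export
filter_trial_posts <- function(text,
                               investigational_lexicon = c(
                                 "sabatolimab", "magrolimab", "tamibarotene"
                               )) {
  drug_hit <- stringr::str_detect(
    tolower(text),
    paste0("\\b(", .regex_or(tolower(investigational_lexicon)), ")\\b"))
  participation <- stringr::str_detect(
    tolower(text),
    paste0("\\bi (decided to (start|join|enroll in)|joined|started|",
           "enrolled in|signed up for|am (in|on))",
           "( a| the| this)? (clinical )?trial\\b"))
  keep <- !(drug_hit | participation)
  reason <- dplyr::case_when(
    drug_hit ~ "investigational drug mention",
    participation ~ "trial participation",
    .default = NA_character_
  )
  tibble::tibble(keep = keep, reason = reason)
}

#' De-identify a whole corpus
#'
#' Runs the full anonymization stage: drops trial/investigational posts,
#' normalizes brands to INNs, scrubs PII from every post and thread title,
#' and replaces raw usernames with salted tokens (in posts and the user
#' table). Distinct users mapping to the same token is treated as fatal.
#'
#' @param corpus A `forum_corpus`.
#' @param salt Secret salt for [tokenize_username()].
#' @param lexicon PII lexicon.
#' @param brand_map Brand -> INN map.
#' @param investigational_lexicon Passed to [filter_trial_posts()].
#' @return List with `corpus` (anonymized) and `audit` (per-post scrub spans,
#'   keyed by post id).
#' @export
anonymize_corpus <- function(corpus, salt,
                             lexicon = default_pii_lexicon(),
                             brand_map = default_brand_map(),
                             investigational_lexicon = c(
                               "sabatolimab", "magrolimab", "tamibarotene"
                             )) {
  posts <- corpus$posts
  flags <- filter_trial_posts(posts$text, investigational_lexicon)
  n_trial <- sum(!flags$keep)
  posts <- posts[flags$keep, , drop = FALSE]

  posts$text <- map_brand_to_inn(posts$text, brand_map)

  audits <- vector("list", nrow(posts))
  for (i in seq_len(nrow(posts))) {
    s <- scrub_pii(posts$text[i], lexicon)
    posts$text[i] <- s$text
    if (nrow(s$audit) > 0) {
      s$audit$post_id <- posts$post_id[i]
      audits[[i]] <- s$audit
    }
  }
  audit <- dplyr::bind_rows(audits)

  users <- corpus$users
  token <- tokenize_username(users$user_ref, salt)
  if (anyDuplicated(token) > 0) {
    abort("username tokenization produced a collision; change the salt")
  }
  map <- setNames(token, users$user_ref)
  posts$user_ref <- unname(map[posts$user_ref])
  users$user_ref <- unname(map[users$user_ref])

  threads <- corpus$threads
  threads$title <- vapply(threads$title, function(t) {
    scrub_pii(t, lexicon)$text
  }, character(1), USE.NAMES = FALSE)

  out <- new_corpus(posts, threads = threads, users = users,
                    study_window = corpus$study_window,
                    provenance = corpus$provenance)
  out <- log_event(out, "anonymize: trial/investigational posts dropped",
                   n_trial)
  out <- log_event(out, "anonymize: pii spans scrubbed",
                   nrow(audit))
  list(corpus = out, audit = audit)
}
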