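test_that("jsonl corpora load, validate, and round-trip", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "posts.jsonl")
  posts <- tiny_posts()
  write_corpus(new_corpus(posts), path, format = "jsonl")
  corp <- load_corpus(path, format = "jsonl")
  expect_equal(nrow(corp$posts), 6)
  expect_equal(sort(corp$posts$post_id), sort(posts$post_id))
  expect_equal(corp$threads$n_posts[corp$threads$thread_id == "t1"], 2L)

  # round trip is exact for well-formed corpora
  path2 <- file.path(dir, "again.jsonl")
  write_corpus(corp, path2, format = "jsonl")
  expect_identical(readLines(path), readLines(path2))

  # empty file -> empty corpus, zero counts
  empty_path <- file.path(dir, "empty.jsonl")
  writeLines(character(0), empty_path)
  empty <- load_corpus(empty_path)
  expect_equal(nrow(empty$posts), 0)
  expect_equal(nrow(empty$threads), 0)
  expect_equal(nrow(empty$users), 0)
})

test_that("malformed records are skipped and logged, excess is fatal", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "posts.jsonl")
  good <- '{"post_id":"a","thread_id":"t","user_ref":"u","timestamp":"2019-01-01","source":"f","text":"hello"}'
  no_ts <- '{"post_id":"b","thread_id":"t","user_ref":"u","source":"f","text":"no date"}'
  writeLines(c(good, no_ts), path)
  corp <- load_corpus(path)
  expect_equal(nrow(corp$posts), 1)
  skipped <- corp$provenance$log$n[
    corp$provenance$log$event == "load: malformed records skipped"]
  expect_equal(skipped, 1L)

  writeLines(c(good, no_ts, no_ts, "not json at all"), path)
  expect_error(load_corpus(path), "malformed")
  expect_error(load_corpus(file.path(dir, "missing.jsonl")), "not found")
})

test_that("csv loading matches the jsonl dialect", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "posts.csv")
  write_corpus(new_corpus(tiny_posts()), path, format = "csv")
  corp <- load_corpus(path, format = "csv")
  expect_equal(nrow(corp$posts), 6)
  expect_s3_class(corp$posts$timestamp, "Date")
})

test_that("deduplication keeps the earliest copy per (user, normalized text)", {
  posts <- tiny_posts()
  dup <- posts[1, ]
  dup$post_id <- "p7"
  dup$timestamp <- as.Date("2019-03-01")
  dup$text <- paste0("  ", toupper(posts$text[1]), " ") # normalization-equal
  corp <- new_corpus(dplyr::bind_rows(posts, dup))
  out <- deduplicate(corp)
  expect_equal(nrow(out$posts), 6)
  expect_true("p1" %in% out$posts$post_id)
  expect_false("p7" %in% out$posts$post_id)

  # same text from different users is retained
  other <- posts[1, ]
  other$post_id <- "p8"
  other$user_ref <- "zed"
  corp2 <- deduplicate(new_corpus(dplyr::bind_rows(posts, other)))
  expect_equal(nrow(corp2$posts), 7)

  # idempotent
  again <- deduplicate(out)
  expect_equal(nrow(again$posts), nrow(out$posts))
  removed <- utils::tail(again$provenance$log$n, 1)
  expect_equal(removed, 0L)
})

test_that("spell correction fixes edit-distance-1 typos and nothing else", {
  dict <- tibble::tibble(word = c("receive", "doctor", "the", "was", "kind"),
                         freq = c(1L, 1L, 10L, 10L, 1L))
  out <- correct_spelling("the docter was kind", dict)
  expect_equal(out$text, "the doctor was kind")
  expect_equal(out$log$token, "docter")

  # adjacent transposition counts as one edit
  out2 <- correct_spelling("i will recieve results", dict)
  expect_match(out2$text, "receive")

  # in-dictionary tokens and hopeless tokens are untouched
  out3 <- correct_spelling("the zzzqqq doctor", dict)
  expect_equal(out3$text, "the zzzqqq doctor")
})

test_that("clean_text flags invalid encodings and never grows token counts", {
  post <- tiny_posts()[1, ]
  cleaned <- clean_text(post)
  expect_false(attr(cleaned, "exclude"))
  expect_equal(cleaned$text, post$text)

  bad <- post
  bad$text <- rawToChar(as.raw(c(0x49, 0xFF, 0xFE)))
  flagged <- clean_text(bad)
  expect_true(attr(flagged, "exclude"))

  # property: over a generated corpus, cleaning never increases token count
  # and never alters in-dictionary tokens
  g <- synth_small()
  dict <- default_dictionary()
  idx <- seq(1, nrow(g$corpus$posts), length.out = 50)
  for (i in as.integer(idx)) {
    before <- g$corpus$posts$text[i]
    after <- correct_spelling(before, dict)$text
    expect_lte(lengths(strsplit(after, "\\s+")),
               lengths(strsplit(before, "\\s+")))
    toks_before <- unlist(stringr::str_extract_all(before, "[a-z']+"))
    toks_after <- unlist(stringr::str_extract_all(after, "[a-z']+"))
    in_dict <- toks_before %in% dict$word
    expect_identical(toks_after[in_dict], toks_before[in_dict])
  }
})

test_that("exclusion filters respect inclusive window bounds and cue phrases", {
  posts <- tiny_posts()
  posts$timestamp <- as.Date(c("2009-01-01", "2007-12-31", "2009-01-05",
                               "2010-06-01", "2012-01-01", "2012-01-02"))
  posts$text[4] <- "This news article summarizes recent MDS research."
  corp <- new_corpus(posts)
  rules <- exclusion_rules(window = as.Date(c("2009-01-01", "2012-01-01")),
                           cue_phrases = "news article")
  out <- apply_exclusion_filters(corp, rules)
  kept <- out$posts$post_id
  expect_false("p2" %in% kept) # before window
  expect_true("p1" %in% kept)  # exactly on window start (inclusive)
  expect_true("p5" %in% kept)  # exactly on window end (inclusive)
  expect_false("p6" %in% kept) # after window
  expect_false("p4" %in% kept) # cue phrase
  expect_true(all(out$posts$timestamp >= rules$window[1] &
                    out$posts$timestamp <= rules$window[2]))
  log <- out$provenance$log
  expect_equal(log$n[log$event == "exclude: outside study window"], 2L)
  expect_equal(log$n[log$event == "exclude: no-experience cue matched"], 1L)
})
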