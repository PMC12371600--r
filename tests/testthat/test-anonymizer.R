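test_that("provider titles, allowlisted institutions, and clean text behave", {
  s <- scrub_pii("Dr Smith said to wait")
  expect_equal(s$text, "PROVIDER NAME said to wait")
  expect_equal(s$audit$category, "PROVIDER NAME")

  s2 <- scrub_pii("treated at Dana Farber")
  expect_equal(s2$text, "treated at Dana Farber")

  s3 <- scrub_pii("feeling tired after the visit")
  expect_equal(s3$text, "feeling tired after the visit")
  expect_equal(nrow(s3$audit), 0)
})

test_that("names, contacts, and manufacturers are scrubbed with exact audit", {
  txt <- paste("My name is Alice Abbott and you can email me at",
               "AA123@example.com or call 555-0148. The pills come from",
               "Celgene.")
  s <- scrub_pii(txt)
  expect_false(grepl("Alice", s$text))
  expect_false(grepl("@", s$text))
  expect_false(grepl("555-0148", s$text))
  expect_match(s$text, "PRODUCT MANUFACTURER")
  expect_match(s$text, "NAME")
  expect_setequal(
    unique(s$audit$category),
    c("NAME", "EMAIL", "PHONE", "PRODUCT MANUFACTURER"))

  # audit spans reconstruct the scrubbed text from the original
  rebuilt <- txt
  for (i in rev(seq_len(nrow(s$audit)))) {
    rebuilt <- paste0(substring(rebuilt, 1, s$audit$start[i] - 1),
                      s$audit$replacement[i],
                      substring(rebuilt, s$audit$end[i] + 1))
  }
  expect_identical(rebuilt, s$text)
})

test_that("scrubbing and brand mapping are idempotent", {
  texts <- c("My name is Alice Abbott.",
             "Dr Keller is my hematologist, email AA1@example.com",
             "started Venclexta today with Mylotarg on deck")
  for (t in texts) {
    once <- scrub_pii(map_brand_to_inn(t))
    twice <- scrub_pii(map_brand_to_inn(once$text))
    expect_identical(twice$text, once$text)
    expect_equal(nrow(twice$audit), 0)
  }
})

test_that("the full brand map reproduces its INN conversions exactly", {
  map <- default_brand_map()
  expect_length(map, 8)
  for (brand in names(map)) {
    expect_identical(map_brand_to_inn(paste0("started ", brand, " today")),
                     paste0("started ", map[[brand]], " today"))
    # case-insensitive whole-word matching
    expect_identical(map_brand_to_inn(toupper(brand)), map[[brand]])
  }
  expect_identical(map_brand_to_inn("started Venclexta today"),
                   "started venetoclax today")
  expect_identical(map_brand_to_inn("Mylotarg infusion"),
                   "gemtuzumab ozogamicin infusion")
  # INNs are fixed points; substrings of other words are untouched
  expect_identical(map_brand_to_inn("venetoclax"), "venetoclax")
  expect_identical(map_brand_to_inn("preVenclextan"), "preVenclextan")
})

test_that("username tokenization is deterministic, collision-free, leak-free", {
  expect_identical(tokenize_username("janedoe42", "salt"),
                   tokenize_username("janedoe42", "salt"))
  expect_false(tokenize_username("janedoe42", "salt") ==
                 tokenize_username("janedoe42", "other-salt"))

  tok <- tokenize_username("janedoe42", "salt")
  expect_match(tok, "^[0-9a-f]{12}$")
  subs <- substring("janedoe42", 1:7, 3:9)
  expect_false(any(vapply(subs, grepl, logical(1), x = tok, fixed = TRUE)))

  set.seed(42)
  many <- unique(paste0(sample(letters, 10000, TRUE), "user",
                        seq_len(10000)))
  expect_equal(length(unique(tokenize_username(many, "salt"))),
               length(many))
  expect_error(tokenize_username("", "salt"), "non-empty")
})

test_that("trial filtering keeps passing references, drops participation", {
  f <- filter_trial_posts(c(
    "my oncologist recommended I look at clinical trials",
    "I decided to start a clinical trial with a new drug called sabatolimab",
    "feeling ok today, counts stable",
    "I enrolled in the trial last week"))
  expect_identical(f$keep, c(TRUE, FALSE, TRUE, FALSE))
  expect_identical(f$reason[2], "investigational drug mention")
  expect_identical(f$reason[4], "trial participation")
})

test_that("end-to-end anonymization removes every planted PII surface", {
  g <- synth_small()
  res <- anonymize_corpus(g$corpus, salt = "test-salt")
  anon <- res$corpus
  pii <- g$ground_truth$pii
  remaining <- vapply(unique(pii$surface), function(s) {
    any(grepl(s, anon$posts$text, fixed = TRUE))
  }, logical(1))
  expect_equal(sum(remaining), 0)

  # longitudinality: token partition equals the raw user partition
  kept <- g$corpus$posts$post_id %in% anon$posts$post_id
  raw_partition <- split(g$corpus$posts$post_id[kept],
                         g$corpus$posts$user_ref[kept])
  tok_partition <- split(anon$posts$post_id, anon$posts$user_ref)
  expect_setequal(
    unname(vapply(raw_partition, paste, character(1), collapse = ",")),
    unname(vapply(tok_partition, paste, character(1), collapse = ",")))
})
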