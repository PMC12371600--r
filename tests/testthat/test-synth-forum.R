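test_that("config validation reports field-level problems", {
  expect_error(synth_config(n_users = -1), "n_users")
  expect_error(synth_config(pii_rate = 1.5), "pii_rate")
  expect_error(synth_config(role_mix = c(patient = 0.7, caregiver = 0.7,
                                         other = 0)), "role_mix")
  expect_error(synth_config(emotion_mix = c(neutral = 1, joy = 0.5)),
               "emotion_mix")
})

test_that("degenerate and forced configurations generate as specified", {
  empty <- generate_corpus(synth_config(n_users = 0))
  expect_equal(nrow(empty$corpus$posts), 0)
  expect_equal(nrow(empty$ground_truth$users), 0)

  allhr <- generate_corpus(synth_config(
    n_users = 50, hr_fraction = 1,
    role_mix = c(patient = 0.5, caregiver = 0.5, other = 0), seed = 7))
  gt <- allhr$ground_truth
  expect_true(all(gt$users$risk == "high"))
  marker_users <- unique(
    gt$posts$user_ref[lengths(gt$posts$risk_markers) > 0])
  expect_setequal(marker_users, gt$users$user_ref)
})

test_that("role mix is honored in expectation at study scale", {
  g <- generate_corpus(synth_config(
    n_users = 2000, role_mix = c(patient = 0.5, caregiver = 0.5, other = 0),
    pii_rate = 0, misspell_rate = 0, duplicate_rate = 0, seed = 31))
  share <- mean(g$ground_truth$users$role == "patient")
  expect_lt(abs(share - 0.5), 0.03) # 3 percentage points ~ 3 sd at n=2000
})

test_that("generation is byte-identical for a fixed seed", {
  cfg <- synth_config(n_users = 40, seed = 99)
  a <- generate_corpus(cfg)
  b <- generate_corpus(cfg)
  expect_identical(a$corpus$posts, b$corpus$posts)
  expect_identical(a$ground_truth, b$ground_truth)

  c_ <- generate_corpus(synth_config(n_users = 40, seed = 100))
  expect_false(identical(a$corpus$posts$text, c_$corpus$posts$text))
})

test_that("per-user post counts are heavy-tailed with superusers", {
  g <- generate_corpus(synth_config(n_users = 500, seed = 12))
  counts <- table(g$ground_truth$posts$user_ref[
    is.na(g$ground_truth$posts$duplicate_of)])
  expect_gte(max(counts), 10 * median(counts))
})

test_that("ground-truth PII spans slice to the recorded surface strings", {
  g <- synth_small()
  pii <- g$ground_truth$pii
  expect_gt(nrow(pii), 0)
  text_of <- setNames(g$corpus$posts$text, g$corpus$posts$post_id)
  sliced <- substr(text_of[pii$post_id], pii$start, pii$end)
  expect_identical(unname(sliced), pii$surface)
})

test_that("planted role and marker structure is present in every post", {
  g <- synth_small()
  gt <- g$ground_truth
  lex <- role_phrase_lexicon()
  posts <- g$corpus$posts
  role_of <- setNames(gt$users$role, gt$users$user_ref)
  lower <- tolower(posts$text)
  pat_hit <- Reduce(`|`, lapply(lex$patient, function(p)
    stringr::str_detect(lower, stringr::regex(p))))
  care_hit <- Reduce(`|`, lapply(lex$caregiver, function(p)
    stringr::str_detect(lower, stringr::regex(p))))
  is_patient <- role_of[posts$user_ref] == "patient"
  is_caregiver <- role_of[posts$user_ref] == "caregiver"
  expect_true(all(pat_hit[is_patient]))
  expect_true(all(care_hit[is_caregiver]))
})

test_that("injection rates hit their expectation at study scale", {
  g <- synth_study()
  gt <- g$ground_truth
  n <- sum(is.na(gt$posts$duplicate_of))
  dup_rate <- sum(!is.na(gt$posts$duplicate_of)) / n
  expect_lt(abs(dup_rate - 0.02), 0.01)
  trial_rate <- mean(gt$posts$trial_mention[is.na(gt$posts$duplicate_of)])
  expect_lt(abs(trial_rate - 0.01), 0.005)
  pii_rate <- length(unique(gt$pii$post_id[
    gt$pii$post_id %in% gt$posts$post_id[is.na(gt$posts$duplicate_of)]])) / n
  expect_lt(abs(pii_rate - 0.05), 0.01)
})

test_that("render_post embeds markers verbatim once and is deterministic", {
  txt <- render_post("generic", markers = "I was diagnosed with MDS",
                     rng_state = 5)
  expect_equal(stringr::str_count(txt, stringr::fixed(
    "I was diagnosed with MDS")), 1)
  both <- render_post("generic",
                      markers = c("I have MDS", "azacitidine"),
                      rng_state = 5)
  expect_match(both, "I have MDS")
  expect_match(both, "azacitidine")
  expect_identical(render_post("generic", "x", 5),
                   render_post("generic", "x", 5))
  expect_error(render_post("nope", "x", 5), "unknown template")
})
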