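test_that("post-level role labeling follows the key-phrase rules", {
  expect_equal(label_post_role("I was diagnosed with MDS in June")$label,
               "patient")
  expect_equal(label_post_role("I was diagnosed with MDS in June")$confidence,
               1)
  expect_equal(label_post_role(
    "My husband was diagnosed with MDS and I care for him")$label,
    "caregiver")
  expect_equal(label_post_role("MDS is a rare disease")$label, "none")
  # spelled-out disease term matches too
  expect_equal(label_post_role(
    "I am living with myelodysplastic syndrome")$label, "patient")
  # both sets matching: earlier match position wins
  both <- paste("My wife has MDS and now I have MDS too")
  expect_equal(label_post_role(both)$label, "caregiver")
})

test_that("user classification honors the 80% rule and its boundary", {
  mk <- function(labels, conf = 1) {
    tibble::tibble(label = labels, confidence = conf)
  }
  nine_one <- classify_user(mk(c(rep("patient", 9), "caregiver")))
  expect_equal(nine_one$role, "patient")
  expect_equal(nine_one$rule_used, "majority_80")
  expect_equal(nine_one$majority_share, 0.9)

  # 4/5 = exactly 80%: boundary inclusive, still the majority rule
  four_one <- classify_user(mk(c(rep("patient", 4), "caregiver")))
  expect_equal(four_one$role, "patient")
  expect_equal(four_one$rule_used, "majority_80")
  expect_equal(four_one$majority_share, 0.8)

  # no 80% majority: earliest confident label decides
  tied <- classify_user(mk(c("caregiver", "patient")))
  expect_equal(tied$role, "caregiver")
  expect_equal(tied$rule_used, "chronological")

  # low-confidence labels are skipped by the chronological scan
  low_first <- classify_user(tibble::tibble(
    label = c("caregiver", "patient"), confidence = c(0.5, 0.95)))
  expect_equal(low_first$role, "patient")

  # none labels are excluded from the denominator
  with_none <- classify_user(mk(c("none", "patient", "none")))
  expect_equal(with_none$role, "patient")
  expect_equal(with_none$majority_share, 1)

  empty <- classify_user(mk(character(0)))
  expect_equal(empty$role, "unknown")
  expect_equal(empty$rule_used, "none")
})

test_that("classification is invariant to duplicating the label list", {
  set.seed(7)
  for (i in 1:25) {
    n <- sample(2:8, 1)
    labels <- tibble::tibble(
      label = sample(c("patient", "caregiver", "none"), n, replace = TRUE),
      confidence = 1)
    base <- classify_user(labels)
    scaled <- classify_user(dplyr::bind_rows(labels, labels, labels))
    expect_identical(scaled$role, base$role)
    # a majority decision never contradicts the strict majority
    if (base$rule_used == "majority_80") {
      tab <- table(labels$label[labels$label != "none"])
      expect_equal(base$role, names(tab)[which.max(tab)])
    }
  }
})

test_that("user role recovery is exact on marker-consistent synthetic users", {
  g <- synth_small()
  res <- classify_corpus_roles(g$corpus)
  truth <- g$ground_truth$users
  pred <- res$decisions$role[match(truth$user_ref, res$decisions$user_ref)]
  clinical <- truth$role %in% c("patient", "caregiver")
  expect_identical(pred[clinical], truth$role[clinical])
  expect_true(all(pred[!clinical] == "unknown"))
})

test_that("the reference fallback classifier labels phrase-free posts", {
  g <- synth_small()
  gt <- g$ground_truth
  role_of <- setNames(gt$users$role, gt$users$user_ref)
  posts <- g$corpus$posts
  keep <- role_of[posts$user_ref] %in% c("patient", "caregiver")
  fb <- train_role_fallback(posts$text[keep],
                            unname(role_of[posts$user_ref[keep]]))
  res <- fb("she was there while they ran the counts and I drove her home")
  expect_true(res$label %in% c("patient", "caregiver", "none"))
  expect_gte(res$confidence, 0)
  # a strongly caregiver-flavored text lands on caregiver
  res2 <- fb("my husband has mds and I am the main caregiver for him")
  expect_equal(res2$label, "caregiver")
})
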