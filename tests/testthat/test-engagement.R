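mk_posts <- function(user, dates, thread = "t1") {
  n <- length(dates)
  tibble::tibble(
    post_id = paste0(user, "_", seq_len(n)), thread_id = thread,
    user_ref = user, timestamp = as.Date(dates), source = "f",
    url = NA_character_, text = "x", reply_to = NA_character_)
}

test_that("engagement spans and summaries use order statistics", {
  posts <- dplyr::bind_rows(
    mk_posts("a", c("2020-01-01", "2020-01-11")),      # span 10
    mk_posts("b", "2020-05-01"),                        # span 0
    mk_posts("c", c("2020-01-01", "2020-01-03")),       # span 2
    mk_posts("d", c("2019-01-01", "2019-02-10")),       # span 40
    mk_posts("e", c("2017-01-01", "2020-04-15")))       # span 1200
  eng <- engagement_metrics(new_corpus(posts))
  spans <- setNames(eng$profiles$active_span_days, eng$profiles$user_ref)
  expect_equal(unname(spans[c("a", "b", "c", "d", "e")]),
               c(10, 0, 2, 40, 1200))
  expect_equal(eng$summary$median_span, 10)
  expect_equal(eng$summary$min_span, 0)
  expect_equal(eng$summary$max_span, 1200)
  expect_equal(eng$summary$retention_2d, 2 / 5)
})

test_that("superuser detection flags the top fraction with tie inclusion", {
  profiles <- tibble::tibble(
    user_ref = paste0("u", 1:100),
    post_count = c(500, rep(3, 99)))
  out <- detect_superusers(profiles, fraction = 0.01)
  expect_identical(out$user_ref[out$is_superuser], "u1")

  # the cut falls inside a tie group: the whole group is flagged
  profiles2 <- tibble::tibble(user_ref = paste0("u", 1:10),
                              post_count = c(9, 7, 7, 7, 1, 1, 1, 1, 1, 1))
  out2 <- detect_superusers(profiles2, fraction = 0.2)
  expect_setequal(out2$user_ref[out2$is_superuser],
                  c("u1", "u2", "u3", "u4"))

  # uniform counts: everyone ties at the cut
  uniform <- tibble::tibble(user_ref = paste0("u", 1:10), post_count = 4)
  out3 <- detect_superusers(uniform, fraction = 0.3)
  expect_equal(sum(out3$is_superuser), 10)
})

test_that("superuser capping bounds per-discussion contributions", {
  posts <- dplyr::bind_rows(
    mk_posts("super", as.character(as.Date("2020-01-01") + 0:29)),
    mk_posts("plain", as.character(as.Date("2020-01-01") + 0:29),
             thread = "t2"))
  profiles <- tibble::tibble(user_ref = c("super", "plain"),
                             post_count = c(30L, 30L),
                             is_superuser = c(TRUE, FALSE))
  w <- normalize_superuser_influence(posts, profiles, cap = 1)
  by_user <- split(w$weight, sub("_.*", "", w$post_id))
  expect_equal(sum(by_user$super), 1)
  expect_equal(sum(by_user$plain), 30)

  # capping never increases any theme prevalence
  g <- synth_small()
  eng <- detect_superusers(engagement_metrics(g$corpus)$profiles)
  assignments <- assign_categories(g$corpus$posts$text,
                                   g$corpus$posts$post_id)
  dm <- g$corpus$posts[, c("post_id", "thread_id")]
  before <- score_prevalence(assignments, dm)
  w2 <- normalize_superuser_influence(g$corpus$posts, eng, cap = 1)
  capped <- assignments[assignments$post_id %in%
                          w2$post_id[w2$weight > 0], ]
  after <- score_prevalence(capped, dm)
  for (node in before$node) {
    a <- after$prevalence[after$node == node]
    expect_lte(if (length(a) == 0) 0L else a,
               before$prevalence[before$node == node])
  }
})

test_that("saturation finds the planted last-new-theme batch", {
  # 10 batches of 10 posts; themes appear per a planted schedule
  mk_schedule <- function(arrivals) {
    posts <- tibble::tibble(
      post_id = paste0("p", 1:100), thread_id = paste0("t", 1:100),
      timestamp = as.Date("2020-01-01") + 1:100)
    rows <- list()
    for (th in names(arrivals)) {
      b <- arrivals[[th]]
      # theme th first appears in batch b, then recurs in all later batches
      later <- if (b * 10 + 1 <= 100) seq(b * 10 + 1, 100, by = 10) else
        integer(0)
      idx <- c((b - 1) * 10 + 1, later)
      rows[[th]] <- tibble::tibble(post_id = paste0("p", idx), node = th)
    }
    list(posts = posts, assignments = dplyr::bind_rows(rows),
         dm = posts[, c("post_id", "thread_id")])
  }

  s1 <- mk_schedule(list(a = 1, b = 1, c = 1))
  r1 <- saturation_analysis(s1$posts, s1$assignments, s1$dm,
                            batch_size = 10, lookahead = 3, threshold = 1)
  expect_equal(r1$saturation_index, 1)
  expect_true(all(diff(r1$curve$cumulative_themes) >= 0))

  s2 <- mk_schedule(setNames(as.list(1:10), letters[1:10]))
  r2 <- saturation_analysis(s2$posts, s2$assignments, s2$dm,
                            batch_size = 10, lookahead = 3, threshold = 1)
  expect_true(is.na(r2$saturation_index))

  s3 <- mk_schedule(list(a = 1, b = 2, c = 4))
  r3 <- saturation_analysis(s3$posts, s3$assignments, s3$dm,
                            batch_size = 10, lookahead = 6, threshold = 1)
  expect_equal(r3$saturation_index, 4)
  expect_lte(max(r3$curve$cumulative_themes),
             length(r3$significant_themes))
})

test_that("the COVID split partitions on the stated boundaries", {
  posts <- mk_posts("u", c("2019-06-15", "2020-03-01", "2017-12-31",
                           "2018-01-01", "2020-02-29", "2021-07-04"))
  out <- covid_split(posts)
  expect_setequal(out$pre$timestamp,
                  as.Date(c("2019-06-15", "2018-01-01", "2020-02-29")))
  expect_setequal(out$post$timestamp,
                  as.Date(c("2020-03-01", "2021-07-04")))
  expect_setequal(out$excluded$timestamp, as.Date("2017-12-31"))
  expect_equal(sum(out$counts$n), nrow(posts))
})
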