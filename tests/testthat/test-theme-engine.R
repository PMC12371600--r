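test_that("keyword category assignment is multilabel with seed-fraction scores", {
  h <- theme_hierarchy()
  a <- assign_categories("thinking about bone marrow transplant risks",
                         "p1", h)
  expect_true("transplants" %in% a$node)

  expect_equal(nrow(assign_categories("", "p1", h)), 0)

  two <- assign_categories(
    "the transplant donor and the treatment regimen", "p1", h)
  cats <- two$node[two$level == "category"]
  expect_true(all(c("transplants", "treatments") %in% cats))
  # score is the matched-seed fraction
  tr <- two[two$node == "transplants", ]
  expect_equal(tr$score, 2 / 5)
})

test_that("planted categories are recovered after cleaning", {
  g <- synth_small()
  corpus <- clean_corpus(g$corpus)
  assigned <- assign_categories(corpus$posts$text, corpus$posts$post_id)
  assigned <- assigned[assigned$level == "category", ]
  by_post <- split(assigned$node, assigned$post_id)
  gt <- g$ground_truth$posts
  gt <- gt[match(corpus$posts$post_id, gt$post_id), ]
  ok <- vapply(seq_len(nrow(gt)), function(i) {
    all(gt$themes[[i]] %in% (by_post[[gt$post_id[i]]] %||% character(0)))
  }, logical(1))
  expect_true(all(ok))
})

test_that("prevalence counts unique discussions", {
  assignments <- tibble::tibble(
    post_id = c("a", "b", "c", "d"),
    node = c("x", "x", "x", "y"))
  dm <- tibble::tibble(post_id = c("a", "b", "c", "d"),
                       thread_id = c("t1", "t1", "t1", "t2"))
  prev <- score_prevalence(assignments, dm)
  expect_equal(prev$prevalence[prev$node == "x"], 1) # 3 posts, 1 thread
  expect_false("z" %in% prev$node)                   # absent theme: 0

  dm2 <- tibble::tibble(post_id = c("a", "b", "c", "d"),
                        thread_id = c("t1", "t2", "t1", "t2"))
  expect_equal(score_prevalence(assignments, dm2)$prevalence[1], 2)
})

test_that("prevalence and network match brute force on random instances", {
  set.seed(21)
  for (rep in 1:5) {
    n_posts <- sample(30:80, 1)
    n_threads <- sample(5:40, 1) # stays within 50 discussions
    themes <- paste0("th", 1:6)
    dm <- tibble::tibble(post_id = paste0("p", seq_len(n_posts)),
                         thread_id = sample(paste0("t", seq_len(n_threads)),
                                            n_posts, replace = TRUE))
    assignments <- tibble::tibble(
      post_id = rep(dm$post_id, times = sample(0:3, n_posts,
                                               replace = TRUE))) |>
      dplyr::mutate(node = sample(themes, dplyr::n(), replace = TRUE))

    prev <- score_prevalence(assignments, dm)
    net <- build_theme_network(assignments, dm)

    # brute-force oracle: explicit scan over discussions
    thread_of <- setNames(dm$thread_id, dm$post_id)
    themes_by_thread <- lapply(
      split(assignments$node, thread_of[assignments$post_id]), unique)
    for (th in themes) {
      oracle <- sum(vapply(themes_by_thread, function(x) th %in% x,
                           logical(1)))
      got <- prev$prevalence[prev$node == th]
      expect_equal(if (length(got) == 0) 0L else got, oracle)
      expect_lte(oracle, length(themes_by_thread))
    }
    for (i in seq_along(themes)) {
      for (j in seq_along(themes)) {
        if (i >= j) next
        a <- themes[i]; b <- themes[j]
        oracle_w <- sum(vapply(themes_by_thread, function(x) {
          a %in% x && b %in% x
        }, logical(1)))
        got <- net$weight[net$from == a & net$to == b]
        expect_equal(if (length(got) == 0) 0L else got, oracle_w)
        pa <- prev$prevalence[prev$node == a]
        pb <- prev$prevalence[prev$node == b]
        if (length(pa) == 1 && length(pb) == 1) {
          expect_lte(oracle_w, min(pa, pb))
        }
      }
    }
    expect_true(all(net$weight >= 1))
    expect_true(all(net$from != net$to))
  }
})

test_that("major/minor thresholding is inclusive and flags actionability", {
  prev <- tibble::tibble(node = c("clinical", "emotional", "treatments"),
                         prevalence = c(10, 0, 9))
  cat_ <- categorize_theme(prev, threshold = 10)
  expect_equal(cat_$status, c("major", "minor", "minor"))
  expect_false(cat_$actionable[cat_$node == "emotional"])
  expect_true(cat_$actionable[cat_$node == "clinical"])
})

test_that("latent topics: determinism, degenerate k, planted purity", {
  set.seed(3)
  vocabularies <- list(
    c("alpha", "bravo", "charlie", "delta", "echo"),
    c("foxtrot", "golf", "hotel", "india", "juliet"),
    c("kilo", "lima", "mike", "november", "oscar"))
  texts <- unlist(lapply(1:3, function(g) {
    vapply(1:25, function(i) {
      paste(sample(vocabularies[[g]], 12, replace = TRUE), collapse = " ")
    }, character(1))
  }))
  planted <- rep(1:3, each = 25)

  purity <- function(assign) {
    sum(vapply(split(planted, assign), function(x) max(table(x)),
               numeric(1))) / length(planted)
  }
  for (method in c("kmeans", "lsa", "agglomerative", "spectral", "lda")) {
    m <- fit_latent_topics(texts, method = method, k = 3, seed = 9)
    expect_gte(purity(m$assignment), 0.9)
    m2 <- fit_latent_topics(texts, method = method, k = 3, seed = 9)
    expect_identical(m$assignment, m2$assignment)
    expect_true(all(m$assignment %in% 1:3))
    # top terms of each topic come from one planted vocabulary
    expect_true(all(lengths(m$top_terms) > 0))
  }

  one <- fit_latent_topics(texts, method = "kmeans", k = 1, seed = 2)
  expect_true(all(one$assignment == 1))
  expect_error(fit_latent_topics(texts[1:3], method = "kmeans", k = 10),
               "exceeds")

  # density methods may emit noise (0) but must find the planted structure
  db <- fit_latent_topics(texts, method = "dbscan", seed = 1,
                          eps = 0.9, min_pts = 4)
  expect_true(all(db$assignment >= 0))
  expect_gte(length(unique(db$assignment[db$assignment > 0])), 3)
  op <- fit_latent_topics(texts, method = "optics", seed = 1,
                          eps = 0.9, min_pts = 4)
  expect_true(all(op$assignment >= 0))
})

test_that("hierarchy merge maps, expands, and discards topics correctly", {
  h <- theme_hierarchy()
  texts <- c("alpha bravo charlie alpha", "alpha charlie bravo bravo",
             "kilo lima mike kilo", "mike kilo lima lima")
  m <- fit_latent_topics(texts, method = "kmeans", k = 2, seed = 4,
                         top_m = 3)
  mapping <- tibble::tibble(
    topic = 1:2,
    action = c("map", "new"),
    node = c("knowledge constraints", "peer mentoring"),
    root = c(NA, "unmet needs"))
  merged <- merge_latent_into_hierarchy(m, h, mapping)
  expect_true("peer mentoring" %in% merged$subthemes$node)
  expect_true(all(h$subthemes$node %in% merged$subthemes$node))
  i <- match("knowledge constraints", merged$subthemes$node)
  expect_true(all(m$top_terms[[1]] %in% merged$subthemes$seeds[[i]]))

  # discard leaves the hierarchy unchanged
  discard_all <- tibble::tibble(topic = 1:2, action = "discard",
                                node = NA, root = NA)
  expect_identical(merge_latent_into_hierarchy(m, h, discard_all), h)

  # two topics mapped onto one node contribute the union of their terms
  same_node <- tibble::tibble(topic = 1:2, action = "map",
                              node = "ongoing research", root = NA)
  merged2 <- merge_latent_into_hierarchy(m, h, same_node)
  j <- match("ongoing research", merged2$subthemes$node)
  expect_true(all(unlist(m$top_terms) %in% merged2$subthemes$seeds[[j]]))

  bad <- tibble::tibble(topic = 1:2, action = "map", node = "nope",
                        root = NA)
  expect_error(merge_latent_into_hierarchy(m, h, bad), "unknown")
  expect_error(merge_latent_into_hierarchy(
    m, h, mapping[1, ]), "cover every topic")
})
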