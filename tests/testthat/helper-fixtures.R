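# Shared fixtures. Expensive synthetic corpora are generated once per test
# run and memoized in this environment.

`%||%` <- function(x, y) if (is.null(x)) y else x

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, .fixture_cache)) {
    assign(key, force(expr), .fixture_cache)
  }
  get(key, .fixture_cache)
}

# A small, fast corpus for unit-level checks.
synth_small <- function() {
  memo("small", generate_corpus(synth_config(n_users = 120, seed = 101)))
}

# The study-scale corpus used by the synthetic acceptance properties.
synth_study <- function() {
  memo("study", generate_corpus(synth_config(n_users = 2000, seed = 404)))
}

pipeline_study <- function() {
  memo("study_report", {
    run_pipeline(synth_study()$corpus, pipeline_config(seed = 5))
  })
}

# Hand-built three-thread corpus for exact-count checks.
tiny_posts <- function() {
  tibble::tibble(
    post_id = paste0("p", 1:6),
    thread_id = c("t1", "t1", "t2", "t2", "t3", "t3"),
    user_ref = c("ann", "ann", "bob", "cat", "cat", "dan"),
    timestamp = as.Date("2019-01-01") + 0:5,
    source = "forum",
    url = NA_character_,
    text = c("I have MDS and wanted to share an update.",
             "The fatigue and nausea have been hard.",
             "My wife has MDS and I am the main caregiver now.",
             "Blood counts are checked every two weeks.",
             "The donor search for the transplant continues.",
             "MDS is a rare disease."),
    reply_to = NA_character_
  )
}

tiny_corpus <- function() new_corpus(tiny_posts())

# Serialize a run report for byte-identity comparisons.
report_bytes <- function(report) {
  jsonlite::toJSON(report[setdiff(names(report), "corpus")],
                   auto_unbox = TRUE, digits = NA, force = TRUE)
}
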