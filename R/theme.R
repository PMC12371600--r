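#' Default theme hierarchy
#'
#' Five root themes (disease burden, treatment decision, unmet needs, life
#' milestones, logistic burden) with keyword-seeded subthemes, alongside the
#' seven broad post categories (clinical, diet and lifestyle, education and
#' logistics, emotional, physical, transplants, treatments). Categories and
#' roots are kept as parallel label systems. Every node carries a seed
#' keyword list and an actionability flag (emotional nodes are
#' nonactionable).
#'
#' @return Object of class `theme_hierarchy`: list with `roots`,
#'   `categories` (tibble `node`, `seeds`, `actionable`) and `subthemes`
#'   (tibble `node`, `root`, `seeds`, `actionable`).
#' @export
theme_hierarchy <- function() {
  roots <- c("disease burden", "treatment decision", "unmet needs",
             "life milestones", "logistic burden")
  categories <- tibble::tibble(
    node = c("clinical", "diet_lifestyle", "education_logistics",
             "emotional", "physical", "transplants", "treatments"),
    seeds = list(
      c("diagnosis", "biopsy", "blood counts", "hemoglobin", "platelets",
        "monitoring", "prognosis"),
      c("diet", "exercise", "nutrition", "daily routine", "lifestyle"),
      c("insurance", "appointment", "second opinion", "care options",
        "forms"),
      c("support", "encouragement", "stay strong", "not alone",
        "thinking of you"),
      c("fatigue", "nausea", "pain", "side effects", "bruising",
        "infection"),
      c("transplant", "donor", "graft", "conditioning", "engraftment"),
      c("treatment", "transfusion", "regimen", "cycle", "chemotherapy")
    ),
    actionable = c(TRUE, TRUE, TRUE, FALSE, TRUE, TRUE, TRUE)
  )
  subthemes <- tibble::tibble(
    node = c("blood counts", "quality of life", "disease progression",
             "complications", "treatment options", "treatment modalities",
             "hematological management", "diagnostic process",
             "navigating the health care system", "knowledge constraints",
             "ongoing research", "therapeutic intervention",
             "emotional support"),
    root = c("disease burden", "disease burden", "disease burden",
             "disease burden", "treatment decision", "treatment decision",
             "treatment decision", "life milestones", "logistic burden",
             "unmet needs", "unmet needs", "treatment decision",
             "unmet needs"),
    seeds = list(
      c("blood counts", "hemoglobin", "platelets"),
      c("quality of life"),
      c("disease progression", "progressed"),
      c("complications", "infections"),
      c("treatment options", "care options"),
      c("regimen", "cycle", "chemotherapy"),
      c("hematological"),
      c("diagnostic process", "diagnosis"),
      c("health care system", "navigating"),
      c("information", "understanding"),
      c("ongoing research", "research"),
      c("therapeutic intervention", "new drug"),
      c("support", "encouragement")
    ),
    actionable = c(TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE,
                   TRUE, TRUE, TRUE, FALSE)
  )
  structure(list(roots = roots, categories = categories,
                 subthemes = subthemes),
            class = "theme_hierarchy")
}

.hierarchy_nodes <- function(hierarchy) {
  dplyr::bind_rows(
    dplyr::mutate(hierarchy$categories, level = "category",
                  root = NA_character_),
    dplyr::mutate(hierarchy$subthemes, level = "subtheme")
  )
}

#' Assign theme categories and subthemes to posts
#'
#' The reference top-down classifier is seeded-keyword scoring: a node is
#' assigned when at least one of its seed keywords occurs (case-insensitive,
#' whole word/phrase) and its score is the matched-seed fraction. A pluggable
#' supervised `model` (function `text -> tibble(node, score)`) may replace
#' it. Posts with no signal get an empty assignment.
#'
#' @param texts Character vector of post texts.
#' @param post_id Matching post ids.
#' @param hierarchy A [theme_hierarchy()].
#' @param model Optional pluggable classifier.
#' @return Tibble (`post_id`, `node`, `level`, `root`, `score`), one row per
#'   assignment.
#' @export
assign_categories <- function(texts, post_id = seq_along(texts),
                              hierarchy = theme_hierarchy(), model = NULL) {
  if (!is.null(model)) {
    out <- purrr::map2_dfr(texts, post_id, function(t, id) {
      res <- model(t)
      if (nrow(res) == 0) return(NULL)
      res$post_id <- id
      res
    })
    return(out)
  }
  lower <- tolower(texts)
  nodes <- .hierarchy_nodes(hierarchy)
  rows <- vector("list", nrow(nodes))
  for (j in seq_len(nrow(nodes))) {
    seeds <- nodes$seeds[[j]]
    n_hit <- rep(0L, length(lower))
    for (s in seeds) {
      n_hit <- n_hit + stringr::str_detect(
        lower, paste0("\\b", stringr::str_escape(tolower(s)), "\\b"))
    }
    hit <- n_hit > 0
    if (any(hit)) {
      rows[[j]] <- tibble::tibble(
        post_id = post_id[hit], node = nodes$node[j],
        level = nodes$level[j], root = nodes$root[j],
        score = n_hit[hit] / length(seeds)
      )
    }
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    return(tibble::tibble(post_id = post_id[0], node = character(0),
                          level = character(0), root = character(0),
                          score = numeric(0)))
  }
  dplyr::arrange(out, .data$post_id, .data$node)
}

.default_stopwords <- function() {
  unique(c(.extra_dictionary_words,
           c("all", "are", "been", "being", "can", "come", "comes", "day",
             "do", "get", "go", "goes", "here", "how", "if", "into", "its",
             "just", "know", "like", "most", "much", "next", "now", "one",
             "out", "over", "some", "than", "then", "there", "these",
             "took", "up", "very", "what", "when", "which", "who", "will",
             "would")))
}

#' Build a document-term matrix
#'
#' Lowercased word tokens, stopword removal, minimum document frequency,
#' term-frequency or tf-idf weighting, optional L2 row normalization.
#'
#' @param texts Character vector.
#' @param weighting `"tfidf"` (default) or `"tf"`.
#' @param min_df Minimum number of documents a term must occur in
#'   (default 2).
#' @param stopwords Character vector of terms to drop.
#' @param normalize L2-normalize document rows (default TRUE for tfidf).
#' @return A sparse `dgCMatrix` (documents x terms).
#' @export
vectorize_corpus <- function(texts, weighting = c("tfidf", "tf"),
                             min_df = 2L,
                             stopwords = .default_stopwords(),
                             normalize = NULL) {
  weighting <- match.arg(weighting)
  if (is.null(normalize)) normalize <- weighting == "tfidf"
  toks <- tokenize_words(texts)
  toks <- lapply(toks, function(t) t[!t %in% stopwords & nchar(t) > 2])
  vocab_df <- table(unlist(lapply(toks, unique)))
  vocab <- names(vocab_df)[vocab_df >= min_df]
  if (length(vocab) == 0) abort("empty vocabulary after filtering")
  i <- rep(seq_along(toks), lengths(toks))
  j <- match(unlist(toks), vocab)
  keep <- !is.na(j)
  m <- Matrix::sparseMatrix(i = i[keep], j = j[keep],
                            x = rep(1, sum(keep)),
                            dims = c(length(texts), length(vocab)),
                            dimnames = list(NULL, vocab))
  if (weighting == "tfidf") {
    df <- Matrix::colSums(m > 0)
    idf <- log(length(texts) / pmax(df, 1))
    m <- m %*% Matrix::Diagonal(x = idf)
    colnames(m) <- vocab
  }
  if (normalize) {
    nrm <- sqrt(Matrix::rowSums(m^2))
    nrm[nrm == 0] <- 1
    m <- Matrix::Diagonal(x = 1 / nrm) %*% m
    colnames(m) <- vocab
  }
  methods::as(m, "CsparseMatrix")
}

# ---- latent topic methods -------------------------------------------------

.top_terms_from_centroids <- function(x, assignment, k, m) {
  terms <- colnames(x)
  lapply(seq_len(k), function(c) {
    idx <- which(assignment == c)
    if (length(idx) == 0) return(character(0))
    mass <- Matrix::colSums(x[idx, , drop = FALSE])
    terms[order(mass, decreasing = TRUE)[seq_len(min(m, length(terms)))]]
  })
}

.lda_gibbs <- function(counts, k, iterations = 100, alpha = 0.1,
                       beta = 0.05) {
  # collapsed Gibbs sampler over the token stream of a count matrix
  counts <- methods::as(counts, "TsparseMatrix")
  doc <- rep(counts@i + 1L, counts@x)
  term <- rep(counts@j + 1L, counts@x)
  n_doc <- nrow(counts)
  n_term <- ncol(counts)
  n_tok <- length(doc)
  z <- sample.int(k, n_tok, replace = TRUE)
  ndk <- matrix(0L, n_doc, k)
  nkw <- matrix(0L, k, n_term)
  nk <- integer(k)
  for (t in seq_len(n_tok)) {
    ndk[doc[t], z[t]] <- ndk[doc[t], z[t]] + 1L
    nkw[z[t], term[t]] <- nkw[z[t], term[t]] + 1L
    nk[z[t]] <- nk[z[t]] + 1L
  }
  for (it in seq_len(iterations)) {
    for (t in seq_len(n_tok)) {
      d <- doc[t]; w <- term[t]; old <- z[t]
      ndk[d, old] <- ndk[d, old] - 1L
      nkw[old, w] <- nkw[old, w] - 1L
      nk[old] <- nk[old] - 1L
      p <- (ndk[d, ] + alpha) * (nkw[, w] + beta) / (nk + n_term * beta)
      new <- sample.int(k, 1, prob = p)
      z[t] <- new
      ndk[d, new] <- ndk[d, new] + 1L
      nkw[new, w] <- nkw[new, w] + 1L
      nk[new] <- nk[new] + 1L
    }
  }
  phi <- (nkw + beta) / (nk + n_term * beta)
  list(assignment = apply(ndk, 1, which.max), phi = phi)
}

.simple_dbscan <- function(d, eps, min_pts) {
  n <- nrow(d)
  labels <- integer(n) # 0 = unvisited/noise
  visited <- logical(n)
  cluster <- 0L
  neighbors <- function(i) which(d[i, ] <= eps)
  for (i in seq_len(n)) {
    if (visited[i]) next
    visited[i] <- TRUE
    nb <- neighbors(i)
    if (length(nb) < min_pts) next
    cluster <- cluster + 1L
    labels[i] <- cluster
    queue <- setdiff(nb, i)
    while (length(queue) > 0) {
      q <- queue[1]
      queue <- queue[-1]
      if (!visited[q]) {
        visited[q] <- TRUE
        nb_q <- neighbors(q)
        if (length(nb_q) >= min_pts) queue <- union(queue, setdiff(nb_q, q))
      }
      if (labels[q] == 0L) labels[q] <- cluster
    }
  }
  labels
}

.simple_optics <- function(d, eps, min_pts) {
  # reachability ordering; clusters extracted with a DBSCAN-equivalent cut
  n <- nrow(d)
  reach <- rep(Inf, n)
  processed <- logical(n)
  order_out <- integer(0)
  core_dist <- vapply(seq_len(n), function(i) {
    dd <- sort(d[i, ])
    if (length(dd) >= min_pts && dd[min_pts] <= eps) dd[min_pts] else Inf
  }, numeric(1))
  seeds <- numeric(0)
  for (start in seq_len(n)) {
    if (processed[start]) next
    queue <- setNames(0, start)
    while (length(queue) > 0) {
      i <- as.integer(names(queue)[which.min(queue)])
      queue <- queue[names(queue) != as.character(i)]
      if (processed[i]) next
      processed[i] <- TRUE
      order_out <- c(order_out, i)
      if (is.finite(core_dist[i])) {
        nb <- which(d[i, ] <= eps & !processed)
        newreach <- pmax(core_dist[i], d[i, nb])
        for (idx in seq_along(nb)) {
          j <- nb[idx]
          if (newreach[idx] < reach[j]) {
            reach[j] <- newreach[idx]
            queue[as.character(j)] <- newreach[idx]
          }
        }
      }
    }
  }
  labels <- integer(n)
  cluster <- 0L
  for (pos in seq_along(order_out)) {
    i <- order_out[pos]
    if (reach[i] > eps) {
      if (is.finite(core_dist[i])) {
        cluster <- cluster + 1L
        labels[i] <- cluster
      } # else noise
    } else {
      labels[i] <- cluster
    }
  }
  labels
}

#' Fit a latent topic model
#'
#' Bottom-up topic discovery over a document-term matrix. Partitional
#' methods (`lda`, `lsa`, `kmeans`, `spectral`, `agglomerative`) assign
#' every document to one of `k` topics; density methods (`dbscan`,
#' `optics`) may label documents as noise (topic 0). All methods are
#' deterministic for a fixed seed.
#'
#' @param x A `dgCMatrix` from [vectorize_corpus()], or a character vector
#'   of texts (vectorized with defaults; `lda` uses raw term counts).
#' @param method One of `"lda"`, `"lsa"`, `"kmeans"`, `"spectral"`,
#'   `"agglomerative"`, `"dbscan"`, `"optics"`.
#' @param k Number of topics (ignored by density methods).
#' @param seed Integer seed.
#' @param top_m Number of top terms reported per topic.
#' @param eps,min_pts Density parameters for `dbscan`/`optics` (cosine
#'   distance scale).
#' @param iterations Gibbs sweeps for `lda`.
#' @return Object of class `latent_topic_model`: `method`, `k`,
#'   `assignment` (integer per document, 0 = noise), `top_terms` (list of
#'   character vectors), `seed`.
#' @export
fit_latent_topics <- function(x, method = c("kmeans", "lda", "lsa",
                                            "spectral", "agglomerative",
                                            "dbscan", "optics"),
                              k = 5L, seed = 1L, top_m = 10L,
                              eps = 0.6, min_pts = 4L, iterations = 100L) {
  method <- match.arg(method)
  if (is.character(x)) {
    x <- vectorize_corpus(x, weighting = if (method == "lda") "tf" else "tfidf")
  }
  n <- nrow(x)
  partitional <- !method %in% c("dbscan", "optics")
  if (partitional && k > n) {
    abort(sprintf("k = %d exceeds the number of documents (%d)", k, n))
  }
  withr::with_seed(as.integer(seed), {
    assignment <- switch(method,
      kmeans = {
        stats::kmeans(as.matrix(x), centers = k, nstart = 5,
                      iter.max = 50)$cluster
      },
      lsa = {
        dense <- as.matrix(x)
        sv <- svd(dense, nu = min(k, n), nv = 0)
        emb <- sv$u * rep(sv$d[seq_len(ncol(sv$u))], each = n)
        stats::kmeans(emb, centers = k, nstart = 5, iter.max = 50)$cluster
      },
      spectral = {
        dense <- as.matrix(x)
        nrm <- sqrt(rowSums(dense^2)); nrm[nrm == 0] <- 1
        dense <- dense / nrm
        s <- dense %*% t(dense)
        s[s < 0] <- 0
        diag(s) <- 0
        deg <- pmax(rowSums(s), 1e-12)
        l <- diag(n) - diag(1 / sqrt(deg)) %*% s %*% diag(1 / sqrt(deg))
        ev <- eigen(l, symmetric = TRUE)
        emb <- ev$vectors[, seq(n, n - k + 1)]
        nrm2 <- sqrt(rowSums(emb^2)); nrm2[nrm2 == 0] <- 1
        stats::kmeans(emb / nrm2, centers = k, nstart = 5,
                      iter.max = 50)$cluster
      },
      agglomerative = {
        cutree(hclust(dist(as.matrix(x)), method = "ward.D2"), k = k)
      },
      lda = {
        .lda_gibbs(x, k, iterations = iterations)$assignment
      },
      dbscan = {
        .simple_dbscan(as.matrix(dist(as.matrix(x))), eps, min_pts)
      },
      optics = {
        .simple_optics(as.matrix(dist(as.matrix(x))), eps, min_pts)
      }
    )
    k_eff <- if (partitional) k else max(assignment, 0L)
    top_terms <- .top_terms_from_centroids(x, assignment,
                                           max(k_eff, 1L), top_m)
    structure(list(method = method, k = k_eff,
                   assignment = as.integer(assignment),
                   top_terms = top_terms, seed = as.integer(seed)),
              class = "latent_topic_model")
  })
}

#' Merge discovered topics into the theme hierarchy
#'
#' Each latent topic is either mapped onto an existing node (whose seed list
#' gains the topic's top terms), added as a new subtheme under a named root,
#' or discarded. The mapping must cover every topic; referencing an unknown
#' topic or node is fatal. Pre-existing nodes are never removed.
#'
#' @param model A `latent_topic_model`.
#' @param hierarchy A [theme_hierarchy()].
#' @param mapping Tibble with columns `topic` (integer), `action` (`"map"`,
#'   `"new"`, `"discard"`), `node` (target or new subtheme name), and for
#'   `action = "new"` a `root` column naming the parent root theme.
#' @return The enlarged `theme_hierarchy`.
#' @export
merge_latent_into_hierarchy <- function(model, hierarchy, mapping) {
  topics <- seq_len(model$k)
  if (!setequal(mapping$topic, topics)) {
    abort("mapping must cover every topic id exactly once")
  }
  if (any(!mapping$action %in% c("map", "new", "discard"))) {
    abort("mapping action must be map/new/discard")
  }
  known <- c(hierarchy$categories$node, hierarchy$subthemes$node)
  for (i in seq_len(nrow(mapping))) {
    act <- mapping$action[i]
    tid <- mapping$topic[i]
    terms <- model$top_terms[[tid]]
    if (act == "discard") next
    if (act == "map") {
      target <- mapping$node[i]
      if (!target %in% known) abort(paste0("unknown hierarchy node: ", target))
      ic <- match(target, hierarchy$categories$node)
      if (!is.na(ic)) {
        hierarchy$categories$seeds[[ic]] <-
          union(hierarchy$categories$seeds[[ic]], terms)
      } else {
        is_ <- match(target, hierarchy$subthemes$node)
        hierarchy$subthemes$seeds[[is_]] <-
          union(hierarchy$subthemes$seeds[[is_]], terms)
      }
    } else { # new subtheme
      root <- mapping$root[i] %||% NA_character_
      if (is.na(root) || !root %in% hierarchy$roots) {
        abort(paste0("new subtheme needs a known root, got: ", root))
      }
      if (mapping$node[i] %in% hierarchy$subthemes$node) {
        is_ <- match(mapping$node[i], hierarchy$subthemes$node)
        hierarchy$subthemes$seeds[[is_]] <-
          union(hierarchy$subthemes$seeds[[is_]], terms)
      } else {
        hierarchy$subthemes <- dplyr::bind_rows(
          hierarchy$subthemes,
          tibble::tibble(node = mapping$node[i], root = root,
                         seeds = list(terms), actionable = TRUE))
      }
    }
  }
  hierarchy
}

#' Score theme prevalence over discussions
#'
#' Prevalence of a theme is the number of unique discussions (threads)
#' containing at least one post assigned that theme.
#'
#' @param assignments Tibble with `post_id` and `node` columns.
#' @param discussion_map Tibble mapping `post_id` to `thread_id`.
#' @return Tibble (`node`, `prevalence`), descending.
#' @export
score_prevalence <- function(assignments, discussion_map) {
  joined <- dplyr::inner_join(assignments, discussion_map, by = "post_id")
  joined |>
    dplyr::distinct(.data$node, .data$thread_id) |>
    dplyr::count(.data$node, name = "prevalence") |>
    dplyr::arrange(dplyr::desc(.data$prevalence), .data$node)
}

#' Categorize themes as major/minor and actionable/nonactionable
#'
#' Major iff prevalence reaches the threshold (inclusive boundary); the
#' actionability flag is passed through from the hierarchy.
#'
#' @param prevalence Tibble from [score_prevalence()].
#' @param threshold Non-negative prevalence threshold (count of
#'   discussions).
#' @param hierarchy A [theme_hierarchy()] supplying actionability flags.
#' @return The prevalence tibble with `status` and `actionable` columns.
#' @export
categorize_theme <- function(prevalence, threshold,
                             hierarchy = theme_hierarchy()) {
  stopifnot(threshold >= 0)
  nodes <- .hierarchy_nodes(hierarchy)
  prevalence$status <- ifelse(prevalence$prevalence >= threshold,
                              "major", "minor")
  prevalence$actionable <- nodes$actionable[
    match(prevalence$node, nodes$node)]
  prevalence
}

#' Build the theme co-mention network
#'
#' Connects two themes when they are co-mentioned in the same discussion;
#' the edge weight is the number of such discussions. Undirected, no
#' self-loops; zero-weight pairs are absent.
#'
#' @inheritParams score_prevalence
#' @return Tibble (`from`, `to`, `weight`) with `from < to`
#'   lexicographically.
#' @export
build_theme_network <- function(assignments, discussion_map) {
  joined <- dplyr::inner_join(assignments, discussion_map, by = "post_id") |>
    dplyr::distinct(.data$thread_id, .data$node)
  per_thread <- split(joined$node, joined$thread_id)
  edges <- list()
  for (nodes in per_thread) {
    if (length(nodes) < 2) next
    nodes <- sort(nodes)
    pr <- utils::combn(nodes, 2)
    edges[[length(edges) + 1]] <- tibble::tibble(from = pr[1, ],
                                                 to = pr[2, ])
  }
  if (length(edges) == 0) {
    return(tibble::tibble(from = character(0), to = character(0),
                          weight = integer(0)))
  }
  dplyr::bind_rows(edges) |>
    dplyr::count(.data$from, .data$to, name = "weight") |>
    dplyr::arrange(dplyr::desc(.data$weight), .data$from, .data$to)
}

#' Export a theme network
#'
#' Writes the co-mention network as a plain edge list (CSV: source, target,
#' weight) and, optionally, GraphML via igraph.
#'
#' @param network Tibble from [build_theme_network()].
#' @param edge_csv Path for the edge-list CSV.
#' @param graphml Optional path for a GraphML export.
#' @return `edge_csv`, invisibly.
#' @export
write_theme_network <- function(network, edge_csv, graphml = NULL) {
  readr::write_csv(
    dplyr::rename(network, source = "from", target = "to"), edge_csv,
    progress = FALSE)
  if (!is.null(graphml)) {
    g <- igraph::graph_from_data_frame(network, directed = FALSE)
    igraph::write_graph(g, graphml, format = "graphml")
  }
  invisible(edge_csv)
}
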