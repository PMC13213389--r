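# Small deterministic fixtures shared across test files.

# path graph v1 - v2 - ... - vn with unit spacing in 1-D
path_graph <- function(n = 5, epsilon = 1) {
  build_knn_graph(cbind(seq_len(n) - 1), k = 1, epsilon = epsilon)
}

# random point cloud graph; labels on a random subset
random_instance <- function(n, d = 3, k = 4, n_labels = 5, seed = 1) {
  withr::with_seed(seed, {
    X <- matrix(rnorm(n * d), n, d)
    g <- build_knn_graph(X, k = k)
    idx <- sort(sample.int(n, n_labels))
    vals <- runif(n_labels)
    list(graph = g, labels = label_set(idx, vals), X = X)
  })
}

# tiny cohort-like tibble with exact linear structure, for protocol tests
toy_cohort <- function(n = 60, seed = 1) {
  withr::with_seed(seed, {
    X <- matrix(rnorm(n * length(biomarker_names())), n)
    colnames(X) <- biomarker_names()
    d <- tibble::as_tibble(X)
    d$ALM <- 10 + 2 * d$height + rnorm(n, sd = 0.01)
    d$BFP <- 30 + d$weight
    d$BMD <- 1 + 0.1 * d$age
    d
  })
}
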