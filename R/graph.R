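#' Gaussian edge weight
#'
#' The similarity kernel `exp(-(d / epsilon)^2)`: a nonnegative, strictly
#' decreasing function of the distance `d`, equal to 1 at distance zero and
#' strictly positive everywhere, so stored weights lie in (0, 1]. `epsilon`
#' is the free scale parameter of the graph.
#'
#' @param dist Nonnegative distance(s).
#' @param epsilon Positive scale parameter.
#' @return Numeric weight(s) in (0, 1].
#' @export
#' @examples
#' edge_weight(0, 1)    # 1
#' edge_weight(1, 1)    # exp(-1)
edge_weight <- function(dist, epsilon) {
  if (!is.numeric(epsilon) || epsilon <= 0) abort("epsilon must be > 0")
  if (any(dist < 0)) abort("distances must be nonnegative")
  pmax(exp(-(dist / epsilon)^2), .Machine$double.xmin)
}

#' Build a symmetric weighted k-NN patient-similarity graph
#'
#' Connects each vertex to its `k` nearest neighbours under Euclidean
#' distance (features are expected to be z-scored beforehand); the edge set
#' is symmetrized by union, so every vertex keeps at least `k` neighbours.
#' Weights come from [edge_weight()]. Distance ties at the k-th neighbour
#' are broken toward the lowest vertex index for determinism. Self-loops are
#' excluded (open neighbourhoods).
#'
#' @param X Numeric matrix (rows = vertices) with no missing values.
#' @param k Number of neighbours, `1 <= k < nrow(X)`.
#' @param epsilon Either `NULL` (default rule: global mean of the k-th
#'   nearest-neighbour distances) or a fixed positive number.
#' @return An object of class `similarity_graph`: list with the sparse
#'   symmetric weight matrix `W`, `n`, `k`, `epsilon`, `epsilon_rule`, and
#'   the vertex degrees.
#' @export
#' @examples
#' g <- build_knn_graph(cbind(c(0, 1, 3)), k = 1, epsilon = 1)
#' g$W
build_knn_graph <- function(X, k, epsilon = NULL) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (anyNA(X)) abort("X must not contain missing values")
  if (k < 1 || k >= n) abort("k must satisfy 1 <= k < n")
  D <- as.matrix(stats::dist(X))
  diag(D) <- Inf

  nb <- matrix(0L, n, k)
  kth <- numeric(n)
  for (i in seq_len(n)) {
    ord <- order(D[i, ], seq_len(n))   # ties toward lower index
    nb[i, ] <- ord[seq_len(k)]
    kth[i] <- D[i, ord[k]]
  }

  rule <- if (is.null(epsilon)) "mean_kth_neighbor_distance" else "fixed"
  if (is.null(epsilon)) {
    epsilon <- mean(kth)
    if (epsilon <= 0) epsilon <- 1  # degenerate all-duplicate input
  }
  if (epsilon <= 0) abort("epsilon must be > 0")

  ii <- rep(seq_len(n), each = k)
  jj <- as.integer(t(nb))
  und <- unique(cbind(pmin(ii, jj), pmax(ii, jj)))
  w <- edge_weight(D[und], epsilon)
  W <- Matrix::sparseMatrix(
    i = c(und[, 1], und[, 2]), j = c(und[, 2], und[, 1]),
    x = c(w, w), dims = c(n, n)
  )
  structure(
    list(
      W = W, n = n, k = as.integer(k), epsilon = epsilon,
      epsilon_rule = rule, degrees = Matrix::colSums(W)
    ),
    class = "similarity_graph"
  )
}

#' @export
print.similarity_graph <- function(x, ...) {
  cat(sprintf(
    "<similarity_graph> n = %d, k = %d, epsilon = %.4g (%s), edges = %d\n",
    x$n, x$k, x$epsilon, x$epsilon_rule, Matrix::nnzero(x$W) / 2
  ))
  invisible(x)
}

#' Open neighbourhood of a vertex
#'
#' Indices of the vertices adjacent to `i` (positive weight, excluding `i`).
#'
#' @param graph A `similarity_graph`.
#' @param i Vertex index.
#' @return Integer vector of neighbour indices.
#' @export
neighborhood <- function(graph, i) {
  W <- graph$W
  ptr <- (W@p[i] + 1):W@p[i + 1]
  if (W@p[i] == W@p[i + 1]) return(integer(0))
  W@i[ptr] + 1L
}

#' Connected components of a similarity graph
#'
#' @param graph A `similarity_graph`.
#' @return List of integer vectors partitioning the vertices.
#' @export
connected_components <- function(graph) {
  ig <- igraph::graph_from_adjacency_matrix(
    graph$W > 0, mode = "undirected", diag = FALSE
  )
  comp <- igraph::components(ig)
  unname(split(seq_len(graph$n), comp$membership))
}

#' Check that every component of the graph is anchored by a label
#'
#' The Dirichlet problem is well-posed on each connected component that
#' contains at least one labeled vertex. In strict mode the graph must be a
#' single component.
#'
#' @param graph A `similarity_graph`.
#' @param labels A [label_set].
#' @param strict If `TRUE`, require exactly one connected component.
#' @return `graph`, invisibly; aborts naming the offending components.
#' @export
ensure_connected <- function(graph, labels, strict = FALSE) {
  comps <- connected_components(graph)
  if (strict && length(comps) > 1) {
    abort(sprintf("graph has %d connected components (strict mode requires 1)",
                  length(comps)))
  }
  unlabeled <- which(!vapply(
    comps, function(cc) any(labels$indices %in% cc), logical(1)
  ))
  if (length(unlabeled) > 0) {
    msg <- vapply(unlabeled, function(ix) {
      cc <- comps[[ix]]
      sprintf("component %d (vertices %s%s)", ix,
              paste(utils::head(cc, 8), collapse = ", "),
              if (length(cc) > 8) ", ..." else "")
    }, character(1))
    abort(paste0(
      "connected component(s) without any labeled vertex: ",
      paste(msg, collapse = "; ")
    ))
  }
  invisible(graph)
}

#' Export / import a similarity graph
#'
#' The weight matrix is written in Matrix Market coordinate format with a
#' JSON sidecar (`<prefix>.json`) carrying `n`, `k`, `epsilon` and the
#' epsilon rule.
#'
#' @param graph A `similarity_graph`.
#' @param prefix Path prefix; files `<prefix>.mtx` and `<prefix>.json` are
#'   written.
#' @return `write_similarity_graph()` returns `prefix` invisibly;
#'   `read_similarity_graph()` returns a `similarity_graph`.
#' @export
write_similarity_graph <- function(graph, prefix) {
  Matrix::writeMM(graph$W, paste0(prefix, ".mtx"))
  jsonlite::write_json(
    list(n = graph$n, k = graph$k, epsilon = graph$epsilon,
         epsilon_rule = graph$epsilon_rule),
    paste0(prefix, ".json"), auto_unbox = TRUE, digits = NA
  )
  invisible(prefix)
}

#' @rdname write_similarity_graph
#' @export
read_similarity_graph <- function(prefix) {
  W <- as(Matrix::readMM(paste0(prefix, ".mtx")), "CsparseMatrix")
  meta <- jsonlite::read_json(paste0(prefix, ".json"))
  structure(
    list(
      W = W, n = meta$n, k = meta$k, epsilon = meta$epsilon,
      epsilon_rule = meta$epsilon_rule, degrees = Matrix::colSums(W)
    ),
    class = "similarity_graph"
  )
}
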