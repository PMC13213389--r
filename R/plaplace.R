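#' Labeled vertex set
#'
#' The training set of the transductive problem: vertex indices whose true
#' target values are remembered, and those values (kg, % or g/cm^2
#' depending on the target).
#'
#' @param indices Distinct, nonempty integer vertex indices.
#' @param values Numeric vector, one value per index.
#' @return An object of class `label_set`.
#' @export
label_set <- function(indices, values) {
  indices <- as.integer(indices)
  if (length(indices) == 0) abort("label set must be nonempty")
  if (anyDuplicated(indices)) abort("label indices must be distinct")
  if (length(indices) != length(values)) {
    abort("one value per labeled index required")
  }
  structure(list(indices = indices, values = as.numeric(values)),
            class = "label_set")
}

#' Solver configuration for the p-Laplacian Dirichlet problem
#'
#' `p` ranges over `[2, Inf]`; the tug-of-war mixing weight is
#' `alpha = 1/(p - 1)`, taken as exactly 0 at `p = Inf`. At `p = 2`
#' (`alpha = 1`) the update is the weighted-mean random-walk step; as `p`
#' grows the min/max (pure tug-of-war) term dominates.
#'
#' @param p Real in `[2, Inf]` (use `Inf` for the infinity-Laplacian limit).
#' @param tol Convergence tolerance on the sup-norm change of one sweep,
#'   relative to the labeled value range.
#' @param max_iter Sweep budget.
#' @return An object of class `plap_config`.
#' @export
plap_config <- function(p = 2, tol = 1e-6, max_iter = 1e5) {
  if (!is.numeric(p) || p < 2) abort("p must lie in [2, Inf]")
  if (tol <= 0) abort("tol must be > 0")
  if (max_iter < 1) abort("max_iter must be >= 1")
  alpha <- if (is.infinite(p)) 0 else 1 / (p - 1)
  structure(
    list(p = p, alpha = alpha, tol = tol, max_iter = as.integer(max_iter)),
    class = "plap_config"
  )
}

#' One dynamic-programming-principle update at a vertex
#'
#' Evaluates the tug-of-war fixed-point map at an unlabeled vertex `i`:
#' `alpha/d_i * sum_j w_ij u(j) + (1 - alpha)/2 * (min_N u + max_N u)`,
#' with the min and max taken over the open neighbourhood of `i` using the
#' current values `u` (labeled neighbours contribute their pinned values).
#'
#' @param u Current value vector over all vertices.
#' @param i Vertex index with nonempty neighbourhood.
#' @param graph A `similarity_graph`.
#' @param alpha Mixing weight in `[0, 1]` (`1/(p - 1)`).
#' @return The updated value at `i`.
#' @export
#' @examples
#' g <- build_knn_graph(cbind(c(0, 1, 2)), k = 1, epsilon = 1)
#' dpp_update(c(0, 0.5, 1), 2, g, alpha = 0.5)
dpp_update <- function(u, i, graph, alpha) {
  if (alpha < 0 || alpha > 1) abort("alpha must lie in [0, 1]")
  nb <- neighborhood(graph, i)
  if (length(nb) == 0) abort(sprintf("vertex %d is isolated", i))
  w <- graph$W[nb, i]
  un <- u[nb]
  alpha * sum(w * un) / graph$degrees[i] +
    (1 - alpha) / 2 * (min(un) + max(un))
}

#' Solve the game-theoretic p-Laplacian Dirichlet problem
#'
#' Pins the labeled vertices to their values and iterates [dpp_update()]
#' over the unlabeled vertices in Gauss-Seidel sweeps (deterministic vertex
#' order) until the sup-norm change of a sweep falls below `tol` times the
#' labeled value range. Every update is a convex combination of neighbour
#' values, so iterates respect the maximum principle throughout. Unlabeled
#' vertices start at the mean of the labels.
#'
#' @param graph A `similarity_graph`.
#' @param labels A [label_set]; every connected component must contain at
#'   least one labeled vertex.
#' @param config A [plap_config].
#' @return An object of class `plap_solution` with fields `u`, `labeled`,
#'   `g`, `p`, `alpha`, `iterations`, `residual`, `converged`.
#' @export
#' @examples
#' g <- build_knn_graph(cbind(0:4), k = 1, epsilon = 1)
#' sol <- solve_plaplace(g, label_set(c(1, 5), c(0, 1)), plap_config(p = 2))
#' sol$u
solve_plaplace <- function(graph, labels, config = plap_config()) {
  ensure_connected(graph, labels)
  n <- graph$n
  g <- labels$values
  range_g <- diff(range(g))
  tol_abs <- config$tol * max(range_g, 1e-12)

  u0 <- rep(mean(g), n)
  u0[labels$indices] <- g
  unlabeled <- setdiff(seq_len(n), labels$indices)

  if (length(unlabeled) == 0) {
    fit <- list(u = u0, iterations = 0L, residual = 0, converged = TRUE)
  } else {
    W <- graph$W
    fit <- plap_sweep_cpp(
      W@p, W@i, W@x, graph$degrees, unlabeled - 1L, u0,
      config$alpha, tol_abs, config$max_iter
    )
  }
  if (!fit$converged && length(unlabeled) > 0) {
    warn(sprintf(
      "solver did not converge in %d sweeps (residual %.3g > tol %.3g)",
      config$max_iter, fit$residual, tol_abs
    ))
  }
  labeled <- logical(n)
  labeled[labels$indices] <- TRUE
  gfull <- rep(NA_real_, n)
  gfull[labels$indices] <- g
  structure(
    list(
      u = fit$u, labeled = labeled, g = gfull,
      p = config$p, alpha = config$alpha,
      iterations = fit$iterations, residual = fit$residual,
      tol = tol_abs, converged = fit$converged
    ),
    class = "plap_solution"
  )
}

#' @export
print.plap_solution <- function(x, ...) {
  cat(sprintf(
    "<plap_solution> p = %s (alpha = %.4g), n = %d (%d labeled), %s in %d sweeps (residual %.3g)\n",
    format(x$p), x$alpha, length(x$u), sum(x$labeled),
    if (x$converged) "converged" else "NOT converged",
    x$iterations, x$residual
  ))
  invisible(x)
}

#' Direct harmonic solution (p = 2 oracle)
#'
#' Solves the random-walk harmonic system
#' `u(i) = (1/d_i) * sum_j w_ij u(j)` on the unlabeled vertices with the
#' labels pinned, by a direct sparse linear solve of the graph Laplacian.
#' Serves as an independent cross-check of the iterative solver at `p = 2`.
#'
#' @inheritParams solve_plaplace
#' @return Numeric value vector over all vertices.
#' @export
harmonic_oracle <- function(graph, labels) {
  ensure_connected(graph, labels)
  n <- graph$n
  unl <- setdiff(seq_len(n), labels$indices)
  u <- numeric(n)
  u[labels$indices] <- labels$values
  if (length(unl) > 0) {
    W <- graph$W
    L <- Matrix::Diagonal(n, graph$degrees) - W
    rhs <- W[unl, labels$indices, drop = FALSE] %*% labels$values
    u[unl] <- as.numeric(Matrix::solve(L[unl, unl, drop = FALSE], rhs))
  }
  u
}

#' Write a solved instance as CSV
#'
#' One row per vertex: id, labeled flag, pinned value (empty when
#' unlabeled) and prediction.
#'
#' @param solution A `plap_solution`.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_solution_csv <- function(solution, path) {
  readr::write_csv(tidy(solution), path, na = "")
  invisible(path)
}
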