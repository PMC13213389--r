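#' Normalised root-mean-square error, in percent
#'
#' `100 * sqrt(mean((y_pred - y_true)^2)) / sqrt(mean(y_true^2))`: the RMSE
#' normalised by the root mean square of the true values, which makes
#' errors comparable across targets of different magnitude and units.
#'
#' @param y_true Numeric vector of true values (not all zero).
#' @param y_pred Numeric vector of predictions, same length.
#' @return A nonnegative percentage.
#' @export
#' @examples
#' rmse_percent(c(2, 2), c(1, 1))  # 50
rmse_percent <- function(y_true, y_pred) {
  if (length(y_true) == 0 || length(y_true) != length(y_pred)) {
    abort("y_true and y_pred must have equal, nonzero length")
  }
  denom <- sqrt(mean(y_true^2))
  if (denom == 0) abort("y_true is identically zero: normalisation undefined")
  100 * sqrt(mean((y_pred - y_true)^2)) / denom
}

#' Cross-validation plan
#'
#' `standard` mode trains on K-1 folds and tests on the held-out fold
#' (training fraction (K-1)/K); `modified` mode trains on a single fold and
#' tests on the other K-1 (training fraction 1/K), the label-efficiency
#' protocol. Each of the `repeats` runs re-randomises the fold assignment.
#'
#' @param K Fold count, `K >= 2`.
#' @param mode `"standard"` or `"modified"`.
#' @param repeats Number of independent runs (default 10).
#' @param seed Base RNG seed for fold assignment.
#' @return An object of class `cv_plan`.
#' @export
#' @examples
#' cv_plan(5, "modified")$training_fraction  # 0.2
cv_plan <- function(K, mode = c("standard", "modified"), repeats = 10,
                    seed = 1) {
  mode <- match.arg(mode)
  if (K < 2) abort("K must be >= 2")
  if (repeats < 1) abort("repeats must be >= 1")
  frac <- if (mode == "standard") (K - 1) / K else 1 / K
  structure(
    list(K = as.integer(K), mode = mode, repeats = as.integer(repeats),
         seed = as.integer(seed), training_fraction = frac),
    class = "cv_plan"
  )
}

#' Random K-fold splits for one run
#'
#' Partitions `1..n` into K near-equal folds, seeded deterministically by
#' `(plan$seed, run)`. In standard mode each fold is the test set once; in
#' modified mode each fold is the training set once and the remaining K-1
#' folds are the test set.
#'
#' @param n Number of observations, `n >= K`.
#' @param plan A [cv_plan].
#' @param run Run index (1-based).
#' @return List of `K` elements, each `list(train =, test =)`.
#' @export
make_splits <- function(n, plan, run = 1) {
  K <- plan$K
  if (K > n) abort("K must not exceed n")
  derived <- (as.numeric(plan$seed) * 131071 + run * 524287) %%
    .Machine$integer.max
  folds <- withr::with_seed(as.integer(derived), {
    perm <- sample.int(n)
    unname(split(perm, rep(seq_len(K), length.out = n)))  # sizes n/K +- 1
  })
  lapply(seq_len(K), function(i) {
    if (plan$mode == "standard") {
      list(train = sort(unlist(folds[-i])), test = sort(folds[[i]]))
    } else {
      list(train = sort(folds[[i]]), test = sort(unlist(folds[-i])))
    }
  })
}

#' Run the p-Laplacian label-efficiency experiment
#'
#' For every combination of run, fold, `k` and `p`: z-scores all vertices
#' (the graph is transductive, so scaling uses every vertex), optionally
#' restricts to the ten most target-correlated biomarkers (`variant =
#' "plap2"`), builds the k-NN similarity graph over all vertices, pins the
#' training-fold labels, solves the Dirichlet problem and scores
#' [rmse_percent()] on the test fold only.
#'
#' In `feature_mode = "fold"` the ten features of `plap2` are recomputed on
#' each training fold (leak-free); `feature_mode = "fixed"` uses the
#' reference lists of [reference_correlations()] for the given dataset.
#'
#' @param cohort Clean cohort tibble (no missing cells) containing the
#'   biomarkers and the target column.
#' @param target `"ALM"`, `"BFP"` or `"BMD"`.
#' @param dataset Label for the results table (`"male"`, `"female"`,
#'   `"combined"`).
#' @param variant `"plap1"` (all 44 biomarkers) or `"plap2"` (top ten).
#' @param p_grid Numeric vector of p values in `[2, Inf]`.
#' @param k_grid Integer vector of neighbour counts.
#' @param cv A [cv_plan].
#' @param feature_mode `"fold"` or `"fixed"` (only used by `plap2`).
#' @param config A [plap_config]; its `p` is overridden by `p_grid`.
#' @return Tibble of class `plap_results` with one row per
#'   `(target, dataset, variant, p, k, training_percent, run, fold)` cell.
#' @export
run_plaplace_experiment <- function(cohort, target,
                                    dataset = "combined",
                                    variant = c("plap1", "plap2"),
                                    p_grid = c(seq(2, 10, by = 0.5), Inf),
                                    k_grid = seq(5, 60, by = 5),
                                    cv = cv_plan(5, "standard"),
                                    feature_mode = c("fold", "fixed"),
                                    config = plap_config()) {
  variant <- match.arg(variant)
  feature_mode <- match.arg(feature_mode)
  target <- match.arg(target, c("ALM", "BFP", "BMD"))
  feats <- intersect(biomarker_names(), names(cohort))
  if (anyNA(cohort[, c(feats, target)])) {
    abort("cohort must be clean (no missing cells); see clean_cohort()")
  }
  y <- cohort[[target]]
  n <- nrow(cohort)
  if (max(k_grid) >= n) abort("k_grid values must be < nrow(cohort)")
  if (any(p_grid < 2)) abort("p_grid values must lie in [2, Inf]")
  Z_all <- zscore_apply(zscore_fit(cohort[, feats]), cohort[, feats])
  training_percent <- 100 * cv$training_fraction

  fixed_feats <- if (variant == "plap1") {
    feats
  } else if (feature_mode == "fixed") {
    reference_correlations(target, dataset)$biomarker
  } else {
    NULL  # recomputed per training fold
  }

  # graph depends only on (feature set, k); cache when fold-independent
  graph_for <- function(cols, k) build_knn_graph(Z_all[, cols], k)
  cache <- new.env(parent = emptyenv())
  cached_graph <- function(cols, k) {
    key <- paste0("k", k)
    if (is.null(cache[[key]])) cache[[key]] <- graph_for(cols, k)
    cache[[key]]
  }

  rows <- list()
  for (run in seq_len(cv$repeats)) {
    splits <- make_splits(n, cv, run)
    for (fold in seq_along(splits)) {
      sp <- splits[[fold]]
      cols <- fixed_feats %||%
        top_m(pearson_rank(Z_all[sp$train, , drop = FALSE], y[sp$train]), 10)
      labels <- label_set(sp$train, y[sp$train])
      for (k in k_grid) {
        graph <- if (is.null(fixed_feats)) graph_for(cols, k)
                 else cached_graph(fixed_feats, k)
        for (p in p_grid) {
          cfg <- plap_config(p = p, tol = config$tol,
                             max_iter = config$max_iter)
          sol <- solve_plaplace(graph, labels, cfg)
          rows[[length(rows) + 1L]] <- tibble::tibble(
            target = target, dataset = dataset, variant = variant,
            p = p, k = k, training_percent = training_percent,
            run = run, fold = fold,
            rmse_percent = rmse_percent(y[sp$test], sol$u[sp$test])
          )
        }
      }
    }
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("plap_results", class(out))
  out
}

#' Average a results table over runs and folds
#'
#' @param results A results tibble from [run_plaplace_experiment()] or
#'   [run_baseline_experiment()].
#' @return Tibble with one row per remaining cell and column
#'   `mean_rmse_percent`.
#' @export
aggregate_results <- function(results) {
  dplyr::group_by(
    results, .data$target, .data$dataset, .data$variant, .data$p, .data$k,
    .data$training_percent
  ) |>
    dplyr::summarise(
      mean_rmse_percent = mean(.data$rmse_percent), .groups = "drop"
    )
}

#' Best (p, k) cell per training fraction
#'
#' Argmin of the averaged error; ties break toward smaller `p`, then
#' smaller `k`.
#'
#' @inheritParams aggregate_results
#' @return Tibble with one row per `(target, dataset, variant,
#'   training_percent)`.
#' @export
best_cells <- function(results) {
  agg <- aggregate_results(results)
  dplyr::group_by(
    agg, .data$target, .data$dataset, .data$variant, .data$training_percent
  ) |>
    dplyr::arrange(.data$mean_rmse_percent, .data$p, .data$k,
                   .by_group = TRUE) |>
    dplyr::slice(1) |>
    dplyr::ungroup()
}

#' Large-p asymptotic sweep
#'
#' Runs the modified-CV experiment at a fixed training fraction over an
#' increasing list of p values and a few neighbour counts, and reports the
#' successive RMSE differences that document convergence of the solution
#' family as p grows.
#'
#' @inheritParams run_plaplace_experiment
#' @param k_values Neighbour counts (default 10, 30, 50).
#' @param p_values Increasing p values (max may be `Inf`).
#' @param K Fold count of the modified plan (default 5, i.e. 20% training).
#' @param repeats Runs to average over.
#' @param seed Base seed.
#' @return Aggregated tibble with columns `p`, `k`, `mean_rmse_percent`
#'   and `delta` (difference from the previous p at the same k).
#' @export
asymptotic_sweep <- function(cohort, target, dataset = "combined",
                             variant = c("plap1", "plap2"),
                             k_values = c(10, 30, 50),
                             p_values = c(2, 3, 5, 10, 50, 100, 200),
                             K = 5, repeats = 2, seed = 1, ...) {
  if (is.unsorted(p_values)) abort("p_values must be increasing")
  variant <- match.arg(variant)
  res <- run_plaplace_experiment(
    cohort, target, dataset = dataset, variant = variant,
    p_grid = p_values, k_grid = k_values,
    cv = cv_plan(K, "modified", repeats = repeats, seed = seed), ...
  )
  aggregate_results(res) |>
    dplyr::group_by(.data$k) |>
    dplyr::arrange(.data$p, .by_group = TRUE) |>
    dplyr::mutate(delta = .data$mean_rmse_percent -
                    dplyr::lag(.data$mean_rmse_percent)) |>
    dplyr::ungroup()
}
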