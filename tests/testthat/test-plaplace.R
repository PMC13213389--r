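test_that("configuration maps p to the tug-of-war weight", {
  expect_equal(plap_config(2)$alpha, 1)
  expect_equal(plap_config(3)$alpha, 0.5)
  expect_equal(plap_config(Inf)$alpha, 0)
  expect_error(plap_config(1.5), "p must lie")
  expect_error(plap_config(2, tol = 0), "tol")
})

test_that("the DPP update mixes weighted mean and midrange", {
  # star: center vertex 1 adjacent to 2 and 3, unit weights
  X <- cbind(c(0, 1, -1))
  g <- build_knn_graph(X, k = 2, epsilon = 1e6)  # weights ~ 1
  u <- c(NA, 0, 1)
  # alpha = 0.5: 0.5 * (0+1)/2 + 0.25 * (0+1) = 0.5
  expect_equal(dpp_update(u, 1, g, alpha = 0.5), 0.5, tolerance = 1e-6)
  # alpha = 1 (p = 2): weighted mean only
  expect_equal(dpp_update(u, 1, g, alpha = 1), 0.5, tolerance = 1e-6)
  # alpha = 0 (p = Inf): midrange of neighbours
  u3 <- c(NA, 0.2, 0.8)
  expect_equal(dpp_update(u3, 1, g, alpha = 0), 0.5, tolerance = 1e-12)
  expect_error(dpp_update(u, 1, g, alpha = 2), "alpha")
})

test_that("alpha = 1 reduces the update to the weighted neighbour mean", {
  inst <- random_instance(20, k = 3, seed = 2)
  withr::with_seed(5, u <- runif(20))
  i <- 7
  nb <- neighborhood(inst$graph, i)
  w <- inst$graph$W[nb, i]
  expect_equal(dpp_update(u, i, inst$graph, 1), sum(w * u[nb]) / sum(w),
               tolerance = 1e-12)
})

test_that("constant labels give the constant solution in one sweep", {
  inst <- random_instance(30, k = 3, n_labels = 4, seed = 3)
  labels <- label_set(inst$labels$indices, rep(2.5, 4))
  sol <- solve_plaplace(inst$graph, labels, plap_config(3))
  expect_equal(sol$u, rep(2.5, 30))
  expect_equal(sol$iterations, 1)
  expect_true(sol$converged)
})

test_that("the path Dirichlet problem is linear for p = 2 and p = Inf", {
  g <- path_graph(5)
  labels <- label_set(c(1, 5), c(0, 1))
  for (p in c(2, Inf)) {
    sol <- solve_plaplace(g, labels, plap_config(p, tol = 1e-9))
    expect_equal(sol$u, c(0, 0.25, 0.5, 0.75, 1), tolerance = 1e-6)
  }
})

test_that("labeled vertices are pinned exactly", {
  inst <- random_instance(40, k = 4, n_labels = 6, seed = 4)
  for (p in c(2, 3.5, 10, Inf)) {
    sol <- solve_plaplace(inst$graph, inst$labels, plap_config(p))
    expect_identical(sol$u[inst$labels$indices], inst$labels$values)
  }
})

test_that("solutions obey the maximum principle", {
  for (seed in 1:8) {
    inst <- random_instance(35, k = 4, n_labels = 5, seed = seed)
    for (p in c(2, 4, Inf)) {
      sol <- solve_plaplace(inst$graph, inst$labels, plap_config(p))
      expect_gte(min(sol$u), min(inst$labels$values) - 1e-9)
      expect_lte(max(sol$u), max(inst$labels$values) + 1e-9)
    }
  }
})

test_that("the solved DPP fixed point holds at every unlabeled vertex", {
  inst <- random_instance(30, k = 4, n_labels = 5, seed = 6)
  cfg <- plap_config(4, tol = 1e-10)
  sol <- solve_plaplace(inst$graph, inst$labels, cfg)
  unl <- which(!sol$labeled)
  resid <- vapply(unl, function(i) {
    dpp_update(sol$u, i, inst$graph, cfg$alpha) - sol$u[i]
  }, numeric(1))
  expect_lt(max(abs(resid)), 1e-7)
})

test_that("the DPP operator is monotone in the boundary data", {
  for (seed in 1:5) {
    inst <- random_instance(30, k = 4, n_labels = 5, seed = seed)
    g1 <- inst$labels$values
    withr::with_seed(seed + 100, bump <- runif(5, 0, 0.5))
    l_hi <- label_set(inst$labels$indices, g1 + bump)
    for (p in c(2, 5, Inf)) {
      lo <- solve_plaplace(inst$graph, inst$labels,
                           plap_config(p, tol = 1e-8))
      hi <- solve_plaplace(inst$graph, l_hi, plap_config(p, tol = 1e-8))
      expect_true(all(hi$u >= lo$u - 1e-6))
    }
  }
})

test_that("solutions are equivariant under affine label maps", {
  inst <- random_instance(30, k = 4, n_labels = 5, seed = 9)
  a <- 3.2
  b <- -1.7
  scaled <- label_set(inst$labels$indices, a * inst$labels$values + b)
  for (p in c(2, 6, Inf)) {
    base <- solve_plaplace(inst$graph, inst$labels,
                           plap_config(p, tol = 1e-9))
    tr <- solve_plaplace(inst$graph, scaled, plap_config(p, tol = 1e-9))
    expect_equal(tr$u, a * base$u + b, tolerance = 1e-5)
  }
})

test_that("p = 2 matches the direct harmonic solve", {
  for (seed in 1:10) {
    inst <- random_instance(20 + 3 * seed, k = 4, n_labels = 5, seed = seed)
    ho <- harmonic_oracle(inst$graph, inst$labels)
    it <- solve_plaplace(inst$graph, inst$labels,
                         plap_config(2, tol = 1e-10))
    expect_lt(max(abs(ho - it$u)), 1e-5)
  }
  # oracle fixtures
  g <- path_graph(5)
  expect_equal(harmonic_oracle(g, label_set(c(1, 5), c(0, 1))),
               c(0, 0.25, 0.5, 0.75, 1), tolerance = 1e-10)
  expect_equal(harmonic_oracle(g, label_set(c(1, 5), c(3, 3))), rep(3, 5),
               tolerance = 1e-10)
})

test_that("large-p solutions stabilise toward the infinity-harmonic limit", {
  inst <- random_instance(40, k = 5, n_labels = 6, seed = 12)
  cfg <- function(p) plap_config(p, tol = 1e-8)
  u100 <- solve_plaplace(inst$graph, inst$labels, cfg(100))$u
  u200 <- solve_plaplace(inst$graph, inst$labels, cfg(200))$u
  uinf <- solve_plaplace(inst$graph, inst$labels, cfg(Inf))$u
  rng <- diff(range(inst$labels$values))
  # the DPP operators at p = 100 and 200 differ by O(alpha) ~ 0.005, so
  # their fixed points must already be within ~1% of the label range
  expect_lt(max(abs(u100 - u200)), 0.01 * rng)
  expect_lte(max(abs(u200 - uinf)), max(abs(u100 - uinf)) + 1e-9)
})

test_that("solver reports non-convergence without failing", {
  inst <- random_instance(40, k = 4, n_labels = 5, seed = 13)
  expect_warning(
    sol <- solve_plaplace(inst$graph, inst$labels,
                          plap_config(2, tol = 1e-12, max_iter = 2)),
    "did not converge"
  )
  expect_false(sol$converged)
  expect_equal(sol$iterations, 2)
  expect_gt(sol$residual, 0)
})

test_that("tidy and glance expose the solution and diagnostics", {
  inst <- random_instance(20, k = 3, n_labels = 4, seed = 14)
  sol <- solve_plaplace(inst$graph, inst$labels, plap_config(3))
  td <- tidy(sol)
  expect_equal(nrow(td), 20)
  expect_equal(sum(td$labeled), 4)
  expect_equal(td$u[td$labeled], inst$labels$values)
  gl <- glance(sol)
  expect_equal(gl$p, 3)
  expect_equal(gl$alpha, 0.5)
  expect_true(gl$converged)
})
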