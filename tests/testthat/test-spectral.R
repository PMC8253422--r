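test_that("comparison matrix is the data minus the null expectation", {
  # W = <P> gives the zero matrix, all eigenvalues 0
  set.seed(20)
  net <- random_weighted_network(7, p = 0.5)
  C0 <- comparison_matrix(net$W, net$W)
  expect_true(all(C0 == 0))

  # 2-node toy: C = [[0,1],[1,0]] has eigenvalues +1 and -1
  W <- matrix(c(0, 2, 2, 0), 2)
  P <- matrix(c(0, 1, 1, 0), 2)
  ev <- eigen(comparison_matrix(W, P), symmetric = TRUE, only.values = TRUE)$values
  expect_equal(ev, c(1, -1))

  # with the configuration-model expectation, C is the modularity matrix
  B <- net$W - outer(strengths(net), strengths(net)) / sum(strengths(net))
  diag(B) <- 0
  expect_equal(comparison_matrix(net$W, wcm_expectation(net)), B,
               ignore_attr = TRUE)

  expect_error(comparison_matrix(W, matrix(0, 3, 3)), "shape")
})

test_that("eigendecomposition bookkeeping: trace identity and ordering", {
  set.seed(21)
  syn <- small_modular_synthetic(seed = 30, n = 45, groups = 3, lambda_s = 30)
  ens <- generate_ensemble(syn$network, N = 10, seed = 1)
  est <- spectral_estimate(syn$network, ens)
  expect_lt(abs(sum(est$eigenvalues) - sum(diag(est$C))), 1e-8)
  expect_true(all(diff(est$eigenvalues) <= 0))
  # retained eigenvectors are orthonormal
  if (est$d_upper > 1) {
    G <- crossprod(est$vectors_upper)
    expect_equal(G, diag(est$d_upper), tolerance = 1e-10, ignore_attr = TRUE)
  }
})

test_that("null spectrum bounds are means of the sampled extremes", {
  set.seed(22)
  net <- random_weighted_network(10, p = 0.5)
  ens <- generate_ensemble(net, N = 1, seed = 5)
  b1 <- null_spectrum_bounds(ens)
  # N = 1: the bound is that sample's extreme eigenvalue
  ev <- eigen(ens$samples[[1]] - ens$P_expect, symmetric = TRUE,
              only.values = TRUE)$values
  expect_equal(b1$lambda_max, max(ev))
  expect_equal(b1$lambda_min, min(ev))

  # degenerate ensemble identical to <P>: both bounds zero
  ens0 <- ens
  ens0$samples <- list(ens$P_expect, ens$P_expect)
  ens0$N <- 2
  b0 <- null_spectrum_bounds(ens0)
  expect_equal(b0$lambda_max, 0)
  expect_equal(b0$lambda_min, 0)

  # the mean bound lies between the per-sample extremes
  ens2 <- generate_ensemble(net, N = 20, seed = 6)
  b2 <- null_spectrum_bounds(ens2)
  expect_gte(b2$lambda_max, min(b2$max_samples))
  expect_lte(b2$lambda_max, max(b2$max_samples))

  # percentile mode returns the upper tail quantile, above the mean typically
  bp <- null_spectrum_bounds(ens2, mode = "percentile", alpha = 0.05)
  expect_equal(bp$lambda_max,
               unname(stats::quantile(b2$max_samples, 0.95)))
})

test_that("dimension counting uses strict bounds and is monotone in the bound", {
  values <- c(5, 3, 1, -1, -4)
  vectors <- diag(5)
  mk_bounds <- function(up, lo) structure(
    list(lambda_max = up, lambda_min = lo, max_samples = up, min_samples = lo,
         mode = "mean", alpha = 0.05), class = "null_bounds")

  est <- detect_dimensions(values, vectors, mk_bounds(2, -2))
  expect_equal(est$d_upper, 2)
  expect_equal(est$d_lower, 1)
  expect_equal(est$values_upper, c(5, 3))
  expect_equal(est$values_lower, -4)

  # a tie falls to the null model
  est_tie <- detect_dimensions(values, vectors, mk_bounds(3, -4))
  expect_equal(est_tie$d_upper, 1)
  expect_equal(est_tie$d_lower, 0)

  # raising the upper bound can only decrease d_upper
  d_seq <- vapply(c(0, 2, 4, 6),
                  function(u) detect_dimensions(values, vectors,
                                                mk_bounds(u, -10))$d_upper, 1L)
  expect_true(all(diff(d_seq) <= 0))

  # everything inside the bounds: no departure from the null model
  est0 <- detect_dimensions(values, vectors, mk_bounds(10, -10))
  expect_equal(est0$d_upper + est0$d_lower, 0)
})

test_that("departure statistic measures the normalised exceedance", {
  expect_equal(departure_statistic(2, 2), 0)
  expect_equal(departure_statistic(4, 2), 0.5)
  expect_lt(departure_statistic(1, 2), 0)
  expect_error(departure_statistic(0, 1), "undefined")
})

test_that("node projection separates planted modules and is orthogonal", {
  # two planted modules on a 20-node toy: the leading coordinate's sign
  # separates them
  set.seed(23)
  syn <- small_modular_synthetic(seed = 31, n = 20, groups = 2,
                                 p_within = 0.9, p_between = 0.05,
                                 lambda_s = 40)
  ens <- generate_ensemble(syn$network, N = 20, seed = 2)
  est <- spectral_estimate(syn$network, ens)
  expect_gte(est$d_upper, 1)
  coords <- project_nodes(est)
  side <- unname(coords[, 1] > 0)
  lab1 <- unname(syn$labels == 1)
  expect_true(identical(side, lab1) || identical(side, !lab1))
  # coordinate columns are mutually orthogonal
  if (ncol(coords) > 1) {
    G <- crossprod(coords)
    expect_lt(max(abs(G[upper.tri(G)])), 1e-8)
  }
  # d = 1 coordinates are proportional to the leading eigenvector
  one <- project_nodes(est)[, 1]
  expect_equal(unname(one), unname(est$values_upper[1] * est$vectors_upper[, 1]))

  # no retained dimensions: projection refuses
  est0 <- est; est0$vectors_upper <- est$vectors_upper[, 0, drop = FALSE]
  expect_error(project_nodes(est0), "no structure")
})

test_that("fixing the ensemble seed makes the whole estimate deterministic", {
  syn <- small_modular_synthetic(seed = 32, n = 45, groups = 3, lambda_s = 30)
  run <- function() {
    ens <- generate_ensemble(syn$network, N = 10, seed = 77)
    est <- spectral_estimate(syn$network, ens)
    list(est$eigenvalues, est$bounds$lambda_max, est$d_upper, est$vectors_upper)
  }
  expect_identical(run(), run())
})
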