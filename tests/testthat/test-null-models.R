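test_that("configuration-model expectation preserves strengths", {
  # s = (1, 1, 2): <P> between a strength-1 and the strength-2 node
  # is 1*2/4 = 0.5
  net <- edge_list_network(c("a", "b"), c("c", "c"), c(1, 1))  # s = (1, 2, 1)
  P <- wcm_expectation(net)
  expect_equal(unname(P["a", "c"]), 0.5)
  expect_equal(P, t(P))
  expect_equal(unname(diag(P)), rep(0, 3))

  # row sums plus the excluded diagonal term s_i^2/sum(s) recover s_i
  set.seed(5)
  net2 <- random_weighted_network(9, p = 0.5)
  s <- strengths(net2)
  P2 <- wcm_expectation(net2)
  expect_equal(rowSums(P2) + s^2 / sum(s), s)

  # uniform strengths give equal off-diagonal entries
  P3 <- wcm_expectation(two_cliques_network(3))
  off <- P3[upper.tri(P3)]
  expect_equal(max(off) - min(off), 0)

  # literal total-weight denominator is twice the strength-sum one
  expect_equal(wcm_expectation(net2, denominator = "total_weight"), 2 * P2)
})

test_that("sparse adjacency sampling matches the degree-sequence probabilities", {
  # two nodes, one link: p = k1 k2 / 2m = 1/2 per draw
  pair <- edge_list_network("a", "b", 1)
  set.seed(6)
  draws <- replicate(4000, sample_sparse_adjacency(pair)[1, 2])
  expect_equal(mean(draws), 0.5, tolerance = 0.05)

  # hub pair with k_i k_j > 2m is always linked (probability clipped at 1)
  W2 <- matrix(0, 5, 5)
  W2[1, 2:5] <- 1; W2[2, 3:5] <- 1
  W2 <- W2 + t(W2)
  net <- weighted_network(W2)  # k = (4, 4, 2, 2, 2), m = 7; k1 k2 / 2m = 8/7
  set.seed(7)
  hits <- replicate(300, sample_sparse_adjacency(net)[1, 2])
  expect_true(all(hits == 1))

  # Monte-Carlo expected link count equals sum of pairwise probabilities
  set.seed(8)
  net6 <- random_weighted_network(6, p = 0.5)
  k6 <- degrees(net6); m6 <- sum(k6) / 2
  ut <- which(upper.tri(diag(6)), arr.ind = TRUE)
  expected_m <- sum(pmin(1, k6[ut[, 1]] * k6[ut[, 2]] / (2 * m6)))
  mc <- replicate(10000, sum(sample_sparse_adjacency(net6)) / 2)
  se <- stats::sd(mc) / sqrt(length(mc))
  expect_lt(abs(mean(mc) - expected_m), 3 * se + 1e-9)
})

test_that("Poisson weight placement distributes N_link in expectation", {
  n <- 5
  A <- 1 - diag(n)
  s <- rep(4, n)
  # uniform strengths on a complete adjacency: identical rates summing to N_link
  set.seed(9)
  reps <- replicate(5000, {
    P <- place_weights_poisson(s, A, N_link = 10)
    c(total = sum(P) / 2, w12 = P[1, 2])
  })
  expect_equal(mean(reps["total", ]), 10, tolerance = 0.05)
  expect_equal(mean(reps["w12", ]), 10 / choose(n, 2), tolerance = 0.1)

  # baseline weight adds 1 to every link deterministically
  P0 <- place_weights_poisson(s, A, N_link = 0, baseline = 1)
  expect_true(all(P0[upper.tri(P0)] == 1))

  expect_error(place_weights_poisson(s, matrix(0, n, n), N_link = 5), "no links")
})

test_that("stub matching conserves weight and matches Poisson placement per pair", {
  # s = (1, 1): the single link is forced
  expect_equal(stub_matching(c(1, 1))[1, 2], 1)
  expect_error(stub_matching(c(1, 2)), "even")

  # conservation on every draw
  set.seed(10)
  s <- c(4, 6, 2, 8, 4)
  totals <- replicate(200, sum(stub_matching(s)) / 2)
  expect_true(all(totals == sum(s) / 2))

  # per-node mean strength matches the analytic multinomial expectation
  # (self-pair exclusion biases small heterogeneous networks slightly, so
  # the oracle is the exact formula, not s itself)
  tot <- sum(s)
  denom <- (tot^2 - sum(s^2)) / 2
  expected_strength <- (tot / 2) * s * (tot - s) / denom
  draws <- replicate(4000, rowSums(stub_matching(s)))
  err <- abs(rowMeans(draws) - expected_strength)
  se <- apply(draws, 1, stats::sd) / sqrt(ncol(draws))
  expect_true(all(err < 3 * se))
  # ... and for uniform strengths the expectation is s exactly
  su <- rep(4, 5)
  draws_u <- replicate(2000, rowSums(stub_matching(su)))
  err_u <- abs(rowMeans(draws_u) - su)
  se_u <- apply(draws_u, 1, stats::sd) / sqrt(ncol(draws_u))
  expect_true(all(err_u < 3 * se_u))

  # oracle equivalence: Poisson and multinomial placement agree per pair
  n <- 6
  A <- 1 - diag(n)
  s6 <- c(4, 4, 6, 2, 8, 4)
  set.seed(12)
  po <- 0; st <- 0
  R <- 4000
  for (r in seq_len(R)) {
    po <- po + place_weights_poisson(s6, A, N_link = sum(s6) / 2)
    st <- st + stub_matching(s6)
  }
  po <- po / R; st <- st / R
  ut <- upper.tri(po)
  # per-pair means: lambda_ij are ~1, so 3 SE over 4000 reps is ~0.05
  se_pair <- sqrt(pmax(po[ut], 0.01) / R) + sqrt(pmax(st[ut], 0.01) / R)
  expect_true(all(abs(po[ut] - st[ut]) < 3 * se_pair))
})

test_that("ensembles are reproducible and respect the model contracts", {
  set.seed(13)
  syn <- small_modular_synthetic(seed = 21, n = 45, groups = 3, lambda_s = 30)
  net <- syn$network

  e1 <- generate_ensemble(net, N = 5, seed = 99)
  e2 <- generate_ensemble(net, N = 5, seed = 99)
  expect_identical(e1$samples, e2$samples)
  expect_equal(e1$N, 5)

  # sparse expectation is the elementwise ensemble mean
  expect_equal(e1$P_expect, Reduce(`+`, e1$samples) / 5, ignore_attr = TRUE)

  # full-model expectation is analytic; samples are dense and conserve
  # weight in ensemble mean (Poisson generation)
  ef <- generate_ensemble(net, model = "wcm_full", N = 40, seed = 100)
  expect_equal(ef$P_expect, wcm_expectation(net))
  w <- sum(strengths(net)) / 2
  tot <- vapply(ef$samples, function(P) sum(P) / 2, 1)
  expect_lt(abs(mean(tot) - w), 3 * stats::sd(tot) / sqrt(length(tot)))

  # every sample is symmetric, nonnegative, zero-diagonal
  for (P in e1$samples[1:2]) {
    expect_equal(P, t(P))
    expect_true(all(P >= 0))
    expect_true(all(diag(P) == 0))
  }

  expect_error(generate_ensemble(net, N = 0), "at least 1")
  netr <- weighted_network(net$W * 0.1, nodes = net$nodes)
  expect_error(generate_ensemble(netr), "quantise")
})

test_that("sparse samples conserve total weight in ensemble mean", {
  set.seed(14)
  syn <- small_modular_synthetic(seed = 22, n = 45, groups = 3, lambda_s = 30)
  net <- syn$network
  w <- sum(strengths(net)) / 2
  ens <- generate_ensemble(net, N = 60, seed = 101)
  tot <- vapply(ens$samples, function(P) sum(P) / 2, 1)
  expect_lt(abs(mean(tot) - w), 3 * stats::sd(tot) / sqrt(length(tot)))
})

test_that("weight-distribution diagnostic exposes the full model's excess density", {
  set.seed(15)
  syn <- small_modular_synthetic(seed = 23, n = 45, groups = 3, lambda_s = 30,
                                 p_within = 0.3, p_between = 0.05)
  net <- syn$network
  ens_full <- generate_ensemble(net, model = "wcm_full", N = 15, seed = 1)
  ens_sparse <- generate_ensemble(net, model = "wcm_sparse", N = 15, seed = 1)
  dg_full <- compare_weight_distributions(net, ens_full)
  dg_sparse <- compare_weight_distributions(net, ens_sparse)
  expect_gt(dg_full$density_ratio, 2)           # much denser than the data
  expect_equal(dg_sparse$density_ratio, 1, tolerance = 0.1)
  # data compared with a degenerate ensemble of itself: identical quantiles
  self_ens <- ens_sparse
  self_ens$samples <- list(net$W)
  dg_self <- compare_weight_distributions(net, self_ens)
  expect_equal(unname(dg_self$data_weight_quantiles),
               unname(dg_self$null_weight_quantiles))
})
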