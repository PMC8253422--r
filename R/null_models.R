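#' Expected weights under the weighted configuration model
#'
#' The full weighted configuration model (WCM) preserves the strength
#' sequence of the network in expectation. The strength-preserving form of
#' the expectation is `<P>_ij = s_i s_j / sum(s)` for `i != j` (the
#' denominator is twice the total unique weight), which makes
#' `C = W - <P>` the classic modularity matrix. The literal
#' `s_i s_j / w` form, with `w` the total unique weight, is available via
#' `denominator = "total_weight"` but does not preserve strengths.
#'
#' @param net a `weighted_network` with positive total weight.
#' @param denominator `"strength_sum"` (default, `sum(s) = 2w`) or
#'   `"total_weight"` (`w`).
#' @return symmetric matrix of expected weights with a zero diagonal.
#' @export
wcm_expectation <- function(net, denominator = c("strength_sum", "total_weight")) {
  denominator <- match.arg(denominator)
  s <- strengths(net)
  if (sum(s) <= 0) stop("network has no weight")
  den <- if (denominator == "strength_sum") sum(s) else sum(s) / 2
  P <- outer(s, s) / den
  diag(P) <- 0
  dimnames(P) <- dimnames(net$W)
  P
}

#' Sample a sparse configuration-model adjacency matrix
#'
#' Draws one Bernoulli adjacency matrix that matches the data network's
#' degree sequence in expectation: each unordered pair `(i, j)` is linked
#' independently with probability `min(1, k_i k_j / 2m)`, where `k` is the
#' data degree sequence and `m` the data's unique link count.
#'
#' @param net a `weighted_network` with at least one link.
#' @return symmetric binary matrix with zero diagonal.
#' @export
sample_sparse_adjacency <- function(net) {
  k <- degrees(net)
  m <- sum(k) / 2
  if (m <= 0) stop("network has no links")
  n <- n_nodes(net)
  ut <- which(upper.tri(diag(n)), arr.ind = TRUE)
  p <- pmin(1, k[ut[, 1]] * k[ut[, 2]] / (2 * m))
  A <- matrix(0, n, n)
  A[upper.tri(A)] <- as.numeric(stats::runif(length(p)) < p)
  A <- A + t(A)
  dimnames(A) <- dimnames(net$W)
  A
}

#' Place link weights by the Poisson model
#'
#' Given a strength sequence `s` and an adjacency matrix `A_star`, each
#' linked pair `(i, j)` receives a weight drawn from
#' `Poisson(lambda_ij)` with `lambda_ij = N_link * p(link|i,j)` and
#' `p(link|i,j) = s_i s_j / sum_{(i,j) in A_star} s_i s_j` (the sum runs
#' over linked unordered pairs), so the expected total placed weight is
#' `N_link`. Optionally every link first receives a `baseline` weight, as
#' used by the sparse configuration model so that sampled links never have
#' weight zero. Non-links always have weight zero.
#'
#' @param s nonnegative strength sequence.
#' @param A_star symmetric binary adjacency matrix.
#' @param N_link nonnegative expected number of unit links to place.
#' @param baseline weight added to every link before the Poisson draw
#'   (0 for the full model, 1 for the sparse model).
#' @return symmetric weight matrix supported on the links of `A_star`.
#' @export
place_weights_poisson <- function(s, A_star, N_link, baseline = 0) {
  n <- length(s)
  stopifnot(nrow(A_star) == n, ncol(A_star) == n)
  if (N_link < 0) stop("N_link must be nonnegative")
  sel <- which(upper.tri(A_star) & A_star > 0)
  if (length(sel) == 0) {
    if (N_link > 0) stop("cannot place weight on an adjacency matrix with no links")
    return(matrix(0, n, n))
  }
  i <- ((sel - 1L) %% n) + 1L
  j <- ((sel - 1L) %/% n) + 1L
  ss <- s[i] * s[j]
  denom <- sum(ss)
  lambda <- if (denom > 0) N_link * ss / denom else rep(0, length(ss))
  P <- matrix(0, n, n)
  P[sel] <- baseline + stats::rpois(length(sel), lambda)
  P <- P + t(P)
  P
}

#' Place link weights by multinomial stub matching
#'
#' The exact generative counterpart of the configuration model for integer
#' weights: each node `i` is given `s_i` stubs and the `sum(s)/2` unit
#' links are distributed over eligible pairs with probabilities
#' proportional to `s_i s_j`, i.e. a single multinomial draw. Serves as
#' the small-network oracle for the Poisson approximation of
#' [place_weights_poisson()].
#'
#' @param s integer strength sequence with even sum.
#' @param A_star symmetric binary adjacency matrix restricting eligible
#'   pairs, or `NULL` for all pairs (the full model).
#' @return symmetric integer weight matrix with total weight `sum(s)/2`.
#' @export
stub_matching <- function(s, A_star = NULL) {
  if (any(s != round(s)) || any(s < 0)) stop("strengths must be nonnegative integers")
  total <- sum(s)
  if (total %% 2 != 0) stop("strength sequence must have an even sum")
  n <- length(s)
  if (is.null(A_star)) A_star <- 1 - diag(n)
  sel <- which(upper.tri(A_star) & A_star > 0)
  if (length(sel) == 0) {
    if (total > 0) stop("no eligible pairs to place stubs on")
    return(matrix(0, n, n))
  }
  i <- ((sel - 1L) %% n) + 1L
  j <- ((sel - 1L) %/% n) + 1L
  prob <- s[i] * s[j]
  if (sum(prob) <= 0) stop("no eligible pair has positive strength product")
  counts <- stats::rmultinom(1, total / 2, prob)[, 1]
  P <- matrix(0, n, n)
  P[sel] <- counts
  P + t(P)
}

#' Generate an ensemble of null-model networks
#'
#' Samples `N` networks from a generative null model preserving (in
#' expectation) the data's strength sequence, and computes the
#' expectation matrix `<P>`:
#'
#' * `"wcm_full"`: every pair of nodes is eligible; `N_link = sum(s)/2`
#'   unit links are placed by the Poisson model (or exactly by stub
#'   matching). `<P>` is analytic ([wcm_expectation()]).
#' * `"wcm_sparse"`: each sample first draws an adjacency matrix matching
#'   the data's degree sequence ([sample_sparse_adjacency()]), gives each
#'   sampled link a baseline weight, then places extra unit links on the
#'   sampled links by the Poisson model. With the default
#'   `nlink_mode = "conserve"` the extra budget is
#'   `N_link = max(0, w - m*)` where `w = sum(s)/2` and `m*` is the
#'   sample's link count — the stub pairs left after every sampled link
#'   consumes one — so the sample's total weight matches the data's in
#'   expectation (with `baseline_weight = 1`). `nlink_mode = "literal"`
#'   uses `N_link = max(0, sum(s)/2 - 2 m*)` instead, which under-budgets
#'   the samples by `m*` and narrows their spectral bulk. `<P>` is the
#'   elementwise ensemble mean.
#'
#' Real-valued networks must be quantised with [quantise_weights()] first;
#' the ensemble is generated on the integer scale and the stored `kappa`
#' lets callers rescale outputs by `1/kappa`.
#'
#' @param net an integer- or binary-weighted `weighted_network`.
#' @param model `"wcm_sparse"` (default) or `"wcm_full"`.
#' @param N number of sampled networks (default 100).
#' @param generation `"poisson"` (default) or `"stub_matching"`.
#' @param seed optional integer seed; when `NULL` the current RNG stream
#'   is used.
#' @param nlink_mode `"conserve"` (`w - m*`, weight-preserving, default)
#'   or `"literal"` (`sum(s)/2 - 2 m*`); sparse model only.
#' @param baseline_weight weight given to every sampled link in the sparse
#'   model before Poisson extras (default 1).
#' @return an object of class `null_ensemble`: list with `model`, `N`,
#'   `generation`, `P_expect`, `samples` (list of `N` weight matrices),
#'   `strengths`, `nodes`, `kappa`.
#' @export
generate_ensemble <- function(net, model = c("wcm_sparse", "wcm_full"),
                              N = 100, generation = c("poisson", "stub_matching"),
                              seed = NULL,
                              nlink_mode = c("conserve", "literal"),
                              baseline_weight = 1) {
  model <- match.arg(model)
  generation <- match.arg(generation)
  nlink_mode <- match.arg(nlink_mode)
  if (N < 1) stop("N must be at least 1")
  if (net$weight_class == "real")
    stop("quantise real-valued weights with quantise_weights() before generating nulls")
  if (!is.null(seed)) set.seed(seed)
  s <- strengths(net)
  n <- n_nodes(net)
  w <- sum(s) / 2
  if (w <= 0) stop("network has no weight")
  samples <- vector("list", N)
  if (model == "wcm_full") {
    A_full <- 1 - diag(n)
    for (r in seq_len(N)) {
      samples[[r]] <- if (generation == "poisson")
        place_weights_poisson(s, A_full, N_link = w, baseline = 0)
      else stub_matching(s, NULL)
    }
    P_expect <- wcm_expectation(net)
  } else {
    for (r in seq_len(N)) {
      A_star <- sample_sparse_adjacency(net)
      if (generation == "poisson") {
        m_star <- sum(A_star) / 2
        N_link <- if (nlink_mode == "conserve") max(0, w - m_star)
          else max(0, w - 2 * m_star)
        samples[[r]] <- place_weights_poisson(s, A_star, N_link,
                                              baseline = baseline_weight)
      } else {
        samples[[r]] <- stub_matching(s, A_star)
      }
    }
    P_expect <- Reduce(`+`, samples) / N
    dimnames(P_expect) <- dimnames(net$W)
  }
  structure(list(model = model, N = N, generation = generation,
                 nlink_mode = nlink_mode, baseline_weight = baseline_weight,
                 P_expect = P_expect, samples = samples,
                 strengths = s, nodes = net$nodes, kappa = net$kappa),
            class = "null_ensemble")
}

#' @export
print.null_ensemble <- function(x, ...) {
  cat(sprintf("<null_ensemble> %s, N = %d samples (%s generation), %d nodes\n",
              x$model, x$N, x$generation, length(x$nodes)))
  invisible(x)
}

#' Compare data and null-model weight distributions
#'
#' Diagnostic (no decision is made) for judging whether a null model
#' reproduces the data network's sparseness and weight distribution: the
#' full configuration model typically produces far denser networks than
#' sparse data, while the sparse model matches the data's link density.
#'
#' @param net the data `weighted_network`.
#' @param ens a `null_ensemble` generated from it.
#' @param probs quantile probabilities for the weight summaries.
#' @return list of class `weight_diagnostic`: data and mean null link
#'   density, their ratio, and quantiles of positive link weights in the
#'   data and pooled over the null samples.
#' @export
compare_weight_distributions <- function(net, ens,
                                         probs = c(0.05, 0.25, 0.5, 0.75, 0.95)) {
  n <- n_nodes(net)
  dens <- function(W) sum(W[upper.tri(W)] > 0) / (n * (n - 1) / 2)
  data_density <- dens(net$W)
  null_density <- mean(vapply(ens$samples, dens, 1))
  wpos <- function(W) { v <- W[upper.tri(W)]; v[v > 0] }
  data_w <- wpos(net$W)
  null_w <- unlist(lapply(ens$samples, wpos))
  structure(list(
    data_density = data_density,
    null_density = null_density,
    density_ratio = null_density / data_density,
    data_weight_quantiles = stats::quantile(data_w, probs, names = TRUE),
    null_weight_quantiles = stats::quantile(null_w, probs, names = TRUE)),
    class = "weight_diagnostic")
}

#' @export
print.weight_diagnostic <- function(x, ...) {
  cat(sprintf("link density: data %.4g, null %.4g (ratio %.3g)\n",
              x$data_density, x$null_density, x$density_ratio))
  q <- rbind(data = x$data_weight_quantiles, null = x$null_weight_quantiles)
  print(round(q, 4))
  invisible(x)
}
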