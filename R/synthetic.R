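#' Specification of a planted-structure synthetic network
#'
#' Parameters of the weighted stochastic block model with an optional
#' noise halo used to benchmark spectral estimation. `n` module nodes are
#' split into `groups` blocks (equal sizes by default); links are drawn
#' independently with probability `p_within` inside a block and
#' `p_between` across blocks. `floor(n * f_noise)` additional noise nodes
#' are connected to every other node (including each other) with
#' probability `p_noise`. Node strengths are drawn from
#' `Poisson(lambda_s)` for modular and noise nodes alike, so the two
#' classes differ only in how their weights are distributed.
#'
#' @param n number of module nodes (default 400).
#' @param groups number of planted blocks (default 4).
#' @param sizes optional explicit block sizes summing to `n`;
#'   defaults to equal sizes (`n` must then be divisible by `groups`).
#' @param p_within,p_between,p_noise link probabilities in `[0, 1]`.
#' @param f_noise noise-halo fraction (default 0: no halo).
#' @param lambda_s Poisson strength parameter (default 200).
#' @return object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n = 400, groups = 4, sizes = NULL,
                           p_within = 0.2, p_between = 0.05,
                           p_noise = 0.05, f_noise = 0, lambda_s = 200) {
  if (is.null(sizes)) {
    if (n %% groups != 0)
      stop("n is not divisible by groups; give explicit sizes")
    sizes <- rep(n / groups, groups)
  }
  if (sum(sizes) != n) stop("sizes must sum to n")
  if (length(sizes) != groups) stop("length(sizes) must equal groups")
  probs <- c(p_within = p_within, p_between = p_between, p_noise = p_noise)
  if (any(probs < 0 | probs > 1)) stop("link probabilities must be in [0, 1]")
  if (f_noise < 0) stop("f_noise must be nonnegative")
  if (lambda_s <= 0) stop("lambda_s must be positive")
  structure(list(n = n, groups = groups, sizes = sizes,
                 p_within = p_within, p_between = p_between,
                 p_noise = p_noise, f_noise = f_noise,
                 lambda_s = lambda_s,
                 n_noise = floor(n * f_noise),
                 n_total = n + floor(n * f_noise)),
            class = "synthetic_spec")
}

#' @export
print.synthetic_spec <- function(x, ...) {
  cat(sprintf(
    "<synthetic_spec> %d nodes in %d blocks + %d noise nodes (T = %d)\n",
    x$n, x$groups, x$n_noise, x$n_total))
  cat(sprintf("  p_within = %g, p_between = %g, p_noise = %g, lambda_s = %g\n",
              x$p_within, x$p_between, x$p_noise, x$lambda_s))
  invisible(x)
}

#' Sample the block-model adjacency matrix
#'
#' Independent Bernoulli draw per unordered pair: `p_within` for pairs in
#' the same block, `p_between` for pairs in different blocks, `p_noise`
#' for any pair involving a noise node.
#'
#' @param spec a `synthetic_spec`.
#' @return list with the binary symmetric `A` and the `labels` vector
#'   (block id `1..groups` for module nodes, `0` for noise nodes).
#' @export
sample_sbm_adjacency <- function(spec) {
  labels <- c(rep(seq_len(spec$groups), spec$sizes), rep(0L, spec$n_noise))
  Tn <- spec$n_total
  ut <- which(upper.tri(diag(Tn)), arr.ind = TRUE)
  gi <- labels[ut[, 1]]; gj <- labels[ut[, 2]]
  p <- ifelse(gi == 0L | gj == 0L, spec$p_noise,
              ifelse(gi == gj, spec$p_within, spec$p_between))
  A <- matrix(0, Tn, Tn)
  A[upper.tri(A)] <- as.numeric(stats::runif(length(p)) < p)
  A <- A + t(A)
  list(A = A, labels = labels)
}

#' Generate a synthetic weighted network with planted structure
#'
#' Draws the block-model adjacency matrix, samples a strength sequence
#' `s_1..s_T ~ Poisson(lambda_s)`, and places integer weights on the
#' links with the same Poisson mechanism as the sparse configuration
#' model ([place_weights_poisson()]): every link gets baseline weight 1
#' plus a `Poisson(N_link p(link|i,j))` extra, with
#' `N_link = max(0, w - m)` (`w = sum(s)/2`; see [generate_ensemble()]
#' for the `nlink_mode` variants) and `p(link|i,j)` proportional to
#' `s_i s_j` over the linked pairs, so realised strengths match the
#' sampled targets in expectation.
#'
#' @param spec a `synthetic_spec`.
#' @param seed optional integer seed.
#' @param nlink_mode,baseline_weight weight-placement options shared with
#'   [generate_ensemble()].
#' @return object of class `synthetic_network`: the `network`
#'   (a `weighted_network`), ground-truth `labels` (0 = noise), the
#'   sampled target `strengths`, and the `spec`.
#' @export
generate_synthetic <- function(spec, seed = NULL,
                               nlink_mode = c("conserve", "literal"),
                               baseline_weight = 1) {
  nlink_mode <- match.arg(nlink_mode)
  if (!is.null(seed)) set.seed(seed)
  sbm <- sample_sbm_adjacency(spec)
  Tn <- spec$n_total
  s <- stats::rpois(Tn, spec$lambda_s)
  m <- sum(sbm$A) / 2
  if (m == 0) stop("sampled adjacency matrix has no links")
  w <- sum(s) / 2
  N_link <- if (nlink_mode == "conserve") max(0, w - m) else max(0, w - 2 * m)
  W <- place_weights_poisson(s, sbm$A, N_link, baseline = baseline_weight)
  nodes <- paste0("n", seq_len(Tn))
  net <- weighted_network(W, nodes = nodes, weight_class = "integer")
  labels <- stats::setNames(sbm$labels, nodes)
  structure(list(network = net, labels = labels, strengths = s,
                 spec = spec),
            class = "synthetic_network")
}

#' @export
print.synthetic_network <- function(x, ...) {
  print(x$spec)
  print(x$network)
  invisible(x)
}

#' Pipeline sweep over synthetic networks
#'
#' Runs the full estimate/reject/cluster pipeline over a grid of
#' synthetic-network parameters, scoring each replicate against the
#' planted ground truth. Used for the detection-transition and
#' noise-rejection benchmark designs.
#'
#' @param grid data.frame whose columns override [synthetic_spec()]
#'   arguments (e.g. `p_within`, `p_noise`, `f_noise`); one sweep cell
#'   per row.
#' @param replicates synthetic networks per cell.
#' @param model,N null-model choice and sample count for
#'   [generate_ensemble()].
#' @param reject run node rejection when structure is found (needed for
#'   TNR/TPR).
#' @param cluster cluster the signal projection at `d + 1` groups and
#'   score VI against the planted labels (noise as one extra group),
#'   restricted to the signal nodes.
#' @param p k-means repeats when clustering.
#' @param seed master seed; replicate `r` of cell `i` uses a seed derived
#'   deterministically from it.
#' @param spec_args further fixed arguments passed to [synthetic_spec()].
#' @return data.frame with one row per replicate: the cell parameters,
#'   `rep`, `detected`, `d`, `modules`, `vi`, `tnr`, `tpr` (NA where a
#'   stage did not run).
#' @export
sweep_synthetic <- function(grid, replicates = 10, model = "wcm_sparse",
                            N = 100, reject = TRUE, cluster = FALSE,
                            p = 100, seed = 1, spec_args = list()) {
  if (nrow(grid) == 0) stop("empty parameter grid")
  rows <- list()
  for (i in seq_len(nrow(grid))) {
    cell <- as.list(grid[i, , drop = FALSE])
    for (r in seq_len(replicates)) {
      set.seed((seed * 10007L + i * 211L + r) %% .Machine$integer.max)
      spec <- do.call(synthetic_spec, c(cell, spec_args))
      syn <- generate_synthetic(spec)
      ens <- generate_ensemble(syn$network, model = model, N = N)
      est <- spectral_estimate(syn$network, ens)
      out <- c(cell, list(rep = r, detected = est$d_upper > 0,
                          d = est$d_upper, modules = NA_integer_,
                          vi = NA_real_, tnr = NA_real_, tpr = NA_real_))
      if (est$d_upper > 0 && (reject || cluster)) {
        rej <- node_rejection(syn$network, est, ens)
        is_noise <- syn$labels == 0L
        rejected <- syn$network$nodes %in% rej$rejected
        if (any(is_noise)) out$tnr <- mean(rejected[is_noise])
        out$tpr <- mean(!rejected[!is_noise])
        if (cluster && n_nodes(rej$signal) > est$d_upper + 1) {
          keep <- rej$signal$nodes
          Csig <- est$C[keep, keep]
          coords <- project_nodes(est)[keep, , drop = FALSE]
          part <- kmeans_partition(coords, c = est$d_upper + 1,
                                   C = Csig, p = p)
          out$modules <- part$c
          truth <- syn$labels[keep]
          truth[truth == 0L] <- spec$groups + 1L  # noise as one extra group
          out$vi <- normalised_vi(part$assignment, truth)
        }
      }
      rows[[length(rows) + 1]] <- as.data.frame(out)
    }
  }
  do.call(rbind, rows)
}
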