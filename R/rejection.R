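#' Projection norms of nodes
#'
#' The L2 norm of each node's position in the retained eigenspace,
#' `L(j) = sqrt(sum_i (lambda_i u_i(j))^2)` for eigenvalue-weighted
#' coordinates. `norm = "signed_sum"` instead returns the literal signed
#' sum of the coordinates.
#'
#' @param coords `n x d` coordinate matrix from [project_nodes()].
#' @param norm `"l2"` (default) or `"signed_sum"`.
#' @return numeric vector of length `n`, named by node.
#' @export
node_norms <- function(coords, norm = c("l2", "signed_sum")) {
  norm <- match.arg(norm)
  if (norm == "l2") sqrt(rowSums(coords^2)) else rowSums(coords)
}

#' Null-model expectations of the projection norms
#'
#' For every sampled null network the comparison matrix
#' `C*_i = P*_i - <P>` is eigendecomposed and its top `d` eigenpairs (or
#' bottom `d` for `side = "lower"`) define that sample's projection; node
#' norms are computed exactly as for the data. The per-node mean over the
#' `N` samples is the rejection threshold `<L(j)*>`.
#'
#' When the data projection is eigenvalue-weighted, the null coordinates
#' are by default weighted with the *data's* retained eigenvalues
#' (`weights`), not each sample's own: the structural data eigenvalues
#' necessarily exceed the null's bulk-edge eigenvalues, so weighting each
#' side by its own spectrum would systematically scale up the data
#' coordinates of every node — including non-contributing ones — relative
#' to the threshold. Pass `weights = NULL` to weight each sample by its
#' own top-`d` eigenvalues instead.
#'
#' @param ens a `null_ensemble`.
#' @param d number of retained dimensions (fixed by the data estimate).
#' @param side `"upper"` or `"lower"`.
#' @param weighted,norm as in [project_nodes()] and [node_norms()];
#'   the treatment matches the data projection.
#' @param weights length-`d` eigenvalue weights applied to every sample's
#'   projection (typically the data's retained eigenvalues), or `NULL`
#'   for each sample's own; ignored when `weighted = FALSE`.
#' @return list with `L_mean` (per-node mean norm) and `L_samples`
#'   (`N x n` matrix of per-sample norms).
#' @export
null_norms <- function(ens, d, side = c("upper", "lower"),
                       weighted = TRUE, norm = "l2", weights = NULL) {
  side <- match.arg(side)
  n <- length(ens$nodes)
  if (d < 1) stop("d must be at least 1")
  if (d > n) stop("d exceeds the number of nodes")
  if (!is.null(weights) && length(weights) != d)
    stop("weights must have length d")
  L <- matrix(NA_real_, ens$N, n, dimnames = list(NULL, ens$nodes))
  for (r in seq_len(ens$N)) {
    e <- eigen(ens$samples[[r]] - ens$P_expect, symmetric = TRUE)
    idx <- if (side == "upper") seq_len(d) else (n - d + 1):n
    V <- e$vectors[, idx, drop = FALSE]
    lam <- if (is.null(weights)) e$values[idx] else weights
    coords <- if (weighted) sweep(V, 2, lam, `*`) else V
    L[r, ] <- node_norms(coords, norm = norm)
  }
  list(L_mean = colMeans(L), L_samples = L)
}

#' Reject nodes whose projection does not exceed the null expectation
#'
#' A node is rejected if `L(j) < <L(j)*>`; nodes exactly at the threshold
#' are retained.
#'
#' @param L_data per-node data norms.
#' @param L_null_mean per-node null expectations, aligned with `L_data`.
#' @return list with logical vector `retained` plus the `retained_nodes`
#'   and `rejected_nodes` label vectors.
#' @export
reject_nodes <- function(L_data, L_null_mean) {
  if (length(L_data) != length(L_null_mean)) stop("norm vectors differ in length")
  keep <- L_data >= L_null_mean
  nodes <- names(L_data)
  list(retained = keep,
       retained_nodes = nodes[keep],
       rejected_nodes = nodes[!keep])
}

#' Extract the signal network from the retained nodes
#'
#' Induces the subnetwork on the retained nodes, strips its leaf nodes
#' (degree 1 in the induced network; a single simultaneous pass by
#' default, or iterated to a 2-core with `strip = "iterate"`), and returns
#' the largest remaining connected component.
#'
#' @param net the original `weighted_network`.
#' @param retained node labels (or indices) to keep.
#' @param strip `"once"` (default), `"iterate"`, or `"none"`.
#' @return list with `signal` (a `weighted_network`, possibly empty with a
#'   warning if stripping removes everything), `leaves` (labels stripped
#'   as leaves) and `off_component` (labels dropped with smaller
#'   components).
#' @export
extract_signal <- function(net, retained, strip = c("once", "iterate", "none")) {
  strip <- match.arg(strip)
  if (length(retained) == 0) stop("retained node set is empty")
  sub <- subnetwork(net, retained)
  leaves <- character(0)
  repeat {
    if (strip == "none" || n_nodes(sub) == 0) break
    deg <- degrees(sub)
    leaf <- deg == 1
    if (!any(leaf)) break
    leaves <- c(leaves, sub$nodes[leaf])
    sub <- subnetwork(sub, which(!leaf))
    if (strip == "once") break
  }
  if (n_nodes(sub) == 0) {
    warning("signal network is empty after leaf stripping")
    return(list(signal = sub, leaves = leaves, off_component = character(0)))
  }
  gc_net <- giant_component(sub)
  off <- setdiff(sub$nodes, gc_net$nodes)
  list(signal = gc_net, leaves = leaves, off_component = off)
}

#' Node rejection against a sampled null model
#'
#' Full rejection step: project the data and every null sample into the
#' retained `d`-dimensional space, compare per-node norms, reject nodes
#' below their null expectation, and extract the leaf-stripped
#' largest-component signal network.
#'
#' @param net the data `weighted_network` used for the estimate.
#' @param est a `spectral_estimate` with `d_upper >= 1` (or `d_lower >= 1`
#'   for `side = "lower"`).
#' @param ens the `null_ensemble` behind the estimate.
#' @param side `"upper"` (community-like dimensions) or `"lower"`
#'   (k-partite dimensions, rejected on their own projection).
#' @param weighted,norm projection and norm options, applied identically
#'   to data and null.
#' @param null_scale eigenvalue weights for the null projections when
#'   `weighted = TRUE`: `"data"` (default) applies the data's retained
#'   eigenvalues to both sides so the comparison is scale-matched per
#'   dimension; `"sample"` weights each null sample by its own top-`d`
#'   eigenvalues (see [null_norms()]).
#' @param strip leaf-stripping mode, see [extract_signal()].
#' @return object of class `rejection_result`: per-node `table`
#'   (data.frame with `node`, `L_data`, `L_null_mean`, `status` in
#'   retained/rejected/leaf/off-component), `retained`/`rejected` label
#'   vectors, `signal` network, `L_samples`.
#' @export
node_rejection <- function(net, est, ens, side = c("upper", "lower"),
                           weighted = TRUE, norm = "l2",
                           null_scale = c("data", "sample"),
                           strip = c("once", "iterate", "none")) {
  side <- match.arg(side)
  strip <- match.arg(strip)
  null_scale <- match.arg(null_scale)
  d <- if (side == "upper") est$d_upper else est$d_lower
  if (d < 1) stop("no retained dimensions on the ", side, " side; nothing to reject against")
  coords <- project_nodes(est, which = side, weighted = weighted)
  L_data <- node_norms(coords, norm = norm)
  wts <- if (null_scale == "data" && weighted)
    (if (side == "upper") est$values_upper else est$values_lower) else NULL
  nn <- null_norms(ens, d = d, side = side, weighted = weighted,
                   norm = norm, weights = wts)
  rej <- reject_nodes(L_data, nn$L_mean)
  sig <- extract_signal(net, rej$retained_nodes, strip = strip)
  status <- ifelse(rej$retained, "retained", "rejected")
  status[match(sig$leaves, net$nodes)] <- "leaf"
  status[match(sig$off_component, net$nodes)] <- "off-component"
  tab <- data.frame(node = net$nodes, L_data = unname(L_data),
                    L_null_mean = unname(nn$L_mean), status = status,
                    stringsAsFactors = FALSE)
  structure(list(table = tab, retained = rej$retained_nodes,
                 rejected = rej$rejected_nodes, signal = sig$signal,
                 leaves_removed = sig$leaves,
                 off_component = sig$off_component,
                 L_samples = nn$L_samples, side = side, d = d),
            class = "rejection_result")
}

#' @export
print.rejection_result <- function(x, ...) {
  cat(sprintf("<rejection_result> (%s side, d = %d)\n", x$side, x$d))
  cat(sprintf("  retained %d / %d nodes (%d rejected)\n",
              length(x$retained), nrow(x$table), length(x$rejected)))
  cat(sprintf("  signal network: %d nodes (%d leaves stripped, %d off-component)\n",
              n_nodes(x$signal), length(x$leaves_removed),
              length(x$off_component)))
  invisible(x)
}
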