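#' Comparison matrix C = W - <P>
#'
#' The departure of the data network from the null model's expected
#' weights. Under the classic configuration-model expectation this is the
#' modularity matrix; for an arbitrary generative null it generalises it.
#'
#' @param W symmetric data weight matrix (or a `weighted_network`).
#' @param P_expect symmetric matrix of expected weights, same shape.
#' @return symmetric matrix `W - P_expect`.
#' @export
comparison_matrix <- function(W, P_expect) {
  if (inherits(W, "weighted_network")) W <- W$W
  if (!all(dim(W) == dim(P_expect))) stop("W and P_expect shapes differ")
  C <- W - P_expect
  (C + t(C)) / 2
}

#' Null-model bounds on the comparison-matrix eigenspectrum
#'
#' For each sampled null network `P*_i` the comparison matrix
#' `C*_i = P*_i - <P>` is eigendecomposed; the upper (lower) bound of the
#' eigenspectrum expected under the null model is estimated as the mean of
#' the `N` maximum (minimum) eigenvalues. `mode = "percentile"` instead
#' returns the empirical `1 - alpha` quantile of the maxima and the
#' `alpha` quantile of the minima, a significance-style variant.
#'
#' @param ens a `null_ensemble`.
#' @param mode `"mean"` (default) or `"percentile"`.
#' @param alpha tail level for the percentile mode.
#' @return list of class `null_bounds`: `lambda_max`, `lambda_min`, the
#'   per-sample extreme vectors `max_samples` and `min_samples`, `mode`,
#'   `alpha`.
#' @export
null_spectrum_bounds <- function(ens, mode = c("mean", "percentile"),
                                 alpha = 0.05) {
  mode <- match.arg(mode)
  ext <- vapply(ens$samples, function(P) {
    ev <- eigen(P - ens$P_expect, symmetric = TRUE, only.values = TRUE)$values
    c(max(ev), min(ev))
  }, numeric(2))
  maxs <- ext[1, ]; mins <- ext[2, ]
  if (mode == "mean") {
    lmax <- mean(maxs); lmin <- mean(mins)
  } else {
    lmax <- unname(stats::quantile(maxs, 1 - alpha))
    lmin <- unname(stats::quantile(mins, alpha))
  }
  structure(list(lambda_max = lmax, lambda_min = lmin,
                 max_samples = maxs, min_samples = mins,
                 mode = mode, alpha = alpha),
            class = "null_bounds")
}

#' Spectral estimate of a network's low-dimensional structure
#'
#' Compares the eigenspectrum of the data comparison matrix
#' `C = W - <P>` to the bounds sampled from the null model. The number of
#' data eigenvalues strictly above the upper bound, `d_upper`, estimates
#' the dimensionality of community-like structure (suggesting `d_upper + 1`
#' groups); eigenvalues strictly below the lower bound (`d_lower`) signal
#' k-partite structure (one such eigenvalue: bipartite). If neither occurs
#' the data network cannot be distinguished from a realisation of the null
#' model.
#'
#' @param net the data `weighted_network` (on the same scale as the
#'   ensemble, i.e. quantised if the ensemble was).
#' @param ens a `null_ensemble` generated from `net`.
#' @param mode,alpha bound estimation mode, see [null_spectrum_bounds()].
#' @return object of class `spectral_estimate`: eigenvalues (descending),
#'   bounds, `d_upper`, `d_lower`, the retained eigenvector matrices
#'   `vectors_upper` / `vectors_lower` (sign-fixed so the largest-magnitude
#'   entry is positive), the retained eigenvalues `values_upper` /
#'   `values_lower`, the `departure` statistic and the comparison matrix
#'   `C`.
#' @export
spectral_estimate <- function(net, ens, mode = c("mean", "percentile"),
                              alpha = 0.05) {
  C <- comparison_matrix(net$W, ens$P_expect)
  e <- eigen(C, symmetric = TRUE)
  bounds <- null_spectrum_bounds(ens, mode = mode, alpha = alpha)
  est <- detect_dimensions(e$values, e$vectors, bounds)
  est$C <- C
  est$nodes <- net$nodes
  rownames(est$vectors_upper) <- rownames(est$vectors_lower) <- net$nodes
  est$kappa <- net$kappa
  est
}

#' Count dimensions above and below the null bounds
#'
#' Core decision step, separated from [spectral_estimate()] so it can be
#' driven with externally computed eigenpairs. Counting uses strict
#' inequalities; ties fall to the null model.
#'
#' @param values eigenvalues of the data comparison matrix, descending.
#' @param vectors matching orthonormal eigenvector matrix (columns).
#' @param bounds a `null_bounds` object.
#' @return a `spectral_estimate` (without the `C`/`nodes` elements).
#' @export
detect_dimensions <- function(values, vectors, bounds) {
  ord <- order(values, decreasing = TRUE)
  values <- values[ord]
  vectors <- vectors[, ord, drop = FALSE]
  d_upper <- sum(values > bounds$lambda_max)
  d_lower <- sum(values < bounds$lambda_min)
  n <- length(values)
  vu <- fix_eigenvector_signs(vectors[, seq_len(d_upper), drop = FALSE])
  vl <- fix_eigenvector_signs(vectors[, seq_len(n) > n - d_lower, drop = FALSE])
  dep <- if (values[1] != 0)
    (values[1] - bounds$lambda_max) / values[1] else NA_real_
  structure(list(eigenvalues = values, bounds = bounds,
                 d_upper = d_upper, d_lower = d_lower,
                 values_upper = values[seq_len(d_upper)],
                 values_lower = values[seq_len(n) > n - d_lower],
                 vectors_upper = vu, vectors_lower = vl,
                 departure = dep),
            class = "spectral_estimate")
}

# make the largest-magnitude entry of each eigenvector positive
fix_eigenvector_signs <- function(V) {
  if (ncol(V) == 0) return(V)
  flip <- apply(V, 2, function(v) v[which.max(abs(v))] < 0)
  V[, flip] <- -V[, flip, drop = FALSE]
  V
}

#' Normalised departure from the null model
#'
#' `(lambda_max - <lambda*_max>) / lambda_max`: how far the data's leading
#' eigenvalue exceeds the null upper bound, as a fraction of itself.
#' Positive values indicate structure; at most 1.
#'
#' @param lambda_max leading data eigenvalue (nonzero).
#' @param lambda_max_null estimated null upper bound.
#' @return the departure statistic.
#' @export
departure_statistic <- function(lambda_max, lambda_max_null) {
  if (lambda_max == 0) stop("departure undefined for lambda_max = 0")
  (lambda_max - lambda_max_null) / lambda_max
}

#' @export
print.spectral_estimate <- function(x, ...) {
  cat("<spectral_estimate>\n")
  cat(sprintf("  null bounds (%s): [%.4g, %.4g]\n",
              x$bounds$mode, x$bounds$lambda_min, x$bounds$lambda_max))
  cat(sprintf("  leading data eigenvalues: %s\n",
              paste(signif(utils::head(x$eigenvalues, 5), 4), collapse = ", ")))
  if (x$d_upper == 0 && x$d_lower == 0) {
    cat("  verdict: no departure from the null model\n")
  } else {
    if (x$d_upper > 0)
      cat(sprintf("  d_upper = %d eigenvalue(s) above the upper bound (suggesting %d groups)\n",
                  x$d_upper, x$d_upper + 1))
    if (x$d_lower > 0)
      cat(sprintf("  d_lower = %d eigenvalue(s) below the lower bound%s\n",
                  x$d_lower,
                  if (x$d_lower == 1) " (bipartite evidence)" else " (k-partite evidence)"))
  }
  cat(sprintf("  departure statistic: %.4g\n", x$departure))
  invisible(x)
}

#' Project nodes into the retained eigenspace
#'
#' Node `j`'s coordinate in retained dimension `i` is `lambda_i u_i(j)`
#' (eigenvalue-weighted by default, so distances reflect how strongly each
#' dimension departs from the null). Use `which = "lower"` for the
#' k-partite eigenvectors.
#'
#' @param est a `spectral_estimate` with at least one retained dimension
#'   on the requested side.
#' @param which `"upper"` (community-like) or `"lower"` (k-partite).
#' @param weighted multiply eigenvectors by their eigenvalues.
#' @return `n x d` coordinate matrix, rows named by node label.
#' @export
project_nodes <- function(est, which = c("upper", "lower"), weighted = TRUE) {
  which <- match.arg(which)
  V <- if (which == "upper") est$vectors_upper else est$vectors_lower
  lam <- if (which == "upper") est$values_upper else est$values_lower
  if (ncol(V) == 0)
    stop("no retained dimensions on the ", which, " side: no structure to project")
  coords <- if (weighted) sweep(V, 2, lam, `*`) else V
  colnames(coords) <- paste0("dim", seq_len(ncol(coords)))
  coords
}
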