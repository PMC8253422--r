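#' Modularity of a partition against a comparison matrix
#'
#' `Q = Tr(S^T C S)` for the binary community indicator matrix `S` and
#' comparison matrix `C = W - <P>`. No normalisation is applied.
#'
#' @param S `n x c` binary indicator matrix (each row sums to 1), or an
#'   assignment vector of community labels.
#' @param C symmetric comparison matrix.
#' @return the modularity value.
#' @export
modularity_trace <- function(S, C) {
  if (is.vector(S) || is.factor(S)) S <- indicator_matrix(S)
  if (nrow(S) != nrow(C)) stop("S and C row counts differ")
  sum(S * (C %*% S))
}

#' Community assignment vector to indicator matrix
#' @param assignment vector of community labels (any type).
#' @return binary `n x c` matrix, one column per distinct label in first
#'   occurrence order.
#' @export
indicator_matrix <- function(assignment) {
  labs <- unique(as.vector(assignment))
  S <- matrix(0, length(assignment), length(labs))
  S[cbind(seq_along(assignment), match(assignment, labs))] <- 1
  rownames(S) <- names(assignment)
  S
}

# canonical integer relabelling by first occurrence, for comparing partitions
canonical_labels <- function(assignment) {
  match(assignment, unique(as.vector(assignment)))
}

new_partition <- function(assignment, C, extra = list()) {
  assignment <- stats::setNames(canonical_labels(assignment),
                                names(assignment))
  S <- indicator_matrix(assignment)
  out <- c(list(assignment = assignment, S = S,
                Q = modularity_trace(S, C), c = ncol(S)), extra)
  structure(out, class = "network_partition")
}

#' @export
print.network_partition <- function(x, ...) {
  cat(sprintf("<network_partition> %d communities over %d nodes, Q = %.4g\n",
              x$c, length(x$assignment), x$Q))
  print(table(communities = x$assignment))
  invisible(x)
}

# one k-means run with retries against degenerate random initialisations
safe_kmeans <- function(coords, k, iter_max = 100) {
  for (attempt in 1:10) {
    fit <- tryCatch(
      suppressWarnings(stats::kmeans(coords, centers = k,
                                     iter.max = iter_max, nstart = 1)),
      error = function(e) NULL)
    if (!is.null(fit)) return(fit)
  }
  # fall back to explicitly distinct rows as centers
  uniq <- unique(coords)
  if (nrow(uniq) < k)
    stop("fewer than ", k, " distinct node positions; cannot form ", k, " clusters")
  ctr <- uniq[sample(nrow(uniq), k), , drop = FALSE]
  stats::kmeans(coords, centers = ctr, iter.max = iter_max)
}

#' Modularity-selected k-means clustering of the node projection
#'
#' Runs k-means (Euclidean distance) `p` times on the retained
#' eigenspace coordinates with `c` target clusters and returns the
#' partition maximising `Q = Tr(S^T C S)`. With `d` retained dimensions
#' the natural target is `c = d + 1` groups.
#'
#' @param coords `n x d` node coordinate matrix (see [project_nodes()]).
#' @param c number of clusters, `2 <= c <= n`.
#' @param C comparison matrix restricted to the same nodes, used to score
#'   partitions.
#' @param p number of k-means repeats (default 100).
#' @param seed optional integer seed.
#' @return a `network_partition` with the extra field `Q_all` (the
#'   modularity of every repeat).
#' @export
kmeans_partition <- function(coords, c, C, p = 100, seed = NULL) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  if (c > n) stop("more clusters than nodes")
  if (c < 2) stop("need at least 2 clusters")
  if (!is.null(seed)) set.seed(seed)
  best <- NULL; bestQ <- -Inf
  Q_all <- numeric(p)
  for (r in seq_len(p)) {
    fit <- safe_kmeans(coords, c)
    a <- stats::setNames(fit$cluster, rownames(coords))
    Q_all[r] <- modularity_trace(indicator_matrix(a), C)
    if (Q_all[r] > bestQ) { bestQ <- Q_all[r]; best <- a }
  }
  new_partition(best, C, extra = list(Q_all = Q_all))
}

#' Expected co-clustering rate under the consensus null
#'
#' The probability that two objects land in the same cluster when
#' partitions have no cluster structure, averaged over the tested cluster
#' counts `c = l..K` with `p` partitions each:
#' `P_con = 1 / (p (K - 1)) * sum_{c = l}^{K} p / c`. Independent of `p`
#' after simplification. `l = K` for the initial consensus round (a single
#' tested `c`), `l = 2` afterwards.
#'
#' @param p partitions per cluster count.
#' @param K largest cluster count tested.
#' @param l smallest cluster count tested, `2 <= l <= K`.
#' @return the scalar expected co-clustering proportion.
#' @export
consensus_null <- function(p, K, l) {
  if (K < l) stop("K must be at least l")
  if (l < 2) stop("l must be at least 2")
  sum(p / (l:K)) / (p * (K - 1))
}

#' Build a consensus matrix from partitions
#' @param partitions list of assignment vectors over the same nodes.
#' @return symmetric matrix `D` with `D_ij` the proportion of partitions
#'   placing `i` and `j` in the same cluster; unit diagonal.
#' @export
consensus_matrix <- function(partitions) {
  n <- length(partitions[[1]])
  D <- matrix(0, n, n)
  for (a in partitions) {
    S <- indicator_matrix(a)
    D <- D + S %*% t(S)
  }
  D / length(partitions)
}

partitions_identical <- function(partitions) {
  ref <- canonical_labels(partitions[[1]])
  all(vapply(partitions, function(a) identical(canonical_labels(a), ref), TRUE))
}

#' Consensus clustering in the retained eigenspace
#'
#' Addresses the degeneracy of near-maximal modularity partitions and the
#' resolution limit by iterated co-clustering. Starting from `p` k-means
#' partitions of the data projection at `c_init` clusters, each round
#' builds the consensus matrix `D`, subtracts the consensus null
#' [consensus_null()] to give `C_con = D - P_con`, sets `K` to the number
#' of positive eigenvalues of `C_con`, projects `C_con` onto its top `K`
#' eigenvectors, and k-means clusters that projection `p` times for every
#' `k` in `2..K`. Rounds repeat until all partitions in a round are
#' identical (up to label permutation).
#'
#' Two stopping rules are applied: the strict rule (every partition of
#' the round identical), and a stability rule for structures with more
#' than two blocks, where sweeping `k < K` necessarily produces merged
#' variants in every round: if the round's best-modularity partition is
#' identical to the previous round's, the procedure has reached a fixed
#' point and that partition is returned.
#'
#' @param coords data-projection coordinates (`n x d`).
#' @param C comparison matrix on the same nodes, used to score partitions.
#' @param c_init initial cluster count; defaults to `ncol(coords) + 1`.
#' @param p k-means repeats per cluster count (default 100).
#' @param max_rounds safety cap; if reached the best-modularity partition
#'   seen is returned with a warning.
#' @param seed optional integer seed.
#' @return a `network_partition` with extra fields `converged`, `rounds`
#'   and `K_trace`.
#' @export
consensus_cluster <- function(coords, C, c_init = NULL, p = 100,
                              max_rounds = 50, seed = NULL) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  if (is.null(c_init)) c_init <- ncol(coords) + 1
  if (c_init < 2 || c_init > n) stop("c_init must be in [2, n]")
  if (!is.null(seed)) set.seed(seed)
  nodes <- rownames(coords)

  run_batch <- function(xy, ks, p) {
    ks <- ks[ks <= nrow(unique(xy))]  # projection may collapse nodes
    if (length(ks) == 0) ks <- 2
    parts <- list()
    for (k in ks) for (r in seq_len(p))
      parts[[length(parts) + 1]] <- stats::setNames(
        safe_kmeans(xy, k)$cluster, nodes)
    parts
  }
  round_best <- function(parts) {
    qs <- vapply(parts, function(a) modularity_trace(indicator_matrix(a), C), 1)
    list(Q = max(qs), assignment = parts[[which.max(qs)]])
  }

  parts <- run_batch(coords, c_init, p)
  best <- round_best(parts)
  prev_best <- NULL
  K <- c_init; l <- c_init
  K_trace <- integer(0)
  for (round in seq_len(max_rounds)) {
    if (partitions_identical(parts))
      return(new_partition(parts[[1]], C,
                           extra = list(converged = TRUE, rounds = round - 1L,
                                        K_trace = K_trace)))
    rb <- round_best(parts)
    if (!is.null(prev_best) &&
        identical(canonical_labels(rb$assignment),
                  canonical_labels(prev_best$assignment)))
      return(new_partition(rb$assignment, C,
                           extra = list(converged = TRUE, rounds = round - 1L,
                                        K_trace = K_trace)))
    prev_best <- rb
    if (rb$Q > best$Q) best <- rb
    D <- consensus_matrix(parts)
    C_con <- D - consensus_null(p, K, l)
    diag(C_con) <- 0
    e <- eigen(C_con, symmetric = TRUE)
    tol <- max(abs(e$values)) * 1e-10
    K <- min(sum(e$values > tol), n - 1L)
    K_trace <- c(K_trace, K)
    if (K < 2) {
      warning("consensus comparison matrix has no positive dimensions; returning best-Q partition")
      return(new_partition(best$assignment, C,
                           extra = list(converged = FALSE, rounds = round,
                                        K_trace = K_trace)))
    }
    V <- fix_eigenvector_signs(e$vectors[, seq_len(K), drop = FALSE])
    xy <- sweep(V, 2, e$values[seq_len(K)], `*`)
    rownames(xy) <- nodes
    parts <- run_batch(xy, 2:max(2, K), p)
    l <- 2
  }
  warning("consensus clustering did not converge in ", max_rounds,
          " rounds; returning best-Q partition")
  new_partition(best$assignment, C,
                extra = list(converged = FALSE, rounds = max_rounds,
                             K_trace = K_trace))
}

#' Louvain community detection benchmark
#'
#' Thin wrapper around [igraph::cluster_louvain()] (configuration-model
#' modularity, agglomerative), repeated several times to expose run-to-run
#' variability in the number of detected modules.
#'
#' @param net a connected `weighted_network`.
#' @param runs repeat count (default 5).
#' @param seed optional integer seed.
#' @return list of class `louvain_benchmark`: `partitions` (assignment
#'   vectors), `n_modules` per run, and their `range`.
#' @export
louvain_benchmark <- function(net, runs = 5, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  g <- as_igraph(net)
  partitions <- vector("list", runs)
  for (r in seq_len(runs)) {
    cl <- igraph::cluster_louvain(g)
    partitions[[r]] <- stats::setNames(igraph::membership(cl), net$nodes)
  }
  n_modules <- vapply(partitions, function(a) length(unique(a)), 1L)
  structure(list(partitions = partitions, n_modules = n_modules,
                 range = range(n_modules)),
            class = "louvain_benchmark")
}

#' @export
print.louvain_benchmark <- function(x, ...) {
  cat(sprintf("<louvain_benchmark> %d runs, modules: %s (range %d-%d)\n",
              length(x$partitions), paste(x$n_modules, collapse = ", "),
              x$range[1], x$range[2]))
  invisible(x)
}

#' Normalised variation of information between two partitions
#'
#' `VI(X, Y) = H(X|Y) + H(Y|X)` in nats, normalised by `log(n)` so the
#' result lies in `[0, 1]`: 0 for identical partitions, 1 for the
#' singletons-versus-one-block extreme.
#'
#' @param a,b assignment vectors over the same nodes. If both are named
#'   they are aligned by name.
#' @return normalised VI in `[0, 1]`.
#' @export
normalised_vi <- function(a, b) {
  if (!is.null(names(a)) && !is.null(names(b))) {
    if (!setequal(names(a), names(b))) stop("partitions cover different node sets")
    b <- b[names(a)]
  } else if (length(a) != length(b)) {
    stop("partitions cover different node sets")
  }
  n <- length(a)
  if (n < 2) return(0)
  joint <- table(a, b) / n
  px <- rowSums(joint); py <- colSums(joint)
  ent <- function(p) { p <- p[p > 0]; -sum(p * log(p)) }
  vi <- 2 * ent(joint) - ent(px) - ent(py)
  max(0, min(1, vi / log(n)))
}
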