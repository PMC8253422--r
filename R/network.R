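#' Construct a weighted undirected network
#'
#' The basic container used throughout the package: a symmetric, nonnegative
#' weight matrix `W` with a zero diagonal, together with node labels and a
#' weight class. The adjacency matrix `A` is implied by `A_ij = 1` iff
#' `W_ij > 0` and is available through [adjacency()].
#'
#' @param W symmetric numeric matrix of nonnegative link weights; the
#'   diagonal must be zero (self-loops are not supported).
#' @param nodes character vector of node labels, recycled from
#'   `rownames(W)` or `"n1".."nn"` when missing.
#' @param weight_class one of `"binary"`, `"integer"`, `"real"`; detected
#'   from the weights when `NULL`.
#' @param kappa positive quantisation factor recorded on the network;
#'   `1` for binary/integer networks. See [quantise_weights()].
#'
#' @return an object of class `weighted_network` with elements `W`,
#'   `nodes`, `weight_class` and `kappa`.
#' @seealso [read_edge_list()], [network_stats()], [giant_component()]
#' @export
weighted_network <- function(W, nodes = NULL, weight_class = NULL, kappa = 1) {
  W <- as.matrix(W)
  if (nrow(W) != ncol(W)) stop("W must be square")
  n <- nrow(W)
  if (n > 0) {
    if (any(!is.finite(W))) stop("W must be finite")
    if (any(W < 0)) stop("negative weights are not allowed")
    if (max(abs(W - t(W))) > 1e-10) stop("W must be symmetric")
    if (any(diag(W) != 0)) stop("self-loops are not supported: diagonal of W must be zero")
    W <- (W + t(W)) / 2  # remove numerically-trivial asymmetry
  }
  if (is.null(nodes)) {
    nodes <- rownames(W)
    if (is.null(nodes)) nodes <- paste0("n", seq_len(n))
  }
  nodes <- as.character(nodes)
  if (length(nodes) != n) stop("length(nodes) must equal nrow(W)")
  if (anyDuplicated(nodes)) stop("node labels must be unique")
  dimnames(W) <- list(nodes, nodes)
  if (is.null(weight_class)) {
    weight_class <- if (all(W %in% c(0, 1))) "binary"
      else if (all(W == round(W))) "integer"
      else "real"
  }
  weight_class <- match.arg(weight_class, c("binary", "integer", "real"))
  if (weight_class %in% c("binary", "integer") && any(W != round(W)))
    stop("non-integer weights in a ", weight_class, " network")
  if (!is.numeric(kappa) || length(kappa) != 1 || kappa <= 0)
    stop("kappa must be a positive scalar")
  structure(list(W = W, nodes = nodes, weight_class = weight_class,
                 kappa = kappa),
            class = "weighted_network")
}

#' @export
print.weighted_network <- function(x, ...) {
  n <- n_nodes(x)
  m <- if (n > 0) sum(x$W[upper.tri(x$W)] > 0) else 0L
  cat(sprintf("<weighted_network> %d nodes, %d links, %s weights",
              n, m, x$weight_class))
  if (x$kappa != 1) cat(sprintf(" (kappa = %g)", x$kappa))
  cat("\n")
  invisible(x)
}

#' Number of nodes in a network
#' @param net a `weighted_network`.
#' @return integer node count.
#' @export
n_nodes <- function(net) nrow(net$W)

#' Adjacency matrix of a weighted network
#'
#' @param net a `weighted_network`.
#' @return binary matrix with `A_ij = 1` iff `W_ij > 0`.
#' @export
adjacency <- function(net) {
  A <- (net$W > 0) * 1
  dimnames(A) <- dimnames(net$W)
  A
}

#' Node strengths (weighted degrees)
#' @param net a `weighted_network`.
#' @return named numeric vector of row sums of `W`.
#' @export
strengths <- function(net) rowSums(net$W)

#' Node degrees
#' @param net a `weighted_network`.
#' @return named numeric vector of row sums of the adjacency matrix.
#' @export
degrees <- function(net) rowSums(adjacency(net))

#' Induced subnetwork on a set of nodes
#' @param net a `weighted_network`.
#' @param nodes character labels or integer indices of the nodes to keep.
#' @return a `weighted_network` on the selected nodes, labels preserved.
#' @export
subnetwork <- function(net, nodes) {
  if (is.character(nodes)) {
    idx <- match(nodes, net$nodes)
    if (anyNA(idx)) stop("unknown node labels: ",
                         paste(nodes[is.na(idx)], collapse = ", "))
  } else idx <- as.integer(nodes)
  weighted_network(net$W[idx, idx, drop = FALSE], nodes = net$nodes[idx],
                   weight_class = net$weight_class, kappa = net$kappa)
}

#' Read a weighted edge list
#'
#' Reads a whitespace/tab-delimited file of `(node_i, node_j, weight)`
#' records into a [weighted_network()]. Node indices are assigned in
#' first-seen order. A record `(i, j, w)` implies the undirected link
#' `i -- j`; if both `(i, j)` and `(j, i)` appear with unequal weights the
#' input is treated as directed and is an error unless `symmetrize = TRUE`,
#' in which case `W <- (W + t(W)) / 2`.
#'
#' @param path file path, or a connection.
#' @param symmetrize average the two directions of a directed edge list.
#' @param header `TRUE`/`FALSE`, or `NA` to auto-detect (a non-numeric
#'   third field on the first line is taken as a header).
#' @return a `weighted_network`.
#' @export
read_edge_list <- function(path, symmetrize = FALSE, header = NA) {
  first <- readLines(path, n = 1L)
  if (length(first) == 0) stop("empty edge list: ", path)
  if (is.na(header)) {
    fields <- strsplit(trimws(first), "[\t ,]+")[[1]]
    header <- length(fields) >= 3 && is.na(suppressWarnings(as.numeric(fields[3])))
  }
  df <- utils::read.table(path, header = header, sep = "",
                          colClasses = c("character", "character", "numeric"),
                          col.names = c("from", "to", "weight"),
                          stringsAsFactors = FALSE)
  edge_list_network(df$from, df$to, df$weight, symmetrize = symmetrize)
}

#' Build a network from edge vectors
#'
#' Workhorse behind [read_edge_list()]; useful for constructing networks
#' programmatically.
#'
#' @param from,to node labels of each record.
#' @param weight nonnegative link weights.
#' @inheritParams read_edge_list
#' @return a `weighted_network`.
#' @export
edge_list_network <- function(from, to, weight = 1, symmetrize = FALSE) {
  from <- as.character(from); to <- as.character(to)
  weight <- rep_len(as.numeric(weight), length(from))
  if (length(from) != length(to)) stop("from/to length mismatch")
  if (any(weight < 0)) stop("negative weights are not allowed")
  if (any(from == to)) stop("self-loop records are not supported (diagonal must be zero)")
  nodes <- unique(c(rbind(from, to)))  # first-seen order along records
  n <- length(nodes)
  i <- match(from, nodes); j <- match(to, nodes)
  key <- paste0(i, ":", j)
  if (anyDuplicated(key)) stop("duplicate records for the same ordered node pair")
  D <- matrix(0, n, n, dimnames = list(nodes, nodes))
  D[cbind(i, j)] <- weight
  if (symmetrize) {
    W <- (D + t(D)) / 2
  } else {
    both <- D > 0 & t(D) > 0
    if (any(D[both] != t(D)[both]))
      stop("unequal weights for (i,j) and (j,i); use symmetrize = TRUE for directed input")
    W <- pmax(D, t(D))
  }
  weighted_network(W, nodes = nodes)
}

#' Write a network as a TSV edge list
#'
#' One `node_i <TAB> node_j <TAB> weight` line per unique link (`i` before
#' `j` in index order). Weights are written at full precision.
#'
#' @param net a `weighted_network`.
#' @param path output file path.
#' @param header write a column-name header line.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(net, path, header = FALSE) {
  W <- net$W
  idx <- which(upper.tri(W) & W > 0, arr.ind = TRUE)
  df <- data.frame(from = net$nodes[idx[, 1]], to = net$nodes[idx[, 2]],
                   weight = format(W[idx], digits = 17, trim = TRUE,
                                   scientific = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = header)
  invisible(path)
}

#' Summary statistics of a network
#'
#' @param net a `weighted_network` with at least two nodes.
#' @return a list of class `network_stats`: node count `n`, unique link
#'   count `links`, `density = links / (n (n - 1))`, total unique weight
#'   `total_weight` (half the strength sum), and the per-node `strengths`
#'   and `degrees` vectors.
#' @export
network_stats <- function(net) {
  n <- n_nodes(net)
  if (n < 2) stop("network_stats needs at least 2 nodes")
  s <- strengths(net)
  k <- degrees(net)
  m <- sum(k) / 2
  structure(list(n = n, links = m, density = m / (n * (n - 1)),
                 total_weight = sum(s) / 2, strengths = s, degrees = k),
            class = "network_stats")
}

#' @export
print.network_stats <- function(x, ...) {
  cat(sprintf("n = %d nodes, m = %g links, density = %.4g, total weight = %g\n",
              x$n, x$links, x$density, x$total_weight))
  cat(sprintf("strength: mean %.3g [%g, %g]; degree: mean %.3g [%g, %g]\n",
              mean(x$strengths), min(x$strengths), max(x$strengths),
              mean(x$degrees), min(x$degrees), max(x$degrees)))
  invisible(x)
}

#' Giant component of a network
#'
#' Induced subnetwork on the largest connected component. Ties between
#' equally large components are broken in favour of the component
#' containing the lowest node index.
#'
#' @param net a `weighted_network` with at least one node.
#' @return a `weighted_network`; node labels are preserved.
#' @export
giant_component <- function(net) {
  n <- n_nodes(net)
  if (n == 0) stop("empty network")
  g <- as_igraph(net)
  comp <- igraph::components(g)
  sizes <- comp$csize
  best <- which(sizes == max(sizes))
  if (length(best) > 1) {
    # component containing the smallest original node index
    first_idx <- vapply(best, function(b) min(which(comp$membership == b)), 1L)
    best <- best[which.min(first_idx)]
  }
  subnetwork(net, which(comp$membership == best))
}

#' Quantise real-valued weights to integers
#'
#' Scales all weights by a conversion factor `kappa` and rounds to the
#' nearest integer (ties away from zero). Weights that round to zero cease
#' to be links. The factor is stored on the result so downstream outputs
#' can be rescaled by `1/kappa`. For an integer network `kappa = 1` is the
#' identity.
#'
#' @param net a `weighted_network`.
#' @param kappa positive conversion factor; use e.g. 2 for weights in
#'   steps of 0.5, or 100 for similarity weights in `[0, 1]` (weights
#'   below 1/200 then stop being links).
#' @return an integer-weighted `weighted_network` carrying `kappa`.
#' @export
quantise_weights <- function(net, kappa) {
  if (!is.numeric(kappa) || length(kappa) != 1 || kappa <= 0)
    stop("kappa must be a positive scalar")
  Wq <- round_half_away(net$W * kappa)
  cls <- if (all(Wq %in% c(0, 1))) "binary" else "integer"
  weighted_network(Wq, nodes = net$nodes, weight_class = cls, kappa = kappa)
}

# nearest integer, ties away from zero (base round() rounds half to even)
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Convert to an igraph graph
#'
#' @param net a `weighted_network`.
#' @return an undirected weighted `igraph` graph with vertex names.
#' @export
as_igraph <- function(net) {
  igraph::graph_from_adjacency_matrix(net$W, mode = "undirected",
                                      weighted = TRUE, diag = FALSE)
}
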