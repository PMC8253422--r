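# small fixture builders used across test files

# path a - b - c - ... with unit weights
path_network <- function(labels) {
  n <- length(labels)
  W <- matrix(0, n, n)
  for (i in seq_len(n - 1)) W[i, i + 1] <- W[i + 1, i] <- 1
  weighted_network(W, nodes = labels)
}

# two cliques of size k each, disconnected, unit weights
two_cliques_network <- function(k = 3) {
  n <- 2 * k
  W <- matrix(0, n, n)
  W[seq_len(k), seq_len(k)] <- 1
  W[(k + 1):n, (k + 1):n] <- 1
  diag(W) <- 0
  weighted_network(W, nodes = letters[seq_len(n)])
}

# Erdos-Renyi weighted network with at least one link
random_weighted_network <- function(n, p = 0.3, max_w = 5) {
  repeat {
    W <- matrix(0, n, n)
    ut <- upper.tri(W)
    link <- stats::runif(sum(ut)) < p
    W[ut][link] <- sample.int(max_w, sum(link), replace = TRUE)
    W <- W + t(W)
    if (sum(W) > 0) return(weighted_network(W))
  }
}

# small planted-structure network that the spectral step detects reliably
small_modular_synthetic <- function(seed, n = 90, groups = 3,
                                    p_within = 0.35, p_between = 0.05,
                                    lambda_s = 60, f_noise = 0,
                                    p_noise = 0.05) {
  spec <- synthetic_spec(n = n, groups = groups, p_within = p_within,
                         p_between = p_between, lambda_s = lambda_s,
                         f_noise = f_noise, p_noise = p_noise)
  generate_synthetic(spec, seed = seed)
}

# write an edge-list data.frame to a temp TSV, returning the path
write_temp_edges <- function(df, header = FALSE) {
  path <- tempfile(fileext = ".tsv")
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = header)
  path
}
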