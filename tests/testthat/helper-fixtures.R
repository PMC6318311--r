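# Shared fixtures, built in code at test time.

# tiny deterministic count matrix with named genes/cells
tiny_counts <- function(values, n_genes, n_cells, genes = NULL,
                        barcodes = NULL, batch = NULL) {
  m <- matrix(values, n_genes, n_cells)
  rownames(m) <- if (is.null(genes)) sprintf("g%03d", seq_len(n_genes)) else genes
  colnames(m) <- if (is.null(barcodes)) sprintf("c%03d", seq_len(n_cells)) else barcodes
  count_matrix(m, batch = batch)
}

# small simulated fixture shared across tests (cached per session)
small_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- simulate_counts(sim_config(
        n_genes = 600, n_types = 3, n_subtypes_per_type = 1,
        cells_per_type_per_batch = 40, markers_per_type = 10,
        submarkers_per_subtype = 0, n_control_genes = 40,
        libsize_log_mean = log(1500), doublet_rate = 0, seed = 401L))
    cache
  }
})

# independent brute-force oracles -------------------------------------------

# upper binomial tail P(X >= m) by direct summation of the pmf formula
oracle_binom_tail <- function(m, n, p) {
  if (m <= 0) return(1)
  k <- m:n
  sum(choose(n, k) * p^k * (1 - p)^(n - k))
}

# BH step-up from its definition
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  ranked <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(ranked)))
  out <- numeric(n)
  out[o] <- pmin(adj, 1)
  out
}

# hypergeometric upper tail P(X >= a) for a 2x2 table: b expressing cells
# of d total, draw c cells (the type)
oracle_hyper_tail <- function(a, b, c, d) {
  if (a <= 0) return(1)
  k <- a:min(b, c)
  sum(choose(b, k) * choose(d - b, c - k) / choose(d, c))
}

# Yates chi-square from the N(|ad-bc|-N/2)^2 formula
oracle_yates <- function(a1, n1, a2, n2) {
  a <- a1; b <- n1 - a1; c <- a2; d <- n2 - a2
  N <- n1 + n2
  N * max(0, abs(a * d - b * c) - N / 2)^2 /
    ((a + b) * (c + d) * (a + c) * (b + d))
}
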