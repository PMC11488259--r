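# Small fixtures built in code, shared across test files.

# Deterministic random count matrix.
random_counts <- function(genes = 30, cells = 20, lambda = 4, seed = 1) {
  set.seed(seed)
  m <- matrix(rpois(genes * cells, lambda), genes, cells,
              dimnames = list(sprintf("g%02d", seq_len(genes)),
                              sprintf("c%02d", seq_len(cells))))
  count_matrix(m)
}

# Two NB populations with a 4-fold mean shift in the first `n_shift`
# genes; returns counts plus the population label per cell.
two_population_counts <- function(genes = 120, cells = 100, n_shift = 50,
                                  mu = 4, size = 4, seed = 1) {
  set.seed(seed)
  pop <- rep(1:2, length.out = cells)
  mu_mat <- matrix(mu, genes, cells)
  mu_mat[seq_len(n_shift), pop == 2] <- mu * 4
  m <- matrix(rnbinom(genes * cells, mu = as.vector(mu_mat), size = size),
              genes, cells,
              dimnames = list(sprintf("g%03d", seq_len(genes)),
                              sprintf("c%03d", seq_len(cells))))
  list(counts = count_matrix(m), pop = pop)
}

# Two well-separated Gaussian clusters in 2-D with unequal abundance.
two_cluster_embedding <- function(n = 1000, frac_b = 0.05, sep = 12, seed = 1) {
  set.seed(seed)
  n_b <- round(n * frac_b)
  coords <- rbind(matrix(rnorm(2 * (n - n_b)), ncol = 2),
                  matrix(rnorm(2 * n_b), ncol = 2) + sep)
  list(coords = coords, is_b = c(rep(FALSE, n - n_b), rep(TRUE, n_b)))
}

# Minimal lineage_series wrapper around a genes x T expression matrix.
as_series <- function(mat, lineage = "CT1") {
  structure(list(expr = mat, metacell_ids = seq_len(ncol(mat)),
                 fate_prob = seq_len(ncol(mat)) / ncol(mat),
                 lineage = lineage),
            class = "lineage_series")
}

# Small default simulated dataset used by several integration tests.
small_sim <- function(n_cells = 600, seed = 11, ...) {
  simulate_dataset(n_cells = n_cells, rng_seed = seed, ...)
}
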