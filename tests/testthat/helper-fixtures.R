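# shared fixtures and independent oracles

# random sparse NB count matrix with named genes/cells
random_cm <- function(n_genes = 50, n_cells = 30, mu = 1, size = 1,
                      seed = 1) {
  set.seed(seed)
  m <- matrix(rnbinom(n_genes * n_cells, mu = mu, size = size),
              n_genes, n_cells)
  count_matrix(Matrix::Matrix(m, sparse = TRUE),
               gene_ids = sprintf("G%03d", seq_len(n_genes)),
               cell_ids = sprintf("C%03d", seq_len(n_cells)))
}

# small two-species generator config for fast tests
small_gen <- function(seed = 1, ...) {
  generator_config(cells_per_type_per_condition = c(control = 40,
                                                    aneurysm = 40),
                   n_ortholog_genes = 500, n_species_specific_genes = 50,
                   seed = seed, ...)
}

# brute-force two-sided Wilcoxon p by enumerating all C(N, nx) group
# assignments of the pooled midranks (independent of the implementation)
enum_wilcox_p <- function(x, y) {
  pool <- c(x, y)
  nx <- length(x)
  N <- length(pool)
  r <- rank(pool)
  mu <- nx * (N - nx) / 2
  combs <- utils::combn(N, nx)
  us <- colSums(matrix(r[combs], nrow = nx)) - nx * (nx + 1) / 2
  u_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-12)
}

# brute-force upper-tail hypergeometric P(X >= k)
enum_hyper_p <- function(k, K, N, n) {
  if (k <= 0) return(1)
  ks <- k:min(K, n)
  sum(choose(K, ks) * choose(N - K, n - ks)) / choose(N, n)
}

# majority truth type of each cluster
majority_type <- function(labels, truth) {
  vapply(split(truth[names(labels)], labels),
         function(v) names(which.max(table(v))), character(1))
}
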