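# Shared fixtures and independent oracles for the test suite. Oracles are
# deliberately naive (double loops, literal textbook formulas, full
# enumeration) and never call the code paths they check.

jaccard <- function(a, b) {
  if (length(a) == 0L && length(b) == 0L) return(1)
  length(intersect(a, b)) / length(union(a, b))
}

# small deterministic matrix with hand-set values
tiny_matrix <- function(values, gene_ids = NULL, array_ids = NULL) {
  if (is.null(gene_ids)) gene_ids <- paste0("g", seq_len(nrow(values)))
  if (is.null(array_ids)) array_ids <- paste0("a", seq_len(ncol(values)))
  dimnames(values) <- list(gene_ids, array_ids)
  expression_matrix(values)
}

# standard implanted-bicluster simulation used across tests
implanted_sim <- function(rng_seed, n_genes = 200, n_arrays = 50,
                          bc_genes = 20, bc_arrays = 10,
                          displacement = 2, sigma = 0.25,
                          missing_rate = 0) {
  simulate_expression(simulation_config(
    n_genes = n_genes, n_arrays = n_arrays,
    biclusters = list(list(n_genes = bc_genes, n_arrays = bc_arrays,
                           displacement = displacement, sigma = sigma)),
    missing_rate = missing_rate, rng_seed = rng_seed))
}

# literal textbook Normal-Inverse-Chi-Squared update, written independently
# of the package internals
textbook_nix2_map <- function(x, mu0, kappa0, nu0, sigma0sq) {
  n <- length(x)
  if (n == 0L) return(list(mu = mu0, sigma2 = sigma0sq))
  xbar <- mean(x)
  S <- sum((x - xbar)^2)
  kappa_n <- kappa0 + n
  mu_n <- (kappa0 * mu0 + n * xbar) / kappa_n
  nu_n <- nu0 + n
  nu_sigma2_n <- nu0 * sigma0sq + S +
    (kappa0 * n / kappa_n) * (xbar - mu0)^2
  list(mu = mu_n, sigma2 = nu_sigma2_n / (nu_n + 3))
}

# full-enumeration hypergeometric mid-P via binomial coefficients
enum_midp <- function(k, K, n, N) {
  kk <- 0:min(K, n)
  mass <- choose(K, kk) * choose(N - K, n - kk) / choose(N, n)
  0.5 * mass[kk == k] + sum(mass[kk > k])
}

# naive double-loop quality statistics
naive_std_within <- function(matrix, genes, arrays) {
  sub <- matrix[genes, arrays, drop = FALSE]
  total <- 0
  count <- 0
  for (j in seq_along(arrays)) {
    xbar <- mean(sub[, j], na.rm = TRUE)
    for (i in seq_along(genes)) {
      if (!is.na(sub[i, j])) {
        total <- total + (sub[i, j] - xbar)^2
        count <- count + 1
      }
    }
  }
  sqrt(total / count)
}

naive_std_across <- function(matrix, genes, arrays) {
  sub <- matrix[genes, arrays, drop = FALSE]
  total <- 0
  for (j in seq_along(arrays)) total <- total + mean(sub[, j], na.rm = TRUE)^2
  sqrt(total / length(arrays))
}

# background/prior/run in one call with package defaults
quick_fit <- function(matrix, seeds, ...) {
  bg <- estimate_background(matrix)
  run_em(matrix, seeds, bg, build_prior(matrix, seeds, bg, ...))
}
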