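# Normal-Inverse-Chi-Squared conjugate machinery for the per-(array, bicluster)
# Gaussians. All functions are vectorized over arrays.

# posterior hyperparameters given sufficient statistics (n, xbar, S) of the
# member-gene values on each array
nix2_posterior <- function(n, xbar, S, mu0, kappa0, nu0, sigma0sq) {
  xbar[n == 0] <- mu0[n == 0]  # irrelevant, keeps arithmetic finite
  S[n == 0] <- 0
  kappa_n <- kappa0 + n
  mu_n <- (kappa0 * mu0 + n * xbar) / kappa_n
  nu_n <- nu0 + n
  nu_sigma2_n <- nu0 * sigma0sq + S + (kappa0 * n / kappa_n) * (xbar - mu0)^2
  list(mu_n = mu_n, kappa_n = kappa_n, nu_n = nu_n, nu_sigma2_n = nu_sigma2_n)
}

# joint mode of the Normal-Inverse-Chi-Squared density in (mu, sigma^2)
nix2_map <- function(post) {
  list(mu = post$mu_n, sigma2 = post$nu_sigma2_n / (post$nu_n + 3))
}

# log density of a scaled inverse chi-squared distribution
ld_sinvchisq <- function(x, nu, tau2) {
  (nu / 2) * log(nu * tau2 / 2) - lgamma(nu / 2) -
    (1 + nu / 2) * log(x) - nu * tau2 / (2 * x)
}

# log Normal-Inverse-Chi-Squared density at (mu, sigma2)
ld_nix2 <- function(mu, sigma2, mu0, kappa0, nu0, sigma0sq) {
  ld_sinvchisq(sigma2, nu0, sigma0sq) +
    stats::dnorm(mu, mu0, sqrt(sigma2 / kappa0), log = TRUE)
}

# sigma^2 at the joint mode of the prior itself
nix2_prior_mode_sigma2 <- function(nu0, sigma0sq) {
  nu0 * sigma0sq / (nu0 + 3)
}

# Candidate MAP fit of every array's bicluster Normal given the current member
# genes, plus the log-prior-density of the fit relative to the prior mode
# (the Occam correction used by the array assignment score). Returns NULL-safe
# values for arrays with no present member values (n = 0).
fit_bicluster_arrays <- function(matrix, member_genes, prior, sigma_floor) {
  sub <- matrix[member_genes, , drop = FALSE]
  present <- !is.na(sub)
  n <- colSums(present)
  xbar <- numeric(ncol(sub))
  pos <- n > 0L
  xbar[pos] <- colMeans(sub[, pos, drop = FALSE], na.rm = TRUE)
  centred <- sweep(sub, 2L, xbar, "-")
  S <- colSums(centred^2, na.rm = TRUE)

  sigma0sq <- prior$sigma0^2
  post <- nix2_posterior(n, xbar, S, prior$mu0, prior$kappa0, prior$nu0,
                         sigma0sq)
  map <- nix2_map(post)
  sigma2 <- pmax(map$sigma2, sigma_floor^2)

  mode_sigma2 <- pmax(nix2_prior_mode_sigma2(prior$nu0, sigma0sq),
                      sigma_floor^2)
  prior_corr <- ld_nix2(map$mu, sigma2, prior$mu0, prior$kappa0, prior$nu0,
                        sigma0sq) -
    ld_nix2(prior$mu0, mode_sigma2, prior$mu0, prior$kappa0, prior$nu0,
            sigma0sq)

  list(mu = map$mu, sigma = sqrt(sigma2), n = n, prior_corr = prior_corr)
}

# G x A matrix of per-cell log-density ratios bicluster vs background;
# mu/sigma are per-array vectors. NA cells stay NA.
log_density_ratio <- function(matrix, mu, sigma, background) {
  d1 <- sweep(matrix, 2L, mu, "-")
  d0 <- sweep(matrix, 2L, background$mu, "-")
  out <- sweep(d0^2, 2L, 2 * background$sigma^2, "/") -
    sweep(d1^2, 2L, 2 * sigma^2, "/")
  sweep(out, 2L, log(background$sigma / sigma), "+")
}
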