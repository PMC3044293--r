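#' Robust per-array background estimation
#'
#' The expression values of genes that do not belong to any bicluster are
#' modelled per array as a Normal distribution. Its parameters are estimated
#' up front, once, by symmetric trimming: on each array the most over- and
#' underexpressed values (a fraction `trim_fraction` at each end) are removed,
#' and the mean and standard deviation of the retained values are taken. The
#' standard deviation is rescaled by the Normal truncation-consistency factor,
#' so that on an uncontaminated Normal array the estimator is (asymptotically)
#' unbiased. The background parameters are fixed and never re-estimated during
#' EM.
#'
#' @param matrix Genes x arrays expression matrix (see [expression_matrix()]).
#' @param trim_fraction Fraction trimmed at each tail, in \[0, 0.45\].
#'   Default 0.1.
#' @param sigma_floor Lower clamp for the background standard deviation.
#'   `NULL` (default) uses `1e-3` times the median of the unclamped per-array
#'   estimates.
#' @return Object of class `probic_background`: list with numeric vectors
#'   `mu` and `sigma` named by array id, and the `sigma_floor` used.
#' @examples
#' m <- matrix(rnorm(2000), 100, 20,
#'             dimnames = list(paste0("g", 1:100), paste0("a", 1:20)))
#' bg <- estimate_background(expression_matrix(m))
#' @export
estimate_background <- function(matrix, trim_fraction = 0.1, sigma_floor = NULL) {
  stopifnot(is.numeric(trim_fraction), length(trim_fraction) == 1L,
            trim_fraction >= 0, trim_fraction <= 0.45)
  array_ids <- colnames(matrix)
  mu <- sigma <- numeric(ncol(matrix))
  for (j in seq_len(ncol(matrix))) {
    x <- matrix[, j]
    x <- x[!is.na(x)]
    n <- length(x)
    if (n < 3L)
      stop_input("array '", array_ids[j], "' has fewer than 3 present values")
    k <- floor(trim_fraction * n)
    if (n - 2L * k < 3L)
      stop_input("array '", array_ids[j],
                 "' retains fewer than 3 values after trimming")
    kept <- sort(x)[(k + 1L):(n - k)]
    alpha <- k / n
    mu[j] <- mean(kept)
    sigma[j] <- stats::sd(kept) / sqrt(trimmed_normal_variance(alpha))
  }
  if (is.null(sigma_floor)) sigma_floor <- 1e-3 * stats::median(sigma)
  stopifnot(sigma_floor > 0)
  sigma <- pmax(sigma, sigma_floor)
  names(mu) <- names(sigma) <- array_ids
  structure(list(mu = mu, sigma = sigma, sigma_floor = sigma_floor,
                 trim_fraction = trim_fraction),
            class = "probic_background")
}

# variance of a standard Normal truncated to its central (1 - 2*alpha) mass;
# dividing the trimmed-sample sd by sqrt of this restores consistency
trimmed_normal_variance <- function(alpha) {
  if (alpha <= 0) return(1)
  b <- stats::qnorm(1 - alpha)
  1 - 2 * b * stats::dnorm(b) / (1 - 2 * alpha)
}

#' Construct a background model from known parameters
#'
#' Bypasses estimation; useful when the per-array background is known (e.g.
#' from a spike-in design or a simulation) or fixed by hand.
#'
#' @param mu Numeric vector of per-array means, named by array id.
#' @param sigma Numeric vector of per-array standard deviations, same length.
#' @param sigma_floor Lower clamp applied to `sigma` (default `1e-8`).
#' @return Object of class `probic_background`.
#' @export
background_model <- function(mu, sigma, sigma_floor = 1e-8) {
  stopifnot(length(mu) == length(sigma), all(sigma > 0), sigma_floor > 0)
  if (is.null(names(mu))) names(mu) <- names(sigma)
  stopifnot(!is.null(names(mu)))
  names(sigma) <- names(mu)
  structure(list(mu = mu, sigma = pmax(sigma, sigma_floor),
                 sigma_floor = sigma_floor, trim_fraction = NA_real_),
            class = "probic_background")
}

#' @export
print.probic_background <- function(x, ...) {
  cat("Per-array background model (", length(x$mu), " arrays)\n", sep = "")
  cat("  mu    in [", round(min(x$mu), 4), ", ", round(max(x$mu), 4), "]\n",
      sep = "")
  cat("  sigma in [", round(min(x$sigma), 4), ", ", round(max(x$sigma), 4),
      "]\n", sep = "")
  cat("  trim fraction ", x$trim_fraction,
      ", sigma floor ", signif(x$sigma_floor, 3), "\n", sep = "")
  invisible(x)
}
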