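# Hidden-variable state, MAP parameter updates and penalized assignment
# scores of the probabilistic bicluster model.

as_seed_list <- function(seed_genes) {
  if (!is.list(seed_genes)) seed_genes <- list(seed_genes)
  if (length(seed_genes) == 0L) stop_input("no seed sets supplied")
  seed_genes
}

as_prior_list <- function(prior, n_biclusters) {
  if (inherits(prior, "probic_prior")) prior <- list(prior)
  if (length(prior) != n_biclusters)
    stop_input("need one prior per bicluster (got ", length(prior),
               " for ", n_biclusters, ")")
  prior
}

#' Initialize the hidden membership variables from a seed set
#'
#' Gene membership starts as exactly the seed genes; array membership starts
#' all-true, so the first maximization step fits every array and the first
#' expectation step prunes arrays by their penalized score.
#'
#' @param matrix Expression matrix.
#' @param seed_genes Character vector of seed gene ids, or a list of such
#'   vectors for multiple biclusters.
#' @return Object of class `probic_assignment`: logical matrices `gene`
#'   (genes x biclusters) and `array` (arrays x biclusters).
#' @export
init_assignments <- function(matrix, seed_genes) {
  seed_genes <- as_seed_list(seed_genes)
  B <- length(seed_genes)
  gene <- matrix(FALSE, nrow(matrix), B,
                 dimnames = list(rownames(matrix), NULL))
  array <- matrix(TRUE, ncol(matrix), B,
                  dimnames = list(colnames(matrix), NULL))
  for (b in seq_len(B)) {
    seeds <- check_seed_genes(matrix, seed_genes[[b]])
    gene[seeds, b] <- TRUE
  }
  structure(list(gene = gene, array = array), class = "probic_assignment")
}

#' MAP update of the bicluster Normal parameters
#'
#' The maximization step of hard EM. For each (array, bicluster) pair the
#' Normal-Inverse-Chi-Squared prior is updated with the member genes' present
#' values on that array, and the joint posterior mode is returned:
#' `mu = mu_n` and `sigma^2 = nu_n * sigma2_n / (nu_n + 3)`, clamped below at
#' `sigma_floor`. An array with no present member values keeps the prior
#' values `(mu0, sigma0)`.
#'
#' @param matrix Expression matrix.
#' @param assignment `probic_assignment`.
#' @param prior `probic_prior`, or list of priors (one per bicluster).
#' @param sigma_floor Lower clamp on the bicluster standard deviation.
#' @return Object of class `probic_params`: numeric matrices `mu` and `sigma`
#'   (arrays x biclusters); values for arrays not assigned to the bicluster
#'   are the candidate fits that the expectation step scores.
#' @export
map_update_params <- function(matrix, assignment, prior, sigma_floor = 1e-8) {
  B <- ncol(assignment$gene)
  priors <- as_prior_list(prior, B)
  mu <- sigma <- matrix(NA_real_, ncol(matrix), B,
                        dimnames = list(colnames(matrix), NULL))
  for (b in seq_len(B)) {
    genes_b <- assignment$gene[, b]
    if (!any(genes_b)) {
      mu[, b] <- priors[[b]]$mu0
      sigma[, b] <- priors[[b]]$sigma0
      next
    }
    fit <- fit_bicluster_arrays(matrix, genes_b, priors[[b]], sigma_floor)
    empty <- fit$n == 0L
    mu[, b] <- ifelse(empty, priors[[b]]$mu0, fit$mu)
    sigma[, b] <- ifelse(empty, priors[[b]]$sigma0, fit$sigma)
  }
  structure(list(mu = mu, sigma = sigma), class = "probic_params")
}

#' Penalized log score for assigning a gene to a bicluster
#'
#' Sum over the bicluster's member arrays (present values only) of the log
#' density ratio between the bicluster Normal and the array's background
#' Normal, minus the per-value penalty `log_penalty` for each such value, plus
#' the log prior odds `log(p_gene / (1 - p_gene))` and the gene's bias offset.
#' The expectation step assigns the gene iff the score is strictly positive.
#'
#' @param gene Gene id.
#' @param bicluster Bicluster index.
#' @param matrix Expression matrix.
#' @param params `probic_params` (current MAP parameters).
#' @param assignment `probic_assignment` (current memberships).
#' @param background `probic_background`.
#' @param prior `probic_prior` or list of priors.
#' @return A single real score; with no member arrays it reduces to the prior
#'   odds and bias terms.
#' @export
gene_log_score <- function(gene, bicluster, matrix, params, assignment,
                           background, prior) {
  prior <- as_prior_list(prior, ncol(assignment$gene))[[bicluster]]
  if (!gene %in% rownames(matrix)) stop_input("unknown gene id: ", gene)
  arrays <- assignment$array[, bicluster]
  x <- matrix[gene, ]
  use <- arrays & !is.na(x)
  lr <- sum(stats::dnorm(x[use], params$mu[use, bicluster],
                         params$sigma[use, bicluster], log = TRUE) -
            stats::dnorm(x[use], background$mu[use], background$sigma[use],
                         log = TRUE))
  lr - sum(use) * prior$log_penalty +
    log(prior$p_gene / (1 - prior$p_gene)) + prior$gene_bias[[gene]]
}

#' Penalized log score for assigning an array to a bicluster
#'
#' Scores the candidate MAP fit of the array's bicluster Normal (computed from
#' the current member genes) against the array's background distribution: the
#' sum over member genes' present values of the log density ratio, minus the
#' per-value penalty, plus the array's bias offset and the log prior density
#' of the candidate parameters relative to the prior mode. The last term
#' charges the assignment for how far the fitted parameters had to move from
#' the prior, which makes every expectation-step update an exact coordinate
#' ascent step on [log_posterior()].
#'
#' @inheritParams gene_log_score
#' @param array Array id.
#' @param sigma_floor Lower clamp on the candidate standard deviation.
#' @return A single real score; the array is assigned iff it is strictly
#'   positive. An array whose member-gene values are all missing scores
#'   `-Inf`.
#' @export
array_log_score <- function(array, bicluster, matrix, assignment, background,
                            prior, sigma_floor = 1e-8) {
  prior <- as_prior_list(prior, ncol(assignment$gene))[[bicluster]]
  if (!array %in% colnames(matrix)) stop_input("unknown array id: ", array)
  genes <- assignment$gene[, bicluster]
  if (!any(genes))
    stop_input("array score undefined for a bicluster with no member genes")
  fit <- fit_bicluster_arrays(matrix, genes, prior, sigma_floor)
  a <- match(array, colnames(matrix))
  if (fit$n[a] == 0L) return(-Inf)
  x <- matrix[genes, a]
  x <- x[!is.na(x)]
  lr <- sum(stats::dnorm(x, fit$mu[a], fit$sigma[a], log = TRUE) -
            stats::dnorm(x, background$mu[a], background$sigma[a], log = TRUE))
  unname(lr - fit$n[a] * prior$log_penalty + prior$array_bias[[array]] +
           fit$prior_corr[a])
}

#' Full log posterior of the model state
#'
#' The objective that hard EM ascends: the log likelihood of every present
#' cell under its assigned distribution (the bicluster Normal for cells in a
#' bicluster's gene x array block, the max-density owner for cells covered by
#' several biclusters, the array background otherwise), minus the per-value
#' assignment penalty for bicluster cells, plus the Bernoulli gene-membership
#' prior, the gene/array bias offsets, and the log prior density of the model
#' parameters (member pairs at their fitted values, all other pairs at the
#' prior mode).
#'
#' @inheritParams gene_log_score
#' @param sigma_floor Lower clamp used for the prior-mode variance.
#' @return A single real value.
#' @export
log_posterior <- function(matrix, assignment, params, background, prior,
                          sigma_floor = 1e-8) {
  B <- ncol(assignment$gene)
  priors <- as_prior_list(prior, B)
  present <- !is.na(matrix)

  bg_ld <- stats::dnorm(matrix,
                        rep(background$mu, each = nrow(matrix)),
                        rep(background$sigma, each = nrow(matrix)),
                        log = TRUE)
  total <- sum(bg_ld[present])

  # density of each cell under its best owning bicluster
  owner_ld <- matrix(-Inf, nrow(matrix), ncol(matrix))
  covered <- matrix(FALSE, nrow(matrix), ncol(matrix))
  for (b in seq_len(B)) {
    genes_b <- assignment$gene[, b]
    arrays_b <- assignment$array[, b]
    if (!any(genes_b) || !any(arrays_b)) next
    ld_b <- stats::dnorm(matrix,
                         rep(params$mu[, b], each = nrow(matrix)),
                         rep(params$sigma[, b], each = nrow(matrix)),
                         log = TRUE)
    block <- outer(genes_b, arrays_b, "&") & present
    owner_ld[block] <- pmax(owner_ld[block], ld_b[block])
    covered <- covered | block
  }
  total <- total + sum(owner_ld[covered] - bg_ld[covered])

  for (b in seq_len(B)) {
    pr <- priors[[b]]
    genes_b <- assignment$gene[, b]
    arrays_b <- assignment$array[, b]
    n_cells <- sum(present[genes_b, arrays_b, drop = FALSE])
    total <- total - n_cells * pr$log_penalty
    total <- total + sum(genes_b) * log(pr$p_gene) +
      sum(!genes_b) * log(1 - pr$p_gene) +
      sum(pr$gene_bias[genes_b]) + sum(pr$array_bias[arrays_b])

    sigma0sq <- pr$sigma0^2
    mode_sigma2 <- pmax(nix2_prior_mode_sigma2(pr$nu0, sigma0sq),
                        sigma_floor^2)
    ld_mode <- ld_nix2(pr$mu0, mode_sigma2, pr$mu0, pr$kappa0, pr$nu0,
                       sigma0sq)
    ld_fit <- ld_nix2(params$mu[, b], params$sigma[, b]^2, pr$mu0, pr$kappa0,
                      pr$nu0, sigma0sq)
    total <- total + sum(ifelse(arrays_b, ld_fit, ld_mode))
  }
  total
}
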