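#' Learn a query-based bicluster by hard-assignment EM
#'
#' Starting from the seed initialization ([init_assignments()]), alternates a
#' maximization step (MAP update of every per-array bicluster Normal given the
#' current member genes, [map_update_params()]) with an expectation step that
#' deterministically reassigns first the arrays (by [array_log_score()], in
#' array-id order) and then the genes (by [gene_log_score()], in gene-id
#' order). Ties (score exactly 0) resolve to non-membership. Iteration stops
#' when the assignments are unchanged over a full sweep, when the absolute
#' change in log posterior drops below `tol`, or after `max_iter` iterations.
#'
#' Seeds are not clamped: the expectation step is free to drop seed genes that
#' do not fit the recovered bicluster, which is what makes the method robust
#' to noisy seed sets.
#'
#' @param matrix Expression matrix.
#' @param seed_genes Character vector of seed gene ids (one bicluster), or a
#'   list of such vectors (several biclusters learned jointly).
#' @param background `probic_background` from [estimate_background()].
#' @param prior `probic_prior` from [build_prior()], or a list of priors
#'   matching `seed_genes`.
#' @param max_iter Maximum number of EM iterations (default 100).
#' @param tol Convergence tolerance on the absolute change of the log
#'   posterior (default 1e-6).
#' @param sigma_floor Lower clamp on bicluster standard deviations. `NULL`
#'   (default) uses the background model's floor.
#' @return Object of class `probic_result` with elements `genes`, `arrays`
#'   (member ids of the first bicluster), `mu`, `sigma` (per member array),
#'   `biclusters` (the same, one entry per bicluster),
#'   `log_posterior_trace`, `n_iterations`, and `converged`. A bicluster that
#'   empties completely yields empty `genes`/`arrays` and is flagged
#'   converged.
#' @examples
#' sim <- simulate_expression(simulation_config(n_genes = 60, n_arrays = 12,
#'   biclusters = list(list(n_genes = 12, n_arrays = 6,
#'                          displacement = 2, sigma = 0.25)),
#'   rng_seed = 7))
#' bg <- estimate_background(sim$matrix)
#' seeds <- sim$ground_truth[[1]]$genes[1:4]
#' pr <- build_prior(sim$matrix, seeds, bg)
#' fit <- run_em(sim$matrix, seeds, bg, pr)
#' @export
run_em <- function(matrix, seed_genes, background, prior, max_iter = 100,
                   tol = 1e-6, sigma_floor = NULL) {
  stopifnot(max_iter >= 1)
  seed_list <- as_seed_list(seed_genes)
  B <- length(seed_list)
  priors <- as_prior_list(prior, B)
  if (is.null(sigma_floor)) sigma_floor <- background$sigma_floor

  assignment <- init_assignments(matrix, seed_list)
  params <- map_update_params(matrix, assignment, priors,
                              sigma_floor = sigma_floor)
  trace <- numeric(0)
  converged <- FALSE
  iter <- 0L

  while (iter < max_iter) {
    iter <- iter + 1L
    changed <- FALSE
    for (b in seq_len(B)) {
      pr <- priors[[b]]
      genes_b <- assignment$gene[, b]
      if (!any(genes_b)) {
        if (any(assignment$array[, b])) changed <- TRUE
        assignment$array[, b] <- FALSE
        params$mu[, b] <- pr$mu0
        params$sigma[, b] <- pr$sigma0
        next
      }
      # M step: candidate MAP fit of every array given current member genes
      fit <- fit_bicluster_arrays(matrix, genes_b, pr, sigma_floor)
      lr <- log_density_ratio(matrix, fit$mu, fit$sigma, background)

      # E step, arrays (deterministic order; scores are order-independent
      # because gene memberships are fixed during the sweep)
      a_score <- colSums(lr[genes_b, , drop = FALSE], na.rm = TRUE) -
        fit$n * pr$log_penalty + pr$array_bias + fit$prior_corr
      a_score[fit$n == 0L] <- -Inf
      new_arrays <- a_score > 0

      # E step, genes, with the refreshed array memberships
      if (any(new_arrays)) {
        sub <- lr[, new_arrays, drop = FALSE]
        n_present <- rowSums(!is.na(matrix[, new_arrays, drop = FALSE]))
        g_lr <- rowSums(sub, na.rm = TRUE)
      } else {
        n_present <- numeric(nrow(matrix))
        g_lr <- numeric(nrow(matrix))
      }
      g_score <- g_lr - n_present * pr$log_penalty +
        log(pr$p_gene / (1 - pr$p_gene)) + pr$gene_bias
      new_genes <- g_score > 0

      if (any(new_arrays != assignment$array[, b]) ||
          any(new_genes != genes_b)) changed <- TRUE
      assignment$array[, b] <- new_arrays
      assignment$gene[, b] <- new_genes
      params$mu[, b] <- fit$mu
      params$sigma[, b] <- fit$sigma
    }
    trace <- c(trace, log_posterior(matrix, assignment, params, background,
                                    priors, sigma_floor = sigma_floor))
    if (!changed) { converged <- TRUE; break }
    if (iter >= 2L && abs(trace[iter] - trace[iter - 1L]) < tol) {
      converged <- TRUE
      break
    }
    if (!any(assignment$gene)) { converged <- TRUE; break }
  }

  biclusters <- lapply(seq_len(B), function(b) {
    member_arrays <- assignment$array[, b]
    list(genes = sort(rownames(matrix)[assignment$gene[, b]]),
         arrays = colnames(matrix)[member_arrays],
         mu = stats::setNames(params$mu[member_arrays, b],
                              colnames(matrix)[member_arrays]),
         sigma = stats::setNames(params$sigma[member_arrays, b],
                                 colnames(matrix)[member_arrays]),
         seed_genes = priors[[b]]$seed_genes)
  })
  structure(list(genes = biclusters[[1L]]$genes,
                 arrays = biclusters[[1L]]$arrays,
                 mu = biclusters[[1L]]$mu,
                 sigma = biclusters[[1L]]$sigma,
                 biclusters = biclusters,
                 assignment = assignment,
                 log_posterior_trace = trace,
                 n_iterations = iter,
                 converged = converged),
            class = "probic_result")
}

#' @export
print.probic_result <- function(x, ...) {
  cat("Query-based bicluster (", length(x$biclusters), " bicluster",
      if (length(x$biclusters) > 1L) "s", ")\n", sep = "")
  for (b in seq_along(x$biclusters)) {
    bc <- x$biclusters[[b]]
    cat("  [", b, "] ", length(bc$genes), " genes x ", length(bc$arrays),
        " arrays (", length(bc$seed_genes), " seeds)\n", sep = "")
  }
  cat("  ", x$n_iterations, " iteration(s), ",
      if (x$converged) "converged" else "not converged", "\n", sep = "")
  if (length(x$log_posterior_trace))
    cat("  final log posterior ",
        format(x$log_posterior_trace[length(x$log_posterior_trace)]),
        "\n", sep = "")
  invisible(x)
}

#' Serialize a bicluster result to JSON
#'
#' Writes gene ids, array ids, per-array (mu, sigma), the per-iteration log
#' posterior, and (when a seed partition is supplied) the category label.
#'
#' @param result `probic_result`.
#' @param path Output path.
#' @param true_seeds,noise_seeds Optional seed partition for categorization.
#' @return `path`, invisibly.
#' @export
write_result_json <- function(result, path, true_seeds = NULL,
                              noise_seeds = character(0)) {
  bc <- result$biclusters[[1L]]
  out <- list(
    genes = bc$genes,
    arrays = bc$arrays,
    mu = as.list(stats::setNames(bc$mu, bc$arrays)),
    sigma = as.list(stats::setNames(bc$sigma, bc$arrays)),
    log_posterior_trace = result$log_posterior_trace,
    n_iterations = result$n_iterations,
    converged = result$converged)
  if (!is.null(true_seeds))
    out$category <- categorize_bicluster(bc$genes, true_seeds, noise_seeds)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
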