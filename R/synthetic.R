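# Generator of expression compendia with known implanted constant-column
# biclusters, noisy seed sets, and cross-validation splits. All randomness is
# driven by explicit integer seeds so every experiment is reproducible.

#' Configuration for the synthetic-compendium generator
#'
#' The generator emulates a log-ratio compendium: every array has its own
#' Normal background, and each implanted bicluster is a set of member genes
#' whose values on each member array share a tight Normal whose mean is
#' displaced from that array's background mean by a fixed number of background
#' standard deviations (a constant-column bicluster). The displacement sign is
#' drawn per member array, so implanted profiles go up on some conditions and
#' down on others, as regulons do.
#'
#' @param n_genes,n_arrays Matrix dimensions.
#' @param bg_mu_range,bg_sigma_range Ranges from which each array's background
#'   mean and standard deviation are drawn uniformly.
#' @param biclusters List of implanted biclusters; each element is a list with
#'   `n_genes`, `n_arrays`, `displacement` (in background-sigma units, >= 0)
#'   and `sigma` (within-bicluster standard deviation, > 0).
#' @param missing_rate Fraction of cells masked as missing, in \[0, 1).
#' @param rng_seed Integer seed.
#' @return Validated list of class `probic_sim_config`.
#' @export
simulation_config <- function(n_genes = 200, n_arrays = 50,
                              bg_mu_range = c(-0.5, 0.5),
                              bg_sigma_range = c(0.75, 1.25),
                              biclusters = list(),
                              missing_rate = 0, rng_seed = 1) {
  stopifnot(n_genes >= 2, n_arrays >= 2,
            length(bg_mu_range) == 2L, length(bg_sigma_range) == 2L,
            all(bg_sigma_range > 0), missing_rate >= 0, missing_rate < 1)
  for (bc in biclusters) {
    stopifnot(is.list(bc),
              all(c("n_genes", "n_arrays", "displacement", "sigma") %in%
                    names(bc)))
    if (bc$n_genes > n_genes || bc$n_arrays > n_arrays)
      stop_input("implanted bicluster larger than the matrix")
    stopifnot(bc$n_genes >= 1, bc$n_arrays >= 1, bc$displacement >= 0,
              bc$sigma > 0)
  }
  structure(list(n_genes = as.integer(n_genes),
                 n_arrays = as.integer(n_arrays),
                 bg_mu_range = bg_mu_range,
                 bg_sigma_range = bg_sigma_range,
                 biclusters = biclusters,
                 missing_rate = missing_rate,
                 rng_seed = as.integer(rng_seed)),
            class = "probic_sim_config")
}

#' Simulate an expression compendium with implanted biclusters
#'
#' Background cells are drawn per array from `Normal(mu_a, sigma_a)`; each
#' implanted bicluster's member cells are redrawn from
#' `Normal(mu_a + s_a * displacement * sigma_a, sigma_within)` where the sign
#' `s_a` is drawn per member array. Cells claimed by several overlapping
#' biclusters belong to the later one. A uniform missing mask is applied
#' last. Fully reproducible from `rng_seed`.
#'
#' @param config `probic_sim_config` from [simulation_config()].
#' @return List with `matrix` (a `probic_matrix`), `ground_truth` (per
#'   bicluster: `genes`, `arrays`, `means` per member array) and `background`
#'   (the true per-array `mu`, `sigma`).
#' @export
simulate_expression <- function(config) {
  stopifnot(inherits(config, "probic_sim_config"))
  set.seed(config$rng_seed)
  G <- config$n_genes
  A <- config$n_arrays
  gene_ids <- sprintf("g%04d", seq_len(G))
  array_ids <- sprintf("a%03d", seq_len(A))
  mu <- stats::runif(A, config$bg_mu_range[1L], config$bg_mu_range[2L])
  sigma <- stats::runif(A, config$bg_sigma_range[1L],
                        config$bg_sigma_range[2L])
  values <- matrix(stats::rnorm(G * A, mean = rep(mu, each = G),
                                sd = rep(sigma, each = G)),
                   G, A, dimnames = list(gene_ids, array_ids))

  ground_truth <- vector("list", length(config$biclusters))
  for (i in seq_along(config$biclusters)) {
    bc <- config$biclusters[[i]]
    genes <- sort(sample(gene_ids, bc$n_genes))
    arrays <- sort(sample(array_ids, bc$n_arrays))
    a_idx <- match(arrays, array_ids)
    signs <- sample(c(-1, 1), bc$n_arrays, replace = TRUE)
    means <- mu[a_idx] + signs * bc$displacement * sigma[a_idx]
    for (j in seq_along(arrays)) {
      values[genes, arrays[j]] <- stats::rnorm(bc$n_genes, means[j],
                                               bc$sigma)
    }
    ground_truth[[i]] <- list(genes = genes, arrays = arrays,
                              means = stats::setNames(means, arrays))
  }
  if (config$missing_rate > 0) {
    mask <- stats::runif(G * A) < config$missing_rate
    values[mask] <- NA_real_
  }
  list(matrix = expression_matrix(values),
       ground_truth = ground_truth,
       background = list(mu = stats::setNames(mu, array_ids),
                         sigma = stats::setNames(sigma, array_ids)))
}

#' Contaminate a seed set with random genes
#'
#' Adds `r` genes drawn without replacement from outside the true seed set,
#' with `r` chosen so that the realized noise fraction `r / (|seeds| + r)` is
#' as close as possible to `noise_fraction` (ties resolve to fewer noise
#' genes).
#'
#' @param true_seeds Character vector of true seed genes.
#' @param all_genes Character vector of all candidate genes (superset of
#'   `true_seeds`).
#' @param noise_fraction Target fraction of random genes in the contaminated
#'   seed set, in \[0, 1).
#' @param rng_seed Integer seed.
#' @return List with `seeds` (true plus noise) and `noise` (the added genes).
#' @export
make_noisy_seed <- function(true_seeds, all_genes, noise_fraction, rng_seed) {
  stopifnot(noise_fraction >= 0, noise_fraction < 1)
  if (!all(true_seeds %in% all_genes))
    stop_input("true_seeds must be a subset of all_genes")
  t <- length(true_seeds)
  if (noise_fraction == 0)
    return(list(seeds = true_seeds, noise = character(0)))
  target <- noise_fraction * t / (1 - noise_fraction)
  candidates <- unique(pmax(c(floor(target), ceiling(target)), 0))
  err <- abs(candidates / (t + candidates) - noise_fraction)
  # ties toward fewer noise genes: candidates are sorted ascending
  r <- candidates[which.min(err)]
  pool <- setdiff(all_genes, true_seeds)
  if (length(pool) < r)
    stop_input("not enough non-seed genes to draw ", r, " noise genes")
  set.seed(rng_seed)
  noise <- sample(pool, r)
  list(seeds = c(true_seeds, noise), noise = noise)
}

#' Cross-validation splits of a regulon
#'
#' Randomly partitions the regulon into `n_folds` near-equal validation
#' folds; split `i` uses fold `i` as validation set and all remaining genes
#' as seed set (four fifths seed / one fifth validation at the default five
#' folds).
#'
#' @param regulon_genes Character vector of at least 5 genes (smaller
#'   regulons are not retained for cross-validation).
#' @param n_folds Number of folds (default 5).
#' @param rng_seed Integer seed.
#' @return List of `n_folds` lists, each with `seeds` and `validation`.
#' @export
cv_split <- function(regulon_genes, n_folds = 5, rng_seed = 1) {
  regulon_genes <- unique(regulon_genes)
  if (length(regulon_genes) < 5L)
    stop_input("regulon has fewer than 5 genes; only regulons with five or ",
               "more genes are retained for cross-validation")
  stopifnot(n_folds >= 2, n_folds <= length(regulon_genes))
  set.seed(rng_seed)
  shuffled <- sample(regulon_genes)
  fold_id <- rep_len(seq_len(n_folds), length(shuffled))
  lapply(seq_len(n_folds), function(i) {
    validation <- shuffled[fold_id == i]
    list(seeds = sort(setdiff(regulon_genes, validation)),
         validation = sort(validation))
  })
}

#' Write simulation ground truth as JSON
#'
#' @param sim Output of [simulate_expression()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(sim, path) {
  jsonlite::write_json(
    list(background = sim$background,
         biclusters = lapply(sim$ground_truth, function(bc)
           list(genes = bc$genes, arrays = bc$arrays,
                means = as.list(bc$means)))),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
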