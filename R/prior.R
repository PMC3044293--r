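#' Build the bicluster prior from a seed gene set
#'
#' The query-based character of the model comes from its conjugate
#' Normal-Inverse-Chi-Squared prior on each per-array bicluster Normal.
#' The prior mean on array `a` is the average expression of the seed genes on
#' that array (the query profile), and the prior standard deviation is the
#' background standard deviation shrunk by `f_bcl`, so the model looks for
#' biclusters that are tighter than background and centred on the seed profile.
#'
#' @param matrix Expression matrix.
#' @param seed_genes Character vector of seed (query) gene ids, all present in
#'   `matrix`.
#' @param background `probic_background` from [estimate_background()].
#' @param f_bcl Prior bicluster-to-background standard-deviation ratio in
#'   (0, 1]; default 0.7. Smaller values ask for tighter biclusters but make
#'   the initial fit fragile when the seed set contains outlying genes.
#' @param kappa0 Prior strength on the mean (pseudo-observations); a high
#'   value anchors the bicluster to the query profile. `NULL` (default) uses
#'   `10 * nrow(matrix)`.
#' @param nu0 Prior strength on the variance (degrees of freedom); default 10.
#' @param log_penalty Per-expression-value assignment penalty: the log of how
#'   many times more likely a value must be under the bicluster distribution
#'   than under the background before assignment is favoured. Default `log(2)`.
#' @param p_gene Prior probability that any gene belongs to the bicluster,
#'   in (0, 1); controls expected bicluster size. Default 0.05.
#' @param gene_bias Optional named numeric vector of per-gene log-prior
#'   offsets (soft knowledge that specific genes belong to the bicluster);
#'   default zero for every gene.
#' @param array_bias Optional named numeric vector of per-array log-prior
#'   offsets; default zero for every array.
#' @return Object of class `probic_prior`: list with per-array `mu0` and
#'   `sigma0`, scalars `kappa0`, `nu0`, `log_penalty`, `p_gene`, `f_bcl`, and
#'   per-gene / per-array bias vectors.
#' @export
build_prior <- function(matrix, seed_genes, background, f_bcl = 0.7,
                        kappa0 = NULL, nu0 = 10, log_penalty = log(2),
                        p_gene = 0.05, gene_bias = NULL, array_bias = NULL) {
  seed_genes <- check_seed_genes(matrix, seed_genes)
  stopifnot(f_bcl > 0, f_bcl <= 1, nu0 > 0,
            p_gene > 0, p_gene < 1)
  if (is.null(kappa0)) kappa0 <- 10 * nrow(matrix)
  stopifnot(kappa0 > 0)

  seed_values <- matrix[seed_genes, , drop = FALSE]
  n_present <- colSums(!is.na(seed_values))
  if (any(n_present == 0L))
    stop_input("all seed values missing on array(s): ",
               paste(colnames(matrix)[n_present == 0L], collapse = ", "))
  mu0 <- colMeans(seed_values, na.rm = TRUE)
  sigma0 <- f_bcl * background$sigma

  gene_bias <- expand_bias(gene_bias, rownames(matrix), "gene")
  array_bias <- expand_bias(array_bias, colnames(matrix), "array")

  structure(list(mu0 = mu0, sigma0 = sigma0, kappa0 = kappa0, nu0 = nu0,
                 log_penalty = log_penalty, p_gene = p_gene, f_bcl = f_bcl,
                 gene_bias = gene_bias, array_bias = array_bias,
                 seed_genes = seed_genes),
            class = "probic_prior")
}

expand_bias <- function(bias, ids, what) {
  full <- stats::setNames(numeric(length(ids)), ids)
  if (is.null(bias)) return(full)
  if (is.null(names(bias)) || !all(names(bias) %in% ids))
    stop_input(what, "_bias must be named by known ", what, " ids")
  full[names(bias)] <- bias
  full
}

#' @export
print.probic_prior <- function(x, ...) {
  cat("Bicluster prior from ", length(x$seed_genes), " seed gene(s)\n",
      sep = "")
  cat("  kappa0 = ", x$kappa0, ", nu0 = ", x$nu0, ", f_bcl = ", x$f_bcl,
      "\n  log_penalty = ", round(x$log_penalty, 4),
      ", p_gene = ", x$p_gene, "\n", sep = "")
  invisible(x)
}
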