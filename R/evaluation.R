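# Bicluster quality statistics, result categorization against (noisy) seed
# sets, and hypergeometric mid-P enrichment.

#' Within-condition standard deviation of a gene set
#'
#' Measures how tightly the selected genes are coexpressed: the root mean
#' squared deviation of each selected value from its array's mean profile,
#' `sqrt( (1/(G*C)) * sum_j sum_i (x_ij - xbar_j)^2 )`, where `xbar_j` is the
#' mean of the selected genes on array `j`. Lower is tighter. Missing values
#' are excluded from the means and the average.
#'
#' @param matrix Expression matrix.
#' @param genes Character vector of at least 2 selected gene ids.
#' @param arrays Character vector of selected array ids.
#' @return Nonnegative real.
#' @export
std_within <- function(matrix, genes, arrays) {
  if (length(genes) < 2L)
    stop_input("std_within needs at least 2 genes")
  if (length(arrays) < 1L)
    stop_input("std_within needs at least 1 array")
  sub <- matrix[genes, arrays, drop = FALSE]
  centred <- sweep(sub, 2L, colMeans(sub, na.rm = TRUE), "-")
  sqrt(mean(centred^2, na.rm = TRUE))
}

#' Uncentred across-condition standard deviation of the mean profile
#'
#' Measures how strongly the selected genes' mean profile departs from zero
#' over the selected arrays: `sqrt( (1/C) * sum_j xbar_j^2 )`. For a seed set
#' the arrays are the whole compendium; for a bicluster they are its member
#' arrays. Higher means a profile more distinct from the (log-ratio zero)
#' baseline.
#'
#' @inheritParams std_within
#' @param genes Character vector of at least 1 selected gene id.
#' @return Nonnegative real.
#' @export
std_across <- function(matrix, genes, arrays) {
  if (length(genes) < 1L)
    stop_input("std_across needs at least 1 gene")
  if (length(arrays) < 1L)
    stop_input("std_across needs at least 1 array")
  sub <- matrix[genes, arrays, drop = FALSE]
  sqrt(mean(colMeans(sub, na.rm = TRUE)^2))
}

#' Expression-quality summary of a gene/array selection
#'
#' @inheritParams std_within
#' @return List with `std_within`, `std_across` and their `ratio`
#'   (across/within; `NA` when within is 0).
#' @export
quality_scores <- function(matrix, genes, arrays) {
  w <- std_within(matrix, genes, arrays)
  a <- std_across(matrix, genes, arrays)
  list(std_within = w, std_across = a,
       ratio = if (w > 0) a / w else NA_real_)
}

#' Categories a bicluster can fall into with respect to its seed set
#' @export
bicluster_categories <- function() {
  c("empty", "only_full_seed_set", "only_part_of_seed_set",
    "only_random_seed", "random_seed_and_additional",
    "full_seed_set_and_additional", "part_of_seed_set_and_additional",
    "drift_away")
}

#' Categorize a bicluster result against its (possibly noisy) seed set
#'
#' In the noisy-seed experiments a bicluster is run from a seed set made of
#' `true_seeds` plus randomly added `noise_seeds`; the result is categorized
#' by which of those it retains and whether it recruited additional genes:
#' `empty`; results without additional genes split into `only_full_seed_set`,
#' `only_part_of_seed_set` and `only_random_seed`; results with additional
#' genes split into `full_seed_set_and_additional`,
#' `part_of_seed_set_and_additional` and `random_seed_and_additional`; and
#' `drift_away` for a non-empty result containing no seed gene at all. The
#' eight categories are mutually exclusive and exhaustive.
#'
#' @param result_genes Character vector of bicluster member genes.
#' @param true_seeds Character vector of true seed genes.
#' @param noise_seeds Character vector of the random genes that were added to
#'   the seed set (disjoint from `true_seeds`; empty for a clean run).
#' @return One of [bicluster_categories()].
#' @export
categorize_bicluster <- function(result_genes, true_seeds,
                                 noise_seeds = character(0)) {
  if (length(intersect(true_seeds, noise_seeds)) > 0L)
    stop_input("true_seeds and noise_seeds must be disjoint")
  r <- unique(result_genes)
  if (length(r) == 0L) return("empty")
  has_full_true <- length(true_seeds) > 0L && all(true_seeds %in% r)
  has_part_true <- length(intersect(r, true_seeds)) > 0L
  has_noise <- length(intersect(r, noise_seeds)) > 0L
  additional <- setdiff(r, union(true_seeds, noise_seeds))
  if (length(additional) == 0L) {
    if (has_full_true) return("only_full_seed_set")
    if (has_part_true) return("only_part_of_seed_set")
    return("only_random_seed")
  }
  if (has_full_true) return("full_seed_set_and_additional")
  if (has_part_true) return("part_of_seed_set_and_additional")
  if (has_noise) return("random_seed_and_additional")
  "drift_away"
}

#' One-sided upper hypergeometric mid-P value
#'
#' For overlap `k` between a bicluster of size `n` and an annotation set of
#' size `K` in a universe of `N` genes, returns
#' `0.5 * P(X = k) + P(X > k)` with `X ~ Hypergeometric(N, K, n)`. Counting
#' only half the observed outcome's mass reduces the conservativeness of the
#' discrete test.
#'
#' @param k Observed overlap.
#' @param K Annotation set size.
#' @param n Bicluster (query) size.
#' @param N Universe size.
#' @return Mid-P value in \[0, 1\].
#' @export
hypergeom_midp <- function(k, K, n, N) {
  stopifnot(length(k) == 1L, length(K) == 1L, length(n) == 1L,
            length(N) == 1L)
  if (K > N || n > N)
    stop_input("annotation or query larger than the universe")
  if (k < 0 || k > min(K, n))
    stop_input("impossible overlap k = ", k, " for K = ", K, ", n = ", n)
  0.5 * stats::dhyper(k, K, N - K, n) +
    stats::phyper(k, K, N - K, n, lower.tail = FALSE)
}

#' Enrichment of bicluster genes in annotation sets
#'
#' Tests the bicluster's genes, after excluding the seed genes, against each
#' annotation set with the one-sided hypergeometric mid-P value over the given
#' universe. Seed genes are excluded so that enrichment reflects the newly
#' recruited genes rather than the query itself. No multiple-testing
#' correction is applied by default; `correct = "BH"` switches on
#' Benjamini-Hochberg adjustment before the significance call.
#'
#' @param bicluster_genes Character vector of bicluster member genes.
#' @param seed_genes Character vector of seed genes to exclude.
#' @param annotations Named list of character vectors (annotation gene sets,
#'   subsets of `universe`).
#' @param universe Character vector: all genes eligible for membership.
#' @param alpha Significance level (default 0.05).
#' @param correct `"none"` (default) or `"BH"`.
#' @return `data.frame` with one row per annotation: `annotation_id`,
#'   `overlap`, `midp`, `significant`. Zero rows (with attribute
#'   `empty_query = TRUE`) when no genes remain after seed exclusion.
#' @export
enrich_bicluster <- function(bicluster_genes, seed_genes, annotations,
                             universe, alpha = 0.05,
                             correct = c("none", "BH")) {
  correct <- match.arg(correct)
  universe <- unique(universe)
  bad <- names(annotations)[!vapply(annotations, function(s)
    all(s %in% universe), logical(1L))]
  if (length(bad) > 0L)
    stop_input("annotation(s) not contained in the universe: ",
               paste(bad, collapse = ", "))
  query <- setdiff(intersect(bicluster_genes, universe), seed_genes)
  if (length(query) == 0L) {
    out <- data.frame(annotation_id = character(0), overlap = integer(0),
                      midp = numeric(0), significant = logical(0))
    attr(out, "empty_query") <- TRUE
    return(out)
  }
  N <- length(universe)
  n <- length(query)
  overlap <- vapply(annotations, function(s)
    length(intersect(query, s)), integer(1L))
  midp <- mapply(function(k, K) hypergeom_midp(k, K, n, N),
                 overlap, lengths(annotations))
  p_eff <- if (correct == "BH") stats::p.adjust(midp, "BH") else midp
  data.frame(annotation_id = names(annotations),
             overlap = unname(overlap),
             midp = unname(midp),
             significant = unname(p_eff < alpha),
             row.names = NULL)
}

#' Recall and enrichment of validation genes in a bicluster
#'
#' Cross-validation readouts: `recall` is the fraction of validation genes
#' retrieved in the bicluster; `enrichment` is the fraction of the bicluster
#' made up of validation genes (0 for an empty bicluster), compensating for
#' the tendency of recall to grow with bicluster size.
#'
#' @param result_genes Character vector of bicluster member genes.
#' @param seed_genes Character vector of seed genes used for the run
#'   (disjoint from `validation_genes`).
#' @param validation_genes Non-empty character vector of held-out genes.
#' @return List with `recall` and `enrichment`.
#' @export
recall_and_enrichment <- function(result_genes, seed_genes,
                                  validation_genes) {
  if (length(validation_genes) == 0L)
    stop_input("validation set is empty")
  if (length(intersect(seed_genes, validation_genes)) > 0L)
    stop_input("seed and validation sets must be disjoint")
  hits <- length(intersect(result_genes, validation_genes))
  list(recall = hits / length(validation_genes),
       enrichment = if (length(result_genes) == 0L) 0
                    else hits / length(unique(result_genes)))
}
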