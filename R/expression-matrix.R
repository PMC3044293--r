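#' Construct and validate an expression matrix
#'
#' The package represents a genes x arrays expression compendium as a plain
#' numeric matrix with unique row names (gene identifiers) and unique column
#' names (array identifiers). Values are log-ratio-style real numbers; missing
#' measurements are `NA`.
#'
#' @param values Numeric matrix, genes in rows, arrays in columns. Row and
#'   column names are required and must be unique.
#' @return The validated matrix with class `"probic_matrix"` prepended.
#' @examples
#' m <- matrix(rnorm(12), 4, 3,
#'             dimnames = list(paste0("g", 1:4), paste0("a", 1:3)))
#' em <- expression_matrix(m)
#' @export
expression_matrix <- function(values) {
  if (!is.matrix(values) || !is.numeric(values))
    stop_input("`values` must be a numeric matrix")
  if (nrow(values) < 2L || ncol(values) < 2L)
    stop_input("expression matrix needs at least 2 genes and 2 arrays")
  gene_ids <- rownames(values)
  array_ids <- colnames(values)
  if (is.null(gene_ids) || is.null(array_ids))
    stop_input("expression matrix must carry gene ids (rownames) and array ids (colnames)")
  if (anyDuplicated(gene_ids))
    stop_input("duplicated gene ids: ",
               paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "))
  if (anyDuplicated(array_ids))
    stop_input("duplicated array ids: ",
               paste(unique(array_ids[duplicated(array_ids)]), collapse = ", "))
  if (any(is.infinite(values)))
    stop_input("expression values must be finite or NA")
  class(values) <- c("probic_matrix", class(values))
  values
}

#' Read an expression matrix from tab-separated text
#'
#' Expected layout: first row holds array identifiers, first column holds gene
#' identifiers, cells hold real values; empty cells or the literal `NA` mark
#' missing values.
#'
#' @param path Path to a TSV file.
#' @return A `probic_matrix` (see [expression_matrix()]).
#' @export
read_expression_matrix <- function(path) {
  if (!file.exists(path)) stop_input("matrix file not found: ", path)
  df <- tryCatch(
    utils::read.delim(path, header = TRUE, row.names = 1L, check.names = FALSE,
                      na.strings = c("NA", ""), comment.char = ""),
    error = function(e) stop_input("malformed matrix file ", path, ": ",
                                   conditionMessage(e)))
  m <- as.matrix(df)
  if (!is.numeric(m)) {
    bad <- which(apply(df, 2L, function(col) any(is.na(suppressWarnings(as.numeric(col))) & !is.na(col))))
    stop_input("non-numeric expression values in ", path,
               " (column ", paste(colnames(df)[bad], collapse = ", "), ")")
  }
  expression_matrix(m)
}

#' Write an expression matrix as tab-separated text
#'
#' Inverse of [read_expression_matrix()]; missing values are written as `NA`.
#'
#' @param matrix A genes x arrays numeric matrix with dimnames.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(matrix, path) {
  df <- data.frame(gene = rownames(matrix), matrix, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a seed (query) gene list
#'
#' Plain text, one gene identifier per line; blank lines and `#` comments are
#' ignored.
#'
#' @param path Path to the gene list.
#' @return Character vector of gene ids.
#' @export
read_seed_genes <- function(path) {
  if (!file.exists(path)) stop_input("seed file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  genes <- lines[nzchar(lines)]
  if (length(genes) == 0L)
    stop_input("seed file ", path, " contains no gene ids")
  if (anyDuplicated(genes)) {
    offenders <- unique(genes[duplicated(genes)])
    stop_input("seed file ", path, " lists genes more than once: ",
               paste(offenders, collapse = ", "))
  }
  genes
}

#' Read annotation gene sets in GMT format
#'
#' One set per line: set id, description, then member gene ids, tab separated.
#'
#' @param path Path to a GMT file.
#' @return Named list of character vectors (names are set ids).
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop_input("GMT file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  sets <- lapply(lines, function(l) {
    fields <- strsplit(l, "\t", fixed = TRUE)[[1L]]
    if (length(fields) < 3L)
      stop_input("GMT line with fewer than 3 fields: ", substr(l, 1L, 60L))
    unique(fields[-(1:2)])
  })
  names(sets) <- vapply(lines, function(l)
    strsplit(l, "\t", fixed = TRUE)[[1L]][1L], character(1L))
  sets
}

# check that requested seed genes exist in the matrix
check_seed_genes <- function(matrix, seed_genes) {
  seed_genes <- unique(as.character(seed_genes))
  if (length(seed_genes) == 0L) stop_input("seed set is empty")
  missing <- setdiff(seed_genes, rownames(matrix))
  if (length(missing) > 0L)
    stop_input("seed gene(s) not in expression matrix: ",
               paste(missing, collapse = ", "))
  seed_genes
}

# input-validation errors carry a dedicated class so the command-line wrapper
# can map them to exit status 1
stop_input <- function(...) {
  stop(structure(class = c("probic_input_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1L))))
}
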