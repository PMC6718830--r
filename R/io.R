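# Readers and writers for the plain-text formats the pipeline exchanges:
# gene x sample TSV matrices, sample-keyed CSV tables, and GMT gene sets.

#' Read a gene-by-sample matrix from TSV
#'
#' Expects gene identifiers in the first column and one column per sample,
#' with a header row of sample identifiers.
#'
#' @param path Path to a tab-separated file.
#' @param integer_counts If `TRUE`, values are validated as non-negative
#'   integers (RNA-seq counts); otherwise any numeric matrix is accepted.
#' @return A numeric matrix with gene ids as rownames and sample (or tissue)
#'   ids as colnames.
#' @export
read_matrix_tsv <- function(path, integer_counts = FALSE) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stopf("matrix file '%s' needs an id column plus data", path)
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids)) stopf("duplicate gene ids in '%s'", path)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "numeric"
  rownames(m) <- ids
  if (anyNA(m)) stopf("missing values in matrix file '%s'", path)
  if (integer_counts && (any(m < 0) || any(m != round(m))))
    stopf("'%s' contains non-integer or negative counts", path)
  m
}

#' Write a gene-by-sample matrix as TSV
#'
#' @param m Numeric matrix with row and column names.
#' @param path Output path.
#' @export
write_matrix_tsv <- function(m, path) {
  df <- data.frame(gene_id = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene sets from a GMT file
#'
#' Each line holds a set name, a description, then tab-separated gene ids.
#'
#' @param path Path to a GMT file.
#' @return A named list of character vectors of gene ids. Set descriptions
#'   are kept in the `"description"` attribute of each element.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(ln) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3) stopf("malformed GMT line: %s", substr(ln, 1, 60))
    genes <- unique(parts[-(1:2)])
    attr(genes, "description") <- parts[2]
    genes
  })
  names(sets) <- vapply(lines, function(ln)
    strsplit(ln, "\t", fixed = TRUE)[[1]][1], character(1))
  if (anyDuplicated(names(sets))) stopf("duplicate set names in '%s'", path)
  sets
}

#' Write gene sets (or derived modules) to a GMT file
#'
#' @param sets Named list of character vectors, or a list of gene modules as
#'   returned by [derive_module()].
#' @param path Output path.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(seq_along(sets), function(i) {
    s <- sets[[i]]
    if (is.list(s) && !is.null(s$genes)) {        # GeneModule
      nm <- s$label
      desc <- attr(s$genes, "description") %||% "gene module"
      genes <- s$genes
    } else {
      nm <- names(sets)[i]
      desc <- attr(s, "description") %||% "gene set"
      genes <- s
    }
    paste(c(nm, desc, genes), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a sample-keyed CSV table
#'
#' @param path CSV path; must contain a `sample_id` column.
#' @return A data.frame.
#' @export
read_sample_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!"sample_id" %in% names(df))
    stopf("'%s' lacks the required sample_id column", path)
  df
}

#' Write a sample-keyed CSV table
#' @param df data.frame with a `sample_id` column.
#' @param path Output path.
#' @export
write_sample_csv <- function(df, path) {
  if (!"sample_id" %in% names(df)) stopf("table lacks a sample_id column")
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
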