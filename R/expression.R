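#' Construct an ExpressionMatrix
#'
#' The central data container of the package: a genes x samples matrix of
#' log-scale expression values with unique, case-sensitive identifiers.
#' Row names are gene identifiers, column names are sample identifiers.
#' Identifiers are whitespace-trimmed on construction.
#'
#' @param values numeric matrix, genes in rows, samples in columns. Must carry
#'   row and column names (or supply `gene_ids`/`sample_ids`).
#' @param gene_ids optional character vector overriding `rownames(values)`.
#' @param sample_ids optional character vector overriding `colnames(values)`.
#' @return An object of class `ExpressionMatrix` (a named numeric matrix).
#' @examples
#' m <- matrix(rnorm(12), 3, 4,
#'             dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
#' expr <- expression_matrix(m)
#' dim(expr)
#' @export
expression_matrix <- function(values, gene_ids = NULL, sample_ids = NULL) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix (genes x samples)")
  if (!is.null(gene_ids)) rownames(values) <- gene_ids
  if (!is.null(sample_ids)) colnames(values) <- sample_ids
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("gene and sample identifiers are required")
  rownames(values) <- trimws(rownames(values))
  colnames(values) <- trimws(colnames(values))
  validate_expression_matrix(values)
  structure(values, class = c("ExpressionMatrix", "matrix", "array"))
}

validate_expression_matrix <- function(values) {
  dup_g <- unique(rownames(values)[duplicated(rownames(values))])
  if (length(dup_g))
    stop("duplicated gene identifiers: ", paste(dup_g, collapse = ", "))
  dup_s <- unique(colnames(values)[duplicated(colnames(values))])
  if (length(dup_s))
    stop("duplicated sample identifiers: ", paste(dup_s, collapse = ", "))
  invisible(values)
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d genes x %d samples\n", nrow(x), ncol(x)))
  if (anyNA(x)) cat(sprintf("  %d missing values\n", sum(is.na(x))))
  invisible(x)
}

gene_ids <- function(expr) rownames(expr)
sample_ids <- function(expr) colnames(expr)

# Network computations need >= 3 samples, >= 2 genes and all-finite values;
# called at the entry of similarity()/pca_overview() rather than at read time
# so partially-missing data can still be loaded and cleaned.
assert_network_ready <- function(expr) {
  if (nrow(expr) < 2L) stop("need at least 2 genes")
  if (ncol(expr) < 3L) stop("need at least 3 samples")
  if (!all(is.finite(expr)))
    stop("expression matrix contains non-finite values; apply drop_incomplete_genes() first")
  invisible(expr)
}

#' Drop genes with missing values
#'
#' Default missing-data policy: genes with any non-finite value across the
#' retained samples are removed before network construction, keeping all
#' downstream matrices dense and deterministic (pairwise-complete correlation
#' is deliberately not used).
#'
#' @param expr an [expression_matrix()].
#' @return An `ExpressionMatrix` restricted to complete genes.
#' @export
drop_incomplete_genes <- function(expr) {
  keep <- apply(is.finite(unclass(expr)), 1L, all)
  expression_matrix(unclass(expr)[keep, , drop = FALSE])
}

#' Read an expression matrix from delimited text
#'
#' Orientation is never guessed: the caller states whether genes are in rows
#' (default; first column holds gene identifiers, header holds sample
#' identifiers) or samples are in rows.
#'
#' @param path path to a TSV/CSV file.
#' @param orientation `"genes-in-rows"` or `"samples-in-rows"`.
#' @param sep field separator; `"\t"` default, use `","` for CSV.
#' @return An `ExpressionMatrix`.
#' @export
read_expression <- function(path, orientation = c("genes-in-rows", "samples-in-rows"),
                            sep = "\t") {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2L) stop("parse error in ", path, ": need header plus data rows")
  fields <- strsplit(lines, sep, fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != nf[1L]))
    stop("parse error in ", path, ": ragged row at line ",
         which(nf != nf[1L])[1L])
  header <- trimws(fields[[1L]])
  ids <- vapply(fields[-1L], function(f) trimws(f[1L]), character(1))
  body <- t(vapply(fields[-1L], function(f) {
    v <- suppressWarnings(as.numeric(f[-1L]))
    v
  }, numeric(length(header) - 1L)))
  if (length(header) == 2L) body <- matrix(body, ncol = 1L)
  dimnames(body) <- list(ids, header[-1L])
  m <- if (orientation == "genes-in-rows") body else t(body)
  expression_matrix(m)
}

#' Write an expression matrix to delimited text
#'
#' Inverse of [read_expression()]; values are written with full precision so
#' the round trip is the identity to 1e-12.
#'
#' @param expr an `ExpressionMatrix`.
#' @param path output path.
#' @param sep field separator.
#' @export
write_expression <- function(expr, path, sep = "\t") {
  df <- data.frame(gene_id = rownames(expr), unclass(expr),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(format(df, digits = 17, trim = TRUE, scientific = FALSE),
                     path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Parse a GEO series-matrix file
#'
#' Reads the plain-text series-matrix dialect used by the Gene Expression
#' Omnibus: `!`-prefixed metadata lines, then a tab-separated expression table
#' between `!series_matrix_table_begin` and `!series_matrix_table_end` whose
#' first column is the probe identifier and whose header row names the
#' samples. Quoted fields are dequoted.
#'
#' @param path path to a series-matrix text file (uncompressed).
#' @return An `ExpressionMatrix` with a `"metadata"` attribute: a named list
#'   mapping each metadata key (without the leading `!`) to its character
#'   values.
#' @export
read_geo_series_matrix <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  dequote <- function(x) gsub('^"|"$', "", trimws(x))
  beg <- grep("^!series_matrix_table_begin", lines)
  end <- grep("^!series_matrix_table_end", lines)
  if (length(beg) != 1L || length(end) != 1L || end <= beg + 1L)
    stop("format error: missing !series_matrix_table_begin/!series_matrix_table_end delimiters")
  meta_lines <- grep("^!", lines[seq_len(beg - 1L)], value = TRUE)
  meta <- list()
  for (ln in meta_lines) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
    key <- sub("^!", "", parts[1L])
    vals <- dequote(parts[-1L])
    meta[[key]] <- c(meta[[key]], vals)
  }
  tbl <- strsplit(lines[(beg + 1L):(end - 1L)], "\t", fixed = TRUE)
  header <- dequote(tbl[[1L]])
  rows <- tbl[-1L]
  ids <- vapply(rows, function(r) dequote(r[1L]), character(1))
  vals <- t(vapply(rows, function(r) suppressWarnings(as.numeric(r[-1L])),
                   numeric(length(header) - 1L)))
  if (length(header) == 2L) vals <- matrix(vals, ncol = 1L)
  dimnames(vals) <- list(ids, header[-1L])
  out <- expression_matrix(vals)
  attr(out, "metadata") <- meta
  out
}
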