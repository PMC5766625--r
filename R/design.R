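#' Construct a PairedDesign
#'
#' Describes a paired two-condition layout: each subject (pair) contributes
#' exactly two samples, one control (`condition = 0`) and one case
#' (`condition = 1`, e.g. tumour vs matched normal). Subject-level covariates
#' such as age or tumour stage are constant within a pair.
#'
#' @param sample_id character vector of sample identifiers.
#' @param pair_id character vector of subject/pair identifiers.
#' @param condition integer/numeric vector of 0 (control) / 1 (case).
#' @param covariates optional data.frame of subject-level covariates, one row
#'   per sample, constant within pair.
#' @return A data.frame of class `PairedDesign` with columns `sample_id`,
#'   `pair_id`, `condition`, plus any covariates.
#' @export
paired_design <- function(sample_id, pair_id, condition, covariates = NULL) {
  df <- data.frame(sample_id = trimws(as.character(sample_id)),
                   pair_id = trimws(as.character(pair_id)),
                   condition = as.numeric(condition),
                   stringsAsFactors = FALSE)
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    if (nrow(covariates) != nrow(df))
      stop("covariates must have one row per sample")
    df <- cbind(df, covariates)
  }
  validate_paired_design(df)
  class(df) <- c("PairedDesign", "data.frame")
  df
}

covariate_names <- function(design)
  setdiff(names(design), c("sample_id", "pair_id", "condition"))

validate_paired_design <- function(df) {
  if (anyDuplicated(df$sample_id))
    stop("duplicated sample_id in design: ",
         paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", "))
  if (!all(df$condition %in% c(0, 1)))
    stop("condition must be coded 0 (control) / 1 (case)")
  bad <- character(0)
  for (p in unique(df$pair_id)) {
    cond <- df$condition[df$pair_id == p]
    if (length(cond) != 2L || anyNA(cond) || !identical(sort(cond), c(0, 1)))
      bad <- c(bad, p)
  }
  if (length(bad))
    stop("pairs without exactly one control and one case sample: ",
         paste(bad, collapse = ", "))
  covs <- setdiff(names(df), c("sample_id", "pair_id", "condition"))
  for (cv in covs) {
    per_pair <- tapply(df[[cv]], df$pair_id, function(v) length(unique(v)))
    if (any(per_pair > 1L))
      stop("covariate '", cv, "' varies within pairs: ",
           paste(names(per_pair)[per_pair > 1L], collapse = ", "))
  }
  invisible(df)
}

#' @export
print.PairedDesign <- function(x, ...) {
  cat(sprintf("PairedDesign: %d pairs (%d samples)", nrow(x) / 2L, nrow(x)))
  covs <- covariate_names(x)
  if (length(covs)) cat("; covariates:", paste(covs, collapse = ", "))
  cat("\n")
  invisible(x)
}

#' Read a paired design table
#'
#' Expects delimited text with required columns `sample_id`, `pair_id`,
#' `condition` (0 = control, 1 = case); any further columns are treated as
#' subject-level covariates.
#'
#' @param path path to the table.
#' @param sep field separator.
#' @return A `PairedDesign`.
#' @export
read_design <- function(path, sep = "\t") {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, sep = sep, header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("sample_id", "pair_id", "condition")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("design table missing required columns: ", paste(miss, collapse = ", "))
  covs <- df[setdiff(names(df), need)]
  paired_design(df$sample_id, df$pair_id, df$condition,
                if (ncol(covs)) covs else NULL)
}

#' Write a paired design table
#' @param design a `PairedDesign`.
#' @param path output path.
#' @param sep field separator.
#' @export
write_design <- function(design, path, sep = "\t") {
  utils::write.table(design, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Align a design to an expression matrix: every design sample must exist in
# the matrix; the matrix is restricted and re-ordered to the design's samples
# (control before case within each pair, pairs in first-appearance order).
align_design <- function(expr, design) {
  missing <- setdiff(design$sample_id, colnames(expr))
  if (length(missing))
    stop("design samples absent from expression matrix: ",
         paste(missing, collapse = ", "))
  ord <- order(match(design$pair_id, unique(design$pair_id)), design$condition)
  design <- design[ord, , drop = FALSE]
  class(design) <- c("PairedDesign", "data.frame")
  list(expr = expression_matrix(unclass(expr)[, design$sample_id, drop = FALSE]),
       design = design)
}
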