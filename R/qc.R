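#' Principal-component overview of samples
#'
#' Projects samples onto the top principal axes of the samples x genes matrix
#' after per-gene centering, the standard first look at array data for batch
#' effects and gross outliers.
#'
#' @param expr an [expression_matrix()].
#' @param k number of components, `k <= min(genes, samples)`.
#' @return A list of class `QCReport` with `pc_scores` (samples x k),
#'   `pc_variance_fraction` (length k, non-increasing, sums to <= 1).
#' @export
pca_overview <- function(expr, k = 2L) {
  assert_network_ready(expr)
  k <- as.integer(k)
  if (k < 1L || k > min(dim(expr))) stop("k must be in 1..min(genes, samples)")
  x <- t(unclass(expr))                       # samples x genes
  x <- sweep(x, 2L, colMeans(x))              # per-gene centering
  total <- sum(x^2)
  if (total <= .Machine$double.eps)
    stop("degenerate variance: expression matrix is constant")
  sv <- svd(x, nu = k, nv = k)
  scores <- sv$u %*% diag(sv$d[seq_len(k)], k, k)
  dimnames(scores) <- list(colnames(expr), paste0("PC", seq_len(k)))
  structure(list(pc_scores = scores,
                 pc_variance_fraction = sv$d[seq_len(k)]^2 / sum(sv$d^2),
                 sample_tree = NULL,
                 flagged_samples = character(0),
                 excluded_pairs = character(0)),
            class = "QCReport")
}

# Average-linkage tree over samples, Euclidean distance on genes standardized
# to mean 0 / SD 1 (zero-variance genes dropped). The per-sample "merge
# height" is the height at which the sample's leaf first joins the tree.
sample_tree <- function(expr) {
  x <- unclass(expr)
  sds <- apply(x, 1L, stats::sd)
  x <- x[sds > 0, , drop = FALSE]
  if (nrow(x)) {
    x <- sweep(x, 1L, rowMeans(x))
    x <- sweep(x, 1L, apply(x, 1L, stats::sd), "/")
    d <- stats::dist(t(x))
  } else {
    # all genes constant: every sample is at distance zero
    d <- stats::dist(matrix(0, ncol(expr), 1L,
                            dimnames = list(colnames(expr), NULL)))
  }
  stats::hclust(d, method = "average")
}

leaf_merge_heights <- function(hc) {
  n <- length(hc$order)
  h <- numeric(n)
  for (m in seq_len(nrow(hc$merge))) {
    for (leaf in hc$merge[m, ]) {
      if (leaf < 0) h[-leaf] <- hc$height[m]
    }
  }
  names(h) <- hc$labels
  h
}

#' Flag outlier samples from the sample dendrogram
#'
#' Reproducible stand-in for the visual outlier call common in co-expression
#' QC: a sample is flagged when the height at which its leaf joins the
#' average-linkage sample tree exceeds `mean + z_cut * sd` of all leaf merge
#' heights.
#'
#' @param expr an [expression_matrix()] with >= 4 samples.
#' @param z_cut z-score threshold on leaf merge heights (default 2.5;
#'   `Inf` flags nothing).
#' @return Character vector of flagged sample ids (possibly empty), with the
#'   sample tree as attribute `"tree"`.
#' @export
flag_outlier_samples <- function(expr, z_cut = 2.5) {
  if (ncol(expr) < 4L) stop("need at least 4 samples to assess outliers")
  hc <- sample_tree(expr)
  h <- leaf_merge_heights(hc)
  thr <- mean(h) + z_cut * stats::sd(h)
  flagged <- names(h)[!is.na(thr) & h > thr]
  if (is.infinite(z_cut)) flagged <- character(0)
  structure(flagged, tree = hc)
}

#' Remove whole pairs containing flagged samples
#'
#' Pairing is only useful when complete, so excluding one sample means
#' excluding its partner too (flagging two control arrays removes the two
#' matched case samples as well).
#'
#' @param expr an [expression_matrix()].
#' @param design a [paired_design()] whose samples are in `expr`.
#' @param flagged character vector of flagged sample ids.
#' @return List with reduced `expr`, `design`, and `excluded_pairs`.
#' @export
exclude_pairs <- function(expr, design, flagged) {
  stopifnot(all(flagged %in% design$sample_id))
  if (!length(flagged))
    return(list(expr = expr, design = design, excluded_pairs = character(0)))
  bad_pairs <- unique(design$pair_id[design$sample_id %in% flagged])
  keep <- !(design$pair_id %in% bad_pairs)
  if (sum(keep) / 2L < 3L)
    stop("insufficient data: fewer than 3 pairs remain after exclusion")
  design2 <- design[keep, , drop = FALSE]
  class(design2) <- c("PairedDesign", "data.frame")
  validate_paired_design(design2)
  expr2 <- expression_matrix(
    unclass(expr)[, setdiff(colnames(expr), design$sample_id[!keep]), drop = FALSE])
  list(expr = expr2, design = design2, excluded_pairs = bad_pairs)
}

#' Sample-level QC in one call
#'
#' Runs [pca_overview()], [flag_outlier_samples()] and [exclude_pairs()],
#' returning a full `QCReport` plus the reduced data.
#'
#' @inheritParams exclude_pairs
#' @param k components for the PCA overview.
#' @param z_cut see [flag_outlier_samples()].
#' @return List with `report` (class `QCReport`), `expr`, `design`.
#' @export
run_qc <- function(expr, design, k = 2L, z_cut = 2.5) {
  aligned <- align_design(expr, design)
  expr <- aligned$expr; design <- aligned$design
  rep <- pca_overview(expr, k)
  flagged <- flag_outlier_samples(expr, z_cut)
  rep$sample_tree <- attr(flagged, "tree")
  rep$flagged_samples <- as.character(flagged)
  red <- exclude_pairs(expr, design, rep$flagged_samples)
  rep$excluded_pairs <- red$excluded_pairs
  list(report = rep, expr = red$expr, design = red$design)
}

#' @export
print.QCReport <- function(x, ...) {
  cat(sprintf("QCReport: %d samples, %d PCs (%.1f%% variance)\n",
              nrow(x$pc_scores), ncol(x$pc_scores),
              100 * sum(x$pc_variance_fraction)))
  cat(sprintf("  flagged: %s\n",
              if (length(x$flagged_samples)) paste(x$flagged_samples, collapse = ", ")
              else "none"))
  invisible(x)
}

# Newick-ish text export of an hclust tree (labels + merge heights), enough to
# re-draw the sample dendrogram outside R.
hclust_to_newick <- function(hc) {
  build <- function(i) {
    if (i < 0) return(hc$labels[-i])
    left <- build(hc$merge[i, 1L]); right <- build(hc$merge[i, 2L])
    sprintf("(%s,%s):%g", left, right, hc$height[i])
  }
  paste0(build(nrow(hc$merge)), ";")
}
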