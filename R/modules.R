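# Colour-name labels by module size rank, largest first; overflow falls back
# to "module<k>". "grey" is reserved for unassigned genes.
module_palette <- c(
  "turquoise", "blue", "brown", "yellow", "green", "red", "black", "pink",
  "magenta", "purple", "greenyellow", "tan", "salmon", "cyan", "midnightblue",
  "lightcyan", "grey60", "lightgreen", "lightyellow", "royalblue")

#' Cluster genes on topological-overlap dissimilarity
#'
#' Average-linkage hierarchical clustering with `dissTOM = 1 - TOM` as the
#' dissimilarity. The dissimilarity matrix is attached to the returned tree
#' (attribute `"diss"`) so that [cut_tree()] can run its hybrid rescue pass.
#'
#' @param tomm a [tom()] result, or a symmetric dissimilarity matrix with
#'   gene ids as dimnames.
#' @return An `hclust` object over genes.
#' @export
cluster_genes <- function(tomm) {
  diss <- if (inherits(tomm, "TOMMatrix")) tomm$diss else tomm
  if (!isSymmetric(unname(diss), tol = 1e-8))
    stop("dissimilarity matrix must be symmetric")
  if (is.null(rownames(diss)) && inherits(tomm, "TOMMatrix"))
    dimnames(diss) <- list(tomm$gene_ids, tomm$gene_ids)
  hc <- stats::hclust(stats::as.dist(diss), method = "average")
  attr(hc, "diss") <- diss
  hc
}

#' Cut the gene tree into modules
#'
#' `method = "static"` cuts all branches at `cut_height` and sends clusters
#' smaller than `min_module_size` to the grey (unassigned) module.
#' `method = "hybrid"` (default) additionally rescues each grey gene into the
#' module with the smallest average dissimilarity to it, provided that
#' average is below `cut_height` — a single-pass stand-in for the dynamic
#' hybrid tree cut's assignment stage. Modules are labelled by size rank with
#' the standard colour palette (largest = "turquoise", then "blue", "brown",
#' ...); size ties break toward the cluster containing the lexicographically
#' smallest gene id.
#'
#' @param hc an `hclust` from [cluster_genes()].
#' @param method `"hybrid"` or `"static"`.
#' @param cut_height cut level on the dissimilarity scale; default
#'   `0.99 * max(hc$height)`. Must lie in `[0, max merge height]`.
#' @param min_module_size smallest allowed non-grey module (default 30).
#' @return A list of class `ModuleSet`: `assignment` (named character,
#'   gene -> label), `labels` (non-grey labels by size rank, then "grey" if
#'   present), `sizes`.
#' @export
cut_tree <- function(hc, method = c("hybrid", "static"), cut_height = NULL,
                     min_module_size = 30L) {
  method <- match.arg(method)
  if (min_module_size < 2L) stop("min_module_size must be >= 2")
  max_h <- max(hc$height)
  if (is.null(cut_height)) cut_height <- 0.99 * max_h
  if (cut_height < 0 || cut_height > max_h)
    stop("cut_height must lie in [0, ", signif(max_h, 6), "]")
  cl <- stats::cutree(hc, h = cut_height)
  genes <- names(cl)
  sizes <- table(cl)
  keep <- names(sizes)[sizes >= min_module_size]
  raw <- ifelse(cl %in% keep, as.character(cl), NA_character_)
  names(raw) <- genes

  if (method == "hybrid" && anyNA(raw) && length(keep)) {
    diss <- attr(hc, "diss")
    if (is.null(diss)) stop("hybrid cut needs the dissimilarity attached by cluster_genes()")
    for (g in genes[is.na(raw)]) {
      avg <- vapply(keep, function(m)
        mean(diss[g, genes[!is.na(raw) & raw == m & genes != g]]), numeric(1))
      if (min(avg) < cut_height) raw[g] <- keep[which.min(avg)]
    }
  }
  relabel_modules(raw, genes)
}

# Order clusters by decreasing size (ties: cluster holding the smallest gene
# id first), map to colour names, unassigned -> grey.
relabel_modules <- function(raw, genes) {
  assignment <- stats::setNames(rep("grey", length(genes)), genes)
  ids <- unique(raw[!is.na(raw)])
  if (length(ids)) {
    sz <- vapply(ids, function(m) sum(raw == m, na.rm = TRUE), numeric(1))
    first_gene <- vapply(ids, function(m) min(genes[!is.na(raw) & raw == m]),
                         character(1))
    ord <- ids[order(-sz, first_gene)]
    labels <- c(module_palette, paste0("module", seq_along(ord)))[seq_along(ord)]
    for (i in seq_along(ord))
      assignment[!is.na(raw) & raw == ord[i]] <- labels[i]
  } else labels <- character(0)
  labs <- c(labels, if (any(assignment == "grey")) "grey")
  structure(list(assignment = assignment, labels = labs,
                 sizes = vapply(labs, function(l) sum(assignment == l), numeric(1))),
            class = "ModuleSet")
}

#' @export
print.ModuleSet <- function(x, ...) {
  cat("ModuleSet:", length(x$assignment), "genes in",
      sum(x$labels != "grey"), "modules (+ grey)\n")
  print(x$sizes)
  invisible(x)
}

module_genes <- function(modset, label) {
  names(modset$assignment)[modset$assignment == label]
}

#' Module eigengene
#'
#' First principal component of the module's genes x samples submatrix after
#' per-gene standardization, scaled to unit variance across samples and
#' oriented so that its mean correlation with the module's genes is
#' non-negative. The eigengene summarizes the module's overall expression
#' level per sample; the grey module's eigengene is computed the same way so
#' the unassigned set can also be tested for association.
#'
#' @param expr an [expression_matrix()].
#' @param modset a [cut_tree()] result.
#' @param label module label present in `modset`.
#' @return Numeric vector (one value per sample) with attribute
#'   `"explained_variance_fraction"`.
#' @export
module_eigengene <- function(expr, modset, label) {
  genes <- module_genes(modset, label)
  if (!length(genes)) stop("module not found or empty: ", label)
  x <- unclass(expr)[genes, , drop = FALSE]
  x <- sweep(x, 1L, rowMeans(x))
  sds <- apply(x, 1L, stats::sd)
  if (any(sds == 0)) stop("zero-variance gene(s) in module ", label)
  x <- sweep(x, 1L, sds, "/")
  sv <- svd(t(x), nu = 1L, nv = 1L)
  me <- sv$u[, 1L]
  me <- me / stats::sd(me)
  if (mean(stats::cor(me, t(x))) < 0) me <- -me
  names(me) <- colnames(expr)
  attr(me, "explained_variance_fraction") <- sv$d[1L]^2 / sum(sv$d^2)
  me
}

#' All module eigengenes
#'
#' @inheritParams module_eigengene
#' @param include_grey also compute the grey (unassigned) eigengene.
#' @return A list of class `Eigengenes`: `me` (samples x modules matrix) and
#'   `explained_variance_fraction` (named vector).
#' @export
module_eigengenes <- function(expr, modset, include_grey = TRUE) {
  labs <- modset$labels
  if (!include_grey) labs <- setdiff(labs, "grey")
  mes <- lapply(labs, function(l) module_eigengene(expr, modset, l))
  me <- do.call(cbind, mes)
  dimnames(me) <- list(colnames(expr), labs)
  structure(list(
    me = me,
    explained_variance_fraction = stats::setNames(
      vapply(mes, attr, numeric(1), "explained_variance_fraction"), labs)),
    class = "Eigengenes")
}

#' Module membership of a gene
#'
#' `MM(i) = cor(x_i, ME)`: the signed Pearson correlation between a gene's
#' profile and a module's eigengene; `|MM|` measures how central the gene is
#' to the module.
#'
#' @param expr an [expression_matrix()].
#' @param eig a [module_eigengenes()] result.
#' @param gene_id gene identifier.
#' @param label module label.
#' @return Signed correlation in `[-1, 1]`.
#' @export
module_membership <- function(expr, eig, gene_id, label) {
  if (!gene_id %in% rownames(expr)) stop("unknown gene: ", gene_id)
  if (!label %in% colnames(eig$me)) stop("unknown module: ", label)
  x <- unclass(expr)[gene_id, ]
  if (stats::sd(x) == 0) stop("zero-variance gene: ", gene_id)
  stats::cor(x, eig$me[, label])
}

#' Hierarchical clustering of module eigengenes
#'
#' Average-linkage tree on `1 - cor(ME_a, ME_b)` (signed: anticorrelated
#' eigengenes are at dissimilarity 2), used to study inter-module
#' relationships.
#'
#' @param eig a [module_eigengenes()] result with >= 2 modules.
#' @return An `hclust` over modules.
#' @export
eigengene_dendrogram <- function(eig) {
  if (ncol(eig$me) < 2L) stop("need at least 2 modules")
  d <- 1 - stats::cor(eig$me)
  stats::hclust(stats::as.dist(d), method = "average")
}

#' Merge modules with highly correlated eigengenes
#'
#' Optional post-processing: while any pair of non-grey eigengenes satisfies
#' `1 - cor(ME_a, ME_b) < merge_cut`, the two closest modules are merged and
#' eigengenes recomputed. Off by default in the pipeline.
#'
#' @inheritParams module_eigengene
#' @param merge_cut dissimilarity threshold below which modules merge.
#' @return A `ModuleSet`.
#' @export
merge_close_modules <- function(expr, modset, merge_cut = 0.25) {
  repeat {
    labs <- setdiff(modset$labels, "grey")
    if (length(labs) < 2L) return(modset)
    eig <- module_eigengenes(expr, modset, include_grey = FALSE)
    d <- 1 - stats::cor(eig$me[, labs, drop = FALSE])
    diag(d) <- Inf
    if (min(d) >= merge_cut) return(modset)
    ij <- which(d == min(d), arr.ind = TRUE)[1L, ]
    a <- labs[ij[1L]]; b <- labs[ij[2L]]
    raw <- modset$assignment
    raw[raw == b] <- a
    raw[raw == "grey"] <- NA_character_
    modset <- relabel_modules(raw, names(raw))
  }
}

#' Write a module assignment as two-column TSV (gene_id, module)
#' @param modset a `ModuleSet`.
#' @param path output path.
#' @export
write_modules <- function(modset, path) {
  utils::write.table(
    data.frame(gene_id = names(modset$assignment), module = modset$assignment),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write eigengenes as samples x modules TSV
#' @param eig an `Eigengenes` object.
#' @param path output path.
#' @export
write_eigengenes <- function(eig, path) {
  df <- data.frame(sample_id = rownames(eig$me), eig$me, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
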