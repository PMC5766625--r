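#' Dichotomize a weighted network into an edge list
#'
#' Keeps edges among one module's genes whose weight (TOM by default, or
#' adjacency) is at least `threshold`. The grey module is refused: its genes
#' are by construction not co-expressed, so a hub there is meaningless.
#'
#' @param net a [tom()] or [adjacency()] result.
#' @param modset a [cut_tree()] result.
#' @param label a non-grey module label.
#' @param threshold minimum edge weight in `[0, 1]` (default 0.1).
#' @return A list of class `EdgeList`: `edges` (data.frame `source`,
#'   `target`, `weight`, each unordered pair once, `source < target`),
#'   `threshold`, `weight_kind`, `genes` (the module's genes).
#' @export
build_edges <- function(net, modset, label, threshold = 0.1) {
  if (label == "grey")
    stop("refusing grey module: unassigned genes are not co-expressed")
  if (threshold < 0 || threshold > 1) stop("threshold must lie in [0, 1]")
  genes <- module_genes(modset, label)
  if (!length(genes)) stop("module not found or empty: ", label)
  if (inherits(net, "TOMMatrix")) {
    w <- net$tom; kind <- "tom"
  } else if (inherits(net, "AdjacencyMatrix")) {
    w <- net$a; dimnames(w) <- list(net$gene_ids, net$gene_ids); kind <- "adjacency"
  } else stop("net must be a TOMMatrix or AdjacencyMatrix")
  w <- w[genes, genes, drop = FALSE]
  idx <- which(upper.tri(w) & w >= threshold, arr.ind = TRUE)
  edges <- data.frame(source = genes[idx[, 1L]], target = genes[idx[, 2L]],
                      weight = w[idx], stringsAsFactors = FALSE)
  swap <- edges$source > edges$target
  tmp <- edges$source[swap]
  edges$source[swap] <- edges$target[swap]
  edges$target[swap] <- tmp
  edges <- edges[order(edges$source, edges$target), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(edges = edges, threshold = threshold, weight_kind = kind,
                 genes = genes), class = "EdgeList")
}

#' Node degrees of an edge list
#'
#' @param el an [build_edges()] result.
#' @return Named integer vector over the module's genes; genes with no edge
#'   get 0.
#' @export
degrees <- function(el) {
  stopifnot(inherits(el, "EdgeList"))
  d <- stats::setNames(integer(length(el$genes)), el$genes)
  if (nrow(el$edges)) {
    t1 <- table(el$edges$source); t2 <- table(el$edges$target)
    d[names(t1)] <- d[names(t1)] + as.integer(t1)
    d[names(t2)] <- d[names(t2)] + as.integer(t2)
  }
  d
}

#' Module hub
#'
#' The module's gene with the largest degree in the dichotomized network.
#' Ties break by larger summed edge weight, then lexicographically smaller
#' gene id, making the hub deterministic.
#'
#' @param el an [build_edges()] result with at least one edge.
#' @return The hub gene id (character scalar) with attribute `"degree"`.
#' @export
hub <- function(el) {
  if (!nrow(el$edges)) stop("module has no edges at this threshold; no hub")
  d <- degrees(el)
  wsum <- stats::setNames(numeric(length(el$genes)), el$genes)
  for (i in seq_len(nrow(el$edges))) {
    wsum[el$edges$source[i]] <- wsum[el$edges$source[i]] + el$edges$weight[i]
    wsum[el$edges$target[i]] <- wsum[el$edges$target[i]] + el$edges$weight[i]
  }
  ord <- order(-d, -wsum, names(d))
  structure(names(d)[ord[1L]], degree = unname(d[ord[1L]]))
}

#' Export an edge list in SIF format
#'
#' One line per edge, `source <TAB> co <TAB> target`, loadable by Cytoscape.
#' @param el an `EdgeList`.
#' @param path output path.
#' @export
write_sif <- function(el, path) {
  writeLines(sprintf("%s\tco\t%s", el$edges$source, el$edges$target), path)
  invisible(path)
}

#' Export an edge list as weighted TSV (source, target, weight)
#' @param el an `EdgeList`.
#' @param path output path.
#' @export
write_edges <- function(el, path) {
  utils::write.table(format(el$edges, digits = 17, trim = TRUE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Re-import a weighted edge TSV written by [write_edges()]
#' @param path input path.
#' @param threshold,weight_kind,genes metadata to restore; `genes` defaults
#'   to the ids present in the file.
#' @return An `EdgeList`.
#' @export
read_edges <- function(path, threshold = 0, weight_kind = "tom", genes = NULL) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  df$weight <- as.numeric(df$weight)
  if (is.null(genes)) genes <- sort(unique(c(df$source, df$target)))
  structure(list(edges = df, threshold = threshold, weight_kind = weight_kind,
                 genes = genes), class = "EdgeList")
}

#' Node-attribute table for network viewers
#'
#' @param modset a [cut_tree()] result.
#' @param genestats a [gene_significance()] table.
#' @param mmgs a [mm_gs_scatter_table()] result.
#' @param degree_by_module named list of [degrees()] vectors per module
#'   (optional).
#' @return A data.frame `gene_id`, `module`, `gs`, `mm`, `degree`.
#' @export
node_attributes <- function(modset, genestats, mmgs, degree_by_module = list()) {
  tab <- mmgs$table
  gs <- stats::setNames(genestats$gs, genestats$gene_id)
  deg <- rep(NA_integer_, nrow(tab))
  for (l in names(degree_by_module)) {
    hit <- tab$module == l & tab$gene_id %in% names(degree_by_module[[l]])
    deg[hit] <- degree_by_module[[l]][tab$gene_id[hit]]
  }
  data.frame(gene_id = tab$gene_id, module = tab$module,
             gs = gs[tab$gene_id], mm = tab$mm, degree = deg)
}
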