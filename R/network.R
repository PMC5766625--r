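#' Co-expression similarity matrix
#'
#' Unsigned co-expression similarity `s_ij = |cor(x_i, x_j)|`: the absolute
#' Pearson correlation between the two genes' profiles across all samples,
#' cases and controls pooled. Pooling is justified for paired designs by the
#' mixture-correlation identity (see [mixture_correlation()]): the pooled
#' expression of a gene is a two-component mixture over condition, and its
#' Pearson correlation with another gene has the same closed form whether or
#' not samples are paired.
#'
#' @param expr an [expression_matrix()] with >= 3 samples and no
#'   zero-variance gene.
#' @return A list of class `SimilarityMatrix` with `s` (genes x genes,
#'   symmetric, unit diagonal, entries in `[0, 1]`) and `gene_ids`.
#' @export
similarity <- function(expr) {
  assert_network_ready(expr)
  x <- unclass(expr)
  sds <- apply(x, 1L, stats::sd)
  if (any(sds == 0))
    stop("zero-variance genes: ", paste(rownames(x)[sds == 0], collapse = ", "))
  s <- abs(stats::cor(t(x)))
  s[s > 1] <- 1          # guard against fp overshoot
  diag(s) <- 1
  structure(list(gene_ids = rownames(x), s = s), class = "SimilarityMatrix")
}

#' Mixture correlation of two genes pooled over conditions
#'
#' Closed form for the Pearson correlation of two pooled expression variables
#' `Z_i = (1 - theta) X_i + theta Y_i`, where `theta ~ Bernoulli(p)` indicates
#' case status, `X_i` is gene i in controls, `Y_i` in cases, and
#' `delta_i = E(Y_i) - E(X_i)` is the condition mean shift:
#'
#' \deqn{corr(Z_1, Z_2) = \frac{(1-p)Cov(X_1,X_2) + p\,Cov(Y_1,Y_2)
#'   + p(1-p)\delta_1\delta_2}{\sqrt{[(1-p)\sigma^2_{X_1} + p\sigma^2_{Y_1}
#'   + p(1-p)\delta_1^2][(1-p)\sigma^2_{X_2} + p\sigma^2_{Y_2}
#'   + p(1-p)\delta_2^2]}}}
#'
#' The identity holds regardless of pairing, which is what licenses pooled
#' Pearson similarity on paired samples.
#'
#' @param p case fraction, in (0, 1).
#' @param cov_x,cov_y covariance of the two genes in controls / cases.
#' @param var_x1,var_x2,var_y1,var_y2 per-gene variances (must be > 0).
#' @param delta1,delta2 case-minus-control mean shifts.
#' @return The pooled Pearson correlation (scalar).
#' @export
mixture_correlation <- function(p, cov_x, cov_y,
                                var_x1, var_x2, var_y1, var_y2,
                                delta1 = 0, delta2 = 0) {
  if (!(p > 0 && p < 1)) stop("p must lie strictly in (0, 1)")
  if (any(c(var_x1, var_x2, var_y1, var_y2) <= 0))
    stop("variances must be positive")
  q <- 1 - p
  num <- q * cov_x + p * cov_y + p * q * delta1 * delta2
  v1 <- q * var_x1 + p * var_y1 + p * q * delta1^2
  v2 <- q * var_x2 + p * var_y2 + p * q * delta2^2
  num / sqrt(v1 * v2)
}

#' Soft-thresholded adjacency
#'
#' `a_ij = s_ij ^ beta` with integer soft threshold `beta >= 1`; raising the
#' similarity to a power suppresses weak correlations smoothly instead of
#' hard-thresholding them. The diagonal is set to 0 so that row sums are
#' whole-network connectivities.
#'
#' @param sim a [similarity()] result.
#' @param beta soft-thresholding power, `>= 1`.
#' @return A list of class `AdjacencyMatrix` with `a`, `gene_ids`, `beta`.
#' @export
adjacency <- function(sim, beta) {
  stopifnot(inherits(sim, "SimilarityMatrix"))
  if (!is.numeric(beta) || length(beta) != 1L || beta < 1)
    stop("beta must be a single number >= 1")
  a <- sim$s^beta
  diag(a) <- 0
  structure(list(gene_ids = sim$gene_ids, a = a, beta = beta),
            class = "AdjacencyMatrix")
}

#' Scan soft-thresholding powers for scale-free topology fit
#'
#' For each power in `beta_grid` the whole-network connectivity
#' `k_i = sum_j a_ij` is computed, binned into `n_bins` equal-width bins, and
#' `log10` mean frequency is regressed on `log10` mean connectivity over
#' non-empty bins. The signed fit index is `R^2 = cor^2 * (-sign(slope))`, so
#' positive values indicate the decreasing degree distribution a scale-free
#' network must have. The chosen power is the first local maximum of the
#' signed index over the grid (ties toward smaller beta) whose fit is
#' adequate (`R^2 >= peak_min`, guarding against spurious noise peaks on the
#' flat low-beta part of the curve); if there is none, the smallest beta with
#' `R^2 >= 0.90`; failing that, the grid argmax with a warning — on data
#' whose connectivity distribution is not scale-free (e.g. strongly modular
#' synthetic data) the scan is uninformative and the power should be set
#' explicitly.
#'
#' @param sim a [similarity()] result.
#' @param beta_grid ascending integer powers (default `1:20`).
#' @param n_bins number of connectivity bins (default 10, minimum 5).
#' @param peak_min minimum signed `R^2` for a grid point to count as the
#'   peak (default 0.8).
#' @return A list of class `ScaleFreeScan` with `beta_grid`, `r2`,
#'   `mean_connectivity`, `chosen_beta`, `k` (connectivity at `chosen_beta`),
#'   and `pk_bins` (the binned degree distribution at `chosen_beta`).
#' @export
scale_free_scan <- function(sim, beta_grid = 1:20, n_bins = 10L,
                            peak_min = 0.8) {
  stopifnot(inherits(sim, "SimilarityMatrix"))
  if (!length(beta_grid) || is.unsorted(beta_grid, strictly = TRUE))
    stop("beta_grid must be non-empty and strictly ascending")
  if (n_bins < 5L) stop("n_bins must be >= 5")
  r2 <- mean_k <- numeric(length(beta_grid))
  for (i in seq_along(beta_grid)) {
    a <- sim$s^beta_grid[i]
    diag(a) <- 0
    k <- rowSums(a)
    mean_k[i] <- mean(k)
    r2[i] <- scale_free_r2(k, n_bins)
  }
  chosen <- pick_first_peak(beta_grid, r2, peak_min)
  a <- sim$s^chosen
  diag(a) <- 0
  k <- rowSums(a)
  structure(list(beta_grid = as.integer(beta_grid), r2 = r2,
                 mean_connectivity = mean_k, chosen_beta = chosen,
                 k = stats::setNames(k, sim$gene_ids),
                 pk_bins = bin_connectivity(k, n_bins)),
            class = "ScaleFreeScan")
}

bin_connectivity <- function(k, n_bins) {
  if (diff(range(k)) == 0)
    stop("degenerate connectivity: all genes have identical k")
  breaks <- seq(min(k), max(k), length.out = n_bins + 1L)
  idx <- findInterval(k, breaks, rightmost.closed = TRUE, all.inside = TRUE)
  data.frame(
    mean_k = as.numeric(tapply(k, factor(idx, levels = seq_len(n_bins)), mean)),
    freq = as.numeric(table(factor(idx, levels = seq_len(n_bins)))) / length(k))
}

scale_free_r2 <- function(k, n_bins) {
  if (all(k == 0)) stop("degenerate network: all connectivities are zero")
  bins <- bin_connectivity(k, n_bins)
  bins <- bins[bins$freq > 0 & bins$mean_k > 0, , drop = FALSE]
  if (nrow(bins) < 3L) return(NA_real_)
  lx <- log10(bins$mean_k); ly <- log10(bins$freq)
  if (stats::sd(lx) == 0 || stats::sd(ly) == 0) return(NA_real_)
  r <- stats::cor(lx, ly)
  slope <- r * stats::sd(ly) / stats::sd(lx)
  r^2 * (-sign(slope))
}

pick_first_peak <- function(grid, r2, peak_min = 0.8) {
  ok <- !is.na(r2)
  n <- length(grid)
  # the last grid point never counts as a peak: a rise that has not turned
  # over by the end of the grid falls through to the R^2 >= 0.90 rule
  for (i in seq_len(n - 1L)) {
    if (!ok[i] || r2[i] < peak_min) next
    left <- if (i > 1L && ok[i - 1L]) r2[i - 1L] else -Inf
    right <- if (ok[i + 1L]) r2[i + 1L] else -Inf
    if (r2[i] > left && r2[i] > right) return(as.integer(grid[i]))
  }
  cand <- which(ok & r2 >= 0.90)
  if (length(cand)) return(as.integer(grid[cand[1L]]))
  warning("no local maximum and no beta with signed R^2 >= 0.90; using grid argmax")
  as.integer(grid[which.max(replace(r2, !ok, -Inf))])
}

#' Topological overlap matrix
#'
#' Standard unsigned topological overlap: for `i != j`
#' \deqn{TOM_{ij} = \frac{\sum_{u \ne i,j} a_{iu} a_{uj} + a_{ij}}
#'   {\min(k_i, k_j) + 1 - a_{ij}}}
#' with unit diagonal, measuring how much two genes share network neighbours
#' over and above their direct connection. `dissTOM = 1 - TOM` is the
#' clustering dissimilarity.
#'
#' @param adj an [adjacency()] result (zero diagonal).
#' @return A list of class `TOMMatrix` with `tom`, `diss = 1 - tom`,
#'   `gene_ids`.
#' @export
tom <- function(adj) {
  stopifnot(inherits(adj, "AdjacencyMatrix"))
  a <- adj$a
  k <- rowSums(a)
  num <- a %*% a + a        # diag(a) = 0 removes u = i and u = j terms
  den <- outer(k, k, pmin) + 1 - a
  t <- num / den
  diag(t) <- 1
  t[t > 1] <- 1
  dimnames(t) <- list(adj$gene_ids, adj$gene_ids)
  structure(list(gene_ids = adj$gene_ids, tom = t, diss = 1 - t),
            class = "TOMMatrix")
}

#' Write a square network matrix as TSV
#' @param m matrix with gene ids as dimnames (or a Similarity/Adjacency/TOM
#'   object, whose primary matrix is used).
#' @param path output path.
#' @export
write_network_matrix <- function(m, path) {
  if (inherits(m, "SimilarityMatrix")) m <- `dimnames<-`(m$s, list(m$gene_ids, m$gene_ids))
  if (inherits(m, "AdjacencyMatrix")) m <- `dimnames<-`(m$a, list(m$gene_ids, m$gene_ids))
  if (inherits(m, "TOMMatrix")) m <- m$tom
  df <- data.frame(gene_id = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a scale-free scan as TSV (beta, signed R2, mean connectivity)
#' @param scan a [scale_free_scan()] result.
#' @param path output path.
#' @export
write_scan <- function(scan, path) {
  utils::write.table(
    data.frame(beta = scan$beta_grid, r2 = scan$r2,
               mean_connectivity = scan$mean_connectivity),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
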