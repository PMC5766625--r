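#' Random-intercept mixed model for a paired response
#'
#' Fits, by REML, the linear mixed-effects model
#' `y_ij = b_0i + beta1 * condition_j + sum_c beta_c * covariate_ci + e_ij`
#' with a subject-specific random intercept `b_0i ~ N(beta0, tau^2)` and
#' residuals `e_ij ~ N(0, sigma^2)`, the within-pair-correlation-aware
#' replacement for the independent-samples association test. The response can
#' be a module eigengene or a single gene's expression profile.
#'
#' For the balanced complete-pair design the REML problem separates exactly
#' into two independent strata, which is how the fit is computed:
#' within-pair differences `d_i = y_i,case - y_i,ctrl ~ N(beta1, 2 sigma^2)`
#' carry all information about `beta1`, and pair means
#' `m_i ~ N(mu + x_i' beta_c, tau^2 + sigma^2/2)` carry the subject-level
#' covariate effects and the between-pair variance. With `tau^2` interior the
#' condition test is therefore *exactly* the classical paired t-test:
#' `t = mean(d) / (sd(d)/sqrt(n))` on `n_pairs - 1` degrees of freedom
#' (containment rule; condition varies within pairs, subject-level covariates
#' do not and so never change this df). When the unconstrained between-pair
#' variance estimate would be negative, `tau^2` is truncated at 0 and
#' `sigma^2` re-profiled over both strata for the reported variance
#' components; the fit is returned with `boundary = TRUE` rather than refit
#' by OLS. The Wald standard error for `beta1` is always taken from the
#' difference stratum (`sd(d)/sqrt(n)`), which coincides with the REML
#' standard error whenever `tau^2` is interior and keeps the condition test
#' exactly the paired t-test even at the boundary.
#'
#' @param response numeric vector named by (or ordered as) the design's
#'   sample ids.
#' @param design a [paired_design()] with >= 3 complete pairs.
#' @param covariates character vector of subject-level covariate names to
#'   adjust for (subset of the design's covariate columns).
#' @param stage_coding how to code a covariate named `stage`: `"numeric"`
#'   score (default) or `"categorical"` dummy coding.
#' @return A list of class `AssociationResult`: `estimate` (beta1), `se`,
#'   `statistic` (t), `df`, `p_value`, `random_intercept_sd` (tau),
#'   `residual_sd` (sigma), `boundary`, `converged`, and `covariate_effects`
#'   (estimates from the pair-mean stratum).
#' @examples
#' des <- paired_design(sample_id = paste0("s", 1:8),
#'                      pair_id = rep(paste0("p", 1:4), each = 2),
#'                      condition = rep(c(0, 1), 4))
#' y <- stats::setNames(rnorm(8), des$sample_id)
#' fit_paired_lmm(y, des)
#' @export
fit_paired_lmm <- function(response, design, covariates = character(0),
                           stage_coding = c("numeric", "categorical")) {
  stage_coding <- match.arg(stage_coding)
  if (!is.null(names(response))) {
    miss <- setdiff(design$sample_id, names(response))
    if (length(miss)) stop("response missing samples: ", paste(miss, collapse = ", "))
    response <- response[design$sample_id]
  } else if (length(response) != nrow(design)) {
    stop("unnamed response must match design length")
  }
  if (!all(is.finite(response))) stop("response contains non-finite values")
  pairs <- unique(design$pair_id)
  n <- length(pairs)
  if (n < 3L) stop("need at least 3 complete pairs")
  bad <- setdiff(covariates, covariate_names(design))
  if (length(bad)) stop("unknown covariates: ", paste(bad, collapse = ", "))

  idx_case <- match(pairs, design$pair_id[design$condition == 1])
  idx_ctrl <- match(pairs, design$pair_id[design$condition == 0])
  y_case <- response[which(design$condition == 1)[idx_case]]
  y_ctrl <- response[which(design$condition == 0)[idx_ctrl]]
  d <- as.numeric(y_case - y_ctrl)          # difference stratum
  m <- as.numeric(y_case + y_ctrl) / 2      # pair-mean stratum
  est <- mean(d)
  ss_d <- sum((d - est)^2)

  # pair-mean stratum: OLS of pair means on intercept + subject covariates
  X <- matrix(1, n, 1L, dimnames = list(NULL, "(Intercept)"))
  for (cv in covariates) {
    v <- design[[cv]][design$condition == 0][idx_ctrl]
    if (cv == "stage" && stage_coding == "categorical") {
      f <- factor(v)
      if (nlevels(f) > 1L) {
        dm <- stats::model.matrix(~f)[, -1L, drop = FALSE]
        colnames(dm) <- paste0("stage", levels(f)[-1L])
        X <- cbind(X, dm)
        next
      } else next
    }
    X <- cbind(X, stats::setNames(data.frame(as.numeric(v)), cv))
  }
  X <- as.matrix(X)
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) stop("singular design in pair-mean stratum")
  beta_m <- qr.coef(qr_x, m)
  res_m <- m - X %*% beta_m
  ss_m <- sum(res_m^2)
  df_m <- n - qr_x$rank

  # unconstrained REML: 2*sigma^2 from differences, tau^2 + sigma^2/2 from means
  sigma2_d <- ss_d / (2 * (n - 1L))
  sigma2 <- sigma2_d
  psi <- if (df_m > 0) ss_m / df_m else sigma2 / 2
  boundary <- FALSE
  if (psi < sigma2 / 2) {      # tau^2 would be negative: profile with tau = 0
    boundary <- TRUE
    sigma2 <- (ss_d / 2 + 2 * ss_m) / (n - 1L + df_m)
    tau2 <- 0
  } else {
    tau2 <- psi - sigma2 / 2
  }

  se <- sqrt(2 * sigma2_d / n)   # difference-stratum SE: exact paired t
  df <- n - 1L
  stat <- if (se > 0) est / se else if (est == 0) 0 else sign(est) * Inf
  structure(list(
    estimate = est, se = se, statistic = stat, df = df,
    p_value = 2 * stats::pt(abs(stat), df, lower.tail = FALSE),
    random_intercept_sd = sqrt(tau2), residual_sd = sqrt(sigma2),
    boundary = boundary, converged = TRUE,
    covariate_effects = stats::setNames(as.numeric(beta_m), colnames(X)),
    n_pairs = n), class = "AssociationResult")
}

#' @export
print.AssociationResult <- function(x, ...) {
  cat(sprintf("paired LMM: beta1 = %.4g (se %.4g), t = %.3f on %d df, p = %.3g\n",
              x$estimate, x$se, x$statistic, x$df, x$p_value))
  cat(sprintf("  tau = %.4g, sigma = %.4g%s\n", x$random_intercept_sd,
              x$residual_sd, if (x$boundary) " (boundary: tau^2 = 0)" else ""))
  invisible(x)
}

#' Module-trait association table
#'
#' Fits the paired mixed model to every module eigengene (grey included) and
#' tabulates the condition effect, ordered by decreasing `|t|`. Per-module
#' failures are recorded (`NA` row) without aborting the rest.
#'
#' @param eig a [module_eigengenes()] result.
#' @param design a [paired_design()] over the same samples.
#' @param covariates subject-level covariates to adjust for.
#' @return A data.frame with columns `module`, `estimate`, `se`, `statistic`,
#'   `df`, `p_value`, `fdr`, `boundary`, `error`.
#' @export
module_trait_table <- function(eig, design, covariates = character(0)) {
  labs <- colnames(eig$me)
  rows <- lapply(labs, function(l) {
    fit <- tryCatch(fit_paired_lmm(eig$me[, l], design, covariates),
                    error = function(e) e)
    if (inherits(fit, "error"))
      data.frame(module = l, estimate = NA_real_, se = NA_real_,
                 statistic = NA_real_, df = NA_real_, p_value = NA_real_,
                 boundary = NA, error = conditionMessage(fit))
    else
      data.frame(module = l, estimate = fit$estimate, se = fit$se,
                 statistic = fit$statistic, df = fit$df,
                 p_value = fit$p_value, boundary = fit$boundary, error = "")
  })
  out <- do.call(rbind, rows)
  out$fdr <- stats::p.adjust(out$p_value, method = "BH")
  out[order(-abs(out$statistic), out$module, na.last = TRUE),
      c("module", "estimate", "se", "statistic", "df", "p_value", "fdr",
        "boundary", "error")]
}

#' Per-gene paired-design significance
#'
#' Gene significance under pairing: each gene's profile is fit with the
#' random-intercept mixed model and reduced to `gs_signed = t` and
#' `gs = |t|`. Because t statistics of the stated model can exceed 1, a
#' normalized companion `gs_scaled = |t| / max |t|` is also emitted for
#' `[0, 1]`-scale displays. Per-gene failures get `NA` and are excluded from
#' module significance.
#'
#' @param expr an [expression_matrix()].
#' @param design a [paired_design()].
#' @param covariates subject-level covariates to adjust for.
#' @return A data.frame ordered by gene id: `gene_id`, `estimate`,
#'   `gs_signed`, `gs`, `gs_scaled`, `p_value`, `fdr`, `boundary`, `error`.
#' @export
gene_significance <- function(expr, design, covariates = character(0)) {
  genes <- sort(rownames(expr))
  rows <- lapply(genes, function(g) {
    fit <- tryCatch(fit_paired_lmm(unclass(expr)[g, ], design, covariates),
                    error = function(e) e)
    if (inherits(fit, "error"))
      data.frame(gene_id = g, estimate = NA_real_, gs_signed = NA_real_,
                 gs = NA_real_, p_value = NA_real_, boundary = NA,
                 error = conditionMessage(fit))
    else
      data.frame(gene_id = g, estimate = fit$estimate,
                 gs_signed = fit$statistic, gs = abs(fit$statistic),
                 p_value = fit$p_value, boundary = fit$boundary, error = "")
  })
  out <- do.call(rbind, rows)
  mx <- max(out$gs, na.rm = TRUE)
  out$gs_scaled <- if (is.finite(mx) && mx > 0) out$gs / mx else out$gs
  out$fdr <- stats::p.adjust(out$p_value, method = "BH")
  out[, c("gene_id", "estimate", "gs_signed", "gs", "gs_scaled", "p_value",
          "fdr", "boundary", "error")]
}

#' Module significance
#'
#' `MS = mean GS` over the module's genes with valid fits; `NA` when no gene
#' in the module has one.
#'
#' @param genestats a [gene_significance()] table.
#' @param modset a [cut_tree()] result over the same genes.
#' @return A data.frame `module`, `ms`, `n_genes`, `n_valid`, ordered by
#'   decreasing `ms`.
#' @export
module_significance <- function(genestats, modset) {
  gs <- stats::setNames(genestats$gs, genestats$gene_id)
  rows <- lapply(modset$labels, function(l) {
    g <- module_genes(modset, l)
    miss <- setdiff(g, names(gs))
    if (length(miss)) stop("genes without GS entry: ", paste(miss, collapse = ", "))
    v <- gs[g]
    data.frame(module = l, ms = if (any(!is.na(v))) mean(v, na.rm = TRUE) else NA_real_,
               n_genes = length(g), n_valid = sum(!is.na(v)))
  })
  out <- do.call(rbind, rows)
  out[order(-out$ms, na.last = TRUE), ]
}

#' Module membership vs gene significance table
#'
#' For each module, pairs every member gene's `|MM|` (absolute correlation
#' with the module eigengene) with its `gs`, plus the per-module Pearson
#' correlation of the two — the diagnostic showing whether trait-associated
#' genes are also central to their module. Correlation is `NA` for modules
#' with fewer than 3 genes with valid values.
#'
#' @param genestats a [gene_significance()] table.
#' @param modset a [cut_tree()] result.
#' @param eig a [module_eigengenes()] result.
#' @param expr the [expression_matrix()] MM is computed on.
#' @return A list: `table` (gene_id, module, mm, abs_mm, gs) and `cor`
#'   (named per-module correlation of `|MM|` and `gs`).
#' @export
mm_gs_scatter_table <- function(genestats, modset, eig, expr) {
  gs <- stats::setNames(genestats$gs, genestats$gene_id)
  rows <- lapply(intersect(modset$labels, colnames(eig$me)), function(l) {
    g <- module_genes(modset, l)
    mm <- vapply(g, function(gi) module_membership(expr, eig, gi, l), numeric(1))
    data.frame(gene_id = g, module = l, mm = mm, abs_mm = abs(mm), gs = gs[g])
  })
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  cors <- vapply(unique(tab$module), function(l) {
    sub <- tab[tab$module == l & !is.na(tab$gs), ]
    if (nrow(sub) < 3L || stats::sd(sub$abs_mm) == 0 || stats::sd(sub$gs) == 0)
      return(NA_real_)
    stats::cor(sub$abs_mm, sub$gs)
  }, numeric(1))
  list(table = tab, cor = stats::setNames(cors, unique(tab$module)))
}
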