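#' Configure the paired-design co-expression simulator
#'
#' The generator emulates the statistical structure the pipeline assumes:
#' each subject contributes one control and one case sample; each planted
#' module has a latent per-sample score; gene `g` of module `m` is
#' `loading_g * score + b_gi + shift_m * condition + e`, with a per-gene,
#' per-pair random intercept `b_gi ~ N(0, pair_sd^2)` and residual
#' `e ~ N(0, residual_sd^2)`. Noise genes have no latent score and no shift.
#' Pair intercepts are independent across genes, so noise genes stay mutually
#' uncorrelated. Condition shifts are given in within-pair-SD units, where
#' one unit is `sqrt(2) * residual_sd` — the SD of a paired difference for a
#' pure-noise gene — so `shift = 1` gives a per-gene paired-t noncentrality
#' of about `sqrt(n_pairs)`.
#'
#' Defaults mirror a typical miRNA-array study scale: 38 pairs, three modules
#' of 250/190/80 genes with shifts 1.5/0.75/0.25, 300 noise genes.
#'
#' @param n_pairs number of subject pairs (>= 3).
#' @param modules data.frame with columns `size`, `loading_mean` (in (0, 1]),
#'   `shift` (within-pair-SD units).
#' @param n_noise_genes number of unstructured genes.
#' @param pair_sd between-pair (random intercept) SD, > 0.
#' @param residual_sd residual SD, > 0.
#' @param covariate_effects optional named numeric `c(age = ..., stage = ...)`
#'   added to every gene through subject covariates.
#' @param leader_loading optional loading in (0, 1] planted on the first gene
#'   of each module, overriding its random draw. Off (`NULL`) by default;
#'   used to make "the top-loading gene" well separated when testing hub
#'   recovery, since with i.i.d. loadings the argmax is nearly tied.
#' @param seed integer seed; all randomness derives from it.
#' @return A list of class `SimConfig`.
#' @export
sim_config <- function(n_pairs = 38L,
                       modules = data.frame(size = c(250L, 190L, 80L),
                                            loading_mean = c(0.9, 0.9, 0.9),
                                            shift = c(1.5, 0.75, 0.25)),
                       n_noise_genes = 300L,
                       pair_sd = 0.5, residual_sd = 0.5,
                       covariate_effects = NULL, leader_loading = NULL,
                       seed = 1L) {
  stopifnot(n_pairs >= 3L, all(modules$size >= 1L),
            all(modules$loading_mean > 0), all(modules$loading_mean <= 1),
            pair_sd > 0, residual_sd > 0, n_noise_genes >= 0L)
  structure(list(n_pairs = as.integer(n_pairs), modules = modules,
                 n_noise_genes = as.integer(n_noise_genes),
                 pair_sd = pair_sd, residual_sd = residual_sd,
                 covariate_effects = covariate_effects,
                 leader_loading = leader_loading,
                 seed = as.integer(seed)), class = "SimConfig")
}

#' Simulate paired two-condition expression data with planted modules
#'
#' @param config a [sim_config()].
#' @return A list of class `SimData`: `expr` (an [expression_matrix()],
#'   genes x samples), `design` (a [paired_design()] with covariates `age`,
#'   `stage`), and `truth` (list: `module` assignment per gene using the
#'   size-rank colour labels plus `"grey"` for noise genes, `loading`,
#'   `shift` in raw units, `pair_intercepts` genes x pairs matrix,
#'   `scores` modules x samples latent scores).
#' @export
simulate_paired <- function(config = sim_config()) {
  stopifnot(inherits(config, "SimConfig"))
  set.seed(config$seed)
  n <- config$n_pairs
  ns <- 2L * n
  mods <- config$modules
  n_mod_genes <- sum(mods$size)
  n_genes <- n_mod_genes + config$n_noise_genes

  pair_ids <- sprintf("p%02d", seq_len(n))
  samp <- data.frame(
    sample_id = as.vector(rbind(paste0(pair_ids, "_ctrl"), paste0(pair_ids, "_case"))),
    pair_id = rep(pair_ids, each = 2L),
    condition = rep(c(0, 1), n))
  age <- round(stats::runif(n, 35, 80))
  stage <- sample(1:4, n, replace = TRUE)
  design <- paired_design(samp$sample_id, samp$pair_id, samp$condition,
                          data.frame(age = rep(age, each = 2L),
                                     stage = rep(stage, each = 2L)))

  gene_ids <- sprintf("g%04d", seq_len(n_genes))
  module_idx <- rep(c(seq_len(nrow(mods)), 0L),
                    c(mods$size, config$n_noise_genes))
  loading <- numeric(n_genes)
  in_mod <- module_idx > 0L
  # multiplicative jitter bounded so loadings stay in (0, 1] without hitting
  # the cap (caps would create exact ties and make "the top-loading gene"
  # ill-defined for hub scoring)
  loading[in_mod] <- pmin(1, pmax(0.05,
    mods$loading_mean[module_idx[in_mod]] * stats::runif(sum(in_mod), 0.8, 1.1)))
  if (!is.null(config$leader_loading)) {
    first_of_module <- match(seq_len(nrow(mods)), module_idx)
    loading[first_of_module] <- config$leader_loading
  }
  unit <- sqrt(2) * config$residual_sd        # one within-pair SD
  shift <- ifelse(in_mod, mods$shift[pmax(module_idx, 1L)] * unit, 0)

  scores <- matrix(stats::rnorm(nrow(mods) * ns), nrow(mods), ns)
  b <- matrix(stats::rnorm(n_genes * n, sd = config$pair_sd), n_genes, n)
  e <- matrix(stats::rnorm(n_genes * ns, sd = config$residual_sd), n_genes, ns)
  cond <- samp$condition
  pair_of_sample <- rep(seq_len(n), each = 2L)

  x <- b[, pair_of_sample, drop = FALSE] + e
  x <- x + outer(shift, cond)
  x[in_mod, ] <- x[in_mod, , drop = FALSE] +
    loading[in_mod] * scores[module_idx[in_mod], , drop = FALSE]
  if (!is.null(config$covariate_effects)) {
    ce <- config$covariate_effects
    covrow <- numeric(ns)
    if ("age" %in% names(ce)) covrow <- covrow + ce[["age"]] * rep(age, each = 2L)
    if ("stage" %in% names(ce)) covrow <- covrow + ce[["stage"]] * rep(stage, each = 2L)
    x <- sweep(x, 2L, covrow, "+")
  }
  dimnames(x) <- list(gene_ids, samp$sample_id)

  truth_labels <- c(module_palette, paste0("module", seq_len(nrow(mods))))
  rank_by_size <- order(-mods$size)
  label_of_module <- character(nrow(mods))
  label_of_module[rank_by_size] <- truth_labels[seq_len(nrow(mods))]
  truth_module <- ifelse(in_mod, label_of_module[pmax(module_idx, 1L)], "grey")

  structure(list(
    expr = expression_matrix(x),
    design = design,
    truth = list(module = stats::setNames(truth_module, gene_ids),
                 loading = stats::setNames(loading, gene_ids),
                 shift = stats::setNames(shift, gene_ids),
                 pair_intercepts = `dimnames<-`(b, list(gene_ids, pair_ids)),
                 scores = scores)), class = "SimData")
}

#' Adjusted Rand index between two labelings
#'
#' Chance-corrected agreement between partitions; 1 for identical
#' partitions (up to label names), ~0 for independent ones.
#'
#' @param a,b label vectors of equal length.
#' @return ARI (scalar).
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n2 <- comb2(length(a))
  expected <- sum_a * sum_b / n2
  mx <- (sum_a + sum_b) / 2
  if (mx == expected) return(ifelse(sum_ij == expected, 1, 0))
  (sum_ij - expected) / (mx - expected)
}

#' Score pipeline recovery against simulation truth
#'
#' Compares detected modules and estimated condition effects to the planted
#' truth: adjusted Rand index (grey and noise treated as one class), per-
#' module mean bias of the condition-effect estimate against the planted raw
#' shift, and whether the detected hub carries the highest planted loading in
#' its matched planted module.
#'
#' @param sim a [simulate_paired()] result.
#' @param modset a [cut_tree()] result on the simulated data.
#' @param genestats optional [gene_significance()] table (for shift bias).
#' @param hubs optional named character vector, detected hub per module.
#' @return A list: `ari`, `n_modules_detected`, `shift_bias` (named, detected
#'   module -> mean(estimate - true shift)), `hub_top_loading` (named logical).
#' @export
recover_and_score <- function(sim, modset, genestats = NULL, hubs = NULL) {
  truth <- sim$truth$module
  found <- modset$assignment[names(truth)]
  if (anyNA(found)) stop("module set does not cover all simulated genes")
  ari <- adjusted_rand_index(truth, found)
  out <- list(ari = ari,
              n_modules_detected = sum(modset$labels != "grey"))
  if (!is.null(genestats)) {
    est <- stats::setNames(genestats$estimate, genestats$gene_id)
    labs <- setdiff(modset$labels, "grey")
    out$shift_bias <- vapply(labs, function(l) {
      g <- module_genes(modset, l)
      mean(est[g] - sim$truth$shift[g], na.rm = TRUE)
    }, numeric(1))
  }
  if (!is.null(hubs)) {
    out$hub_top_loading <- vapply(names(hubs), function(l) {
      g <- module_genes(modset, l)
      # planted module best matching the detected one
      pl <- names(which.max(table(truth[g])))
      top <- names(which.max(sim$truth$loading[names(truth)[truth == pl]]))
      identical(unname(hubs[[l]]), top)
    }, logical(1))
  }
  out
}

#' Write simulated data and truth as TSV files
#' @param sim a [simulate_paired()] result.
#' @param dir output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_sim <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_expression(sim$expr, file.path(dir, "expression.tsv"))
  write_design(sim$design, file.path(dir, "design.tsv"))
  utils::write.table(
    data.frame(gene_id = names(sim$truth$module), module = sim$truth$module,
               loading = sim$truth$loading, shift = sim$truth$shift),
    file.path(dir, "truth.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
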