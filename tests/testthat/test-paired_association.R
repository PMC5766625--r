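test_that("paired-t equivalence: t and df match the classical paired t-test", {
  set.seed(101)
  maxd <- 0
  for (rep in 1:20) {
    n <- sample(4:25, 1)
    des <- tiny_design(n)
    y <- setNames(rep(rnorm(n, sd = 1), each = 2) + rnorm(2 * n) +
                    0.4 * des$condition, des$sample_id)
    fit <- fit_paired_lmm(y, des)
    tt <- t.test(y[des$condition == 1], y[des$condition == 0], paired = TRUE)
    maxd <- max(maxd, abs(fit$statistic - unname(tt$statistic)))
    expect_equal(fit$p_value, unname(tt$p.value), tolerance = 1e-8)
    expect_identical(fit$df, as.integer(unname(tt$parameter)))
  }
  expect_lt(maxd, 1e-8)
})

test_that("REML fit agrees with lme4 on estimate, SE and variance components", {
  skip_if_not_installed("lme4")
  set.seed(202)
  for (rep in 1:10) {
    n <- sample(6:20, 1)
    use_cov <- rep %% 2 == 0
    des <- tiny_design(n, covariates = use_cov, seed = rep)
    tau <- runif(1, 0, 1.2)
    y <- setNames(rep(rnorm(n, sd = tau), each = 2) + rnorm(2 * n, sd = 0.8) +
                    rnorm(1) * des$condition +
                    if (use_cov) 0.02 * des$age else 0, des$sample_id)
    covs <- if (use_cov) c("age", "stage") else character(0)
    fit <- fit_paired_lmm(y, des, covariates = covs)
    dat <- data.frame(y = y, cond = des$condition, pair = des$pair_id)
    if (use_cov) { dat$age <- des$age; dat$stage <- des$stage }
    form <- if (use_cov) y ~ cond + age + stage + (1 | pair) else y ~ cond + (1 | pair)
    lf <- suppressWarnings(suppressMessages(lme4::lmer(form, dat, REML = TRUE)))
    co <- lme4::fixef(lf)
    se <- sqrt(diag(as.matrix(lme4::vcov.merMod(lf))))
    expect_equal(fit$estimate, unname(co["cond"]), tolerance = 1e-5)
    # at the tau^2 boundary our Wald SE stays in the difference stratum (exact
    # paired t) while lmer pools; compare only interior fits
    if (!fit$boundary)
      expect_equal(fit$se, unname(se["cond"]), tolerance = 1e-4)
    vc <- as.data.frame(lme4::VarCorr(lf))
    expect_equal(fit$random_intercept_sd, vc$sdcor[1], tolerance = 1e-3)
    expect_equal(fit$residual_sd, vc$sdcor[2], tolerance = 1e-3)
    if (use_cov)
      expect_equal(unname(fit$covariate_effects["age"]), unname(co["age"]),
                   tolerance = 1e-5)
  }
})

test_that("degenerate and invalid inputs are handled as specified", {
  des <- tiny_design(5)
  # identical response within each pair: estimate 0, statistic 0
  y <- setNames(rep(rnorm(5), each = 2), des$sample_id)
  fit <- fit_paired_lmm(y, des)
  expect_identical(fit$estimate, 0)
  expect_identical(fit$statistic, 0)
  expect_true(fit$boundary || fit$residual_sd == 0)

  expect_error(fit_paired_lmm(y[-1], des), "missing samples")
  expect_error(fit_paired_lmm(unname(y[-1]), des), "unnamed response")
  expect_error(fit_paired_lmm(y, des, covariates = "bmi"), "unknown covariates")
  des3 <- tiny_design(2)
  expect_error(fit_paired_lmm(setNames(rnorm(4), des3$sample_id), des3),
               "at least 3")
  yna <- y; yna[2] <- NA
  expect_error(fit_paired_lmm(yna, des), "non-finite")
})

test_that("stage can be coded numeric or categorical", {
  des <- tiny_design(10, covariates = TRUE, seed = 31)
  set.seed(31)
  y <- setNames(rnorm(20) + 0.3 * des$stage, des$sample_id)
  fn <- fit_paired_lmm(y, des, covariates = "stage", stage_coding = "numeric")
  fc <- fit_paired_lmm(y, des, covariates = "stage", stage_coding = "categorical")
  expect_identical(names(fn$covariate_effects), c("(Intercept)", "stage"))
  expect_true(any(grepl("^stage", names(fc$covariate_effects))))
  # condition inference is unaffected by subject-level covariate coding
  expect_equal(fn$statistic, fc$statistic, tolerance = 1e-12)
  expect_identical(fn$df, fc$df)
})

test_that("condition antisymmetry and scale invariance of the t statistic", {
  des <- tiny_design(8, seed = 17)
  set.seed(17)
  y <- setNames(rnorm(16) + 0.8 * des$condition + rep(rnorm(8), each = 2),
                des$sample_id)
  fit <- fit_paired_lmm(y, des)
  flipped <- paired_design(des$sample_id, des$pair_id, 1 - des$condition)
  fit_f <- fit_paired_lmm(y, flipped)
  expect_equal(fit_f$statistic, -fit$statistic, tolerance = 1e-12)
  # affine rescaling leaves t unchanged
  fit_s <- fit_paired_lmm(5 * y + 3, des)
  expect_equal(fit_s$statistic, fit$statistic, tolerance = 1e-10)
})

test_that("module_trait_table orders by |t|, keeps grey, records failures", {
  sim <- small_sim(seed = 12)
  tm <- tom(adjacency(similarity(sim$expr), 6))
  modset <- cut_tree(cluster_genes(tm), min_module_size = 10)
  eig <- module_eigengenes(sim$expr, modset)
  mt <- module_trait_table(eig, sim$design)
  expect_setequal(mt$module, modset$labels)
  expect_true("grey" %in% mt$module)
  expect_true(all(diff(abs(mt$statistic)) <= 1e-12))
  # the strongly shifted planted module is most significant
  expect_identical(mt$module[1], "turquoise")
  expect_true(all(mt$p_value >= 0 & mt$p_value <= 1))
  expect_true(all(abs(mt$statistic - mt$estimate / mt$se) < 1e-10))
})

test_that("gene significance: paired-t oracle, permutation null, affine invariance", {
  sim <- small_sim(seed = 13)
  gs <- gene_significance(sim$expr, sim$design)
  expect_identical(gs$gene_id, sort(rownames(sim$expr)))
  expect_equal(gs$gs, abs(gs$gs_signed), tolerance = 1e-15)
  expect_equal(max(gs$gs_scaled), 1, tolerance = 1e-12)

  # oracle: per-gene paired t
  for (g in gs$gene_id[1:10]) {
    y <- unclass(sim$expr)[g, ]
    tt <- t.test(y[sim$design$condition == 1], y[sim$design$condition == 0],
                 paired = TRUE)
    expect_equal(gs$gs_signed[gs$gene_id == g], unname(tt$statistic),
                 tolerance = 1e-8)
  }

  # permuting condition within pairs destroys the planted signal: averaged
  # over permutations, the strongly shifted module's mean GS falls to well
  # below its observed level (single permutations are noisy because module
  # genes share the latent score, hence the average over 10)
  sim2 <- simulate_paired(sim_config(
    n_pairs = 20L,
    modules = data.frame(size = c(40L, 30L), loading_mean = 0.9,
                         shift = c(1.5, 0.5)),
    n_noise_genes = 30L, seed = 13))
  gs2 <- gene_significance(sim2$expr, sim2$design)
  m1 <- names(sim2$truth$module)[sim2$truth$module == "turquoise"]
  planted_level <- mean(gs2$gs[gs2$gene_id %in% m1])
  set.seed(99)
  perm_level <- mean(vapply(1:10, function(i) {
    flip <- rep(sample(c(0, 1), 20, replace = TRUE), each = 2)
    pc <- ifelse(flip == 1, 1 - sim2$design$condition, sim2$design$condition)
    dp <- paired_design(sim2$design$sample_id, sim2$design$pair_id, pc)
    gsp <- gene_significance(sim2$expr, dp)
    mean(gsp$gs[gsp$gene_id %in% m1])
  }, numeric(1)))
  expect_lt(perm_level, 0.6 * planted_level)

  # per-gene affine rescaling leaves GS untouched
  scaled <- expression_matrix(unclass(sim$expr) * 3.7 + 11)
  gs_s <- gene_significance(scaled, sim$design)
  expect_equal(gs_s$gs, gs$gs, tolerance = 1e-8)
})

test_that("module significance is the mean GS with linearity over unions", {
  genestats <- data.frame(gene_id = paste0("g", 1:10),
                          gs = c(rep(2, 4), rep(5, 6)))
  ms_obj <- structure(list(
    assignment = setNames(c(rep("turquoise", 4), rep("blue", 6)), paste0("g", 1:10)),
    labels = c("turquoise", "blue"),
    sizes = c(turquoise = 4, blue = 6)), class = "ModuleSet")
  ms <- module_significance(genestats, ms_obj)
  expect_equal(ms$ms[ms$module == "turquoise"], 2)
  expect_equal(ms$ms[ms$module == "blue"], 5)
  # union = size-weighted mean
  union_ms <- (4 * 2 + 6 * 5) / 10
  ms_union <- structure(list(
    assignment = setNames(rep("turquoise", 10), paste0("g", 1:10)),
    labels = "turquoise", sizes = c(turquoise = 10)), class = "ModuleSet")
  expect_equal(module_significance(genestats, ms_union)$ms, union_ms)
  expect_error(module_significance(genestats[-1, ], ms_obj), "without GS")

  # planted associated module ranks first on simulated data
  sim <- small_sim(seed = 14)
  tm <- tom(adjacency(similarity(sim$expr), 6))
  modset <- cut_tree(cluster_genes(tm), min_module_size = 10)
  msx <- module_significance(gene_significance(sim$expr, sim$design), modset)
  expect_identical(msx$module[1], "turquoise")
})

test_that("MM-GS table: exact linear case and planted-module correlation", {
  sim <- small_sim(seed = 15)
  tm <- tom(adjacency(similarity(sim$expr), 6))
  modset <- cut_tree(cluster_genes(tm), min_module_size = 10)
  eig <- module_eigengenes(sim$expr, modset)
  gs <- gene_significance(sim$expr, sim$design)
  mmgs <- mm_gs_scatter_table(gs, modset, eig, sim$expr)
  expect_setequal(unique(mmgs$table$module), modset$labels)
  # strongly associated planted module: |MM| and GS substantially correlated
  expect_gt(mmgs$cor[["turquoise"]], 0.5)

  # gs an exact linear function of |MM| -> correlation 1
  fake <- gs
  mm_map <- setNames(mmgs$table$abs_mm, paste(mmgs$table$module, mmgs$table$gene_id))
  tq <- module_genes(modset, "turquoise")
  fake$gs[match(tq, fake$gene_id)] <- 2 * mm_map[paste("turquoise", tq)] + 1
  mmgs2 <- mm_gs_scatter_table(fake, modset, eig, sim$expr)
  expect_equal(mmgs2$cor[["turquoise"]], 1, tolerance = 1e-12)

  # gene-order permutation leaves per-module correlations unchanged
  perm <- sample(nrow(sim$expr))
  expr_p <- expression_matrix(unclass(sim$expr)[perm, ])
  mmgs3 <- mm_gs_scatter_table(gs, modset, eig, expr_p)
  expect_equal(mmgs3$cor[names(mmgs$cor)], mmgs$cor, tolerance = 1e-10)
})

test_that("type-I error is controlled under the null generator (small check)", {
  # small companion to the acceptance-scale run: 300 null genes
  p <- numeric(0)
  for (s in 1:3) {
    sim <- simulate_paired(sim_config(
      n_pairs = 15L,
      modules = data.frame(size = integer(0), loading_mean = numeric(0),
                           shift = numeric(0)),
      n_noise_genes = 100L, seed = 400 + s))
    p <- c(p, gene_significance(sim$expr, sim$design)$p_value)
  }
  rate <- mean(p < 0.05)
  expect_gte(rate, 0.02)
  expect_lte(rate, 0.09)
})
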