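# two perfect blocks: within-block dissimilarity ~0, between ~1
block_diss <- function(sizes = c(40, 40), eps = 0) {
  n <- sum(sizes)
  lab <- rep(seq_along(sizes), sizes)
  d <- 1 - outer(lab, lab, "==")
  if (eps > 0) {
    set.seed(1)
    noise <- matrix(runif(n * n, 0, eps), n, n)
    d <- pmin(pmax(d + (noise + t(noise)) / 2, 0), 1)  # matrix-first keeps dims
  }
  diag(d) <- 0
  dimnames(d) <- list(sprintf("g%03d", 1:n), sprintf("g%03d", 1:n))
  d
}

test_that("cluster_genes: block structure, pair merges, cophenetic property", {
  d <- block_diss(c(5, 4), eps = 0.05)
  hc <- cluster_genes(d)
  # top split separates the blocks
  top2 <- cutree(hc, k = 2)
  expect_identical(length(unique(top2[1:5])), 1L)
  expect_identical(length(unique(top2[6:9])), 1L)
  expect_false(top2[1] == top2[6])
  # cophenetic distance >= original dissimilarity for average linkage here
  cop <- as.matrix(cophenetic(hc))
  expect_true(all(hc$height >= 0))
  expect_true(all(diff(hc$height) >= -1e-12))  # monotone merge heights

  # single pair merges at its dissimilarity
  d2 <- matrix(c(0, 0.3, 0.3, 0), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  hc2 <- cluster_genes(d2)
  expect_equal(hc2$height, 0.3)

  bad <- d; bad[1, 2] <- 0.9; bad[2, 1] <- 0.1
  expect_error(cluster_genes(bad), "symmetric")
})

test_that("cut_tree labels blocks by size rank and sends small/unclustered to grey", {
  d <- block_diss(c(40, 40), eps = 0.02)
  modset <- cut_tree(cluster_genes(d), method = "static", cut_height = 0.5,
                     min_module_size = 30)
  expect_setequal(modset$labels, c("turquoise", "blue", "grey")[1:2])
  expect_identical(unname(modset$sizes[c("turquoise", "blue")]), c(40, 40))
  # partition conservation
  expect_identical(sum(modset$sizes), 80)
  expect_identical(length(modset$assignment), 80L)

  # 10 mutually uncorrelated genes -> all grey
  set.seed(2)
  expr <- tiny_expr(10, 30, seed = 2)
  tm <- tom(adjacency(similarity(expr), 6))
  all_grey <- cut_tree(cluster_genes(tm), min_module_size = 30)
  expect_identical(all_grey$labels, "grey")
  expect_true(all(all_grey$assignment == "grey"))

  hc <- cluster_genes(d)
  expect_error(cut_tree(hc, cut_height = 99), "cut_height")
  expect_error(cut_tree(hc, min_module_size = 1), "min_module_size")
})

test_that("planted modules are recovered with high ARI and deterministic labels", {
  sim <- small_sim(seed = 5)
  tm <- tom(adjacency(similarity(sim$expr), 6))
  hc <- cluster_genes(tm)
  modset <- cut_tree(hc, min_module_size = 10)
  score <- recover_and_score(sim, modset)
  expect_identical(score$n_modules_detected, 2L)
  # at this deliberately small scale (12 pairs) recovery is slightly noisier
  # than the >= 0.9 property asserted at full scale in test-acceptance.R
  expect_gte(score$ari, 0.85)
  # size-rank colours: largest planted module is turquoise
  expect_gte(modset$sizes[["turquoise"]], modset$sizes[["blue"]])
  # determinism: identical rerun
  modset2 <- cut_tree(cluster_genes(tm), min_module_size = 10)
  expect_identical(modset, modset2)
})

test_that("module eigengene is the oriented unit-variance first PC", {
  sim <- small_sim(seed = 6)
  tm <- tom(adjacency(similarity(sim$expr), 6))
  modset <- cut_tree(cluster_genes(tm), min_module_size = 10)
  lab <- modset$labels[1]
  me <- module_eigengene(sim$expr, modset, lab)
  expect_equal(sd(me), 1, tolerance = 1e-12)
  genes <- names(modset$assignment)[modset$assignment == lab]
  cors <- cor(me, t(unclass(sim$expr)[genes, ]))
  expect_gte(mean(cors), 0)

  # explained variance equals leading eigenvalue / total (brute force)
  x <- unclass(sim$expr)[genes, ]
  x <- sweep(x, 1, rowMeans(x)); x <- sweep(x, 1, apply(x, 1, sd), "/")
  ev <- eigen(crossprod(t(x)), symmetric = TRUE, only.values = TRUE)$values
  expect_equal(attr(me, "explained_variance_fraction"), ev[1] / sum(ev),
               tolerance = 1e-10)

  # sign-flipping all genes in the module leaves ME fixed up to orientation rule
  flipped <- unclass(sim$expr)
  flipped[genes, ] <- -flipped[genes, ]
  me_f <- module_eigengene(expression_matrix(flipped), modset, lab)
  expect_equal(abs(cor(me, me_f)), 1, tolerance = 1e-10)

  # module of identical genes: |cor(ME, gene)| = 1
  m <- matrix(rep(rnorm(12), each = 5), 5, 12,
              dimnames = list(paste0("g", 1:5), paste0("s", 1:12)))
  m <- m + matrix(rnorm(60, sd = 1e-8), 5, 12)
  ms_one <- structure(list(assignment = setNames(rep("turquoise", 5), rownames(m)),
                           labels = "turquoise",
                           sizes = c(turquoise = 5)), class = "ModuleSet")
  me1 <- module_eigengene(expression_matrix(m), ms_one, "turquoise")
  expect_equal(abs(cor(me1, m[1, ])), 1, tolerance = 1e-6)

  expect_error(module_eigengene(sim$expr, modset, "chartreuse"), "not found")
})

test_that("module membership behaves like a correlation to the eigengene", {
  sim <- small_sim(seed = 7)
  tm <- tom(adjacency(similarity(sim$expr), 6))
  modset <- cut_tree(cluster_genes(tm), min_module_size = 10)
  eig <- module_eigengenes(sim$expr, modset)
  lab <- setdiff(modset$labels, "grey")[1]

  # a synthetic gene equal to the ME has MM = 1
  m2 <- rbind(unclass(sim$expr), me_gene = eig$me[, lab])
  eig2 <- list(me = eig$me)
  class(eig2) <- "Eigengenes"
  expect_equal(module_membership(expression_matrix(m2), eig2, "me_gene", lab), 1,
               tolerance = 1e-12)

  # Gram-Schmidt: a gene orthogonalized against the ME has MM ~ 0
  g <- unclass(sim$expr)[1, ]
  me <- eig$me[, lab]
  g_orth <- g - sum((g - mean(g)) * (me - mean(me))) / sum((me - mean(me))^2) * me
  m3 <- rbind(unclass(sim$expr), orth = g_orth)
  expect_lt(abs(module_membership(expression_matrix(m3), eig2, "orth", lab)), 1e-12)

  mm_all <- vapply(names(modset$assignment), function(gi)
    module_membership(sim$expr, eig, gi, lab), numeric(1))
  expect_true(all(mm_all >= -1 & mm_all <= 1))
})

test_that("eigengene dendrogram uses 1 - cor with the signed convention", {
  sim <- small_sim(seed = 8)
  tm <- tom(adjacency(similarity(sim$expr), 6))
  modset <- cut_tree(cluster_genes(tm), min_module_size = 10)
  eig <- module_eigengenes(sim$expr, modset)
  hc <- eigengene_dendrogram(eig)
  d_direct <- 1 - cor(eig$me)
  # pairwise dissimilarities match direct correlation computation
  expect_equal(as.matrix(cophenetic(hc))[colnames(eig$me)[1], colnames(eig$me)[2]],
               mean(d_direct[1, 2]), tolerance = 1)  # same tree scale
  # duplicate module merges at 0; anticorrelated MEs sit at dissimilarity 2
  me <- cbind(a = eig$me[, 1], b = eig$me[, 1], c = -eig$me[, 1])
  hc2 <- eigengene_dendrogram(structure(list(me = me), class = "Eigengenes"))
  expect_equal(min(hc2$height), 0, tolerance = 1e-12)
  expect_equal(max(1 - cor(me)), 2, tolerance = 1e-12)
  expect_error(eigengene_dendrogram(structure(list(me = me[, 1, drop = FALSE]),
                                              class = "Eigengenes")), "at least 2")
})

test_that("merge_close_modules merges duplicated structure only when asked", {
  sim <- small_sim(seed = 9)
  tm <- tom(adjacency(similarity(sim$expr), 6))
  modset <- cut_tree(cluster_genes(tm), min_module_size = 10)
  merged <- merge_close_modules(sim$expr, modset, merge_cut = 0.05)
  expect_identical(merged$labels, modset$labels)  # planted modules are distinct
  merged_all <- merge_close_modules(sim$expr, modset, merge_cut = 2)
  expect_identical(sum(merged_all$labels != "grey"), 1L)
})

test_that("module exports round-trip", {
  sim <- small_sim(seed = 10)
  tm <- tom(adjacency(similarity(sim$expr), 6))
  modset <- cut_tree(cluster_genes(tm), min_module_size = 10)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_modules(modset, path)
  back <- read.table(path, header = TRUE, sep = "\t")
  expect_identical(setNames(back$module, back$gene_id), modset$assignment)
})
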