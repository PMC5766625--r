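# Shared fixtures and independent oracles. Oracles are deliberately naive
# (loops, direct formulas) and never call the implementation they check.

tiny_expr <- function(n_genes = 5, n_samples = 8, seed = 1) {
  set.seed(seed)
  expression_matrix(matrix(rnorm(n_genes * n_samples), n_genes, n_samples,
                           dimnames = list(paste0("g", seq_len(n_genes)),
                                           paste0("s", seq_len(n_samples)))))
}

tiny_design <- function(n_pairs = 4, covariates = FALSE, seed = 1) {
  set.seed(seed)
  covs <- if (covariates)
    data.frame(age = rep(round(runif(n_pairs, 40, 75)), each = 2),
               stage = rep(sample(1:4, n_pairs, TRUE), each = 2))
  paired_design(sample_id = paste0("s", seq_len(2 * n_pairs)),
                pair_id = rep(paste0("p", seq_len(n_pairs)), each = 2),
                condition = rep(c(0, 1), n_pairs),
                covariates = covs)
}

# small simulation used across tests: 12 pairs, two planted modules + noise
small_sim <- function(seed = 3, shifts = c(1.5, 0.5)) {
  simulate_paired(sim_config(
    n_pairs = 12L,
    modules = data.frame(size = c(40L, 30L), loading_mean = 0.9,
                         shift = shifts),
    n_noise_genes = 30L, seed = seed))
}

# brute-force unsigned TOM, triple loop
tom_brute <- function(a) {
  n <- nrow(a)
  out <- matrix(1, n, n)
  k <- rowSums(a)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    shared <- 0
    for (u in seq_len(n)) if (u != i && u != j) shared <- shared + a[i, u] * a[u, j]
    out[i, j] <- (shared + a[i, j]) / (min(k[i], k[j]) + 1 - a[i, j])
  }
  out
}

# brute-force absolute Pearson correlation via covariance/SD quotient loops
abs_cor_brute <- function(x) {
  n <- nrow(x)
  out <- diag(n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i >= j) next
    xi <- x[i, ]; xj <- x[j, ]
    cov_ij <- sum((xi - mean(xi)) * (xj - mean(xj))) / (length(xi) - 1)
    r <- cov_ij / (sd(xi) * sd(xj))
    out[i, j] <- out[j, i] <- abs(r)
  }
  out
}

# Monte-Carlo mixture correlation: Z_i = (1-theta) X_i + theta Y_i
mixture_mc <- function(p, cov_x, cov_y, var_x1, var_x2, var_y1, var_y2,
                       delta1, delta2, n = 1e6, seed = 1) {
  set.seed(seed)
  rbvn <- function(v1, v2, cv, m1 = 0, m2 = 0) {
    z1 <- rnorm(n); z2 <- rnorm(n)
    x1 <- sqrt(v1) * z1
    rho <- cv / sqrt(v1 * v2)
    x2 <- sqrt(v2) * (rho * z1 + sqrt(1 - rho^2) * z2)
    cbind(m1 + x1, m2 + x2)
  }
  X <- rbvn(var_x1, var_x2, cov_x)
  Y <- rbvn(var_y1, var_y2, cov_y, delta1, delta2)
  th <- rbinom(n, 1, p)
  z1 <- (1 - th) * X[, 1] + th * Y[, 1]
  z2 <- (1 - th) * X[, 2] + th * Y[, 2]
  r <- cor(z1, z2)
  list(r = r, se = (1 - r^2) / sqrt(n))
}

random_mixture_params <- function() {
  v <- runif(4, 0.5, 2)
  rho_x <- runif(1, -0.8, 0.8); rho_y <- runif(1, -0.8, 0.8)
  list(p = runif(1, 0.1, 0.9),
       cov_x = rho_x * sqrt(v[1] * v[2]), cov_y = rho_y * sqrt(v[3] * v[4]),
       var_x1 = v[1], var_x2 = v[2], var_y1 = v[3], var_y2 = v[4],
       delta1 = runif(1, -1, 1), delta2 = runif(1, -1, 1))
}

# independent scale-free fit oracle: equal-width binning + lm on log10/log10
scale_free_oracle <- function(s, beta, n_bins = 10) {
  a <- s^beta; diag(a) <- 0
  k <- rowSums(a)
  br <- seq(min(k), max(k), length.out = n_bins + 1)
  idx <- findInterval(k, br, rightmost.closed = TRUE, all.inside = TRUE)
  mk <- tapply(k, idx, mean); fr <- as.numeric(table(idx)) / length(k)
  keep <- fr > 0 & mk > 0
  fit <- lm(log10(fr[keep]) ~ log10(mk[keep]))
  summary(fit)$r.squared * -sign(coef(fit)[2])
}

# similarity matrix carrying a preferential-attachment degree structure:
# graph edges get strong weights, non-edges weak background
pa_similarity <- function(n = 800, m = 3, seed = 5) {
  set.seed(seed)
  g <- igraph::sample_pa(n, power = 1, m = m, directed = FALSE)
  A <- as.matrix(igraph::as_adjacency_matrix(g))
  s <- matrix(runif(n * n, 0, 0.3), n, n)
  s[A == 1] <- runif(sum(A == 1), 0.5, 0.95)
  s <- (s + t(s)) / 2
  diag(s) <- 1
  dimnames(s) <- list(paste0("g", seq_len(n)), paste0("g", seq_len(n)))
  structure(list(gene_ids = rownames(s), s = s), class = "SimilarityMatrix")
}

geo_fixture_lines <- function() {
  c('!Series_title\t"paired miRNA arrays, synthetic fixture"',
    '!Series_geo_accession\t"GSEsynthetic"',
    '!Sample_title\t"tumour 1"\t"normal 1"',
    '!Sample_geo_accession\t"GSM0001"\t"GSM0002"',
    "!series_matrix_table_begin",
    paste("\"ID_REF\"", "\"GSM0001\"", "\"GSM0002\"", sep = "\t"),
    paste('"miR-0001"', "7.25", "6.5", sep = "\t"),
    paste('"miR-0002"', "5.125", "5.75", sep = "\t"),
    "!series_matrix_table_end")
}
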