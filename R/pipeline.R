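#' Build a pipeline run configuration
#'
#' Every parameter has a documented default; a JSON file with the same keys
#' can be loaded with [read_run_config()], and CLI flags override config
#' keys. Paths are validated before any computation.
#'
#' @param expression_path path to the expression TSV (genes in rows).
#' @param design_path path to the paired design TSV.
#' @param out_dir output directory for all artifacts.
#' @param orientation expression file orientation, see [read_expression()].
#' @param z_cut outlier z-score cut, see [flag_outlier_samples()]; `Inf`
#'   disables exclusion.
#' @param beta fixed soft threshold; `NULL` (default) selects it by
#'   [scale_free_scan()].
#' @param beta_grid powers scanned when `beta` is `NULL`.
#' @param n_bins connectivity bins for the scan.
#' @param cut_method,cut_height,min_module_size see [cut_tree()].
#' @param merge_cut eigengene merge threshold; `NULL` (default) skips merging.
#' @param covariates subject-level covariates for the association stage.
#' @param edge_weight `"tom"` or `"adjacency"` for hub edges.
#' @param edge_threshold dichotomization threshold for hub edges.
#' @param seed integer seed (recorded; the pipeline itself is deterministic).
#' @return A list of class `RunConfig`.
#' @export
run_config <- function(expression_path, design_path, out_dir,
                       orientation = "genes-in-rows", z_cut = 2.5,
                       beta = NULL, beta_grid = 1:20, n_bins = 10L,
                       cut_method = "hybrid", cut_height = NULL,
                       min_module_size = 30L, merge_cut = NULL,
                       covariates = character(0),
                       edge_weight = "tom", edge_threshold = 0.1,
                       seed = 1L) {
  cfg <- list(expression_path = expression_path, design_path = design_path,
              out_dir = out_dir, orientation = orientation,
              z_cut = as.numeric(z_cut),
              beta = if (!is.null(beta)) as.integer(beta),
              beta_grid = as.integer(beta_grid), n_bins = as.integer(n_bins),
              cut_method = cut_method,
              cut_height = if (!is.null(cut_height)) as.numeric(cut_height),
              min_module_size = as.integer(min_module_size),
              merge_cut = if (!is.null(merge_cut)) as.numeric(merge_cut),
              covariates = as.character(covariates), edge_weight = edge_weight,
              edge_threshold = as.numeric(edge_threshold),
              seed = as.integer(seed))
  validate_run_config(cfg)
  structure(cfg, class = "RunConfig")
}

validate_run_config <- function(cfg) {
  for (p in c("expression_path", "design_path")) {
    if (is.null(cfg[[p]]) || !nzchar(cfg[[p]]))
      stop("run config missing required path: ", p)
    if (!file.exists(cfg[[p]])) stop(p, " does not exist: ", cfg[[p]])
  }
  if (!cfg$edge_weight %in% c("tom", "adjacency"))
    stop("edge_weight must be 'tom' or 'adjacency'")
  invisible(cfg)
}

#' Load a run configuration from JSON
#'
#' @param path JSON file whose keys match [run_config()] arguments.
#' @param overrides named list of values taking precedence over the file.
#' @return A `RunConfig`.
#' @export
read_run_config <- function(path, overrides = list()) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  raw[names(overrides)] <- overrides
  do.call(run_config, raw)
}

pipeline_log <- function(con, ...) {
  msg <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), paste0(...))
  message(msg)
  if (!is.null(con)) writeLines(msg, con)
}

#' Run the full paired co-expression pipeline
#'
#' Stages, in order: read inputs, sample QC with pair-consistent exclusion,
#' similarity and soft-threshold scan, adjacency and TOM, gene clustering and
#' module detection, eigengenes, mixed-model module-trait and per-gene
#' association, module significance, MM-GS tables, hub detection, and edge
#' exports. Every intermediate table is persisted under `out_dir`, and a
#' machine-readable `summary.json` records module sizes, the chosen power and
#' its fit, per-module statistics, and hubs. A stage failure aborts with the
#' stage name; artifacts already written are kept.
#'
#' @param config a [run_config()] (or path to a JSON config).
#' @return The summary list, invisibly; also written as `summary.json`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  validate_run_config(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  logf <- file(file.path(config$out_dir, "run.log"), open = "wt")
  on.exit(close(logf))
  set.seed(config$seed)
  pipeline_log(logf, "paircoex ", as.character(utils::packageVersion("paircoex")),
               " | R ", getRversion(), " | seed ", config$seed)
  pipeline_log(logf, "config: ", jsonlite::toJSON(unclass(config),
                                                  auto_unbox = TRUE, null = "null"))
  stage <- function(name, fun) {
    pipeline_log(logf, "stage: ", name)
    tryCatch(fun(), error = function(e)
      stop("pipeline failed at stage '", name, "': ", conditionMessage(e),
           call. = FALSE))
  }

  io <- stage("read_inputs", function() {
    expr <- drop_incomplete_genes(
      read_expression(config$expression_path, config$orientation))
    design <- read_design(config$design_path)
    align_design(expr, design)
  })
  qc <- stage("qc", function() {
    res <- run_qc(io$expr, io$design, z_cut = config$z_cut)
    utils::write.table(
      data.frame(sample_id = rownames(res$report$pc_scores), res$report$pc_scores),
      file.path(config$out_dir, "pc_scores.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    writeLines(res$report$flagged_samples,
               file.path(config$out_dir, "flagged_samples.txt"))
    writeLines(hclust_to_newick(res$report$sample_tree),
               file.path(config$out_dir, "sample_tree.newick"))
    res
  })
  net <- stage("network", function() {
    sim <- similarity(qc$expr)
    scan <- NULL
    beta <- config$beta
    if (is.null(beta)) {
      scan <- scale_free_scan(sim, config$beta_grid, config$n_bins)
      write_scan(scan, file.path(config$out_dir, "scale_free_scan.tsv"))
      beta <- scan$chosen_beta
    }
    adj <- adjacency(sim, beta)
    list(sim = sim, scan = scan, adj = adj, tomm = tom(adj))
  })
  mods <- stage("modules", function() {
    hc <- cluster_genes(net$tomm)
    modset <- cut_tree(hc, config$cut_method, config$cut_height,
                       config$min_module_size)
    if (!is.null(config$merge_cut))
      modset <- merge_close_modules(qc$expr, modset, config$merge_cut)
    write_modules(modset, file.path(config$out_dir, "modules.tsv"))
    eig <- module_eigengenes(qc$expr, modset)
    write_eigengenes(eig, file.path(config$out_dir, "eigengenes.tsv"))
    list(modset = modset, eig = eig)
  })
  assoc <- stage("association", function() {
    mt <- module_trait_table(mods$eig, qc$design, config$covariates)
    utils::write.table(mt, file.path(config$out_dir, "module_trait.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    gstats <- gene_significance(qc$expr, qc$design, config$covariates)
    ms <- module_significance(gstats, mods$modset)
    utils::write.table(ms, file.path(config$out_dir, "module_significance.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    mmgs <- mm_gs_scatter_table(gstats, mods$modset, mods$eig, qc$expr)
    utils::write.table(mmgs$table, file.path(config$out_dir, "mm_gs.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    gstats$module <- mods$modset$assignment[gstats$gene_id]
    mm <- stats::setNames(mmgs$table$mm,
                          paste(mmgs$table$module, mmgs$table$gene_id))
    gstats$mm <- mm[paste(gstats$module, gstats$gene_id)]
    utils::write.table(
      gstats[, c("gene_id", "module", "estimate", "gs_signed", "gs",
                 "gs_scaled", "mm", "p_value", "fdr")],
      file.path(config$out_dir, "gene_stats.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    list(mt = mt, gstats = gstats, ms = ms, mmgs = mmgs)
  })
  hubs <- stage("hubs", function() {
    labs <- setdiff(mods$modset$labels, "grey")
    net_obj <- if (config$edge_weight == "tom") net$tomm else net$adj
    out <- list()
    for (l in labs) {
      el <- build_edges(net_obj, mods$modset, l, config$edge_threshold)
      write_sif(el, file.path(config$out_dir, paste0("edges_", l, ".sif")))
      write_edges(el, file.path(config$out_dir, paste0("edges_", l, ".tsv")))
      out[[l]] <- if (nrow(el$edges)) {
        h <- hub(el)
        list(hub = as.character(h), degree = attr(h, "degree"),
             n_edges = nrow(el$edges))
      } else list(hub = NA_character_, degree = 0L, n_edges = 0L)
    }
    out
  })

  summary <- list(
    n_genes = nrow(qc$expr), n_samples = ncol(qc$expr),
    flagged_samples = qc$report$flagged_samples,
    excluded_pairs = qc$report$excluded_pairs,
    chosen_beta = net$adj$beta,
    scale_free_r2 = if (!is.null(net$scan))
      net$scan$r2[match(net$scan$chosen_beta, net$scan$beta_grid)] else NA,
    module_sizes = as.list(mods$modset$sizes),
    module_trait = assoc$mt[, c("module", "estimate", "statistic", "df",
                                "p_value", "fdr")],
    module_significance = assoc$ms,
    hubs = hubs,
    seed = config$seed)
  jsonlite::write_json(summary, file.path(config$out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = 10, dataframe = "rows",
                       na = "null")
  pipeline_log(logf, "done: ", sum(mods$modset$labels != "grey"),
               " modules, beta = ", net$adj$beta)
  invisible(summary)
}
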