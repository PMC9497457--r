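#' Default pipeline configuration
#'
#' Returns the nested configuration list the pipeline runner expects,
#' emulating the merged five-batch case/control study design end to end.
#' Every block can be overridden; \code{run_pipeline} validates that all
#' required blocks are present.
#'
#' @param seed Global seed recorded in the config.
#' @return Nested named list with blocks \code{simulate},
#'   \code{preprocess}, \code{diagnose}, \code{cluster}, \code{enrich},
#'   \code{lncrna}, \code{modules}, \code{score}.
#' @export
default_pipeline_config <- function(seed = 42L) {
  list(
    simulate = list(seed = seed),     # remaining knobs: simulation_config()
    preprocess = list(),
    diagnose = list(alpha = 0.05, n_folds = 10L),
    cluster = list(K_range = 2:6, n_reps = 1000L, p_item = 0.8),
    enrich = list(run_gsva = TRUE),
    lncrna = list(r_thresh = 0.4, p_thresh = 0.001),
    modules = list(top_variance_frac = 0.25, min_module_size = 30L),
    score = list(rule = "median", lfc_cutoff = 1, alpha = 0.05)
  )
}

#' Run the full analysis pipeline
#'
#' Orchestrates the stages in dependency order on a synthetic cohort:
#' simulate, batch-correct, build and validate the regulator diagnostic
#' model, consensus-cluster the cases into patterns, score the immune
#' microenvironment (ssGSEA, optionally GSVA), select regulator-related
#' lncRNAs and cluster on their overlap, detect co-expression modules,
#' compute the per-sample methylation score, and cross-tabulate all
#' derived labels. Every stage's outputs are written under \code{outdir}
#' as TSV/GMT/JSON and a run manifest with input/output checksums is
#' returned and written.
#'
#' @param config Path to a YAML config or a nested list as produced by
#'   \code{\link{default_pipeline_config}}.
#' @param outdir Output directory (created if needed).
#' @param seed Optional override of the simulation seed.
#' @return The run manifest (invisibly also written to
#'   \code{manifest.json}).
#' @export
run_pipeline <- function(config = default_pipeline_config(), outdir, seed = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  required <- c("simulate", "diagnose", "cluster", "enrich", "lncrna",
                "modules", "score")
  missing <- setdiff(required, names(config))
  if (length(missing))
    stop("config is missing required block(s): ", paste(missing, collapse = ", "))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(seed)) config$simulate$seed <- as.integer(seed)
  out <- function(f) file.path(outdir, f)
  written <- character(0)
  emit <- function(path) { written <<- c(written, path); path }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  # --- simulate ---------------------------------------------------------
  sim <- stage("simulate", {
    cfg <- do.call(simulation_config, config$simulate)
    cohort <- simulate_cohort(cfg)
    sets <- make_fixture_genesets(cfg, cohort$truth)
    write_expression(cohort$expression, emit(out("expression.tsv")))
    ann <- cohort$annotation
    names(ann)[names(ann) == "pattern"] <- "true_pattern"
    write_annotation(ann, emit(out("annotation.tsv")))
    jsonlite::write_json(cohort$truth[c("diagnostic_genes", "linked_lncrnas",
                                        "immune_up_sets")],
                         emit(out("truth.json")), auto_unbox = FALSE)
    write_gmt(sets, emit(out("genesets.gmt")))
    list(cfg = cfg, expr = cohort$expression, ann = ann,
         truth = cohort$truth, sets = sets)
  })
  ann <- sim$ann
  groups <- ann$group
  cases <- ann$sample_id[groups == "case"]

  # --- preprocess -------------------------------------------------------
  expr <- stage("preprocess", {
    e <- collapse_duplicate_genes(sim$expr)
    e <- if (sim$cfg$n_batches > 1L) correct_batches(e, ann) else e
    write_expression(e, emit(out("corrected_expression.tsv")))
    e
  })
  catalog6 <- regulator_catalog("m6A")
  regs <- intersect(catalog6$gene, rownames(expr))

  # --- diagnose ---------------------------------------------------------
  model <- stage("diagnose", {
    m <- build_diagnostic_model(expr, groups, regs,
                                alpha = config$diagnose$alpha %||% 0.05,
                                n_folds = config$diagnose$n_folds %||% 10L,
                                seed = sim$cfg$seed)
    vcfg_args <- config$simulate
    vcfg_args$seed <- sim$cfg$seed + 1000L
    vcohort <- simulate_cohort(do.call(simulation_config, vcfg_args))
    val <- validate_external(m, vcohort$expression, vcohort$annotation$group)
    jsonlite::write_json(list(features = m$features,
                              intercept = m$intercept,
                              coefficients = as.list(m$coefficients),
                              odds_ratios = m$odds_ratios,
                              auc = m$auc, auc_ci = m$auc_ci,
                              c_index = m$c_index,
                              validation_auc = val$auc,
                              validation_auc_ci = val$ci),
                         emit(out("diagnostic_model.json")),
                         auto_unbox = TRUE, digits = NA)
    m$validation <- val
    m
  })

  # --- cluster ----------------------------------------------------------
  cc <- stage("cluster", {
    res <- select_k_and_label(expr[regs, cases, drop = FALSE],
                              K_range = config$cluster$K_range %||% 2:6,
                              n_reps = config$cluster$n_reps %||% 1000L,
                              p_item = config$cluster$p_item %||% 0.8,
                              seed = sim$cfg$seed)
    ann$pattern <- res$labels[ann$sample_id]
    utils::write.table(data.frame(K = res$K_range, pac = unname(res$pac)),
                       emit(out("consensus_pac.tsv")), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    res
  })

  # --- enrich -----------------------------------------------------------
  enr <- stage("enrich", {
    ss <- ssgsea_scores(expr, sim$sets)
    write_scores(ss, emit(out("ssgsea_scores.tsv")))
    rep_cells <- group_difference_report(
      ss[, cases, drop = FALSE],
      ann$pattern[match(cases, ann$sample_id)], family = "immune_by_pattern")
    utils::write.table(rep_cells, emit(out("immune_differences.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    gs <- NULL
    if (isTRUE(config$enrich$run_gsva %||% TRUE)) {
      gs <- gsva_scores(expr, sim$sets)
      write_scores(gs, emit(out("gsva_scores.tsv")))
    }
    list(ssgsea = ss, gsva = gs, report = rep_cells)
  })

  # --- lncrna -----------------------------------------------------------
  lnc <- stage("lncrna", {
    rt <- config$lncrna$r_thresh %||% 0.4
    pt <- config$lncrna$p_thresh %||% 0.001
    cat5 <- regulator_catalog("m5C")
    l6 <- select_related_lncrnas(expr, sim$truth$lncrna_ids, catalog6, "m6A",
                                 r_thresh = rt, p_thresh = pt)
    l5 <- suppressWarnings(
      select_related_lncrnas(expr, sim$truth$lncrna_ids, cat5, "m5C",
                             r_thresh = rt, p_thresh = pt))
    both <- intersect_link_sets(l6, l5)
    utils::write.table(l6$links, emit(out("lncrna_links_m6a.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(l5$links, emit(out("lncrna_links_m5c.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    writeLines(both, emit(out("lncrna_overlap.txt")))
    cluster_ids <- if (length(both) >= 3L) both else l6$lncrnas
    lcc <- select_k_and_label(expr[cluster_ids, cases, drop = FALSE],
                              K_range = config$cluster$K_range %||% 2:6,
                              n_reps = config$cluster$n_reps %||% 1000L,
                              p_item = config$cluster$p_item %||% 0.8,
                              seed = sim$cfg$seed + 1L)
    ann$lncrna_cluster <- lcc$labels[ann$sample_id]
    lmodel <- tryCatch(
      build_diagnostic_model(expr, groups, l6$lncrnas,
                             n_folds = config$diagnose$n_folds %||% 10L,
                             seed = sim$cfg$seed),
      error = function(e) NULL)
    if (!is.null(lmodel))
      jsonlite::write_json(list(features = lmodel$features, auc = lmodel$auc,
                                auc_ci = lmodel$auc_ci),
                           emit(out("lncrna_model.json")),
                           auto_unbox = TRUE, digits = NA)
    list(m6a = l6, m5c = l5, overlap = both, clusters = lcc, model = lmodel)
  })

  # --- modules ----------------------------------------------------------
  mods <- stage("modules", {
    case_expr <- expr[, cases, drop = FALSE]
    pat <- ann$pattern[match(cases, ann$sample_id)]
    traits <- as.data.frame(lapply(sort(unique(pat)), function(p)
      as.numeric(pat == p)))
    names(traits) <- paste0("pattern_", sort(unique(pat)))
    ma <- detect_modules(case_expr, traits = traits,
                         top_variance_frac = config$modules$top_variance_frac %||% 0.25,
                         min_module_size = config$modules$min_module_size %||% 30L)
    utils::write.table(data.frame(gene = names(ma$modules), module = ma$modules),
                       emit(out("modules.tsv")), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    if (!is.null(ma$module_trait))
      utils::write.table(ma$module_trait, emit(out("module_trait.tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    ma
  })

  # --- score ------------------------------------------------------------
  sc <- stage("score", {
    pat <- ann$pattern[match(cases, ann$sample_id)]
    case_expr <- expr[, cases, drop = FALSE]
    pairs <- utils::combn(sort(unique(pat)), 2L, simplify = FALSE)
    pairs <- Filter(function(pr) all(table(pat[pat %in% pr]) >= 2L), pairs)
    degs <- unique(unlist(lapply(pairs, function(pr) {
      idx <- pat %in% pr
      tab <- moderated_t_deg(case_expr[, idx, drop = FALSE], pat[idx],
                             lfc_cutoff = config$score$lfc_cutoff %||% 1,
                             alpha = config$score$alpha %||% 0.05)
      tab$gene[tab$deg]
    })))
    sig <- if (length(degs) >= 2L) degs else regs
    tab <- compute_m6ascore(case_expr, sig)
    tab <- split_by_score(tab, rule = config$score$rule %||% "median")
    cmp <- compare_scores_across(pat, tab)
    ann$score_group <- tab$score_group[match(ann$sample_id, tab$sample_id)]
    utils::write.table(tab, emit(out("m6ascore.tsv")), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    ct <- crosstab_alluvial(ann[ann$group == "case", ])
    utils::write.table(ct, emit(out("score_crosstab.tsv")), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    list(n_pattern_genes = length(degs), score = tab, comparison = cmp,
         crosstab = ct)
  })

  write_annotation(ann, emit(out("annotation_derived.tsv")))

  cfg_path <- out("config.yaml")
  yaml::write_yaml(config, cfg_path)
  manifest <- list(
    package_version = as.character(utils::packageVersion("m6aPatterns")),
    config_hash = unname(tools::md5sum(cfg_path)),
    seed = sim$cfg$seed,
    timestamp = format(Sys.time(), tz = "UTC"),
    outputs = as.list(tools::md5sum(sort(unique(written)))))
  names(manifest$outputs) <- basename(names(manifest$outputs))
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE)
  invisible(list(manifest = manifest, model = model, clustering = cc,
                 enrichment = enr, lncrna = lnc, modules = mods, score = sc,
                 annotation = ann))
}

write_scores <- function(scores, path) {
  df <- data.frame(set = rownames(scores), scores, check.names = FALSE,
                   row.names = NULL)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
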