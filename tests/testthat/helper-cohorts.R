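# Shared small-cohort fixtures, built in code at load time.

small_config <- function(seed = 7L, ...) {
  defaults <- list(n_cases = 90L, n_controls = 60L, n_batches = 3L,
                   n_genes = 600L, n_lncrnas = 60L, seed = seed)
  args <- utils::modifyList(defaults, list(...))
  do.call(simulation_config, args)
}

# one cohort reused across read-only tests
.shared <- local({
  cfg <- small_config()
  cohort <- simulate_cohort(cfg)
  sets <- make_fixture_genesets(cfg, cohort$truth)
  corrected <- suppressWarnings(correct_batches(cohort$expression,
                                                cohort$annotation))
  list(cfg = cfg, cohort = cohort, sets = sets, corrected = corrected,
       cases = cohort$annotation$sample_id[cohort$annotation$group == "case"],
       regs = intersect(regulator_catalog("m6A")$gene,
                        rownames(cohort$expression)))
})

# adjusted Rand index between two labelings (wrapper kept local to tests)
ari <- function(a, b) mclust::adjustedRandIndex(a, b)
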