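test_that("config validation names the violated field", {
  expect_error(simulation_config(n_cases = 0), "n_cases")
  expect_error(simulation_config(n_patterns = 1), "n_patterns")
  expect_error(simulation_config(n_genes = 50, n_regulators = 26,
                                 n_lncrnas = 40), "n_lncrnas|n_genes")
  expect_error(simulation_config(lncrna_link_r = 1), "lncrna_link_r")
  expect_error(simulation_config(n_diagnostic = 30), "n_diagnostic")
  expect_error(simulation_config(noise_sd = 0), "noise_sd")
})

test_that("the generator is bit-reproducible given the seed", {
  cfg <- small_config(seed = 3)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$expression, b$expression)
  expect_identical(a$annotation, b$annotation)
  expect_identical(a$truth, b$truth)
  c2 <- simulate_cohort(small_config(seed = 4))
  expect_false(identical(a$expression, c2$expression))
})

test_that("ground truth is structurally consistent", {
  co <- .shared$cohort
  tr <- co$truth
  cases <- .shared$cases
  expect_setequal(names(tr$pattern_of_sample), cases)
  expect_length(intersect(names(tr$linked_lncrnas), tr$diagnostic_genes), 0)
  expect_true(all(tr$linked_lncrnas %in% rownames(co$expression)))
  expect_true(all(names(tr$linked_lncrnas) %in% tr$lncrna_ids))
  expect_equal(dim(co$expression),
               c(.shared$cfg$n_genes, .shared$cfg$n_cases + .shared$cfg$n_controls))
})

test_that("a null configuration plants no case/control signal", {
  cfg <- small_config(seed = 11, case_effect = 0, pattern_effect = 0,
                      batch_shift_sd = 0, batch_scale_sd = 0)
  co <- simulate_cohort(cfg)
  grp <- co$annotation$group
  regs <- intersect(regulator_catalog("m6A")$gene, rownames(co$expression))
  p <- vapply(regs, function(g)
    wilcoxon_rank_sum(co$expression[g, grp == "case"],
                      co$expression[g, grp == "control"])$p_value, 0)
  expect_gt(min(p), 1e-4)                 # no real effect anywhere
  expect_lte(sum(p < 0.05), 5)            # ~5% of 26 by chance
  # genome-wide p-values look uniform
  pall <- apply(co$expression, 1L, function(v)
    wilcoxon_rank_sum(v[grp == "case"], v[grp == "control"])$p_value)
  expect_gt(stats::ks.test(pall, "punif")$p.value, 0.001)
})

test_that("planted case effect is recovered within 3 SE", {
  co <- .shared$cohort
  grp <- co$annotation$group
  for (g in co$truth$diagnostic_genes) {
    x <- .shared$corrected[g, grp == "case"]
    y <- .shared$corrected[g, grp == "control"]
    d <- mean(x) - mean(y)
    se <- sqrt(stats::var(x) / length(x) + stats::var(y) / length(y))
    expect_lt(abs(d - .shared$cfg$case_effect), 3 * se)
  }
})

test_that("k-means on regulator rows recovers the planted patterns", {
  cfg <- small_config(seed = 21, n_patterns = 3, pattern_effect = 2,
                      noise_sd = 0.5, n_cases = 90)
  co <- simulate_cohort(cfg)
  cb <- suppressWarnings(correct_batches(co$expression, co$annotation))
  cases <- co$annotation$sample_id[co$annotation$group == "case"]
  regs <- intersect(regulator_catalog("m6A")$gene, rownames(cb))
  set.seed(1)
  km <- stats::kmeans(t(cb[regs, cases]), centers = 3, nstart = 10)
  expect_gt(ari(km$cluster, co$truth$pattern_of_sample[cases]), 0.9)
  # oracle: nearest planted-centroid assignment agrees with truth
  centroids <- sapply(sort(unique(co$truth$pattern_of_sample)), function(p)
    rowMeans(cb[regs, names(co$truth$pattern_of_sample)[
      co$truth$pattern_of_sample == p], drop = FALSE]))
  near <- colnames(centroids)[apply(cb[regs, cases], 2L, function(v)
    which.min(colSums((centroids - v)^2)))]
  expect_gt(ari(near, co$truth$pattern_of_sample[cases]), 0.95)
})

test_that("fixture gene sets have the expected structure", {
  sets <- .shared$sets
  expect_length(sets, 23 + 17)
  expect_true(all(lengths(sets) > 0))
  expect_false(anyDuplicated(names(sets)) > 0)
  # planted up-sets draw from their pattern's elevated block
  tr <- .shared$cohort$truth
  for (p in names(tr$immune_up_sets)) {
    for (nm in tr$immune_up_sets[[p]]) {
      expect_gt(length(intersect(sets[[nm]], tr$immune_block_genes[[p]])), 10)
    }
  }
  # unplanted sets avoid all elevated blocks
  unplanted <- setdiff(names(sets), unlist(tr$immune_up_sets))
  blocked <- unlist(tr$immune_block_genes)
  for (nm in unplanted) expect_length(intersect(sets[[nm]], blocked), 0)
})

test_that("pattern_effect = 0 yields background-only gene sets", {
  cfg <- small_config(seed = 5, pattern_effect = 0)
  co <- simulate_cohort(cfg)
  expect_length(co$truth$immune_up_sets, 0)
  sets <- make_fixture_genesets(cfg, co$truth)
  blocked <- unlist(co$truth$immune_block_genes)
  expect_length(intersect(unlist(sets), blocked), 0)
})
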