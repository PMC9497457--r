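toy_gmt <- function(lines) {
  f <- withr::local_tempfile(fileext = ".gmt", .local_envir = parent.frame())
  writeLines(lines, f)
  f
}

test_that("GMT parsing round-trips and rejects malformed input", {
  f <- toy_gmt(c("setA\tdesc A\tg1\tg2\tg3", "setB\tdesc B\tg2\tg4"))
  sets <- read_gmt(f)
  expect_equal(names(sets), c("setA", "setB"))
  expect_equal(sets$setB, c("g2", "g4"))
  f2 <- toy_gmt(c("setA\td\tg1", "setA\td\tg2"))
  expect_error(read_gmt(f2), "duplicated set name")
  f3 <- toy_gmt(c("setA\td\tg1", "short\tonly"))
  expect_error(read_gmt(f3), "line 2")
  f4 <- toy_gmt("setA\td\tg1\tg1\tg2")
  expect_equal(read_gmt(f4)$setA, c("g1", "g2"))   # members deduplicated
  out <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(sets, out)
  expect_equal(read_gmt(out)[], sets[])
})

test_that("GMT reader agrees with the fgsea reference parser", {
  skip_if_not_installed("fgsea")
  f <- toy_gmt(c("s1\tx\tg1\tg2\tg5", "s2\tx\tg3\tg4"))
  ours <- read_gmt(f)
  ref <- fgsea::gmtPathways(f)
  expect_equal(lapply(ours, sort)[], lapply(ref, sort)[])
})

test_that("ssGSEA walk matches the hand-computed toy integral", {
  m <- matrix(c(3, 2, 1), 3, 1, dimnames = list(c("top", "mid", "low"), "s1"))
  sc <- ssgsea_scores(m, list(S = "top"), alpha = 0, normalize = FALSE)
  expect_equal(sc["S", "s1"], 1.5)
  # set at the bottom of the ranking scores negative
  sc2 <- ssgsea_scores(m, list(S = "low"), alpha = 0, normalize = FALSE)
  expect_lt(sc2["S", "s1"], 0)
})

test_that("ssGSEA is rank-based and normalizes to unit global range", {
  set.seed(12)
  m <- matrix(rnorm(200 * 8), 200, 8,
              dimnames = list(sprintf("g%03d", 1:200), paste0("s", 1:8)))
  m[, 2] <- m[, 1]                               # identical ranks
  sets <- list(A = rownames(m)[1:20], B = rownames(m)[21:60])
  sc <- ssgsea_scores(m, sets)
  expect_equal(sc[, 1], sc[, 2])
  expect_equal(max(sc) - min(sc), 1, tolerance = 1e-12)
  # strictly monotone per-sample transform leaves scores unchanged
  sc2 <- ssgsea_scores(exp(m), sets)
  expect_equal(sc, sc2)
  # dropped and oversized sets
  expect_warning(ssgsea_scores(m, c(sets, list(none = "zz"))), "no gene overlap")
  expect_error(ssgsea_scores(m, list(all = rownames(m))), "every gene")
})

test_that("planted up-sets score higher in their pattern", {
  co <- .shared$cohort
  sc <- ssgsea_scores(.shared$corrected[, .shared$cases], .shared$sets)
  truth <- co$truth$pattern_of_sample[.shared$cases]
  for (p in names(co$truth$immune_up_sets)) {
    for (nm in co$truth$immune_up_sets[[p]]) {
      res <- wilcoxon_rank_sum(sc[nm, truth == p], sc[nm, truth != p])
      expect_lt(res$p_value, 0.01)
      expect_gt(res$effect, 0)
    }
  }
})

test_that("GSVA scores are antisymmetric and near zero on flat data", {
  m <- matrix(c(5, 4, 3, 2, 1, 6,
                1, 2, 3, 6, 5, 4,
                3, 3, 3, 3, 3, 4), 6, 3,
              dimnames = list(paste0("g", 1:6), paste0("s", 1:3)))
  sc <- gsva_scores(m, list(S = c("g1", "g2")))
  expect_true(is.finite(sc["S", "s1"]))
  expect_error(gsva_scores(m[, 1:2], list(S = c("g1", "g2"))), ">= 3 samples")
  # constant rows: scores collapse toward zero
  flat <- matrix(3, 20, 5, dimnames = list(paste0("g", 1:20), paste0("s", 1:5)))
  scf <- gsva_scores(flat, list(S = paste0("g", seq(1, 19, by = 2))))
  expect_lt(max(abs(scf)), 0.3)
})

test_that("GSVA and ssGSEA order samples concordantly on planted signal", {
  sub <- .shared$corrected[, .shared$cases[1:60]]
  planted <- unique(unlist(.shared$cohort$truth$immune_up_sets))
  sets <- .shared$sets[planted]
  ss <- ssgsea_scores(sub, sets)
  gs <- gsva_scores(sub, sets)
  rho <- vapply(planted, function(nm)
    stats::cor(ss[nm, ], gs[nm, ], method = "spearman"), 0)
  expect_gt(mean(rho), 0.8)
})

test_that("group difference report covers two- and k-group families", {
  m <- matrix(rep(1:6, each = 3), 3, 6,
              dimnames = list(paste0("r", 1:3), paste0("s", 1:6)))
  g3 <- rep(c("a", "b", "c"), each = 2)
  # hand Kruskal-Wallis: ranks 1..6 in pairs, H = 12/(6*7)*sum(n R^2) - 21
  res <- group_difference_report(m, g3, family = "toy")
  expect_equal(res$statistic, rep(32 / 7, 3), tolerance = 1e-12)
  # identical two-group rows give p = 1
  m2 <- matrix(rep(c(1, 2, 3, 1, 2, 3), 2), 2, 6, byrow = TRUE,
               dimnames = list(c("r1", "r2"), paste0("s", 1:6)))
  res2 <- group_difference_report(m2, rep(c("x", "y"), each = 3))
  expect_equal(res2$p_value, c(1, 1))
  # a shifted row has the smallest p among three groups
  set.seed(3)
  m3 <- matrix(rnorm(5 * 30), 5, 30,
               dimnames = list(paste0("r", 1:5), paste0("s", 1:30)))
  g <- rep(c("a", "b", "c"), each = 10)
  m3[3, g == "b"] <- m3[3, g == "b"] + 3
  res3 <- group_difference_report(m3, g)
  expect_equal(which.min(res3$p_value), 3L)
  expect_error(group_difference_report(m3, rep("a", 30)), ">= 2 groups")
})
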