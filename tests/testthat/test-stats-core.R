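# independent enumeration oracle for the two-sample Mann-Whitney p-value
enumerate_wilcoxon_p <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combs <- utils::combn(length(pooled), n1)
  u_all <- apply(combs, 2L, function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2)
  min(1, 2 * min(mean(u_all <= u_obs), mean(u_all >= u_obs)))
}

test_that("Wilcoxon p matches exact enumeration for all small splits", {
  expect_equal(wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6))$p_value, 0.1)
  set.seed(5)
  for (n1 in 2:3) for (n2 in 2:(6 - n1)) {
    for (rep in 1:5) {
      x <- rnorm(n1); y <- rnorm(n2)
      expect_equal(wilcoxon_rank_sum(x, y)$p_value,
                   enumerate_wilcoxon_p(x, y), tolerance = 1e-12)
    }
  }
})

test_that("Wilcoxon degenerate and tied inputs behave sensibly", {
  expect_equal(wilcoxon_rank_sum(c(1, 2, 3), c(1, 2, 3))$p_value, 1)
  expect_equal(wilcoxon_rank_sum(c(2, 2), c(2, 2))$p_value, 1)
  res <- wilcoxon_rank_sum(rep(c(1, 2), 20), rep(c(1, 2, 2), 15))
  expect_true(res$p_value >= 0 && res$p_value <= 1)
})

test_that("BH adjustment matches the hand step-up and its invariants", {
  expect_equal(benjamini_hochberg(c(0.01, 0.02, 0.03, 0.04)),
               rep(0.04, 4))
  expect_equal(benjamini_hochberg(rep(0.2, 5)), rep(0.2, 5))
  expect_equal(benjamini_hochberg(0.37), 0.37)
  expect_error(benjamini_hochberg(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(2)
  p <- runif(50)
  adj <- benjamini_hochberg(p)
  expect_true(all(adj >= p))
  expect_gte(min(adj), min(p))
  # monotone: sorting p sorts the adjusted values identically
  expect_equal(sort(benjamini_hochberg(sort(p))), sort(adj))
})

test_that("correlation test handles exact, null and permutation cases", {
  x <- 1:10
  res <- correlation_test(x, 2 * x + 1)
  expect_equal(res$effect, 1)
  expect_equal(res$p_value, 0)
  res0 <- correlation_test(c(1, -1, 1, -1), c(1, 1, -1, -1))
  expect_equal(res0$effect, 0)
  expect_equal(res0$p_value, 1)
  expect_error(correlation_test(rep(1, 5), rnorm(5)), "constant")
  # spearman equals pearson on ranks
  set.seed(9)
  a <- rnorm(30); b <- a + rnorm(30)
  expect_equal(correlation_test(a, b, "spearman")$effect,
               stats::cor(rank(a), rank(b)))
  # permutation oracle for the pearson p-value
  set.seed(10)
  x <- rnorm(20); y <- 0.4 * x + rnorm(20)
  p_t <- correlation_test(x, y)$p_value
  r_obs <- abs(cor(x, y))
  perm <- replicate(10000, abs(cor(x, sample(y))))
  p_perm <- mean(perm >= r_obs)
  expect_lt(abs(p_t - p_perm), 3 * sqrt(p_perm * (1 - p_perm) / 10000) + 0.01)
})

test_that("moderated t flags planted DEGs and tracks the ordinary t", {
  set.seed(3)
  n <- 20
  m <- matrix(rnorm(100 * 2 * n, sd = 0.3), 100, 2 * n,
              dimnames = list(sprintf("g%03d", 1:100), sprintf("s%02d", 1:(2 * n))))
  grp <- rep(c("case", "control"), each = n)
  m["g001", grp == "case"] <- m["g001", grp == "case"] + 2
  tab <- moderated_t_deg(m, grp)
  expect_true(tab$deg[tab$gene == "g001"])
  expect_equal(sum(tab$deg), 1)
  expect_equal(tab$log2fc[tab$gene == "g001"],
               mean(m["g001", grp == "case"]) - mean(m["g001", grp == "control"]))
  # with many equal-variance genes, moderated t ~ ordinary equal-variance t
  t_ord <- apply(m, 1L, function(v)
    stats::t.test(v[grp == "case"], v[grp == "control"],
                  var.equal = TRUE)$statistic)
  expect_gt(stats::cor(tab$statistic, t_ord), 0.99)
  expect_lt(stats::median(abs(tab$statistic - t_ord) / abs(t_ord)), 0.15)
  expect_error(moderated_t_deg(m[, c(1, 21, 22)], grp[c(1, 21, 22)]),
               ">=2 samples")
})

test_that("null data produce no DEG excess and uniform adjusted ranks", {
  set.seed(4)
  m <- matrix(rnorm(500 * 30), 500, 30,
              dimnames = list(sprintf("g%03d", 1:500), sprintf("s%02d", 1:30)))
  grp <- rep(c("case", "control"), each = 15)
  tab <- moderated_t_deg(m, grp)
  expect_lte(sum(tab$deg), 2)
  expect_gt(stats::ks.test(tab$p_value, "punif")$p.value, 0.001)
})

test_that("hypergeometric ORA matches enumeration", {
  universe <- paste0("u", 1:10)
  sets <- list(S = universe[1:5], D = paste0("u", 11:15),
               ALL = universe)
  hits <- c("u1", "u2", "u3", "u6")
  res <- hypergeometric_ora(hits, universe, sets)
  expect_equal(res$p_value[res$set == "S"], 55 / 210, tolerance = 1e-12)
  expect_equal(res$p_value[res$set == "D"], 1)     # disjoint after intersection
  expect_equal(res$overlap[res$set == "ALL"], 4)
  expect_equal(res$p_value[res$set == "ALL"], 1)
  expect_error(hypergeometric_ora(hits, character(0), sets), "empty universe")
  expect_error(hypergeometric_ora(c(hits, "zz"), universe, sets), "subset")
})
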