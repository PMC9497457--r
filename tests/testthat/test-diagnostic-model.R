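make_binary_matrix <- function() {
  # 2x2 design: feature 1 among cases 20/10, among controls 10/20
  x <- c(rep(1, 20), rep(0, 10), rep(1, 10), rep(0, 20))
  m <- rbind(f1 = x, f2 = rnorm(60))
  colnames(m) <- sprintf("s%02d", 1:60)
  list(m = m, groups = rep(c("case", "control"), each = 30))
}

test_that("univariate screen keeps signal and rejects constants", {
  set.seed(1)
  n <- 60
  grp <- rep(c("case", "control"), each = n / 2)
  y <- as.numeric(grp == "case")
  m <- rbind(signal = y + rnorm(n, sd = 0.1), noise = rnorm(n))
  colnames(m) <- sprintf("s%02d", 1:n)
  res <- suppressWarnings(univariate_logistic_screen(m, grp))
  expect_true("signal" %in% res$selected)
  m2 <- rbind(m, flat = 1)
  expect_error(suppressWarnings(univariate_logistic_screen(m2, grp)),
               "constant feature: flat")
})

test_that("LASSO selection is deterministic and recovers planted features", {
  co <- .shared$cohort
  regs <- .shared$regs
  sel1 <- lasso_logistic_cv(.shared$corrected[regs, ], co$annotation$group,
                            seed = 5)
  sel2 <- lasso_logistic_cv(.shared$corrected[regs, ], co$annotation$group,
                            seed = 5)
  expect_identical(sel1$selected, sel2$selected)
  recall <- mean(co$truth$diagnostic_genes %in% sel1$selected)
  expect_gt(recall, 0.7)
  # nonzero count non-increasing along the lambda path (largest lambda first)
  fit <- glmnet::glmnet(t(.shared$corrected[regs, ]),
                        as.numeric(co$annotation$group == "case"),
                        family = "binomial")
  nz <- colSums(as.matrix(fit$beta) != 0)
  expect_true(all(diff(rev(nz)) <= 0 | diff(nz) >= 0))
  idx <- c(1:6, 91:98)                    # 6 cases, 8 controls: under 10 each
  expect_error(lasso_logistic_cv(.shared$corrected[regs, idx],
                                 co$annotation$group[idx], n_folds = 10),
               "n_folds")
})

test_that("multivariate logistic reproduces the closed-form 2x2 odds ratio", {
  d <- make_binary_matrix()
  model <- fit_multivariate_logistic(d$m, d$groups, "f1")
  expect_equal(model$odds_ratios$or[1], 4.0, tolerance = 1e-6)
  expect_equal(model$odds_ratios$or,
               exp(unname(model$coefficients)), tolerance = 1e-12)
  expect_equal(model$c_index, model$auc)
  expect_error(fit_multivariate_logistic(d$m, d$groups, character(0)),
               "zero features")
  expect_error(fit_multivariate_logistic(d$m, d$groups, "nope"), "absent")
})

test_that("AUC equals the all-pairs concordance fraction", {
  expect_equal(roc_auc(c(1, 2, 3, 10, 11, 12),
                       c(0, 0, 0, 1, 1, 1))$auc, 1)
  expect_equal(roc_auc(rep(1, 10), rep(c(0, 1), 5))$auc, 0.5)
  set.seed(8)
  scores <- sample(seq(0, 1, by = 0.05), 60, replace = TRUE)  # forces ties
  labels <- rep(c(0, 1), each = 30)
  auc <- roc_auc(scores, labels)$auc
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  conc <- mean(outer(pos, neg, function(a, b)
    (a > b) + 0.5 * (a == b)))
  expect_equal(auc, conc, tolerance = 1e-12)
  # invariance under strictly monotone transforms
  expect_equal(roc_auc(exp(3 * scores), labels)$auc, auc)
  expect_error(roc_auc(scores, rep(1, 60)), "both classes")
})

test_that("Hosmer-Lemeshow handles exact fits and degenerate g", {
  y <- rep(c(0, 1), each = 20)
  perfect <- as.numeric(y)
  res <- suppressWarnings(hosmer_lemeshow(perfect, y, g = 4))
  expect_equal(res$statistic, 0)
  expect_error(hosmer_lemeshow(runif(10), rbinom(10, 1, 0.5), g = 2), "g must be")
  expect_error(hosmer_lemeshow(runif(10), rbinom(10, 1, 0.5), g = 10), "n >= 2 g")
  set.seed(2)
  p <- runif(200)
  res2 <- hosmer_lemeshow(p, rbinom(200, 1, p))
  expect_equal(res2$df, 8)
  expect_true(res2$p_value > 0 && res2$p_value <= 1)
})

test_that("external validation freezes coefficients", {
  d <- make_binary_matrix()
  set.seed(3)
  d$m["f2", ] <- d$m["f2", ] + 0.5 * as.numeric(d$groups == "case")
  model <- fit_multivariate_logistic(d$m, d$groups, c("f1", "f2"))
  same <- validate_external(model, d$m, d$groups)
  expect_equal(same$auc, model$auc, tolerance = 1e-12)
  set.seed(4)
  perm <- validate_external(model, d$m, sample(d$groups))
  expect_lt(abs(perm$auc - 0.5), 0.2)
  expect_error(validate_external(model, d$m[1, , drop = FALSE], d$groups),
               "missing model feature")
})

test_that("the two-stage screen plus model separates a synthetic cohort", {
  co <- .shared$cohort
  model <- build_diagnostic_model(.shared$corrected, co$annotation$group,
                                  .shared$regs, seed = 2)
  expect_gt(model$auc, 0.9)
  expect_true(all(model$odds_ratios$ci_low < model$odds_ratios$ci_high))
  # held-out cohort from the same generator
  vcfg <- small_config(seed = 1234)
  vco <- simulate_cohort(vcfg)
  val <- validate_external(model, vco$expression, vco$annotation$group)
  expect_gt(val$auc, 0.85)
})
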