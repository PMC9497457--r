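#' Univariate logistic screen of candidate features
#'
#' Fits one single-predictor logistic regression per feature (IRLS via
#' \code{glm}) of case status on expression and keeps features whose Wald
#' p-value falls below \code{alpha}. Features whose fit shows signs of
#' perfect separation are kept and flagged with a warning.
#'
#' @param matrix Expression matrix (features x samples).
#' @param groups Vector of \code{"case"}/\code{"control"} per sample.
#' @param alpha Retention threshold on the Wald p-value (default 0.05).
#' @return List with \code{selected} (feature ids) and \code{results}
#'   (data.frame: feature, coefficient, statistic, p_value, separated).
#' @export
univariate_logistic_screen <- function(matrix, groups, alpha = 0.05) {
  validate_expression(matrix)
  y <- as_case_indicator(groups)
  rows <- lapply(rownames(matrix), function(g) {
    x <- matrix[g, ]
    if (stats::sd(x) == 0) stop("constant feature: ", g)
    fit <- suppressWarnings(
      stats::glm(y ~ x, family = stats::binomial(),
                 control = stats::glm.control(epsilon = 1e-8, maxit = 100)))
    co <- summary(fit)$coefficients
    sep <- !fit$converged || abs(co["x", "Estimate"]) > 20
    data.frame(feature = g, coefficient = co["x", "Estimate"],
               statistic = co["x", "z value"], p_value = co["x", "Pr(>|z|)"],
               separated = sep, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  if (any(res$separated))
    warning("possible perfect separation for: ",
            paste(res$feature[res$separated], collapse = ", "))
  list(selected = res$feature[res$p_value < alpha | res$separated],
       results = res)
}

as_case_indicator <- function(groups) {
  if (is.numeric(groups) && all(groups %in% c(0, 1))) return(as.numeric(groups))
  if (!all(groups %in% c("case", "control")))
    stop("groups must be 'case'/'control' (or a 0/1 vector)")
  as.numeric(groups == "case")
}

#' LASSO-penalized logistic feature selection with 10-fold CV
#'
#' L1-penalized logistic regression (glmnet coordinate descent on
#' standardized features, 100-value log-spaced lambda grid) with
#' class-stratified k-fold cross-validation on binomial deviance.
#' Features with nonzero coefficients at lambda_min are returned; the
#' lambda rule is configurable to \code{"lambda.1se"}.
#'
#' @param matrix Expression matrix (features x samples).
#' @param groups \code{"case"}/\code{"control"} per sample.
#' @param n_folds CV folds (default 10).
#' @param seed Seed controlling fold assignment.
#' @param lambda_rule \code{"lambda.min"} (default) or \code{"lambda.1se"}.
#' @return List with \code{selected}, \code{lambda} (chosen value),
#'   \code{lambda_path}, \code{cv_deviance}, \code{coefficients} (at the
#'   chosen lambda, original scale), \code{n_folds}, \code{seed}.
#' @export
lasso_logistic_cv <- function(matrix, groups, n_folds = 10L, seed = 1L,
                              lambda_rule = c("lambda.min", "lambda.1se")) {
  validate_expression(matrix)
  lambda_rule <- match.arg(lambda_rule)
  y <- as_case_indicator(groups)
  if (length(unique(y)) < 2L || min(table(y)) < n_folds)
    stop("need >= n_folds samples per class for stratified CV")
  X <- t(matrix)
  set.seed(seed)
  foldid <- integer(length(y))
  for (cl in c(0, 1)) {
    idx <- which(y == cl)
    foldid[idx] <- sample(rep_len(seq_len(n_folds), length(idx)))
  }
  cv <- glmnet::cv.glmnet(X, y, family = "binomial",
                          type.measure = "deviance",
                          foldid = foldid, nlambda = 100,
                          lambda.min.ratio = 1e-4, standardize = TRUE)
  lam <- cv[[lambda_rule]]
  beta <- as.matrix(stats::coef(cv, s = lam))
  nz <- rownames(beta)[beta[, 1] != 0 & rownames(beta) != "(Intercept)"]
  list(selected = nz, lambda = lam,
       lambda_path = cv$lambda, cv_deviance = cv$cvm,
       coefficients = stats::setNames(beta[, 1], rownames(beta)),
       n_folds = n_folds, seed = seed)
}

#' Fit the multivariate logistic diagnostic model
#'
#' Unpenalized logistic fit of case status on the selected features, with
#' per-feature odds ratios exp(beta) and Wald 95\% CIs exp(beta +/- 1.96 SE),
#' in-sample ROC/AUC with DeLong CI, and the concordance index (equal to
#' the AUC for a binary outcome).
#'
#' @param matrix Expression matrix containing all \code{features}.
#' @param groups \code{"case"}/\code{"control"} per sample.
#' @param features Feature ids to include (>= 1).
#' @return A \code{diagnostic_model} list: \code{features},
#'   \code{intercept}, \code{coefficients}, \code{odds_ratios} (data.frame
#'   with or, ci_low, ci_high, p_value), \code{auc}, \code{auc_ci},
#'   \code{c_index}, \code{fitted_probabilities}.
#' @export
fit_multivariate_logistic <- function(matrix, groups, features) {
  validate_expression(matrix)
  if (length(features) == 0L) stop("zero features: nothing to fit")
  missing <- setdiff(features, rownames(matrix))
  if (length(missing))
    stop("feature(s) absent from matrix: ", paste(missing, collapse = ", "))
  y <- as_case_indicator(groups)
  if (length(y) <= length(features) + 1L)
    stop("need n > |features| + 1 samples")
  df <- as.data.frame(t(matrix[features, , drop = FALSE]))
  safe <- make.names(features)          # model.matrix-safe column names
  colnames(df) <- safe
  df$.y <- y
  fit <- suppressWarnings(
    stats::glm(.y ~ ., data = df, family = stats::binomial(),
               control = stats::glm.control(epsilon = 1e-8, maxit = 100)))
  if (!fit$converged)
    stop("multivariate logistic fit did not converge after 100 iterations; ",
         "consider reducing the feature set")
  co <- summary(fit)$coefficients
  beta <- co[safe, "Estimate"]
  se <- co[safe, "Std. Error"]
  ors <- data.frame(feature = features,
                    coefficient = beta,
                    or = exp(beta),
                    ci_low = exp(beta - 1.96 * se),
                    ci_high = exp(beta + 1.96 * se),
                    p_value = co[safe, "Pr(>|z|)"],
                    row.names = NULL, stringsAsFactors = FALSE)
  prob <- stats::fitted(fit)
  roc <- roc_auc(prob, y)
  structure(list(features = features,
                 intercept = unname(co["(Intercept)", "Estimate"]),
                 coefficients = stats::setNames(unname(beta), features),
                 odds_ratios = ors,
                 auc = roc$auc, auc_ci = roc$ci, c_index = roc$auc,
                 fitted_probabilities = stats::setNames(unname(prob),
                                                        colnames(matrix))),
            class = "diagnostic_model")
}

#' @export
print.diagnostic_model <- function(x, ...) {
  cat("Diagnostic logistic model:", length(x$features), "features\n")
  cat(sprintf("  AUC %.3f (95%% CI %.3f-%.3f); C-index %.3f\n",
              x$auc, x$auc_ci[1], x$auc_ci[2], x$c_index))
  invisible(x)
}

#' ROC AUC with DeLong confidence interval
#'
#' AUC computed by the Mann-Whitney statistic (midranks for tied scores,
#' i.e. ties count one half) with a 95\% DeLong CI via pROC.
#'
#' @param scores Numeric predictor (higher = more case-like).
#' @param labels \code{"case"}/\code{"control"} or 0/1 per score.
#' @return List with \code{auc}, \code{ci} (length-2), and \code{roc}
#'   (the underlying \code{pROC::roc} object, for curve export).
#' @export
roc_auc <- function(scores, labels) {
  y <- as_case_indicator(labels)
  if (length(unique(y)) < 2L) stop("both classes must be present")
  roc <- pROC::roc(response = y, predictor = scores,
                   levels = c(0, 1), direction = "<", quiet = TRUE)
  auc <- as.numeric(pROC::auc(roc))
  ci <- if (stats::var(scores) == 0) c(0.5, 0.5)
        else as.numeric(pROC::ci.auc(roc, method = "delong"))[c(1, 3)]
  list(auc = auc, ci = ci, roc = roc)
}

#' Hosmer-Lemeshow goodness-of-fit test
#'
#' Deciles-of-risk calibration test: samples are cut into \code{g} groups
#' by predicted probability (ties broken by stable order), and
#' chi-square = sum (O - E)^2 / (E (1 - E / n_g)) is referred to g - 2
#' degrees of freedom. Groups with zero expected count are merged with
#' their neighbor (with a warning).
#'
#' @param probabilities Predicted event probabilities.
#' @param labels Observed outcomes (\code{"case"}/\code{"control"} or 0/1).
#' @param g Number of risk groups (default 10; needs n >= 2 g and g >= 3).
#' @return One-row data.frame (\code{statistic}, \code{p_value}, \code{df}).
#' @export
hosmer_lemeshow <- function(probabilities, labels, g = 10L) {
  y <- as_case_indicator(labels)
  n <- length(y)
  stopifnot(length(probabilities) == n)
  if (g < 3L) stop("g must be >= 3 (df = g - 2 would be degenerate)")
  if (n < 2L * g) stop("need n >= 2 g observations")
  ord <- order(probabilities)            # stable: ties keep input order
  p <- probabilities[ord]; yo <- y[ord]
  grp <- ceiling(seq_len(n) / (n / g))
  obs <- tapply(yo, grp, sum)
  expd <- tapply(p, grp, sum)
  ng <- tapply(yo, grp, length)
  zero <- expd == 0
  if (any(zero)) {
    warning("merging ", sum(zero), " zero-expectation group(s) with neighbors")
    keep <- !zero
    for (i in which(zero)) {
      j <- if (i == 1L) which(keep)[1L] else max(which(keep & seq_along(keep) < i))
      obs[j] <- obs[j] + obs[i]; expd[j] <- expd[j] + expd[i]; ng[j] <- ng[j] + ng[i]
    }
    obs <- obs[keep]; expd <- expd[keep]; ng <- ng[keep]
  }
  num <- (obs - expd)^2
  den <- expd * (1 - expd / ng)
  chisq <- sum(ifelse(num == 0, 0, num / den))   # exact fits contribute 0
  df <- length(obs) - 2L
  data.frame(statistic = chisq, p_value = stats::pchisq(chisq, df, lower.tail = FALSE),
             df = df)
}

#' Validate a frozen diagnostic model on external data
#'
#' Applies the stored intercept and coefficients (no refitting) to a
#' validation expression matrix and reports AUC with DeLong CI.
#'
#' @param model A \code{diagnostic_model}.
#' @param matrix Validation expression matrix containing all model features.
#' @param groups Validation labels.
#' @return As \code{\link{roc_auc}}, plus \code{probabilities}.
#' @export
validate_external <- function(model, matrix, groups) {
  stopifnot(inherits(model, "diagnostic_model"))
  validate_expression(matrix)
  missing <- setdiff(model$features, rownames(matrix))
  if (length(missing))
    stop("validation matrix is missing model feature(s): ",
         paste(missing, collapse = ", "))
  eta <- model$intercept +
    as.numeric(crossprod(matrix[model$features, , drop = FALSE],
                         model$coefficients))
  prob <- stats::plogis(eta)
  out <- roc_auc(prob, groups)
  out$probabilities <- stats::setNames(prob, colnames(matrix))
  out
}

#' Two-stage diagnostic model construction
#'
#' Convenience wrapper running the published two-stage screen on a feature
#' panel: univariate logistic filter (p < alpha), LASSO with stratified
#' 10-fold CV at lambda_min, then the unpenalized multivariate logistic
#' model on the surviving features.
#'
#' @inheritParams lasso_logistic_cv
#' @param features Candidate feature ids (rows of \code{matrix}).
#' @param alpha Univariate retention threshold.
#' @return A \code{diagnostic_model} with the screening trail attached
#'   (\code{screen}, \code{lasso}).
#' @export
build_diagnostic_model <- function(matrix, groups, features, alpha = 0.05,
                                   n_folds = 10L, seed = 1L) {
  sub <- matrix[intersect(features, rownames(matrix)), , drop = FALSE]
  screen <- univariate_logistic_screen(sub, groups, alpha = alpha)
  if (length(screen$selected) == 0L) stop("no feature passed the univariate screen")
  lasso <- lasso_logistic_cv(sub[screen$selected, , drop = FALSE], groups,
                             n_folds = n_folds, seed = seed)
  sel <- lasso$selected
  if (length(sel) == 0L) stop("LASSO selected no features")
  model <- fit_multivariate_logistic(matrix, groups, sel)
  model$screen <- screen
  model$lasso <- lasso[c("lambda", "lambda_path", "cv_deviance", "n_folds", "seed")]
  model
}
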