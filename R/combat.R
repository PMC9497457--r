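#' Empirical-Bayes batch-effect correction (ComBat-style)
#'
#' Removes additive and multiplicative batch effects from a log2 expression
#' matrix using the parametric empirical-Bayes location/scale model: each
#' gene is standardized against its grand mean and pooled batch-residual
#' variance, per-batch location (gamma) and scale (delta^2) estimates are
#' shrunk toward method-of-moments priors (normal for gamma, inverse-gamma
#' for delta^2), the standardized data are adjusted batch-wise, and every
#' gene's grand mean is restored exactly on the way back. No biological
#' covariates are protected (batch-only model).
#'
#' @param matrix Expression matrix (genes x samples).
#' @param annotation Sample annotation with \code{sample_id} and
#'   \code{batch} columns covering every column of \code{matrix}.
#' @return Adjusted expression matrix, same dimensions and dimnames.
#'   Zero-variance genes are returned unadjusted with a warning.
#' @export
correct_batches <- function(matrix, annotation) {
  validate_expression(matrix)
  batch <- annotation$batch[match(colnames(matrix), annotation$sample_id)]
  if (anyNA(batch)) stop("annotation does not cover all samples")
  batch <- factor(batch)
  if (nlevels(batch) < 2L) stop("need >=2 batches for batch correction")
  nb <- table(batch)
  if (any(nb < 2L))
    stop("batch(es) with <2 samples: ", paste(names(nb)[nb < 2L], collapse = ", "))

  n <- ncol(matrix)
  grand <- rowMeans(matrix)
  # pooled variance of the residuals around the per-batch means (the
  # batch-model residual variance, as in the canonical EB algorithm)
  batch_means <- vapply(levels(batch), function(b)
    rowMeans(matrix[, batch == b, drop = FALSE]), numeric(nrow(matrix)))
  fitted <- batch_means[, as.integer(batch), drop = FALSE]
  pooled_var <- rowSums((matrix - fitted)^2) / n
  const <- pooled_var <= .Machine$double.eps
  if (any(const))
    warning(sum(const), " zero-variance gene(s) left unadjusted")
  out <- matrix
  if (all(const)) return(out)

  X <- matrix[!const, , drop = FALSE]
  mu <- grand[!const]
  sigma <- sqrt(pooled_var[!const])
  Z <- (X - mu) / sigma

  for (b in levels(batch)) {
    idx <- which(batch == b)
    Zb <- Z[, idx, drop = FALSE]
    m <- length(idx)
    gamma_hat <- rowMeans(Zb)
    delta2_hat <- rowSums((Zb - gamma_hat)^2) / (m - 1)

    # method-of-moments hyperpriors across genes
    gamma_bar <- mean(gamma_hat)
    tau2 <- stats::var(gamma_hat)
    d_bar <- mean(delta2_hat)
    s2 <- stats::var(delta2_hat)
    a_prior <- (2 * s2 + d_bar^2) / s2
    b_prior <- (d_bar * s2 + d_bar^3) / s2

    gamma_star <- gamma_hat
    delta2_star <- delta2_hat
    for (it in seq_len(200L)) {
      g_new <- (m * tau2 * gamma_hat + delta2_star * gamma_bar) /
        (m * tau2 + delta2_star)
      ss <- rowSums((Zb - g_new)^2)
      d_new <- (0.5 * ss + b_prior) / (m / 2 + a_prior - 1)
      if (max(abs(g_new - gamma_star), abs(d_new - delta2_star)) < 1e-10) {
        gamma_star <- g_new; delta2_star <- d_new
        break
      }
      gamma_star <- g_new; delta2_star <- d_new
    }
    Z[, idx] <- (Zb - gamma_star) / sqrt(delta2_star)
  }

  # back-transform; recenter so each gene's grand mean is restored exactly
  zm <- rowMeans(Z)
  out[!const, ] <- (Z - zm) * sigma + mu
  out
}
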