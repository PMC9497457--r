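#' Soft-threshold power selection by scale-free topology fit
#'
#' For each candidate power beta the unsigned adjacency
#' a_ij = |cor(i, j)|^beta is formed and the gene connectivities
#' k_i = sum_j a_ij are binned; the scale-free fit index is the R^2 of
#' log10(freq(k)) on log10(mean k) over the occupied bins. The chosen beta
#' is the smallest power reaching \code{target_r2}; if none does, the
#' power with the highest R^2 is returned with a warning.
#'
#' @param matrix Expression matrix (genes x samples), >= 20 genes.
#' @param powers Candidate powers (default 1:20).
#' @param target_r2 Scale-free fit target (default 0.85).
#' @param n_bins Connectivity histogram bins (default 10).
#' @param fallback_beta Power used (with a warning) when no candidate
#'   reaches the target, e.g. on modular but non-scale-free data; default
#'   6, the conventional unsigned-network power.
#' @return List with \code{beta}, \code{fit} (data.frame power, r2,
#'   mean_k) and \code{reached_target}.
#' @export
pick_soft_threshold <- function(matrix, powers = 1:20, target_r2 = 0.85,
                                n_bins = 10L, fallback_beta = 6L) {
  validate_expression(matrix)
  if (nrow(matrix) < 20L) stop("need >= 20 genes for scale-free fitting")
  ac <- abs(suppressWarnings(stats::cor(t(matrix))))
  ac[!is.finite(ac)] <- 0
  diag(ac) <- 0
  fit <- lapply(powers, function(b) {
    k <- rowSums(ac^b)
    r2 <- scale_free_r2(k, n_bins)
    data.frame(power = b, r2 = r2, mean_k = mean(k))
  })
  fit <- do.call(rbind, fit)
  # powers that crush mean connectivity below 1 mimic scale-free decay on
  # pure noise; exclude them from qualifying (standard WGCNA guidance)
  ok <- which(fit$r2 >= target_r2 & fit$mean_k >= 1)
  if (length(ok)) {
    beta <- fit$power[ok[1L]]
    reached <- TRUE
  } else {
    warning("no power reached scale-free R^2 >= ", target_r2,
            "; falling back to the conventional power ", fallback_beta)
    beta <- fallback_beta
    reached <- FALSE
  }
  list(beta = beta, fit = fit, reached_target = reached)
}

# signed scale-free fit index: R^2 of log10(freq) ~ log10(k), negated when
# the slope is positive (a scale-free degree distribution must decay)
scale_free_r2 <- function(k, n_bins) {
  if (max(k) <= 0 || stats::sd(k) == 0) return(0)
  bins <- cut(k, breaks = n_bins)
  freq <- tapply(k, bins, length)
  kmean <- tapply(k, bins, mean)
  keep <- !is.na(freq) & freq > 0 & kmean > 0
  if (sum(keep) < 3L) return(0)
  lf <- log10(freq[keep]); lk <- log10(kmean[keep])
  if (stats::sd(lk) == 0 || stats::sd(lf) == 0) return(0)
  fit <- stats::lm(lf ~ lk)
  -sign(stats::coef(fit)[[2]]) * summary(fit)$r.squared
}

#' Topological overlap matrix (TOM) similarity
#'
#' TOM_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij), with
#' k_i the total connectivity of node i and a unit diagonal. Shared
#' network neighborhoods raise the similarity beyond the direct adjacency.
#'
#' @param adjacency Symmetric matrix in [0, 1] with unit diagonal.
#' @return TOM similarity matrix (same dimension, values in [0, 1],
#'   unit diagonal).
#' @export
tom_similarity <- function(adjacency) {
  a <- adjacency
  if (!isSymmetric(unname(a), tol = 1e-10)) stop("adjacency must be symmetric")
  if (any(a < 0 | a > 1)) stop("adjacency entries must lie in [0, 1]")
  diag(a) <- 0
  k <- rowSums(a)
  L <- a %*% a                        # sum_u a_iu a_uj (u != i, j handled below)
  # subtract the u = i and u = j contributions (zero since diag(a) = 0)
  kmin <- outer(k, k, pmin)
  tom <- (L + a) / (kmin + 1 - a)
  diag(tom) <- 1
  dimnames(tom) <- dimnames(adjacency)
  tom
}

#' Detect co-expression modules (WGCNA-lite)
#'
#' Simplified weighted co-expression module detection: genes are filtered
#' to the top variance fraction, the unsigned adjacency |cor|^beta is
#' converted to TOM dissimilarity (1 - TOM), average-linkage hierarchical
#' clustering is cut statically, and clusters below
#' \code{min_module_size} fall into module 0 (unassigned).
#' Each module's eigengene is the unit-norm first principal component of
#' its standardized expression (sign oriented so the mean gene loading is
#' positive), and eigengenes are correlated against trait indicator
#' vectors. The static cut is a deliberate simplification of the WGCNA
#' package's dynamic tree cut; its height is a fraction of the maximum
#' merge height, because inter-module merges sit just below the maximum
#' of the TOM dissimilarity scale while intra-module merges sit well
#' underneath.
#'
#' @param matrix Expression matrix (genes x samples).
#' @param traits Optional data.frame of numeric/binary traits (one row per
#'   sample, in column order of \code{matrix}) for module-trait
#'   correlation.
#' @param top_variance_frac Fraction of most-variable genes kept
#'   (default 0.25).
#' @param min_module_size Minimum genes per module (default 30).
#' @param beta Soft power; \code{NULL} (default) picks it via
#'   \code{\link{pick_soft_threshold}}.
#' @param cut_frac Static cut height as a fraction of the maximum merge
#'   height (default 0.95).
#' @return A \code{module_assignment} list: \code{modules} (named integer
#'   per gene, 0 = unassigned), \code{beta}, \code{eigengenes} (samples x
#'   modules), \code{module_trait} (data.frame module, trait, r, p_value),
#'   \code{genes_used}.
#' @export
detect_modules <- function(matrix, traits = NULL, top_variance_frac = 0.25,
                           min_module_size = 30L, beta = NULL,
                           cut_frac = 0.95) {
  validate_expression(matrix)
  v <- apply(matrix, 1L, stats::var)
  n_keep <- max(20L, ceiling(top_variance_frac * nrow(matrix)))
  keep <- names(sort(v, decreasing = TRUE)[seq_len(min(n_keep, nrow(matrix)))])
  keep <- keep[order(match(keep, rownames(matrix)))]   # stable gene order
  if (length(keep) < 2L * min_module_size)
    stop("top-variance filter leaves fewer than 2*min_module_size genes")
  X <- matrix[keep, , drop = FALSE]

  if (is.null(beta)) beta <- pick_soft_threshold(X)$beta
  ac <- abs(suppressWarnings(stats::cor(t(X))))
  ac[!is.finite(ac)] <- 0
  adj <- ac^beta
  diag(adj) <- 1
  tom <- tom_similarity(adj)
  h <- stats::hclust(stats::as.dist(1 - tom), method = "average")
  raw <- stats::cutree(h, h = cut_frac * max(h$height))
  sizes <- table(raw)
  big <- names(sizes)[sizes >= min_module_size]
  modules <- integer(length(raw))
  # number retained modules by decreasing size
  ord <- names(sort(sizes[big], decreasing = TRUE))
  for (i in seq_along(ord)) modules[raw == as.integer(ord[i])] <- i
  names(modules) <- keep

  eig <- NULL
  mt <- NULL
  mods <- sort(unique(modules[modules > 0]))
  if (length(mods)) {
    eig <- sapply(mods, function(m) module_eigengene(X[modules == m, , drop = FALSE]))
    colnames(eig) <- paste0("ME", mods)
    rownames(eig) <- colnames(matrix)
    if (!is.null(traits)) {
      stopifnot(nrow(traits) == ncol(matrix))
      mt <- do.call(rbind, lapply(colnames(eig), function(me) {
        do.call(rbind, lapply(colnames(traits), function(tr) {
          res <- correlation_test(eig[, me], as.numeric(traits[[tr]]))
          data.frame(module = me, trait = tr, r = res$effect,
                     p_value = res$p_value, stringsAsFactors = FALSE)
        }))
      }))
    }
  }
  structure(list(modules = modules, beta = beta, eigengenes = eig,
                 module_trait = mt, genes_used = keep),
            class = "module_assignment")
}

# unit-norm first PC over samples of the standardized module expression,
# sign oriented so the mean gene loading is positive
module_eigengene <- function(X) {
  Z <- t(scale(t(X)))
  Z[!is.finite(Z)] <- 0
  sv <- svd(Z, nu = 1L, nv = 1L)
  e <- sv$v[, 1L]
  if (mean(sv$u[, 1L]) < 0) e <- -e
  e / sqrt(sum(e^2))
}
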