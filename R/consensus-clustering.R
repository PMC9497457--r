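#' Resampled consensus matrix for one K
#'
#' Monti-style consensus clustering: in each replicate a fraction
#' \code{p_item} of samples is drawn without replacement and the subsample
#' is partitioned into K groups; consensus(i, j) is the number of
#' replicates in which i and j co-clustered divided by the number in which
#' both were drawn. Pairs never co-sampled get consensus 0 with a warning.
#'
#' The default inner clusterer is k-means (Euclidean, on samples over the
#' feature rows) with a small number of random restarts per replicate.
#' Random restarts are what make the consensus informative about the
#' cluster number: at the true K the partition is stable across restarts
#' and subsamples, while at a wrong K k-means oscillates between equally
#' good local optima, raising the proportion of ambiguous pairs.
#' Subsampled average-linkage hierarchical clustering on the
#' 1 - Pearson-correlation distance (\code{method = "hc"}) is also
#' available, but note its pairwise distances are unchanged by
#' subsampling, so wrong-K merges are far more stable and the PAC curve
#' less discriminating.
#'
#' @param matrix Feature matrix (features x samples).
#' @param K Number of clusters (2 <= K < n, and n >= 2 K).
#' @param n_reps Number of subsampling replicates (default 1000).
#' @param p_item Sample subsampling fraction (default 0.8).
#' @param seed RNG seed.
#' @param method Inner clustering: \code{"km"} (k-means, default) or
#'   \code{"hc"} (average-linkage on 1 - Pearson correlation).
#' @param nstart Random restarts per k-means replicate (default 2).
#' @return Symmetric n x n matrix in [0, 1] with unit diagonal.
#' @export
consensus_matrix <- function(matrix, K, n_reps = 1000L, p_item = 0.8,
                             seed = 1L, method = c("km", "hc"),
                             nstart = 2L) {
  validate_expression(matrix)
  method <- match.arg(method)
  n <- ncol(matrix)
  if (K < 2L || K >= n) stop("K must satisfy 2 <= K < n")
  if (n < 2L * K) stop("need at least 2*K samples")
  set.seed(seed)
  m <- ceiling(p_item * n)
  co_cluster <- matrix(0, n, n)
  co_sample <- matrix(0, n, n)
  for (rep in seq_len(n_reps)) {
    idx <- sort(sample.int(n, m))
    sub <- matrix[, idx, drop = FALSE]
    cl <- if (method == "km")
      tryCatch(stats::kmeans(t(sub), centers = K, nstart = nstart,
                             iter.max = 50L)$cluster,
               error = function(e) hclust_euclid_labels(sub, K))
    else hclust_pearson_labels(sub, K)
    ind <- outer(cl, cl, "==")
    co_sample[idx, idx] <- co_sample[idx, idx] + 1
    co_cluster[idx, idx] <- co_cluster[idx, idx] + ind
  }
  never <- co_sample == 0 & upper.tri(co_sample)
  if (any(never))
    warning(sum(never), " sample pair(s) never co-sampled; consensus set to 0")
  cons <- ifelse(co_sample > 0, co_cluster / co_sample, 0)
  diag(cons) <- 1
  dimnames(cons) <- list(colnames(matrix), colnames(matrix))
  cons
}

# k-means can fail when the subsample has fewer than K distinct points
# (duplicated columns); fall back to Euclidean hierarchical labels
hclust_euclid_labels <- function(matrix, K) {
  stats::cutree(stats::hclust(stats::dist(t(matrix)), method = "average"), k = K)
}

# average-linkage hclust on 1 - Pearson correlation between columns
hclust_pearson_labels <- function(matrix, K) {
  cm <- suppressWarnings(stats::cor(matrix))
  cm[!is.finite(cm)] <- 0            # constant columns: no correlation signal
  d <- stats::as.dist(1 - cm)
  stats::cutree(stats::hclust(d, method = "average"), k = K)
}

#' Proportion of ambiguously clustered pairs (PAC)
#'
#' PAC = F(u2) - F(u1), where F is the empirical CDF of the strictly
#' upper-triangular consensus entries: the fraction of sample pairs whose
#' consensus lies in the ambiguous interval (u1, u2]. Lower is crisper.
#'
#' @param consensus Consensus matrix from \code{\link{consensus_matrix}}.
#' @param u1,u2 Interval bounds (defaults 0.1 and 0.9).
#' @return PAC value in [0, 1].
#' @export
pac <- function(consensus, u1 = 0.1, u2 = 0.9) {
  stopifnot(is.matrix(consensus), nrow(consensus) == ncol(consensus))
  v <- consensus[upper.tri(consensus)]
  mean(v <= u2) - mean(v <= u1)
}

#' Consensus clustering with PAC-based selection of K
#'
#' Runs \code{\link{consensus_matrix}} for every K in \code{K_range},
#' computes PAC per K, picks the K with the lowest PAC (ties broken toward
#' the smaller K), and derives final labels by average-linkage clustering
#' of 1 - consensus at the chosen K. When even the best PAC exceeds 0.5
#' the result is flagged low-confidence.
#'
#' @inheritParams consensus_matrix
#' @param K_range Candidate cluster numbers (default 2:6).
#' @return A \code{consensus_result} list: \code{K_range},
#'   \code{consensus} (per-K matrices), \code{pac} (per-K), \code{chosen_K},
#'   \code{labels} (named cluster letters per sample),
#'   \code{low_confidence}.
#' @export
select_k_and_label <- function(matrix, K_range = 2:6, n_reps = 1000L,
                               p_item = 0.8, seed = 1L,
                               method = c("km", "hc"), nstart = 2L) {
  validate_expression(matrix)
  method <- match.arg(method)
  n <- ncol(matrix)
  if (any(K_range <= 1L) || any(K_range >= n))
    stop("K_range must lie within (1, n)")
  cons <- lapply(seq_along(K_range), function(i)
    consensus_matrix(matrix, K_range[i], n_reps = n_reps, p_item = p_item,
                     seed = seed + i - 1L, method = method, nstart = nstart))
  names(cons) <- paste0("K", K_range)
  pacs <- vapply(cons, pac, numeric(1))
  best <- which.min(pacs)              # which.min takes the first (smallest K)
  K <- K_range[best]
  h <- stats::hclust(stats::as.dist(1 - cons[[best]]), method = "average")
  raw <- stats::cutree(h, k = K)
  # relabel clusters by decreasing size: A = largest
  sizes <- sort(table(raw), decreasing = TRUE)
  relab <- stats::setNames(LETTERS[seq_along(sizes)], names(sizes))
  labels <- stats::setNames(unname(relab[as.character(raw)]), colnames(matrix))
  structure(list(K_range = K_range, consensus = cons,
                 pac = stats::setNames(pacs, names(cons)),
                 chosen_K = K, labels = labels,
                 low_confidence = min(pacs) > 0.5),
            class = "consensus_result")
}

#' @export
print.consensus_result <- function(x, ...) {
  cat("Consensus clustering over K =", paste(x$K_range, collapse = ", "), "\n")
  cat("  PAC:", paste(sprintf("%s=%.3f", names(x$pac), x$pac), collapse = "  "), "\n")
  cat("  chosen K =", x$chosen_K,
      if (x$low_confidence) "(low confidence: min PAC > 0.5)" else "", "\n")
  cat("  cluster sizes:", paste(names(table(x$labels)), table(x$labels),
                                sep = ":", collapse = "  "), "\n")
  invisible(x)
}
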