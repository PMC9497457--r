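#' Two-sided Wilcoxon rank-sum (Mann-Whitney) test
#'
#' Thin wrapper around the two-sample Mann-Whitney test used throughout the
#' pipeline: exact enumeration when both groups have at most 8 observations
#' and the pooled sample is tie-free, otherwise the normal approximation
#' with midrank tie handling and continuity correction.
#'
#' @param x,y Numeric vectors (both nonempty).
#' @return A one-row data.frame (\code{statistic}, \code{p_value},
#'   \code{effect}); \code{effect} is \code{mean(x) - mean(y)}.
#' @export
wilcoxon_rank_sum <- function(x, y) {
  stopifnot(length(x) >= 1L, length(y) >= 1L)
  pooled <- c(x, y)
  if (length(unique(pooled)) == 1L) {
    return(test_result(length(x) * length(y) / 2, 1, mean(x) - mean(y)))
  }
  exact <- length(x) <= 8L && length(y) <= 8L && !anyDuplicated(pooled)
  wt <- stats::wilcox.test(x, y, exact = exact, correct = TRUE,
                           alternative = "two.sided")
  test_result(unname(wt$statistic), wt$p.value, mean(x) - mean(y))
}

test_result <- function(statistic, p_value, effect = NA_real_,
                        adjusted_p = NA_real_) {
  data.frame(statistic = statistic, p_value = p_value, effect = effect,
             adjusted_p = adjusted_p)
}

#' Benjamini-Hochberg step-up adjusted p-values
#'
#' @param p Numeric vector of p-values in [0, 1].
#' @return Vector of BH-adjusted p-values (capped at 1).
#' @export
benjamini_hochberg <- function(p) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Correlation with a t-based p-value
#'
#' Pearson or Spearman correlation; in both cases the p-value comes from
#' the transform t = r * sqrt((n - 2) / (1 - r^2)) on n - 2 degrees of
#' freedom (for Spearman, applied to the rank correlation).
#'
#' @param x,y Numeric vectors of equal length >= 3, non-constant.
#' @param method \code{"pearson"} or \code{"spearman"}.
#' @return A one-row data.frame; \code{effect} holds r.
#' @export
correlation_test <- function(x, y, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  n <- length(x)
  stopifnot(length(y) == n)
  if (n < 3L) stop("need n >= 3 for a correlation test")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("constant vector: correlation undefined")
  r <- stats::cor(x, y, method = method)
  if (abs(r) >= 1 - 1e-12) {
    tstat <- sign(r) * Inf
    p <- 0
  } else {
    tstat <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  }
  test_result(tstat, p, r)
}

#' Moderated-t differential expression with the double DEG filter
#'
#' Per-gene differential expression between two groups via limma's
#' empirical-Bayes moderated t-statistic (gene-wise variances shrunk toward
#' a fitted inverse-chi-square prior), BH adjustment, and the conventional
#' DEG call |log2FC| > 1 and adjusted p < 0.05.
#'
#' @param matrix Expression matrix (genes x samples, log2 scale).
#' @param groups Vector of two group labels, one per sample. If one level
#'   is \code{"case"} the reported log2FC is case minus the other group,
#'   otherwise the second factor level minus the first.
#' @param lfc_cutoff,alpha DEG thresholds (defaults 1 and 0.05).
#' @return data.frame with one row per gene: \code{gene}, \code{log2fc},
#'   \code{statistic} (moderated t), \code{p_value}, \code{adjusted_p},
#'   \code{deg}.
#' @export
moderated_t_deg <- function(matrix, groups, lfc_cutoff = 1, alpha = 0.05) {
  validate_expression(matrix)
  f <- factor(groups)
  if (nlevels(f) != 2L) stop("exactly two groups required")
  if (any(table(f) < 2L)) stop("each group needs >=2 samples")
  if ("case" %in% levels(f)) f <- stats::relevel(f, ref = setdiff(levels(f), "case"))
  design <- stats::model.matrix(~f)
  fit <- limma::eBayes(limma::lmFit(matrix, design))
  tab <- limma::topTable(fit, coef = 2L, number = Inf, sort.by = "none",
                         adjust.method = "BH")
  data.frame(gene = rownames(matrix),
             log2fc = tab$logFC,
             statistic = tab$t,
             p_value = tab$P.Value,
             adjusted_p = tab$adj.P.Val,
             deg = abs(tab$logFC) > lfc_cutoff & tab$adj.P.Val < alpha,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Hypergeometric over-representation analysis
#'
#' Upper-tail hypergeometric test of each gene set's overlap with a hit
#' list (P[overlap >= observed]), BH-adjusted across sets, with fold
#' enrichment relative to the universe.
#'
#' @param hit_genes Character vector of hits (must be a subset of
#'   \code{universe}).
#' @param universe Character vector of all testable genes.
#' @param gene_sets Named list of character vectors (gene sets are
#'   intersected with the universe).
#' @return data.frame with one row per set: \code{set}, \code{set_size},
#'   \code{overlap}, \code{fold_enrichment}, \code{p_value},
#'   \code{adjusted_p}.
#' @export
hypergeometric_ora <- function(hit_genes, universe, gene_sets) {
  universe <- unique(universe)
  if (length(universe) == 0L) stop("empty universe")
  hit_genes <- unique(hit_genes)
  if (!all(hit_genes %in% universe))
    stop("hit_genes must be a subset of the universe")
  N <- length(universe)
  nh <- length(hit_genes)
  rows <- lapply(names(gene_sets), function(nm) {
    set <- intersect(unique(gene_sets[[nm]]), universe)
    k <- length(set)
    q <- length(intersect(set, hit_genes))
    p <- if (k == 0L) 1 else stats::phyper(q - 1, k, N - k, nh, lower.tail = FALSE)
    fold <- if (k == 0L || nh == 0L) NA_real_ else (q / nh) / (k / N)
    data.frame(set = nm, set_size = k, overlap = q,
               fold_enrichment = fold, p_value = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$adjusted_p <- benjamini_hochberg(out$p_value)
  out
}
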