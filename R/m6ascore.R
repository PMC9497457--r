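#' Per-sample methylation score from signature-gene PCA
#'
#' Runs a principal component analysis over samples on the centered (and,
#' by default, unit-variance scaled) signature-gene expression rows and
#' defines each sample's score as PC1 + PC2. The sign of each component is
#' fixed so that it correlates positively with the mean signature
#' expression, making the score deterministic.
#'
#' @param matrix Expression matrix (genes x samples).
#' @param signature_genes Gene ids of the signature (>= 2 present in the
#'   matrix; missing ids are dropped with a warning).
#' @param scale_genes Standardize genes to unit variance before the PCA
#'   (default TRUE).
#' @return An \code{m6a_score_table} data.frame: \code{sample_id},
#'   \code{pc1}, \code{pc2}, \code{score}; the variance explained is kept
#'   in the \code{var_explained} attribute.
#' @export
compute_m6ascore <- function(matrix, signature_genes, scale_genes = TRUE) {
  validate_expression(matrix)
  if (ncol(matrix) < 3L) stop("need >= 3 samples")
  genes <- intersect(signature_genes, rownames(matrix))
  if (length(genes) < length(signature_genes))
    warning("dropping ", length(signature_genes) - length(genes),
            " signature gene(s) absent from the matrix")
  genes <- genes[apply(matrix[genes, , drop = FALSE], 1L, stats::sd) > 0]
  if (length(genes) < 2L) stop("fewer than 2 usable (non-constant) signature genes")
  X <- t(matrix[genes, , drop = FALSE])              # samples x genes
  pca <- stats::prcomp(X, center = TRUE, scale. = scale_genes)
  pc <- pca$x[, 1:2, drop = FALSE]
  mean_expr <- rowMeans(X)
  for (k in 1:2) {
    r <- suppressWarnings(stats::cor(pc[, k], mean_expr))
    if (is.finite(r) && r < 0) pc[, k] <- -pc[, k]
  }
  out <- data.frame(sample_id = colnames(matrix),
                    pc1 = unname(pc[, 1L]), pc2 = unname(pc[, 2L]),
                    score = unname(pc[, 1L] + pc[, 2L]),
                    stringsAsFactors = FALSE)
  attr(out, "var_explained") <- (pca$sdev^2 / sum(pca$sdev^2))[1:2]
  attr(out, "scaled") <- scale_genes
  class(out) <- c("m6a_score_table", "data.frame")
  out
}

#' Split samples into high/low score groups
#'
#' @param table An \code{m6a_score_table}.
#' @param rule Threshold rule: \code{"median"} (default) or \code{"mean"}.
#'   High = score strictly above the threshold.
#' @return The table with a \code{score_group} column
#'   (\code{"high"}/\code{"low"}); threshold and rule stored as attributes.
#' @export
split_by_score <- function(table, rule = c("median", "mean")) {
  rule <- match.arg(rule)
  stopifnot(inherits(table, "m6a_score_table"), nrow(table) > 0L)
  if (stats::sd(table$score) == 0)
    stop("all scores identical: no high/low split exists")
  thr <- if (rule == "median") stats::median(table$score) else mean(table$score)
  table$score_group <- ifelse(table$score > thr, "high", "low")
  attr(table, "threshold") <- thr
  attr(table, "rule") <- rule
  table
}

#' Compare scores across labeled groups
#'
#' Omnibus nonparametric comparison of the score across groups: Wilcoxon
#' rank-sum for two groups, Kruskal-Wallis for three or more; when the
#' omnibus p is below \code{alpha}, all pairwise Wilcoxon comparisons are
#' reported with BH adjustment.
#'
#' @param labels Group label per table row (e.g. pattern or cluster).
#' @param table An \code{m6a_score_table}.
#' @param alpha Omnibus threshold gating the pairwise tests (default 0.05).
#' @return List with \code{omnibus} (one-row data.frame) and
#'   \code{pairwise} (data.frame or NULL).
#' @export
compare_scores_across <- function(labels, table, alpha = 0.05) {
  stopifnot(inherits(table, "m6a_score_table"), length(labels) == nrow(table))
  keep <- !is.na(labels)
  f <- factor(labels[keep])
  s <- table$score[keep]
  if (nlevels(f) < 2L) stop("need >= 2 labeled groups")
  if (nlevels(f) == 2L) {
    omni <- wilcoxon_rank_sum(s[f == levels(f)[1L]], s[f == levels(f)[2L]])
  } else {
    kw <- stats::kruskal.test(s, f)
    omni <- test_result(unname(kw$statistic), kw$p.value)
  }
  pairwise <- NULL
  if (omni$p_value < alpha && nlevels(f) > 2L) {
    prs <- utils::combn(levels(f), 2L, simplify = FALSE)
    pairwise <- do.call(rbind, lapply(prs, function(pr) {
      res <- wilcoxon_rank_sum(s[f == pr[1L]], s[f == pr[2L]])
      data.frame(group1 = pr[1L], group2 = pr[2L],
                 statistic = res$statistic, p_value = res$p_value)
    }))
    pairwise$adjusted_p <- benjamini_hochberg(pairwise$p_value)
  }
  list(omnibus = omni, pairwise = pairwise)
}

#' Cross-tabulate derived sample labels for alluvial/Sankey export
#'
#' Counts every observed combination of the requested label columns
#' (e.g. clinical subtype, pattern, lncRNA cluster, score group). The
#' count column sums to the number of annotated samples.
#'
#' @param annotation Sample annotation data.frame.
#' @param columns Label columns to cross (default the four derived ones
#'   that are present).
#' @return data.frame of label combinations plus \code{count}.
#' @export
crosstab_alluvial <- function(annotation,
                              columns = intersect(c("subtype", "pattern",
                                                    "lncrna_cluster",
                                                    "score_group"),
                                                  colnames(annotation))) {
  missing <- setdiff(columns, colnames(annotation))
  if (length(missing))
    stop("annotation is missing column(s): ", paste(missing, collapse = ", "))
  if (length(columns) == 0L) stop("no label columns to cross-tabulate")
  tab <- as.data.frame(table(annotation[columns], useNA = "ifany"),
                       stringsAsFactors = FALSE)
  names(tab)[ncol(tab)] <- "count"
  tab <- tab[tab$count > 0, , drop = FALSE]
  rownames(tab) <- NULL
  tab
}
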