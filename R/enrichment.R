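#' Read or write gene sets in GMT format
#'
#' Standard GMT: one set per line, tab-separated fields
#' \code{name<TAB>description<TAB>member1<TAB>member2...}. Duplicate
#' members within a set are stored once; a duplicated set name or a line
#' with fewer than three fields is an error (reported with its line
#' number).
#'
#' @param path GMT file path.
#' @return \code{read_gmt}: named list of character vectors, with the
#'   descriptions kept in the \code{descriptions} attribute.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(parts) < 3L)
  if (length(short))
    stop("GMT line ", short[1L], " has fewer than 3 fields")
  nms <- vapply(parts, `[[`, "", 1L)
  if (anyDuplicated(nms))
    stop("duplicated set name(s): ",
         paste(unique(nms[duplicated(nms)]), collapse = ", "))
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- nms
  attr(sets, "descriptions") <- stats::setNames(vapply(parts, `[[`, "", 2L), nms)
  sets
}

#' @rdname read_gmt
#' @param sets Named list of character vectors.
#' @param descriptions Optional per-set description (defaults to the name).
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  stopifnot(is.list(sets), !is.null(names(sets)))
  if (is.null(descriptions)) descriptions <- attr(sets, "descriptions")
  if (is.null(descriptions)) descriptions <- stats::setNames(names(sets), names(sets))
  lines <- vapply(names(sets), function(nm)
    paste(c(nm, descriptions[[nm]], sets[[nm]]), collapse = "\t"), "")
  writeLines(lines, path)
  invisible(path)
}

# drop sets with no overlap (warn) and check none swallows the universe
prepare_sets <- function(sets, genes) {
  sets <- lapply(sets, function(s) intersect(unique(s), genes))
  empty <- lengths(sets) == 0L
  if (any(empty)) {
    warning("dropping ", sum(empty), " set(s) with no gene overlap: ",
            paste(names(sets)[empty], collapse = ", "))
    sets <- sets[!empty]
  }
  if (length(sets) == 0L) stop("no gene set overlaps the expression matrix")
  full <- lengths(sets) >= length(genes)
  if (any(full))
    stop("set(s) covering every gene (empty out-set): ",
         paste(names(sets)[full], collapse = ", "))
  sets
}

#' Single-sample GSEA (ssGSEA) enrichment scores
#'
#' Per sample, genes are ranked by expression (midranks for ties) and each
#' set is scored by the integrated weighted Kolmogorov-Smirnov walk: at
#' each position in the descending ranking the in-set step is
#' rank^alpha / sum(in-set rank^alpha) and the out-set step is
#' 1 / (N - |S|); the enrichment score is the sum of the running walk
#' values. With \code{normalize = TRUE} all scores are divided by the
#' global (max - min) of the score matrix, so the global range is exactly 1.
#'
#' @param matrix Expression matrix (genes x samples).
#' @param sets Named list of gene sets (intersected with the matrix genes;
#'   zero-overlap sets are dropped with a warning).
#' @param alpha Rank weighting exponent (default 0.25).
#' @param normalize Apply the global range normalization (default TRUE).
#' @return Sets x samples score matrix with attribute \code{method}.
#' @export
ssgsea_scores <- function(matrix, sets, alpha = 0.25, normalize = TRUE) {
  validate_expression(matrix)
  sets <- prepare_sets(sets, rownames(matrix))
  N <- nrow(matrix)
  genes <- rownames(matrix)
  memb <- lapply(sets, function(s) genes %in% s)
  scores <- matrix(NA_real_, length(sets), ncol(matrix),
                   dimnames = list(names(sets), colnames(matrix)))
  for (j in seq_len(ncol(matrix))) {
    r <- rank(matrix[, j], ties.method = "average")   # higher expr = higher rank
    ord <- order(r, decreasing = TRUE)
    r_ord <- r[ord]
    for (k in seq_along(sets)) {
      inset <- memb[[k]][ord]
      w <- ifelse(inset, abs(r_ord)^alpha, 0)
      step_in <- cumsum(w) / sum(w)
      step_out <- cumsum(!inset) / (N - sum(inset))
      scores[k, j] <- sum(step_in - step_out)
    }
  }
  if (normalize) scores <- scores / (max(scores) - min(scores))
  attr(scores, "method") <- "ssgsea"
  scores
}

#' GSVA enrichment scores
#'
#' Gene set variation analysis: each gene's expression is first mapped to
#' a relative statistic across samples through a Gaussian-kernel empirical
#' CDF (bandwidth = per-gene SD / 4); per sample, genes are ranked by that
#' statistic and weighted by the symmetric rank statistic |N/2 - rank|
#' raised to \code{tau}; a KS-like random walk over the descending ranking
#' yields the score as the signed sum of its maximum positive and maximum
#' negative deviations (the "mx.diff" convention).
#'
#' @inheritParams ssgsea_scores
#' @param tau Weighting exponent on the symmetric rank statistic (default 1).
#' @return Sets x samples score matrix with attribute \code{method}.
#' @export
gsva_scores <- function(matrix, sets, tau = 1) {
  validate_expression(matrix)
  n <- ncol(matrix)
  if (n < 3L) stop("GSVA needs >= 3 samples for the cross-sample kernel CDF")
  sets <- prepare_sets(sets, rownames(matrix))
  N <- nrow(matrix)
  genes <- rownames(matrix)

  # Gaussian-kernel CDF of each sample's value within its gene's distribution
  z <- matrix(0.5, N, n, dimnames = dimnames(matrix))
  for (g in seq_len(N)) {
    x <- matrix[g, ]
    h <- stats::sd(x) / 4
    if (h > 0)
      z[g, ] <- rowMeans(stats::pnorm(outer(x, x, "-") / h))
  }

  memb <- lapply(sets, function(s) genes %in% s)
  scores <- matrix(NA_real_, length(sets), n,
                   dimnames = list(names(sets), colnames(matrix)))
  for (j in seq_len(n)) {
    ord <- order(z[, j], decreasing = TRUE)
    rnk <- seq_len(N)                       # position in the descending order
    stat <- abs(N / 2 - rnk)^tau
    for (k in seq_along(sets)) {
      inset <- memb[[k]][ord]
      w <- ifelse(inset, stat, 0)
      walk <- cumsum(w) / sum(w) - cumsum(!inset) / (N - sum(inset))
      scores[k, j] <- max(c(0, walk[walk > 0])) + min(c(0, walk[walk < 0]))
    }
  }
  attr(scores, "method") <- "gsva"
  scores
}

#' Per-row group-difference report
#'
#' Row-wise nonparametric group comparison for score or expression
#' matrices: two groups give a Wilcoxon rank-sum test per row, three or
#' more give Kruskal-Wallis; p-values are BH-adjusted within the named
#' family. Used for immune-cell panels, immune reactions, HLA-style gene
#' panels and regulator panels alike.
#'
#' @param values Rows x samples numeric matrix (scores or expression).
#' @param labels Group label per sample (>= 2 nonempty groups).
#' @param family Label recorded on the output (one BH family per call).
#' @return data.frame: \code{feature}, \code{statistic}, \code{p_value},
#'   \code{adjusted_p}, \code{effect} (two groups: difference of means;
#'   otherwise NA), \code{family}.
#' @export
group_difference_report <- function(values, labels, family = "default") {
  stopifnot(is.matrix(values), ncol(values) == length(labels))
  f <- factor(labels)
  if (nlevels(f) < 2L) stop("need >= 2 groups")
  if (any(table(f) == 0L)) stop("group with 0 samples")
  two <- nlevels(f) == 2L
  rows <- lapply(seq_len(nrow(values)), function(i) {
    v <- values[i, ]
    if (two) {
      res <- wilcoxon_rank_sum(v[f == levels(f)[1L]], v[f == levels(f)[2L]])
      data.frame(feature = rownames(values)[i], statistic = res$statistic,
                 p_value = res$p_value, effect = res$effect)
    } else {
      kw <- stats::kruskal.test(v, f)
      data.frame(feature = rownames(values)[i],
                 statistic = unname(kw$statistic),
                 p_value = kw$p.value, effect = NA_real_)
    }
  })
  out <- do.call(rbind, rows)
  out$adjusted_p <- benjamini_hochberg(out$p_value)
  out$family <- family
  out
}
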