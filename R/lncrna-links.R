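#' Select regulator-related lncRNAs by correlation thresholding
#'
#' Computes the Pearson correlation of every candidate lncRNA against
#' every regulator of the requested modification and retains a lncRNA when
#' at least one pair satisfies |r| > \code{r_thresh} and p < \code{p_thresh}
#' (strict inequalities; p from the t transform on n - 2 df). All passing
#' pairs are stored.
#'
#' @param matrix Expression matrix (genes x samples).
#' @param lncrna_ids Candidate lncRNA gene ids (ids absent from the matrix
#'   are skipped with a warning).
#' @param catalog Regulator catalog data.frame (gene, modification, role),
#'   e.g. \code{\link{regulator_catalog}}.
#' @param modification Which modification's regulators to use
#'   (\code{"m6A"} or \code{"m5C"}).
#' @param r_thresh,p_thresh Retention thresholds (defaults 0.4 and 0.001).
#' @return A \code{lncrna_link_set}: list with \code{lncrnas} (retained
#'   ids, sorted), \code{links} (data.frame lncrna, regulator, r, p_value)
#'   and \code{modification}.
#' @export
select_related_lncrnas <- function(matrix, lncrna_ids, catalog,
                                   modification = c("m6A", "m5C"),
                                   r_thresh = 0.4, p_thresh = 0.001) {
  validate_expression(matrix)
  modification <- match.arg(modification)
  regs <- catalog$gene[catalog$modification == modification]
  regs_in <- intersect(regs, rownames(matrix))
  if (length(regs_in) == 0L)
    stop("no ", modification, " regulators found in the matrix")
  if (length(regs_in) < length(regs))
    warning("skipping ", length(regs) - length(regs_in),
            " regulator(s) absent from the matrix")
  lnc_in <- intersect(lncrna_ids, rownames(matrix))
  if (length(lnc_in) < length(lncrna_ids))
    warning("skipping ", length(lncrna_ids) - length(lnc_in),
            " lncRNA id(s) absent from the matrix")

  n <- ncol(matrix)
  R <- suppressWarnings(stats::cor(t(matrix[lnc_in, , drop = FALSE]),
                                   t(matrix[regs_in, , drop = FALSE])))
  R[!is.finite(R)] <- 0
  tstat <- R * sqrt((n - 2) / pmax(1 - R^2, 1e-300))
  P <- 2 * stats::pt(-abs(tstat), df = n - 2)
  pass <- abs(R) > r_thresh & P < p_thresh
  idx <- which(pass, arr.ind = TRUE)
  links <- data.frame(lncrna = lnc_in[idx[, 1L]],
                      regulator = regs_in[idx[, 2L]],
                      r = R[pass], p_value = P[pass],
                      stringsAsFactors = FALSE)
  links <- links[order(links$lncrna, links$regulator), , drop = FALSE]
  rownames(links) <- NULL
  structure(list(lncrnas = sort(unique(links$lncrna)), links = links,
                 modification = modification,
                 r_thresh = r_thresh, p_thresh = p_thresh),
            class = "lncrna_link_set")
}

#' Intersect two lncRNA link sets
#'
#' @param a,b \code{lncrna_link_set} objects (e.g. the m6A- and
#'   m5C-related selections).
#' @return Sorted character vector of lncRNA ids retained in both.
#' @export
intersect_link_sets <- function(a, b) {
  stopifnot(inherits(a, "lncrna_link_set"), inherits(b, "lncrna_link_set"))
  sort(intersect(a$lncrnas, b$lncrnas))
}
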