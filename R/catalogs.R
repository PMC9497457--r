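#' Regulator catalogs for m6A and m5C RNA methylation
#'
#' Returns the packaged catalog of epitranscriptomic regulator genes with
#' their functional role: writers (methyltransferases), erasers
#' (demethylases) and readers (binding proteins). The m6A panel holds 26
#' genes (9 writers, 3 erasers, 14 readers); the m5C panel holds 14 genes
#' (10 writers, 3 erasers, 1 reader). Both are transcribed-from-publication
#' gene panels shipped under \code{inst/extdata}.
#'
#' @param modification Which mark, \code{"m6A"} or \code{"m5C"}.
#' @return A data.frame with columns \code{gene}, \code{modification},
#'   \code{role}.
#' @examples
#' cat6 <- regulator_catalog("m6A")
#' table(cat6$role)
#' @export
regulator_catalog <- function(modification = c("m6A", "m5C")) {
  modification <- match.arg(modification)
  file <- if (modification == "m6A") "m6a_regulators.tsv" else "m5c_regulators.tsv"
  path <- system.file("extdata", file, package = "m6aPatterns", mustWork = TRUE)
  cat <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(!anyDuplicated(cat$gene),
            all(cat$role %in% c("writer", "eraser", "reader")))
  cat
}

#' Published diagnostic signatures
#'
#' The two diagnostic feature panels reported for juvenile idiopathic
#' arthritis: 14 m6A regulator genes selected by the univariate-logistic +
#' LASSO screen, and 8 regulator-related lncRNAs selected the same way.
#'
#' @param type \code{"regulator"} for the 14-gene m6A regulator signature,
#'   \code{"lncrna"} for the 8-lncRNA signature.
#' @return Character vector of gene identifiers.
#' @export
diagnostic_signature <- function(type = c("regulator", "lncrna")) {
  type <- match.arg(type)
  file <- if (type == "regulator") "diagnostic_regulators.txt" else "diagnostic_lncrnas.txt"
  path <- system.file("extdata", file, package = "m6aPatterns", mustWork = TRUE)
  readLines(path)
}
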