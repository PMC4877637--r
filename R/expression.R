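#' Pseudocounted fold change
#'
#' Ratio of two non-negative relative-expression values with a shared
#' pseudocount \code{epsilon} added to numerator and denominator:
#' \code{(num + eps) / (den + eps)}. The symmetric pseudocount keeps
#' \code{foldChange(x, x) = 1}, makes reactivation from complete silence
#' register as a large finite fold, and converges to the plain ratio as
#' \code{epsilon} approaches 0 for strictly positive inputs.
#'
#' @param numerator,denominator non-negative expression values (vectorized)
#' @param epsilon pseudocount (default 1e-3)
#' @return strictly positive numeric fold change.
#' @examples
#' foldChange(8, 1)    # ~ 8-fold
#' foldChange(0, 0)    # 1: no change
#' foldChange(5, 0)    # ~ 5001: reactivation from silence
#' @export
foldChange <- function(numerator, denominator, epsilon = 1e-3) {
  if (any(numerator < 0) || any(denominator < 0))
    stop("expression values must be non-negative", call. = FALSE)
  stopifnot(epsilon > 0)
  (numerator + epsilon) / (denominator + epsilon)
}

#' Two-criterion silencing verdict for one gene
#'
#' Applies the expression evidence for epigenetic silencing to one gene's
#' measurements across conditions: (a) the gene is expressed in normal
#' colon (value at least \code{expressedMin}) and downregulated more than
#' \code{foldMin}-fold in the tumor line relative to normal colon; (b) it
#' is reactivated more than \code{foldMin}-fold by demethylating-drug
#' treatment of the tumor line or in the DNMT-knockout derivative
#' (disjunction by default; \code{requireBoth = TRUE} demands both). All
#' fold comparisons are strict. A missing drug or knockout condition makes
#' the corresponding reactivation flag FALSE; a missing normal-colon or
#' tumor-line value makes the gene not evaluable.
#'
#' @param measures \code{data.frame} with columns \code{condition} and
#'   \code{value} for one gene (conditions \code{normal_colon},
#'   \code{tumor_line}, optional \code{tumor_line_aza},
#'   \code{demethylated_line})
#' @param foldMin fold-change threshold, exclusive (default 2)
#' @param expressedMin minimum relative expression defining "expressed in
#'   normal colon" (default 0.01)
#' @param epsilon pseudocount passed to \code{\link{foldChange}}
#' @param requireBoth require reactivation under both the drug and the
#'   knockout (default FALSE: either suffices)
#' @return one-row \code{data.frame}: flags \code{expressed_in_normal},
#'   \code{down_in_tumor}, \code{reactivated_aza}, \code{reactivated_ko},
#'   \code{criterion_a}, \code{criterion_b}, \code{passes},
#'   \code{evaluable}, and folds \code{fold_down}, \code{fold_aza},
#'   \code{fold_ko}.
#' @export
judgeGene <- function(measures, foldMin = 2, expressedMin = 0.01,
                      epsilon = 1e-3, requireBoth = FALSE) {
  val <- function(cond) {
    v <- measures$value[measures$condition == cond]
    if (length(v) == 0L) NA_real_ else v[1]
  }
  normal <- val("normal_colon"); tumor <- val("tumor_line")
  aza <- val("tumor_line_aza"); ko <- val("demethylated_line")
  if (is.na(normal) || is.na(tumor)) {
    return(data.frame(expressed_in_normal = NA, down_in_tumor = NA,
                      reactivated_aza = NA, reactivated_ko = NA,
                      criterion_a = NA, criterion_b = NA, passes = NA,
                      evaluable = FALSE, fold_down = NA_real_,
                      fold_aza = NA_real_, fold_ko = NA_real_))
  }
  fold_down <- foldChange(normal, tumor, epsilon)
  fold_aza <- if (is.na(aza)) NA_real_ else foldChange(aza, tumor, epsilon)
  fold_ko <- if (is.na(ko)) NA_real_ else foldChange(ko, tumor, epsilon)
  expressed_in_normal <- normal >= expressedMin
  down_in_tumor <- fold_down > foldMin
  reactivated_aza <- !is.na(fold_aza) && fold_aza > foldMin
  reactivated_ko <- !is.na(fold_ko) && fold_ko > foldMin
  criterion_a <- expressed_in_normal && down_in_tumor
  criterion_b <- if (requireBoth) reactivated_aza && reactivated_ko
                 else reactivated_aza || reactivated_ko
  data.frame(expressed_in_normal = expressed_in_normal,
             down_in_tumor = down_in_tumor,
             reactivated_aza = reactivated_aza,
             reactivated_ko = reactivated_ko,
             criterion_a = criterion_a, criterion_b = criterion_b,
             passes = criterion_a && criterion_b, evaluable = TRUE,
             fold_down = fold_down, fold_aza = fold_aza, fold_ko = fold_ko)
}

#' Silencing verdicts for a whole expression table
#'
#' Applies \code{\link{judgeGene}} to every gene in a long-format
#' expression table.
#'
#' @param expression \code{data.frame} with columns \code{gene_id},
#'   \code{condition}, \code{value} (\code{\link{readExpression}})
#' @param ... passed to \code{\link{judgeGene}}
#' @return \code{data.frame} with one row per gene, \code{gene_id} first.
#' @export
judgeExpression <- function(expression, ...) {
  ids <- unique(expression$gene_id)
  out <- do.call(rbind, lapply(ids, function(g)
    judgeGene(expression[expression$gene_id == g, , drop = FALSE], ...)))
  cbind(data.frame(gene_id = ids, stringsAsFactors = FALSE), out)
}
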