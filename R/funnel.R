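#' Format a count fraction as a percent string
#'
#' Formats \code{numerator / denominator} as a percentage with one decimal
#' place, rounding half away from zero (so 44.75 prints as "44.8%", not
#' banker's-rounded).
#'
#' @param numerator,denominator non-negative counts;
#'   \code{numerator <= denominator}, \code{denominator > 0}
#' @return character, e.g. \code{"20.9\%"}.
#' @examples
#' formatFraction(399, 1027)
#' @export
formatFraction <- function(numerator, denominator) {
  if (any(denominator <= 0)) stop("denominator must be positive", call. = FALSE)
  if (any(numerator < 0) || any(numerator > denominator))
    stop("need 0 <= numerator <= denominator", call. = FALSE)
  pct <- 100 * numerator / denominator
  sprintf("%.1f%%", floor(pct * 10 + 0.5) / 10)
}

.pct1 <- function(num, den) {
  if (den == 0) return(NA_real_)
  floor(100 * num / den * 10 + 0.5) / 10
}

#' Collapse transcript-level screen records to genes
#'
#' A gene passes under \code{any_tss} (default) when any of its
#' transcripts passes — a gene silenced at any promoter is a candidate —
#' and under \code{all_tss} when all do. NA (not-evaluated) transcript
#' flags count as non-passing.
#'
#' @param records \code{data.frame} of transcript-level records with
#'   \code{gene_id} and a logical \code{final_hit} column
#' @param mode \code{"any_tss"} or \code{"all_tss"}
#' @return \code{data.frame}: \code{gene_id}, \code{n_tss},
#'   \code{final_hit}.
#' @export
collapseToGenes <- function(records, mode = c("any_tss", "all_tss")) {
  mode <- match.arg(mode)
  flag <- records$final_hit
  flag[is.na(flag)] <- FALSE
  agg <- if (mode == "any_tss") any else all
  ids <- unique(records$gene_id)
  hit <- vapply(ids, function(g) agg(flag[records$gene_id == g]), logical(1))
  n <- vapply(ids, function(g) sum(records$gene_id == g), integer(1))
  data.frame(gene_id = ids, n_tss = n, final_hit = unname(hit),
             stringsAsFactors = FALSE)
}

#' Default screen thresholds
#'
#' The threshold set used by \code{\link{runScreen}}: H3K4me3 window
#' halfwidth 2000 bp, broad-mark halfwidth 5000 bp, promoter halfwidth
#' 500 bp, CpG depth filter 10 reads, 3 CpGs for availability, tumor
#' methylation > 60\%, all normals < 40\%, fold threshold 2, expression
#' floor 0.01, quantitative gain mode with minimum signal ratio 2,
#' gene collapse by any transcript.
#'
#' @param ... named overrides of any default
#' @return named list of thresholds.
#' @export
screenConfig <- function(...) {
  cfg <- list(k4Halfwidth = 2000, broadHalfwidth = 5000,
              promoterHalfwidth = 500, minDepth = 10, minCpgs = 3,
              tumorMin = 60, normalMax = 40, normalsMode = "all",
              foldMin = 2, expressedMin = 0.01, epsilon = 1e-3,
              gainMode = "quantitative", minRatio = 2,
              collapseMode = "any_tss",
              parentLine = "tumor_line", derivativeLine = "demethylated_line",
              tumorTissue = "tumor_line")
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown))
    stop(sprintf("unknown screen option(s): %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  cfg[names(dots)] <- dots
  cfg
}

#' Run the full silencing screen
#'
#' Executes the integrative screen on a \code{\link{ScreenBundle}} in the
#' fixed stage order: (1) the TSS universe; (2) H3K4me3 positivity in the
#' parent and/or demethylated line; (3) H3K4me3 gain after demethylation;
#' (4) promoter RRBS availability in tumor plus at least one normal;
#' (5) cancer-specific methylation (tumor high, normals low); (6) promoter
#' CGI; (7) expression validation (expressed in normal colon, downregulated
#' in the tumor line, reactivated by demethylation). Each stage is
#' evaluated only for survivors of the previous stage; non-survivors carry
#' \code{NA} ("not evaluated") for later flags, so a failed early stage is
#' distinguishable from a failed late one.
#'
#' @param bundle a \code{\link{ScreenBundle}}
#' @param config threshold list from \code{\link{screenConfig}}
#' @return a \code{\linkS4class{ScreenResult}} with per-transcript
#'   records, the staged funnel table, the two-line H3K4me3 status table,
#'   the fraction of gained TSSs with a parent-line H3K27me3 mark, and the
#'   gene-level hit list.
#' @export
runScreen <- function(bundle, config = screenConfig()) {
  stopifnot(is(bundle, "ScreenBundle"))
  tss <- bundle@tss
  ids <- mcols(tss)$transcript_id
  pk <- function(mark, line) {
    nm <- paste0(mark, ":", line)
    if (nm %in% names(bundle@peaks)) bundle@peaks[[nm]] else GRanges()
  }

  k4_parent <- callMark(tss, pk("H3K4me3", config$parentLine), config$k4Halfwidth)
  k4_deriv <- callMark(tss, pk("H3K4me3", config$derivativeLine), config$k4Halfwidth)
  k27_parent <- callMark(tss, pk("H3K27me3", config$parentLine), config$broadHalfwidth)
  gain <- detectGain(k4_parent, k4_deriv, mode = config$gainMode,
                     minRatio = config$minRatio)

  k4_any <- k4_parent$positive | k4_deriv$positive
  k4_gained <- gain$gained

  if (!config$tumorTissue %in% names(bundle@cpg))
    stop(sprintf("tumor methylome '%s' not in bundle", config$tumorTissue),
         call. = FALSE)
  tumor_sum <- summarizePromoter(bundle@cpg[[config$tumorTissue]], tss,
                                 config$promoterHalfwidth, config$minDepth,
                                 config$minCpgs)
  normal_names <- setdiff(names(bundle@cpg), config$tumorTissue)
  normal_sums <- lapply(bundle@cpg[normal_names], summarizePromoter, tss = tss,
                        halfwidth = config$promoterHalfwidth,
                        minDepth = config$minDepth, minCpgs = config$minCpgs)
  meth <- cancerSpecificFilter(tumor_sum, normal_sums,
                               tumorMin = config$tumorMin,
                               normalMax = config$normalMax,
                               normalsMode = config$normalsMode)
  cgi <- cgiOverlap(tss, bundle@cgi, config$promoterHalfwidth)
  verdicts <- judgeExpression(bundle@expression, foldMin = config$foldMin,
                              expressedMin = config$expressedMin,
                              epsilon = config$epsilon)

  ## staged evaluation: a stage is NA unless every earlier stage passed
  rrbs_available <- ifelse(k4_gained, meth$evaluable, NA)
  meth_pass <- ifelse(!is.na(rrbs_available) & rrbs_available,
                      meth$passes, NA)
  cgi_pass <- ifelse(!is.na(meth_pass) & meth_pass, cgi, NA)
  gidx <- match(mcols(tss)$gene_id, verdicts$gene_id)
  expr_ok <- verdicts$passes[gidx]
  expr_pass <- ifelse(!is.na(cgi_pass) & cgi_pass,
                      !is.na(expr_ok) & expr_ok, NA)
  final_hit <- !is.na(expr_pass) & expr_pass

  records <- data.frame(
    transcript_id = ids, gene_id = mcols(tss)$gene_id,
    k4_positive_any = k4_any, k4_gained = k4_gained,
    k27_parent = k27_parent$positive,
    rrbs_available = rrbs_available, meth_pass = meth_pass,
    cgi_pass = cgi_pass, expr_pass = expr_pass, final_hit = final_hit,
    stringsAsFactors = FALSE)
  records <- records[order(records$transcript_id), ]
  rownames(records) <- NULL

  tcount <- function(x) sum(!is.na(x) & x)
  counts <- c(universe = length(ids),
              k4_positive_any = tcount(k4_any),
              k4_gained = tcount(k4_gained),
              rrbs_available = tcount(rrbs_available),
              meth_pass = tcount(meth_pass),
              cgi_pass = tcount(cgi_pass),
              expr_pass = tcount(expr_pass))
  prev <- c(NA, counts[-length(counts)])
  funnel <- data.frame(
    stage = names(counts), count = as.integer(counts),
    pct_of_previous = mapply(function(n, d)
      if (is.na(d) || d == 0) NA_real_ else .pct1(n, d), counts, prev),
    pct_of_universe = vapply(counts, function(n)
      if (counts[1] == 0) NA_real_ else .pct1(n, counts[1]), numeric(1)),
    stringsAsFactors = FALSE)
  rownames(funnel) <- NULL

  n_gained <- sum(k4_gained)
  k27frac <- if (n_gained) sum(k27_parent$positive[k4_gained]) / n_gained else NA_real_

  genes <- collapseToGenes(records, mode = config$collapseMode)
  new("ScreenResult", records = records, funnel = funnel,
      k4Status = k4StatusCounts(k4_parent, k4_deriv),
      k27GainedFraction = k27frac,
      geneHits = sort(genes$gene_id[genes$final_hit]),
      config = config)
}
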