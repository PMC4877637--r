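.meth_bins <- c("0-20%", "20-40%", "40-60%", "60-80%", "80-100%")

#' Five-bin promoter methylation category
#'
#' Maps a percent methylation level onto the five stratification bins
#' 0-20\%, 20-40\%, 40-60\%, 60-80\%, 80-100\%. Bins are lower-inclusive
#' and upper-exclusive except the top bin, which is closed at 100 so that
#' the bins partition [0, 100]: 20.0 falls in 20-40\%, 100.0 in 80-100\%.
#'
#' @param level percent methylation in [0, 100] (vectorized)
#' @return factor with the five bin labels as levels.
#' @examples
#' binLevel(c(0, 19.9, 20, 65, 100))
#' @export
binLevel <- function(level) {
  if (any(is.na(level)) || any(level < 0 | level > 100))
    stop("methylation level must lie in [0, 100]", call. = FALSE)
  idx <- pmin(findInterval(level, c(0, 20, 40, 60, 80)), 5L)
  factor(.meth_bins[idx], levels = .meth_bins)
}

#' Summarize promoter methylation from CpG counts
#'
#' For each TSS, averages the per-CpG methylation levels of sufficiently
#' covered CpG sites inside the promoter window (0-based
#' \code{[tss - halfwidth, tss + halfwidth)}; default +/-500 bp). Sites
#' with fewer than \code{minDepth} reads are excluded; a promoter is
#' \code{available} only when at least \code{minCpgs} sites survive —
#' unavailability models the incomplete CpG coverage of
#' reduced-representation bisulfite sequencing and is a value, not an
#' error. The summary is the unweighted mean of per-site levels (the
#' conventional region-level RRBS percentage); set
#' \code{weighted = TRUE} for a read-weighted mean.
#'
#' @param cpg width-1 CpG \code{GRanges} from one tissue
#'   (\code{\link{readCpgCoverage}})
#' @param tss width-1 TSS \code{GRanges}
#' @param halfwidth promoter window halfwidth in bp (default 500)
#' @param minDepth minimum reads per CpG site (default 10)
#' @param minCpgs minimum surviving CpGs per promoter (default 3)
#' @param weighted read-weight the mean instead of averaging site levels
#' @return \code{data.frame}: \code{transcript_id}, \code{tissue},
#'   \code{mean_level} (percent; NA when unavailable), \code{n_cpgs},
#'   \code{available}, \code{bin} (factor; NA when unavailable).
#' @export
summarizePromoter <- function(cpg, tss, halfwidth = 500, minDepth = 10,
                              minCpgs = 3, weighted = FALSE) {
  win <- tssWindow(tss, halfwidth)
  keep <- mcols(cpg)$total_reads >= minDepth
  cpg <- cpg[keep]
  hits <- findOverlaps(win, cpg, ignore.strand = TRUE)
  q <- S4Vectors::queryHits(hits); s <- S4Vectors::subjectHits(hits)
  lev <- mcols(cpg)$meth_reads / mcols(cpg)$total_reads
  n_cpgs <- integer(length(tss))
  tabn <- table(q)
  n_cpgs[as.integer(names(tabn))] <- as.integer(tabn)
  mean_level <- rep(NA_real_, length(tss))
  if (length(hits)) {
    m <- if (weighted) {
      num <- tapply(mcols(cpg)$meth_reads[s], q, sum)
      den <- tapply(mcols(cpg)$total_reads[s], q, sum)
      num / den
    } else {
      tapply(lev[s], q, mean)
    }
    mean_level[as.integer(names(m))] <- 100 * as.numeric(m)
  }
  available <- n_cpgs >= minCpgs
  mean_level[!available] <- NA_real_
  bin <- factor(rep(NA_character_, length(tss)), levels = .meth_bins)
  bin[available] <- binLevel(mean_level[available])
  tissue <- metadata(cpg)$tissue
  data.frame(transcript_id = mcols(tss)$transcript_id,
             tissue = rep(if (is.null(tissue)) NA_character_ else tissue,
                          length.out = length(tss)),
             mean_level = mean_level, n_cpgs = n_cpgs,
             available = available, bin = bin,
             stringsAsFactors = FALSE)
}

#' Cancer-specific promoter methylation filter
#'
#' Flags promoters methylated at high levels in the tumor line (strictly
#' above \code{tumorMin} percent, default 60) and at low levels in the
#' normal tissues (strictly below \code{normalMax} percent, default 40).
#' By default every available normal tissue must be low
#' (\code{normalsMode = "all"}, the strictest reading); \code{"any"}
#' requires only one. Unavailable normals are ignored; a transcript whose
#' tumor summary is unavailable, or with no available normal, is not
#' evaluable (\code{NA} flags) rather than failing.
#'
#' @param tumor promoter summary \code{data.frame} for the tumor line
#'   (\code{\link{summarizePromoter}})
#' @param normals list of promoter summary \code{data.frame}s, one per
#'   normal tissue, over the same transcripts
#' @param tumorMin tumor methylation threshold in percent (exclusive)
#' @param normalMax normal methylation ceiling in percent (exclusive)
#' @param normalsMode \code{"all"} (default) or \code{"any"}
#' @return \code{data.frame}: \code{transcript_id}, \code{tumor_high},
#'   \code{normals_low}, \code{evaluable}, \code{passes}.
#' @export
cancerSpecificFilter <- function(tumor, normals, tumorMin = 60,
                                 normalMax = 40,
                                 normalsMode = c("all", "any")) {
  normalsMode <- match.arg(normalsMode)
  ids <- tumor$transcript_id
  nrm_levels <- vapply(normals, function(nf) {
    nf <- nf[match(ids, nf$transcript_id), ]
    ifelse(nf$available, nf$mean_level, NA_real_)
  }, numeric(length(ids)))
  nrm_levels <- matrix(nrm_levels, nrow = length(ids))
  n_avail <- rowSums(!is.na(nrm_levels))
  evaluable <- tumor$available & n_avail >= 1L
  tumor_high <- ifelse(evaluable, tumor$mean_level > tumorMin, NA)
  low <- nrm_levels < normalMax
  normals_low <- ifelse(evaluable,
                        if (normalsMode == "all")
                          rowSums(!low, na.rm = TRUE) == 0
                        else rowSums(low, na.rm = TRUE) > 0,
                        NA)
  data.frame(transcript_id = ids, tumor_high = as.logical(tumor_high),
             normals_low = as.logical(normals_low), evaluable = evaluable,
             passes = as.logical(tumor_high & normals_low),
             stringsAsFactors = FALSE)
}

#' CpG-island overlap with the promoter window
#'
#' A transcript has a promoter CGI when any CpG-island interval overlaps
#' its promoter window (the same 0-based \code{[tss - halfwidth,
#' tss + halfwidth)} window used for the methylation summary; one shared
#' base suffices).
#'
#' @param tss width-1 TSS \code{GRanges}
#' @param cgi CGI \code{GRanges}
#' @param halfwidth promoter window halfwidth in bp (default 500)
#' @return logical vector parallel to \code{tss}.
#' @export
cgiOverlap <- function(tss, cgi, halfwidth = 500) {
  win <- tssWindow(tss, halfwidth)
  IRanges::overlapsAny(win, cgi, ignore.strand = TRUE)
}
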