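#' @import methods
#' @importFrom S4Vectors mcols mcols<- DataFrame metadata metadata<-
#' @importFrom GenomicRanges GRanges seqnames start end strand strand<- granges
#' @importFrom IRanges IRanges findOverlaps
NULL

setClassUnion("data.frameOrNULL", c("data.frame", "NULL"))

#' Container for one complete screen input bundle
#'
#' A \code{ScreenBundle} holds every input the silencing screen consumes:
#' the transcript/TSS annotation, CpG-island intervals, per-mark and
#' per-cell-line ChIP-seq peak sets, per-tissue CpG bisulfite counts, the
#' expression table across the four conditions, the clinical cohort table,
#' and (for simulated bundles) the planted truth set.
#'
#' Interval data are stored as \link[GenomicRanges]{GRanges} using the
#' Bioconductor 1-based closed convention; BED-style 0-based half-open
#' coordinates are converted at the I/O boundary.
#'
#' @slot tss \code{GRanges} of width-1 TSS positions with metadata columns
#'   \code{transcript_id} and \code{gene_id}.
#' @slot cgi \code{GRanges} of CpG-island intervals.
#' @slot peaks named \code{list} of \code{GRanges}; names are
#'   \code{"<mark>:<cell_line>"} (e.g. \code{"H3K4me3:tumor_line"}), each with
#'   a numeric \code{score} column (non-negative).
#' @slot cpg named \code{list} of \code{GRanges}, one per tissue, width-1
#'   CpG sites with integer columns \code{meth_reads} and \code{total_reads}.
#' @slot expression \code{data.frame} with columns \code{gene_id},
#'   \code{condition}, \code{value}.
#' @slot clinical \code{data.frame} with columns \code{sample_id},
#'   \code{group}, \code{methylation}, and optional \code{expression},
#'   \code{surv_time}, \code{event}.
#' @slot truth \code{data.frame} (or NULL) with at least \code{gene_id} and
#'   \code{is_silenced}; present for simulated bundles.
#' @slot config \code{list} of the generator/screen parameters in force.
#'
#' @seealso \code{\link{generateBundle}}, \code{\link{runScreen}}
#' @export
setClass("ScreenBundle",
  representation(
    tss = "GRanges",
    cgi = "GRanges",
    peaks = "list",
    cpg = "list",
    expression = "data.frame",
    clinical = "data.frame",
    truth = "data.frameOrNULL",
    config = "list"
  )
)

setValidity("ScreenBundle", function(object) {
  msg <- character()
  tid <- mcols(object@tss)$transcript_id
  if (is.null(tid) || is.null(mcols(object@tss)$gene_id))
    msg <- c(msg, "tss must carry transcript_id and gene_id metadata columns")
  else if (anyDuplicated(tid))
    msg <- c(msg, "transcript_id values must be unique")
  if (length(object@peaks) && is.null(names(object@peaks)))
    msg <- c(msg, "peaks list must be named '<mark>:<cell_line>'")
  for (nm in names(object@peaks)) {
    sc <- mcols(object@peaks[[nm]])$score
    if (!is.null(sc) && any(sc < 0))
      msg <- c(msg, sprintf("negative peak score in '%s'", nm))
  }
  for (ts in names(object@cpg)) {
    g <- object@cpg[[ts]]
    m <- mcols(g)
    if (!all(c("meth_reads", "total_reads") %in% colnames(m))) {
      msg <- c(msg, sprintf("cpg['%s'] lacks meth_reads/total_reads", ts))
      next
    }
    if (any(m$total_reads <= 0))
      msg <- c(msg, sprintf("cpg['%s'] has non-positive total_reads", ts))
    if (any(m$meth_reads > m$total_reads))
      msg <- c(msg, sprintf("cpg['%s'] has meth_reads > total_reads", ts))
  }
  if (length(msg)) msg else TRUE
})

#' Result of a full screen run
#'
#' Produced by \code{\link{runScreen}}: the per-transcript stage flags, the
#' staged funnel report, the H3K4me3 two-by-two status table, and gene-level
#' collapsed hits.
#'
#' @slot records \code{data.frame}, one row per transcript, with logical
#'   stage flags (\code{NA} = stage not evaluated because an earlier stage
#'   failed).
#' @slot funnel \code{data.frame} with columns \code{stage}, \code{count},
#'   \code{pct_of_previous}, \code{pct_of_universe}.
#' @slot k4Status 2x2 \code{table} of H3K4me3 presence in the parent and
#'   demethylated lines.
#' @slot k27GainedFraction fraction of H3K4me3-gained TSSs carrying a
#'   parent-line H3K27me3 mark.
#' @slot geneHits character vector of gene-level final hits.
#' @slot config \code{list} of thresholds used.
#' @export
setClass("ScreenResult",
  representation(
    records = "data.frame",
    funnel = "data.frame",
    k4Status = "table",
    k27GainedFraction = "numeric",
    geneHits = "character",
    config = "list"
  )
)

setValidity("ScreenResult", function(object) {
  msg <- character()
  cnt <- object@funnel$count
  if (length(cnt) > 1 && any(diff(cnt) > 0))
    msg <- c(msg, "funnel counts must be non-increasing")
  pc <- c(object@funnel$pct_of_previous, object@funnel$pct_of_universe)
  pc <- pc[!is.na(pc)]
  if (any(pc < 0 | pc > 100))
    msg <- c(msg, "funnel percentages must lie in [0, 100]")
  if (length(msg)) msg else TRUE
})

#' Optimal-cutoff survival analysis result
#'
#' Produced by \code{\link{findCutoff}}: the methylation (or beta-value)
#' cutoff minimizing the log-rank p-value over all admissible dichotomizing
#' cutoffs, together with the full scan table and Kaplan-Meier support
#' points for the two groups at the best cutoff. The minimal p-value is
#' reported uncorrected for the multiple cutoffs examined; see
#' \code{\link{generateNullClinical}} for the optimism this induces.
#'
#' @slot bestCutoff numeric; cutoff attaining the minimal log-rank p.
#' @slot chi2 numeric; 1-df log-rank chi-square at the best cutoff.
#' @slot pAtBest numeric; uncorrected p at the best cutoff.
#' @slot groupSizes integer vector (low, high) at the best cutoff.
#' @slot scan \code{data.frame} with columns \code{cutoff}, \code{n_low},
#'   \code{n_high}, \code{chi2}, \code{p} for every admissible cutoff.
#' @slot km \code{data.frame} of Kaplan-Meier support points at the best
#'   cutoff: \code{group}, \code{time}, \code{surv}.
#' @slot method character; scan-method label stored in output metadata.
#' @export
setClass("SurvivalCutoff",
  representation(
    bestCutoff = "numeric",
    chi2 = "numeric",
    pAtBest = "numeric",
    groupSizes = "integer",
    scan = "data.frame",
    km = "data.frame",
    method = "character"
  )
)

setValidity("SurvivalCutoff", function(object) {
  msg <- character()
  if (nrow(object@scan) && object@pAtBest > min(object@scan$p) + 1e-12)
    msg <- c(msg, "bestCutoff must attain the minimal p in the scan table")
  if (object@chi2 < 0) msg <- c(msg, "chi2 must be non-negative")
  if (length(msg)) msg else TRUE
})

#' @describeIn ScreenBundle compact display of bundle contents
#' @param object a \code{ScreenBundle}
#' @export
setMethod("show", "ScreenBundle", function(object) {
  cat("ScreenBundle\n")
  cat(sprintf("  %d TSSs (%d genes), %d CGIs\n",
              length(object@tss),
              length(unique(mcols(object@tss)$gene_id)),
              length(object@cgi)))
  cat(sprintf("  peak sets: %s\n", paste(names(object@peaks), collapse = ", ")))
  cat(sprintf("  methylomes: %s\n", paste(names(object@cpg), collapse = ", ")))
  cat(sprintf("  expression rows: %d; clinical samples: %d\n",
              nrow(object@expression), nrow(object@clinical)))
  if (!is.null(object@truth))
    cat(sprintf("  planted silenced genes: %d\n", sum(object@truth$is_silenced)))
})

#' @describeIn ScreenResult funnel summary display
#' @param object a \code{ScreenResult}
#' @export
setMethod("show", "ScreenResult", function(object) {
  cat("ScreenResult\n")
  f <- object@funnel
  for (i in seq_len(nrow(f))) {
    cat(sprintf("  %-28s %5d  (%s of universe)\n", f$stage[i], f$count[i],
                formatFraction(f$count[i], f$count[1])))
  }
  cat(sprintf("  gene-level hits: %d\n", length(object@geneHits)))
})

#' @describeIn SurvivalCutoff summary display
#' @param object a \code{SurvivalCutoff}
#' @export
setMethod("show", "SurvivalCutoff", function(object) {
  cat("SurvivalCutoff (", object@method, ")\n", sep = "")
  cat(sprintf("  best cutoff: %.4g  (groups %d low / %d high)\n",
              object@bestCutoff, object@groupSizes[1], object@groupSizes[2]))
  cat(sprintf("  log-rank chi2 = %.4g, uncorrected p = %.4g over %d cutoffs\n",
              object@chi2, object@pAtBest, nrow(object@scan)))
})
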