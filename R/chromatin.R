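#' Symmetric window around a TSS
#'
#' Builds the mark-specific scoring window around each TSS: 2 kb halfwidth
#' for the promoter mark H3K4me3, 5 kb for the broad marks H3K27me3 and
#' H3K79me2. The window covers \code{halfwidth} bases on each side of the
#' TSS (0-based half-open \code{[tss - halfwidth, tss + halfwidth)}),
#' strand-independent, clamped at the chromosome start so a TSS near
#' position 0 still yields a valid (truncated) window.
#'
#' @param tss width-1 TSS \code{GRanges} (see \code{\link{readTssAnnotation}})
#' @param halfwidth window halfwidth in bp (> 0)
#' @return \code{GRanges} of windows, parallel to \code{tss}, metadata
#'   columns retained.
#' @examples
#' tss <- GenomicRanges::GRanges("chr1", IRanges::IRanges(10001, 10001),
#'                               transcript_id = "t1", gene_id = "g1")
#' tssWindow(tss, 2000)  # spans 0-based [8000, 12000)
#' @export
tssWindow <- function(tss, halfwidth) {
  stopifnot(is.numeric(halfwidth), length(halfwidth) == 1L, halfwidth > 0)
  halfwidth <- as.integer(halfwidth)
  p <- start(tss)
  win <- GRanges(seqnames(tss),
                 IRanges(pmax(1L, p - halfwidth), p + halfwidth - 1L))
  mcols(win) <- mcols(tss)
  win
}

#' Call a histone mark at each TSS
#'
#' A TSS is positive for a mark in a cell line when at least one peak
#' interval overlaps its window by one or more bases (no minimum overlap
#' fraction). \code{signal} is the maximum peak score among overlapping
#' peaks (0 for negative calls, and for positive calls from score-less
#' peak files).
#'
#' Chromosomes present in the annotation but absent from the peak set give
#' all-negative calls, not an error: an empty chromosome is a biological
#' observation in a genome-wide scan.
#'
#' @param tss width-1 TSS \code{GRanges}
#' @param peaks peak \code{GRanges}, optionally with a numeric
#'   non-negative \code{score} column
#' @param halfwidth mark-specific window halfwidth in bp (2000 for
#'   H3K4me3, 5000 for H3K27me3/H3K79me2)
#' @return \code{data.frame} with one row per TSS: \code{transcript_id},
#'   \code{positive} (logical), \code{signal} (numeric).
#' @export
callMark <- function(tss, peaks, halfwidth) {
  win <- tssWindow(tss, halfwidth)
  sc <- mcols(peaks)$score
  if (is.null(sc)) sc <- rep(0, length(peaks))
  if (any(sc < 0)) stop("peak scores must be non-negative", call. = FALSE)
  ## differing seqlevels (chromosome absent from the peak file) are an
  ## expected all-negative case, not worth a warning
  hits <- suppressWarnings(findOverlaps(win, peaks, ignore.strand = TRUE))
  positive <- logical(length(tss))
  positive[unique(S4Vectors::queryHits(hits))] <- TRUE
  signal <- numeric(length(tss))
  if (length(hits)) {
    agg <- tapply(sc[S4Vectors::subjectHits(hits)],
                  S4Vectors::queryHits(hits), max)
    signal[as.integer(names(agg))] <- as.numeric(agg)
  }
  data.frame(transcript_id = mcols(tss)$transcript_id,
             positive = positive, signal = signal,
             stringsAsFactors = FALSE)
}

#' Detect H3K4me3 gain after DNA demethylation
#'
#' Compares per-TSS H3K4me3 calls between the parent tumor line and its
#' demethylated derivative and flags TSSs whose mark is acquired or
#' upregulated after demethylation.
#'
#' Two interpretations of "upregulated" are offered. In \code{binary} mode
#' a TSS is gained when it is negative in the parent and positive in the
#' derivative (de novo acquisition, as in a presence/absence status table).
#' In \code{quantitative} mode (the default) a TSS is gained when it is
#' positive in the derivative and either negative in the parent or its
#' signal ratio \code{(derivative + 1) / (parent + 1)} (pseudocount 1 on
#' both signals) is at least \code{minRatio}. With \code{minRatio = Inf}
#' quantitative mode reduces to binary mode.
#'
#' @param parent,derivative call \code{data.frame}s from
#'   \code{\link{callMark}} over the same transcript universe
#' @param mode \code{"quantitative"} (default) or \code{"binary"}
#' @param minRatio minimum derivative/parent signal ratio for a gain call
#'   on a parent-positive TSS (quantitative mode; default 2)
#' @return \code{data.frame}: \code{transcript_id}, \code{gained}
#'   (logical), \code{mode}, \code{ratio} (pseudocounted signal ratio; NA
#'   in binary mode).
#' @export
detectGain <- function(parent, derivative, mode = c("quantitative", "binary"),
                       minRatio = 2) {
  mode <- match.arg(mode)
  if (!setequal(parent$transcript_id, derivative$transcript_id) ||
      nrow(parent) != nrow(derivative))
    stop("parent and derivative calls cover different transcript universes",
         call. = FALSE)
  derivative <- derivative[match(parent$transcript_id, derivative$transcript_id), ]
  ratio <- (derivative$signal + 1) / (parent$signal + 1)
  gained <- if (mode == "binary") {
    !parent$positive & derivative$positive
  } else {
    derivative$positive & (!parent$positive | ratio >= minRatio)
  }
  data.frame(transcript_id = parent$transcript_id, gained = gained,
             mode = rep(mode, length(gained)),
             ratio = if (mode == "quantitative") ratio
                     else rep(NA_real_, length(gained)),
             stringsAsFactors = FALSE)
}

#' H3K4me3 universe and two-line status table
#'
#' \code{h3k4Universe} returns the transcripts positive for H3K4me3 in the
#' parent and/or the demethylated line — the set of TSSs with evidence of
#' transcription in either line. \code{k4StatusCounts} tabulates the
#' presence/absence combinations across the two lines (both /
#' parent-only / derivative-only / neither).
#'
#' @param parent,derivative call \code{data.frame}s from
#'   \code{\link{callMark}} over the same transcript universe
#' @return \code{h3k4Universe}: character vector of transcript ids;
#'   \code{k4StatusCounts}: a 2x2 \code{table} (rows = parent, columns =
#'   derivative, levels \code{negative}/\code{positive}).
#' @export
h3k4Universe <- function(parent, derivative) {
  sort(union(parent$transcript_id[parent$positive],
             derivative$transcript_id[derivative$positive]))
}

#' @rdname h3k4Universe
#' @export
k4StatusCounts <- function(parent, derivative) {
  if (!setequal(parent$transcript_id, derivative$transcript_id))
    stop("parent and derivative calls cover different transcript universes",
         call. = FALSE)
  derivative <- derivative[match(parent$transcript_id, derivative$transcript_id), ]
  lv <- c("negative", "positive")
  table(parent = factor(lv[parent$positive + 1L], levels = lv),
        derivative = factor(lv[derivative$positive + 1L], levels = lv))
}
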