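suppressPackageStartupMessages({
  library(GenomicRanges)
  library(IRanges)
})

## Build a width-1 TSS GRanges from 0-based positions.
makeTss <- function(pos0, chrom = "chrT", strand = "+",
                    ids = sprintf("t%02d", seq_along(pos0)),
                    genes = sprintf("g%02d", seq_along(pos0))) {
  GRanges(chrom, IRanges(pos0 + 1L, width = 1L), strand = strand,
          transcript_id = ids, gene_id = genes)
}

## Build a GRanges from 0-based half-open intervals.
makeIntervals <- function(start0, end0, chrom = "chrT", score = NULL) {
  gr <- GRanges(rep(chrom, length(start0)), IRanges(start0 + 1L, end0))
  if (!is.null(score)) mcols(gr)$score <- score
  gr
}

## Per-base brute-force overlap oracle, all in 0-based coordinates:
## does window [max(0, tss0 - hw), tss0 + hw) share any base with any
## [s0, e0) interval?
bruteWindowOverlap <- function(tss0, hw, s0, e0) {
  vapply(tss0, function(p) {
    bases <- seq.int(max(0, p - hw), p + hw - 1L)
    any(vapply(seq_along(s0), function(i)
      any(bases >= s0[i] & bases < e0[i]), logical(1)))
  }, logical(1))
}

## Hand-summed O/E/V log-rank oracle (group A observed vs expected).
bruteLogRank <- function(tA, eA, tB, eB) {
  times <- c(tA, tB); events <- c(eA, eB)
  grpA <- c(rep(TRUE, length(tA)), rep(FALSE, length(tB)))
  dt <- sort(unique(times[events == 1]))
  O1 <- E1 <- V <- 0
  for (t in dt) {
    at_risk <- times >= t
    n1 <- sum(at_risk & grpA); n2 <- sum(at_risk & !grpA)
    n <- n1 + n2
    d1 <- sum(times == t & events == 1 & grpA)
    d2 <- sum(times == t & events == 1 & !grpA)
    d <- d1 + d2
    O1 <- O1 + d1
    E1 <- E1 + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (n2 / n) * (n - d) / (n - 1)
  }
  chi2 <- (O1 - E1)^2 / V
  list(chi2 = chi2, p = pchisq(chi2, 1, lower.tail = FALSE))
}

## Exhaustive re-implementation of the cutoff scan for the oracle check.
bruteCutoffScan <- function(clin, minGroupFrac = 0.10) {
  d <- clin[!is.na(clin$surv_time) & !is.na(clin$event), ]
  vals <- sort(unique(d$methylation))
  cand <- (vals[-1] + vals[-length(vals)]) / 2
  minN <- ceiling(minGroupFrac * nrow(d))
  out <- NULL
  for (ct in cand) {
    hi <- d$methylation > ct
    if (sum(hi) < minN || sum(!hi) < minN) next
    if (sum(d$event) == 0) next
    lr <- bruteLogRank(d$surv_time[!hi], d$event[!hi],
                       d$surv_time[hi], d$event[hi])
    out <- rbind(out, data.frame(cutoff = ct, n_low = sum(!hi),
                                 n_high = sum(hi), chi2 = lr$chi2, p = lr$p))
  }
  out
}

## Coverage GRanges from 0-based positions and read counts.
makeCpg <- function(pos0, meth, total, tissue, chrom = "chrT") {
  gr <- GRanges(chrom, IRanges(pos0 + 1L, width = 1L),
                meth_reads = as.integer(meth), total_reads = as.integer(total))
  gr <- sort(gr, ignore.strand = TRUE)
  S4Vectors::metadata(gr)$tissue <- tissue
  gr
}

## Hand-built five-transcript bundle exercising one failure per stage:
##   t1 full hit; t2 fails tumor methylation; t3 lacks a promoter CGI;
##   t4 fails expression reactivation; t5 never gains H3K4me3.
makeTinyBundle <- function() {
  pos0 <- c(10000, 30000, 50000, 70000, 90000)
  tss <- makeTss(pos0)
  peak_at <- function(idx, score) if (length(idx))
    makeIntervals(pos0[idx] - 200, pos0[idx] + 400, score = score)
  else makeIntervals(integer(), integer(), score = numeric())
  peaks <- list(
    "H3K4me3:tumor_line" = peak_at(5, score = 20),
    "H3K4me3:demethylated_line" = peak_at(1:5, score = c(30, 30, 30, 30, 25)),
    "H3K27me3:tumor_line" = peak_at(1, score = 1),
    "H3K79me2:tumor_line" = peak_at(integer(), numeric())
  )
  cpg_for <- function(level10) {
    ## three CpGs per promoter at offsets -100/0/+100, depth 10
    pos <- as.vector(vapply(pos0, function(p) p + c(-100, 0, 100), numeric(3)))
    meth <- rep(level10, each = 3)
    makeCpg(pos, meth, rep(10, length(pos)), tissue = NA)
  }
  tumor <- cpg_for(c(9, 2, 9, 9, 1))   # t2 low in tumor
  normal <- cpg_for(c(1, 1, 1, 1, 1))
  S4Vectors::metadata(tumor)$tissue <- "tumor_line"
  S4Vectors::metadata(normal)$tissue <- "colonic_mucosa"
  cgi <- makeIntervals(pos0[c(1, 2, 4, 5)] - 300, pos0[c(1, 2, 4, 5)] + 300)
  expr <- data.frame(
    gene_id = rep(sprintf("g%02d", 1:5), 4),
    condition = rep(c("normal_colon", "tumor_line", "tumor_line_aza",
                      "demethylated_line"), each = 5),
    value = c(8, 8, 8, 8, 8,          # normal colon
              1, 1, 1, 1, 8,          # tumor line
              6, 6, 6, 1.2, 8,        # + demethylating drug
              0.5, 6, 6, 1.1, 8),     # knockout derivative
    stringsAsFactors = FALSE)
  clinical <- data.frame(sample_id = sprintf("s%02d", 1:25),
                         group = "carcinoma",
                         methylation = seq(2, 98, length.out = 25),
                         expression = NA_real_,
                         surv_time = rep(c(10, 20, 30, 40, 50), 5),
                         event = rep(c(1, 0, 1, 1, 0), 5),
                         stringsAsFactors = FALSE)
  new("ScreenBundle", tss = tss, cgi = cgi, peaks = peaks,
      cpg = list(tumor_line = tumor, colonic_mucosa = normal),
      expression = expr, clinical = clinical, truth = NULL, config = list())
}
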