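#' @importFrom utils read.table write.table
NULL

## All on-disk interval formats are BED-style 0-based half-open; internal
## containers are GRanges (1-based closed). Conversion happens only here.

.bed2gr <- function(chrom, start0, end0, ...) {
  GRanges(chrom, IRanges(start0 + 1L, end0), ...)
}

.gr2bed_start <- function(gr) start(gr) - 1L
.gr2bed_end <- function(gr) end(gr)

.parse_stop <- function(path, line, fmt, ...) {
  stop(sprintf("%s: line %d: %s", path, line, sprintf(fmt, ...)), call. = FALSE)
}

.read_lines_nocomment <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  lines <- readLines(path)
  keep <- !grepl("^\\s*$|^#|^track\\b|^browser\\b", lines)
  list(lines = lines[keep], lineno = which(keep))
}

.as_int <- function(x) {
  suppressWarnings(v <- as.integer(x))
  v
}

#' Read a BED interval file
#'
#' Reads BED3/BED6 (tab-separated, 0-based half-open) into a
#' \code{GRanges}. Track, browser, comment and blank lines are skipped.
#' Optional columns 4-6 become \code{name}, \code{score} and strand.
#'
#' @param path path to a BED file
#' @return \code{GRanges}; a \code{score} column, when present, is numeric
#'   and non-negative.
#' @examples
#' f <- tempfile(fileext = ".bed")
#' writeLines("chr1\t100\t200\tpk1\t25\t+", f)
#' readBed(f)
#' @export
readBed <- function(path) {
  src <- .read_lines_nocomment(path)
  if (!length(src$lines)) return(GRanges())
  fields <- strsplit(src$lines, "\t", fixed = TRUE)
  n <- lengths(fields)
  bad <- which(n < 3L)
  if (length(bad))
    .parse_stop(path, src$lineno[bad[1]], "expected >=3 tab-separated columns, got %d", n[bad[1]])
  chrom <- vapply(fields, `[[`, "", 1L)
  s <- .as_int(vapply(fields, `[[`, "", 2L))
  e <- .as_int(vapply(fields, `[[`, "", 3L))
  bad <- which(is.na(s) | is.na(e))
  if (length(bad))
    .parse_stop(path, src$lineno[bad[1]], "non-integer coordinates")
  bad <- which(s < 0L | e <= s)
  if (length(bad))
    .parse_stop(path, src$lineno[bad[1]], "invalid interval [%d, %d): need 0 <= start < end", s[bad[1]], e[bad[1]])
  gr <- .bed2gr(chrom, s, e)
  if (all(n >= 4L)) mcols(gr)$name <- vapply(fields, `[[`, "", 4L)
  if (all(n >= 5L)) {
    sc <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 5L)))
    bad <- which(is.na(sc) | sc < 0)
    if (length(bad))
      .parse_stop(path, src$lineno[bad[1]], "score must be a non-negative number")
    mcols(gr)$score <- sc
  }
  if (all(n >= 6L)) {
    st <- vapply(fields, `[[`, "", 6L)
    bad <- which(!st %in% c("+", "-", "."))
    if (length(bad))
      .parse_stop(path, src$lineno[bad[1]], "unknown strand '%s'", st[bad[1]])
    st[st == "."] <- "*"
    strand(gr) <- st
  }
  sort(gr, ignore.strand = TRUE)
}

#' Write intervals as BED
#'
#' Inverse of \code{\link{readBed}}: writes a \code{GRanges} as tab-separated
#' 0-based half-open BED. \code{name}/\code{score} columns and strand are
#' written when present (BED6), otherwise BED3.
#'
#' @param gr a \code{GRanges}
#' @param path output path
#' @return \code{path}, invisibly.
#' @export
writeBed <- function(gr, path) {
  df <- data.frame(chrom = as.character(seqnames(gr)),
                   start = .gr2bed_start(gr), end = .gr2bed_end(gr))
  has_score <- "score" %in% colnames(mcols(gr))
  st <- as.character(strand(gr))
  if (has_score || any(st != "*")) {
    df$name <- if ("name" %in% colnames(mcols(gr))) mcols(gr)$name
               else rep(".", length(gr))
    df$score <- if (has_score) sprintf("%.17g", mcols(gr)$score)
                else rep("0", length(gr))
    st[st == "*"] <- "."
    df$strand <- st
  }
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read per-CpG bisulfite counts
#'
#' Reads a Bismark-coverage-style TSV (\code{chrom}, \code{start},
#' \code{end}, \code{meth_reads}, \code{total_reads}; 0-based half-open,
#' one row per CpG site, strand-collapsed) into a width-1 \code{GRanges}.
#'
#' Rows with zero coverage, methylated counts exceeding total counts, or
#' duplicated positions within the tissue are rejected: each indicates an
#' upstream aggregation bug rather than recoverable data.
#'
#' @param path path to the coverage TSV
#' @param tissue tissue label attached to the calls
#' @return \code{GRanges} with integer columns \code{meth_reads},
#'   \code{total_reads} and the tissue in \code{metadata(x)$tissue};
#'   per-site methylation level is \code{meth_reads / total_reads}.
#' @export
readCpgCoverage <- function(path, tissue) {
  stopifnot(is.character(tissue), length(tissue) == 1L)
  src <- .read_lines_nocomment(path)
  if (!length(src$lines)) {
    gr <- GRanges()
    mcols(gr)$meth_reads <- integer()
    mcols(gr)$total_reads <- integer()
    metadata(gr)$tissue <- tissue
    return(gr)
  }
  fields <- strsplit(src$lines, "\t", fixed = TRUE)
  n <- lengths(fields)
  bad <- which(n < 5L)
  if (length(bad))
    .parse_stop(path, src$lineno[bad[1]], "expected 5 columns, got %d", n[bad[1]])
  chrom <- vapply(fields, `[[`, "", 1L)
  s <- .as_int(vapply(fields, `[[`, "", 2L))
  e <- .as_int(vapply(fields, `[[`, "", 3L))
  meth <- .as_int(vapply(fields, `[[`, "", 4L))
  tot <- .as_int(vapply(fields, `[[`, "", 5L))
  bad <- which(is.na(s) | is.na(e) | is.na(meth) | is.na(tot))
  if (length(bad)) .parse_stop(path, src$lineno[bad[1]], "non-numeric field")
  bad <- which(s < 0L | e != s + 1L)
  if (length(bad))
    .parse_stop(path, src$lineno[bad[1]], "CpG rows must be single-base intervals")
  bad <- which(tot <= 0L)
  if (length(bad)) .parse_stop(path, src$lineno[bad[1]], "total_reads must be positive")
  bad <- which(meth < 0L | meth > tot)
  if (length(bad))
    .parse_stop(path, src$lineno[bad[1]], "meth_reads (%d) exceeds total_reads (%d)", meth[bad[1]], tot[bad[1]])
  key <- paste(chrom, s)
  bad <- which(duplicated(key))
  if (length(bad))
    .parse_stop(path, src$lineno[bad[1]], "duplicate CpG site %s:%d in tissue '%s'", chrom[bad[1]], s[bad[1]], tissue)
  gr <- .bed2gr(chrom, s, e, meth_reads = meth, total_reads = tot)
  gr <- sort(gr, ignore.strand = TRUE)
  metadata(gr)$tissue <- tissue
  gr
}

#' @rdname readCpgCoverage
#' @param gr width-1 \code{GRanges} with \code{meth_reads}/\code{total_reads}
#' @export
writeCpgCoverage <- function(gr, path) {
  df <- data.frame(chrom = as.character(seqnames(gr)),
                   start = .gr2bed_start(gr), end = .gr2bed_end(gr),
                   meth = mcols(gr)$meth_reads, total = mcols(gr)$total_reads)
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a TSS annotation table
#'
#' Reads a header-bearing TSV with columns \code{transcript_id},
#' \code{gene_id}, \code{chrom}, \code{start}, \code{end}, \code{strand}
#' (0-based half-open transcript intervals) and derives each transcript's
#' TSS: the interval start on the plus strand, the last base
#' (\code{end - 1} in 0-based coordinates) on the minus strand — the
#' biological 5' end, following UCSC practice.
#'
#' @param path path to the annotation TSV
#' @return width-1 \code{GRanges} positioned at each TSS, strand retained,
#'   with \code{transcript_id} and \code{gene_id} metadata columns.
#' @export
readTssAnnotation <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                   colClasses = "character")
  need <- c("transcript_id", "gene_id", "chrom", "start", "end", "strand")
  miss <- setdiff(need, colnames(df))
  if (length(miss))
    stop(sprintf("%s: missing column(s): %s", path, paste(miss, collapse = ", ")), call. = FALSE)
  s <- .as_int(df$start); e <- .as_int(df$end)
  bad <- which(is.na(s) | is.na(e) | s < 0L | e <= s)
  if (length(bad))
    .parse_stop(path, bad[1] + 1L, "invalid transcript interval")
  bad <- which(!df$strand %in% c("+", "-"))
  if (length(bad))
    .parse_stop(path, bad[1] + 1L, "strand must be '+' or '-', got '%s'", df$strand[bad[1]])
  bad <- which(duplicated(df$transcript_id))
  if (length(bad))
    .parse_stop(path, bad[1] + 1L, "duplicate transcript_id '%s'", df$transcript_id[bad[1]])
  tss0 <- ifelse(df$strand == "+", s, e - 1L)
  gr <- GRanges(df$chrom, IRanges(tss0 + 1L, width = 1L), strand = df$strand,
                transcript_id = df$transcript_id, gene_id = df$gene_id)
  gr
}

#' @rdname readTssAnnotation
#' @param tss width-1 TSS \code{GRanges} as returned by
#'   \code{readTssAnnotation}
#' @export
writeTssAnnotation <- function(tss, path) {
  df <- data.frame(transcript_id = mcols(tss)$transcript_id,
                   gene_id = mcols(tss)$gene_id,
                   chrom = as.character(seqnames(tss)),
                   start = .gr2bed_start(tss), end = .gr2bed_end(tss),
                   strand = as.character(strand(tss)))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.expr_conditions <- c("normal_colon", "tumor_line", "tumor_line_aza",
                      "demethylated_line")

#' Read a relative-expression table
#'
#' Header-bearing TSV with columns \code{gene_id}, \code{condition},
#' \code{value}; values are relative expression normalized to a
#' housekeeping control and must be non-negative. The canonical conditions
#' are \code{normal_colon}, \code{tumor_line}, \code{tumor_line_aza}
#' (demethylating-drug treatment) and \code{demethylated_line} (DNMT
#' knockout derivative); other labels are allowed and pass through.
#'
#' @param path path to the expression TSV
#' @return \code{data.frame} with the three columns, \code{value} numeric.
#' @export
readExpression <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  need <- c("gene_id", "condition", "value")
  miss <- setdiff(need, colnames(df))
  if (length(miss))
    stop(sprintf("%s: missing column(s): %s", path, paste(miss, collapse = ", ")), call. = FALSE)
  df$value <- as.numeric(df$value)
  bad <- which(is.na(df$value) | df$value < 0)
  if (length(bad))
    .parse_stop(path, bad[1] + 1L, "expression value must be a non-negative number")
  df[, need]
}

#' @rdname readExpression
#' @param df expression \code{data.frame}
#' @export
writeExpression <- function(df, path) {
  out <- data.frame(gene_id = df$gene_id, condition = df$condition,
                    value = sprintf("%.17g", df$value))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.clinical_groups <- c("normal", "adenoma", "advanced_adenoma", "carcinoma")

#' Read a clinical cohort table
#'
#' Header-bearing TSV with columns \code{sample_id}, \code{group},
#' \code{methylation} (percent in [0, 100]) and optional \code{expression},
#' \code{surv_time}, \code{event} ("." or empty = missing). Groups are
#' \code{normal}, \code{adenoma}, \code{advanced_adenoma},
#' \code{carcinoma}. An event indicator must be present exactly when a
#' survival time is.
#'
#' @param path path to the clinical TSV
#' @return \code{data.frame} with typed columns; missing optionals are NA.
#' @export
readClinical <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                   colClasses = "character", na.strings = c(".", "", "NA"))
  need <- c("sample_id", "group", "methylation")
  miss <- setdiff(need, colnames(df))
  if (length(miss))
    stop(sprintf("%s: missing column(s): %s", path, paste(miss, collapse = ", ")), call. = FALSE)
  bad <- which(!df$group %in% .clinical_groups)
  if (length(bad))
    .parse_stop(path, bad[1] + 1L, "unknown group label '%s'", df$group[bad[1]])
  df$methylation <- as.numeric(df$methylation)
  bad <- which(is.na(df$methylation) | df$methylation < 0 | df$methylation > 100)
  if (length(bad))
    .parse_stop(path, bad[1] + 1L, "methylation must be a percent in [0, 100]")
  for (opt in c("expression", "surv_time", "event"))
    df[[opt]] <- if (opt %in% colnames(df)) as.numeric(df[[opt]]) else NA_real_
  bad <- which(!is.na(df$expression) & df$expression < 0)
  if (length(bad)) .parse_stop(path, bad[1] + 1L, "expression must be non-negative")
  bad <- which(!is.na(df$surv_time) & df$surv_time <= 0)
  if (length(bad)) .parse_stop(path, bad[1] + 1L, "surv_time must be positive")
  bad <- which(xor(is.na(df$surv_time), is.na(df$event)))
  if (length(bad))
    .parse_stop(path, bad[1] + 1L, "event must be present exactly when surv_time is")
  bad <- which(!is.na(df$event) & !df$event %in% c(0, 1))
  if (length(bad)) .parse_stop(path, bad[1] + 1L, "event must be 0 or 1")
  df[, c("sample_id", "group", "methylation", "expression", "surv_time", "event")]
}

#' @rdname readClinical
#' @param df clinical \code{data.frame}
#' @export
writeClinical <- function(df, path) {
  fmt <- function(x) ifelse(is.na(x), ".", sprintf("%.17g", x))
  out <- data.frame(sample_id = df$sample_id, group = df$group,
                    methylation = fmt(df$methylation),
                    expression = fmt(df$expression),
                    surv_time = fmt(df$surv_time),
                    event = ifelse(is.na(df$event), ".", sprintf("%d", as.integer(df$event))))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Serialize and reload a screen result
#'
#' \code{writeFunnelReport} writes a \code{\link{ScreenResult}} as JSON
#' (stage counts, per-transcript flags, H3K4me3 status table, gene hits and
#' thresholds); \code{readFunnelReport} reconstructs it. The pair
#' round-trips all counts and flags exactly.
#'
#' @param result a \code{ScreenResult}
#' @param path output (input) JSON path
#' @return \code{writeFunnelReport}: \code{path}, invisibly;
#'   \code{readFunnelReport}: a \code{ScreenResult}.
#' @export
writeFunnelReport <- function(result, path) {
  stopifnot(is(result, "ScreenResult"))
  payload <- list(
    funnel = result@funnel,
    records = result@records,
    k4_status = list(dimnames = dimnames(result@k4Status),
                     counts = as.vector(result@k4Status)),
    k27_gained_fraction = result@k27GainedFraction,
    gene_hits = as.list(result@geneHits),
    config = result@config
  )
  json <- jsonlite::toJSON(payload, digits = NA, na = "null", null = "null",
                           auto_unbox = TRUE, pretty = TRUE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(json, con)
  invisible(path)
}

#' @rdname writeFunnelReport
#' @export
readFunnelReport <- function(path) {
  p <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  k4 <- p$k4_status$counts
  dn <- p$k4_status$dimnames
  tab <- as.table(matrix(as.integer(k4), nrow = length(dn[[1]]),
                         dimnames = list(parent = dn[[1]], derivative = dn[[2]])))
  recs <- as.data.frame(p$records)
  for (cc in colnames(recs))
    if (is.logical(recs[[cc]]) || all(recs[[cc]] %in% c(TRUE, FALSE, NA)))
      recs[[cc]] <- as.logical(recs[[cc]])
  recs$transcript_id <- as.character(p$records$transcript_id)
  recs$gene_id <- as.character(p$records$gene_id)
  new("ScreenResult",
      records = recs,
      funnel = as.data.frame(p$funnel),
      k4Status = tab,
      k27GainedFraction = as.numeric(p$k27_gained_fraction),
      geneHits = as.character(unlist(p$gene_hits)),
      config = as.list(p$config))
}
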