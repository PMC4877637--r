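#' Simulation parameters for a synthetic screen bundle
#'
#' Parameters of the synthetic epigenome generator. Defaults describe a
#' desk-scale study on one synthetic chromosome: 200 lncRNA genes of which
#' 20 are truly silenced by promoter hypermethylation; per-CpG
#' beta-binomial bisulfite counts (site-level Beta mean 0.85,
#' concentration 50, for silenced tumor promoters; 0.05 for unmethylated
#' promoters; Poisson read depth, mean 30; Poisson CpGs per promoter,
#' mean 12); expression with an 8-fold reduction in the tumor line for
#' silenced genes and a 6-fold reactivation under demethylation; clinical
#' cohorts of 46 normal / 38 adenoma / 41 advanced adenoma / 101 carcinoma
#' samples with group mean methylation 5 / 12 / 30 / 35 percent and a
#' hazard ratio of 2 for carcinoma samples above the cohort methylation
#' median.
#'
#' @param seed integer RNG seed; the generated bundle is a deterministic
#'   function of the full configuration including the seed
#' @param nGenes number of genes (one transcript each)
#' @param nSilenced number of planted silenced genes
#' @param chromLength synthetic chromosome length in bp
#' @param promoterHalfwidth promoter halfwidth in bp
#' @param tumorMethHigh Beta mean of silenced-gene tumor promoter CpGs
#' @param methLow Beta mean of unmethylated promoter CpGs
#' @param methConc Beta concentration (a + b) for CpG site levels
#' @param cpgsPerPromoter Poisson mean CpGs per promoter
#' @param readDepth Poisson mean reads per CpG
#' @param exprBase log-normal meanlog of normal-colon expression
#' @param exprSd log-normal sdlog of normal-colon expression
#' @param silencingFold tumor-line expression fold-reduction (silenced genes)
#' @param reactivationFold fold-increase under drug/knockout demethylation
#' @param k27Fraction fraction of silenced genes with a parent-line
#'   H3K27me3 mark
#' @param noiseGainFraction fraction of inactive unmethylated genes that
#'   nevertheless gain an H3K4me3 peak in the demethylated line
#'   (chromatin noise the methylation filter must reject)
#' @param nClinical named counts per clinical group
#' @param clinicalMeans named group mean methylation percentages
#' @param clinicalConc Beta concentration of clinical methylation values
#' @param survBaseRate baseline exponential hazard (per month)
#' @param survHazardRatio hazard multiplier for high-methylation carcinomas
#' @param chrom synthetic chromosome name
#' @return validated named list of class \code{"SimulationConfig"}.
#' @export
simulationConfig <- function(seed = 1L,
                             nGenes = 200L, nSilenced = 20L,
                             chromLength = 1e7, promoterHalfwidth = 500L,
                             tumorMethHigh = 0.85, methLow = 0.05,
                             methConc = 50,
                             cpgsPerPromoter = 12, readDepth = 30,
                             exprBase = 0, exprSd = 0.5,
                             silencingFold = 8, reactivationFold = 6,
                             k27Fraction = 0.39, noiseGainFraction = 0.2,
                             nClinical = c(normal = 46L, adenoma = 38L,
                                           advanced_adenoma = 41L,
                                           carcinoma = 101L),
                             clinicalMeans = c(normal = 5, adenoma = 12,
                                               advanced_adenoma = 30,
                                               carcinoma = 35),
                             clinicalConc = 8,
                             survBaseRate = 1 / 60, survHazardRatio = 2,
                             chrom = "chrS") {
  cfg <- as.list(environment())
  if (cfg$nSilenced > cfg$nGenes)
    stop("nSilenced must not exceed nGenes", call. = FALSE)
  if (cfg$tumorMethHigh <= 0 || cfg$tumorMethHigh >= 1 ||
      cfg$methLow <= 0 || cfg$methLow >= 1)
    stop("Beta means must lie in (0, 1)", call. = FALSE)
  if (cfg$silencingFold <= 1 || cfg$reactivationFold <= 1)
    stop("fold parameters must exceed 1", call. = FALSE)
  if (!setequal(names(cfg$nClinical), .clinical_groups))
    stop("nClinical must name the four clinical groups", call. = FALSE)
  class(cfg) <- "SimulationConfig"
  cfg
}

.normal_tissues <- c("colonic_mucosa", "rectal_mucosa", "rectal_muscle",
                     "stomach_muscle", "duodenum_mucosa")

.beta_ab <- function(mean, conc) c(mean * conc, (1 - mean) * conc)

## site-level Beta mean, binomial reads: the standard bisulfite noise model
.rcpg <- function(n, mean, conc, depth) {
  p <- rbeta(n, mean * conc, (1 - mean) * conc)
  total <- pmax(1L, rpois(n, depth))
  meth <- rbinom(n, total, p)
  list(meth = meth, total = total)
}

#' Generate a complete synthetic screen bundle
#'
#' Builds an internally consistent input bundle — TSS annotation, CGIs,
#' peak sets for two cell lines and three marks, CpG bisulfite counts for
#' the tumor line and five normal gastrointestinal tissues, an expression
#' table over four conditions, and a clinical cohort table — with a
#' planted truth set of silenced genes.
#'
#' Planted silenced genes have hypermethylated tumor promoters and
#' unmethylated normal promoters, a promoter CGI, no parent-line H3K4me3
#' peak but a derivative-line peak (a configurable fraction also carry a
#' parent-line H3K27me3 mark), and expression that is present in normal
#' colon, reduced \code{silencingFold}-fold in the tumor line, and
#' reactivated \code{reactivationFold}-fold under both the demethylating
#' drug and the knockout. The remaining genes split into genes active in
#' both lines (low methylation everywhere, stable expression), inactive
#' unmethylated genes (no H3K4me3, not expressed; a fraction gain a
#' derivative-line peak as chromatin noise), and tissue-silent genes
#' (expressed in normal colon but not reactivated by demethylation).
#' Clinical methylation group means rise from normal through carcinoma,
#' and carcinoma samples above the cohort methylation median carry a
#' multiplied death hazard.
#'
#' @param config a \code{\link{simulationConfig}}
#' @return a \code{\linkS4class{ScreenBundle}} whose \code{truth} slot
#'   marks the planted silenced genes and their planted parameters.
#' @examples
#' bundle <- generateBundle(simulationConfig(seed = 7, nGenes = 40,
#'                                           nSilenced = 4))
#' bundle
#' @export
generateBundle <- function(config = simulationConfig()) {
  stopifnot(inherits(config, "SimulationConfig"))
  set.seed(config$seed)
  n <- config$nGenes
  chrom <- config$chrom
  hw <- config$promoterHalfwidth

  ## gene layout: evenly spaced TSSs with jitter, random strand
  spacing <- floor(config$chromLength / (n + 1))
  tss0 <- as.integer(spacing * seq_len(n) +
                       round(runif(n, -0.2, 0.2) * spacing))
  tss0 <- pmax(tss0, 6000L)  # keep broad windows on-chromosome
  strand <- sample(c("+", "-"), n, replace = TRUE)
  gene_id <- sprintf("LNC%04d", seq_len(n))
  transcript_id <- paste0(gene_id, ".1")

  silenced <- sort(sample(seq_len(n), config$nSilenced))
  is_silenced <- seq_len(n) %in% silenced
  other <- setdiff(seq_len(n), silenced)
  cls <- rep(NA_character_, n)
  cls[silenced] <- "silenced"
  n_o <- length(other)
  cls[other] <- sample(rep(c("active", "inactive_unmeth", "tissue_silent"),
                           length.out = n_o))

  tss <- GRanges(chrom, IRanges(tss0 + 1L, width = 1L), strand = strand,
                 transcript_id = transcript_id, gene_id = gene_id)

  ## CGIs: all silenced promoters and about half the rest
  has_cgi <- is_silenced | runif(n) < 0.5
  cgi_start <- pmax(0L, tss0[has_cgi] - as.integer(round(runif(sum(has_cgi), 150, 400))))
  cgi_end <- pmin(config$chromLength,
                  tss0[has_cgi] + as.integer(round(runif(sum(has_cgi), 150, 400))))
  cgi <- sort(GRanges(chrom, IRanges(cgi_start + 1L, cgi_end)),
              ignore.strand = TRUE)

  ## peaks
  mk_peaks <- function(idx, halfjit = c(100, 600), width = c(400, 1500),
                       score) {
    if (!length(idx)) {
      g <- GRanges()
      mcols(g)$score <- numeric()
      return(g)
    }
    s0 <- pmax(0L, tss0[idx] - as.integer(round(runif(length(idx), halfjit[1], halfjit[2]))))
    e0 <- pmin(config$chromLength,
               s0 + as.integer(round(runif(length(idx), width[1], width[2]))))
    g <- GRanges(chrom, IRanges(s0 + 1L, e0))
    mcols(g)$score <- score
    sort(g, ignore.strand = TRUE)
  }
  active <- which(cls == "active")
  inact <- which(cls == "inactive_unmeth")
  noise_gain <- inact[runif(length(inact)) < config$noiseGainFraction]
  base_score <- function(k) rlnorm(k, log(30), 0.4)
  sc_active_parent <- base_score(length(active))
  peaks <- list(
    "H3K4me3:tumor_line" = mk_peaks(active, score = sc_active_parent),
    "H3K4me3:demethylated_line" = mk_peaks(
      c(active, silenced, noise_gain),
      score = c(sc_active_parent * exp(rnorm(length(active), 0, 0.15)),
                base_score(length(silenced) + length(noise_gain)))),
    "H3K27me3:tumor_line" = mk_peaks(
      silenced[runif(length(silenced)) < config$k27Fraction],
      score = NULL),
    "H3K27me3:demethylated_line" = mk_peaks(integer(), score = NULL),
    "H3K79me2:tumor_line" = mk_peaks(active, score = NULL),
    "H3K79me2:demethylated_line" = mk_peaks(active, score = NULL)
  )
  for (nm in names(peaks))
    if (is.null(mcols(peaks[[nm]])$score))
      mcols(peaks[[nm]])$score <- rep(1, length(peaks[[nm]]))

  ## methylomes: CpG positions per promoter, shared across tissues
  n_cpg <- pmax(2L, rpois(n, config$cpgsPerPromoter))
  cpg_gene <- rep(seq_len(n), n_cpg)
  cpg_pos0 <- unlist(lapply(seq_len(n), function(i)
    sort(sample(seq(tss0[i] - hw, tss0[i] + hw - 1L), n_cpg[i]))))
  tumor_mean <- ifelse(is_silenced, config$tumorMethHigh,
                       ifelse(cls == "tissue_silent", 0.20, config$methLow))
  mk_methylome <- function(site_means, tissue) {
    draw <- .rcpg(length(cpg_pos0), site_means, config$methConc,
                  config$readDepth)
    g <- GRanges(chrom, IRanges(cpg_pos0 + 1L, width = 1L),
                 meth_reads = draw$meth, total_reads = draw$total)
    g <- sort(g, ignore.strand = TRUE)
    metadata(g)$tissue <- tissue
    g
  }
  cpg <- c(
    list(tumor_line = mk_methylome(tumor_mean[cpg_gene], "tumor_line")),
    setNames(lapply(.normal_tissues, function(ts)
      mk_methylome(rep(config$methLow, length(cpg_pos0)), ts)),
      .normal_tissues)
  )

  ## expression: four conditions per gene
  noise <- function(k) exp(rnorm(k, 0, 0.2))
  base <- rlnorm(n, config$exprBase, config$exprSd)
  normal_v <- tumor_v <- aza_v <- ko_v <- numeric(n)
  for (i in seq_len(n)) {
    switch(cls[i],
      silenced = {
        normal_v[i] <- base[i]
        tumor_v[i] <- base[i] / config$silencingFold * noise(1)
        aza_v[i] <- tumor_v[i] * config$reactivationFold * noise(1)
        ko_v[i] <- tumor_v[i] * config$reactivationFold * noise(1)
      },
      active = {
        normal_v[i] <- base[i]
        tumor_v[i] <- base[i] * noise(1)
        aza_v[i] <- tumor_v[i] * noise(1)
        ko_v[i] <- tumor_v[i] * noise(1)
      },
      inactive_unmeth = {
        normal_v[i] <- 0.001 * noise(1)
        tumor_v[i] <- 0.001 * noise(1)
        aza_v[i] <- 0.001 * noise(1)
        ko_v[i] <- 0.001 * noise(1)
      },
      tissue_silent = {
        normal_v[i] <- base[i]
        tumor_v[i] <- base[i] / config$silencingFold * noise(1)
        aza_v[i] <- tumor_v[i] * noise(1)  # no reactivation
        ko_v[i] <- tumor_v[i] * noise(1)
      })
  }
  expression <- data.frame(
    gene_id = rep(gene_id, 4),
    condition = rep(c("normal_colon", "tumor_line", "tumor_line_aza",
                      "demethylated_line"), each = n),
    value = c(normal_v, tumor_v, aza_v, ko_v),
    stringsAsFactors = FALSE)

  clinical <- .generate_clinical(config)

  truth <- data.frame(gene_id = gene_id, class = cls,
                      is_silenced = is_silenced,
                      tumor_promoter_mean = tumor_mean,
                      silencing_fold = ifelse(is_silenced, config$silencingFold, NA),
                      reactivation_fold = ifelse(is_silenced, config$reactivationFold, NA),
                      stringsAsFactors = FALSE)

  cfg_list <- unclass(config)
  cfg_list$nClinical <- as.list(cfg_list$nClinical)
  cfg_list$clinicalMeans <- as.list(cfg_list$clinicalMeans)
  new("ScreenBundle", tss = tss, cgi = cgi, peaks = peaks, cpg = cpg,
      expression = expression, clinical = clinical, truth = truth,
      config = cfg_list)
}

.generate_clinical <- function(config) {
  groups <- .clinical_groups
  rows <- lapply(groups, function(g) {
    k <- config$nClinical[[g]]
    m <- config$clinicalMeans[[g]] / 100
    meth <- 100 * rbeta(k, m * config$clinicalConc,
                        (1 - m) * config$clinicalConc)
    data.frame(sample_id = sprintf("%s_%03d", toupper(substr(g, 1, 3)), seq_len(k)),
               group = g, methylation = meth,
               expression = NA_real_, surv_time = NA_real_,
               event = NA_real_, stringsAsFactors = FALSE)
  })
  clin <- do.call(rbind, rows)
  ## methylation-expression anticorrelation in normals + carcinomas
  sel <- clin$group %in% c("normal", "carcinoma")
  clin$expression[sel] <- exp(-2.5 * clin$methylation[sel] / 100 +
                                rnorm(sum(sel), 0, 0.3))
  ## survival for the carcinoma cohort: exponential, hazard multiplied
  ## above the cohort methylation median, administrative censoring
  ca <- which(clin$group == "carcinoma")
  high <- clin$methylation[ca] > median(clin$methylation[ca])
  rate <- config$survBaseRate * ifelse(high, config$survHazardRatio, 1)
  t_event <- rexp(length(ca), rate)
  t_cens <- runif(length(ca), 24, 120)
  clin$surv_time[ca] <- pmin(t_event, t_cens)
  clin$event[ca] <- as.numeric(t_event <= t_cens)
  clin
}

#' Null clinical cohort for cutoff-scan calibration
#'
#' Generates a cohort whose methylation (uniform on [0, 100]) is
#' independent of its exponential survival times. Running
#' \code{\link{findCutoff}} over replicates of this null documents the
#' optimism of minimal-p cutoff optimization: the distribution of the
#' uncorrected best p-value is strongly sub-uniform, so far more than 5
#' percent of null scans reach p < 0.05.
#'
#' @param n cohort size (>= 20)
#' @param seed integer RNG seed
#' @param baseRate exponential event rate (default 1/50)
#' @return clinical \code{data.frame} (all samples \code{carcinoma}).
#' @export
generateNullClinical <- function(n, seed = 1L, baseRate = 1 / 50) {
  if (n < 20) stop("need n >= 20", call. = FALSE)
  set.seed(seed)
  t_event <- rexp(n, baseRate)
  t_cens <- runif(n, 24, 120)
  data.frame(sample_id = sprintf("NULL_%04d", seq_len(n)),
             group = "carcinoma",
             methylation = runif(n, 0, 100),
             expression = NA_real_,
             surv_time = pmin(t_event, t_cens),
             event = as.numeric(t_event <= t_cens),
             stringsAsFactors = FALSE)
}

#' Write or reload a bundle as plain-text files
#'
#' \code{writeBundle} serializes every component of a
#' \code{\link{ScreenBundle}} into the screen's on-disk formats inside
#' \code{dir}: \code{tss.tsv}, \code{cgi.bed}, one BED per peak set
#' (\code{peaks_<mark>_<cell>.bed}), one coverage TSV per tissue
#' (\code{cpg_<tissue>.tsv}), \code{expression.tsv}, \code{clinical.tsv},
#' \code{truth.tsv} (when present) and the resolved configuration as
#' \code{config.json}. \code{readBundle} reconstructs the bundle; the pair
#' round-trips the data model exactly, and a fixed configuration plus seed
#' yields byte-identical directories.
#'
#' @param bundle a \code{ScreenBundle}
#' @param dir output (input) directory; created if needed
#' @return \code{writeBundle}: \code{dir}, invisibly; \code{readBundle}:
#'   a \code{ScreenBundle}.
#' @export
writeBundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeTssAnnotation(bundle@tss, file.path(dir, "tss.tsv"))
  writeBed(bundle@cgi, file.path(dir, "cgi.bed"))
  for (nm in names(bundle@peaks))
    writeBed(bundle@peaks[[nm]],
             file.path(dir, sprintf("peaks_%s.bed", gsub(":", "_", nm))))
  for (ts in names(bundle@cpg))
    writeCpgCoverage(bundle@cpg[[ts]], file.path(dir, sprintf("cpg_%s.tsv", ts)))
  writeExpression(bundle@expression, file.path(dir, "expression.tsv"))
  writeClinical(bundle@clinical, file.path(dir, "clinical.tsv"))
  if (!is.null(bundle@truth))
    write.table(bundle@truth, file.path(dir, "truth.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  cfg <- jsonlite::toJSON(bundle@config, digits = NA, auto_unbox = TRUE,
                          pretty = TRUE, null = "null")
  writeLines(cfg, file.path(dir, "config.json"))
  invisible(dir)
}

#' @rdname writeBundle
#' @export
readBundle <- function(dir) {
  tss <- readTssAnnotation(file.path(dir, "tss.tsv"))
  cgi <- readBed(file.path(dir, "cgi.bed"))
  peak_files <- list.files(dir, pattern = "^peaks_.*\\.bed$", full.names = TRUE)
  peaks <- lapply(peak_files, function(f) {
    g <- readBed(f)
    if (is.null(mcols(g)$score)) mcols(g)$score <- rep(0, length(g))
    g
  })
  names(peaks) <- sub("^peaks_([^_]+)_(.*)\\.bed$", "\\1:\\2",
                      basename(peak_files))
  cov_files <- list.files(dir, pattern = "^cpg_.*\\.tsv$", full.names = TRUE)
  tissues <- sub("^cpg_(.*)\\.tsv$", "\\1", basename(cov_files))
  cpg <- mapply(readCpgCoverage, cov_files, tissues, SIMPLIFY = FALSE)
  names(cpg) <- tissues
  truth_path <- file.path(dir, "truth.tsv")
  truth <- if (file.exists(truth_path))
    read.table(truth_path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  else NULL
  cfg_path <- file.path(dir, "config.json")
  cfg <- if (file.exists(cfg_path)) jsonlite::fromJSON(cfg_path) else list()
  new("ScreenBundle", tss = tss, cgi = cgi, peaks = peaks, cpg = cpg,
      expression = readExpression(file.path(dir, "expression.tsv")),
      clinical = readClinical(file.path(dir, "clinical.tsv")),
      truth = truth, config = as.list(cfg))
}

#' Compare recovered hits against the planted truth
#'
#' Precision, recall and F1 of a gene-level hit list against the planted
#' silenced genes of a simulated bundle.
#'
#' @param hits character vector of recovered gene ids
#' @param truth truth \code{data.frame} with \code{gene_id},
#'   \code{is_silenced}
#' @return list with \code{tp}, \code{fp}, \code{fn}, \code{precision},
#'   \code{recall}, \code{f1}.
#' @export
scoreRecovery <- function(hits, truth) {
  planted <- truth$gene_id[truth$is_silenced]
  tp <- length(intersect(hits, planted))
  fp <- length(setdiff(hits, planted))
  fn <- length(setdiff(planted, hits))
  precision <- if (tp + fp) tp / (tp + fp) else NA_real_
  recall <- if (tp + fn) tp / (tp + fn) else NA_real_
  f1 <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0)
    2 * precision * recall / (precision + recall) else 0
  list(tp = tp, fp = fp, fn = fn, precision = precision, recall = recall,
       f1 = f1)
}
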