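test_that("the generator is a deterministic function of the configuration", {
  cfg <- simulationConfig(seed = 5, nGenes = 40, nSilenced = 4)
  b1 <- generateBundle(cfg)
  b2 <- generateBundle(cfg)
  expect_identical(b1@tss, b2@tss)
  expect_identical(b1@cgi, b2@cgi)
  expect_identical(b1@peaks, b2@peaks)
  expect_identical(lapply(b1@cpg, function(g) mcols(g)$meth_reads),
                   lapply(b2@cpg, function(g) mcols(g)$meth_reads))
  expect_identical(b1@expression, b2@expression)
  expect_identical(b1@clinical, b2@clinical)
  ## different seed, different draws
  b3 <- generateBundle(simulationConfig(seed = 6, nGenes = 40, nSilenced = 4))
  expect_false(identical(b1@clinical$methylation, b3@clinical$methylation))
})

test_that("configuration invariants are enforced", {
  expect_error(simulationConfig(nGenes = 10, nSilenced = 11), "nSilenced")
  expect_error(simulationConfig(tumorMethHigh = 1.2), "Beta means")
  expect_error(simulationConfig(silencingFold = 0.5), "fold")
  cfg <- simulationConfig(seed = 2, nGenes = 50, nSilenced = 5)
  truth <- truthSet(generateBundle(cfg))
  expect_equal(sum(truth$is_silenced), 5)
  expect_true(all(truth$gene_id[truth$is_silenced] %in% truth$gene_id))
})

test_that("observed promoter means converge to the planted Beta means at high depth", {
  cfg <- simulationConfig(seed = 8, nGenes = 30, nSilenced = 6,
                          readDepth = 10000, cpgsPerPromoter = 20)
  b <- generateBundle(cfg)
  s <- summarizePromoter(cpgCalls(b)$tumor_line, tssAnnotation(b))
  truth <- truthSet(b)
  silenced <- truth$gene_id[truth$is_silenced]
  obs <- s$mean_level[match(paste0(silenced, ".1"), s$transcript_id)]
  expect_true(all(abs(obs - 100 * cfg$tumorMethHigh) <= 2))
})

test_that("generated bundles survive the disk round trip through the readers", {
  b <- generateBundle(simulationConfig(seed = 9, nGenes = 30, nSilenced = 3))
  dir <- withr::local_tempdir()
  writeBundle(b, dir)
  back <- readBundle(dir)
  expect_identical(start(back@tss), start(b@tss))
  expect_identical(mcols(back@tss)$transcript_id, mcols(b@tss)$transcript_id)
  expect_setequal(names(back@peaks), names(b@peaks))
  for (nm in names(b@peaks)) {
    expect_identical(start(back@peaks[[nm]]), start(b@peaks[[nm]]))
    expect_identical(mcols(back@peaks[[nm]])$score, mcols(b@peaks[[nm]])$score)
  }
  expect_setequal(names(back@cpg), names(b@cpg))
  for (ts in names(b@cpg))
    expect_identical(mcols(back@cpg[[ts]])$meth_reads,
                     mcols(b@cpg[[ts]])$meth_reads)
  expect_identical(back@expression$value, b@expression$value)
  expect_identical(back@clinical$methylation, b@clinical$methylation)
  expect_identical(back@truth$is_silenced, b@truth$is_silenced)
  ## screens on the original and reloaded bundles agree
  expect_identical(geneHits(runScreen(b)), geneHits(runScreen(back)))
})

test_that("generated intervals stay on the chromosome and CpGs in their promoters", {
  cfg <- simulationConfig(seed = 10, nGenes = 50, nSilenced = 5)
  b <- generateBundle(cfg)
  for (nm in names(b@peaks)) {
    pk <- b@peaks[[nm]]
    if (!length(pk)) next
    expect_true(all(start(pk) >= 1))
    expect_true(all(end(pk) <= cfg$chromLength))
  }
  ## every CpG lies inside some promoter window
  tss <- tssAnnotation(b)
  win <- tssWindow(tss, cfg$promoterHalfwidth)
  for (ts in names(b@cpg))
    expect_true(all(IRanges::overlapsAny(b@cpg[[ts]], win, ignore.strand = TRUE)))
  ## clinical group means are ordered normal < adenoma < advanced <= carcinoma
  cl <- clinicalTable(b)
  means <- tapply(cl$methylation, cl$group, mean)
  expect_true(means["normal"] < means["adenoma"])
  expect_true(means["adenoma"] < means["advanced_adenoma"])
})

test_that("the null clinical generator is valid, deterministic and guarded", {
  expect_error(generateNullClinical(10), "n >= 20")
  clin <- generateNullClinical(100, seed = 12)
  expect_equal(nrow(clin), 100)
  expect_true(all(clin$surv_time > 0))
  expect_true(all(clin$event %in% c(0, 1)))
  expect_true(all(clin$methylation >= 0 & clin$methylation <= 100))
  expect_identical(clin, generateNullClinical(100, seed = 12))
})
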