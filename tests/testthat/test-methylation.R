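test_that("the five bins partition [0, 100] with a closed top bin", {
  expect_equal(as.character(binLevel(65)), "60-80%")
  expect_equal(as.character(binLevel(20)), "20-40%")   # lower-inclusive
  expect_equal(as.character(binLevel(100)), "80-100%") # closed top
  expect_equal(as.character(binLevel(0)), "0-20%")
  grid <- seq(0, 100, by = 0.1)
  b <- binLevel(grid)
  expect_false(anyNA(b))
  expect_equal(levels(b), c("0-20%", "20-40%", "40-60%", "60-80%", "80-100%"))
  ## every boundary lands in exactly the upper bin
  expect_equal(as.character(binLevel(c(20, 40, 60, 80))),
               c("20-40%", "40-60%", "60-80%", "80-100%"))
  expect_error(binLevel(-1), "\\[0, 100\\]")
  expect_error(binLevel(100.1), "\\[0, 100\\]")
})

test_that("promoter summaries average site levels inside the half-open window", {
  tss <- makeTss(10000)
  cpg <- makeCpg(c(9800, 10200), c(8, 2), c(10, 10), "tumor_line")
  s <- summarizePromoter(cpg, tss, minCpgs = 2)
  expect_equal(s$mean_level, 50)
  expect_equal(s$n_cpgs, 2L)
  expect_true(s$available)
  expect_equal(as.character(s$bin), "40-60%")
  expect_equal(s$tissue, "tumor_line")
  ## same counts but minCpgs = 3: unavailable, no level, no bin
  s3 <- summarizePromoter(cpg, tss, minCpgs = 3)
  expect_false(s3$available)
  expect_true(is.na(s3$mean_level))
  expect_true(is.na(s3$bin))
})

test_that("window edges and the depth filter behave as documented", {
  tss <- makeTss(10000)
  ## 0-based promoter window [9500, 10500): +499 in, +500 out
  inside <- makeCpg(c(9500, 10000, 10499), c(10, 10, 10), c(10, 10, 10), "t")
  outside <- makeCpg(c(9499, 10500, 10000, 10001, 10002),
                     c(10, 10, 10, 10, 10), c(10, 10, 10, 10, 10), "t")
  expect_equal(summarizePromoter(inside, tss)$n_cpgs, 3L)
  expect_equal(summarizePromoter(outside, tss)$n_cpgs, 3L)
  ## raising minDepth never increases n_cpgs
  mixed <- makeCpg(c(9700, 9900, 10100, 10300), c(5, 5, 5, 5),
                   c(9, 10, 25, 40), "t")
  n <- vapply(c(1, 10, 26, 50),
              function(d) summarizePromoter(mixed, tss, minDepth = d)$n_cpgs,
              integer(1))
  expect_equal(n, c(4L, 3L, 1L, 0L))
  expect_true(all(diff(n) <= 0))
  ## read-weighted mean differs as expected
  two <- makeCpg(c(9800, 10200), c(8, 2), c(10, 30), "t")
  expect_equal(summarizePromoter(two, tss, minCpgs = 2)$mean_level,
               100 * mean(c(0.8, 2 / 30)))
  expect_equal(summarizePromoter(two, tss, minCpgs = 2, weighted = TRUE)$mean_level,
               100 * 10 / 40)
})

test_that("the cancer-specific filter applies strict thresholds over available normals", {
  mk <- function(level, avail = TRUE) data.frame(
    transcript_id = "t01", tissue = "x",
    mean_level = ifelse(avail, level, NA), n_cpgs = ifelse(avail, 5L, 1L),
    available = avail, bin = NA, stringsAsFactors = FALSE)
  normals5 <- lapply(c(10, 15, 5, 20, 30), mk)
  r <- cancerSpecificFilter(mk(75), normals5)
  expect_true(r$tumor_high && r$normals_low && r$passes)
  ## exactly 60 fails the strict tumor threshold
  expect_false(cancerSpecificFilter(mk(60), normals5)$tumor_high)
  ## one normal at 45 breaks "all normals low"
  r2 <- cancerSpecificFilter(mk(80), lapply(c(10, 45), mk))
  expect_false(r2$normals_low)
  expect_false(r2$passes)
  ## but "any" mode accepts it
  r3 <- cancerSpecificFilter(mk(80), lapply(c(10, 45), mk), normalsMode = "any")
  expect_true(r3$normals_low)
  ## unavailable normals are ignored; none available -> not evaluable
  r4 <- cancerSpecificFilter(mk(80), list(mk(90, avail = FALSE), mk(10)))
  expect_true(r4$passes)
  r5 <- cancerSpecificFilter(mk(80), list(mk(10, avail = FALSE)))
  expect_false(r5$evaluable)
  expect_true(is.na(r5$passes))
  r6 <- cancerSpecificFilter(mk(80, avail = FALSE), list(mk(10)))
  expect_false(r6$evaluable)
})

test_that("the filter is monotone in tumor and normal levels", {
  mk <- function(level) data.frame(transcript_id = "t", tissue = "x",
                                   mean_level = level, n_cpgs = 5L,
                                   available = TRUE, bin = NA)
  set.seed(7)
  for (i in 1:50) {
    tu <- runif(1, 0, 100); nm <- runif(3, 0, 100)
    base <- cancerSpecificFilter(mk(tu), lapply(nm, mk))$passes
    up <- cancerSpecificFilter(mk(min(tu + runif(1, 0, 30), 100)),
                               lapply(nm, mk))$passes
    dn <- cancerSpecificFilter(mk(tu),
                               lapply(pmax(nm - runif(3, 0, 30), 0), mk))$passes
    if (isTRUE(base)) {
      expect_true(up)
      expect_true(dn)
    }
  }
})

test_that("CGI overlap uses the promoter window and matches brute force", {
  tss <- makeTss(10000)
  expect_true(cgiOverlap(tss, makeIntervals(9700, 10400)))
  expect_false(cgiOverlap(tss, makeIntervals(10600, 11000)))  # window ends at 10500
  expect_true(cgiOverlap(tss, makeIntervals(10499, 11000)))
  set.seed(103)
  for (i in 1:150) {
    tss0 <- sample(0:2999, 3)
    s0 <- sample(0:2999, 5, replace = TRUE)
    e0 <- s0 + sample(1:600, 5, replace = TRUE)
    got <- cgiOverlap(makeTss(tss0), makeIntervals(s0, e0))
    expect_identical(got, unname(bruteWindowOverlap(tss0, 500, s0, e0)))
  }
})
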