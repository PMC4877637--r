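test_that("TSS windows are symmetric, strand-independent and clamped at 0", {
  tss <- makeTss(c(10000, 10000, 300), strand = c("+", "-", "+"))
  w2 <- tssWindow(tss, 2000)
  expect_equal(start(w2) - 1L, c(8000L, 8000L, 0L))  # 0-based starts
  expect_equal(end(w2), c(12000L, 12000L, 2300L))    # 0-based exclusive ends
  w5 <- tssWindow(tss[1], 5000)
  expect_equal(c(start(w5) - 1L, end(w5)), c(5000L, 15000L))
  expect_error(tssWindow(tss, 0))
})

test_that("mark calls use half-open overlap: one shared base is enough", {
  tss <- makeTss(10000)
  ## window is 0-based [8000, 12000)
  expect_true(callMark(tss, makeIntervals(11999, 12500), 2000)$positive)
  expect_false(callMark(tss, makeIntervals(12000, 12500), 2000)$positive)
  expect_true(callMark(tss, makeIntervals(0, 8001), 2000)$positive)
  expect_false(callMark(tss, makeIntervals(0, 8000), 2000)$positive)
})

test_that("signal is the max score over overlapping peaks and implies positivity", {
  tss <- makeTss(10000)
  pk <- makeIntervals(c(9000, 9500, 13000), c(9400, 9900, 14000),
                      score = c(5, 17, 99))
  call <- callMark(tss, pk, 2000)
  expect_true(call$positive)
  expect_equal(call$signal, 17)
  ## absent chromosome: all-negative, not an error
  far <- makeIntervals(1, 100, chrom = "chrOther", score = 3)
  call2 <- callMark(tss, far, 2000)
  expect_false(call2$positive)
  expect_equal(call2$signal, 0)
  expect_error(callMark(tss, makeIntervals(9000, 9400, score = -1), 2000),
               "non-negative")
})

test_that("mark calls match a per-base brute-force scan on random instances", {
  set.seed(101)
  for (i in 1:250) {
    n_tss <- sample(1:6, 1)
    tss0 <- sample(0:2999, n_tss)
    hw <- sample(c(5, 50, 500), 1)
    n_pk <- sample(0:8, 1)
    s0 <- sample(0:2999, n_pk, replace = TRUE)
    e0 <- s0 + sample(1:400, max(n_pk, 1), replace = TRUE)[seq_len(n_pk)]
    tss <- makeTss(tss0)
    pk <- if (n_pk) makeIntervals(s0, e0) else makeIntervals(integer(), integer())
    got <- callMark(tss, pk, hw)$positive
    want <- bruteWindowOverlap(tss0, hw, s0, e0)
    expect_identical(got, unname(want))
  }
})

test_that("enlarging the window never turns a positive call negative", {
  set.seed(102)
  for (i in 1:40) {
    tss0 <- sample(0:5000, 4)
    s0 <- sample(0:5000, 6, replace = TRUE)
    pk <- makeIntervals(s0, s0 + sample(1:500, 6, replace = TRUE))
    tss <- makeTss(tss0)
    small <- callMark(tss, pk, 100)$positive
    big <- callMark(tss, pk, 1000)$positive
    expect_true(all(big[small]))
  }
})

test_that("gain detection distinguishes de novo acquisition from upregulation", {
  mkcall <- function(pos, sig) data.frame(
    transcript_id = c("a", "b", "c"), positive = pos, signal = sig,
    stringsAsFactors = FALSE)
  parent <- mkcall(c(FALSE, TRUE, FALSE), c(0, 10, 0))
  deriv <- mkcall(c(TRUE, TRUE, FALSE), c(30, 30, 0))
  bin <- detectGain(parent, deriv, mode = "binary")
  expect_equal(bin$gained, c(TRUE, FALSE, FALSE))
  quant <- detectGain(parent, deriv, mode = "quantitative", minRatio = 2)
  ## b: ratio (30+1)/(10+1) ~ 2.82 >= 2 -> gained in quantitative mode
  expect_equal(quant$gained, c(TRUE, TRUE, FALSE))
  expect_equal(quant$ratio[2], 31 / 11)
  ## minRatio = Inf reduces quantitative mode to binary mode
  inf <- detectGain(parent, deriv, mode = "quantitative", minRatio = Inf)
  expect_equal(inf$gained, bin$gained)
  ## mismatched universes are a consistency error
  expect_error(detectGain(parent, deriv[1:2, ], mode = "binary"),
               "universe")
})

test_that("the H3K4me3 universe is the union of positives in either line", {
  parent <- data.frame(transcript_id = c("a", "b", "c"),
                       positive = c(TRUE, FALSE, FALSE), signal = c(1, 0, 0))
  deriv <- data.frame(transcript_id = c("a", "b", "c"),
                      positive = c(TRUE, TRUE, FALSE), signal = c(1, 1, 0))
  expect_equal(h3k4Universe(parent, deriv), c("a", "b"))
  ## disjoint positives counted once each
  parent$positive <- c(TRUE, FALSE, FALSE)
  deriv$positive <- c(FALSE, TRUE, FALSE)
  expect_equal(h3k4Universe(parent, deriv), c("a", "b"))
  expect_equal(h3k4Universe(parent[0, ], deriv[0, ]), character(0))
  tab <- k4StatusCounts(parent, deriv)
  expect_equal(as.vector(tab), c(1L, 1L, 1L, 0L))  # neither, parent-only, deriv-only, both
})
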