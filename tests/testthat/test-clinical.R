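test_that("elevation is strict at the threshold and composes into frequencies", {
  expect_equal(classifyElevated(c(15, 15.1, 10, 30)),
               c(FALSE, TRUE, FALSE, TRUE))
  expect_error(classifyElevated(101), "\\[0, 100\\]")
  expect_equal(formatFraction(sum(classifyElevated(c(10, 20, 30))), 3), "66.7%")
  clin <- data.frame(sample_id = as.character(1:6),
                     group = rep(c("normal", "carcinoma"), each = 3),
                     methylation = c(5, 10, 16, 20, 30, 14))
  tab <- elevationByGroup(clin)
  expect_equal(tab$n_elevated, c(1L, 2L))
  expect_equal(tab$frequency, c("33.3%", "66.7%"))
})

test_that("the pooled t statistic matches the closed-form hand computation", {
  ## identical groups: t = 0, p = 1
  r0 <- twoGroupTTest(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r0$t, 0)
  expect_equal(r0$p, 1)
  ## swapping groups negates t, p unchanged
  a <- c(0.3, 1.1, 2.7); b <- c(1.9, 2.2, 4.0)
  expect_equal(twoGroupTTest(a, b)$t, -twoGroupTTest(b, a)$t)
  expect_equal(twoGroupTTest(a, b)$p, twoGroupTTest(b, a)$p)
  ## hand computation: pooled s2 = 1/3, se = sqrt(1/6), t = -sqrt(6), df = 6
  r <- twoGroupTTest(c(0, 0, 1, 1), c(1, 1, 2, 2))
  expect_equal(r$t, -sqrt(6), tolerance = 1e-12)
  expect_equal(r$df, 6)
  expect_equal(r$p, 2 * pt(-sqrt(6), 6), tolerance = 1e-12)
  expect_error(twoGroupTTest(c(1, 1), c(1, 1)), "variance")
  expect_error(twoGroupTTest(1, c(1, 2)), "at least 2")
})

test_that("Pearson correlation matches hand computations and is exact on linear data", {
  expect_equal(pearsonCor(c(0, 1, 2), c(0, 1, 2))$r, 1)
  expect_equal(pearsonCor(c(1, 2, 3), c(3, 2, 1))$r, -1)
  ## hand computation: cov = 1/2 of sx*sy -> r = 0.5
  r <- pearsonCor(c(1, 2, 3), c(1, 3, 2))
  expect_equal(r$r, 0.5, tolerance = 1e-12)
  tt <- 0.5 * sqrt(1 / (1 - 0.25))
  expect_equal(r$p, 2 * pt(-tt, 1), tolerance = 1e-12)
  expect_false(r$significant)
  expect_error(pearsonCor(c(1, 1, 1), c(1, 2, 3)), "constant")
  set.seed(105)
  for (i in 1:20) {
    x <- rnorm(10); a <- runif(1, -3, 3); b <- runif(1, -5, 5)
    if (abs(a) < 0.1) a <- 1
    expect_equal(abs(pearsonCor(x, a * x + b)$r), 1)
  }
})

test_that("the product-limit estimator handles events and censoring correctly", {
  km <- kmEstimate(c(1, 2, 3), c(1, 1, 1))
  expect_equal(km$surv, c(2 / 3, 1 / 3, 0))
  ## all censored: survival stays at 1
  expect_true(all(kmEstimate(c(1, 2, 3), c(0, 0, 0))$surv == 1))
  ## censoring removes from the risk set only: S(1) = 2/3, S(3) = 0
  km2 <- kmEstimate(c(1, 2, 3), c(1, 0, 1))
  expect_equal(km2$surv[km2$time == 1], 2 / 3)
  expect_equal(km2$surv[km2$time == 3], 0)
  expect_error(kmEstimate(numeric(0), numeric(0)), "empty")
  expect_error(kmEstimate(c(0, 1), c(1, 1)), "positive")
})

test_that("with no censoring the KM curve equals the empirical survival function", {
  set.seed(106)
  for (i in 1:100) {
    t <- round(rexp(sample(5:40, 1), 0.1), 2) + 0.01
    km <- kmEstimate(t, rep(1, length(t)))
    ecdf_surv <- vapply(km$time, function(x) mean(t > x), numeric(1))
    expect_equal(km$surv, ecdf_surv, tolerance = 1e-12)
  }
})

test_that("the log-rank statistic matches a hand-built O/E/V table", {
  ## identical groups -> chi2 = 0, p = 1
  r0 <- logRank(c(1, 2, 3), c(1, 1, 1), c(1, 2, 3), c(1, 1, 1))
  expect_equal(r0$chi2, 0)
  expect_equal(r0$p, 1)
  ## six-subject example against the O/E/V oracle
  tA <- c(3, 6, 9); eA <- c(1, 1, 0)
  tB <- c(2, 5, 8); eB <- c(1, 1, 1)
  got <- logRank(tA, eA, tB, eB)
  want <- bruteLogRank(tA, eA, tB, eB)
  expect_equal(got$chi2, want$chi2, tolerance = 1e-10)
  expect_equal(got$p, want$p, tolerance = 1e-10)
  ## label swap leaves the statistic unchanged
  sw <- logRank(tB, eB, tA, eA)
  expect_equal(sw$chi2, got$chi2)
  expect_error(logRank(c(1, 2), c(0, 0), c(3), c(0)), "no events")
  expect_error(logRank(numeric(0), numeric(0), c(1), c(1)), "non-empty")
})

test_that("log-rank agrees with the O/E/V oracle on random censored data", {
  set.seed(107)
  for (i in 1:30) {
    nA <- sample(5:15, 1); nB <- sample(5:15, 1)
    tA <- ceiling(rexp(nA, 0.05)); eA <- rbinom(nA, 1, 0.7)
    tB <- ceiling(rexp(nB, 0.1)); eB <- rbinom(nB, 1, 0.7)
    if (sum(eA) + sum(eB) == 0) next
    got <- logRank(tA, eA, tB, eB)
    want <- bruteLogRank(tA, eA, tB, eB)
    expect_equal(got$chi2, want$chi2, tolerance = 1e-8)
  }
})

test_that("the cutoff scan is exhaustive, admissible and minimal-p", {
  clin <- generateNullClinical(40, seed = 3)
  res <- findCutoff(clin)
  scan <- scanTable(res)
  ## best p never exceeds any scanned p; group sizes respect the constraint
  expect_equal(res@pAtBest, min(scan$p))
  expect_true(all(scan$n_low >= ceiling(0.1 * 40)))
  expect_true(all(scan$n_high >= ceiling(0.1 * 40)))
  expect_true(all(scan$n_low + scan$n_high == 40))
  ## the best cutoff is in the scan and attains the minimum
  expect_true(any(abs(scan$cutoff - bestCutoff(res)) < 1e-12 &
                    abs(scan$p - res@pAtBest) < 1e-12))
  ## KM support points exist for both groups and start at or below 1
  km <- kmSupport(res)
  expect_setequal(unique(km$group), c("low", "high"))
  expect_true(all(km$surv <= 1 & km$surv >= 0))
})

test_that("degenerate cutoff inputs are rejected with clear errors", {
  clin <- generateNullClinical(30, seed = 4)
  expect_error(findCutoff(clin[1:10, ]), "need >= 20")
  same <- clin; same$methylation <- 50
  expect_error(findCutoff(same), "distinct")
  ## min group fraction of 60% leaves no admissible split
  expect_error(findCutoff(clin, minGroupFrac = 0.6), "admissible")
})

test_that("ties in p break toward the more balanced split", {
  ## symmetric cohort: two mirrored cutoffs give identical statistics
  clin <- data.frame(sample_id = as.character(1:24), group = "carcinoma",
                     methylation = rep(c(10, 20, 30, 40), each = 6),
                     expression = NA_real_,
                     surv_time = rep(c(5, 10, 15, 20, 25, 30), 4),
                     event = rep(1, 24))
  res <- findCutoff(clin)
  scan <- scanTable(res)
  minp <- scan[abs(scan$p - min(scan$p)) < 1e-12, ]
  if (nrow(minp) > 1) {
    bal <- abs(minp$n_low - minp$n_high)
    got <- abs(res@groupSizes[1] - res@groupSizes[2])
    expect_equal(unname(got), min(bal))
  }
  expect_s4_class(res, "SurvivalCutoff")
})
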