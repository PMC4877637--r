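#' @importFrom stats t.test cor.test pchisq rbeta rbinom rexp rlnorm rnorm
#'   rpois runif median setNames
#' @importFrom survival Surv survfit survdiff
NULL

#' Elevated-methylation classification
#'
#' A clinical methylation percentage counts as elevated when it strictly
#' exceeds the threshold (default 15.0 percent); exactly 15.0 is not
#' elevated.
#'
#' @param methylation percent methylation in [0, 100] (vectorized)
#' @param threshold elevation threshold in percent (default 15)
#' @return logical vector.
#' @examples
#' classifyElevated(c(10, 15, 15.1, 30))
#' @export
classifyElevated <- function(methylation, threshold = 15) {
  if (any(is.na(methylation)) || any(methylation < 0 | methylation > 100))
    stop("methylation must lie in [0, 100]", call. = FALSE)
  methylation > threshold
}

#' Per-group elevation frequencies
#'
#' Tabulates, per clinical group, the number and formatted percentage of
#' samples with elevated methylation.
#'
#' @param clinical clinical \code{data.frame} (\code{\link{readClinical}})
#' @param threshold elevation threshold in percent (default 15)
#' @return \code{data.frame}: \code{group}, \code{n}, \code{n_elevated},
#'   \code{frequency} (formatted percent string).
#' @export
elevationByGroup <- function(clinical, threshold = 15) {
  elev <- classifyElevated(clinical$methylation, threshold)
  groups <- intersect(.clinical_groups, unique(clinical$group))
  do.call(rbind, lapply(groups, function(g) {
    sel <- clinical$group == g
    data.frame(group = g, n = sum(sel), n_elevated = sum(elev[sel]),
               frequency = formatFraction(sum(elev[sel]), sum(sel)),
               stringsAsFactors = FALSE)
  }))
}

#' Unpaired two-tailed Student's t test
#'
#' Equal-variance pooled t statistic with a two-sided p-value on
#' \code{length(a) + length(b) - 2} degrees of freedom; set
#' \code{welch = TRUE} for the unequal-variance variant.
#'
#' @param a,b numeric vectors, each of length >= 2
#' @param welch use the Welch correction instead of pooled variance
#' @return list with \code{t}, \code{p}, \code{df}.
#' @export
twoGroupTTest <- function(a, b, welch = FALSE) {
  if (length(a) < 2 || length(b) < 2)
    stop("each group needs at least 2 observations", call. = FALSE)
  if (stats::var(a) + stats::var(b) == 0)
    stop("degenerate input: zero pooled variance", call. = FALSE)
  fit <- t.test(a, b, var.equal = !welch, alternative = "two.sided")
  list(t = unname(fit$statistic), p = fit$p.value,
       df = unname(fit$parameter))
}

#' Pearson correlation with two-sided p-value
#'
#' Product-moment correlation with the t-based two-sided p-value
#' (\code{t = r * sqrt((n - 2) / (1 - r^2))}); significance is declared at
#' \code{p < alpha} (default 0.01, two-sided).
#'
#' @param x,y numeric vectors of equal length >= 3, both non-constant
#' @param alpha significance level (default 0.01)
#' @return list with \code{r}, \code{p}, \code{n}, \code{significant}.
#' @export
pearsonCor <- function(x, y, alpha = 0.01) {
  if (length(x) != length(y) || length(x) < 3)
    stop("need paired vectors of length >= 3", call. = FALSE)
  if (stats::var(x) == 0 || stats::var(y) == 0)
    stop("degenerate input: constant vector", call. = FALSE)
  fit <- cor.test(x, y, method = "pearson", alternative = "two.sided")
  r <- unname(fit$estimate)
  p <- fit$p.value
  list(r = r, p = p, n = length(x), significant = p < alpha)
}

#' Kaplan-Meier product-limit estimate
#'
#' Right-censored product-limit survival estimate. The returned step
#' function starts at S = 1 and is non-increasing; censoring removes
#' subjects from the risk set without an event step.
#'
#' @param times positive event/censoring times
#' @param events event indicators (1 = death, 0 = censored)
#' @return \code{data.frame} with one row per distinct event or censoring
#'   time: \code{time}, \code{n_risk}, \code{n_event}, \code{surv}.
#' @export
kmEstimate <- function(times, events) {
  if (length(times) == 0) stop("empty survival input", call. = FALSE)
  if (any(times <= 0)) stop("times must be positive", call. = FALSE)
  if (!all(events %in% c(0, 1))) stop("events must be 0/1", call. = FALSE)
  fit <- survfit(Surv(times, events) ~ 1, conf.type = "none")
  data.frame(time = fit$time, n_risk = fit$n.risk,
             n_event = fit$n.event, surv = fit$surv)
}

#' Two-group log-rank test
#'
#' Standard 1-df log-rank chi-square comparing two survival curves
#' (observed vs expected events summed over distinct event times), with
#' the p-value from the chi-square reference distribution. Symmetric in
#' the two groups.
#'
#' @param timesA,eventsA times and 0/1 event indicators for group A
#' @param timesB,eventsB same for group B
#' @return list with \code{chi2}, \code{p}.
#' @export
logRank <- function(timesA, eventsA, timesB, eventsB) {
  if (length(timesA) == 0 || length(timesB) == 0)
    stop("both groups must be non-empty", call. = FALSE)
  if (sum(eventsA) + sum(eventsB) == 0)
    stop("degenerate input: no events", call. = FALSE)
  grp <- factor(c(rep("A", length(timesA)), rep("B", length(timesB))))
  fit <- survdiff(Surv(c(timesA, timesB), c(eventsA, eventsB)) ~ grp, rho = 0)
  chi2 <- unname(fit$chisq)
  list(chi2 = chi2, p = pchisq(chi2, df = 1, lower.tail = FALSE))
}

#' Optimal-cutoff survival dichotomization
#'
#' Scans every admissible dichotomizing cutoff of a continuous methylation
#' marker (candidate cutoffs are midpoints between consecutive sorted
#' distinct values; a cutoff is admissible when both resulting groups hold
#' at least \code{minGroupFrac} of the samples) and selects the cutoff
#' minimizing the log-rank p-value — the "minimal log-rank p" variant of
#' cutoff optimization. Ties on p are broken toward the more balanced
#' split, then toward the lower cutoff.
#'
#' The reported p-value is \emph{uncorrected} for the multiple cutoffs
#' examined and is therefore optimistic; see
#' \code{\link{generateNullClinical}} for a null generator that documents
#' the inflation.
#'
#' @param clinical clinical \code{data.frame} with \code{methylation},
#'   \code{surv_time}, \code{event} (rows without survival are dropped)
#' @param minGroupFrac minimum fraction of samples on each side of the
#'   cutoff (default 0.10)
#' @param minSamples minimum number of samples with survival (default 20)
#' @return a \code{\linkS4class{SurvivalCutoff}} object.
#' @export
findCutoff <- function(clinical, minGroupFrac = 0.10, minSamples = 20) {
  d <- clinical[!is.na(clinical$surv_time) & !is.na(clinical$event), ]
  n <- nrow(d)
  if (n < minSamples)
    stop(sprintf("need >= %d samples with survival data, got %d",
                 minSamples, n), call. = FALSE)
  vals <- sort(unique(d$methylation))
  if (length(vals) < 2)
    stop("need >= 2 distinct methylation values", call. = FALSE)
  cand <- (vals[-1] + vals[-length(vals)]) / 2
  minN <- ceiling(minGroupFrac * n)
  rows <- lapply(cand, function(ct) {
    hi <- d$methylation > ct
    n_hi <- sum(hi); n_lo <- n - n_hi
    if (n_hi < minN || n_lo < minN) return(NULL)
    lr <- tryCatch(
      logRank(d$surv_time[!hi], d$event[!hi], d$surv_time[hi], d$event[hi]),
      error = function(e) NULL)
    if (is.null(lr)) return(NULL)
    data.frame(cutoff = ct, n_low = n_lo, n_high = n_hi,
               chi2 = lr$chi2, p = lr$p)
  })
  scan <- do.call(rbind, rows)
  if (is.null(scan) || nrow(scan) == 0)
    stop("no admissible cutoff under the group-size constraint", call. = FALSE)
  ord <- order(scan$p, abs(scan$n_low - scan$n_high), scan$cutoff)
  best <- scan[ord[1], ]
  hi <- d$methylation > best$cutoff
  km <- rbind(
    cbind(group = "low", kmEstimate(d$surv_time[!hi], d$event[!hi])),
    cbind(group = "high", kmEstimate(d$surv_time[hi], d$event[hi])))
  new("SurvivalCutoff",
      bestCutoff = best$cutoff, chi2 = best$chi2, pAtBest = best$p,
      groupSizes = c(low = as.integer(best$n_low), high = as.integer(best$n_high)),
      scan = scan[order(scan$cutoff), , drop = FALSE],
      km = km[, c("group", "time", "surv")],
      method = "minimal log-rank p (uncorrected)")
}
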