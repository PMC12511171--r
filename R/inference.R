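# Cohort-level inference: paired signed-rank comparisons between regions and
# the median-cutoff univariate survival screen (Kaplan-Meier / Cox).

#' Wilcoxon signed-rank test for paired samples
#'
#' Classical signed-rank conventions: zero differences are dropped; tied
#' absolute differences receive average ranks; W is the sum of ranks of
#' positive differences. The two-sided p-value is exact (from the signed-rank
#' distribution, equivalent to enumerating all 2^n sign assignments) when the
#' number of non-zero differences is at most `exactMax` and there are no
#' ties; otherwise a normal approximation with tie correction and continuity
#' correction is used.
#'
#' @param a,b paired numeric vectors of equal length.
#' @param exactMax largest n for which the exact distribution is used
#'   (default 25).
#' @return list with `statistic` (W), `p_value` (two-sided), `n_used`
#'   (non-zero differences), and `exact` (logical).
#' @export
wilcoxonSignedRank <- function(a, b, exactMax = 25L) {
  stopifnot(length(a) == length(b))
  d <- a - b
  d <- d[!is.na(d)]
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) stop("no informative pairs: all differences are zero")
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  ties <- anyDuplicated(abs(d)) > 0L
  if (!ties && n <= exactMax) {
    # exact two-sided p from the null distribution of W over sign assignments
    pLo <- stats::psignrank(W, n)
    pHi <- 1 - stats::psignrank(W - 1, n)
    p <- min(1, 2 * min(pLo, pHi))
    exact <- TRUE
  } else {
    mu <- n * (n + 1) / 4
    tieTab <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(tieTab^3 - tieTab) / 48
    cc <- sign(W - mu) * 0.5                  # continuity correction toward mu
    z <- (W - mu - cc) / sqrt(sigma2)
    p <- 2 * stats::pnorm(-abs(z))
    exact <- FALSE
  }
  list(statistic = W, p_value = p, n_used = n, exact = exact)
}

#' Paired comparison of a metric between two regions
#'
#' Assembles per-patient pairs of the metric in the two regions, excludes
#' patients with a missing value in either region (pairwise exclusion), and
#' runs the Wilcoxon signed-rank test. Medians are reported per region over
#' the included patients.
#'
#' @param tbl tidy data.frame with columns `patient_id`, `region_label`, and
#'   the metric value (already filtered to a single metric, i.e. one row per
#'   patient and region).
#' @param valueCol name of the value column.
#' @param regionPair character vector of two region labels, compared as
#'   first vs second.
#' @param metricName label recorded in the result.
#' @return one-row data.frame: `metric`, `region_a`, `region_b`, `n_pairs`,
#'   `statistic`, `p_value`, `median_a`, `median_b`.
#' @export
compareRegions <- function(tbl, valueCol, regionPair, metricName = valueCol) {
  stopifnot(length(regionPair) == 2L,
            all(c("patient_id", "region_label", valueCol) %in% names(tbl)))
  a <- tbl[tbl$region_label == regionPair[1L], c("patient_id", valueCol)]
  b <- tbl[tbl$region_label == regionPair[2L], c("patient_id", valueCol)]
  if (anyDuplicated(a$patient_id) || anyDuplicated(b$patient_id))
    stop("tbl must hold one row per patient and region; filter to one metric")
  m <- merge(a, b, by = "patient_id", suffixes = c("_a", "_b"))
  va <- m[[paste0(valueCol, "_a")]]
  vb <- m[[paste0(valueCol, "_b")]]
  ok <- !is.na(va) & !is.na(vb)
  if (sum(ok) < 2L)
    stop("fewer than 2 informative pairs for ", metricName, " ",
         regionPair[1L], " vs ", regionPair[2L])
  wt <- wilcoxonSignedRank(va[ok], vb[ok])
  data.frame(metric = metricName,
             region_a = regionPair[1L], region_b = regionPair[2L],
             n_pairs = sum(ok), statistic = wt$statistic,
             p_value = wt$p_value,
             median_a = stats::median(va[ok]), median_b = stats::median(vb[ok]))
}

#' Median split of a per-patient feature
#'
#' The cohort median is the pre-specified cutoff: values strictly above the
#' median are `high`, values at or below are `low`; missing values are
#' excluded.
#'
#' @param values numeric vector (optionally named by patient).
#' @return list with `groups` (factor `low`/`high`, `NA` for missing) and
#'   `cutoff` (the median of the non-missing values).
#' @export
medianSplit <- function(values) {
  ok <- !is.na(values)
  if (sum(ok) < 2L) stop("need at least 2 non-missing values")
  med <- stats::median(values[ok])
  if (all(values[ok] == values[ok][1L]))
    stop("degenerate split: all values identical")
  g <- rep(NA_character_, length(values))
  g[ok] <- ifelse(values[ok] > med, "high", "low")
  list(groups = factor(g, levels = c("low", "high")), cutoff = med)
}

#' Kaplan-Meier estimate
#'
#' Product-limit estimate of the survival function. The median is the
#' earliest time at which the estimated survival drops to 0.5 or below,
#' undefined (`NA`) if never reached.
#'
#' @param times survival times in months (> 0).
#' @param events logical event indicators (TRUE = event, FALSE = censored).
#' @return list with `time`, `surv`, `n_risk` (step function over the
#'   observed times) and `median`.
#' @export
kmEstimate <- function(times, events) {
  stopifnot(length(times) == length(events), length(times) >= 1L,
            all(times > 0))
  fit <- survival::survfit(survival::Surv(times, events) ~ 1)
  med <- if (any(fit$surv <= 0.5)) fit$time[which(fit$surv <= 0.5)[1L]]
         else NA_real_
  list(time = fit$time, surv = fit$surv, n_risk = fit$n.risk, median = med)
}

#' Univariate Cox proportional-hazards fit for a median-split group
#'
#' Fits a proportional-hazards model with the single binary covariate
#' high-vs-low (low is reference), Efron handling of tied event times. The
#' hazard ratio is exp(coefficient); the 95 percent confidence interval is
#' exp(coefficient +/- 1.96 SE) with the standard error from the observed
#' information; the p-value is the Wald test. If one group has no events
#' together with complete separation the fit does not converge and the result
#' says so (fields set to `NA`, `converged = FALSE`) rather than reporting a
#' spurious number.
#'
#' @param groups factor with levels `low`, `high` (as from [medianSplit()]).
#' @param times survival times in months.
#' @param events logical event indicators.
#' @param featureName,endpoint,cutoff labels recorded in the result.
#' @return one-row data.frame: `feature`, `endpoint`, `cutoff`, `n_high`,
#'   `n_low`, `hazard_ratio`, `ci_lower`, `ci_upper`, `p_value`, `converged`.
#' @export
univariateCox <- function(groups, times, events, featureName = "feature",
                          endpoint = "OS", cutoff = NA_real_) {
  ok <- !is.na(groups) & !is.na(times) & !is.na(events)
  groups <- groups[ok]; times <- times[ok]; events <- events[ok]
  nHigh <- sum(groups == "high"); nLow <- sum(groups == "low")
  if (nHigh == 0L || nLow == 0L) stop("both groups must be non-empty")
  if (sum(events) == 0L) stop("at least one event is required")
  base <- data.frame(feature = featureName, endpoint = endpoint,
                     cutoff = cutoff, n_high = nHigh, n_low = nLow)
  x <- as.integer(groups == "high")
  fit <- tryCatch(
    suppressWarnings(survival::coxph(
      survival::Surv(times, events) ~ x, ties = "efron")),
    error = function(e) NULL)
  beta <- if (is.null(fit)) NA_real_ else unname(stats::coef(fit))
  se <- if (is.null(fit)) NA_real_ else sqrt(unname(diag(fit$var)))[1L]
  badFit <- is.null(fit) || !is.finite(beta) || !is.finite(se) ||
    abs(beta) > 15
  if (badFit) {
    cbind(base, data.frame(hazard_ratio = NA_real_, ci_lower = NA_real_,
                           ci_upper = NA_real_, p_value = NA_real_,
                           converged = FALSE))
  } else {
    z <- beta / se
    cbind(base, data.frame(
      hazard_ratio = exp(beta),
      ci_lower = exp(beta - 1.96 * se),
      ci_upper = exp(beta + 1.96 * se),
      p_value = 2 * stats::pnorm(-abs(z)),
      converged = TRUE))
  }
}

#' Median-cutoff univariate survival screen
#'
#' For every feature column and endpoint: split the cohort at the feature
#' median (high = strictly above) and fit the univariate proportional-hazards
#' model. Raw p-values are reported without multiplicity adjustment by
#' default; set `adjust = "BH"` for Benjamini-Hochberg adjusted values in an
#' extra column. Degenerate features (all values identical, or a group
#' without patients) are skipped with a warning.
#'
#' @param features data.frame with `patient_id` plus one numeric column per
#'   feature.
#' @param clinical clinical records data.frame (needs `patient_id`,
#'   `os_months`, `os_event`, `pfs_months`, `pfs_event`).
#' @param endpoints subset of `c("OS", "PFS")`.
#' @param adjust `"none"` (default) or `"BH"`.
#' @return data.frame of [univariateCox()] rows, one per feature x endpoint.
#' @export
runSurvivalScreen <- function(features, clinical,
                              endpoints = c("OS", "PFS"), adjust = "none") {
  stopifnot("patient_id" %in% names(features), nrow(clinical) >= 2L)
  endpoints <- match.arg(endpoints, c("OS", "PFS"), several.ok = TRUE)
  m <- merge(features, clinical, by = "patient_id")
  featCols <- setdiff(names(features), "patient_id")
  rows <- list()
  for (ep in endpoints) {
    tm <- if (ep == "OS") m$os_months else m$pfs_months
    ev <- if (ep == "OS") m$os_event else m$pfs_event
    for (fc in featCols) {
      res <- tryCatch({
        sp <- medianSplit(m[[fc]])
        univariateCox(sp$groups, tm, ev, featureName = fc, endpoint = ep,
                      cutoff = sp$cutoff)
      }, error = function(e) {
        warning("skipping feature '", fc, "' (", ep, "): ",
                conditionMessage(e), call. = FALSE)
        NULL
      })
      if (!is.null(res)) rows[[length(rows) + 1L]] <- res
    }
  }
  out <- do.call(rbind, rows)
  if (!is.null(out) && adjust == "BH")
    out$p_adjusted <- stats::p.adjust(out$p_value, method = "BH")
  out
}
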