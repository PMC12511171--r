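test_that("signed-rank test matches hand-computed exact cases", {
  # n=5, all differences positive: W = 15, exact two-sided p = 2/32
  res <- wilcoxonSignedRank(c(2, 4, 6, 8, 10), c(1, 2, 3, 4, 5))
  expect_equal(res$statistic, 15)
  expect_equal(res$p_value, 0.0625)
  expect_true(res$exact)
  # all differences zero -> no informative pairs
  expect_error(wilcoxonSignedRank(1:4, 1:4), "no informative pairs")
  # zero differences are dropped, not ranked
  res2 <- wilcoxonSignedRank(c(1, 2, 4, 6, 8, 10), c(1, 1, 2, 3, 4, 5))
  expect_equal(res2$n_used, 5L)
  expect_equal(res2$statistic, 15)
})

test_that("swapping the samples mirrors W and keeps p", {
  set.seed(31)
  a <- rnorm(12); b <- rnorm(12)
  r1 <- wilcoxonSignedRank(a, b)
  r2 <- wilcoxonSignedRank(b, a)
  expect_equal(r1$p_value, r2$p_value)
  n <- r1$n_used
  expect_equal(r2$statistic, n * (n + 1) / 2 - r1$statistic)
})

test_that("signed-rank p agrees with the reference implementation", {
  set.seed(91)
  # exact branch (no ties)
  a <- rnorm(15); b <- rnorm(15)
  expect_equal(wilcoxonSignedRank(a, b)$p_value,
               wilcox.test(a, b, paired = TRUE, exact = TRUE)$p.value)
  # tied branch: normal approximation with tie + continuity correction
  a2 <- c(5, 5, 5, 3, 3, 8, 8, 1, 2, 9, 4, 4, 7, 7, 6, 6, 2, 3, 8, 5,
          1, 1, 9, 9, 2, 6, 4, 3, 7, 8)
  b2 <- c(3, 3, 6, 6, 1, 1, 9, 4, 4, 2, 2, 8, 8, 5, 5, 3, 7, 7, 2, 2,
          6, 4, 4, 1, 9, 9, 3, 8, 8, 5)
  expect_equal(wilcoxonSignedRank(a2, b2)$p_value,
               suppressWarnings(
                 wilcox.test(a2, b2, paired = TRUE, exact = FALSE,
                             correct = TRUE)$p.value))
})

test_that("compareRegions pairs patients and excludes missing values pairwise", {
  tbl <- data.frame(
    patient_id = rep(paste0("P", 1:6), each = 2),
    region_label = rep(c("CORE", "PERIPHERY"), 6),
    density = c(10, 2, 20, 4, 30, 6, 40, 8, 50, 10, 60, 12))
  # drop P6's periphery row entirely
  tbl <- tbl[-12, ]
  res <- compareRegions(tbl, "density", c("CORE", "PERIPHERY"), "tumor")
  expect_equal(res$n_pairs, 5L)
  expect_equal(res$statistic, 15)
  expect_equal(res$p_value, 0.0625)
  expect_equal(res$median_a, 30)
  expect_equal(res$median_b, 6)
  # an NA value excludes that pair too
  tbl$density[2] <- NA
  expect_equal(compareRegions(tbl, "density", c("CORE", "PERIPHERY"))$n_pairs,
               4L)
  expect_error(compareRegions(tbl[1:3, ], "density",
                              c("CORE", "PERIPHERY")),
               "fewer than 2")
})

test_that("median split uses strictly-above-median as high", {
  sp <- medianSplit(c(1, 2, 3, 4, 5))
  expect_equal(as.character(sp$groups), c("low", "low", "low", "high", "high"))
  expect_equal(sp$cutoff, 3)
  sp2 <- medianSplit(c(10, 20, 30, 40))
  expect_equal(sum(sp2$groups == "high"), 2L)
  expect_equal(sum(sp2$groups == "low"), 2L)
  expect_error(medianSplit(rep(7, 10)), "degenerate")
  sp3 <- medianSplit(c(1, 2, NA, 4))
  expect_true(is.na(sp3$groups[3]))
})

test_that("Kaplan-Meier estimates match the empirical survival function without censoring", {
  t <- c(3, 1, 4, 1, 5, 9, 2, 6)
  km <- kmEstimate(t, rep(TRUE, 8))
  emp <- sapply(km$time, function(x) mean(t > x))
  expect_equal(km$surv, emp)
  expect_equal(km$median, 3)   # first time with S(t) <= 0.5
  # all censored: curve stays at 1, median undefined
  km2 <- kmEstimate(t, rep(FALSE, 8))
  expect_true(all(km2$surv == 1))
  expect_true(is.na(km2$median))
  # single death
  km3 <- kmEstimate(14, TRUE)
  expect_equal(km3$surv, 0)
  expect_equal(km3$median, 14)
})

test_that("Cox fits are symmetric, invert under relabeling, and flag non-convergence", {
  # identical survival experience in both groups -> HR 1
  tms <- rep(c(2, 4, 6, 8, 10), 2)
  ev <- rep(TRUE, 10)
  g <- factor(rep(c("low", "high"), each = 5), levels = c("low", "high"))
  r <- univariateCox(g, tms, ev)
  expect_equal(r$hazard_ratio, 1, tolerance = 1e-8)
  # relabeling inverts the HR and swaps/inverts the CI exactly
  set.seed(17)
  tm <- rexp(40, rate = ifelse(rep(0:1, each = 20), 0.5, 0.1))
  ev2 <- rep(TRUE, 40)
  g1 <- factor(ifelse(rep(0:1, each = 20), "high", "low"),
               levels = c("low", "high"))
  g2 <- factor(ifelse(g1 == "high", "low", "high"), levels = c("low", "high"))
  r1 <- univariateCox(g1, tm, ev2)
  r2 <- univariateCox(g2, tm, ev2)
  expect_equal(r2$hazard_ratio, 1 / r1$hazard_ratio)
  expect_equal(r2$ci_lower, 1 / r1$ci_upper)
  expect_equal(r2$ci_upper, 1 / r1$ci_lower)
  expect_equal(r2$p_value, r1$p_value)
  # complete separation with no events in one group -> flagged, not a number
  gsep <- factor(rep(c("low", "high"), each = 10), levels = c("low", "high"))
  tsep <- c(1:10, 11:20)
  esep <- rep(c(TRUE, FALSE), each = 10)
  rs <- univariateCox(gsep, tsep, esep)
  expect_false(rs$converged)
  expect_true(is.na(rs$hazard_ratio))
  expect_error(univariateCox(factor(rep("high", 5),
                                    levels = c("low", "high")),
                             1:5, rep(TRUE, 5)),
               "non-empty")
})

test_that("the survival screen runs per feature and endpoint and skips degenerate features", {
  set.seed(23)
  n <- 40
  clin <- data.frame(
    patient_id = paste0("P", 1:n),
    os_months = rexp(n, 0.05), os_event = runif(n) < 0.8,
    pfs_months = rexp(n, 0.1), pfs_event = runif(n) < 0.9)
  feats <- data.frame(patient_id = clin$patient_id,
                      informative = rnorm(n),
                      constant = 1)
  w <- capture_warnings(scr <- runSurvivalScreen(feats, clin))
  expect_true(any(grepl("constant", w)))
  expect_equal(nrow(scr), 2L)                    # informative x {OS, PFS}
  expect_setequal(scr$endpoint, c("OS", "PFS"))
  expect_true(all(scr$feature == "informative"))
  expect_true(all(scr$n_high + scr$n_low == n))
  scrBH <- suppressWarnings(runSurvivalScreen(feats, clin, adjust = "BH"))
  expect_true("p_adjusted" %in% names(scrBH))
})

test_that("Cox log-HR bias shrinks as the cohort grows", {
  sm <- list(medianOS = 14, medianPFS = 7.6, logHR = log(0.5),
             censorRange = c(5, 60))
  meanEst <- function(n, nRep) {
    est <- numeric(nRep)
    for (r in seq_len(nRep)) {
      x <- rbinom(n, 1, 0.5)
      sv <- simulateSurvival(x, sm)
      g <- factor(ifelse(x == 1, "high", "low"), levels = c("low", "high"))
      est[r] <- log(univariateCox(g, sv$os_months, sv$os_event)$hazard_ratio)
    }
    mean(est)
  }
  set.seed(61)
  # shrinking tolerance with n; widths are ~3 SE of the replicate mean
  expect_lt(abs(meanEst(54, 120) - log(0.5)), 0.12)
  expect_lt(abs(meanEst(216, 80) - log(0.5)), 0.08)
  expect_lt(abs(meanEst(864, 50) - log(0.5)), 0.05)
})

test_that("the zonal comparison detects a strong core-periphery gradient at n = 54", {
  # count-level sampling from the generator (Poisson counts around ordered
  # log-normal intensities) -- the distribution the density table sees
  cfg <- syntheticCohortConfig(seed = 1)
  area <- 0.5
  hits <- vapply(1:100, function(s) {
    set.seed(50000 + s)
    lam <- samplePatientIntensities(cfg, n = 54)["TUMOR", , ]
    counts <- matrix(rpois(length(lam), lam * area), nrow = 3)
    tbl <- data.frame(patient_id = rep(paste0("P", 1:54), each = 3),
                      region_label = rep(REGION_LABELS, 54),
                      density = as.vector(counts) / area)
    compareRegions(tbl, "density", c("CORE", "PERIPHERY"))$p_value < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("features unrelated to survival rarely reach significance", {
  set.seed(71)
  hits <- vapply(1:50, function(s) {
    n <- 54
    x <- rbinom(n, 1, 0.5)
    sv <- simulateSurvival(x, list(medianOS = 14, medianPFS = 7.6,
                                   logHR = 0, censorRange = c(57, 236)))
    clin <- data.frame(patient_id = paste0("P", 1:n), sv[1:4])
    feats <- data.frame(patient_id = clin$patient_id, noise = rnorm(n))
    runSurvivalScreen(feats, clin, endpoints = "OS")$p_value < 0.05
  }, logical(1))
  expect_gte(mean(!hits), 0.9)
})

test_that("a feature tracking the true risk covariate recovers the configured direction", {
  set.seed(47)
  n <- 120
  x <- rbinom(n, 1, 0.5)
  sv <- simulateSurvival(x, list(medianOS = 14, medianPFS = 7.6,
                                 logHR = log(0.4), censorRange = c(40, 80)))
  clin <- data.frame(patient_id = paste0("P", 1:n), sv[1:4])
  feats <- data.frame(patient_id = clin$patient_id,
                      risk = x + rnorm(n, sd = 0.01))
  scr <- runSurvivalScreen(feats, clin, endpoints = "OS")
  expect_lt(scr$hazard_ratio, 1)
  expect_lt(scr$p_value, 0.05)
})
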