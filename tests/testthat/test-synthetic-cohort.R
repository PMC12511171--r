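test_that("concentric band geometry hits the requested net areas exactly", {
  rs <- makeRegionGeometry(c(CORE = 1, TRANSITION = 1, PERIPHERY = 1))
  expect_equal(unname(sapply(regions(rs), regionArea)), c(1, 1, 1),
               tolerance = 1e-9)
  rs2 <- makeRegionGeometry(c(CORE = 1, TRANSITION = 2, PERIPHERY = 0.5),
                            exclusionAreas = c(CORE = 0.1))
  expect_equal(regionArea(regions(rs2)$CORE), 0.9, tolerance = 1e-9)
  expect_equal(regionArea(regions(rs2)$TRANSITION), 2, tolerance = 1e-9)
  expect_error(makeRegionGeometry(c(CORE = 1, PERIPHERY = 0)), "positive")
})

test_that("patient intensities are log-normal around the configured medians", {
  cfg <- syntheticCohortConfig(seed = 1)
  # degenerate sigma: every patient sits exactly at the median
  cfg0 <- syntheticCohortConfig(sigma = 0)
  set.seed(1)
  lam0 <- samplePatientIntensities(cfg0, n = 5)
  for (p in 1:5)
    expect_equal(lam0[, , p], cfg0$intensityMedians)
  # cohort median of many draws approaches the configured median
  set.seed(2)
  lam <- samplePatientIntensities(cfg, n = 10000)
  expect_equal(median(lam["TUMOR", "CORE", ]), 2301, tolerance = 0.05)
  expect_equal(median(lam["FOXP3", "PERIPHERY", ]), 0.1, tolerance = 0.05)
  # comonotone regions (rho = 1): ordered medians give ordered draws
  cfg1 <- syntheticCohortConfig(rho = 1)
  set.seed(3)
  lam1 <- samplePatientIntensities(cfg1, n = 200)
  expect_true(all(lam1["TUMOR", "CORE", ] > lam1["TUMOR", "PERIPHERY", ]))
})

test_that("point patterns have Poisson counts at the requested intensity", {
  reg <- Region("CORE", rectRing(0, 2000, 0, 1000))   # 2 mm^2
  set.seed(4)
  counts <- replicate(60, {
    pp <- simulatePointPattern(reg, c(IBA1 = 512))
    nrow(pp)
  })
  # mean 1024, SE sqrt(1024/60) ~ 4.1; accept within 3 SE
  expect_lt(abs(mean(counts) - 1024), 3 * sqrt(1024 / 60))
  expect_equal(nrow(simulatePointPattern(reg, c(CD8 = 0))), 0L)
  # points land inside the region net geometry
  regx <- Region("CORE", rectRing(0, 1000, 0, 1000),
                 list(rectRing(0, 500, 0, 500)))
  set.seed(5)
  pp <- simulatePointPattern(regx, c(TUMOR = 2000))
  expect_true(all(pp$x_um >= 0 & pp$x_um <= 1000))
  expect_false(any(pp$x_um < 500 & pp$y_um < 500))
})

test_that("Thomas clustering raises short-range tumor-immune co-occurrence", {
  reg <- Region("CORE", rectRing(0, 2000, 0, 2000))
  lam <- c(TUMOR = 800, IBA1 = 400)
  clustered <- list(enabled = TRUE, classes = "IBA1", proportion = 0.7,
                    sigmaC = 10)
  set.seed(6)
  nearFrac <- function(clustering) {
    pp <- simulatePointPattern(reg, lam, clustering)
    tum <- as.matrix(pp[pp$cell_class == "TUMOR", c("x_um", "y_um")])
    iba <- as.matrix(pp[pp$cell_class == "IBA1", c("x_um", "y_um")])
    mean(countNeighborsWithin(tum, iba, 30) >= 1)
  }
  fOn <- mean(replicate(5, nearFrac(clustered)))
  fOff <- mean(replicate(5, nearFrac(list(enabled = FALSE))))
  expect_gt(fOn, fOff)
  # total intensity is preserved under clustering
  set.seed(7)
  nOn <- mean(replicate(20, sum(simulatePointPattern(
    reg, lam, clustered)$cell_class == "IBA1")))
  expect_lt(abs(nOn - 1600), 3 * sqrt(1600 / 20))
})

test_that("survival simulation hits the configured medians and effect direction", {
  sm <- list(medianOS = 14, medianPFS = 7.6, logHR = 0,
             censorRange = c(1e6, 2e6))   # effectively no censoring
  set.seed(8)
  sv <- simulateSurvival(rep(0L, 20000), sm)
  expect_equal(median(sv$os_months), 14, tolerance = 0.05)
  expect_equal(median(sv$pfs_months), 7.6, tolerance = 0.05)
  expect_true(all(sv$pfs_months <= sv$os_months))
  expect_true(all(sv$os_event & sv$pfs_event))
  # protective covariate (log HR = ln 0.46) lengthens survival for high
  sm2 <- list(medianOS = 14, medianPFS = 7.6, logHR = log(0.46),
              censorRange = c(1e6, 2e6))
  set.seed(9)
  sv2 <- simulateSurvival(rep(c(0L, 1L), each = 5000), sm2)
  expect_gt(median(sv2$os_months[5001:10000]),
            median(sv2$os_months[1:5000]))
})

test_that("cohort generation is reproducible bit for bit from the master seed", {
  cfg <- syntheticCohortConfig(nPatients = 3,
                               regionAreas = c(CORE = 0.2, TRANSITION = 0.2,
                                               PERIPHERY = 0.2), seed = 99)
  c1 <- generateCohort(cfg)
  c2 <- generateCohort(cfg)
  expect_identical(lapply(c1$cellMaps, cells), lapply(c2$cellMaps, cells))
  expect_identical(c1$clinical, c2$clinical)
  expect_identical(c1$truth$lambda, c2$truth$lambda)
  c3 <- generateCohort(syntheticCohortConfig(nPatients = 3,
    regionAreas = cfg$regionAreas, seed = 100))
  expect_false(identical(cells(c1$cellMaps[[1]]), cells(c3$cellMaps[[1]])))
})

test_that("missing regions appear at the configured rate", {
  cfg <- syntheticCohortConfig(nPatients = 40,
                               regionAreas = c(CORE = 0.05, TRANSITION = 0.05,
                                               PERIPHERY = 0.05),
                               missingRegionProb = 0.2, seed = 12)
  co <- generateCohort(cfg)
  slots <- sum(sapply(co$regionSets, function(rs) length(regionLabels(rs))))
  nMissing <- 40 * 3 - slots
  # binomial(120, 0.2): mean 24, sd 4.4 -> accept within 4 sd
  expect_gt(nMissing, 24 - 4 * 4.4)
  expect_lt(nMissing, 24 + 4 * 4.4)
  # every patient keeps at least one region and tables still build
  expect_true(all(sapply(co$regionSets, function(rs)
    length(regionLabels(rs))) >= 1))
  dt <- cohortDensityTable(co$cellMaps, co$regionSets)
  expect_true(all(table(dt$patient_id) %% 5 == 0))
})

test_that("pipeline densities recover the latent intensities at default areas", {
  batch <- defaultCohortBatch(20L)
  cfg <- batch[[1]]$config
  # per-patient estimates are unbiased: mean relative error, averaged over
  # patients and seeds, is tiny wherever the expected count is nontrivial
  meanRel <- Reduce(`+`, lapply(batch, `[[`, "relErr")) / length(batch)
  expected <- cfg$intensityMedians *
    matrix(cfg$regionAreas, nrow = 5, ncol = 3, byrow = TRUE)
  expect_lt(max(abs(meanRel[expected >= 10])), 0.05)
  # cohort medians of estimated densities track the cohort medians of the
  # latent intensities within 5% where the area resolves the density
  # (expected median count >= 10); below that the estimate is quantized by
  # 1/area and tight recovery is not a meaningful ask
  devs <- sapply(batch, function(b)
    (b$densMed / b$latentMed - 1)[expected >= 10])
  expect_lt(max(abs(rowMeans(devs))), 0.05)
})

test_that("the survival covariate marks patients with high latent core tumor intensity", {
  cfg <- syntheticCohortConfig(nPatients = 30,
                               regionAreas = c(CORE = 0.05, TRANSITION = 0.05,
                                               PERIPHERY = 0.05), seed = 21)
  co <- generateCohort(cfg)
  lamCore <- co$truth$lambda["TUMOR", "CORE", ]
  expect_identical(co$truth$covariate,
                   as.integer(lamCore > cfg$intensityMedians["TUMOR", "CORE"]))
})
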