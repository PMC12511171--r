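test_that("neighbor counting is Euclidean, inclusive, and self-excluding", {
  expect_equal(countNeighborsWithin(cbind(0, 0), cbind(c(10, 25, 40), 0), 30),
               2L)
  # boundary distance exactly r is counted
  expect_equal(countNeighborsWithin(cbind(0, 0), cbind(30, 0), 30), 1L)
  expect_equal(countNeighborsWithin(cbind(0, 0), cbind(30.0001, 0), 30), 0L)
  # empty neighbor set
  expect_equal(countNeighborsWithin(cbind(c(0, 5), c(0, 0)),
                                    cbind(numeric(0), numeric(0)), 30),
               c(0L, 0L))
  # shared members never count themselves
  pts <- cbind(c(0, 10), c(0, 0))
  expect_equal(countNeighborsWithin(pts, pts, 30, refIds = 1:2, nbrIds = 1:2),
               c(1L, 1L))
  expect_equal(countNeighborsWithin(pts, pts, 30), c(2L, 2L))
})

test_that("grid counts equal brute-force counts on random instances", {
  set.seed(101)
  for (i in 1:25) {
    n <- sample(2:800, 1)
    m <- sample(1:800, 1)
    side <- runif(1, 50, 3000)
    r <- runif(1, 1, 100)
    ref <- cbind(runif(n, 0, side), runif(n, 0, side))
    nbr <- cbind(runif(m, 0, side), runif(m, 0, side))
    expect_identical(countNeighborsWithin(ref, nbr, r),
                     bruteForceNeighborCounts(ref, nbr, r))
  }
  # radius larger than the slide diagonal sees every neighbor (minus self)
  pts <- cbind(runif(50, 0, 100), runif(50, 0, 100))
  expect_equal(countNeighborsWithin(pts, pts, 1000, refIds = 1:50,
                                    nbrIds = 1:50),
               rep(49L, 50))
})

test_that("neighbor counts bin into b0 / 1-4 / 5-9 / 10+", {
  b <- binNeighborCounts(c(0, 1, 4, 5, 9, 10, 37))
  expect_equal(as.character(b),
               c("b0", "b1_4", "b1_4", "b5_9", "b5_9", "b10plus", "b10plus"))
  expect_equal(levels(b), c("b0", "b1_4", "b5_9", "b10plus"))
  custom <- binNeighborCounts(c(0, 1, 2, 3), bins = list(c(1, 2), c(3, Inf)))
  expect_equal(as.character(custom), c("b0", "b1_2", "b1_2", "b3plus"))
  expect_error(proximityConfig(bins = list(c(2, 4))), "starting at 1")
  expect_error(proximityConfig(radius = 0), "radius")
})

test_that("proximity tables attribute references to regions but count neighbors across boundaries", {
  rs <- RegionSet("PT", list(
    Region("CORE", rectRing(0, 1000, 0, 1000)),
    Region("TRANSITION", rectRing(1000, 2000, 0, 1000))))
  # tumor cell near the CORE/TRANSITION boundary; its only IBA1 neighbor is
  # across the boundary, within 30 um
  scm <- SlideCellMap("PT", data.frame(
    cell_id = c("t1", "i1", "t2"),
    x_um = c(995, 1015, 500), y_um = c(500, 500, 100),
    cell_class = c("TUMOR", "IBA1", "TUMOR")))
  pt <- buildProximityTable(assignCellsToRegions(scm, rs), rs)
  core <- pt[pt$region_label == "CORE" & pt$neighbor_class == "IBA1", ]
  expect_equal(core$n_reference_in_bin[core$bin_label == "b1_4"], 1L)
  expect_equal(core$n_reference_in_bin[core$bin_label == "b0"], 1L)
  expect_equal(core$fraction[core$bin_label == "b1_4"], 0.5)
  # TRANSITION has no reference cells: fraction undefined, density zero
  tz <- pt[pt$region_label == "TRANSITION" & pt$neighbor_class == "IBA1", ]
  expect_true(all(is.na(tz$fraction)))
  expect_true(all(tz$density == 0))
})

test_that("bin fractions sum to one and excluded cells are dropped", {
  set.seed(55)
  rs <- RegionSet("PT", list(
    Region("CORE", rectRing(0, 1000, 0, 1000),
           list(rectRing(0, 200, 0, 200)))))
  n <- 400
  scm <- SlideCellMap("PT", data.frame(
    cell_id = paste0("c", 1:n),
    x_um = runif(n, 0, 1000), y_um = runif(n, 0, 1000),
    cell_class = sample(c("TUMOR", "IBA1", "CD8"), n, TRUE)))
  lab <- assignCellsToRegions(scm, rs)
  pt <- buildProximityTable(lab, rs)
  sums <- tapply(pt$fraction, interaction(pt$region_label, pt$neighbor_class),
                 sum)
  expect_true(all(abs(sums - 1) < 1e-12))
  # total references per class = non-excluded tumor cells in region
  expect_equal(sum(pt$n_reference_in_bin[pt$neighbor_class == "IBA1"]),
               sum(lab$region_label == "CORE" & lab$cell_class == "TUMOR"))
})

test_that("the fraction with at least one neighbor is monotone in radius", {
  set.seed(77)
  n <- 500
  ref <- cbind(runif(n, 0, 1000), runif(n, 0, 1000))
  nbr <- cbind(runif(n, 0, 1000), runif(n, 0, 1000))
  prev <- 0
  for (r in c(5, 15, 30, 60, 120)) {
    frac <- mean(countNeighborsWithin(ref, nbr, r) >= 1)
    expect_gte(frac, prev)
    prev <- frac
  }
})

test_that("Poisson bin probabilities follow the closed form", {
  expect_equal(poissonBinProbability(0, 30, c(0, 0)), 1)
  expect_equal(poissonBinProbability(0, 30, c(1, 4)), 0)
  mu <- 512e-6 * pi * 900
  expect_equal(poissonBinProbability(512, 30, c(1, 4)),
               sum(dpois(1:4, mu)))
  # complement identity for the open top bin
  expect_equal(poissonBinProbability(512, 30, c(10, Inf)),
               1 - ppois(9, mu))
  probs <- sapply(list(c(0, 0), c(1, 4), c(5, 9), c(10, Inf)),
                  function(b) poissonBinProbability(512, 30, b))
  expect_equal(sum(probs), 1)
  # monotone in intensity: P(>=1 neighbor) grows with density
  p1 <- 1 - poissonBinProbability(100, 30, c(0, 0))
  p2 <- 1 - poissonBinProbability(500, 30, c(0, 0))
  expect_gt(p2, p1)
})

test_that("clustered immune recruitment exceeds the Poisson null prediction", {
  # Thomas clustering ON: the fraction of tumor cells with >= 1 IBA1 neighbor
  # should beat the independence null in essentially every replicate; a
  # one-sided sign test over 20 seeds must reject at alpha = 0.01
  lam <- c(TUMOR = 800, IBA1 = 400)
  reg <- Region("CORE", rectRing(0, 1500, 0, 1500))
  clustering <- list(enabled = TRUE, classes = "IBA1", proportion = 0.6,
                     sigmaC = 12)
  pNull <- 1 - poissonBinProbability(400, 30, c(0, 0))
  exceeds <- vapply(1:20, function(s) {
    set.seed(6000 + s)
    pp <- simulatePointPattern(reg, lam, clustering)
    tum <- as.matrix(pp[pp$cell_class == "TUMOR", c("x_um", "y_um")])
    iba <- as.matrix(pp[pp$cell_class == "IBA1", c("x_um", "y_um")])
    mean(countNeighborsWithin(tum, iba, 30) >= 1) > pNull
  }, logical(1))
  expect_lt(binom.test(sum(exceeds), 20, 0.5,
                       alternative = "greater")$p.value, 0.01)
})

test_that("Poisson bin probabilities agree with Monte-Carlo draws", {
  set.seed(202)
  mu <- 512e-6 * pi * 900
  draws <- rpois(1e6, mu)
  expect_lt(abs(poissonBinProbability(512, 30, c(1, 4)) -
                mean(draws >= 1 & draws <= 4)), 2e-3)
  expect_lt(abs(poissonBinProbability(512, 30, c(5, 9)) -
                mean(draws >= 5 & draws <= 9)), 2e-3)
})
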