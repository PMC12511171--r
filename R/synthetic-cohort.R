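# Synthetic cohort generator. Emulates the statistical structure the zonal
# analysis assumes -- per-region log-normal interpatient intensity with the
# calibrated cohort medians, homogeneous Poisson cell placement (optionally
# Thomas-clustered immune recruitment around tumor cells), and exponential
# survival with administrative censoring -- so every pipeline stage can be
# exercised at desk scale without patient material.

.DEFAULT_MEDIANS <- matrix(
  c(2301, 1141, 250,     # P53+ tumor cells, core/transition/periphery
     512,  419, 179,     # IBA1+ microglia-macrophages
      14,   10,   3,     # CD8+ cytotoxic T cells
     1.7,  1.2, 0.1,     # FOXP3+ regulatory T cells
     800, 1000, 1500),   # unstained cells (normal brain rises outward)
  nrow = 5L, byrow = TRUE,
  dimnames = list(CELL_CLASSES, REGION_LABELS))

#' Synthetic cohort configuration
#'
#' Defaults reproduce the study conditions the pipeline is calibrated to:
#' a 54-patient cohort; cohort-median densities per class and region equal to
#' the published zonal medians (tumor 2301/1141/250, IBA1 512/419/179,
#' CD8 14/10/3, FOXP3 1.7/1.2/0.1 cells/mm^2, plus an unstained background of
#' 800/1000/1500 chosen so the core stays just above 60 percent tumor);
#' log-normal interpatient heterogeneity with log-scale sigma 0.6 and
#' cross-region correlation rho 0.5 (most, not all, patients have core above
#' periphery, reproducing waterfall sign flips); exponential survival with
#' median OS 14 and median PFS 7.6 months, a binary covariate (high core
#' tumor intensity) acting with log hazard ratio log(0.46), and
#' administrative censoring uniform between 57 and 236 months of potential
#' follow-up.
#'
#' @param nPatients number of patients (>= 2); default 54.
#' @param regionAreas named net areas in mm^2 for CORE, TRANSITION,
#'   PERIPHERY; defaults 6, 6, 8.
#' @param intensityMedians class x region matrix of cohort median densities
#'   (cells/mm^2).
#' @param sigma log-scale standard deviation of interpatient intensity.
#' @param rho cross-region correlation of log intensities within a class.
#' @param clustering list: `enabled` (default FALSE), `classes` (immune
#'   classes recruited around tumor cells), `proportion` of points that are
#'   Thomas offspring, `sigmaC` Gaussian displacement SD in micrometers.
#' @param survivalModel list: `medianOS`, `medianPFS` (months, baseline
#'   group), `logHR` (effect of the binary covariate on the hazard),
#'   `censorRange` months of administrative follow-up (uniform).
#' @param missingRegionProb probability a patient lacks a given region.
#' @param seed master seed; every draw derives from it.
#' @return list of class `SyntheticCohortConfig`.
#' @export
syntheticCohortConfig <- function(
    nPatients = 54L,
    regionAreas = c(CORE = 6, TRANSITION = 6, PERIPHERY = 8),
    intensityMedians = .DEFAULT_MEDIANS,
    sigma = 0.6,
    rho = 0.5,
    clustering = list(enabled = FALSE, classes = "IBA1", proportion = 0.5,
                      sigmaC = 15),
    survivalModel = list(medianOS = 14, medianPFS = 7.6, logHR = log(0.46),
                         censorRange = c(57, 236)),
    missingRegionProb = 0,
    seed = 1L) {
  stopifnot(nPatients >= 2L, all(regionAreas > 0),
            all(REGION_LABELS %in% names(regionAreas)),
            all(rownames(intensityMedians) == CELL_CLASSES),
            all(colnames(intensityMedians) == REGION_LABELS),
            all(intensityMedians >= 0), sigma >= 0, rho >= 0, rho <= 1,
            survivalModel$medianOS > 0, survivalModel$medianPFS > 0,
            survivalModel$medianPFS <= survivalModel$medianOS,
            missingRegionProb >= 0, missingRegionProb < 1)
  structure(list(nPatients = as.integer(nPatients),
                 regionAreas = regionAreas[REGION_LABELS],
                 intensityMedians = intensityMedians, sigma = sigma,
                 rho = rho, clustering = clustering,
                 survivalModel = survivalModel,
                 missingRegionProb = missingRegionProb,
                 seed = as.integer(seed)),
            class = "SyntheticCohortConfig")
}

#' Concentric-band region geometry with exact areas
#'
#' Builds the canonical zonal layout: a central square tumor core, a
#' transition-zone band around it, and a periphery band around that, each
#' with exactly the requested net area (bands are represented as
#' multipolygons of four rectangles). Optional exclusion zones are carved as
#' axis-aligned rectangles centered in a part of the named region.
#'
#' @param areas named vector of areas in mm^2 (CORE, TRANSITION, PERIPHERY);
#'   a label may be omitted to build a partial slide.
#' @param exclusionAreas optional named vector (names in the region labels)
#'   of exclusion areas in mm^2.
#' @param patientId identifier for the resulting [RegionSet-class].
#' @return a [RegionSet-class].
#' @examples
#' rs <- makeRegionGeometry(c(CORE = 1, TRANSITION = 1, PERIPHERY = 1))
#' sapply(regions(rs), regionArea)
#' @export
makeRegionGeometry <- function(areas, exclusionAreas = NULL,
                               patientId = "synthetic") {
  areas <- areas[intersect(REGION_LABELS, names(areas))]
  if (!length(areas)) stop("no region areas given")
  if (any(areas <= 0)) stop("region areas must be strictly positive")
  um2 <- areas * 1e6
  rect <- function(x1, x2, y1, y2) cbind(c(x1, x2, x2, x1), c(y1, y1, y2, y2))
  # outer square side after adding each band's area
  sides <- sqrt(cumsum(um2))
  half <- sides / 2
  parts <- list()
  for (i in seq_along(areas)) {
    lab <- names(areas)[i]
    if (i == 1L) {
      parts[[lab]] <- list(rect(-half[1L], half[1L], -half[1L], half[1L]))
    } else {
      hIn <- half[i - 1L]; hOut <- half[i]
      parts[[lab]] <- list(
        rect(-hOut, hOut, -hOut, -hIn),       # bottom strip
        rect(-hOut, hOut, hIn, hOut),         # top strip
        rect(-hOut, -hIn, -hIn, hIn),         # left strip
        rect(hIn, hOut, -hIn, hIn))           # right strip
    }
  }
  regs <- lapply(names(parts), function(lab) {
    excl <- list()
    if (!is.null(exclusionAreas) && lab %in% names(exclusionAreas)) {
      aEx <- exclusionAreas[[lab]] * 1e6
      p <- parts[[lab]][[1L]]
      w <- diff(range(p[, 1L])); h <- diff(range(p[, 2L]))
      cx <- mean(range(p[, 1L])); cy <- mean(range(p[, 2L]))
      # centered rectangle of the requested area, capped at 90% of the part
      ew <- min(sqrt(aEx * w / h), 0.9 * w)
      eh <- aEx / ew
      if (eh > 0.9 * h)
        stop("exclusion area too large for region ", lab)
      excl <- list(rect(cx - ew / 2, cx + ew / 2, cy - eh / 2, cy + eh / 2))
    }
    Region(lab, parts[[lab]], excl)
  })
  RegionSet(patientId, regs)
}

#' Sample per-patient intensity matrices
#'
#' Log-normal interpatient intensities: for each class, log intensities over
#' the three regions are jointly Gaussian with equicorrelation `rho`, so the
#' cohort median of each (class, region) intensity equals the configured
#' median (the log-normal median is exp of the log-mean). Classes are
#' independent. Draws come from the current RNG state.
#'
#' @param config a [syntheticCohortConfig()].
#' @param n number of patients to draw (default `config$nPatients`).
#' @return numeric array class x region x patient (cells/mm^2).
#' @export
samplePatientIntensities <- function(config, n = config$nPatients) {
  med <- config$intensityMedians
  nr <- ncol(med)                               # regions
  out <- array(NA_real_, dim = c(nrow(med), nr, n),
               dimnames = list(rownames(med), colnames(med), NULL))
  # equicorrelated construction: z = sqrt(rho) shared + sqrt(1-rho) private
  # (handles rho = 1, where the Cholesky factor is singular)
  a <- sqrt(config$rho); bpriv <- sqrt(1 - config$rho)
  for (p in seq_len(n)) {
    for (cl in seq_len(nrow(med))) {
      z <- a * stats::rnorm(1) + bpriv * stats::rnorm(nr)
      out[cl, , p] <- med[cl, ] * exp(config$sigma * z)
    }
  }
  out
}

# uniform points in the net region (parts minus exclusions), by rejection
.samplePointsInRegion <- function(region, n) {
  if (n == 0L)
    return(cbind(x = numeric(0), y = numeric(0)))
  partAreas <- vapply(region@parts, .ringArea, numeric(1))
  out <- matrix(NA_real_, nrow = n, ncol = 2L)
  got <- 0L
  while (got < n) {
    need <- n - got
    pi_ <- sample.int(length(region@parts), need, replace = TRUE,
                      prob = partAreas)
    xs <- numeric(need); ys <- numeric(need); keep <- logical(need)
    for (k in unique(pi_)) {
      sel <- pi_ == k
      p <- region@parts[[k]]
      bb <- .bboxOfParts(list(p))
      m <- sum(sel)
      x <- stats::runif(m, bb["xmin"], bb["xmax"])
      y <- stats::runif(m, bb["ymin"], bb["ymax"])
      inside <- .pointsInParts(x, y, list(p))
      if (length(region@exclusions))
        inside <- inside & !.pointsInParts(x, y, region@exclusions)
      xs[sel] <- x; ys[sel] <- y; keep[sel] <- inside
    }
    acc <- which(keep)
    nTake <- min(length(acc), need)
    if (nTake > 0L) {
      idx <- acc[seq_len(nTake)]
      out[got + seq_len(nTake), ] <- cbind(xs[idx], ys[idx])
      got <- got + nTake
    }
  }
  colnames(out) <- c("x", "y")
  out
}

#' Simulate the cell point pattern of one region
#'
#' Per class, a homogeneous Poisson process over the region's net geometry:
#' the count is Poisson(lambda x net area) and positions are uniform. When
#' clustering is enabled for an immune class, a configured proportion of its
#' points are Thomas-process offspring: each picks a uniformly chosen tumor
#' parent and lands at an isotropic Gaussian displacement (SD `sigmaC`),
#' resampled until inside the region, so the total intensity is preserved
#' while tumor-immune co-occurrence within short ranges rises above the
#' independence null.
#'
#' @param region a [Region-class].
#' @param lambda named vector of intensities (cells/mm^2) per cell class.
#' @param clustering clustering config (see [syntheticCohortConfig()]).
#' @return data.frame with `x_um`, `y_um`, `cell_class`.
#' @export
simulatePointPattern <- function(region, lambda,
                                 clustering = list(enabled = FALSE)) {
  area <- regionArea(region)
  res <- list()
  tumorPts <- NULL
  for (cl in intersect(CELL_CLASSES, names(lambda))) {
    lam <- lambda[[cl]]
    n <- if (lam > 0) stats::rpois(1L, lam * area) else 0L
    clustered <- isTRUE(clustering$enabled) &&
      cl %in% clustering$classes && !is.null(tumorPts) &&
      nrow(tumorPts) > 0L && n > 0L
    if (!clustered) {
      pts <- .samplePointsInRegion(region, n)
    } else {
      nOff <- round(clustering$proportion * n)
      pts <- .samplePointsInRegion(region, n - nOff)
      if (nOff > 0L) {
        off <- matrix(NA_real_, nrow = nOff, ncol = 2L)
        for (k in seq_len(nOff)) {
          for (try in 1:200) {
            par <- tumorPts[sample.int(nrow(tumorPts), 1L), ]
            cand <- par + stats::rnorm(2L, sd = clustering$sigmaC)
            okIn <- .pointsInParts(cand[1L], cand[2L], region@parts)
            if (okIn && length(region@exclusions))
              okIn <- !.pointsInParts(cand[1L], cand[2L], region@exclusions)
            if (okIn) { off[k, ] <- cand; break }
          }
          if (anyNA(off[k, ]))                  # pathological geometry
            off[k, ] <- .samplePointsInRegion(region, 1L)
        }
        pts <- rbind(pts, off)
      }
    }
    if (cl == "TUMOR") tumorPts <- pts
    if (nrow(pts))
      res[[cl]] <- data.frame(x_um = pts[, 1L], y_um = pts[, 2L],
                              cell_class = cl)
  }
  if (!length(res))
    return(data.frame(x_um = numeric(0), y_um = numeric(0),
                      cell_class = character(0)))
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Simulate survival endpoints
#'
#' Exponential event times: the death hazard is log(2)/medianOS scaled by
#' exp(logHR x covariate); progression occurs at an additional competing
#' exponential time calibrated so the baseline PFS median is `medianPFS`
#' (PFS = first of progression or death, hence PFS <= OS by construction).
#' Administrative censoring is uniform over `censorRange` months.
#'
#' @param covariate binary vector (0/1), one per patient.
#' @param survivalModel list as in [syntheticCohortConfig()].
#' @return data.frame with `os_months`, `os_event`, `pfs_months`,
#'   `pfs_event`, `true_death_months`.
#' @export
simulateSurvival <- function(covariate, survivalModel) {
  n <- length(covariate)
  hrf <- exp(survivalModel$logHR * covariate)
  rateOS <- log(2) / survivalModel$medianOS
  rateProg <- log(2) / survivalModel$medianPFS - rateOS
  stopifnot(rateProg >= 0)
  td <- stats::rexp(n, rateOS * hrf)
  tp <- if (rateProg > 0) stats::rexp(n, rateProg * hrf) else rep(Inf, n)
  tpfs <- pmin(td, tp)
  cr <- survivalModel$censorRange
  cens <- stats::runif(n, cr[1L], cr[2L])
  data.frame(os_months = pmin(td, cens), os_event = td <= cens,
             pfs_months = pmin(tpfs, cens), pfs_event = tpfs <= cens,
             true_death_months = td)
}

.subSeed <- function(master, i) {
  as.integer((as.numeric(master) * 7919 + i * 104729) %% 2147483647)
}

#' Generate a complete synthetic cohort
#'
#' Produces `nPatients` synthetic patients: shared concentric-band region
#' geometry, per-patient intensity matrices, Poisson (optionally
#' Thomas-clustered) cell maps, clinical records with simulated survival, and
#' a truth record holding every latent parameter for recovery tests. All
#' randomness derives from the master seed through per-patient substreams, so
#' output is reproducible bit for bit.
#'
#' The survival covariate of a patient is the indicator that their latent
#' core tumor intensity exceeds the configured cohort median, tying survival
#' to core tumor density.
#'
#' @param config a [syntheticCohortConfig()].
#' @return list with `cellMaps` (list of [SlideCellMap-class]), `regionSets`
#'   (list of [RegionSet-class]), `clinical` (data.frame), `truth` (list),
#'   and `config`.
#' @export
generateCohort <- function(config = syntheticCohortConfig()) {
  stopifnot(inherits(config, "SyntheticCohortConfig"))
  n <- config$nPatients
  template <- makeRegionGeometry(config$regionAreas)
  pids <- sprintf("SP%03d", seq_len(n))
  lambdas <- array(NA_real_,
                   dim = c(length(CELL_CLASSES), length(REGION_LABELS), n),
                   dimnames = list(CELL_CLASSES, REGION_LABELS, pids))
  cellMaps <- vector("list", n)
  regionSets <- vector("list", n)
  covariate <- integer(n)
  surv <- vector("list", n)
  ageP <- 30 / 54; maleP <- 35 / 54
  demo <- vector("list", n)
  for (i in seq_len(n)) {
    set.seed(.subSeed(config$seed, i))
    lam <- samplePatientIntensities(config, n = 1L)[, , 1L]
    lambdas[, , i] <- lam
    keep <- stats::runif(length(REGION_LABELS)) >= config$missingRegionProb
    if (!any(keep)) keep[1L] <- TRUE            # a slide has >= 1 region
    regs <- regions(template)[REGION_LABELS[keep]]
    rs <- RegionSet(pids[i], regs)
    regionSets[[i]] <- rs
    cellRows <- list()
    for (rl in regionLabels(rs))
      cellRows[[rl]] <- simulatePointPattern(regions(rs)[[rl]], lam[, rl],
                                             config$clustering)
    allCells <- data.frame(
      cell_id = paste0(pids[i], "_c",
                       seq_len(sum(vapply(cellRows, nrow, integer(1))))),
      x_um = unlist(lapply(cellRows, `[[`, "x_um"), use.names = FALSE),
      y_um = unlist(lapply(cellRows, `[[`, "y_um"), use.names = FALSE),
      cell_class = unlist(lapply(cellRows, `[[`, "cell_class"),
                          use.names = FALSE))
    cellMaps[[i]] <- SlideCellMap(pids[i], allCells)
    covariate[i] <- as.integer(lam["TUMOR", "CORE"] >
                                 config$intensityMedians["TUMOR", "CORE"])
    surv[[i]] <- simulateSurvival(covariate[i], config$survivalModel)
    demo[[i]] <- data.frame(
      age_group = if (stats::runif(1) < ageP) "under65" else "at_least65",
      sex = if (stats::runif(1) < maleP) "male" else "female")
  }
  sv <- do.call(rbind, surv)
  dm <- do.call(rbind, demo)
  clinical <- data.frame(
    patient_id = pids,
    os_months = sv$os_months, os_event = sv$os_event,
    pfs_months = sv$pfs_months, pfs_event = sv$pfs_event,
    age_group = factor(dm$age_group, levels = .CLINICAL_LEVELS$age_group),
    sex = factor(dm$sex, levels = .CLINICAL_LEVELS$sex),
    performance_status = factor("ps0_2",
                                levels = .CLINICAL_LEVELS$performance_status),
    treatment = factor("rt_chemo", levels = .CLINICAL_LEVELS$treatment),
    mgmt = factor("unknown", levels = .CLINICAL_LEVELS$mgmt),
    surgery = factor("partial", levels = .CLINICAL_LEVELS$surgery),
    midline = factor("missing", levels = .CLINICAL_LEVELS$midline))
  names(cellMaps) <- pids
  names(regionSets) <- pids
  list(cellMaps = cellMaps, regionSets = regionSets, clinical = clinical,
       truth = list(lambda = lambdas, covariate = covariate,
                    logHR = config$survivalModel$logHR,
                    true_death_months = sv$true_death_months,
                    seed = config$seed),
       config = config)
}
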