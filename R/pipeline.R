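# Cohort-level orchestration: in-memory stage functions plus file-based
# runSimulate / runQuantify / runProximity / runStats commands used by the
# command-line wrapper (inst/cli/gliospatial.R). Results go to files; progress
# messages go to stderr via message().

.REGION_PAIRS <- list(c("CORE", "PERIPHERY"), c("TRANSITION", "PERIPHERY"),
                      c("CORE", "TRANSITION"))

#' Density table for a cohort
#'
#' Assigns each slide's cells to its regions and stacks the per-slide density
#' tables.
#'
#' @param cellMaps named list of [SlideCellMap-class] objects.
#' @param regionSets named list of [RegionSet-class] objects (same names).
#' @return combined density table data.frame.
#' @export
cohortDensityTable <- function(cellMaps, regionSets) {
  stopifnot(length(cellMaps) >= 1L, all(names(cellMaps) %in% names(regionSets)))
  out <- lapply(names(cellMaps), function(pid) {
    lab <- assignCellsToRegions(cellMaps[[pid]], regionSets[[pid]])
    buildDensityTable(lab, regionSets[[pid]])
  })
  do.call(rbind, out)
}

#' Proximity table for a cohort
#'
#' @inheritParams cohortDensityTable
#' @param config a [proximityConfig()].
#' @return combined proximity table data.frame.
#' @export
cohortProximityTable <- function(cellMaps, regionSets,
                                 config = proximityConfig()) {
  out <- lapply(names(cellMaps), function(pid) {
    lab <- assignCellsToRegions(cellMaps[[pid]], regionSets[[pid]])
    buildProximityTable(lab, regionSets[[pid]], config)
  })
  do.call(rbind, out)
}

#' All paired region comparisons for the cohort tables
#'
#' Runs the Wilcoxon signed-rank comparison for every metric and region pair:
#' per-class densities (unstained excluded), the four density ratios, and
#' (when a proximity table is given) per-bin proximity fractions. Metrics for
#' which fewer than two informative pairs exist are skipped.
#'
#' @param densityTable cohort density table.
#' @param ratioTable cohort ratio table (or `NULL`).
#' @param proximityTable cohort proximity table (or `NULL`).
#' @return data.frame of [compareRegions()] rows.
#' @export
cohortComparisons <- function(densityTable, ratioTable = NULL,
                              proximityTable = NULL) {
  rows <- list()
  add <- function(tbl, valueCol, metricName) {
    for (rp in .REGION_PAIRS) {
      res <- tryCatch(compareRegions(tbl, valueCol, rp, metricName),
                      error = function(e) NULL)
      if (!is.null(res)) rows[[length(rows) + 1L]] <<- res
    }
  }
  for (cl in setdiff(CELL_CLASSES, "UNSTAINED"))
    add(densityTable[densityTable$cell_class == cl, ], "density",
        paste0("density_", cl))
  if (!is.null(ratioTable))
    for (rn in unique(ratioTable$ratio_name))
      add(ratioTable[ratioTable$ratio_name == rn, ], "value",
          paste0("ratio_", rn))
  if (!is.null(proximityTable)) {
    key <- unique(proximityTable[, c("neighbor_class", "bin_label")])
    key <- key[key$bin_label != "b0", ]
    for (k in seq_len(nrow(key)))
      add(proximityTable[
            proximityTable$neighbor_class == key$neighbor_class[k] &
            proximityTable$bin_label == key$bin_label[k], ], "fraction",
          paste0("proximity_", key$neighbor_class[k], "_", key$bin_label[k]))
  }
  do.call(rbind, rows)
}

#' Per-patient feature matrix for the survival screen
#'
#' One column per (region, class) density (unstained excluded), per (region,
#' ratio), and per (region, neighbor class, positive bin) proximity density.
#'
#' @inheritParams cohortComparisons
#' @return data.frame with `patient_id` and one numeric column per feature.
#' @export
survivalFeatures <- function(densityTable, ratioTable = NULL,
                             proximityTable = NULL) {
  pids <- unique(densityTable$patient_id)
  out <- data.frame(patient_id = pids)
  put <- function(tbl, keyCols, valueCol, prefix) {
    keys <- unique(tbl[, keyCols, drop = FALSE])
    for (k in seq_len(nrow(keys))) {
      sel <- rep(TRUE, nrow(tbl))
      for (col in keyCols) sel <- sel & tbl[[col]] == keys[k, col]
      sub <- tbl[sel, ]
      nm <- paste(c(prefix, unlist(keys[k, ])), collapse = "_")
      out[[nm]] <<- sub[[valueCol]][match(pids, sub$patient_id)]
    }
  }
  dt <- densityTable[densityTable$cell_class != "UNSTAINED", ]
  put(dt, c("region_label", "cell_class"), "density", "density")
  if (!is.null(ratioTable))
    put(ratioTable, c("region_label", "ratio_name"), "value", "ratio")
  if (!is.null(proximityTable)) {
    pt <- proximityTable[proximityTable$bin_label != "b0", ]
    put(pt, c("region_label", "neighbor_class", "bin_label"), "density",
        "proxdens")
  }
  out
}

# ---- file-based pipeline commands -------------------------------------------

.checkOutdir <- function(outdir, force) {
  if (dir.exists(outdir) && length(dir(outdir)) && !force)
    stop("output directory ", outdir,
         " is not empty; use force = TRUE to overwrite")
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
}

#' Simulate a synthetic cohort to disk
#'
#' Writes one cell table CSV and one region GeoJSON per patient, the clinical
#' table, the truth record (JSON), and run metadata.
#'
#' @param config a [syntheticCohortConfig()].
#' @param outdir output directory.
#' @param force overwrite a non-empty output directory.
#' @return the generated cohort (invisibly).
#' @export
runSimulate <- function(config = syntheticCohortConfig(), outdir,
                        force = FALSE) {
  .checkOutdir(outdir, force)
  cohort <- generateCohort(config)
  for (pid in names(cohort$cellMaps)) {
    writeCellTable(cohort$cellMaps[[pid]],
                   file.path(outdir, sprintf("cells_%s.csv", pid)))
    writeRegionAnnotations(cohort$regionSets[[pid]],
                           file.path(outdir, sprintf("regions_%s.geojson", pid)))
  }
  writeClinicalTable(cohort$clinical, file.path(outdir, "clinical.csv"))
  truth <- cohort$truth
  truth$lambda <- apply(truth$lambda, 3L, function(m)
    as.data.frame(as.table(m)), simplify = FALSE)
  jsonlite::write_json(truth, file.path(outdir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  meta <- list(seed = config$seed, n_patients = config$nPatients,
               package_version =
                 as.character(utils::packageVersion("glioSpatial")),
               config_hash = .configHash(config))
  jsonlite::write_json(meta, file.path(outdir, "run_info.json"),
                       auto_unbox = TRUE, digits = NA)
  message("wrote ", config$nPatients, " synthetic patients to ", outdir)
  invisible(cohort)
}

.loadCohortDir <- function(indir) {
  cellFiles <- sort(dir(indir, pattern = "^cells_.*\\.csv$",
                        full.names = TRUE))
  if (!length(cellFiles)) stop("no cells_*.csv files in ", indir)
  cellMaps <- lapply(cellFiles, readCellTable)
  pids <- vapply(cellMaps, patientId, character(1))
  names(cellMaps) <- pids
  regionSets <- lapply(pids, function(pid) {
    f <- file.path(indir, sprintf("regions_%s.geojson", pid))
    if (!file.exists(f)) stop("missing region annotation file ", f)
    readRegionAnnotations(f, patientId = pid)
  })
  names(regionSets) <- pids
  clin <- file.path(indir, "clinical.csv")
  clinical <- if (file.exists(clin)) readClinicalTable(clin) else NULL
  if (!is.null(clinical)) {
    lost <- setdiff(pids, clinical$patient_id)
    if (length(lost))
      warning("patients with cells but no clinical record: ",
              paste(lost, collapse = ", "))
  }
  list(cellMaps = cellMaps, regionSets = regionSets, clinical = clinical)
}

#' Quantify densities, ratios and waterfalls from a cohort directory
#'
#' @param indir directory with `cells_*.csv`, `regions_*.geojson` and
#'   optionally `clinical.csv` (as written by [runSimulate()]).
#' @param outdir output directory for the tidy tables.
#' @param force overwrite a non-empty output directory.
#' @param seed seed recorded in the run metadata (the stage itself is
#'   deterministic).
#' @return list of the three tables (invisibly).
#' @export
runQuantify <- function(indir, outdir, force = FALSE, seed = NULL) {
  .checkOutdir(outdir, force)
  co <- .loadCohortDir(indir)
  dt <- cohortDensityTable(co$cellMaps, co$regionSets)
  rt <- buildRatioTable(dt)
  wt <- buildWaterfallTable(dt)
  writeResults(list(density = dt, ratios = rt, waterfall = wt), outdir,
               seed = seed, config = list(indir = indir))
  for (cl in setdiff(CELL_CLASSES, "UNSTAINED")) {
    med <- vapply(REGION_LABELS, function(rl)
      stats::median(dt$density[dt$cell_class == cl & dt$region_label == rl]),
      numeric(1))
    message(sprintf("%-9s cohort median density: %s", cl,
                    paste(sprintf("%s=%.4g", REGION_LABELS, med),
                          collapse = " ")))
  }
  invisible(list(density = dt, ratios = rt, waterfall = wt))
}

#' Proximity quantification from a cohort directory
#'
#' @inheritParams runQuantify
#' @param config a [proximityConfig()].
#' @return the cohort proximity table (invisibly).
#' @export
runProximity <- function(indir, outdir, config = proximityConfig(),
                         force = FALSE, seed = NULL) {
  .checkOutdir(outdir, force)
  co <- .loadCohortDir(indir)
  pt <- cohortProximityTable(co$cellMaps, co$regionSets, config)
  writeResults(list(proximity = pt), outdir, seed = seed, config = config)
  invisible(pt)
}

#' Cohort statistics from quantify/proximity outputs
#'
#' Reads the tidy tables written by [runQuantify()] and [runProximity()],
#' runs all paired region comparisons, and (when a clinical table is present
#' in `indir`) the median-cutoff univariate survival screen for OS and PFS.
#'
#' @param tablesDir directory holding `density.csv`, `ratios.csv`, and
#'   optionally `proximity.csv`.
#' @param indir cohort input directory (for `clinical.csv`).
#' @param outdir output directory.
#' @param force overwrite a non-empty output directory.
#' @param adjust multiplicity adjustment for the screen: `"none"` or `"BH"`.
#' @return list with `comparisons` and `survival_screen` (invisibly).
#' @export
runStats <- function(tablesDir, indir, outdir, force = FALSE,
                     adjust = "none") {
  .checkOutdir(outdir, force)
  readTbl <- function(nm, required = TRUE) {
    f <- file.path(tablesDir, paste0(nm, ".csv"))
    if (!file.exists(f)) {
      if (required) stop("missing ", f, "; run the quantify stage first")
      return(NULL)
    }
    utils::read.csv(f)
  }
  dt <- readTbl("density")
  rt <- readTbl("ratios", required = FALSE)
  pt <- readTbl("proximity", required = FALSE)
  cmp <- cohortComparisons(dt, rt, pt)
  message("ran ", nrow(cmp), " paired region comparisons (n_pairs per test: ",
          paste(range(cmp$n_pairs), collapse = "-"), ")")
  out <- list(comparisons = cmp)
  clin <- file.path(indir, "clinical.csv")
  if (file.exists(clin)) {
    clinical <- readClinicalTable(clin)
    feats <- survivalFeatures(dt, rt, pt)
    scr <- withCallingHandlers(
      runSurvivalScreen(feats, clinical, adjust = adjust),
      warning = function(w) {
        message("screen: ", conditionMessage(w))
        invokeRestart("muffleWarning")
      })
    out$survival_screen <- scr
  }
  writeResults(out, outdir, config = list(tablesDir = tablesDir,
                                          adjust = adjust))
  invisible(out)
}
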