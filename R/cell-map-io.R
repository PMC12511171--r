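# I/O for the three standard inputs (cell tables, region annotations, clinical
# tables) and tidy result export. Dialect: comma-separated UTF-8 CSV with a
# header row and "." as decimal separator; coordinates are written as decimal
# text at full precision so write-then-read round-trips exactly.

.num17 <- function(x) sprintf("%.17g", x)

#' Read a classified cell table (CSV) into a SlideCellMap
#'
#' Expects a header with columns `cell_id`, `x_um`, `y_um`, `cell_class`
#' (case-insensitive; extra columns are ignored). Coordinates are micrometers
#' in slide space. Class labels must be one of
#' `r paste(CELL_CLASSES, collapse = ", ")`. Row order is preserved.
#'
#' @param source path to a CSV file, or a character vector of CSV lines.
#' @param patientId patient identifier; if `NULL`, taken from a `patient_id`
#'   column (which must then be constant).
#' @return a [SlideCellMap-class].
#' @export
readCellTable <- function(source, patientId = NULL) {
  df <- if (length(source) == 1L && file.exists(source))
    utils::read.csv(source, colClasses = "character", check.names = FALSE)
  else utils::read.csv(text = source, colClasses = "character",
                       check.names = FALSE)
  names(df) <- tolower(names(df))
  for (col in c("cell_id", "x_um", "y_um", "cell_class"))
    if (!col %in% names(df))
      stop("cell table is missing required column '", col, "'")
  if (is.null(patientId)) {
    if (!"patient_id" %in% names(df))
      stop("no patientId given and no patient_id column present")
    pid <- unique(df$patient_id)
    if (length(pid) != 1L)
      stop("patient_id column is not constant")
    patientId <- pid
  }
  for (col in c("x_um", "y_um")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(!is.finite(v))
    if (length(bad))
      stop(sprintf("non-numeric or non-finite %s at data row %d (file line %d)",
                   col, bad[1L], bad[1L] + 1L))
    df[[col]] <- v
  }
  cc <- toupper(df$cell_class)
  unknown <- setdiff(unique(cc), CELL_CLASSES)
  if (length(unknown))
    stop("unknown cell_class value(s) ", paste(unknown, collapse = ", "),
         "; allowed classes: ", paste(CELL_CLASSES, collapse = ", "))
  if (anyDuplicated(df$cell_id))
    stop("duplicate cell_id: ", df$cell_id[anyDuplicated(df$cell_id)][1L])
  SlideCellMap(patientId,
               data.frame(cell_id = df$cell_id, x_um = df$x_um,
                          y_um = df$y_um, cell_class = cc))
}

#' Write a SlideCellMap as CSV
#'
#' Columns, in order: `patient_id`, `cell_id`, `x_um`, `y_um`, `cell_class`.
#' Coordinates are written at full precision so the file re-reads exactly.
#'
#' @param cellMap a [SlideCellMap-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeCellTable <- function(cellMap, path) {
  cl <- cells(cellMap)
  out <- data.frame(patient_id = patientId(cellMap), cell_id = cl$cell_id,
                    x_um = .num17(cl$x_um), y_um = .num17(cl$y_um),
                    cell_class = as.character(cl$cell_class))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# ---- region annotations (GeoJSON) -------------------------------------------

.geojsonRings <- function(geom, featIdx) {
  rings <- switch(geom$type,
    Polygon = list(geom$coordinates),
    MultiPolygon = geom$coordinates,
    stop(sprintf("feature %d: unsupported geometry type '%s'",
                 featIdx, geom$type)))
  lapply(seq_along(rings), function(k) {
    poly <- rings[[k]]
    if (length(poly) > 1L)
      stop(sprintf("feature %d: polygon holes are not supported; %s",
                   featIdx, "model holes as EXCLUDE features instead"))
    ring <- poly[[1L]]
    m <- do.call(rbind, lapply(ring, function(pt) c(pt[[1L]], pt[[2L]])))
    m <- .normalizeRing(m)
    err <- .checkRing(m)
    if (!is.null(err)) stop(sprintf("feature %d: %s", featIdx, err))
    m
  })
}

#' Read region annotations (GeoJSON) into a RegionSet
#'
#' Expects a FeatureCollection in which every feature carries a property
#' `region_label` in CORE, TRANSITION, PERIPHERY, EXCLUDE and a Polygon or
#' MultiPolygon geometry in micrometer coordinates. EXCLUDE geometries are
#' attached as exclusion zones to every region of the slide (they are
#' intersected with each region's geometry before area subtraction, so an
#' exclusion only affects regions it actually overlaps).
#'
#' @param source path to a GeoJSON file, or a GeoJSON string.
#' @param patientId patient identifier; if `NULL`, taken from a top-level
#'   `patient_id` property.
#' @return a [RegionSet-class].
#' @export
readRegionAnnotations <- function(source, patientId = NULL) {
  txt <- if (length(source) == 1L && file.exists(source))
    paste(readLines(source, warn = FALSE), collapse = "\n") else
    paste(source, collapse = "\n")
  gj <- jsonlite::fromJSON(txt, simplifyVector = FALSE)
  if (is.null(gj$type) || gj$type != "FeatureCollection")
    stop("expected a GeoJSON FeatureCollection")
  if (is.null(patientId))
    patientId <- if (!is.null(gj$patient_id)) gj$patient_id else "unknown"
  regParts <- list()
  exclusions <- list()
  for (i in seq_along(gj$features)) {
    f <- gj$features[[i]]
    lab <- f$properties$region_label
    if (is.null(lab) || !(lab %in% c(REGION_LABELS, "EXCLUDE")))
      stop(sprintf(
        "feature %d: unknown region_label '%s'; allowed: %s", i,
        if (is.null(lab)) "<missing>" else lab,
        paste(c(REGION_LABELS, "EXCLUDE"), collapse = ", ")))
    rings <- .geojsonRings(f$geometry, i)
    if (lab == "EXCLUDE") exclusions <- c(exclusions, rings)
    else regParts[[lab]] <- c(regParts[[lab]], rings)
  }
  if (!length(regParts))
    stop("no CORE/TRANSITION/PERIPHERY features present")
  regs <- lapply(names(regParts), function(lab)
    Region(lab, regParts[[lab]], exclusions))
  RegionSet(patientId, regs)
}

#' Write a RegionSet as GeoJSON
#'
#' Region geometries become MultiPolygon features with a `region_label`
#' property; the slide's exclusion zones (deduplicated across regions) become
#' `EXCLUDE` features. Coordinates are written at full precision.
#'
#' @param regionSet a [RegionSet-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeRegionAnnotations <- function(regionSet, path) {
  ringCoords <- function(m) {
    m <- rbind(m, m[1L, ])                     # close the ring
    list(lapply(seq_len(nrow(m)), function(i) c(m[i, 1L], m[i, 2L])))
  }
  feats <- lapply(regions(regionSet), function(r) list(
    type = "Feature",
    properties = list(region_label = r@label),
    geometry = list(type = "MultiPolygon",
                    coordinates = lapply(r@parts, ringCoords))))
  excl <- unlist(lapply(regions(regionSet), function(r) r@exclusions),
                 recursive = FALSE)
  if (length(excl)) {
    keys <- vapply(excl, function(m) paste(.num17(m), collapse = ","),
                   character(1))
    excl <- excl[!duplicated(keys)]
    feats <- c(feats, lapply(excl, function(m) list(
      type = "Feature",
      properties = list(region_label = "EXCLUDE"),
      geometry = list(type = "Polygon", coordinates = ringCoords(m)))))
  }
  gj <- list(type = "FeatureCollection", patient_id = patientId(regionSet),
             features = unname(feats))
  jsonlite::write_json(gj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# ---- clinical table ----------------------------------------------------------

.CLINICAL_LEVELS <- list(
  age_group = c("under65", "at_least65"),
  sex = c("male", "female"),
  performance_status = c("ps0_2", "gt2", "missing"),
  treatment = c("rt_chemo", "palliative", "none"),
  mgmt = c("methylated", "unmethylated", "unknown"),
  surgery = c("biopsy", "partial", "total"),
  midline = c("yes", "none", "missing"))

.CLINICAL_MISSING_LEVEL <- c(performance_status = "missing", mgmt = "unknown",
                             midline = "missing")

#' Read a per-patient clinical table (CSV)
#'
#' Expected columns: `patient_id`, `os_months`, `os_event`, `pfs_months`,
#' `pfs_event`, `age_group`, `sex`, `performance_status`, `treatment`,
#' `mgmt`, `surgery`, `midline`. OS is months from initial surgery to death
#' or censoring; PFS is months from initial surgery to progression or
#' censoring. Event flags accept TRUE/FALSE, 1/0, yes/no. Values equal to
#' `missingToken` in `performance_status`, `mgmt` or `midline` map to that
#' variable's missing/unknown level.
#'
#' @param source path to a CSV file, or a character vector of CSV lines.
#' @param missingToken string denoting a missing categorical value
#'   (default `""`; set to `"NA"` for NA-coded files).
#' @return data.frame of clinical records with factor-coded categoricals.
#' @export
readClinicalTable <- function(source, missingToken = "") {
  df <- if (length(source) == 1L && file.exists(source))
    utils::read.csv(source, colClasses = "character", check.names = FALSE,
                    na.strings = NULL)
  else utils::read.csv(text = source, colClasses = "character",
                       check.names = FALSE, na.strings = NULL)
  names(df) <- tolower(names(df))
  need <- c("patient_id", "os_months", "os_event", "pfs_months", "pfs_event",
            names(.CLINICAL_LEVELS))
  for (col in need)
    if (!col %in% names(df))
      stop("clinical table is missing required column '", col, "'")
  parseBool <- function(v, col) {
    out <- rep(NA, length(v))
    out[tolower(v) %in% c("true", "1", "yes")] <- TRUE
    out[tolower(v) %in% c("false", "0", "no")] <- FALSE
    bad <- which(is.na(out))
    if (length(bad))
      stop(sprintf("unparseable %s '%s' at data row %d", col, v[bad[1L]],
                   bad[1L]))
    out
  }
  for (col in c("os_months", "pfs_months")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(!is.finite(v))
    if (length(bad))
      stop(sprintf("non-numeric %s at data row %d", col, bad[1L]))
    if (any(v < 0))
      stop(sprintf("negative %s at data row %d", col, which(v < 0)[1L]))
    df[[col]] <- v
  }
  df$os_event <- parseBool(df$os_event, "os_event")
  df$pfs_event <- parseBool(df$pfs_event, "pfs_event")
  for (col in names(.CLINICAL_LEVELS)) {
    v <- df[[col]]
    if (col %in% names(.CLINICAL_MISSING_LEVEL))
      v[v == missingToken] <- .CLINICAL_MISSING_LEVEL[[col]]
    bad <- which(!(v %in% .CLINICAL_LEVELS[[col]]))
    if (length(bad))
      stop(sprintf("unparseable %s value '%s' at data row %d", col,
                   v[bad[1L]], bad[1L]))
    df[[col]] <- factor(v, levels = .CLINICAL_LEVELS[[col]])
  }
  df[c(need)]
}

#' Write a clinical table as CSV
#'
#' @param clinical data.frame as returned by [readClinicalTable()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeClinicalTable <- function(clinical, path) {
  out <- clinical
  out$os_months <- .num17(out$os_months)
  out$pfs_months <- .num17(out$pfs_months)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Summarize cohort characteristics
#'
#' Reproduces the usual cohort-characteristics summary: counts and
#' percentages of alive patients, patients under 65, RT+chemotherapy-treated
#' patients; male-to-female ratio; median and range of OS and PFS.
#' Percentages are 100*count/n. The reporting precision mirrors clinical
#' convention: `digitsSmall` decimals (default 1) for the alive percentage,
#' `digits` decimals (default 0) for the others; both configurable.
#'
#' @param clinical data.frame of clinical records.
#' @param digitsSmall decimals for the alive percentage.
#' @param digits decimals for the other percentages.
#' @return a list with fields `n_patients`, `n_alive`, `pct_alive`,
#'   `n_under65`, `pct_under65`, `male_to_female_ratio`, `n_rt_chemo`,
#'   `pct_rt_chemo`, `median_os`, `os_range`, `median_pfs`, `pfs_range`.
#'   The ratio is `NA` when no females are present.
#' @export
summarizeCohort <- function(clinical, digitsSmall = 1L, digits = 0L) {
  stopifnot(nrow(clinical) >= 1L)
  n <- nrow(clinical)
  nAlive <- sum(!clinical$os_event)
  nU65 <- sum(clinical$age_group == "under65")
  nM <- sum(clinical$sex == "male")
  nF <- sum(clinical$sex == "female")
  nRC <- sum(clinical$treatment == "rt_chemo")
  list(
    n_patients = n,
    n_alive = nAlive,
    pct_alive = round(100 * nAlive / n, digitsSmall),
    n_under65 = nU65,
    pct_under65 = round(100 * nU65 / n, digits),
    male_to_female_ratio = if (nF > 0) round(nM / nF, 1L) else NA_real_,
    n_rt_chemo = nRC,
    pct_rt_chemo = round(100 * nRC / n, digits),
    median_os = stats::median(clinical$os_months),
    os_range = range(clinical$os_months),
    median_pfs = stats::median(clinical$pfs_months),
    pfs_range = range(clinical$pfs_months))
}

#' Synthetic clinical table with the study cohort's marginal characteristics
#'
#' Builds a deterministic 54-patient clinical table whose marginal counts
#' match the published cohort summary this pipeline is calibrated to:
#' 52 dead / 2 alive; OS median 14 (range 1.7-192) months; 53 with
#' progression or death; PFS median 7.6 (range 1.5-153) months; 30 patients
#' under 65; 35 male / 19 female; performance status 0-2 in 49, >2 in 5;
#' midline crossing yes 7 / none 43 / missing 4; long-course RT+chemotherapy
#' 40, palliative 9, none 5; MGMT methylated 32 / unmethylated 19 / unknown 3;
#' surgery biopsy 2 / partial 30 / total 22. Within these marginals the
#' per-patient joint assignment is arbitrary (and fixed); survival values
#' between the anchored order statistics are interpolated. PFS never exceeds
#' OS for a patient.
#'
#' @return data.frame of 54 clinical records.
#' @export
makeTable1Cohort <- function() {
  n <- 54L
  # OS sorted: anchors min 1.7, both middle order stats 14, max 192
  os <- c(seq(1.7, 14, length.out = 27L), seq(14, 192, length.out = 27L))
  # PFS sorted: min 1.5, middle 7.6, max 153; elementwise below OS
  pfs <- c(seq(1.5, 7.6, length.out = 27L), seq(7.6, 153, length.out = 27L))
  stopifnot(all(pfs <= os))
  osEvent <- rep(TRUE, n); osEvent[c(53L, 54L)] <- FALSE      # 2 alive
  pfsEvent <- rep(TRUE, n); pfsEvent[54L] <- FALSE            # 1 without event
  rep_lv <- function(counts) {
    v <- rep(names(counts), times = as.integer(counts))
    factor(v, levels = names(counts))
  }
  data.frame(
    patient_id = sprintf("P%02d", seq_len(n)),
    os_months = os, os_event = osEvent,
    pfs_months = pfs, pfs_event = pfsEvent,
    age_group = rep_lv(c(under65 = 30, at_least65 = 24)),
    sex = rep_lv(c(male = 35, female = 19)),
    performance_status = rep_lv(c(ps0_2 = 49, gt2 = 5, missing = 0)),
    treatment = rep_lv(c(rt_chemo = 40, palliative = 9, none = 5)),
    mgmt = rep_lv(c(methylated = 32, unmethylated = 19, unknown = 3)),
    surgery = rep_lv(c(biopsy = 2, partial = 30, total = 22)),
    midline = rep_lv(c(yes = 7, none = 43, missing = 4)))
}

# ---- tidy result export ------------------------------------------------------

.configHash <- function(x) {
  # polynomial rolling hash over the serialized object; stable fingerprint
  # for run metadata
  bytes <- as.integer(serialize(x, NULL, version = 2L))
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Write tidy pipeline tables plus run metadata
#'
#' Each table is written as `<name>.csv` with its documented column order; a
#' `run_info.json` records the seed, package version, and a hash of the
#' configuration so outputs are traceable. Re-running with identical inputs
#' produces byte-identical files.
#'
#' @param tables named list of nonempty data.frames.
#' @param dir output directory (created if needed).
#' @param seed the seed used for the run (or `NULL`).
#' @param config the configuration object used (hashed into the metadata).
#' @return character vector of files written, invisibly.
#' @export
writeResults <- function(tables, dir, seed = NULL, config = NULL) {
  stopifnot(is.list(tables), length(tables) > 0L,
            !is.null(names(tables)), all(nzchar(names(tables))))
  for (nm in names(tables))
    if (!is.data.frame(tables[[nm]]) || nrow(tables[[nm]]) == 0L)
      stop("table '", nm, "' is empty; refusing to write an empty file")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(dir)) stop("cannot create output directory ", dir)
  files <- character(0)
  for (nm in names(tables)) {
    f <- file.path(dir, paste0(nm, ".csv"))
    utils::write.csv(tables[[nm]], f, row.names = FALSE, quote = FALSE)
    files <- c(files, f)
  }
  meta <- list(
    seed = seed,
    package_version = as.character(utils::packageVersion("glioSpatial")),
    config_hash = .configHash(config),
    tables = names(tables))
  f <- file.path(dir, "run_info.json")
  jsonlite::write_json(meta, f, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(c(files, f))
}
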