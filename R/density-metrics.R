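#' Cell density in cells per square millimeter
#'
#' @param count nonnegative cell count(s).
#' @param area region net area(s) in mm^2, strictly positive.
#' @return count/area, cells per mm^2.
#' @examples
#' cellDensity(250, 1.0)   # periphery-scale tumor density
#' @export
cellDensity <- function(count, area) {
  if (any(area <= 0)) stop("area must be strictly positive")
  if (any(count < 0)) stop("count must be nonnegative")
  count / area
}

#' Per-region, per-class counts and densities for one slide
#'
#' One row per present region x all five cell classes (classes absent from a
#' region get a zero-count row). Cells labeled `EXCLUDED` or `NONE` are never
#' counted; areas are region net areas (exclusions subtracted).
#'
#' @param labeledCells cells data.frame from [assignCellsToRegions()].
#' @param regionSet the [RegionSet-class] used for the assignment.
#' @return data.frame with columns `patient_id`, `region_label`,
#'   `cell_class`, `count`, `area_mm2`, `density`.
#' @export
buildDensityTable <- function(labeledCells, regionSet) {
  stopifnot("region_label" %in% names(labeledCells))
  pid <- patientId(regionSet)
  labs <- intersect(REGION_LABELS, regionLabels(regionSet))
  areas <- vapply(regions(regionSet)[labs], regionArea, numeric(1))
  counted <- labeledCells[labeledCells$region_label %in% labs, ]
  tab <- table(factor(counted$region_label, levels = labs),
               factor(counted$cell_class, levels = CELL_CLASSES))
  out <- expand.grid(cell_class = CELL_CLASSES, region_label = labs,
                     stringsAsFactors = FALSE)[, 2:1]
  out$patient_id <- pid
  out$count <- as.integer(tab[cbind(out$region_label, out$cell_class)])
  out$area_mm2 <- areas[out$region_label]
  out$density <- cellDensity(out$count, out$area_mm2)
  rownames(out) <- NULL
  out[, c("patient_id", "region_label", "cell_class", "count", "area_mm2",
          "density")]
}

.RATIO_DEFS <- list(
  IBA1_per_tumor = c("IBA1", "TUMOR"),
  CD8_per_tumor = c("CD8", "TUMOR"),
  FOXP3_per_tumor = c("FOXP3", "TUMOR"),
  FOXP3_per_CD8 = c("FOXP3", "CD8"))

#' Immune-to-tumor and FOXP3+/CD8+ density ratios
#'
#' Ratios are computed per patient and region from the density table
#' (numerator and denominator share the region area, so the density ratio
#' equals the count ratio). A zero denominator count yields a missing value
#' (`NA`), excluded pairwise from cohort tests, never an infinity. Ratios:
#' IBA1/tumor, CD8/tumor, FOXP3/tumor, and the immunosuppression index
#' FOXP3/CD8. Unstained cells take part in no ratio.
#'
#' @param densityTable data.frame from [buildDensityTable()] (one or many
#'   patients).
#' @return data.frame with columns `patient_id`, `region_label`,
#'   `ratio_name`, `value`.
#' @export
buildRatioTable <- function(densityTable) {
  key <- interaction(densityTable$patient_id, densityTable$region_label,
                     drop = TRUE)
  rows <- list()
  for (k in levels(key)) {
    sub <- densityTable[key == k, ]
    dens <- stats::setNames(sub$density, sub$cell_class)
    cnt <- stats::setNames(sub$count, sub$cell_class)
    for (rn in names(.RATIO_DEFS)) {
      nd <- .RATIO_DEFS[[rn]]
      num <- nd[1L]; den <- nd[2L]
      val <- if (!num %in% names(cnt) || !den %in% names(cnt) ||
                 cnt[[den]] == 0L) NA_real_ else dens[[num]] / dens[[den]]
      rows[[length(rows) + 1L]] <- data.frame(
        patient_id = sub$patient_id[1L], region_label = sub$region_label[1L],
        ratio_name = rn, value = val)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

.CONTRASTS <- list(
  core_minus_periphery = c("CORE", "PERIPHERY"),
  tz_minus_periphery = c("TRANSITION", "PERIPHERY"),
  core_minus_tz = c("CORE", "TRANSITION"))

#' Per-patient region-difference (waterfall) statistics
#'
#' For each patient and cell class, the signed density difference between two
#' regions: core minus periphery, transition minus periphery, and core minus
#' transition. Patients lacking one of the two regions are omitted from that
#' contrast. Sorted, these differences form the waterfall plots that expose
#' interpatient heterogeneity (most patients positive, some negative).
#'
#' @param densityTable data.frame from [buildDensityTable()].
#' @return data.frame with columns `patient_id`, `cell_class`, `contrast`,
#'   `difference` (cells/mm^2).
#' @export
buildWaterfallTable <- function(densityTable) {
  rows <- list()
  for (cn in names(.CONTRASTS)) {
    a <- .CONTRASTS[[cn]][1L]; b <- .CONTRASTS[[cn]][2L]
    da <- densityTable[densityTable$region_label == a, ]
    db <- densityTable[densityTable$region_label == b, ]
    m <- merge(da[, c("patient_id", "cell_class", "density")],
               db[, c("patient_id", "cell_class", "density")],
               by = c("patient_id", "cell_class"), suffixes = c("_a", "_b"))
    if (nrow(m) == 0L) next
    rows[[length(rows) + 1L]] <- data.frame(
      patient_id = m$patient_id, cell_class = m$cell_class, contrast = cn,
      difference = m$density_a - m$density_b)
  }
  out <- do.call(rbind, rows)
  out <- out[order(match(out$contrast, names(.CONTRASTS)),
                   match(out$cell_class, CELL_CLASSES), out$patient_id), ]
  rownames(out) <- NULL
  out
}
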