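#' Net area of a region in square millimeters
#'
#' Computes the polygon area of the region geometry minus the area of its
#' exclusion zones, where each exclusion is first intersected with the
#' geometry (an exclusion lying outside the region has no effect). Exclusions
#' are assumed pairwise disjoint. Areas are converted from square micrometers
#' by 1 mm^2 = 1e6 um^2.
#'
#' @param region a [Region-class].
#' @return net area in mm^2 (scalar).
#' @examples
#' sq <- cbind(c(0, 1000, 1000, 0), c(0, 0, 1000, 1000))
#' ex <- cbind(c(0, 500, 500, 0), c(0, 0, 500, 500))
#' regionArea(Region("CORE", sq, list(ex)))  # 0.75
#' @export
regionArea <- function(region) {
  stopifnot(methods::is(region, "Region"))
  gross <- .partsArea(region@parts)
  cut <- 0
  for (ex in region@exclusions)
    cut <- cut + sum(vapply(region@parts, function(p)
      .polyIntersectionArea(p, ex), numeric(1)))
  net <- (gross - cut) / 1e6
  if (net <= 0)
    stop("region '", region@label, "' has non-positive net area after exclusions")
  net
}

#' Assign cells to labeled regions
#'
#' Each cell receives exactly one label: the region containing its point
#' (boundary points count as inside; where two regions share a boundary the
#' first label in CORE, TRANSITION, PERIPHERY order wins), `EXCLUDED` if the
#' point lies in any exclusion zone (artifact areas are dropped from all
#' downstream counts), or `NONE` if outside all region polygons.
#'
#' @param cellMap a [SlideCellMap-class].
#' @param regionSet a [RegionSet-class] for the same slide.
#' @return the cells data.frame with an added factor column `region_label`
#'   with levels `r paste(ASSIGNMENT_LABELS, collapse = ", ")`.
#' @export
assignCellsToRegions <- function(cellMap, regionSet) {
  stopifnot(methods::is(cellMap, "SlideCellMap"),
            methods::is(regionSet, "RegionSet"))
  methods::validObject(regionSet)
  cl <- cells(cellMap)
  lab <- rep("NONE", nrow(cl))
  x <- cl$x_um; y <- cl$y_um

  excl <- unlist(lapply(regions(regionSet), function(r) r@exclusions),
                 recursive = FALSE)
  excluded <- if (length(excl)) .pointsInParts(x, y, excl) else
    rep(FALSE, length(x))

  for (rl in intersect(REGION_LABELS, regionLabels(regionSet))) {
    todo <- which(lab == "NONE" & !excluded)
    if (!length(todo)) break
    hit <- .pointsInParts(x[todo], y[todo], regions(regionSet)[[rl]]@parts)
    lab[todo[hit]] <- rl
  }
  lab[excluded] <- "EXCLUDED"
  cl$region_label <- factor(lab, levels = ASSIGNMENT_LABELS)
  cl
}

#' Tumor-fraction grid over a slide
#'
#' Tiles the cell bounding box with square tiles of side `tileSize` and
#' computes, per tile, the total cell count, the tumor (P53+) cell count, and
#' the tumor fraction tumor/total. The denominator is the total cell
#' population, unstained cells included. Tiles holding fewer than `minCells`
#' cells get an undefined (NA) fraction rather than a noisy estimate.
#'
#' @param cellMap a [SlideCellMap-class].
#' @param tileSize tile side length in micrometers.
#' @param minCells minimum occupancy for a defined fraction (default 20).
#' @return a list with `tileSize`, integer matrices `total` and `tumor`
#'   (rows = y tiles, columns = x tiles), numeric matrix `fraction`,
#'   and the grid `origin` (xmin, ymin).
#' @export
tumorFractionGrid <- function(cellMap, tileSize, minCells = 20L) {
  stopifnot(methods::is(cellMap, "SlideCellMap"), tileSize > 0)
  cl <- cells(cellMap)
  x0 <- min(cl$x_um); y0 <- min(cl$y_um)
  ix <- pmin(floor((cl$x_um - x0) / tileSize),
             max(floor((max(cl$x_um) - x0 - 1e-9) / tileSize), 0)) + 1L
  iy <- pmin(floor((cl$y_um - y0) / tileSize),
             max(floor((max(cl$y_um) - y0 - 1e-9) / tileSize), 0)) + 1L
  nx <- max(ix); ny <- max(iy)
  total <- matrix(0L, nrow = ny, ncol = nx)
  tumor <- matrix(0L, nrow = ny, ncol = nx)
  tt <- table(factor(iy, levels = seq_len(ny)), factor(ix, levels = seq_len(nx)))
  total[] <- as.integer(tt)
  isT <- cl$cell_class == "TUMOR"
  if (any(isT)) {
    tu <- table(factor(iy[isT], levels = seq_len(ny)),
                factor(ix[isT], levels = seq_len(nx)))
    tumor[] <- as.integer(tu)
  }
  frac <- ifelse(total >= minCells, tumor / total, NA_real_)
  list(tileSize = tileSize, total = total, tumor = tumor, fraction = frac,
       origin = c(xmin = x0, ymin = y0))
}

#' Suggest tumor-core tiles from a tumor-fraction grid
#'
#' Marks tiles whose tumor fraction strictly exceeds the threshold (the core
#' criterion is "over 60 percent" P53+ of the total cell population, so the
#' default 0.60 is compared strictly). Tiles with undefined fraction are never
#' marked. The mask is advisory: analyses always use the supplied ROIs.
#'
#' @param grid result of [tumorFractionGrid()].
#' @param threshold tumor fraction in (0, 1); default 0.60.
#' @return logical matrix of the same shape as `grid$fraction`.
#' @export
suggestCoreMask <- function(grid, threshold = 0.60) {
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold <= 0 || threshold >= 1)
    stop("threshold must be a single value strictly between 0 and 1")
  mask <- grid$fraction > threshold
  mask[is.na(mask)] <- FALSE
  mask
}
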