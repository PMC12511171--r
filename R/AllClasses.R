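#' Cell classes recognised by the pipeline
#'
#' The five phenotype classes emitted by the upstream cell classifier:
#' P53+ tumor cells, IBA1+ microglia/macrophages, CD8+ cytotoxic T cells,
#' FOXP3+ regulatory T cells, and unstained (marker-negative) cells.
#'
#' @export
CELL_CLASSES <- c("TUMOR", "IBA1", "CD8", "FOXP3", "UNSTAINED")

#' Region labels of the zonal model
#'
#' Concentric histological zones of an infiltrating glioblastoma: dense tumor
#' core, transition zone of decreasing tumor-cell density, and periphery with
#' single-cell infiltration into near-normal brain.
#'
#' @export
REGION_LABELS <- c("CORE", "TRANSITION", "PERIPHERY")

#' Labels a cell can receive during region assignment
#' @export
ASSIGNMENT_LABELS <- c(REGION_LABELS, "NONE", "EXCLUDED")

.IMMUNE_CLASSES <- c("IBA1", "CD8", "FOXP3")

#' SlideCellMap: classified cell coordinates for one patient slide
#'
#' Holds one row per classified cell with coordinates in micrometers (slide
#' space, y increasing downward as in the image convention; only relative
#' distances are used so the orientation is inert) and the phenotype class.
#'
#' @slot patientId single character identifier.
#' @slot cells data.frame with columns `cell_id` (character, unique),
#'   `x_um`, `y_um` (finite numerics, micrometers) and `cell_class`
#'   (factor with levels [CELL_CLASSES]).
#'
#' @seealso [SlideCellMap()] constructor, [readCellTable()]
#' @export
setClass("SlideCellMap",
  representation(patientId = "character", cells = "data.frame"))

setValidity("SlideCellMap", function(object) {
  msgs <- character()
  if (length(object@patientId) != 1L || is.na(object@patientId) ||
      !nzchar(object@patientId))
    msgs <- c(msgs, "patientId must be a single non-empty string")
  cl <- object@cells
  need <- c("cell_id", "x_um", "y_um", "cell_class")
  if (!all(need %in% names(cl))) {
    msgs <- c(msgs, paste0("cells must have columns: ",
                           paste(setdiff(need, names(cl)), collapse = ", ")))
  } else {
    if (nrow(cl) < 1L)
      msgs <- c(msgs, "a slide must contain at least one cell")
    if (anyDuplicated(cl$cell_id))
      msgs <- c(msgs, "cell_id values must be unique within a slide")
    if (!all(is.finite(cl$x_um)) || !all(is.finite(cl$y_um)))
      msgs <- c(msgs, "cell coordinates must be finite")
    cc <- as.character(cl$cell_class)
    if (!all(cc %in% CELL_CLASSES))
      msgs <- c(msgs, paste0("unknown cell_class values: ",
                             paste(unique(setdiff(cc, CELL_CLASSES)),
                                   collapse = ", "),
                             "; allowed: ", paste(CELL_CLASSES, collapse = ", ")))
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a SlideCellMap
#'
#' @param patientId single character identifier.
#' @param cells data.frame with columns `cell_id`, `x_um`, `y_um`,
#'   `cell_class`.
#' @return A [SlideCellMap-class] object.
#' @examples
#' scm <- SlideCellMap("P01", data.frame(
#'   cell_id = c("c1", "c2"), x_um = c(10, 20), y_um = c(5, 5),
#'   cell_class = c("TUMOR", "IBA1")))
#' nCells(scm)
#' @export
SlideCellMap <- function(patientId, cells) {
  cells <- as.data.frame(cells)
  cells$cell_id <- as.character(cells$cell_id)
  cells$cell_class <- factor(as.character(cells$cell_class),
                             levels = CELL_CLASSES)
  methods::new("SlideCellMap", patientId = as.character(patientId),
               cells = cells)
}

#' Region: one labeled zone polygon with exclusions
#'
#' Geometry is a polygon or multipolygon in micrometer coordinates, stored as
#' a list of parts; each part is a numeric matrix of vertices (columns x, y,
#' open ring, i.e. first vertex not repeated). Exclusion polygons mark artifact
#' areas (bleeding, necrosis, folds, background staining); they are intersected
#' with the geometry before any area subtraction, and cells falling inside them
#' are dropped from all counts.
#'
#' @slot label one of [REGION_LABELS].
#' @slot parts list of vertex matrices (simple polygons, pairwise disjoint).
#' @slot exclusions list of vertex matrices (may be empty).
#' @export
setClass("Region",
  representation(label = "character", parts = "list", exclusions = "list"))

setValidity("Region", function(object) {
  msgs <- character()
  if (length(object@label) != 1L || !(object@label %in% REGION_LABELS))
    msgs <- c(msgs, paste0("label must be one of ",
                           paste(REGION_LABELS, collapse = ", ")))
  if (length(object@parts) < 1L)
    msgs <- c(msgs, "geometry must have at least one polygon part")
  for (i in seq_along(object@parts)) {
    err <- .checkRing(object@parts[[i]])
    if (!is.null(err)) msgs <- c(msgs, sprintf("geometry part %d: %s", i, err))
  }
  for (i in seq_along(object@exclusions)) {
    err <- .checkRing(object@exclusions[[i]])
    if (!is.null(err)) msgs <- c(msgs, sprintf("exclusion %d: %s", i, err))
  }
  if (!length(msgs)) {
    a <- tryCatch(regionArea(object), error = function(e) conditionMessage(e))
    if (is.character(a)) msgs <- c(msgs, a)
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a Region
#'
#' @param label one of `r paste(REGION_LABELS, collapse = ", ")`.
#' @param parts a single vertex matrix or a list of vertex matrices
#'   (micrometers; open rings).
#' @param exclusions optional list of vertex matrices.
#' @return A [Region-class] object.
#' @examples
#' sq <- cbind(c(0, 1000, 1000, 0), c(0, 0, 1000, 1000))
#' regionArea(Region("CORE", sq))  # 1 mm^2
#' @export
Region <- function(label, parts, exclusions = list()) {
  if (is.matrix(parts)) parts <- list(parts)
  if (is.matrix(exclusions)) exclusions <- list(exclusions)
  parts <- lapply(parts, .normalizeRing)
  exclusions <- lapply(exclusions, .normalizeRing)
  methods::new("Region", label = as.character(label), parts = parts,
               exclusions = exclusions)
}

#' RegionSet: the labeled zones of one slide
#'
#' At most one [Region-class] per label; region geometries must be pairwise
#' non-overlapping (shared boundaries are allowed, positive-area overlap is
#' an error).
#'
#' @slot patientId single character identifier.
#' @slot regions named list of [Region-class] objects, names are the labels.
#' @export
setClass("RegionSet",
  representation(patientId = "character", regions = "list"))

setValidity("RegionSet", function(object) {
  msgs <- character()
  if (length(object@patientId) != 1L || !nzchar(object@patientId))
    msgs <- c(msgs, "patientId must be a single non-empty string")
  regs <- object@regions
  if (length(regs) < 1L)
    msgs <- c(msgs, "at least one region must be present")
  labs <- vapply(regs, function(r) r@label, character(1))
  if (!identical(unname(names(regs)), unname(labs)))
    msgs <- c(msgs, "regions list names must equal the region labels")
  if (anyDuplicated(labs))
    msgs <- c(msgs, "at most one region per label")
  if (!length(msgs) && length(regs) > 1L) {
    for (i in seq_len(length(regs) - 1L)) {
      for (j in seq(i + 1L, length(regs))) {
        ov <- .partsIntersectionArea(regs[[i]]@parts, regs[[j]]@parts)
        tot <- min(.partsArea(regs[[i]]@parts), .partsArea(regs[[j]]@parts))
        if (ov > 1e-9 * tot)
          msgs <- c(msgs, sprintf("regions %s and %s overlap (area %.3g um^2)",
                                  labs[i], labs[j], ov))
      }
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a RegionSet
#'
#' @param patientId single character identifier.
#' @param regions a list of [Region-class] objects.
#' @return A [RegionSet-class] object.
#' @export
RegionSet <- function(patientId, regions) {
  if (methods::is(regions, "Region")) regions <- list(regions)
  names(regions) <- vapply(regions, function(r) r@label, character(1))
  ord <- order(match(names(regions), REGION_LABELS))
  methods::new("RegionSet", patientId = as.character(patientId),
               regions = regions[ord])
}

# ---- generics & accessors ----------------------------------------------------

#' @rdname SlideCellMap-class
#' @param object,x an object.
#' @export
setGeneric("patientId", function(x) standardGeneric("patientId"))

#' @rdname SlideCellMap-class
#' @export
setMethod("patientId", "SlideCellMap", function(x) x@patientId)

#' @rdname RegionSet-class
#' @param x an object.
#' @export
setMethod("patientId", "RegionSet", function(x) x@patientId)

#' Cells of a SlideCellMap
#' @param x a [SlideCellMap-class].
#' @return the cells data.frame.
#' @export
setGeneric("cells", function(x) standardGeneric("cells"))

#' @rdname cells
#' @export
setMethod("cells", "SlideCellMap", function(x) x@cells)

#' Number of cells on a slide
#' @param x a [SlideCellMap-class].
#' @export
nCells <- function(x) nrow(cells(x))

#' Regions of a RegionSet
#' @param x a [RegionSet-class].
#' @return named list of [Region-class] objects.
#' @export
setGeneric("regions", function(x) standardGeneric("regions"))

#' @rdname regions
#' @export
setMethod("regions", "RegionSet", function(x) x@regions)

#' Labels present in a RegionSet
#' @param x a [RegionSet-class].
#' @export
regionLabels <- function(x) names(regions(x))

#' @rdname Region-class
#' @param object a [Region-class].
#' @export
setMethod("show", "Region", function(object) {
  cat(sprintf("Region '%s': %d part(s), %d exclusion(s), net area %.4f mm^2\n",
              object@label, length(object@parts), length(object@exclusions),
              regionArea(object)))
})

#' @rdname RegionSet-class
#' @param object a [RegionSet-class].
#' @export
setMethod("show", "RegionSet", function(object) {
  cat(sprintf("RegionSet for patient '%s' (%d region(s))\n",
              object@patientId, length(object@regions)))
  for (r in object@regions) methods::show(r)
})

#' @rdname SlideCellMap-class
#' @export
setMethod("show", "SlideCellMap", function(object) {
  tab <- table(object@cells$cell_class)
  cat(sprintf("SlideCellMap for patient '%s': %d cells (micrometers)\n",
              object@patientId, nrow(object@cells)))
  cat(" ", paste(sprintf("%s=%d", names(tab), as.integer(tab)),
                 collapse = ", "), "\n")
})
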