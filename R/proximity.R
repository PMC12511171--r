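#' Proximity analysis configuration
#'
#' Defaults follow the proximity statistic of the zonal analysis: for every
#' reference tumor cell, count neighbor cells of a given immune class within a
#' 30 micrometer radius (Euclidean, center-to-center, inclusive boundary) and
#' bin the counts into 1-4, 5-9, and 10-or-more neighbors; references with no
#' neighbor in range form the explicit zero bin `b0` so the four bin fractions
#' are a proper distribution.
#'
#' @param radius search radius in micrometers (> 0); default 30.
#' @param bins list of integer intervals `c(lo, hi)` (hi may be `Inf`),
#'   disjoint, ascending, starting at 1.
#' @param referenceClass the reference cell class; default `"TUMOR"`.
#' @param neighborClasses neighbor classes to profile; default the three
#'   immune classes IBA1, CD8, FOXP3.
#' @return a list of class `ProximityConfig`.
#' @export
proximityConfig <- function(radius = 30,
                            bins = list(c(1, 4), c(5, 9), c(10, Inf)),
                            referenceClass = "TUMOR",
                            neighborClasses = c("IBA1", "CD8", "FOXP3")) {
  stopifnot(is.numeric(radius), length(radius) == 1L, radius > 0,
            referenceClass %in% CELL_CLASSES,
            all(neighborClasses %in% CELL_CLASSES))
  lo <- vapply(bins, function(b) b[1L], numeric(1))
  hi <- vapply(bins, function(b) b[2L], numeric(1))
  if (lo[1L] != 1 || any(hi < lo) ||
      (length(bins) > 1L && any(lo[-1L] != hi[-length(hi)] + 1)))
    stop("bins must be disjoint ascending integer intervals starting at 1")
  structure(list(radius = radius, bins = bins,
                 referenceClass = referenceClass,
                 neighborClasses = neighborClasses),
            class = "ProximityConfig")
}

.binLabels <- function(bins) {
  labs <- vapply(bins, function(b)
    if (is.infinite(b[2L])) sprintf("b%dplus", as.integer(b[1L]))
    else sprintf("b%d_%d", as.integer(b[1L]), as.integer(b[2L])),
    character(1))
  c("b0", labs)
}

#' Count neighbors within a fixed radius (spatial grid search)
#'
#' For each reference point, the number of neighbor points at Euclidean
#' center-to-center distance less than or equal to `radius`. When `refIds`
#' and `nbrIds` are given, a neighbor with the same id as the reference is
#' skipped, so a point never counts itself when the two collections share
#' members.
#'
#' @param ref two-column matrix (or data.frame) of reference x,y in
#'   micrometers.
#' @param nbr two-column matrix (or data.frame) of neighbor x,y.
#' @param radius search radius in micrometers (> 0).
#' @param refIds,nbrIds optional integer identity vectors for self-exclusion.
#' @return integer vector, one count per reference point.
#' @examples
#' countNeighborsWithin(cbind(0, 0), cbind(c(10, 25, 40), 0), 30)  # 2
#' @export
countNeighborsWithin <- function(ref, nbr, radius, refIds = NULL,
                                 nbrIds = NULL) {
  stopifnot(radius > 0)
  ref <- as.matrix(ref); nbr <- as.matrix(nbr)
  if (nrow(ref) == 0L) return(integer(0))
  useIds <- !is.null(refIds) && !is.null(nbrIds)
  cpp_count_neighbors(as.numeric(ref[, 1L]), as.numeric(ref[, 2L]),
                      as.numeric(nbr[, 1L]), as.numeric(nbr[, 2L]),
                      as.numeric(radius),
                      if (useIds) as.integer(refIds) else integer(0),
                      if (useIds) as.integer(nbrIds) else integer(0))
}

#' Brute-force neighbor counts (O(n^2) oracle)
#'
#' Same contract as [countNeighborsWithin()], computed by exhaustive pairwise
#' distances. Intended as an independent check of the grid implementation.
#'
#' @inheritParams countNeighborsWithin
#' @return integer vector, one count per reference point.
#' @export
bruteForceNeighborCounts <- function(ref, nbr, radius, refIds = NULL,
                                     nbrIds = NULL) {
  stopifnot(radius > 0)
  ref <- as.matrix(ref); nbr <- as.matrix(nbr)
  nR <- nrow(ref)
  if (nR == 0L) return(integer(0))
  if (nrow(nbr) == 0L) return(integer(nR))
  useIds <- !is.null(refIds) && !is.null(nbrIds)
  r2 <- radius^2
  out <- integer(nR)
  for (i in seq_len(nR)) {
    d2 <- (nbr[, 1L] - ref[i, 1L])^2 + (nbr[, 2L] - ref[i, 2L])^2
    hit <- d2 <= r2
    if (useIds) hit <- hit & (nbrIds != refIds[i])
    out[i] <- sum(hit)
  }
  out
}

#' Bin per-reference neighbor counts
#'
#' Maps each nonnegative integer count to its bin label: 0 to `b0`, and each
#' configured interval to its label (defaults `b1_4`, `b5_9`, `b10plus`).
#'
#' @param counts integer vector of neighbor counts (>= 0).
#' @param bins bin intervals as in [proximityConfig()].
#' @return factor of bin labels with all levels present.
#' @export
binNeighborCounts <- function(counts, bins = proximityConfig()$bins) {
  stopifnot(all(counts >= 0))
  labs <- .binLabels(bins)
  breaks <- c(-0.5, 0.5, vapply(bins, function(b) b[2L] + 0.5, numeric(1)))
  breaks[length(breaks)] <- Inf
  cut(counts, breaks = breaks, labels = labs)
}

#' Proximity table for one slide
#'
#' For each region and neighbor class: per reference cell (default tumor)
#' attributed to that region, the number of neighbor-class cells within the
#' configured radius is counted over ALL non-excluded cells of the slide —
#' neighbors are counted across region boundaries, only the reference cell's
#' own position determines its region. Counts are binned; the table reports,
#' per (region, neighbor class, bin), the number of reference cells in the
#' bin, their fraction of all reference cells of the region, and their
#' density over the region net area (the un-normalized variant).
#'
#' @param labeledCells cells data.frame from [assignCellsToRegions()].
#' @param regionSet the [RegionSet-class] used for the assignment.
#' @param config a [proximityConfig()].
#' @return data.frame with columns `patient_id`, `region_label`,
#'   `neighbor_class`, `bin_label`, `n_reference_in_bin`, `fraction`,
#'   `density`. Fractions are `NA` for regions without reference cells.
#' @export
buildProximityTable <- function(labeledCells, regionSet,
                                config = proximityConfig()) {
  stopifnot(inherits(config, "ProximityConfig"),
            "region_label" %in% names(labeledCells))
  pid <- patientId(regionSet)
  labs <- intersect(REGION_LABELS, regionLabels(regionSet))
  areas <- vapply(regions(regionSet)[labs], regionArea, numeric(1))
  ok <- !(labeledCells$region_label %in% "EXCLUDED")
  alive <- labeledCells[ok, ]                   # excluded cells drop entirely
  binLabs <- .binLabels(config$bins)
  rows <- list()
  for (rl in labs) {
    isRef <- alive$region_label == rl &
      alive$cell_class == config$referenceClass
    refs <- alive[isRef, ]
    nRef <- nrow(refs)
    for (ncl in config$neighborClasses) {
      nbrs <- alive[alive$cell_class == ncl, ]
      if (nRef > 0L) {
        cnt <- countNeighborsWithin(
          refs[, c("x_um", "y_um")], nbrs[, c("x_um", "y_um")],
          config$radius,
          refIds = match(refs$cell_id, alive$cell_id),
          nbrIds = match(nbrs$cell_id, alive$cell_id))
        tab <- table(binNeighborCounts(cnt, config$bins))
      } else {
        tab <- stats::setNames(rep(0L, length(binLabs)), binLabs)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        patient_id = pid, region_label = rl, neighbor_class = ncl,
        bin_label = binLabs,
        n_reference_in_bin = as.integer(tab[binLabs]),
        fraction = if (nRef > 0L) as.integer(tab[binLabs]) / nRef
                   else NA_real_,
        density = as.integer(tab[binLabs]) / areas[[rl]])
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Poisson null probability of a neighbor-count bin
#'
#' Under the independence null (neighbor cells a homogeneous Poisson process
#' of the given intensity, independent of the reference cells), the number of
#' neighbors within radius r is Poisson with mean
#' mu = intensity * 1e-6 * pi * r^2 (the 1e-6 converts cells/mm^2 to
#' cells/um^2). Returns the probability that the count falls in `bin`.
#'
#' @param intensity neighbor-class intensity in cells/mm^2 (>= 0).
#' @param radius radius in micrometers.
#' @param bin integer interval `c(lo, hi)`; `hi` may be `Inf`; `c(0, 0)`
#'   gives the zero bin.
#' @return probability in \[0, 1\].
#' @examples
#' poissonBinProbability(512, 30, c(1, 4))
#' @export
poissonBinProbability <- function(intensity, radius, bin) {
  stopifnot(intensity >= 0, radius > 0, length(bin) == 2L, bin[1L] <= bin[2L])
  mu <- intensity * 1e-6 * pi * radius^2
  lo <- bin[1L]; hi <- bin[2L]
  upper <- if (is.infinite(hi)) 1 else stats::ppois(hi, mu)
  lower <- if (lo <= 0) 0 else stats::ppois(lo - 1, mu)
  upper - lower
}
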