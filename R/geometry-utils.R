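# Planar polygon primitives for ROI geometry.
#
# Polygons are stored as open rings: numeric matrices with columns (x, y) in
# micrometers, first vertex NOT repeated at the end. Intersection areas are
# computed exactly (up to floating point) by ear-clipping both polygons into
# triangles and clipping triangle pairs with Sutherland-Hodgman; triangles are
# convex so the clip is exact for arbitrary simple polygons.

.normalizeRing <- function(m) {
  m <- as.matrix(m)
  if (!is.numeric(m) || ncol(m) != 2L)
    stop("a polygon ring must be a numeric matrix with two columns (x, y)")
  storage.mode(m) <- "double"                  # guard integer overflow
  n <- nrow(m)
  # drop a repeated closing vertex (GeoJSON convention)
  if (n >= 2L && isTRUE(all(m[1L, ] == m[n, ]))) m <- m[-n, , drop = FALSE]
  # drop consecutive duplicate vertices
  if (nrow(m) >= 2L) {
    keep <- c(TRUE, rowSums(abs(diff(m))) > 0)
    m <- m[keep, , drop = FALSE]
  }
  dimnames(m) <- NULL
  m
}

.ringSignedArea <- function(m) {
  n <- nrow(m)
  j <- c(2:n, 1L)
  sum(m[, 1L] * m[j, 2L] - m[j, 1L] * m[, 2L]) / 2
}

.ringArea <- function(m) abs(.ringSignedArea(m))

.partsArea <- function(parts) sum(vapply(parts, .ringArea, numeric(1)))

# do open segments (p1,p2) and (p3,p4) properly cross (interior intersection)?
.segmentsCross <- function(p1, p2, p3, p4) {
  d1 <- (p4[1] - p3[1]) * (p1[2] - p3[2]) - (p4[2] - p3[2]) * (p1[1] - p3[1])
  d2 <- (p4[1] - p3[1]) * (p2[2] - p3[2]) - (p4[2] - p3[2]) * (p2[1] - p3[1])
  d3 <- (p2[1] - p1[1]) * (p3[2] - p1[2]) - (p2[2] - p1[2]) * (p3[1] - p1[1])
  d4 <- (p2[1] - p1[1]) * (p4[2] - p1[2]) - (p2[2] - p1[2]) * (p4[1] - p1[1])
  (d1 * d2 < 0) && (d3 * d4 < 0)
}

.ringSelfIntersects <- function(m) {
  n <- nrow(m)
  if (n < 4L) return(FALSE)
  idx <- cbind(seq_len(n), c(2:n, 1L))
  for (a in seq_len(n - 2L)) {
    bmax <- if (a == 1L) n - 1L else n
    for (b in seq(a + 2L, bmax)) {
      if (.segmentsCross(m[idx[a, 1L], ], m[idx[a, 2L], ],
                         m[idx[b, 1L], ], m[idx[b, 2L], ]))
        return(TRUE)
    }
  }
  FALSE
}

# NULL when valid, else an error message
.checkRing <- function(m) {
  if (!is.matrix(m) || !is.numeric(m) || ncol(m) != 2L)
    return("ring must be a numeric two-column matrix")
  if (!all(is.finite(m))) return("ring has non-finite coordinates")
  if (nrow(m) < 3L) return("ring must have at least 3 vertices")
  if (.ringArea(m) <= 0) return("ring has zero area")
  if (.ringSelfIntersects(m)) return("ring is self-intersecting")
  NULL
}

# ear-clipping triangulation of a simple polygon; returns list of 3x2 matrices
.triangulate <- function(m) {
  if (.ringSignedArea(m) < 0) m <- m[rev(seq_len(nrow(m))), , drop = FALSE]
  n <- nrow(m)
  if (n == 3L) return(list(m))
  idx <- seq_len(n)
  tris <- vector("list", n - 2L)
  k <- 0L
  eps <- 1e-12 * max(abs(m), 1)
  cross2 <- function(o, a, b)
    (a[1] - o[1]) * (b[2] - o[2]) - (a[2] - o[2]) * (b[1] - o[1])
  while (length(idx) > 3L) {
    nn <- length(idx)
    found <- FALSE
    for (ii in seq_len(nn)) {
      ip <- idx[if (ii == 1L) nn else ii - 1L]
      ic <- idx[ii]
      iq <- idx[if (ii == nn) 1L else ii + 1L]
      a <- m[ip, ]; b <- m[ic, ]; c <- m[iq, ]
      cr <- cross2(a, b, c)
      if (cr <= eps) next                        # reflex or collinear: not an ear
      # no other remaining vertex inside or on the boundary of triangle abc
      # (boundary-inclusive: clipping an ear whose diagonal passes through a
      # vertex would leave a degenerate polygon)
      others <- setdiff(idx, c(ip, ic, iq))
      ok <- TRUE
      for (io in others) {
        p <- m[io, ]
        if (cross2(a, b, p) >= -eps && cross2(b, c, p) >= -eps &&
            cross2(c, a, p) >= -eps) { ok <- FALSE; break }
      }
      if (ok) {
        k <- k + 1L
        tris[[k]] <- rbind(a, b, c)
        idx <- idx[-ii]
        found <- TRUE
        break
      }
    }
    if (!found) {
      # numerically degenerate: drop the vertex with the flattest angle
      nn <- length(idx)
      crs <- vapply(seq_len(nn), function(ii) {
        ip <- idx[if (ii == 1L) nn else ii - 1L]
        ic <- idx[ii]
        iq <- idx[if (ii == nn) 1L else ii + 1L]
        abs(cross2(m[ip, ], m[ic, ], m[iq, ]))
      }, numeric(1))
      idx <- idx[-which.min(crs)]
    }
  }
  k <- k + 1L
  tris[[k]] <- m[idx, , drop = FALSE]
  tris[seq_len(k)]
}

# Sutherland-Hodgman: clip subject polygon by a CONVEX clip polygon (CCW)
.clipByConvex <- function(subject, clip) {
  if (.ringSignedArea(clip) < 0)
    clip <- clip[rev(seq_len(nrow(clip))), , drop = FALSE]
  out <- subject
  nc <- nrow(clip)
  for (e in seq_len(nc)) {
    if (nrow(out) == 0L) return(out)
    a <- clip[e, ]
    b <- clip[if (e == nc) 1L else e + 1L, ]
    ex <- b[1] - a[1]; ey <- b[2] - a[2]
    inp <- out
    n <- nrow(inp)
    side <- ex * (inp[, 2L] - a[2]) - ey * (inp[, 1L] - a[1])
    res <- matrix(numeric(0), ncol = 2L)
    for (i in seq_len(n)) {
      j <- if (i == n) 1L else i + 1L
      si <- side[i]; sj <- side[j]
      if (si >= 0) res <- rbind(res, inp[i, ])
      if ((si > 0 && sj < 0) || (si < 0 && sj > 0)) {
        t <- si / (si - sj)
        res <- rbind(res, inp[i, ] + t * (inp[j, ] - inp[i, ]))
      }
    }
    out <- res
  }
  out
}

# exact area of intersection of two simple polygons (triangulate x clip)
.polyIntersectionArea <- function(ringA, ringB) {
  ta <- .triangulate(ringA)
  tb <- .triangulate(ringB)
  total <- 0
  for (x in ta) {
    bbx <- range(x[, 1L]); bby <- range(x[, 2L])
    for (y in tb) {
      if (max(y[, 1L]) < bbx[1L] || min(y[, 1L]) > bbx[2L] ||
          max(y[, 2L]) < bby[1L] || min(y[, 2L]) > bby[2L]) next
      p <- .clipByConvex(x, y)
      if (nrow(p) >= 3L) total <- total + .ringArea(p)
    }
  }
  total
}

# intersection area of two multipolygons (lists of rings, parts disjoint)
.partsIntersectionArea <- function(partsA, partsB) {
  total <- 0
  for (a in partsA) for (b in partsB)
    total <- total + .polyIntersectionArea(a, b)
  total
}

# axis-aligned rectangle (4 vertices, 2 distinct x, 2 distinct y)?
.isAxisRect <- function(p) {
  nrow(p) == 4L && length(unique(p[, 1L])) == 2L &&
    length(unique(p[, 2L])) == 2L
}

# points inside any part (closed polygons: boundary points count as inside);
# axis-aligned rectangles take a vectorized range test instead of the general
# point-in-polygon routine
.pointsInParts <- function(x, y, parts) {
  inside <- rep(FALSE, length(x))
  for (p in parts) {
    todo <- which(!inside)
    if (!length(todo)) break
    hit <- if (.isAxisRect(p)) {
      xr <- range(p[, 1L]); yr <- range(p[, 2L])
      x[todo] >= xr[1L] & x[todo] <= xr[2L] &
        y[todo] >= yr[1L] & y[todo] <= yr[2L]
    } else {
      pracma::inpolygon(x[todo], y[todo], p[, 1L], p[, 2L], boundary = TRUE)
    }
    inside[todo[hit]] <- TRUE
  }
  inside
}

.bboxOfParts <- function(parts) {
  xs <- unlist(lapply(parts, function(p) range(p[, 1L])))
  ys <- unlist(lapply(parts, function(p) range(p[, 2L])))
  c(xmin = min(xs), xmax = max(xs), ymin = min(ys), ymax = max(ys))
}
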