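#' Exact polygon geometry for region agreement
#'
#' Areas, unions, intersections and the Jaccard similarity index (JSI) of
#' region annotations are computed by exact polygon clipping (Vatti
#' clipping via the polyclip library), not by rasterisation, so results
#' are resolution independent. Rings are vertex matrices in base-resolution
#' pixels, stored unclosed.
#'
#' @name geometry
NULL

# polyclip representation: list of list(x=, y=) rings. Hole rings come
# back with opposite orientation, so areas are summed signed.
to_pc <- function(ring) list(x = ring[, 1L], y = ring[, 2L])
rings_to_pc <- function(rings) lapply(rings, to_pc)

signed_area_pc <- function(p) {
  x <- p$x; y <- p$y
  n <- length(x)
  j <- c(n, seq_len(n - 1L))
  sum(x[j] * y - x * y[j]) / 2
}

pc_area <- function(pcs) {
  if (!length(pcs)) return(0)
  abs(sum(vapply(pcs, signed_area_pc, numeric(1L))))
}

#' Area of a polygon ring (shoelace)
#'
#' @param ring Numeric matrix of vertices (columns x, y), unclosed.
#' @return Non-negative area in square pixels; orientation independent.
#' @examples
#' ring_area(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1)))  # 1
#' @export
ring_area <- function(ring) {
  ring <- as_geometry(ring)
  n <- nrow(ring)
  if (n > 1L && all(ring[1L, ] == ring[n, ])) {
    ring <- ring[-n, , drop = FALSE]
  }
  if (nrow(unique(ring)) < 3L) {
    stop("degenerate ring: fewer than 3 distinct vertices", call. = FALSE)
  }
  abs(signed_area_pc(to_pc(ring)))
}

#' Convert an area from square pixels to square millimetres
#'
#' @param area_px2 Area in px^2 at base resolution.
#' @param mpp Microns per pixel (> 0).
#' @return Area in mm^2: `area_px2 * (mpp / 1000)^2`.
#' @examples
#' px2_to_mm2(16e6, 0.25)  # 1 mm^2
#' @export
px2_to_mm2 <- function(area_px2, mpp) {
  if (!is.numeric(mpp) || mpp <= 0) stop("mpp must be > 0", call. = FALSE)
  area_px2 * (mpp / 1000)^2
}

#' A set of region polygons from one annotator for one label
#'
#' @param rings List of vertex matrices (or a single matrix).
#' @param label Feature name.
#' @param annotator_id,slide_id Provenance.
#' @return Object of class `region_set`.
#' @export
region_set <- function(rings, label = "", annotator_id = "",
                       slide_id = "") {
  if (is.matrix(rings)) rings <- list(rings)
  rings <- lapply(rings, as_geometry)
  structure(list(rings = rings, label = label,
                 annotator_id = annotator_id, slide_id = slide_id),
            class = "region_set")
}

as_region_rings <- function(x) {
  if (inherits(x, "region_set")) x$rings
  else if (is.matrix(x)) list(x)
  else lapply(x, as_geometry)
}

# set-union of rings as a polyclip region
pc_union <- function(rings) {
  pcs <- rings_to_pc(rings)
  if (length(pcs) <= 1L) return(pcs)
  acc <- pcs[1L]
  for (k in 2L:length(pcs)) {
    acc <- polyclip::polyclip(acc, pcs[k], op = "union",
                              fillA = "nonzero", fillB = "nonzero")
  }
  acc
}

#' Area of the union of a set of polygons
#'
#' Overlapping polygons are counted once, which is what prevents
#' double-counting in both the Jaccard index and the exhaustiveness
#' numerator.
#'
#' @param regions A `region_set`, a list of vertex matrices, or a single
#'   matrix.
#' @return Union area in px^2 (0 for an empty set).
#' @export
union_area <- function(regions) {
  rings <- as_region_rings(regions)
  if (!length(rings)) return(0)
  pc_area(pc_union(rings))
}

#' Jaccard similarity index of two region sets
#'
#' `area(A intersect B) / area(A union B)` on the set-unions of each
#' annotator's polygons. When both sets are empty the index is defined as
#' 1 (perfect agreement on absence); empty versus non-empty gives 0.
#'
#' @param a,b Region sets (see [union_area()] for accepted forms).
#' @return Similarity in \[0, 1\], symmetric in `a` and `b`.
#' @examples
#' sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
#' jaccard(sq, sq + cbind(rep(0.5, 4), 0))  # 1/3
#' @export
jaccard <- function(a, b) {
  ra <- as_region_rings(a)
  rb <- as_region_rings(b)
  if (!length(ra) && !length(rb)) return(1)
  if (!length(ra) || !length(rb)) return(0)
  ua <- pc_union(ra)
  ub <- pc_union(rb)
  inter <- polyclip::polyclip(ua, ub, op = "intersection",
                              fillA = "nonzero", fillB = "nonzero")
  uni <- polyclip::polyclip(ua, ub, op = "union",
                            fillA = "nonzero", fillB = "nonzero")
  ia <- pc_area(inter)
  uu <- pc_area(uni)
  if (uu == 0) return(1)
  min(1, ia / uu)
}

#' Intersect polygons with a clip window
#'
#' @param rings List of vertex matrices.
#' @param clip A single vertex matrix (e.g. a box ring).
#' @return List of vertex matrices of the clipped region (possibly empty).
#' @keywords internal
clip_rings <- function(rings, clip) {
  if (!length(rings)) return(list())
  out <- polyclip::polyclip(pc_union(rings), list(to_pc(as_geometry(clip))),
                            op = "intersection",
                            fillA = "nonzero", fillB = "nonzero")
  lapply(out, function(p) cbind(x = p$x, y = p$y))
}

#' Approximate a circle by a regular polygon
#'
#' Circle constructs are stored as centre + radius and buffered to a
#' 64-gon before any clipping operation.
#'
#' @param centre Length-2 numeric (x, y).
#' @param radius Radius in px.
#' @param n Number of vertices.
#' @return Vertex matrix.
#' @export
circle_ring <- function(centre, radius, n = 64L) {
  th <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  cbind(x = centre[1L] + radius * cos(th),
        y = centre[2L] + radius * sin(th))
}

# Ring form of a record's geometry for area work: polygons as-is, boxes
# as 4-corner rings, circles as 64-gons. NULL for other constructs.
record_ring <- function(rec) {
  switch(rec$construct,
    polygon = rec$geometry,
    bounding_box = {
      g <- rec$geometry
      x0 <- min(g[, 1L]); x1 <- max(g[, 1L])
      y0 <- min(g[, 2L]); y1 <- max(g[, 2L])
      rbind(c(x0, y0), c(x1, y0), c(x1, y1), c(x0, y1))
    },
    circle = circle_ring(as.numeric(rec$geometry), rec$radius),
    NULL
  )
}

# Winding-number point-in-region test against a polyclip region (list of
# signed rings, holes opposite orientation). Vectorised over points.
points_in_pc <- function(px, py, pcs) {
  wind <- numeric(length(px))
  for (p in pcs) {
    x <- p$x; y <- p$y
    n <- length(x)
    j <- c(2:n, 1L)
    for (k in seq_len(n)) {
      x1 <- x[k]; y1 <- y[k]; x2 <- x[j[k]]; y2 <- y[j[k]]
      up <- (y1 <= py) & (y2 > py)
      dn <- (y1 > py) & (y2 <= py)
      if (any(up)) {
        isleft <- (x2 - x1) * (py[up] - y1) - (px[up] - x1) * (y2 - y1)
        wind[up] <- wind[up] + (isleft > 0)
      }
      if (any(dn)) {
        isleft <- (x2 - x1) * (py[dn] - y1) - (px[dn] - x1) * (y2 - y1)
        wind[dn] <- wind[dn] - (isleft < 0)
      }
    }
  }
  wind != 0
}
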