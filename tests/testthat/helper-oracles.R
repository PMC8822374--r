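# Independent oracles used across the suite. These deliberately take a
# different computational route from the package code they check.

# random star-shaped (hence simple) polygon
random_star <- function(centre = c(0, 0), r_mean = 5, n = 12L) {
  th <- sort(runif(n, 0, 2 * pi))
  r <- r_mean * runif(n, 0.5, 1.5)
  cbind(x = centre[1L] + r * cos(th), y = centre[2L] + r * sin(th))
}

# rasterisation oracle for Jaccard: count grid points (spacing `step`)
# inside each polygon with sp::point.in.polygon
raster_jaccard <- function(ring_a, ring_b, step = 0.05) {
  xr <- range(ring_a[, 1L], ring_b[, 1L])
  yr <- range(ring_a[, 2L], ring_b[, 2L])
  gx <- seq(xr[1L] - step, xr[2L] + step, by = step)
  gy <- seq(yr[1L] - step, yr[2L] + step, by = step)
  g <- expand.grid(x = gx, y = gy)
  in_a <- sp::point.in.polygon(g$x, g$y, ring_a[, 1L], ring_a[, 2L]) > 0
  in_b <- sp::point.in.polygon(g$x, g$y, ring_b[, 1L], ring_b[, 2L]) > 0
  u <- sum(in_a | in_b)
  if (u == 0) return(1)
  sum(in_a & in_b) / u
}

# brute-force optimal matching: enumerate all feasible assignments,
# maximise cardinality then minimise total distance
brute_force_match <- function(pa, pb, radius) {
  n <- nrow(pa); m <- nrow(pb)
  d <- sqrt(outer(pa[, 1L], pb[, 1L], "-")^2 +
            outer(pa[, 2L], pb[, 2L], "-")^2)
  best <- list(k = -1L, dist = Inf)
  recurse <- function(i, used_b, k, dist) {
    if (i > n) {
      if (k > best$k || (k == best$k && dist < best$dist - 1e-12)) {
        best <<- list(k = k, dist = dist)
      }
      return(invisible())
    }
    recurse(i + 1L, used_b, k, dist)  # leave a_i unmatched
    for (j in seq_len(m)) {
      if (!used_b[j] && d[i, j] <= radius) {
        used_b[j] <- TRUE
        recurse(i + 1L, used_b, k + 1L, dist + d[i, j])
        used_b[j] <- FALSE
      }
    }
  }
  recurse(1L, rep(FALSE, m), 0L, 0)
  best
}

# textbook kappa via agreement weights: v = 1 - w, kappa = (po - pe)/(1 - pe)
textbook_kappa <- function(cm, weighting = "none", dictionary = NULL) {
  cm <- unclass(cm)
  total <- sum(cm)
  if (total == 0) return(NA_real_)
  p <- cm / total
  e <- outer(rowSums(p), colSums(p))
  labs <- rownames(cm)
  k <- nrow(cm)
  v <- diag(k)  # agreement weights
  if (weighting != "none" && !is.null(dictionary)) {
    grp <- vapply(labs, function(nm) {
      l <- dictionary$labels[[nm]]
      if (is.null(l) || is.null(l$ordinal_group)) NA_character_
      else l$ordinal_group
    }, character(1L))
    rnk <- vapply(labs, function(nm) {
      l <- dictionary$labels[[nm]]
      if (is.null(l) || is.null(l$ordinal_rank)) NA_integer_
      else l$ordinal_rank
    }, integer(1L))
    for (i in seq_len(k)) for (j in seq_len(k)) {
      if (i == j) next
      if (!is.na(grp[i]) && !is.na(grp[j]) && grp[i] == grp[j]) {
        kg <- max(rnk[grp == grp[i]], na.rm = TRUE)
        frac <- abs(rnk[i] - rnk[j]) / (kg - 1)
        v[i, j] <- 1 - (if (weighting == "quadratic") frac^2 else frac)
      }
    }
  }
  po <- sum(v * p)
  pe <- sum(v * e)
  if (pe >= 1) return(NA_real_)
  (po - pe) / (1 - pe)
}

# tiny two-label dictionary for agreement unit tests
toy_cell_dictionary <- function() {
  anno_dictionary(
    labels = list(
      anno_label("tumour NP1", "cell", "np", 1L),
      anno_label("tumour NP2", "cell", "np", 2L),
      anno_label("tumour NP3", "cell", "np", 3L),
      anno_label("TILs", "cell"),
      anno_label("stroma cell", "cell")
    ),
    required_annotators = 1L
  )
}

make_point_record <- function(id, xy, label, annotator = "A",
                              slide = "s1") {
  anno_record(id, slide, annotator, "H&E", "cell", "point", label,
              geometry = matrix(xy, ncol = 2L),
              created_at = "2026-01-01T00:00:00Z")
}

make_polygon_record <- function(id, ring, label, annotator = "A",
                                slide = "s1") {
  anno_record(id, slide, annotator, "H&E", "region", "polygon", label,
              geometry = ring, created_at = "2026-01-01T00:00:00Z")
}

unit_square <- function(x0 = 0, y0 = 0, side = 1) {
  rbind(c(x0, y0), c(x0 + side, y0), c(x0 + side, y0 + side),
        c(x0, y0 + side))
}
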