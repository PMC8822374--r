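#' A single annotation record
#'
#' One annotated construct on a slide: a region polygon, a cell point or
#' circle, a bounding box, a line, or a textual case/descriptive label,
#' together with its identity and provenance (slide, annotator, stain).
#' Coordinates are 0-based base-resolution pixels, origin top-left, x
#' rightward, y downward. Polygons are stored unclosed (the closing edge
#' back to the first vertex is implicit).
#'
#' @param annotation_id Unique id string.
#' @param slide_id,annotator_id,stain_type Provenance strings (stain e.g.
#'   `"H&E"`, `"IHC"`).
#' @param level One of `"case"`, `"region"`, `"cell"`, `"descriptive"`.
#' @param construct One of `"bounding_box"`, `"point"`, `"circle"`,
#'   `"polygon"`, `"line"`, `"text"`.
#' @param feature_name Label name (validated against a dictionary by
#'   [validate_annotations()]).
#' @param geometry Numeric matrix with columns x, y: one row for point and
#'   circle (the centre), two opposite corners for bounding_box, >= 3
#'   vertices for polygon, >= 2 for line; `NULL` for text.
#' @param radius Circle radius in pixels (circle construct only).
#' @param text_value Optional free text.
#' @param created_at ISO 8601 UTC timestamp string.
#' @return An object of class `anno_record`.
#' @export
anno_record <- function(annotation_id, slide_id, annotator_id, stain_type,
                        level, construct, feature_name,
                        geometry = NULL, radius = NULL, text_value = NULL,
                        created_at = format_utc(Sys.time())) {
  rec <- structure(
    list(annotation_id = as.character(annotation_id),
         slide_id = as.character(slide_id),
         annotator_id = as.character(annotator_id),
         stain_type = as.character(stain_type),
         level = as.character(level),
         construct = as.character(construct),
         feature_name = as.character(feature_name),
         geometry = if (!is.null(geometry)) as_geometry(geometry),
         radius = if (!is.null(radius)) as.numeric(radius),
         text_value = text_value,
         created_at = as.character(created_at)),
    class = "anno_record"
  )
  err <- record_structural_error(rec)
  if (!is.null(err)) stop(err$description, call. = FALSE)
  rec
}

as_geometry <- function(g) {
  if (is.list(g)) g <- do.call(rbind, lapply(g, function(v) unlist(v)[1:2]))
  g <- matrix(as.numeric(g), ncol = 2L,
              dimnames = list(NULL, c("x", "y")))
  g
}

format_utc <- function(t) format(t, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")

#' @export
print.anno_record <- function(x, ...) {
  nv <- if (is.null(x$geometry)) 0L else nrow(x$geometry)
  cat(sprintf("<anno_record %s> %s/%s %s %s '%s' (%d vertices)\n",
              x$annotation_id, x$slide_id, x$annotator_id,
              x$level, x$construct, x$feature_name, nv))
  invisible(x)
}

#' Slide context: physical resolution and pixel dimensions
#'
#' @param slide_id Slide identifier.
#' @param microns_per_pixel Physical resolution at the base level, in
#'   micrometres per pixel (~0.25 at x40 magnification).
#' @param width_px,height_px Base-level dimensions in pixels.
#' @param tissue_mask_path Optional path to a stored tissue mask PNG (see
#'   [write_tissue_mask()]).
#' @return An object of class `slide_context`.
#' @export
slide_context <- function(slide_id, microns_per_pixel, width_px, height_px,
                          tissue_mask_path = NULL) {
  stopifnot(is.numeric(microns_per_pixel), microns_per_pixel > 0,
            width_px > 0, height_px > 0)
  structure(
    list(slide_id = as.character(slide_id),
         microns_per_pixel = as.numeric(microns_per_pixel),
         width_px = as.integer(width_px), height_px = as.integer(height_px),
         tissue_mask_path = tissue_mask_path),
    class = "slide_context"
  )
}

# ---- issue log ---------------------------------------------------------

#' The documented QC rule catalogue
#'
#' Every [qc_issue()] carries a `rule_id` from this table.
#'
#' @return A data.frame with columns `rule_id`, `severity`, `meaning`.
#' @export
qc_rules <- function() {
  data.frame(
    rule_id = c("GEOMETRY_ARITY", "SELF_INTERSECTION", "BAD_COORDINATE",
                "UNKNOWN_CONSTRUCT", "UNKNOWN_LEVEL", "MISSING_FIELD",
                "UNKNOWN_LABEL", "CONSTRUCT_NOT_ALLOWED", "LEVEL_MISMATCH",
                "OUT_OF_BOUNDS", "DUPLICATE_ID", "INCOMPLETE",
                "LOW_EXHAUSTIVENESS", "NO_TISSUE_IN_BOX", "NO_TISSUE_MASK",
                "EMPTY_PROJECT", "STAGE_FAILURE"),
    severity = c("error", "error", "error", "error", "error", "error",
                 "error", "error", "error", "error", "error", "warning",
                 "warning", "warning", "warning", "warning", "error"),
    meaning = c(
      "geometry vertex count does not match the construct",
      "polygon ring crosses itself",
      "coordinate non-finite, negative, or radius non-positive",
      "construct kind not one of the six defined kinds",
      "level not one of case/region/cell/descriptive",
      "required record field missing or empty",
      "feature name absent from the data dictionary",
      "construct not allowed for this label",
      "record level differs from the label's dictionary level",
      "coordinates outside the slide bounds",
      "annotation id shared by more than one record",
      "slide does not meet required box/annotator counts",
      "annotated tissue percentage below the dictionary threshold",
      "designated box contains no tissue",
      "no tissue mask; exhaustiveness denominator fell back to box area",
      "no annotation records in the project",
      "a pipeline stage failed on one slide"),
    stringsAsFactors = FALSE
  )
}

#' Construct one QC issue
#'
#' Issues are the rows of the pipeline's issue log: each carries the
#' offending annotation id (empty for slide-level issues), the slide (WSI)
#' id, a logged date, a rule id from [qc_rules()], a severity and a human
#' readable description.
#'
#' @param rule_id A rule id from [qc_rules()].
#' @param description Human-readable description.
#' @param wsi_id Slide id the issue belongs to.
#' @param annotation_id Offending annotation id, or `""` for slide-level.
#' @param severity `"error"` or `"warning"`; defaults to the catalogue
#'   severity for `rule_id`.
#' @param logged_date ISO 8601 UTC timestamp.
#' @return A one-row data.frame; bind issues with `rbind()`.
#' @export
qc_issue <- function(rule_id, description, wsi_id, annotation_id = "",
                     severity = NULL,
                     logged_date = format_utc(Sys.time())) {
  cat_ <- qc_rules()
  if (!rule_id %in% cat_$rule_id) {
    stop("rule_id '", rule_id, "' is not in the rule catalogue",
         call. = FALSE)
  }
  if (is.null(severity)) {
    severity <- cat_$severity[match(rule_id, cat_$rule_id)]
  }
  data.frame(annotation_id = as.character(annotation_id),
             wsi_id = as.character(wsi_id),
             logged_date = as.character(logged_date),
             rule_id = rule_id, severity = severity,
             description = description, stringsAsFactors = FALSE)
}

no_issues <- function() {
  qc_issue("EMPTY_PROJECT", "x", "x")[0L, , drop = FALSE]
}

# ---- structural validation --------------------------------------------

# Returns NULL if the record is structurally valid, else a list with
# rule_id and description.
record_structural_error <- function(rec) {
  for (f in c("annotation_id", "slide_id", "annotator_id", "level",
              "construct", "feature_name")) {
    v <- rec[[f]]
    if (is.null(v) || length(v) != 1L || is.na(v) || !nzchar(v)) {
      return(list(rule_id = "MISSING_FIELD",
                  description = paste0("field '", f, "' missing or empty")))
    }
  }
  if (!rec$construct %in% anno_constructs()) {
    return(list(rule_id = "UNKNOWN_CONSTRUCT",
                description = paste0("unknown construct '", rec$construct,
                                     "'")))
  }
  if (!rec$level %in% anno_levels()) {
    return(list(rule_id = "UNKNOWN_LEVEL",
                description = paste0("unknown level '", rec$level, "'")))
  }
  g <- rec$geometry
  if (rec$construct %in% c("text")) {
    return(NULL)  # geometry absent by definition
  }
  if (is.null(g) || nrow(g) == 0L) {
    return(list(rule_id = "GEOMETRY_ARITY",
                description = paste0("construct '", rec$construct,
                                     "' requires geometry")))
  }
  if (!all(is.finite(g)) || any(g < 0)) {
    return(list(rule_id = "BAD_COORDINATE",
                description = "coordinates must be finite and non-negative"))
  }
  n <- nrow(g)
  arity_err <- function(need) {
    list(rule_id = "GEOMETRY_ARITY",
         description = sprintf("construct '%s' needs %s vertices, got %d",
                               rec$construct, need, n))
  }
  switch(rec$construct,
    point = if (n != 1L) return(arity_err("exactly 1")),
    circle = {
      if (n != 1L) return(arity_err("exactly 1"))
      if (is.null(rec$radius) || !is.finite(rec$radius) || rec$radius <= 0) {
        return(list(rule_id = "BAD_COORDINATE",
                    description = "circle requires a positive radius"))
      }
    },
    bounding_box = {
      if (n != 2L) return(arity_err("exactly 2"))
      if (g[1L, 1L] == g[2L, 1L] || g[1L, 2L] == g[2L, 2L]) {
        return(list(rule_id = "BAD_COORDINATE",
                    description = "bounding box must have positive extent"))
      }
    },
    polygon = {
      if (n < 3L || nrow(unique(g)) < 3L) return(arity_err("at least 3"))
      if (ring_self_intersects(g)) {
        return(list(rule_id = "SELF_INTERSECTION",
                    description = "polygon ring is self-intersecting"))
      }
    },
    line = if (n < 2L) return(arity_err("at least 2"))
  )
  NULL
}

# Segment-crossing test on the implicitly closed ring: any two
# non-adjacent edges that properly intersect, or collinear-overlap, make
# the ring invalid.
ring_self_intersects <- function(g) {
  n <- nrow(g)
  # drop an explicit closing vertex if present
  if (n > 1L && all(g[1L, ] == g[n, ])) {
    g <- g[-n, , drop = FALSE]
    n <- n - 1L
  }
  if (n < 4L) return(FALSE)  # a triangle cannot self-intersect
  a1 <- g
  a2 <- g[c(2:n, 1L), , drop = FALSE]
  for (i in seq_len(n - 2L)) {
    jmax <- if (i == 1L) n - 1L else n
    for (j in (i + 2L):jmax) {
      if (segments_intersect(a1[i, ], a2[i, ], a1[j, ], a2[j, ])) {
        return(TRUE)
      }
    }
  }
  FALSE
}

cross2 <- function(o, a, b) {
  (a[1L] - o[1L]) * (b[2L] - o[2L]) - (a[2L] - o[2L]) * (b[1L] - o[1L])
}

on_segment <- function(p, q, r) {
  min(p[1L], q[1L]) <= r[1L] && r[1L] <= max(p[1L], q[1L]) &&
    min(p[2L], q[2L]) <= r[2L] && r[2L] <= max(p[2L], q[2L])
}

segments_intersect <- function(p1, p2, q1, q2) {
  d1 <- cross2(q1, q2, p1)
  d2 <- cross2(q1, q2, p2)
  d3 <- cross2(p1, p2, q1)
  d4 <- cross2(p1, p2, q2)
  if (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
      ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))) {
    return(TRUE)
  }
  (d1 == 0 && on_segment(q1, q2, p1)) ||
    (d2 == 0 && on_segment(q1, q2, p2)) ||
    (d3 == 0 && on_segment(p1, p2, q1)) ||
    (d4 == 0 && on_segment(p1, p2, q2))
}

# ---- dictionary validation --------------------------------------------

#' Validate annotation records against a data dictionary
#'
#' Checks conformance of structurally valid records with the project data
#' dictionary: every feature name must be a dictionary label, the construct
#' must be allowed for that label, the record level must match the label's
#' level, coordinates must lie inside the slide bounds (when a
#' `slide_context` is supplied), and annotation ids must be unique.
#' Validation is pure: records are never modified.
#'
#' @param records List of [anno_record()] objects.
#' @param dictionary An [anno_dictionary()].
#' @param slide Optional [slide_context()] enabling the bounds check.
#' @param logged_date Timestamp stamped on emitted issues.
#' @return Issue data.frame (zero rows when fully conformant); see
#'   [qc_issue()].
#' @export
validate_annotations <- function(records, dictionary, slide = NULL,
                                 logged_date = format_utc(Sys.time())) {
  stopifnot(inherits(dictionary, "anno_dictionary"))
  issues <- list()
  add <- function(rule, desc, rec) {
    issues[[length(issues) + 1L]] <<-
      qc_issue(rule, desc, wsi_id = rec$slide_id,
               annotation_id = rec$annotation_id, logged_date = logged_date)
  }
  labs <- dictionary$labels
  for (rec in records) {
    lab <- labs[[rec$feature_name]]
    if (is.null(lab)) {
      add("UNKNOWN_LABEL",
          paste0("feature name '", rec$feature_name,
                 "' is not in the data dictionary"), rec)
      next
    }
    allowed <- dictionary$allowed_constructs[[rec$feature_name]]
    if (!is.null(allowed) && !rec$construct %in% allowed) {
      add("CONSTRUCT_NOT_ALLOWED",
          paste0("construct '", rec$construct, "' not allowed for label '",
                 rec$feature_name, "'"), rec)
    }
    if (rec$level != lab$level) {
      add("LEVEL_MISMATCH",
          paste0("record level '", rec$level, "' but label '",
                 rec$feature_name, "' is ", lab$level, "-level"), rec)
    }
    if (!is.null(slide) && !is.null(rec$geometry)) {
      g <- rec$geometry
      r <- rec$radius %||% 0
      if (any(g[, 1L] - r < 0) || any(g[, 2L] - r < 0) ||
          any(g[, 1L] + r > slide$width_px) ||
          any(g[, 2L] + r > slide$height_px)) {
        add("OUT_OF_BOUNDS", "coordinates outside slide bounds", rec)
      }
    }
  }
  ids <- vapply(records, `[[`, character(1L), "annotation_id")
  dup <- unique(ids[duplicated(ids)])
  for (d in dup) {
    for (k in which(ids == d)) {
      add("DUPLICATE_ID",
          paste0("annotation id '", d, "' used by ", sum(ids == d),
                 " records"), records[[k]])
    }
  }
  if (length(issues)) do.call(rbind, issues) else no_issues()
}

#' Coarsen labels via the dictionary's merge parents
#'
#' Relabels every record whose label declares a `merge_parent` to that
#' parent, following chains to their root (so the operation is
#' idempotent). Used e.g. to collapse nuclear pleomorphism grades
#' NP1/NP2/NP3 to a single tumour-cell class before computing agreement
#' "without tumour cell categorisation". All other record fields are
#' unchanged and the record count is preserved.
#'
#' @inheritParams validate_annotations
#' @return The record list with `feature_name` coarsened.
#' @export
merge_labels <- function(records, dictionary) {
  stopifnot(inherits(dictionary, "anno_dictionary"))
  root <- merge_roots(dictionary)
  lapply(records, function(rec) {
    r <- root[[rec$feature_name]]
    if (!is.null(r)) rec$feature_name <- r
    rec
  })
}

# map each label to the root of its merge_parent chain
merge_roots <- function(dictionary) {
  parents <- vapply(dictionary$labels,
                    function(l) l$merge_parent %||% NA_character_,
                    character(1L))
  out <- list()
  for (nm in names(parents)) {
    cur <- nm
    while (!is.na(parents[[cur]])) cur <- parents[[cur]]
    out[[nm]] <- cur
  }
  out
}
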