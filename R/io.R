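#' Read an annotation file in the project JSON dialect
#'
#' The dialect is a JSON object `{"schema_version": "1.0", "slide_id": ...,
#' "annotations": [...]}` where each annotation carries `annotation_id`,
#' `slide_id`, `annotator_id`, `stain_type`, `level`, `construct`,
#' `feature_name`, `geometry` (array of `[x, y]` pairs), optional `radius`
#' (circle construct), optional `text_value`, and `created_at`.
#'
#' Records that fail a structural invariant (wrong vertex count for the
#' construct, self-intersecting ring, bad coordinates, unknown construct)
#' are not silently dropped: each yields an error issue and the record is
#' excluded from the returned list. Record order is preserved.
#'
#' @param path Path to the annotation JSON file.
#' @param dictionary Optional [anno_dictionary()]; when supplied, the
#'   loaded records are additionally checked with
#'   [validate_annotations()] and those issues appended.
#' @return A list of [anno_record()] objects with attribute `"issues"`
#'   (an issue data.frame, zero rows if none).
#' @export
load_annotations <- function(path, dictionary = NULL) {
  if (!file.exists(path)) stop("annotation file not found: ", path,
                               call. = FALSE)
  doc <- jsonlite::read_json(path)
  slide_default <- doc$slide_id %||% ""
  issues <- list()
  records <- list()
  for (a in doc$annotations %||% list()) {
    rec <- structure(
      list(annotation_id = as.character(a$annotation_id %||% ""),
           slide_id = as.character(a$slide_id %||% slide_default),
           annotator_id = as.character(a$annotator_id %||% ""),
           stain_type = as.character(a$stain_type %||% ""),
           level = as.character(a$level %||% ""),
           construct = as.character(a$construct %||% ""),
           feature_name = as.character(a$feature_name %||% ""),
           geometry = if (length(a$geometry)) as_geometry(a$geometry),
           radius = if (!is.null(a$radius)) as.numeric(a$radius),
           text_value = a$text_value,
           created_at = as.character(a$created_at %||% "")),
      class = "anno_record"
    )
    err <- record_structural_error(rec)
    if (is.null(err)) {
      records[[length(records) + 1L]] <- rec
    } else {
      issues[[length(issues) + 1L]] <-
        qc_issue(err$rule_id, err$description,
                 wsi_id = rec$slide_id, annotation_id = rec$annotation_id)
    }
  }
  issues <- if (length(issues)) do.call(rbind, issues) else no_issues()
  if (!is.null(dictionary)) {
    issues <- rbind(issues, validate_annotations(records, dictionary))
  }
  attr(records, "issues") <- issues
  records
}

#' Write annotation records in the project JSON dialect
#'
#' Round-trip safe: `load_annotations(save_annotations(x, p))` reproduces
#' `x` field-for-field with bit-exact coordinates (numbers are serialised
#' at full precision).
#'
#' @param records List of [anno_record()] objects (all structurally
#'   valid).
#' @param path Destination path.
#' @param slide_id Top-level slide id; defaults to the records' common
#'   slide id (empty when records span slides or the list is empty).
#' @return `path`, invisibly.
#' @export
save_annotations <- function(records, path, slide_id = NULL) {
  for (rec in records) {
    err <- record_structural_error(rec)
    if (!is.null(err)) {
      stop("record '", rec$annotation_id, "': ", err$description,
           call. = FALSE)
    }
  }
  if (is.null(slide_id)) {
    sids <- unique(vapply(records, `[[`, character(1L), "slide_id"))
    slide_id <- if (length(sids) == 1L) sids else ""
  }
  anns <- lapply(records, function(rec) {
    out <- list(annotation_id = rec$annotation_id,
                slide_id = rec$slide_id,
                annotator_id = rec$annotator_id,
                stain_type = rec$stain_type,
                level = rec$level,
                construct = rec$construct,
                feature_name = rec$feature_name)
    if (!is.null(rec$geometry)) {
      out$geometry <- apply(rec$geometry, 1L, identity, simplify = FALSE)
    }
    if (!is.null(rec$radius)) out$radius <- rec$radius
    if (!is.null(rec$text_value)) out$text_value <- rec$text_value
    out$created_at <- rec$created_at
    out
  })
  doc <- list(schema_version = "1.0", slide_id = slide_id,
              annotations = anns)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

# ---- GeoJSON interoperability -----------------------------------------

#' Convert annotation records to / from GeoJSON
#'
#' `export_geojson()` writes an RFC 7946 FeatureCollection: polygons
#' become Polygon features with the ring explicitly closed, bounding boxes
#' become 4-vertex Polygon features, points and circles become Point
#' features (circles carry a `radius` property), lines become LineString
#' features, and text/case records become geometry-less features. Feature
#' properties carry `annotation_id`, `slide_id`, `annotator_id`,
#' `stain_type`, `level`, `construct`, `feature_name`, `created_at` and,
#' when a dictionary with styles is given, the label's display style.
#'
#' `import_geojson()` inverts the export: for every record kind the round
#' trip `import_geojson(export_geojson(x))` reproduces `x` field-for-field
#' (the explicit GeoJSON ring closure is removed again on import).
#'
#' @param records List of [anno_record()] objects.
#' @param path Destination (export) or source (import) file path.
#' @param dictionary Optional [anno_dictionary()] supplying styles.
#' @return `export_geojson()` returns `path` invisibly; `import_geojson()`
#'   returns a list of [anno_record()] objects.
#' @export
export_geojson <- function(records, path, dictionary = NULL) {
  features <- lapply(records, function(rec) {
    props <- list(annotation_id = rec$annotation_id,
                  slide_id = rec$slide_id,
                  annotator_id = rec$annotator_id,
                  stain_type = rec$stain_type,
                  level = rec$level,
                  construct = rec$construct,
                  feature_name = rec$feature_name,
                  created_at = rec$created_at)
    if (!is.null(rec$text_value)) props$text_value <- rec$text_value
    if (!is.null(rec$radius)) props$radius <- rec$radius
    if (!is.null(dictionary) &&
        !is.null(dictionary$style[[rec$feature_name]])) {
      props$style <- dictionary$style[[rec$feature_name]]
    }
    geom <- switch(rec$construct,
      polygon = {
        ring <- rbind(rec$geometry, rec$geometry[1L, , drop = FALSE])
        list(type = "Polygon",
             coordinates = list(apply(ring, 1L, identity, simplify = FALSE)))
      },
      bounding_box = {
        g <- rec$geometry
        x0 <- min(g[, 1L]); x1 <- max(g[, 1L])
        y0 <- min(g[, 2L]); y1 <- max(g[, 2L])
        ring <- list(c(x0, y0), c(x1, y0), c(x1, y1), c(x0, y1), c(x0, y0))
        list(type = "Polygon", coordinates = list(ring))
      },
      point = list(type = "Point", coordinates = as.numeric(rec$geometry)),
      circle = list(type = "Point", coordinates = as.numeric(rec$geometry)),
      line = list(type = "LineString",
                  coordinates = apply(rec$geometry, 1L, identity,
                                      simplify = FALSE)),
      NULL  # text / descriptive: geometry-less feature
    )
    list(type = "Feature", geometry = geom, properties = props)
  })
  doc <- list(type = "FeatureCollection", features = features)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = I(17),
                       null = "null")
  invisible(path)
}

#' @rdname export_geojson
#' @export
import_geojson <- function(path) {
  doc <- jsonlite::read_json(path)
  lapply(doc$features, function(f) {
    p <- f$properties
    construct <- p$construct
    geometry <- NULL
    if (!is.null(f$geometry) && !is.null(f$geometry$type)) {
      geometry <- switch(f$geometry$type,
        Point = matrix(unlist(f$geometry$coordinates), ncol = 2L),
        Polygon = {
          ring <- as_geometry(f$geometry$coordinates[[1L]])
          if (construct == "bounding_box") {
            # reduce the closed 4-corner ring back to two opposite corners
            matrix(c(min(ring[, 1L]), min(ring[, 2L]),
                     max(ring[, 1L]), max(ring[, 2L])),
                   ncol = 2L, byrow = TRUE)
          } else {
            n <- nrow(ring)
            if (all(ring[1L, ] == ring[n, ])) ring[-n, , drop = FALSE]
            else ring
          }
        },
        LineString = as_geometry(f$geometry$coordinates)
      )
    }
    anno_record(annotation_id = p$annotation_id,
                slide_id = p$slide_id, annotator_id = p$annotator_id,
                stain_type = p$stain_type, level = p$level,
                construct = construct, feature_name = p$feature_name,
                geometry = geometry, radius = p$radius,
                text_value = p$text_value, created_at = p$created_at)
  })
}
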