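#' Completeness of a slide's annotations
#'
#' A slide is complete when it carries at least the dictionary-required
#' number of region-level bounding boxes, cell-level bounding boxes, and
#' distinct annotators. Each unmet requirement is reported as a deficit
#' `(requirement, expected, observed)`.
#'
#' @param records The slide's [anno_record()] list (one `slide_id`).
#' @param dictionary An [anno_dictionary()].
#' @return Object of class `completeness_result`: list with `complete`
#'   (logical) and `deficits` (data.frame); `complete` is `TRUE` iff
#'   `deficits` has zero rows.
#' @export
completeness <- function(records, dictionary) {
  stopifnot(inherits(dictionary, "anno_dictionary"))
  lv <- vapply(records, `[[`, character(1L), "level")
  con <- vapply(records, `[[`, character(1L), "construct")
  ann <- vapply(records, `[[`, character(1L), "annotator_id")
  observed <- c(
    region_boxes = sum(con == "bounding_box" & lv == "region"),
    cell_boxes = sum(con == "bounding_box" & lv == "cell"),
    annotators = length(unique(ann))
  )
  expected <- c(region_boxes = dictionary$required_region_boxes,
                cell_boxes = dictionary$required_cell_boxes,
                annotators = dictionary$required_annotators)
  short <- observed < expected
  deficits <- data.frame(requirement = names(expected)[short],
                         expected = unname(expected[short]),
                         observed = unname(observed[short]),
                         stringsAsFactors = FALSE)
  structure(list(complete = nrow(deficits) == 0L, deficits = deficits),
            class = "completeness_result")
}

#' @export
print.completeness_result <- function(x, ...) {
  cat("<completeness>", if (x$complete) "complete" else "incomplete", "\n")
  if (nrow(x$deficits)) print(x$deficits)
  invisible(x)
}

#' Exhaustiveness of a designated box
#'
#' The percentage of tissue inside a region-level bounding box that is
#' covered by region annotations:
#' `100 * area(union(regions) & box & tissue) / area(box & tissue)`.
#' Region polygons are clipped to the box first (annotation spilling
#' outside the box does not inflate the numerator) and unioned so that
#' overlaps are never double-counted. With a tissue mask, both numerator
#' and denominator are evaluated on the mask grid; without one, the
#' denominator falls back to the full box area and a warning issue is
#' attached. A box with no tissue yields `NA` with a warning.
#'
#' @param box A bounding-box [anno_record()], or `c(xmin, ymin, xmax,
#'   ymax)`.
#' @param regions Region records (polygon/bounding_box/circle constructs),
#'   a `region_set`, or a list of vertex matrices.
#' @param mask Optional [compute_tissue_mask()] result.
#' @param dictionary Optional [anno_dictionary()] supplying the flagging
#'   threshold (default threshold 50 when absent).
#' @return Object of class `exhaustiveness_result`: list with `box_id`,
#'   `percentage`, `denominator_px2`, `flagged`, `issues`.
#' @export
exhaustiveness <- function(box, regions, mask = NULL, dictionary = NULL) {
  box_id <- ""
  wsi_id <- ""
  if (inherits(box, "anno_record")) {
    box_id <- box$annotation_id
    wsi_id <- box$slide_id
    box <- as_box(record_ring(box))
  } else {
    box <- as_box(box)
  }
  threshold <- if (!is.null(dictionary)) {
    dictionary$exhaustiveness_threshold
  } else 50
  rings <- regions_as_rings(regions)
  box_ring <- rbind(c(box[1L], box[2L]), c(box[3L], box[2L]),
                    c(box[3L], box[4L]), c(box[1L], box[4L]))
  clipped <- clip_rings(rings, box_ring)
  issues <- no_issues()
  if (is.null(mask)) {
    denom <- (box[3L] - box[1L]) * (box[4L] - box[2L])
    numer <- if (length(clipped)) pc_area(rings_to_pc(clipped)) else 0
    issues <- rbind(issues, qc_issue(
      "NO_TISSUE_MASK",
      "no tissue mask; exhaustiveness denominator is the full box area",
      wsi_id = wsi_id, annotation_id = box_id))
  } else {
    denom <- tissue_area_in(mask, box)
    if (denom == 0) {
      return(structure(list(box_id = box_id, percentage = NA_real_,
                            denominator_px2 = 0, flagged = NA,
                            issues = qc_issue(
                              "NO_TISSUE_IN_BOX",
                              "box contains no tissue; exhaustiveness not applicable",
                              wsi_id = wsi_id, annotation_id = box_id)),
                       class = "exhaustiveness_result"))
    }
    # tissue mask pixels (centres) inside the box that fall in the
    # clipped annotation union
    numer <- 0
    if (length(clipped)) {
      ds <- mask$downsample
      cx <- mask$origin[1L] + (seq_len(ncol(mask$mask)) - 0.5) * ds
      cy <- mask$origin[2L] + (seq_len(nrow(mask$mask)) - 0.5) * ds
      ix <- which(cx >= box[1L] & cx <= box[3L])
      iy <- which(cy >= box[2L] & cy <= box[4L])
      if (length(ix) && length(iy)) {
        grid <- expand.grid(x = cx[ix], y = cy[iy])
        tis <- as.vector(t(mask$mask[iy, ix, drop = FALSE]))
        # t(): expand.grid varies x fastest, mask slice is [y, x]
        grid <- grid[tis, , drop = FALSE]
        if (nrow(grid)) {
          inside <- points_in_pc(grid$x, grid$y, rings_to_pc(clipped))
          numer <- sum(inside) * ds^2
        }
      }
    }
  }
  pct <- max(0, min(100, 100 * numer / denom))
  structure(list(box_id = box_id, percentage = pct,
                 denominator_px2 = denom,
                 flagged = pct < threshold, issues = issues),
            class = "exhaustiveness_result")
}

#' @export
print.exhaustiveness_result <- function(x, ...) {
  cat(sprintf("<exhaustiveness> box %s: %s%% (flagged: %s)\n",
              x$box_id,
              if (is.na(x$percentage)) "NA" else
                sprintf("%.1f", x$percentage),
              x$flagged))
  invisible(x)
}

regions_as_rings <- function(regions) {
  if (inherits(regions, "region_set")) return(regions$rings)
  if (is.matrix(regions)) return(list(regions))
  if (length(regions) && inherits(regions[[1L]], "anno_record")) {
    keep <- vapply(regions, function(r) {
      r$construct %in% c("polygon", "circle")
    }, logical(1L))
    return(lapply(regions[keep], record_ring))
  }
  lapply(regions, as_geometry)
}

#' Diversity of region annotations on a slide
#'
#' The number of distinct region types annotated, between 1 and the
#' number of region labels defined in the dictionary. Bounding boxes
#' (designated annotation areas, not region types) and "unknown" labels do
#' not count.
#'
#' @param records The slide's region-level [anno_record()] list.
#' @param dictionary An [anno_dictionary()].
#' @return Integer count.
#' @export
diversity <- function(records, dictionary) {
  stopifnot(inherits(dictionary, "anno_dictionary"))
  keep <- vapply(records, function(r) {
    r$level == "region" && r$construct != "bounding_box" &&
      !r$feature_name %in% dictionary$unknown_labels
  }, logical(1L))
  length(unique(vapply(records[keep], `[[`, character(1L), "feature_name")))
}
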