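#' Annotation label definition
#'
#' A label is one entry of a project's annotation data dictionary: a named
#' category that annotators may assign, tied to an annotation level
#' (case, region, cell or descriptive). Labels that form an ordered chain
#' (e.g. nuclear pleomorphism grades NP1 < NP2 < NP3) declare an
#' `ordinal_group` and a `ordinal_rank` within it; weighted kappa uses the
#' rank distance. A `merge_parent` names the label this one collapses to in
#' coarsened analyses (e.g. NP1/NP2/NP3 -> tumour cell).
#'
#' @param name Unique label name.
#' @param level One of `"case"`, `"region"`, `"cell"`, `"descriptive"`.
#' @param ordinal_group Optional name of the ordered chain this label
#'   belongs to. Must be given together with `ordinal_rank`.
#' @param ordinal_rank Optional integer position (1-based) within
#'   `ordinal_group`.
#' @param merge_parent Optional name of the label this one merges into.
#' @return An object of class `anno_label`.
#' @seealso [anno_dictionary()]
#' @export
anno_label <- function(name, level,
                       ordinal_group = NULL, ordinal_rank = NULL,
                       merge_parent = NULL) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  level <- match.arg(level, c("case", "region", "cell", "descriptive"))
  if (is.null(ordinal_group) != is.null(ordinal_rank)) {
    stop("ordinal_rank must be present if and only if ordinal_group is",
         call. = FALSE)
  }
  if (!is.null(ordinal_rank)) {
    ordinal_rank <- as.integer(ordinal_rank)
    stopifnot(length(ordinal_rank) == 1L, ordinal_rank >= 1L)
  }
  structure(
    list(name = name, level = level,
         ordinal_group = ordinal_group, ordinal_rank = ordinal_rank,
         merge_parent = merge_parent),
    class = "anno_label"
  )
}

#' Annotation data dictionary
#'
#' The data dictionary is the project's standard reference document: it
#' fixes the set of labels, which geometric constructs each label may use,
#' how many region-level and cell-level bounding boxes each slide requires,
#' how many annotators must cover each slide, display styles, and the
#' exhaustiveness threshold below which a box is flagged. Validation,
#' completeness and the agreement metrics are all driven by it.
#'
#' @param labels List of [anno_label()] objects. Names must be unique, and
#'   ranks within each ordinal group must form a contiguous 1..k sequence.
#' @param allowed_constructs Named list mapping label name to a character
#'   vector drawn from `"bounding_box"`, `"point"`, `"circle"`,
#'   `"polygon"`, `"line"`, `"text"`.
#' @param required_region_boxes,required_cell_boxes Non-negative integers:
#'   bounding boxes of each level required per slide.
#' @param required_annotators Positive integer: annotators required per
#'   slide.
#' @param style Optional named list mapping label name to a display style
#'   list (e.g. `list(colour = "#FF0000", linewidth = 2, linestyle =
#'   "solid")`).
#' @param exhaustiveness_threshold Percentage in \[0, 100\]; boxes whose
#'   annotated-tissue percentage falls below it are flagged.
#' @param unknown_labels Character vector of label names that represent the
#'   "unknown" category; these are excluded from confusion matrices, kappa
#'   and the diversity count by default.
#' @return An object of class `anno_dictionary`.
#' @examples
#' d <- anno_dictionary(
#'   labels = list(
#'     anno_label("tumour", "region"),
#'     anno_label("stroma", "region")
#'   ),
#'   allowed_constructs = list(tumour = "polygon", stroma = "polygon"),
#'   required_region_boxes = 1, required_cell_boxes = 0,
#'   required_annotators = 1
#' )
#' dict_labels(d, level = "region")
#' @export
anno_dictionary <- function(labels,
                            allowed_constructs = list(),
                            required_region_boxes = 0L,
                            required_cell_boxes = 0L,
                            required_annotators = 1L,
                            style = list(),
                            exhaustiveness_threshold = 50,
                            unknown_labels = character()) {
  stopifnot(is.list(labels), length(labels) > 0L)
  ok <- vapply(labels, inherits, logical(1L), "anno_label")
  if (!all(ok)) stop("labels must all be anno_label objects", call. = FALSE)
  nms <- vapply(labels, `[[`, character(1L), "name")
  if (anyDuplicated(nms)) {
    stop("duplicate label names: ",
         paste(unique(nms[duplicated(nms)]), collapse = ", "), call. = FALSE)
  }
  names(labels) <- nms
  ranks_by_group <- split(
    vapply(labels, function(l) l$ordinal_rank %||% NA_integer_, integer(1L)),
    vapply(labels, function(l) l$ordinal_group %||% NA_character_,
           character(1L))
  )
  for (g in names(ranks_by_group)) {
    if (is.na(g)) next
    r <- unname(sort(ranks_by_group[[g]]))
    if (!identical(r, seq_along(r))) {
      stop("ordinal_group '", g, "' ranks must be a contiguous 1..k sequence",
           call. = FALSE)
    }
  }
  for (nm in names(allowed_constructs)) {
    if (!nm %in% nms) {
      stop("allowed_constructs key '", nm, "' is not a dictionary label",
           call. = FALSE)
    }
    bad <- setdiff(allowed_constructs[[nm]], anno_constructs())
    if (length(bad)) {
      stop("unknown construct(s) for '", nm, "': ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
  }
  if (length(style) && !all(names(style) %in% nms)) {
    stop("style keys must be dictionary labels", call. = FALSE)
  }
  required_region_boxes <- as.integer(required_region_boxes)
  required_cell_boxes <- as.integer(required_cell_boxes)
  required_annotators <- as.integer(required_annotators)
  stopifnot(required_region_boxes >= 0L, required_cell_boxes >= 0L,
            required_annotators >= 1L)
  stopifnot(is.numeric(exhaustiveness_threshold),
            exhaustiveness_threshold >= 0, exhaustiveness_threshold <= 100)
  stopifnot(all(unknown_labels %in% nms))
  # check merge parents exist and form no cycle
  parents <- vapply(labels, function(l) l$merge_parent %||% NA_character_,
                    character(1L))
  for (p in parents[!is.na(parents)]) {
    if (!p %in% nms) stop("merge_parent '", p, "' is not a dictionary label",
                          call. = FALSE)
  }
  for (nm in nms) {
    seen <- character()
    cur <- nm
    while (!is.na(parents[[cur]])) {
      if (cur %in% seen) stop("merge_parent cycle involving '", nm, "'",
                              call. = FALSE)
      seen <- c(seen, cur)
      cur <- parents[[cur]]
    }
  }
  structure(
    list(labels = labels,
         allowed_constructs = allowed_constructs,
         required_region_boxes = required_region_boxes,
         required_cell_boxes = required_cell_boxes,
         required_annotators = required_annotators,
         style = style,
         exhaustiveness_threshold = exhaustiveness_threshold,
         unknown_labels = unknown_labels),
    class = "anno_dictionary"
  )
}

#' The six annotation construct kinds
#' @return Character vector of construct names.
#' @keywords internal
anno_constructs <- function() {
  c("bounding_box", "point", "circle", "polygon", "line", "text")
}

#' The four annotation levels
#' @keywords internal
anno_levels <- function() c("case", "region", "cell", "descriptive")

#' Label names of a dictionary, optionally restricted by level
#'
#' Declaration order is preserved; it fixes confusion-matrix ordering.
#'
#' @param dictionary An [anno_dictionary()].
#' @param level Optional level filter.
#' @param drop_unknown Drop labels listed in the dictionary's
#'   `unknown_labels`?
#' @return Character vector of label names.
#' @export
dict_labels <- function(dictionary, level = NULL, drop_unknown = FALSE) {
  stopifnot(inherits(dictionary, "anno_dictionary"))
  labs <- dictionary$labels
  if (!is.null(level)) {
    labs <- labs[vapply(labs, `[[`, character(1L), "level") == level]
  }
  nms <- names(labs)
  if (drop_unknown) nms <- setdiff(nms, dictionary$unknown_labels)
  nms
}

#' @export
print.anno_dictionary <- function(x, ...) {
  lv <- vapply(x$labels, `[[`, character(1L), "level")
  cat("<anno_dictionary>", length(x$labels), "labels (",
      paste(sprintf("%s: %d", names(table(lv)), table(lv)), collapse = ", "),
      ")\n")
  cat("  required per slide:", x$required_region_boxes, "region box(es),",
      x$required_cell_boxes, "cell box(es),",
      x$required_annotators, "annotator(s)\n")
  cat("  exhaustiveness threshold:", x$exhaustiveness_threshold, "%\n")
  invisible(x)
}

#' Read / write a data dictionary as JSON
#'
#' The on-disk form mirrors the dictionary fields one-to-one, with labels
#' as an array of objects.
#'
#' @param path File path.
#' @return `read_dictionary()` returns an [anno_dictionary()];
#'   `write_dictionary()` returns `path` invisibly.
#' @export
read_dictionary <- function(path) {
  x <- jsonlite::read_json(path)
  labels <- lapply(x$labels, function(l) {
    anno_label(l$name, l$level,
               ordinal_group = l$ordinal_group,
               ordinal_rank = l$ordinal_rank,
               merge_parent = l$merge_parent)
  })
  anno_dictionary(
    labels = labels,
    allowed_constructs = lapply(x$allowed_constructs, unlist),
    required_region_boxes = x$required_region_boxes %||% 0L,
    required_cell_boxes = x$required_cell_boxes %||% 0L,
    required_annotators = x$required_annotators %||% 1L,
    style = x$style %||% list(),
    exhaustiveness_threshold = x$exhaustiveness_threshold %||% 50,
    unknown_labels = unlist(x$unknown_labels) %||% character()
  )
}

#' @rdname read_dictionary
#' @param dictionary An [anno_dictionary()].
#' @export
write_dictionary <- function(dictionary, path) {
  stopifnot(inherits(dictionary, "anno_dictionary"))
  out <- unclass(dictionary)
  out$labels <- lapply(unname(dictionary$labels), function(l) {
    l[!vapply(l, is.null, logical(1L))]
  })
  out$allowed_constructs <- lapply(out$allowed_constructs, as.list)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = I(17),
                       pretty = TRUE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
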