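#' Tissue masking
#'
#' Exhaustiveness is defined over tissue, not glass: the denominator for
#' "what percentage of tissue inside the box is annotated" must exclude the
#' near-white slide background. [compute_tissue_mask()] performs the basic
#' segmentation this requires: Otsu thresholding on the HSV saturation
#' channel (background is bright and unsaturated, stained tissue is not),
#' followed by morphological opening, removal of small specks and filling
#' of small holes. Masks are usually computed on a thumbnail; `downsample`
#' records how many base pixels one mask pixel spans along each axis.
#'
#' @param image RGB array `[height, width, 3]` with values in \[0, 1\]
#'   (values in 0..255 are rescaled automatically).
#' @param downsample Base pixels per mask pixel (> 0).
#' @param origin Base-resolution (x, y) of mask pixel (1, 1)'s top-left
#'   corner.
#' @param min_saturation Saturation floor: pixels at or below it are never
#'   tissue, and the Otsu threshold cannot drop below it. Makes uniform
#'   images behave sensibly (all white -> 0% tissue, uniform stain ->
#'   100%).
#' @param min_object_area Connected tissue components smaller than this
#'   (in mask px) are removed.
#' @param max_hole_area Background holes inside tissue smaller than this
#'   (in mask px) are filled.
#' @param open_brush Diameter (mask px) of the opening structuring
#'   element; 0 disables opening.
#' @return An object of class `tissue_mask`: list with `mask` (logical
#'   matrix, `[row = y, col = x]`, `TRUE` = tissue), `downsample`,
#'   `origin`, and attribute `"issues"` carrying a warning when the image
#'   contains no tissue at all.
#' @export
compute_tissue_mask <- function(image, downsample = 32, origin = c(0, 0),
                                min_saturation = 0.05,
                                min_object_area = 16L,
                                max_hole_area = 64L,
                                open_brush = 3L) {
  stopifnot(length(dim(image)) == 3L, dim(image)[3L] >= 3L,
            downsample > 0)
  if (max(image, na.rm = TRUE) > 1) image <- image / 255
  r <- image[, , 1L]; g <- image[, , 2L]; b <- image[, , 3L]
  mx <- pmax(r, g, b)
  mn <- pmin(r, g, b)
  sat <- ifelse(mx > 0, (mx - mn) / mx, 0)
  thr <- min_saturation
  if (diff(range(sat)) > 1e-6) {
    thr <- max(EBImage::otsu(EBImage::Image(t(sat)), range = c(0, 1)),
               min_saturation)
  }
  mask <- sat > thr
  if (any(mask)) {
    img <- EBImage::Image(t(mask) * 1)
    if (open_brush >= 2L) {
      img <- EBImage::opening(img, EBImage::makeBrush(make_odd(open_brush),
                                                      shape = "disc"))
    }
    # drop specks below min_object_area
    lbl <- EBImage::bwlabel(img)
    sizes <- table(lbl[lbl > 0])
    keep <- as.integer(names(sizes)[sizes >= min_object_area])
    img <- EBImage::Image((lbl %in% keep) * 1, dim = dim(lbl))
    # fill holes smaller than max_hole_area
    filled <- EBImage::fillHull(img)
    holes <- filled - img
    hlbl <- EBImage::bwlabel(holes)
    hsizes <- table(hlbl[hlbl > 0])
    small <- as.integer(names(hsizes)[hsizes < max_hole_area])
    img <- img + EBImage::Image((hlbl %in% small) * 1, dim = dim(hlbl))
    mask <- t(EBImage::imageData(img) > 0)
  }
  issues <- no_issues()
  if (!any(mask)) {
    issues <- qc_issue("NO_TISSUE_IN_BOX",
                       "tissue segmentation found no tissue in the image",
                       wsi_id = "")
  }
  structure(list(mask = mask, downsample = as.numeric(downsample),
                 origin = as.numeric(origin), issues = issues),
            class = "tissue_mask")
}

make_odd <- function(n) { n <- as.integer(n); if (n %% 2L == 0L) n + 1L else n }

#' @export
print.tissue_mask <- function(x, ...) {
  cat(sprintf("<tissue_mask> %d x %d at downsample %g, %.1f%% tissue\n",
              ncol(x$mask), nrow(x$mask), x$downsample,
              100 * mean(x$mask)))
  invisible(x)
}

#' Tissue fraction of a mask
#' @param mask A `tissue_mask`.
#' @return Fraction of mask pixels that are tissue, in \[0, 1\].
#' @export
tissue_fraction <- function(mask) mean(mask$mask)

#' Tissue area inside a bounding box
#'
#' Counts tissue mask pixels whose centres fall inside the box and
#' rescales by `downsample^2` to base-resolution px^2.
#'
#' @param mask A `tissue_mask`.
#' @param box Numeric `c(xmin, ymin, xmax, ymax)` in base-resolution px,
#'   or a 2-row corner matrix.
#' @return Tissue area in px^2.
#' @export
tissue_area_in <- function(mask, box) {
  stopifnot(inherits(mask, "tissue_mask"))
  box <- as_box(box)
  ds <- mask$downsample
  h <- nrow(mask$mask); w <- ncol(mask$mask)
  ext_x <- mask$origin[1L] + c(0, w * ds)
  ext_y <- mask$origin[2L] + c(0, h * ds)
  if (box[1L] >= ext_x[2L] || box[3L] <= ext_x[1L] ||
      box[2L] >= ext_y[2L] || box[4L] <= ext_y[1L]) {
    stop("box lies outside the mask extent", call. = FALSE)
  }
  cx <- mask$origin[1L] + (seq_len(w) - 0.5) * ds
  cy <- mask$origin[2L] + (seq_len(h) - 0.5) * ds
  in_x <- cx >= box[1L] & cx <= box[3L]
  in_y <- cy >= box[2L] & cy <= box[4L]
  sum(mask$mask[in_y, in_x, drop = FALSE]) * ds^2
}

as_box <- function(box) {
  if (is.matrix(box)) {
    box <- c(min(box[, 1L]), min(box[, 2L]), max(box[, 1L]), max(box[, 2L]))
  }
  stopifnot(length(box) == 4L, box[3L] > box[1L], box[4L] > box[2L])
  as.numeric(box)
}

#' Read / write a tissue mask
#'
#' Stored as a single-channel PNG (0 = background, 255 = tissue) with a
#' JSON sidecar `<path>.json` holding `downsample` and `origin`. A stored
#' mask supplied through a slide context always overrides on-the-fly
#' computation in the pipeline.
#'
#' @param mask A `tissue_mask`.
#' @param path PNG file path.
#' @return `write_tissue_mask()` returns `path` invisibly;
#'   `read_tissue_mask()` returns a `tissue_mask`.
#' @export
write_tissue_mask <- function(mask, path) {
  stopifnot(inherits(mask, "tissue_mask"))
  png::writePNG(mask$mask * 1, path)
  jsonlite::write_json(list(downsample = mask$downsample,
                            origin = mask$origin),
                       paste0(path, ".json"), auto_unbox = TRUE,
                       digits = I(17))
  invisible(path)
}

#' @rdname write_tissue_mask
#' @export
read_tissue_mask <- function(path) {
  m <- png::readPNG(path)
  if (length(dim(m)) == 3L) m <- m[, , 1L]
  side <- jsonlite::read_json(paste0(path, ".json"))
  structure(list(mask = m > 0.5,
                 downsample = as.numeric(side$downsample),
                 origin = as.numeric(unlist(side$origin)),
                 issues = no_issues()),
            class = "tissue_mask")
}

#' A synthetic all-tissue mask covering a slide
#'
#' Convenience for tests and for the fallback when only the box-area
#' denominator is wanted explicitly.
#'
#' @param width_px,height_px Slide dimensions (base px).
#' @param downsample Mask scale.
#' @return A `tissue_mask` that is tissue everywhere.
#' @export
full_tissue_mask <- function(width_px, height_px, downsample = 32) {
  structure(list(mask = matrix(TRUE,
                               nrow = ceiling(height_px / downsample),
                               ncol = ceiling(width_px / downsample)),
                 downsample = as.numeric(downsample),
                 origin = c(0, 0), issues = no_issues()),
            class = "tissue_mask")
}
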