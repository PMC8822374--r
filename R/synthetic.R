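#' Built-in breast annotation dictionary
#'
#' The dictionary used by the simulator, modelled on a breast-cancer
#' annotation protocol: designated region- and cell-level bounding boxes;
#' region types tumour, stroma, tumour-associated stroma, normal
#' epithelial, TILs and unknown; cell types for tumour nuclei graded by
#' nuclear pleomorphism (NP1 < NP2 < NP3, an ordinal chain merging to
#' "tumour cell"), TILs, stromal and epithelial cells, and an unknown
#' category. Defaults require 2 region boxes, 1 cell box and 2 annotators
#' per slide, with a 50% exhaustiveness threshold.
#'
#' @param required_region_boxes,required_cell_boxes,required_annotators
#'   Per-slide completeness requirements.
#' @param exhaustiveness_threshold Flagging threshold in percent.
#' @return An [anno_dictionary()].
#' @export
breast_dictionary <- function(required_region_boxes = 2L,
                              required_cell_boxes = 1L,
                              required_annotators = 2L,
                              exhaustiveness_threshold = 50) {
  np <- function(k) {
    anno_label(paste0("tumour NP", k), "cell",
               ordinal_group = "nuclear-pleomorphism", ordinal_rank = k,
               merge_parent = "tumour cell")
  }
  labels <- list(
    anno_label("case grade", "case"),
    anno_label("region box", "region"),
    anno_label("cell box", "cell"),
    anno_label("tumour", "region"),
    anno_label("stroma", "region"),
    anno_label("tumour-associated stroma", "region"),
    anno_label("normal epithelial", "region"),
    anno_label("TILs region", "region"),
    anno_label("unknown region", "region"),
    np(1L), np(2L), np(3L),
    anno_label("tumour cell", "cell"),
    anno_label("TILs", "cell"),
    anno_label("stroma cell", "cell"),
    anno_label("epithelial cell", "cell"),
    anno_label("unknown cell", "cell")
  )
  region_labels <- c("tumour", "stroma", "tumour-associated stroma",
                     "normal epithelial", "TILs region", "unknown region")
  cell_labels <- c("tumour NP1", "tumour NP2", "tumour NP3", "tumour cell",
                   "TILs", "stroma cell", "epithelial cell", "unknown cell")
  allowed <- c(
    list("case grade" = "text",
         "region box" = "bounding_box",
         "cell box" = "bounding_box"),
    stats::setNames(rep(list(c("polygon", "circle")),
                        length(region_labels)), region_labels),
    stats::setNames(rep(list(c("point", "circle")),
                        length(cell_labels)), cell_labels)
  )
  pal <- c("#e41a1c", "#377eb8", "#4daf4a", "#984ea3", "#ff7f00",
           "#999999")
  style <- stats::setNames(
    lapply(seq_along(region_labels), function(i) {
      list(colour = pal[i], linewidth = 2, linestyle = "solid")
    }), region_labels)
  anno_dictionary(labels, allowed_constructs = allowed,
                  required_region_boxes = required_region_boxes,
                  required_cell_boxes = required_cell_boxes,
                  required_annotators = required_annotators,
                  style = style,
                  exhaustiveness_threshold = exhaustiveness_threshold,
                  unknown_labels = c("unknown region", "unknown cell"))
}

#' Default cell-label prevalence for the simulator
#'
#' Tumour-nucleus grades dominate, with TILs and stromal cells as the
#' main minority classes, loosely matching the composition of exhaustive
#' breast H&E cell annotation.
#'
#' @return Named probability vector over the breast dictionary cell
#'   labels (excluding the merged parent and unknown).
#' @export
default_prevalence <- function() {
  c("tumour NP1" = 0.25, "tumour NP2" = 0.25, "tumour NP3" = 0.10,
    "TILs" = 0.20, "stroma cell" = 0.15, "epithelial cell" = 0.05)
}

#' Behaviour profile of a simulated annotator
#'
#' @param miss_rate Probability a true cell (or region) is omitted.
#' @param spurious_rate Expected spurious cells per true cell.
#' @param confusion_kernel Row-stochastic matrix: row = true label,
#'   column = reported label. `NULL` means the identity (perfect
#'   labelling).
#' @param position_jitter_sigma Isotropic Gaussian jitter (px) applied to
#'   reported cell positions.
#' @param boundary_jitter_sigma Gaussian jitter (px) applied to region
#'   polygon vertices (resampled until the ring stays simple).
#' @param seed Integer seed making this annotator's randomness
#'   reproducible.
#' @return Object of class `annotator_profile`.
#' @export
annotator_profile <- function(miss_rate = 0, spurious_rate = 0,
                              confusion_kernel = NULL,
                              position_jitter_sigma = 0,
                              boundary_jitter_sigma = 0,
                              seed = 1L) {
  stopifnot(miss_rate >= 0, miss_rate <= 1, spurious_rate >= 0,
            position_jitter_sigma >= 0, boundary_jitter_sigma >= 0)
  if (!is.null(confusion_kernel)) {
    stopifnot(is.matrix(confusion_kernel),
              !is.null(rownames(confusion_kernel)),
              !is.null(colnames(confusion_kernel)),
              all(abs(rowSums(confusion_kernel) - 1) < 1e-8),
              all(confusion_kernel >= 0))
  }
  structure(list(miss_rate = miss_rate, spurious_rate = spurious_rate,
                 confusion_kernel = confusion_kernel,
                 position_jitter_sigma = position_jitter_sigma,
                 boundary_jitter_sigma = boundary_jitter_sigma,
                 seed = as.integer(seed)),
            class = "annotator_profile")
}

#' An adjacent-grade confusion kernel over the NP chain
#'
#' Each NP grade is reported as an adjacent grade with probability
#' `adjacent` (split evenly when both neighbours exist); all other labels
#' are reported correctly.
#'
#' @param labels Label universe (kernel dimnames).
#' @param adjacent Total probability mass moved to adjacent NP grades.
#' @return Row-stochastic matrix.
#' @export
np_confusion_kernel <- function(labels = names(default_prevalence()),
                                adjacent = 0.1) {
  k <- diag(length(labels))
  dimnames(k) <- list(labels, labels)
  np <- intersect(paste0("tumour NP", 1:3), labels)
  for (i in seq_along(np)) {
    nb <- np[c(i - 1L, i + 1L)]
    nb <- nb[!is.na(nb)]
    k[np[i], np[i]] <- 1 - adjacent
    k[np[i], nb] <- adjacent / length(nb)
  }
  k
}

#' Generate a ground-truth slide
#'
#' Lays out non-overlapping region- and cell-level bounding boxes on a
#' synthetic slide, fills region boxes with simple (star-shaped, hence
#' never self-intersecting) polygons, and fills cell boxes with labelled
#' cell points placed with a minimum pairwise separation (default twice
#' the matching radius, so truth matched against itself is unambiguous
#' and perfect). A matching data dictionary is attached.
#'
#' @param slide_id Identifier for the synthetic slide.
#' @param width_px,height_px Slide size in base px.
#' @param mpp Microns per pixel.
#' @param n_region_boxes,n_cell_boxes Number of designated boxes.
#' @param cells_per_box Cell points per cell box.
#' @param regions_per_box Region polygons per region box.
#' @param prevalence Named probability vector over cell labels.
#' @param min_separation Minimum pairwise cell distance in px; `NULL`
#'   gives twice the slide's default matching radius. Set 0 for a
#'   "crowded" mode that stresses the optimal matcher.
#' @param seed Integer seed.
#' @return Object of class `ground_truth`: list with `slide`
#'   ([slide_context()]), `records` (truth annotations by annotator
#'   `"truth"`), `dictionary`, `label_prevalence`, `boxes` (list of box
#'   records).
#' @export
generate_ground_truth <- function(slide_id = "synthetic-slide-1",
                                  width_px = 4096, height_px = 4096,
                                  mpp = 0.25,
                                  n_region_boxes = 2L, n_cell_boxes = 1L,
                                  cells_per_box = 100L,
                                  regions_per_box = 3L,
                                  prevalence = default_prevalence(),
                                  min_separation = NULL,
                                  seed = 1L) {
  stopifnot(abs(sum(prevalence) - 1) < 1e-8)
  set.seed(seed)
  slide <- slide_context(slide_id, mpp, width_px, height_px)
  if (is.null(min_separation)) {
    min_separation <- 2 * default_radius_px(slide)
  }
  dictionary <- breast_dictionary(required_region_boxes = n_region_boxes,
                                  required_cell_boxes = n_cell_boxes)
  region_labels <- setdiff(dict_labels(dictionary, "region",
                                       drop_unknown = TRUE), "region box")
  nid <- local({ i <- 0L
    function() { i <<- i + 1L; sprintf("%s-T-%05d", slide_id, i) } })
  ts <- "2026-01-01T00:00:00Z"
  records <- list()
  boxes <- list()
  # tile the slide into a grid of candidate box slots
  n_boxes <- n_region_boxes + n_cell_boxes
  ncols <- ceiling(sqrt(n_boxes))
  nrows <- ceiling(n_boxes / ncols)
  bw <- floor(width_px / ncols)
  bh <- floor(height_px / nrows)
  margin <- 0.05
  slot <- 0L
  add_box <- function(level, label) {
    slot <<- slot + 1L
    cx <- (slot - 1L) %% ncols
    cy <- (slot - 1L) %/% ncols
    box <- c(cx * bw + margin * bw, cy * bh + margin * bh,
             (cx + 1) * bw - margin * bw, (cy + 1) * bh - margin * bh)
    rec <- anno_record(nid(), slide_id, "truth", "H&E", level,
                       "bounding_box", label,
                       geometry = rbind(box[1:2], box[3:4]),
                       created_at = ts)
    records[[length(records) + 1L]] <<- rec
    boxes[[length(boxes) + 1L]] <<- rec
    box
  }
  for (b in seq_len(n_region_boxes)) {
    box <- add_box("region", "region box")
    # exhaustive-style truth: wobbly vertical strips tiling the box
    for (ring in strip_polygons(box, regions_per_box)) {
      records[[length(records) + 1L]] <-
        anno_record(nid(), slide_id, "truth", "H&E", "region", "polygon",
                    sample(region_labels, 1L), geometry = ring,
                    created_at = ts)
    }
  }
  for (b in seq_len(n_cell_boxes)) {
    box <- add_box("cell", "cell box")
    pts <- poisson_disc(box, cells_per_box, min_separation)
    labs <- sample(names(prevalence), nrow(pts), replace = TRUE,
                   prob = prevalence)
    for (i in seq_len(nrow(pts))) {
      records[[length(records) + 1L]] <-
        anno_record(nid(), slide_id, "truth", "H&E", "cell", "point",
                    labs[i], geometry = pts[i, , drop = FALSE],
                    created_at = ts)
    }
  }
  structure(list(slide = slide, records = records,
                 dictionary = dictionary, label_prevalence = prevalence,
                 boxes = boxes),
            class = "ground_truth")
}

# star-shaped simple polygon: sorted angles + positive radii
star_polygon <- function(centre, r_mean, n_vertices = 10L) {
  th <- sort(stats::runif(n_vertices, 0, 2 * pi))
  r <- r_mean * stats::runif(n_vertices, 0.6, 1.4)
  cbind(x = centre[1L] + r * cos(th), y = centre[2L] + r * sin(th))
}

# k simple polygons tiling a box: vertical strips whose shared
# boundaries wobble in x but never cross (jitter < half strip width)
strip_polygons <- function(box, k, n_y = 6L) {
  w <- box[3L] - box[1L]
  xs <- box[1L] + w * (0:k) / k
  ys <- seq(box[2L], box[4L], length.out = n_y)
  jitter_amp <- 0.2 * w / k
  bounds <- lapply(seq_along(xs), function(j) {
    x <- rep(xs[j], n_y)
    if (j > 1L && j < length(xs)) {
      x <- x + stats::runif(n_y, -jitter_amp, jitter_amp)
    }
    cbind(x = x, y = ys)
  })
  lapply(seq_len(k), function(i) {
    rbind(bounds[[i]], bounds[[i + 1L]][n_y:1L, , drop = FALSE])
  })
}

# dart-throwing with a minimum pairwise separation
poisson_disc <- function(box, n, min_sep, max_tries = 200L) {
  pts <- matrix(numeric(), ncol = 2L)
  if (n == 0L) return(pts)
  for (i in seq_len(n)) {
    placed <- FALSE
    for (t in seq_len(max_tries)) {
      cand <- c(stats::runif(1, box[1L], box[3L]),
                stats::runif(1, box[2L], box[4L]))
      if (nrow(pts) == 0L || min_sep <= 0 ||
          min((pts[, 1L] - cand[1L])^2 + (pts[, 2L] - cand[2L])^2) >=
            min_sep^2) {
        pts <- rbind(pts, cand)
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      stop("cell density infeasible at min_separation = ", min_sep,
           call. = FALSE)
    }
  }
  dimnames(pts) <- list(NULL, c("x", "y"))
  pts
}

#' Simulate an annotator from ground truth
#'
#' Each true cell is independently dropped with probability `miss_rate`;
#' otherwise it is reported with a label drawn from the profile's
#' confusion kernel row and a position jittered by isotropic Gaussian
#' noise. Spurious cells (labels drawn from the truth prevalence,
#' positions uniform in the cell boxes) are added with expected count
#' `spurious_rate * n_true`. Regions are dropped with `miss_rate` and
#' their vertices jittered, resampling any ring that becomes
#' self-intersecting. Bounding boxes and case records are copied
#' unchanged. Reproducible for a fixed profile seed.
#'
#' @param truth A [generate_ground_truth()] result.
#' @param profile An [annotator_profile()].
#' @param annotator_id Id given to the simulated annotator.
#' @return List of [anno_record()] objects.
#' @export
simulate_annotator <- function(truth, profile, annotator_id = "sim-A") {
  stopifnot(inherits(truth, "ground_truth"),
            inherits(profile, "annotator_profile"))
  set.seed(profile$seed)
  nid <- local({ i <- 0L; sid <- truth$slide$slide_id
    function() { i <<- i + 1L; sprintf("%s-%s-%05d", sid, annotator_id, i) } })
  ts <- "2026-01-02T00:00:00Z"
  kernel <- profile$confusion_kernel
  out <- list()
  n_true_cells <- 0L
  for (rec in truth$records) {
    if (rec$construct == "bounding_box" || rec$level %in%
        c("case", "descriptive")) {
      rec$annotation_id <- nid()
      rec$annotator_id <- annotator_id
      rec$created_at <- ts
      out[[length(out) + 1L]] <- rec
      next
    }
    if (stats::runif(1) < profile$miss_rate) next
    if (rec$level == "cell") {
      n_true_cells <- n_true_cells + 1L
      lab <- rec$feature_name
      if (!is.null(kernel) && lab %in% rownames(kernel)) {
        lab <- sample(colnames(kernel), 1L, prob = kernel[lab, ])
      }
      g <- rec$geometry
      if (profile$position_jitter_sigma > 0) {
        g <- g + stats::rnorm(2L, 0, profile$position_jitter_sigma)
        g <- pmax(g, 0)
      }
      out[[length(out) + 1L]] <-
        anno_record(nid(), rec$slide_id, annotator_id, rec$stain_type,
                    "cell", rec$construct, lab, geometry = g,
                    radius = rec$radius, created_at = ts)
    } else {
      g <- rec$geometry
      if (profile$boundary_jitter_sigma > 0) {
        for (try in 1:50) {
          gj <- g + matrix(stats::rnorm(length(g), 0,
                                        profile$boundary_jitter_sigma),
                           ncol = 2L)
          gj <- pmax(gj, 0)
          if (!ring_self_intersects(gj)) { g <- gj; break }
        }
      }
      out[[length(out) + 1L]] <-
        anno_record(nid(), rec$slide_id, annotator_id, rec$stain_type,
                    rec$level, rec$construct, rec$feature_name,
                    geometry = g, radius = rec$radius, created_at = ts)
    }
  }
  # spurious cells: uniform in the cell boxes, labels from prevalence
  n_true_cells <- sum(vapply(truth$records, function(r) {
    r$level == "cell" && r$construct != "bounding_box"
  }, logical(1L)))
  if (profile$spurious_rate > 0 && n_true_cells > 0L) {
    cell_boxes <- Filter(function(b) b$level == "cell", truth$boxes)
    n_spur <- stats::rpois(1L, profile$spurious_rate * n_true_cells)
    if (n_spur > 0L && length(cell_boxes)) {
      for (i in seq_len(n_spur)) {
        box <- as_box(record_ring(
          cell_boxes[[sample.int(length(cell_boxes), 1L)]]))
        pt <- c(stats::runif(1, box[1L], box[3L]),
                stats::runif(1, box[2L], box[4L]))
        lab <- sample(names(truth$label_prevalence), 1L,
                      prob = truth$label_prevalence)
        out[[length(out) + 1L]] <-
          anno_record(nid(), truth$slide$slide_id, annotator_id, "H&E",
                      "cell", "point", lab,
                      geometry = matrix(pt, ncol = 2L), created_at = ts)
      }
    }
  }
  out
}

#' Closed-form expected kappa for two simulated annotators
#'
#' Under the simulator's model — annotators conditionally independent
#' given the true label — the joint label distribution over matched cells
#' is `p(i, j) = sum_t pi_t A[t, i] B[t, j]`. The expected unweighted
#' kappa is `(p_o - p_e) / (1 - p_e)` with `p_o` the diagonal mass and
#' `p_e` the product of marginals; the weighted variants apply the same
#' ordinal weight matrix as [cohens_kappa()].
#'
#' @param kernel_a,kernel_b Row-stochastic confusion kernels with matching
#'   dimnames.
#' @param prevalence Named distribution over true labels (kernel rows).
#' @param weighting,dictionary As in [cohens_kappa()].
#' @return Expected kappa (scalar); `NA` if chance agreement is
#'   degenerate.
#' @export
analytic_expected_kappa <- function(kernel_a, kernel_b, prevalence,
                                    weighting = "none",
                                    dictionary = NULL) {
  stopifnot(identical(rownames(kernel_a), rownames(kernel_b)),
            all(names(prevalence) %in% rownames(kernel_a)),
            abs(sum(prevalence) - 1) < 1e-8)
  labs <- colnames(kernel_a)
  joint <- matrix(0, length(labs), length(labs),
                  dimnames = list(labs, labs))
  for (t in names(prevalence)) {
    joint <- joint + prevalence[[t]] *
      outer(kernel_a[t, ], kernel_b[t, ])
  }
  w <- kappa_weights(labs, weighting, dictionary)
  e <- outer(rowSums(joint), colSums(joint))
  swe <- sum(w * e)
  if (swe == 0) return(NA_real_)
  1 - sum(w * joint) / swe
}

#' Closed-form expected agree/disagree/missed breakdown
#'
#' For two simulated annotators with miss rates `miss_a`, `miss_b`,
#' spurious rates `spur_a`, `spur_b` and confusion kernels, conditionally
#' independent given truth and with jitter well below the matching
#' radius: a true cell is seen by both with probability
#' `(1 - miss_a)(1 - miss_b)` (matched), by exactly one with probability
#' `miss_b (1 - miss_a) + miss_a (1 - miss_b)` (missed), by neither with
#' `miss_a * miss_b` (absent from the comparison). Spurious cells are
#' additional missed singletons. Matched pairs agree with probability
#' `sum_t pi_t sum_i A[t,i] B[t,i]`.
#'
#' @param miss_a,miss_b Miss rates.
#' @param kernel_a,kernel_b Confusion kernels (`NULL` = identity).
#' @param prevalence Truth label distribution.
#' @param spur_a,spur_b Spurious rates (per true cell).
#' @return List with `agreed_pct`, `disagreed_pct`, `missed_pct`.
#' @export
expected_breakdown <- function(miss_a = 0, miss_b = 0,
                               kernel_a = NULL, kernel_b = NULL,
                               prevalence = default_prevalence(),
                               spur_a = 0, spur_b = 0) {
  p_both <- (1 - miss_a) * (1 - miss_b)
  p_one <- miss_b * (1 - miss_a) + miss_a * (1 - miss_b)
  # per true cell; spurious cells add unmatched singletons
  denom <- p_both + p_one + spur_a + spur_b
  p_agree_given_match <- if (is.null(kernel_a) && is.null(kernel_b)) {
    1
  } else {
    labs <- names(prevalence)
    ka <- kernel_a %||% { k <- diag(length(labs))
                          dimnames(k) <- list(labs, labs); k }
    kb <- kernel_b %||% { k <- diag(length(labs))
                          dimnames(k) <- list(labs, labs); k }
    sum(vapply(labs, function(t) {
      prevalence[[t]] * sum(ka[t, ] * kb[t, colnames(ka)])
    }, numeric(1L)))
  }
  list(agreed_pct = 100 * p_both * p_agree_given_match / denom,
       disagreed_pct = 100 * p_both * (1 - p_agree_given_match) / denom,
       missed_pct = 100 * (p_one + spur_a + spur_b) / denom)
}

#' Write a complete simulated project to disk
#'
#' Emits a dictionary JSON, one annotation file per simulated annotator
#' per slide, and a slide-context JSON, in the package's standard
#' formats — a self-contained project directory for pipeline runs.
#'
#' @param out_dir Output directory (created if needed).
#' @param n_slides Number of slides.
#' @param profiles List of [annotator_profile()]s (one file per profile
#'   per slide); default two annotators with mild disagreement.
#' @param seed Integer base seed; slide and annotator seeds are derived
#'   from it.
#' @param ... Passed to [generate_ground_truth()].
#' @return Invisibly, a list with `dictionary_path`, `slides`
#'   (contexts), `annotation_paths`.
#' @export
simulate_project <- function(out_dir, n_slides = 3L, profiles = NULL,
                             seed = 1L, ...) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(profiles)) {
    profiles <- list(
      A = annotator_profile(miss_rate = 0.1, position_jitter_sigma = 2),
      B = annotator_profile(miss_rate = 0.2,
                            confusion_kernel = np_confusion_kernel(),
                            position_jitter_sigma = 2)
    )
  }
  if (is.null(names(profiles))) {
    names(profiles) <- paste0("annot-", seq_along(profiles))
  }
  slides <- list()
  paths <- character()
  dict_path <- file.path(out_dir, "dictionary.json")
  for (s in seq_len(n_slides)) {
    truth <- generate_ground_truth(
      slide_id = sprintf("slide-%03d", s),
      seed = seed * 1000L + s, ...)
    if (s == 1L) write_dictionary(truth$dictionary, dict_path)
    slides[[truth$slide$slide_id]] <- truth$slide
    for (k in seq_along(profiles)) {
      prof <- profiles[[k]]
      prof$seed <- seed * 1000L + s * 10L + k
      recs <- simulate_annotator(truth, prof,
                                 annotator_id = names(profiles)[k])
      p <- file.path(out_dir, sprintf("%s_%s.json",
                                      truth$slide$slide_id,
                                      names(profiles)[k]))
      save_annotations(recs, p)
      paths <- c(paths, p)
    }
  }
  ctx_path <- file.path(out_dir, "slides.json")
  jsonlite::write_json(lapply(slides, unclass), ctx_path,
                       auto_unbox = TRUE, digits = I(17))
  invisible(list(dictionary_path = dict_path, slides = slides,
                 annotation_paths = paths, slide_context_path = ctx_path))
}
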