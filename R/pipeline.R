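#' Run the automatic annotation QC pipeline
#'
#' Orchestrates, in order: load annotation files, validate against the
#' data dictionary, completeness, exhaustiveness per designated box,
#' diversity, per-label counts and areas, and pairwise inter-annotator
#' agreement, producing a QC report with an issue log. A stage failure on
#' one slide is logged as an issue and does not abort the other slides.
#'
#' @param annotation_paths Character vector of annotation JSON files (or
#'   a list of pre-loaded record lists).
#' @param dictionary An [anno_dictionary()] or path to a dictionary JSON.
#' @param slides Named list of [slide_context()]s (names = slide ids), or
#'   path to a slide-context JSON as written by [simulate_project()].
#' @param config List of options: `radius_um` (default 3), `kappa_weighting`
#'   (`"linear"`), `exhaustiveness_threshold` (dictionary's),
#'   `reproducible` (logical; pins all timestamps), `timestamp` (the
#'   pinned ISO 8601 value), `tissue_masks` (named list of
#'   [compute_tissue_mask()] objects per slide id).
#' @return Object of class `qc_report`: list with `project_id`,
#'   `generated_at`, `per_slide` (data.frame), `per_box` (exhaustiveness
#'   data.frame), `label_stats` (counts/areas per label), `per_pair`
#'   (list), `summary`, `issues`.
#' @export
run_qc <- function(annotation_paths, dictionary, slides = list(),
                   config = list()) {
  if (is.character(dictionary)) dictionary <- read_dictionary(dictionary)
  stopifnot(inherits(dictionary, "anno_dictionary"))
  if (is.character(slides)) slides <- read_slide_contexts(slides)
  cfg <- utils::modifyList(
    list(project_id = "project", radius_um = 3.0,
         kappa_weighting = "linear",
         reproducible = FALSE, timestamp = NULL, tissue_masks = list()),
    config)
  now <- if (isTRUE(cfg$reproducible)) {
    cfg$timestamp %||% "1970-01-01T00:00:00Z"
  } else {
    format_utc(Sys.time())
  }
  issues <- no_issues()
  records <- list()
  if (length(annotation_paths) && is.character(annotation_paths)) {
    for (p in annotation_paths) {
      recs <- load_annotations(p)
      li <- attr(recs, "issues")
      if (nrow(li)) { li$logged_date <- now; issues <- rbind(issues, li) }
      records <- c(records, recs)
    }
  } else {
    records <- do.call(c, c(list(list()), annotation_paths))
  }
  if (!length(records)) {
    issues <- rbind(issues, qc_issue("EMPTY_PROJECT",
                                     "no annotation records in project",
                                     wsi_id = "", logged_date = now))
  }
  vi <- validate_annotations(records, dictionary, logged_date = now)
  issues <- rbind(issues, vi)
  sids <- vapply(records, `[[`, character(1L), "slide_id")
  per_slide <- list()
  per_box <- list()
  label_stats <- list()
  per_pair <- list()
  for (sid in unique(sids)) {
    res <- tryCatch(
      qc_one_slide(records[sids == sid], dictionary,
                   slides[[sid]], cfg, now),
      error = function(e) {
        issues <<- rbind(issues, qc_issue(
          "STAGE_FAILURE", paste0("slide stage failed: ",
                                  conditionMessage(e)),
          wsi_id = sid, logged_date = now))
        NULL
      })
    if (is.null(res)) next
    per_slide[[sid]] <- res$slide_row
    per_box[[sid]] <- res$box_rows
    label_stats[[sid]] <- res$label_rows
    per_pair <- c(per_pair, res$pairs)
    issues <- rbind(issues, res$issues)
  }
  summary <- if (length(per_pair)) {
    aggregate_pairs(per_pair, weighting = cfg$kappa_weighting,
                    dictionary = dictionary)
  } else NULL
  structure(list(project_id = cfg$project_id, generated_at = now,
                 per_slide = bind_rows_safe(per_slide),
                 per_box = bind_rows_safe(per_box),
                 label_stats = bind_rows_safe(label_stats),
                 per_pair = per_pair, summary = summary, issues = issues),
            class = "qc_report")
}

bind_rows_safe <- function(lst) {
  lst <- lst[!vapply(lst, function(x) is.null(x) || nrow(x) == 0L,
                     logical(1L))]
  if (!length(lst)) return(data.frame())
  out <- do.call(rbind, lst)
  rownames(out) <- NULL
  out
}

read_slide_contexts <- function(path) {
  x <- jsonlite::read_json(path)
  out <- lapply(x, function(s) {
    tmp <- s$tissue_mask_path
    if (!is.character(tmp) || !length(tmp)) tmp <- NULL
    slide_context(s$slide_id, s$microns_per_pixel, s$width_px,
                  s$height_px, tmp)
  })
  stats::setNames(out, vapply(out, `[[`, character(1L), "slide_id"))
}

qc_one_slide <- function(records, dictionary, slide, cfg, now) {
  sid <- records[[1L]]$slide_id
  issues <- no_issues()
  comp <- completeness(records, dictionary)
  if (!comp$complete) {
    issues <- rbind(issues, qc_issue(
      "INCOMPLETE",
      paste0("unmet requirements: ",
             paste(sprintf("%s %d/%d", comp$deficits$requirement,
                           comp$deficits$observed, comp$deficits$expected),
                   collapse = "; ")),
      wsi_id = sid, logged_date = now))
  }
  lv <- vapply(records, `[[`, character(1L), "level")
  con <- vapply(records, `[[`, character(1L), "construct")
  region_boxes <- records[lv == "region" & con == "bounding_box"]
  # annotators duplicate the designated boxes; keep one per geometry
  if (length(region_boxes) > 1L) {
    keys <- vapply(region_boxes, function(b) {
      paste(as_box(record_ring(b)), collapse = ",")
    }, character(1L))
    region_boxes <- region_boxes[!duplicated(keys)]
  }
  region_polys <- records[lv == "region" & con %in% c("polygon", "circle")]
  mask <- cfg$tissue_masks[[sid]]
  if (is.null(mask) && !is.null(slide) &&
      is.character(slide$tissue_mask_path) &&
      file.exists(slide$tissue_mask_path)) {
    mask <- read_tissue_mask(slide$tissue_mask_path)
  }
  box_rows <- list()
  for (bx in region_boxes) {
    ex <- exhaustiveness(bx, region_polys, mask = mask,
                         dictionary = dictionary)
    li <- ex$issues
    if (nrow(li)) { li$logged_date <- now; issues <- rbind(issues, li) }
    if (isTRUE(ex$flagged)) {
      issues <- rbind(issues, qc_issue(
        "LOW_EXHAUSTIVENESS",
        sprintf("box %s exhaustiveness %.1f%% below threshold %g%%",
                ex$box_id, ex$percentage,
                dictionary$exhaustiveness_threshold),
        wsi_id = sid, annotation_id = ex$box_id, logged_date = now))
    }
    box_rows[[length(box_rows) + 1L]] <-
      data.frame(slide_id = sid, box_id = ex$box_id,
                 exhaustiveness_pct = ex$percentage,
                 denominator_px2 = ex$denominator_px2,
                 flagged = isTRUE(ex$flagged), stringsAsFactors = FALSE)
  }
  div <- diversity(records, dictionary)
  # per-label counts and areas (px^2, mm^2) for prioritisation
  mpp <- if (!is.null(slide)) slide$microns_per_pixel else NA_real_
  region_labels <- vapply(region_polys, `[[`, character(1L),
                          "feature_name")
  label_rows <- lapply(unique(region_labels), function(lb) {
    rings <- lapply(region_polys[region_labels == lb], record_ring)
    a <- union_area(rings)
    data.frame(slide_id = sid, label = lb,
               n = sum(region_labels == lb), area_px2 = a,
               area_mm2 = if (is.na(mpp)) NA_real_ else px2_to_mm2(a, mpp),
               stringsAsFactors = FALSE)
  })
  cell_counts <- records[lv == "cell" & con %in% c("point", "circle")]
  cell_labels <- vapply(cell_counts, `[[`, character(1L), "feature_name")
  label_rows <- c(label_rows, lapply(unique(cell_labels), function(lb) {
    data.frame(slide_id = sid, label = lb,
               n = sum(cell_labels == lb), area_px2 = NA_real_,
               area_mm2 = NA_real_, stringsAsFactors = FALSE)
  }))
  # pairwise agreement over all unordered annotator pairs
  annos <- vapply(records, `[[`, character(1L), "annotator_id")
  ids <- sort(unique(annos))
  pairs <- list()
  radius_px <- if (!is.null(slide)) {
    default_radius_px(slide, cfg$radius_um)
  } else {
    cfg$radius_um / 0.25
  }
  if (length(ids) >= 2L) {
    for (i in seq_len(length(ids) - 1L)) for (j in (i + 1L):length(ids)) {
      ra <- records[annos == ids[i]]
      rb <- records[annos == ids[j]]
      pr <- pair_cell_agreement(ra, rb, dictionary,
                                slide %||% slide_context(sid, 0.25, 1, 1),
                                radius_px = radius_px,
                                weighting = cfg$kappa_weighting)
      pr$jsi <- if (!is.null(slide)) {
        region_agreement(ra, rb, dictionary, slide)
      } else NULL
      pr$slide_id <- sid
      pr$pair <- paste(ids[i], ids[j], sep = "~")
      pairs[[paste(sid, pr$pair)]] <- pr
    }
  }
  slide_row <- data.frame(
    slide_id = sid, complete = comp$complete,
    n_deficits = nrow(comp$deficits), diversity = div,
    n_records = length(records),
    n_annotators = length(ids),
    mean_exhaustiveness_pct = if (length(box_rows)) {
      mean(vapply(box_rows, function(r) r$exhaustiveness_pct, numeric(1L)),
           na.rm = TRUE)
    } else NA_real_,
    stringsAsFactors = FALSE)
  list(slide_row = slide_row, box_rows = bind_rows_safe(box_rows),
       label_rows = bind_rows_safe(label_rows), pairs = pairs,
       issues = issues)
}

#' @export
print.qc_report <- function(x, ...) {
  cat("<qc_report>", x$project_id, "generated", x$generated_at, "\n")
  cat("  slides:", nrow(x$per_slide), " pairs:", length(x$per_pair),
      " issues:", nrow(x$issues),
      sprintf("(%d errors)", sum(x$issues$severity == "error")), "\n")
  if (!is.null(x$summary)) {
    cat(sprintf(
      "  mean agreed %.1f%% | disagreed %.1f%% | missed %.1f%% | pooled kappa %.3f\n",
      x$summary$mean_agreed_pct, x$summary$mean_disagreed_pct,
      x$summary$mean_missed_pct, x$summary$pooled_kappa))
  }
  invisible(x)
}

#' Write a QC report to a directory
#'
#' Emits `qc_report.json` (full report; re-readable with
#' [read_qc_report()]), `per_slide_metrics.csv`, `label_counts_areas.csv`,
#' `region_jsi.csv`, one `cell_confusion_<pair>.csv` per annotator pair,
#' and `issues.csv`.
#'
#' @param report A [run_qc()] result.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_report <- function(report, out_dir) {
  stopifnot(inherits(report, "qc_report"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  emit_csv <- function(df, name) {
    p <- file.path(out_dir, name)
    utils::write.csv(df, p, row.names = FALSE)
    paths <<- c(paths, p)
  }
  emit_csv(report$per_slide, "per_slide_metrics.csv")
  emit_csv(report$label_stats, "label_counts_areas.csv")
  jsi <- bind_rows_safe(lapply(report$per_pair, function(p) {
    if (is.null(p$jsi) || !nrow(p$jsi)) return(NULL)
    cbind(slide_id = p$slide_id, pair = p$pair, p$jsi)
  }))
  emit_csv(jsi, "region_jsi.csv")
  for (p in report$per_pair) {
    nm <- sprintf("cell_confusion_%s_%s.csv",
                  gsub("[^A-Za-z0-9._-]", "_", p$slide_id),
                  gsub("[^A-Za-z0-9._-]", "_", p$pair))
    pth <- file.path(out_dir, nm)
    utils::write.csv(as.data.frame(unclass(p$confusion)), pth)
    paths <- c(paths, pth)
  }
  emit_csv(report$issues, "issues.csv")
  jp <- file.path(out_dir, "qc_report.json")
  jsonlite::write_json(report_to_json(report), jp, auto_unbox = TRUE,
                       digits = I(17), null = "null", na = "null")
  paths <- c(paths, jp)
  invisible(paths)
}

report_to_json <- function(report) {
  list(project_id = report$project_id,
       generated_at = report$generated_at,
       per_slide = report$per_slide,
       per_box = report$per_box,
       label_stats = report$label_stats,
       per_pair = lapply(unname(report$per_pair), function(p) {
         list(slide_id = p$slide_id, pair = p$pair,
              breakdown = unclass(p$breakdown),
              kappa = p$kappa,
              confusion = list(labels = rownames(p$confusion),
                               counts = unclass(p$confusion)),
              jsi = p$jsi)
       }),
       summary = if (!is.null(report$summary)) {
         s <- report$summary
         list(mean_agreed_pct = s$mean_agreed_pct,
              mean_disagreed_pct = s$mean_disagreed_pct,
              mean_missed_pct = s$mean_missed_pct,
              n_pairs = s$n_pairs,
              pooled_kappa = s$pooled_kappa,
              pooled_confusion = list(
                labels = rownames(s$pooled_confusion),
                counts = unclass(s$pooled_confusion)),
              mean_jsi_by_label = s$mean_jsi_by_label)
       },
       issues = report$issues)
}

#' Read back a written QC report
#'
#' @param path Path to a `qc_report.json` written by [write_report()].
#' @return The parsed report (lists/data.frames mirroring the report
#'   fields).
#' @export
read_qc_report <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
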