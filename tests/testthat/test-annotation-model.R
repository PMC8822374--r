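test_that("dictionary invariants are enforced", {
  expect_error(anno_label("x", "cell", ordinal_group = "g"),
               "ordinal_rank")
  expect_error(
    anno_dictionary(list(anno_label("a", "cell", "g", 1L),
                         anno_label("b", "cell", "g", 3L))),
    "contiguous")
  expect_error(
    anno_dictionary(list(anno_label("a", "cell")),
                    allowed_constructs = list(zz = "point")),
    "not a dictionary label")
  expect_error(
    anno_dictionary(list(anno_label("a", "cell")),
                    exhaustiveness_threshold = 101),
    "exhaustiveness_threshold")
  expect_error(
    anno_dictionary(list(anno_label("a", "cell", merge_parent = "b"),
                         anno_label("b", "cell", merge_parent = "a"))),
    "cycle")
})

test_that("dictionary JSON round-trips", {
  d <- breast_dictionary()
  p <- withr::local_tempfile(fileext = ".json")
  write_dictionary(d, p)
  d2 <- read_dictionary(p)
  expect_equal(unclass(d2), unclass(d))
})

test_that("structural invariants reject malformed records", {
  expect_error(anno_record("i", "s", "a", "H&E", "cell", "point", "x",
                           geometry = rbind(c(0, 0), c(1, 1))),
               "exactly 1")
  expect_error(anno_record("i", "s", "a", "H&E", "region", "polygon", "x",
                           geometry = rbind(c(0, 0), c(1, 1))),
               "at least 3")
  # bow-tie: self-intersecting
  expect_error(anno_record("i", "s", "a", "H&E", "region", "polygon", "x",
                           geometry = rbind(c(0, 0), c(2, 2), c(2, 0),
                                            c(0, 2))),
               "self-intersecting")
  expect_error(anno_record("i", "s", "a", "H&E", "cell", "circle", "x",
                           geometry = matrix(c(1, 1), ncol = 2)),
               "radius")
  expect_error(anno_record("i", "s", "a", "H&E", "cell", "point", "x",
                           geometry = matrix(c(-1, 1), ncol = 2)),
               "non-negative")
  expect_error(anno_record("i", "s", "a", "H&E", "region", "bounding_box",
                           "x", geometry = rbind(c(1, 1), c(1, 5))),
               "positive extent")
  expect_error(anno_record("i", "s", "a", "H&E", "cell", "blob", "x",
                           geometry = matrix(c(1, 1), ncol = 2)),
               "unknown construct")
})

test_that("annotation JSON round-trips field-for-field", {
  gt <- generate_ground_truth(cells_per_box = 25L, seed = 101L)
  p <- withr::local_tempfile(fileext = ".json")
  save_annotations(gt$records, p)
  back <- load_annotations(p)
  expect_equal(nrow(attr(back, "issues")), 0L)
  expect_identical(lapply(unname(back), unclass),
                   lapply(gt$records, unclass))
  # empty collection round-trips to an empty valid file
  save_annotations(list(), p)
  empty <- load_annotations(p)
  expect_length(empty, 0L)
  expect_equal(nrow(attr(empty, "issues")), 0L)
})

test_that("a large simulated record set round-trips exactly", {
  set.seed(5)
  gt <- generate_ground_truth(cells_per_box = 400L, n_cell_boxes = 2L,
                              seed = 9L)
  recs <- c(gt$records,
            simulate_annotator(gt, annotator_profile(
              miss_rate = 0.2, position_jitter_sigma = 2,
              confusion_kernel = np_confusion_kernel(), seed = 2L), "B"))
  expect_gt(length(recs), 1000L)
  p <- withr::local_tempfile(fileext = ".json")
  save_annotations(recs, p)
  back <- load_annotations(p)
  expect_identical(lapply(unname(back), unclass), lapply(recs, unclass))
})

test_that("malformed records yield per-record issues, not silent drops", {
  p <- withr::local_tempfile(fileext = ".json")
  doc <- list(
    schema_version = "1.0", slide_id = "s1",
    annotations = list(
      list(annotation_id = "ok1", slide_id = "s1", annotator_id = "A",
           stain_type = "H&E", level = "region", construct = "polygon",
           feature_name = "tumour",
           geometry = list(c(0, 0), c(10, 0), c(10, 10)),
           created_at = "2026-01-01T00:00:00Z"),
      list(annotation_id = "bad1", slide_id = "s1", annotator_id = "A",
           stain_type = "H&E", level = "region", construct = "polygon",
           feature_name = "tumour", geometry = list(c(0, 0), c(1, 1)),
           created_at = "2026-01-01T00:00:00Z"),
      list(annotation_id = "bad2", slide_id = "s1", annotator_id = "A",
           stain_type = "H&E", level = "cell", construct = "squiggle",
           feature_name = "TILs", geometry = list(c(1, 1)),
           created_at = "2026-01-01T00:00:00Z")
    ))
  jsonlite::write_json(doc, p, auto_unbox = TRUE)
  recs <- load_annotations(p)
  issues <- attr(recs, "issues")
  expect_length(recs, 1L)
  expect_equal(recs[[1]]$annotation_id, "ok1")
  expect_setequal(issues$rule_id, c("GEOMETRY_ARITY", "UNKNOWN_CONSTRUCT"))
  expect_true(all(issues$severity == "error"))
  expect_true(all(nzchar(issues$wsi_id)))
  expect_error(load_annotations(tempfile()), "not found")
})

test_that("dictionary validation flags every conformance violation", {
  d <- breast_dictionary()
  sl <- slide_context("s1", 0.25, 1000, 1000)
  ok <- make_polygon_record("r1", unit_square(0, 0, 10), "tumour")
  expect_equal(nrow(validate_annotations(list(ok), d, sl)), 0L)

  unknown <- make_polygon_record("r2", unit_square(), "mystery tissue")
  iss <- validate_annotations(list(unknown), d)
  expect_equal(iss$rule_id, "UNKNOWN_LABEL")

  wrong_construct <- make_point_record("r3", c(5, 5), "tumour")
  wrong_construct$level <- "region"
  iss <- validate_annotations(list(wrong_construct), d)
  expect_equal(iss$rule_id, "CONSTRUCT_NOT_ALLOWED")

  wrong_level <- make_point_record("r4", c(5, 5), "TILs")
  wrong_level$level <- "region"
  iss <- validate_annotations(list(wrong_level), d)
  expect_true("LEVEL_MISMATCH" %in% iss$rule_id)

  outside <- make_point_record("r5", c(5000, 5), "TILs")
  iss <- validate_annotations(list(outside), d, sl)
  expect_equal(iss$rule_id, "OUT_OF_BOUNDS")

  # validation is pure
  before <- lapply(list(ok, unknown), unclass)
  validate_annotations(list(ok, unknown), d, sl)
  expect_identical(lapply(list(ok, unknown), unclass), before)
})

test_that("duplicate ids are flagged for every sharing record", {
  d <- breast_dictionary()
  recs <- list(make_point_record("dup", c(1, 1), "TILs"),
               make_point_record("dup", c(9, 9), "TILs"),
               make_point_record("uniq", c(5, 5), "TILs"))
  iss <- validate_annotations(recs, d)
  dup_iss <- iss[iss$rule_id == "DUPLICATE_ID", ]
  # brute-force duplicate scan oracle
  ids <- vapply(recs, `[[`, character(1), "annotation_id")
  expected_n <- sum(ids %in% ids[duplicated(ids)])
  expect_equal(nrow(dup_iss), expected_n)
  expect_true(all(dup_iss$annotation_id == "dup"))
})

test_that("merge_labels coarsens NP grades and is idempotent", {
  d <- breast_dictionary()
  recs <- list(make_point_record("1", c(1, 1), "tumour NP1"),
               make_point_record("2", c(5, 5), "tumour NP2"),
               make_point_record("3", c(9, 9), "tumour NP3"),
               make_point_record("4", c(3, 3), "TILs"))
  merged <- merge_labels(recs, d)
  labs <- vapply(merged, `[[`, character(1), "feature_name")
  expect_equal(labs, c("tumour cell", "tumour cell", "tumour cell",
                       "TILs"))
  expect_length(merged, length(recs))
  expect_identical(lapply(merge_labels(merged, d), unclass),
                   lapply(merged, unclass))
  # no merge parents -> identity
  d2 <- anno_dictionary(list(anno_label("TILs", "cell")))
  recs2 <- list(make_point_record("1", c(1, 1), "TILs"))
  expect_identical(lapply(merge_labels(recs2, d2), unclass),
                   lapply(recs2, unclass))
})

test_that("GeoJSON export closes rings and round-trips", {
  gt <- generate_ground_truth(cells_per_box = 20L, seed = 77L)
  p <- withr::local_tempfile(fileext = ".geojson")
  export_geojson(gt$records, p, gt$dictionary)
  doc <- jsonlite::read_json(p)
  expect_equal(doc$type, "FeatureCollection")
  polys <- Filter(function(f) {
    !is.null(f$geometry) && identical(f$geometry$type, "Polygon")
  }, doc$features)
  for (f in polys) {
    ring <- f$geometry$coordinates[[1]]
    expect_identical(ring[[1]], ring[[length(ring)]])
  }
  pts <- Filter(function(f) {
    !is.null(f$geometry) && identical(f$geometry$type, "Point")
  }, doc$features)
  expect_true(all(vapply(pts, function(f) {
    nzchar(f$properties$feature_name)
  }, logical(1))))
  back <- import_geojson(p)
  expect_identical(lapply(back, unclass), lapply(gt$records, unclass))
})

test_that("a 500-record simulated set round-trips through GeoJSON", {
  gt <- generate_ground_truth(cells_per_box = 250L, n_cell_boxes = 2L,
                              seed = 13L)
  expect_gte(length(gt$records), 500L)
  p <- withr::local_tempfile(fileext = ".geojson")
  export_geojson(gt$records, p)
  expect_identical(lapply(import_geojson(p), unclass),
                   lapply(gt$records, unclass))
})
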