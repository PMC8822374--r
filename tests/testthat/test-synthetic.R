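test_that("ground truth generation is deterministic in the seed", {
  g1 <- generate_ground_truth(cells_per_box = 30L, seed = 42L)
  g2 <- generate_ground_truth(cells_per_box = 30L, seed = 42L)
  expect_identical(lapply(g1$records, unclass), lapply(g2$records, unclass))
  g3 <- generate_ground_truth(cells_per_box = 30L, seed = 43L)
  expect_false(identical(lapply(g1$records, unclass),
                         lapply(g3$records, unclass)))
})

test_that("cell labels follow the requested prevalence", {
  prev <- c("TILs" = 0.5, "stroma cell" = 0.5)
  gt <- generate_ground_truth(cells_per_box = 200L, prevalence = prev,
                              seed = 7L)
  labs <- vapply(Filter(function(r) r$level == "cell" &&
                          r$construct == "point", gt$records),
                 `[[`, character(1), "feature_name")
  expect_length(labs, 200L)
  n_til <- sum(labs == "TILs")
  # within 3 sigma of Binomial(200, 0.5)
  expect_lt(abs(n_til - 100), 3 * sqrt(200 * 0.25))
})

test_that("truth matched against itself is perfect", {
  gt <- generate_ground_truth(cells_per_box = 80L, seed = 3L)
  cells <- Filter(function(r) r$level == "cell" &&
                    r$construct == "point", gt$records)
  pts <- do.call(rbind, lapply(cells, `[[`, "geometry"))
  labs <- vapply(cells, `[[`, character(1), "feature_name")
  m <- match_points(pts, pts, default_radius_px(gt$slide))
  bd <- cell_agreement(m, labs, labs)
  expect_equal(bd$agreed_pct, 100)
  expect_equal(nrow(m$pairs), nrow(pts))
  expect_equal(m$pairs$distance, rep(0, nrow(pts)))
})

test_that("cells respect the minimum separation and infeasible density errors", {
  gt <- generate_ground_truth(cells_per_box = 60L, seed = 5L)
  cells <- Filter(function(r) r$level == "cell" &&
                    r$construct == "point", gt$records)
  pts <- do.call(rbind, lapply(cells, `[[`, "geometry"))
  dmat <- as.matrix(dist(pts))
  diag(dmat) <- Inf
  expect_gte(min(dmat), 2 * default_radius_px(gt$slide))
  expect_error(
    generate_ground_truth(width_px = 256, height_px = 256,
                          n_region_boxes = 0L,
                          cells_per_box = 500L, min_separation = 24,
                          seed = 1L),
    "infeasible")
})

test_that("the identity profile reproduces truth up to ids", {
  gt <- generate_ground_truth(cells_per_box = 40L, seed = 11L)
  sim <- simulate_annotator(gt, annotator_profile(seed = 4L), "A")
  expect_length(sim, length(gt$records))
  strip <- function(r) {
    r$annotation_id <- r$annotator_id <- r$created_at <- NULL
    unclass(r)
  }
  expect_identical(lapply(sim, strip), lapply(gt$records, strip))
})

test_that("miss rate drops the binomially expected number of cells", {
  gt <- generate_ground_truth(cells_per_box = 500L, n_cell_boxes = 2L,
                              n_region_boxes = 0L, seed = 21L)
  n_true <- sum(vapply(gt$records, function(r) {
    r$level == "cell" && r$construct == "point"
  }, logical(1)))
  sim <- simulate_annotator(gt, annotator_profile(miss_rate = 0.3,
                                                  seed = 6L), "B")
  n_sim <- sum(vapply(sim, function(r) {
    r$level == "cell" && r$construct == "point"
  }, logical(1)))
  dropped <- n_true - n_sim
  expect_lt(abs(dropped - 0.3 * n_true), 3 * sqrt(n_true * 0.3 * 0.7))
})

test_that("small jitter with identity kernel gives zero disagreement", {
  gt <- generate_ground_truth(cells_per_box = 100L, seed = 31L)
  r <- default_radius_px(gt$slide)
  sim <- simulate_annotator(gt, annotator_profile(
    position_jitter_sigma = r / 10, seed = 8L), "A")
  pr <- pair_cell_agreement(gt$records, sim, gt$dictionary, gt$slide)
  expect_equal(pr$breakdown$disagreed_pct, 0)
  expect_equal(pr$breakdown$agreed_pct, 100)
})

test_that("analytic_expected_kappa closed form behaves at the poles", {
  prev <- c(a = 0.3, b = 0.5, c = 0.2)
  id <- diag(3); dimnames(id) <- list(names(prev), names(prev))
  expect_equal(analytic_expected_kappa(id, id, prev), 1)
  # labels independent of truth: every row equals the prevalence
  rand <- matrix(rep(prev, each = 3), 3, byrow = FALSE)
  rand <- matrix(rep(prev, times = 3), 3, byrow = TRUE)
  dimnames(rand) <- list(names(prev), names(prev))
  expect_equal(analytic_expected_kappa(rand, rand, prev), 0,
               tolerance = 1e-12)
})

test_that("analytic kappa matches Monte-Carlo simulation of the model", {
  prev <- default_prevalence()
  ker <- np_confusion_kernel(adjacent = 0.1)
  expected <- analytic_expected_kappa(ker, ker, prev)
  set.seed(1234)
  n <- 2e5
  truth <- sample(names(prev), n, replace = TRUE, prob = prev)
  draw <- function(t) {
    vapply(t, function(x) sample(colnames(ker), 1, prob = ker[x, ]),
           character(1))
  }
  # vectorised draw per truth label for speed
  la <- character(n); lb <- character(n)
  for (t in names(prev)) {
    idx <- which(truth == t)
    la[idx] <- sample(colnames(ker), length(idx), replace = TRUE,
                      prob = ker[t, ])
    lb[idx] <- sample(colnames(ker), length(idx), replace = TRUE,
                      prob = ker[t, ])
  }
  labs <- colnames(ker)
  cm <- table(factor(la, labs), factor(lb, labs))
  emp <- cohens_kappa(unclass(matrix(as.integer(cm), nrow = length(labs),
                                     dimnames = list(labs, labs))))
  expect_lt(abs(emp - expected), 0.01)
})

test_that("expected_breakdown matches direct probability accounting", {
  # A = truth, B missing 30%: missed fraction is 30%
  eb <- expected_breakdown(miss_a = 0, miss_b = 0.3)
  expect_equal(eb$missed_pct, 30)
  expect_equal(eb$agreed_pct, 70)
  # both miss 20%: N excludes cells neither saw
  eb2 <- expected_breakdown(miss_a = 0.2, miss_b = 0.2)
  p_both <- 0.8 * 0.8; p_one <- 2 * 0.2 * 0.8
  expect_equal(eb2$missed_pct, 100 * p_one / (p_both + p_one))
  # kernels reduce agreement among matched pairs only
  ker <- np_confusion_kernel(adjacent = 0.1)
  eb3 <- expected_breakdown(miss_a = 0, miss_b = 0, kernel_a = ker,
                            kernel_b = ker)
  expect_equal(eb3$missed_pct, 0)
  expect_equal(eb3$agreed_pct + eb3$disagreed_pct, 100)
  expect_lt(eb3$agreed_pct, 100)
})

test_that("simulate_project writes a loadable self-consistent project", {
  td <- withr::local_tempdir()
  res <- simulate_project(td, n_slides = 2L, seed = 5L,
                          cells_per_box = 20L)
  expect_true(file.exists(res$dictionary_path))
  expect_length(res$annotation_paths, 4L)  # 2 slides x 2 annotators
  d <- read_dictionary(res$dictionary_path)
  for (p in res$annotation_paths) {
    recs <- load_annotations(p, d)
    expect_gt(length(recs), 0L)
    expect_equal(nrow(attr(recs, "issues")), 0L)
  }
})
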