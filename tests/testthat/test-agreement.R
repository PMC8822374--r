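test_that("default matching radius encodes 3 um at any resolution", {
  expect_equal(default_radius_px(slide_context("s", 0.25, 10, 10)), 12)
  expect_equal(default_radius_px(0.5), 6)
  expect_equal(default_radius_px(1.0), 3)
  expect_error(default_radius_px(0), "mpp")
})

test_that("match_points handles the canonical small cases", {
  m <- match_points(rbind(c(0, 0)), rbind(c(1, 0)), 12)
  expect_equal(nrow(m$pairs), 1L)
  expect_equal(m$pairs$distance, 1)

  m2 <- match_points(rbind(c(0, 0)), rbind(c(20, 0)), 12)
  expect_equal(nrow(m2$pairs), 0L)
  expect_equal(m2$unmatched_a, 1L)
  expect_equal(m2$unmatched_b, 1L)

  # global optimum beats the greedy pairing (total 8 vs 10)
  m3 <- match_points(rbind(c(0, 0), c(5, 0)), rbind(c(4, 0), c(9, 0)), 12)
  expect_equal(nrow(m3$pairs), 2L)
  expect_equal(sum(m3$pairs$distance), 8)
  expect_equal(m3$pairs$b[m3$pairs$a == 1], 1L)
  expect_equal(m3$pairs$b[m3$pairs$a == 2], 2L)

  # empty inputs
  m4 <- match_points(matrix(numeric(), ncol = 2), rbind(c(0, 0)), 5)
  expect_equal(nrow(m4$pairs), 0L)
  expect_equal(m4$unmatched_b, 1L)
})

test_that("match_points equals brute-force enumeration on random instances", {
  set.seed(99)
  for (i in 1:120) {
    n <- sample(0:6, 1); m <- sample(0:6, 1)
    pa <- matrix(runif(2 * n, 0, 20), ncol = 2)
    pb <- matrix(runif(2 * m, 0, 20), ncol = 2)
    radius <- runif(1, 2, 10)
    got <- match_points(pa, pb, radius)
    if (n == 0 || m == 0) {
      expect_equal(nrow(got$pairs), 0L)
      next
    }
    best <- brute_force_match(pa, pb, radius)
    expect_equal(nrow(got$pairs), best$k)
    expect_equal(sum(got$pairs$distance), best$dist, tolerance = 1e-9)
    # symmetry under A <-> B swap
    rev <- match_points(pb, pa, radius)
    expect_equal(nrow(rev$pairs), nrow(got$pairs))
    expect_equal(sum(rev$pairs$distance), sum(got$pairs$distance),
                 tolerance = 1e-9)
    expect_setequal(rev$unmatched_a, got$unmatched_b)
    expect_setequal(rev$unmatched_b, got$unmatched_a)
  }
})

test_that("matched pairs never exceed the radius and indices are unique", {
  set.seed(17)
  pa <- matrix(runif(100, 0, 30), ncol = 2)
  pb <- matrix(runif(120, 0, 30), ncol = 2)
  m <- match_points(pa, pb, 4)
  expect_true(all(m$pairs$distance <= 4))
  expect_false(anyDuplicated(m$pairs$a) > 0)
  expect_false(anyDuplicated(m$pairs$b) > 0)
  expect_setequal(c(m$pairs$a, m$unmatched_a), seq_len(nrow(pa)))
  expect_setequal(c(m$pairs$b, m$unmatched_b), seq_len(nrow(pb)))
})

test_that("cell_agreement computes the agreed/disagreed/missed split", {
  pa <- rbind(c(0, 0), c(10, 0), c(20, 0))
  pb <- rbind(c(1, 0), c(11, 0), c(21, 0))
  m <- match_points(pa, pb, 5)
  all_same <- cell_agreement(m, c("x", "y", "z"), c("x", "y", "z"))
  expect_equal(all_same$agreed_pct, 100)
  expect_equal(all_same$disagreed_pct, 0)
  expect_equal(all_same$missed_pct, 0)

  none <- match_points(pa, pb + 100, 5)
  all_missed <- cell_agreement(none, c("x", "y", "z"), c("x", "y", "z"))
  expect_equal(all_missed$missed_pct, 100)

  # 6 agree + 2 disagree + 2 missed -> 60/20/20
  pa2 <- cbind(seq(0, 90, by = 10), 0)           # 10 points
  pb2 <- cbind(seq(0, 70, by = 10) + 1, 0)       # first 8 match
  m2 <- match_points(pa2, pb2, 5)
  la <- c(rep("x", 6), "y", "y", "x", "x")
  lb <- c(rep("x", 6), "z", "z")
  bd <- cell_agreement(m2, la, lb)
  expect_equal(bd$agreed_pct, 60)
  expect_equal(bd$disagreed_pct, 20)
  expect_equal(bd$missed_pct, 20)
  expect_equal(bd$agreed_pct + bd$disagreed_pct + bd$missed_pct, 100)

  na_bd <- cell_agreement(match_points(NULL, NULL, 5),
                          character(), character())
  expect_true(is.na(na_bd$agreed_pct))
  expect_equal(na_bd$n, 0L)
})

test_that("confusion matrix uses dictionary order and excludes unknown", {
  d <- breast_dictionary()
  la <- c("tumour NP1", "tumour NP1", "tumour NP2", "unknown cell")
  lb <- c("tumour NP1", "tumour NP2", "tumour NP2", "TILs")
  cm <- confusion_matrix(la, lb, d)
  expect_equal(sum(cm), 3L)  # unknown pair excluded
  expect_equal(cm["tumour NP1", "tumour NP1"], 1L)
  expect_equal(cm["tumour NP1", "tumour NP2"], 1L)
  expect_equal(cm["tumour NP2", "tumour NP2"], 1L)
  # NP chain contiguous and in declaration order
  labs <- rownames(cm)
  np_pos <- match(paste0("tumour NP", 1:3), labs)
  expect_equal(np_pos, min(np_pos):(min(np_pos) + 2))

  cm_u <- confusion_matrix(la, lb, d, include_unknown = TRUE)
  expect_equal(sum(cm_u), 4L)
  expect_error(confusion_matrix(c("nope"), c("TILs"), d),
               "not in dictionary")
})

test_that("confusion over matched pairs counts only matches", {
  d <- toy_cell_dictionary()
  pa <- cbind(seq(0, 40, by = 10), 0)
  pb <- cbind(c(1, 11, 21, 100, 200), 0)
  m <- match_points(pa, pb, 5)
  la <- rep("tumour NP1", 5)
  lb <- rep("tumour NP2", 5)
  cm <- confusion_matrix(la, lb, d, matching = m)
  expect_equal(sum(cm), nrow(m$pairs))
  expect_equal(cm["tumour NP1", "tumour NP2"], 3L)
})

test_that("cohens_kappa matches hand computations and invariants", {
  cm <- matrix(c(10, 5, 5, 10), 2,
               dimnames = list(c("x", "y"), c("x", "y")))
  expect_equal(cohens_kappa(cm), 1 / 3)
  diag3 <- diag(c(5, 5, 5))
  dimnames(diag3) <- list(letters[1:3], letters[1:3])
  expect_equal(cohens_kappa(diag3), 1)
  # scale invariance
  expect_equal(cohens_kappa(cm * 7), cohens_kappa(cm))
  # empty and degenerate matrices are not applicable
  expect_true(is.na(cohens_kappa(matrix(0, 2, 2))))
  one_cell <- matrix(c(10, 0, 0, 0), 2,
                     dimnames = list(c("x", "y"), c("x", "y")))
  expect_true(is.na(cohens_kappa(one_cell)))  # p_e = 1
})

test_that("kappa matches an independent direct-formula implementation", {
  d <- toy_cell_dictionary()
  labs <- dict_labels(d, "cell")
  set.seed(31)
  for (i in 1:200) {
    k <- sample(2:5, 1)
    use <- labs[seq_len(k)]
    cm <- matrix(rpois(k * k, 4), k, dimnames = list(use, use))
    for (wt in c("none", "linear", "quadratic")) {
      expect_lt(abs(cohens_kappa(cm, wt, d) - textbook_kappa(cm, wt, d)),
                1e-12)
    }
  }
})

test_that("linear-weighted kappa equals unweighted for 2 classes", {
  d <- toy_cell_dictionary()
  set.seed(8)
  for (i in 1:20) {
    use <- c("tumour NP1", "tumour NP2")
    cm <- matrix(rpois(4, 6) + 1, 2, dimnames = list(use, use))
    expect_equal(cohens_kappa(cm, "linear", d), cohens_kappa(cm, "none"),
                 tolerance = 1e-12)
  }
})

test_that("region_agreement reports per-label JSI and areas", {
  d <- breast_dictionary()
  sl <- slide_context("s1", 0.25, 10000, 10000)
  sq <- unit_square(0, 0, 1000)
  a <- list(make_polygon_record("a1", sq, "tumour", "A"),
            make_polygon_record("a2", unit_square(2000, 0, 1000),
                                "stroma", "A"))
  b <- list(make_polygon_record("b1", sq, "tumour", "B"))
  tab <- region_agreement(a, b, d, sl)
  trow <- tab[tab$label == "tumour", ]
  expect_equal(trow$jsi, 1)
  expect_equal(trow$union_area_mm2, px2_to_mm2(1e6, 0.25))
  expect_false(trow$one_sided)
  srow <- tab[tab$label == "stroma", ]
  expect_equal(srow$jsi, 0)
  expect_true(srow$one_sided)

  # half-overlapping unit squares -> 1/3 with union 1.5 px^2
  a2 <- list(make_polygon_record("a1", unit_square(), "tumour", "A"))
  b2 <- list(make_polygon_record("b1", unit_square(0.5, 0), "tumour",
                                 "B"))
  tab2 <- region_agreement(a2, b2, d, sl)
  expect_equal(tab2$jsi, 1 / 3)
  expect_equal(tab2$union_area_mm2, px2_to_mm2(1.5, 0.25))
})

test_that("aggregate_pairs averages breakdowns and pools confusion", {
  d <- toy_cell_dictionary()
  mk_pair <- function(missed, cm_counts) {
    cm <- matrix(cm_counts, 2,
                 dimnames = list(c("tumour NP1", "tumour NP2"),
                                 c("tumour NP1", "tumour NP2")))
    list(breakdown = structure(
           list(agreed_pct = 100 - missed, disagreed_pct = 0,
                missed_pct = missed, n = 100L),
           class = "agreement_breakdown"),
         confusion = structure(cm, class = c("confusion_matrix",
                                             "matrix")))
  }
  p1 <- mk_pair(30, c(20, 5, 5, 20))
  p2 <- mk_pair(38, c(10, 2, 3, 12))
  agg <- aggregate_pairs(list(p1, p2), weighting = "none")
  expect_equal(agg$mean_missed_pct, 34)
  expect_equal(unclass(agg$pooled_confusion),
               unclass(p1$confusion) + unclass(p2$confusion),
               ignore_attr = TRUE)
  # pooled kappa equals kappa of the summed matrix
  expect_equal(agg$pooled_kappa,
               cohens_kappa(unclass(p1$confusion) +
                              unclass(p2$confusion)))
  # single pair: summary equals that pair
  agg1 <- aggregate_pairs(list(p1), weighting = "none")
  expect_equal(agg1$mean_missed_pct, 30)
  expect_equal(agg1$pooled_kappa, cohens_kappa(p1$confusion))
})
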