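#' Default cell-matching radius for a slide
#'
#' Two pathologists' point annotations are taken to mark the same cell
#' when they lie within a fixed physical distance: 12 pixels at 0.25
#' micrometre-per-pixel resolution, i.e. 3.0 micrometres. Expressing the
#' criterion in micrometres makes it invariant to scan resolution.
#'
#' @param slide A [slide_context()], or a numeric microns-per-pixel value.
#' @param radius_um Physical matching radius in micrometres.
#' @return Radius in this slide's base pixels.
#' @examples
#' default_radius_px(slide_context("s", 0.25, 100, 100))  # 12
#' @export
default_radius_px <- function(slide, radius_um = 3.0) {
  mpp <- if (inherits(slide, "slide_context")) slide$microns_per_pixel
         else as.numeric(slide)
  if (!is.finite(mpp) || mpp <= 0) stop("mpp must be > 0", call. = FALSE)
  radius_um / mpp
}

#' Optimally match two annotators' cell points within a radius
#'
#' Finds the one-to-one correspondence between two point sets in which
#' only pairs within `radius_px` are eligible, the number of matched
#' pairs is maximal, and among all maximum-cardinality matchings the total
#' matched distance is minimal (a minimum-cost assignment, solved exactly
#' per connected component of the within-radius graph). Global optimality
#' makes the matching deterministic and symmetric in A and B, unlike
#' greedy nearest-neighbour pairing.
#'
#' @param points_a,points_b Numeric matrices (columns x, y) of cell
#'   centres.
#' @param radius_px Positive matching radius in pixels.
#' @return Object of class `cell_matching`: list with `pairs` (data.frame
#'   `a`, `b`, `distance` — row indices into the inputs), `unmatched_a`,
#'   `unmatched_b` (index vectors) and `radius_px`.
#' @export
match_points <- function(points_a, points_b, radius_px) {
  stopifnot(is.numeric(radius_px), radius_px > 0)
  pa <- as_points(points_a)
  pb <- as_points(points_b)
  n <- nrow(pa); m <- nrow(pb)
  empty <- list(pairs = data.frame(a = integer(), b = integer(),
                                   distance = numeric()),
                unmatched_a = seq_len(n), unmatched_b = seq_len(m),
                radius_px = radius_px)
  if (n == 0L || m == 0L) return(structure(empty, class = "cell_matching"))
  d <- sqrt(outer(pa[, 1L], pb[, 1L], "-")^2 +
            outer(pa[, 2L], pb[, 2L], "-")^2)
  feasible <- d <= radius_px
  # decompose into connected components of the feasibility graph so the
  # assignment solver only sees small dense blocks
  comp <- bipartite_components(feasible)
  pairs <- list()
  for (cc in comp) {
    ai <- cc$a; bi <- cc$b
    if (!length(ai) || !length(bi)) next
    sub <- solve_component(d[ai, bi, drop = FALSE],
                           feasible[ai, bi, drop = FALSE], radius_px)
    if (nrow(sub)) {
      pairs[[length(pairs) + 1L]] <-
        data.frame(a = ai[sub$a], b = bi[sub$b], distance = sub$distance)
    }
  }
  pairs <- if (length(pairs)) do.call(rbind, pairs)
           else empty$pairs
  pairs <- pairs[order(pairs$a), , drop = FALSE]
  rownames(pairs) <- NULL
  structure(list(pairs = pairs,
                 unmatched_a = setdiff(seq_len(n), pairs$a),
                 unmatched_b = setdiff(seq_len(m), pairs$b),
                 radius_px = radius_px),
            class = "cell_matching")
}

as_points <- function(p) {
  if (is.null(p) || !length(p)) {
    return(matrix(numeric(), ncol = 2L, dimnames = list(NULL, c("x", "y"))))
  }
  as_geometry(p)
}

# connected components of the bipartite feasibility graph via union-find
bipartite_components <- function(feasible) {
  n <- nrow(feasible); m <- ncol(feasible)
  parent <- seq_len(n + m)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  idx <- which(feasible, arr.ind = TRUE)
  for (k in seq_len(nrow(idx))) {
    ra <- find(idx[k, 1L])
    rb <- find(n + idx[k, 2L])
    if (ra != rb) parent[rb] <- ra
  }
  roots_a <- vapply(seq_len(n), find, integer(1L))
  roots_b <- vapply(n + seq_len(m), find, integer(1L))
  comps <- unique(c(roots_a, roots_b))
  lapply(comps, function(r) {
    list(a = which(roots_a == r), b = which(roots_b == r))
  })
}

# exact min-cost max-cardinality assignment on one component.
# Dummy columns (one per row, cost U) absorb unmatched rows; U exceeds
# any achievable total matched distance, so cardinality dominates cost.
solve_component <- function(d, feasible, radius_px) {
  n <- nrow(d); m <- ncol(d)
  if (n == 1L && m == 1L) {
    if (feasible[1L, 1L]) {
      return(data.frame(a = 1L, b = 1L, distance = d[1L, 1L]))
    }
    return(data.frame(a = integer(), b = integer(), distance = numeric()))
  }
  U <- (min(n, m) + 1) * radius_px + 1
  big <- 4 * U * (n + m + 1)
  cost <- matrix(big, n, m + n)
  cost[, seq_len(m)][feasible] <- d[feasible]
  cost[cbind(seq_len(n), m + seq_len(n))] <- U
  sol <- as.integer(clue::solve_LSAP(cost))
  keep <- sol <= m
  keep[keep] <- feasible[cbind(which(keep), sol[keep])]
  data.frame(a = which(keep), b = sol[keep],
             distance = d[cbind(which(keep), sol[keep])])
}

#' @export
print.cell_matching <- function(x, ...) {
  cat(sprintf("<cell_matching> %d pairs (radius %.2f px), %d/%d unmatched\n",
              nrow(x$pairs), x$radius_px,
              length(x$unmatched_a), length(x$unmatched_b)))
  invisible(x)
}

#' Agree / disagree / missed breakdown for matched cells
#'
#' Over the N distinct cells seen by either annotator (matched pairs count
#' once), the percentage that were matched with the same label (agreed),
#' matched with different labels (disagreed), and seen by only one
#' annotator (missed).
#'
#' @param matching A [match_points()] result.
#' @param labels_a,labels_b Character vectors of cell labels aligned with
#'   the point lists given to [match_points()].
#' @return Object of class `agreement_breakdown`: `agreed_pct`,
#'   `disagreed_pct`, `missed_pct` (summing to 100), `n_matched`,
#'   `n_agreed`, `n_disagreed`, `n_missed_by_a`, `n_missed_by_b`, `n`.
#'   All percentages `NA` (not applicable) when both inputs are empty.
#' @export
cell_agreement <- function(matching, labels_a, labels_b) {
  stopifnot(inherits(matching, "cell_matching"))
  p <- matching$pairs
  n_matched <- nrow(p)
  n_miss_by_b <- length(matching$unmatched_a)  # A's cells B did not mark
  n_miss_by_a <- length(matching$unmatched_b)  # B's cells A did not mark
  n_miss_a <- n_miss_by_a
  n_miss_b <- n_miss_by_b
  n <- n_matched + n_miss_a + n_miss_b
  if (n == 0L) {
    return(structure(list(agreed_pct = NA_real_, disagreed_pct = NA_real_,
                          missed_pct = NA_real_, n_matched = 0L,
                          n_agreed = 0L, n_disagreed = 0L,
                          n_missed_by_a = 0L, n_missed_by_b = 0L, n = 0L),
                     class = "agreement_breakdown"))
  }
  agree <- if (n_matched) labels_a[p$a] == labels_b[p$b] else logical()
  n_agreed <- sum(agree)
  n_disagreed <- n_matched - n_agreed
  structure(list(agreed_pct = 100 * n_agreed / n,
                 disagreed_pct = 100 * n_disagreed / n,
                 missed_pct = 100 * (n_miss_a + n_miss_b) / n,
                 n_matched = n_matched, n_agreed = n_agreed,
                 n_disagreed = n_disagreed,
                 n_missed_by_a = n_miss_a, n_missed_by_b = n_miss_b,
                 n = n),
            class = "agreement_breakdown")
}

#' @export
print.agreement_breakdown <- function(x, ...) {
  cat(sprintf(
    "<agreement> agreed %.1f%% | disagreed %.1f%% | missed %.1f%% (n=%d)\n",
    x$agreed_pct, x$disagreed_pct, x$missed_pct, x$n))
  invisible(x)
}

#' Confusion matrix over matched cell pairs
#'
#' Rows are annotator A's labels, columns annotator B's, in dictionary
#' declaration order (so ordinal chains such as NP1..NP3 stay contiguous).
#' Only matched pairs contribute. Labels listed in the dictionary's
#' `unknown_labels` are excluded by default: pairs involving them are
#' dropped from the matrix (and hence from kappa) but still count in the
#' [cell_agreement()] breakdown.
#'
#' @param labels_a,labels_b Aligned label vectors. Either full per-point
#'   vectors together with `matching`, or already-paired vectors with
#'   `matching = NULL`.
#' @param dictionary An [anno_dictionary()]; fixes label order and
#'   supplies `unknown_labels`.
#' @param matching Optional [match_points()] result used to pair the
#'   labels.
#' @param include_unknown Keep "unknown" labels as their own category?
#' @return Object of class `confusion_matrix`: integer matrix with label
#'   dimnames.
#' @export
confusion_matrix <- function(labels_a, labels_b, dictionary,
                             matching = NULL, include_unknown = FALSE) {
  stopifnot(inherits(dictionary, "anno_dictionary"))
  if (!is.null(matching)) {
    stopifnot(inherits(matching, "cell_matching"))
    labels_a <- labels_a[matching$pairs$a]
    labels_b <- labels_b[matching$pairs$b]
  }
  stopifnot(length(labels_a) == length(labels_b))
  all_labs <- dict_labels(dictionary)
  bad <- setdiff(unique(c(labels_a, labels_b)), all_labs)
  if (length(bad)) {
    stop("label(s) not in dictionary: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  labs <- union(
    dict_labels(dictionary, level = "cell",
                drop_unknown = !include_unknown),
    unique(c(labels_a, labels_b))
  )
  labs <- intersect(all_labs, labs)  # restore declaration order
  if (!include_unknown) {
    labs <- setdiff(labs, dictionary$unknown_labels)
    keep <- labels_a %in% labs & labels_b %in% labs
    labels_a <- labels_a[keep]
    labels_b <- labels_b[keep]
  }
  cm <- table(factor(labels_a, levels = labs),
              factor(labels_b, levels = labs))
  cm <- matrix(as.integer(cm), nrow = length(labs),
               dimnames = list(a = labs, b = labs))
  structure(cm, class = c("confusion_matrix", "matrix"))
}

#' Cohen's kappa, unweighted or ordinal-weighted
#'
#' Chance-corrected agreement on the matched-pair confusion matrix. For
#' `weighting = "none"`, `kappa = (p_o - p_e) / (1 - p_e)`. The weighted
#' forms use the penalty formulation `kappa_w = 1 - sum(w * p) /
#' sum(w * e)` with disagreement weights `w` built from the dictionary's
#' ordinal structure: within an ordinal group of k labels, `w =
#' |rank difference| / (k - 1)` (linear) or its square (quadratic); any
#' disagreement across groups, or involving a non-ordinal label, gets
#' full weight 1. With two categories the linear-weighted and unweighted
#' statistics coincide.
#'
#' @param cm A [confusion_matrix()] (or any square count matrix with
#'   label dimnames).
#' @param weighting `"none"`, `"linear"` or `"quadratic"`.
#' @param dictionary Optional [anno_dictionary()]; required for ordinal
#'   weights (without it all disagreements weigh 1, i.e. the weighted
#'   forms reduce to the unweighted statistic).
#' @return Kappa in \[-1, 1\]; `NA` (not applicable) for an empty matrix
#'   or degenerate chance agreement `p_e = 1`.
#' @examples
#' cm <- matrix(c(10, 5, 5, 10), 2, dimnames = list(c("x", "y"), c("x", "y")))
#' cohens_kappa(cm)  # 1/3
#' @export
cohens_kappa <- function(cm, weighting = c("none", "linear", "quadratic"),
                         dictionary = NULL) {
  weighting <- match.arg(weighting)
  cm <- unclass(cm)
  stopifnot(is.matrix(cm), nrow(cm) == ncol(cm))
  total <- sum(cm)
  if (total == 0) return(NA_real_)
  p <- cm / total
  ra <- rowSums(p)
  rb <- colSums(p)
  e <- outer(ra, rb)
  w <- kappa_weights(rownames(cm) %||% as.character(seq_len(nrow(cm))),
                     weighting, dictionary)
  swe <- sum(w * e)
  if (swe == 0) return(NA_real_)  # p_e = 1: chance agreement saturated
  1 - sum(w * p) / swe
}

# disagreement-weight matrix from dictionary ordinal structure
kappa_weights <- function(labs, weighting, dictionary) {
  k <- length(labs)
  w <- 1 - diag(k)
  if (weighting == "none" || is.null(dictionary)) return(w)
  info <- lapply(labs, function(nm) dictionary$labels[[nm]])
  grp <- vapply(info, function(l) {
    if (is.null(l)) NA_character_ else l$ordinal_group %||% NA_character_
  }, character(1L))
  rnk <- vapply(info, function(l) {
    if (is.null(l)) NA_integer_ else l$ordinal_rank %||% NA_integer_
  }, integer(1L))
  for (g in unique(grp[!is.na(grp)])) {
    members <- which(grp == g)
    if (length(members) < 2L) next
    kg <- max(rnk[members])
    for (i in members) for (j in members) {
      if (i == j) next
      frac <- abs(rnk[i] - rnk[j]) / (kg - 1)
      w[i, j] <- if (weighting == "quadratic") frac^2 else frac
    }
  }
  w
}

#' Per-label region agreement between two annotators on one slide
#'
#' For every region label annotated by either annotator: the Jaccard
#' similarity index of the two annotators' polygon unions, and the union
#' area in mm^2. A label annotated by only one annotator has JSI 0 and is
#' flagged one-sided.
#'
#' @param records_a,records_b The two annotators' records for the slide.
#' @param dictionary An [anno_dictionary()].
#' @param slide A [slide_context()] (supplies microns per pixel).
#' @return data.frame with columns `label`, `jsi`, `union_area_mm2`,
#'   `one_sided`.
#' @export
region_agreement <- function(records_a, records_b, dictionary, slide) {
  stopifnot(inherits(slide, "slide_context"))
  rings_by_label <- function(records) {
    keep <- vapply(records, function(r) {
      r$level == "region" && r$construct %in% c("polygon", "circle")
    }, logical(1L))
    records <- records[keep]
    split(lapply(records, record_ring),
          vapply(records, `[[`, character(1L), "feature_name"))
  }
  ra <- rings_by_label(records_a)
  rb <- rings_by_label(records_b)
  labs <- intersect(dict_labels(dictionary),
                    union(names(ra), names(rb)))
  rows <- lapply(labs, function(lb) {
    a <- ra[[lb]] %||% list()
    b <- rb[[lb]] %||% list()
    one_sided <- xor(length(a) > 0L, length(b) > 0L)
    jsi <- if (one_sided) 0 else jaccard(a, b)
    uni <- union_area(c(a, b))
    data.frame(label = lb, jsi = jsi,
               union_area_mm2 = px2_to_mm2(uni, slide$microns_per_pixel),
               one_sided = one_sided, stringsAsFactors = FALSE)
  })
  if (length(rows)) do.call(rbind, rows)
  else data.frame(label = character(), jsi = numeric(),
                  union_area_mm2 = numeric(), one_sided = logical(),
                  stringsAsFactors = FALSE)
}

#' Full pairwise cell agreement between two annotators on one slide
#'
#' Convenience wrapper: extracts the two annotators' cell points and
#' labels, matches them at the slide's default radius, and returns the
#' breakdown, confusion matrix and kappa together.
#'
#' @inheritParams region_agreement
#' @param radius_px Matching radius; default from [default_radius_px()].
#' @param weighting Kappa weighting scheme.
#' @return List with `matching`, `breakdown`, `confusion`, `kappa`.
#' @export
pair_cell_agreement <- function(records_a, records_b, dictionary, slide,
                                radius_px = default_radius_px(slide),
                                weighting = "linear") {
  cells <- function(records) {
    keep <- vapply(records, function(r) {
      r$level == "cell" && r$construct %in% c("point", "circle")
    }, logical(1L))
    records <- records[keep]
    list(points = do.call(rbind, c(list(matrix(numeric(), ncol = 2L)),
                                   lapply(records, `[[`, "geometry"))),
         labels = vapply(records, `[[`, character(1L), "feature_name"))
  }
  ca <- cells(records_a)
  cb <- cells(records_b)
  matching <- match_points(ca$points, cb$points, radius_px)
  breakdown <- cell_agreement(matching, ca$labels, cb$labels)
  cm <- confusion_matrix(ca$labels, cb$labels, dictionary,
                         matching = matching)
  list(matching = matching, breakdown = breakdown, confusion = cm,
       kappa = cohens_kappa(cm, weighting, dictionary))
}

#' Aggregate per-pair agreement results to a project summary
#'
#' Unweighted means of the agreed/disagreed/missed percentages across
#' slide-pairs, the pooled (element-wise summed) confusion matrix with its
#' kappa, and the per-label mean JSI across pairs.
#'
#' @param pair_results List of per-pair results, each a list with
#'   `breakdown` ([cell_agreement()]), `confusion`
#'   ([confusion_matrix()]) and optionally `jsi` (a [region_agreement()]
#'   table).
#' @param weighting,dictionary Passed to [cohens_kappa()] for the pooled
#'   matrix.
#' @return List with `mean_agreed_pct`, `mean_disagreed_pct`,
#'   `mean_missed_pct`, `n_pairs`, `pooled_confusion`, `pooled_kappa`,
#'   `mean_jsi_by_label` (data.frame).
#' @export
aggregate_pairs <- function(pair_results, weighting = "linear",
                            dictionary = NULL) {
  stopifnot(length(pair_results) >= 1L)
  getpct <- function(f) {
    v <- vapply(pair_results, function(p) p$breakdown[[f]], numeric(1L))
    mean(v, na.rm = TRUE)
  }
  cms <- lapply(pair_results, `[[`, "confusion")
  cms <- cms[!vapply(cms, is.null, logical(1L))]
  pooled <- NULL
  if (length(cms)) {
    labs <- Reduce(union, lapply(cms, rownames))
    pooled <- matrix(0L, length(labs), length(labs),
                     dimnames = list(a = labs, b = labs))
    for (cm in cms) {
      pooled[rownames(cm), colnames(cm)] <-
        pooled[rownames(cm), colnames(cm)] + unclass(cm)
    }
    pooled <- structure(pooled, class = c("confusion_matrix", "matrix"))
  }
  jsis <- lapply(pair_results, `[[`, "jsi")
  jsis <- jsis[!vapply(jsis, is.null, logical(1L))]
  mean_jsi <- if (length(jsis)) {
    all_j <- do.call(rbind, jsis)
    out <- aggregate(jsi ~ label, data = all_j, FUN = mean)
    names(out)[2L] <- "mean_jsi"
    out
  } else {
    data.frame(label = character(), mean_jsi = numeric())
  }
  list(mean_agreed_pct = getpct("agreed_pct"),
       mean_disagreed_pct = getpct("disagreed_pct"),
       mean_missed_pct = getpct("missed_pct"),
       n_pairs = length(pair_results),
       pooled_confusion = pooled,
       pooled_kappa = if (!is.null(pooled)) {
         cohens_kappa(pooled, weighting, dictionary)
       } else NA_real_,
       mean_jsi_by_label = mean_jsi)
}
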