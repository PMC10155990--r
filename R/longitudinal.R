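#' Match ROIs between two imaging sessions by mask overlap
#'
#' No geometric transformation is applied: masks are compared in the shared
#' pixel frame. Overlap between two masks is |A intersect B| / min(|A|,
#' |B|) by default (`denominator = "min"`; `"union"` gives Jaccard).
#' Matching is greedy in descending overlap with each ROI used at most
#' once; pairs at or above `threshold` (default 0.5, inclusive) are kept.
#'
#' @param masks_t1,masks_t2 Named (or indexed) lists of logical matrices.
#' @param threshold Minimum overlap fraction (inclusive).
#' @param denominator `"min"` or `"union"`.
#' @return data.frame with `id_t1`, `id_t2`, `overlap_fraction`.
#' @export
match_rois <- function(masks_t1, masks_t2, threshold = 0.5,
                       denominator = c("min", "union")) {
  denominator <- match.arg(denominator)
  ids1 <- names2(masks_t1)
  ids2 <- names2(masks_t2)
  if (anyDuplicated(ids1) || anyDuplicated(ids2))
    stop("duplicate ROI ids")
  n1 <- length(masks_t1)
  n2 <- length(masks_t2)
  cand <- NULL
  sz1 <- vapply(masks_t1, sum, numeric(1))
  sz2 <- vapply(masks_t2, sum, numeric(1))
  for (i in seq_len(n1)) {
    a <- which(masks_t1[[i]])
    for (j in seq_len(n2)) {
      inter <- sum(masks_t2[[j]][a])
      if (inter == 0) next
      den <- if (denominator == "min") min(sz1[i], sz2[j]) else
        sz1[i] + sz2[j] - inter
      cand <- rbind(cand, c(i, j, inter / den))
    }
  }
  pairs <- data.frame(id_t1 = character(), id_t2 = character(),
                      overlap_fraction = numeric())
  if (is.null(cand)) return(pairs)
  cand <- cand[cand[, 3] >= threshold, , drop = FALSE]
  cand <- cand[order(-cand[, 3], cand[, 1], cand[, 2]), , drop = FALSE]
  used1 <- logical(n1); used2 <- logical(n2)
  for (k in seq_len(nrow(cand))) {
    i <- cand[k, 1]; j <- cand[k, 2]
    if (used1[i] || used2[j]) next
    used1[i] <- TRUE; used2[j] <- TRUE
    pairs <- rbind(pairs, data.frame(id_t1 = ids1[i], id_t2 = ids2[j],
                                     overlap_fraction = cand[k, 3]))
  }
  pairs
}

names2 <- function(x) {
  if (!is.null(names(x))) names(x) else as.character(seq_along(x))
}

#' Stable-perimeter analysis region across two sessions
#'
#' Anchors are matched neurons responsive at both timepoints whose
#' preferred orientation changed by less than `ori_tol` degrees (circular,
#' strict) and preferred SF by less than `sf_tol` octaves (strict). The
#' analysis region is the convex hull of the anchors' centroids; the
#' analyzed set is every neuron (matched or not) whose centroid lies inside
#' or on the hull.
#'
#' @param pairs Matched pairs from [match_rois()].
#' @param tuning_t1,tuning_t2 data.frames with columns `id`, `responsive`,
#'   `pref_ori`, `pref_sf`, `cx`, `cy` (ids as character).
#' @param ori_tol Orientation stability tolerance, degrees (strict <).
#' @param sf_tol SF stability tolerance, octaves (strict <).
#' @return List with `anchors` (pair rows), `hull` (polygon matrix x,y),
#'   `analyzed_t1`, `analyzed_t2` (character id vectors).
#' @export
stable_perimeter_region <- function(pairs, tuning_t1, tuning_t2,
                                    ori_tol = 30, sf_tol = 1) {
  t1 <- tuning_t1[match(pairs$id_t1, as.character(tuning_t1$id)), ]
  t2 <- tuning_t2[match(pairs$id_t2, as.character(tuning_t2$id)), ]
  both_resp <- t1$responsive & t2$responsive
  dori <- delta_ori(wrap180(t1$pref_ori), wrap180(t2$pref_ori))
  dsf <- abs(log2(t1$pref_sf / t2$pref_sf))
  stable <- both_resp & !is.na(dori) & !is.na(dsf) &
    dori < ori_tol & dsf < sf_tol
  stable[is.na(stable)] <- FALSE
  if (sum(stable) < 3)
    stop("fewer than 3 stable anchor neurons; simulate a denser ",
         "population or relax the stability tolerances")
  ax <- t1$cx[stable]; ay <- t1$cy[stable]
  h <- grDevices::chull(ax, ay)
  hull <- cbind(x = ax[h], y = ay[h])
  inside <- function(tab) {
    pts <- cbind(tab$cx, tab$cy)
    io <- mgcv::in.out(rbind(hull, hull[1, , drop = FALSE]), pts)
    on_vertex <- apply(pts, 1, function(p)
      any(abs(hull[, 1] - p[1]) < 1e-9 & abs(hull[, 2] - p[2]) < 1e-9))
    as.character(tab$id)[io | on_vertex]
  }
  list(anchors = pairs[stable, , drop = FALSE], hull = hull,
       analyzed_t1 = inside(tuning_t1), analyzed_t2 = inside(tuning_t2))
}

#' Tabulate ocular-dominance category transitions between two sessions
#'
#' Counts category changes over {C, B, I, NR} for the analyzed set.
#' Neurons unmatched (or nonresponsive) at a timepoint count as NR there.
#'
#' @param cat_t1,cat_t2 Named character vectors id -> category.
#' @param pairs Matched pairs from [match_rois()].
#' @param analyzed_t1,analyzed_t2 Ids in the analysis region per timepoint.
#' @return List with `counts` (4x4 matrix, rows = t1), `n`.
#' @export
transition_table <- function(cat_t1, cat_t2, pairs,
                             analyzed_t1 = names(cat_t1),
                             analyzed_t2 = names(cat_t2)) {
  cats <- c("C", "B", "I", "NR")
  if (!all(cat_t1 %in% cats) || !all(cat_t2 %in% cats))
    stop("categories must be in {C, B, I, NR}")
  m12 <- stats::setNames(pairs$id_t2, pairs$id_t1)
  m21 <- stats::setNames(pairs$id_t1, pairs$id_t2)
  counts <- matrix(0L, 4, 4, dimnames = list(t1 = cats, t2 = cats))
  seen_t2 <- character()
  for (id in analyzed_t1) {
    c1 <- cat_t1[[id]]
    partner <- if (id %in% names(m12)) m12[[id]] else NA
    c2 <- if (!is.na(partner) && partner %in% names(cat_t2))
      cat_t2[[partner]] else "NR"
    if (!is.na(partner)) seen_t2 <- c(seen_t2, partner)
    counts[c1, c2] <- counts[c1, c2] + 1L
  }
  # neurons present in the region at t2 with no analyzed t1 partner
  for (id in analyzed_t2) {
    if (id %in% seen_t2) next
    partner <- if (id %in% names(m21)) m21[[id]] else NA
    if (!is.na(partner) && partner %in% analyzed_t1) next
    c2 <- cat_t2[[id]]
    if (c2 == "NR") next  # NR->NR outside both responsive sets not tallied
    counts["NR", c2] <- counts["NR", c2] + 1L
  }
  list(counts = counts, n = sum(counts))
}

#' Exchanged-mask SNR and SR ratios for gained and lost neurons
#'
#' For every matched (or singleton) neuron, extracts/uses the trace at each
#' timepoint, computes SNR and SR at both, and reports t2/t1 ratios
#' together with the neuron's stability cohort: `stable` (responsive at
#' both timepoints), `lost` (responsive at t1 only), `gained` (responsive
#' at t2 only).
#'
#' @param stats_t1,stats_t2 Per-neuron data.frames with `id`, `responsive`,
#'   `snr`, `sr`.
#' @param pairs Matched pairs from [match_rois()].
#' @return data.frame with `id_t1`, `id_t2`, `cohort`, `snr_ratio`,
#'   `sr_ratio`.
#' @export
exchanged_mask_metrics <- function(stats_t1, stats_t2, pairs) {
  i1 <- match(pairs$id_t1, as.character(stats_t1$id))
  i2 <- match(pairs$id_t2, as.character(stats_t2$id))
  ok <- !is.na(i1) & !is.na(i2)
  a <- stats_t1[i1[ok], ]
  b <- stats_t2[i2[ok], ]
  cohort <- ifelse(a$responsive & b$responsive, "stable",
                   ifelse(a$responsive & !b$responsive, "lost",
                          ifelse(!a$responsive & b$responsive, "gained",
                                 "neither")))
  data.frame(id_t1 = pairs$id_t1[ok], id_t2 = pairs$id_t2[ok],
             cohort = cohort,
             snr_ratio = b$snr / a$snr,
             sr_ratio = ifelse(a$sr > 0, b$sr / a$sr, NA_real_))
}
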