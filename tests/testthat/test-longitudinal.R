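disk_mask <- function(r, c, geom = c(40, 40), radius = 3) {
  m <- matrix(FALSE, geom[1], geom[2])
  for (dr in -radius:radius) for (dc in -radius:radius)
    if (dr^2 + dc^2 <= radius^2) m[r + dr, c + dc] <- TRUE
  m
}

test_that("identical mask sets match one-to-one at overlap 1", {
  masks <- list(a = disk_mask(10, 10), b = disk_mask(25, 25),
                c = disk_mask(10, 30))
  p <- match_rois(masks, masks)
  expect_equal(nrow(p), 3)
  expect_true(all(p$overlap_fraction == 1))
  expect_equal(p$id_t1[order(p$id_t1)], p$id_t2[order(p$id_t2)])
})

test_that("the 50% overlap boundary is inclusive and disjoint masks never match", {
  a <- matrix(FALSE, 20, 20); a[5:8, 5:8] <- TRUE          # 16 px
  b <- matrix(FALSE, 20, 20); b[5:8, 7:10] <- TRUE         # 8 px shared
  p <- match_rois(list(a), list(b))
  expect_equal(nrow(p), 1)
  expect_equal(p$overlap_fraction, 0.5)
  far <- matrix(FALSE, 20, 20); far[15:18, 15:18] <- TRUE
  expect_equal(nrow(match_rois(list(a), list(far))), 0)
})

test_that("matching is greedy, one-to-one, and symmetric", {
  m1 <- list(x = disk_mask(10, 10), y = disk_mask(14, 10))
  m2 <- list(u = disk_mask(11, 10), v = disk_mask(15, 10))
  ab <- match_rois(m1, m2)
  ba <- match_rois(m2, m1)
  expect_equal(nrow(ab), 2)
  expect_lte(max(table(ab$id_t1)), 1)
  expect_lte(max(table(ab$id_t2)), 1)
  key_ab <- sort(paste(ab$id_t1, ab$id_t2))
  key_ba <- sort(paste(ba$id_t2, ba$id_t1))
  expect_equal(key_ab, key_ba)
  expect_error(match_rois(list(a = m1$x, a = m1$y), m2), "duplicate")
})

test_that("stable anchors require strict tolerance and bound the region", {
  mk_tab <- function(ori, sf, resp = TRUE) {
    n <- length(ori)
    data.frame(id = as.character(seq_len(n)), responsive = resp,
               pref_ori = ori, pref_sf = sf,
               cx = c(0, 10, 0, 10, 2, 20)[seq_len(n)],
               cy = c(0, 0, 10, 10, 2, 20)[seq_len(n)])
  }
  t1 <- mk_tab(c(10, 50, 90, 130, 20, 70), rep(0.1, 6))
  pairs <- data.frame(id_t1 = as.character(1:6),
                      id_t2 = as.character(1:6),
                      overlap_fraction = 1)
  # neuron 4 moves exactly 30 degrees: excluded (strict inequality)
  t2 <- t1
  t2$pref_ori <- c(12, 48, 92, 160, 22, 100)
  reg <- stable_perimeter_region(pairs, t1, t2)
  expect_setequal(reg$anchors$id_t1, c("1", "2", "3", "5"))
  # neuron 5 (interior) is analyzed, neuron 6 (outside hull) is not
  expect_true("5" %in% reg$analyzed_t1)
  expect_false("6" %in% reg$analyzed_t1)
  # too few anchors errors with guidance
  t2_bad <- t1
  t2_bad$pref_ori <- t1$pref_ori + 40
  expect_error(stable_perimeter_region(pairs, t1, t2_bad), "anchor")
})

test_that("hull membership agrees with a ray-casting oracle", {
  set.seed(66)
  ax <- runif(8, 2, 18); ay <- runif(8, 2, 18)
  h <- grDevices::chull(ax, ay)
  hull <- cbind(x = ax[h], y = ay[h])
  pts <- cbind(runif(50, 0, 20), runif(50, 0, 20))
  io <- mgcv::in.out(rbind(hull, hull[1, , drop = FALSE]), pts)
  oracle <- vapply(seq_len(50), function(i)
    point_in_poly_oracle(pts[i, 1], pts[i, 2], hull), logical(1))
  expect_gte(mean(io == oracle), 0.98)
})

test_that("transition tables conserve counts and match hand enumeration", {
  cat1 <- c(a = "C", b = "C", c = "B", d = "I", e = "NR", f = "B")
  cat2 <- c(a = "B", b = "C", c = "I", d = "I", e = "B", f = "NR")
  pairs <- data.frame(id_t1 = names(cat1), id_t2 = names(cat2)[1:6],
                      overlap_fraction = 1)
  pairs$id_t2 <- names(cat2)
  tt <- transition_table(cat1, cat2, pairs)
  expect_equal(tt$n, 6)
  expect_equal(tt$counts["C", "B"], 1L)
  expect_equal(tt$counts["C", "C"], 1L)
  expect_equal(tt$counts["B", "I"], 1L)
  expect_equal(tt$counts["B", "NR"], 1L)
  expect_equal(tt$counts["I", "I"], 1L)
  expect_equal(tt$counts["NR", "B"], 1L)
  expect_equal(unname(rowSums(tt$counts)),
               as.vector(table(factor(cat1, c("C", "B", "I", "NR")))))
  # identical categories give a diagonal table
  td <- transition_table(cat1, cat1, pairs)
  expect_equal(sum(diag(td$counts)), 6)
  expect_error(transition_table(c(a = "X"), cat2, pairs), "categories")
})

test_that("unmatched neurons count as NR at the missing timepoint", {
  cat1 <- c(a = "C", b = "B")
  cat2 <- c(z = "I")
  pairs <- data.frame(id_t1 = character(), id_t2 = character(),
                      overlap_fraction = numeric())
  tt <- transition_table(cat1, cat2, pairs,
                         analyzed_t1 = names(cat1),
                         analyzed_t2 = names(cat2))
  expect_equal(tt$counts["C", "NR"], 1L)
  expect_equal(tt$counts["B", "NR"], 1L)
  expect_equal(tt$counts["NR", "I"], 1L)
})

test_that("exchanged-mask ratios separate stable, lost, and gained neurons", {
  s1 <- data.frame(id = as.character(1:3),
                   responsive = c(TRUE, TRUE, FALSE),
                   snr = c(2, 3, 1), sr = c(40, 50, 10))
  s2 <- data.frame(id = as.character(1:3),
                   responsive = c(TRUE, FALSE, TRUE),
                   snr = c(2, 1.2, 2.5), sr = c(40, 12, 45))
  pairs <- data.frame(id_t1 = as.character(1:3),
                      id_t2 = as.character(1:3), overlap_fraction = 1)
  em <- exchanged_mask_metrics(s1, s2, pairs)
  expect_equal(em$cohort, c("stable", "lost", "gained"))
  expect_equal(em$snr_ratio[1], 1)
  expect_lt(em$snr_ratio[2], 1)   # silenced neuron
  expect_gt(em$snr_ratio[3], 1)   # recruited neuron
})

test_that("zero-drift simulations match every ground-truth neuron at overlap 1", {
  pop <- sample_population(9, seed = 71, fov = c(60, 60))
  masks <- population_masks(pop, c(60, 60))
  names(masks) <- pop$id
  p <- match_rois(masks, masks)
  expect_equal(nrow(p), 9)
  expect_true(all(p$overlap_fraction == 1))
})
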