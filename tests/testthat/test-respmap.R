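# explicit per-event double-loop reverse correlation, kept independent of
# the package implementation
revcorr_oracle <- function(isr, schedule, delays = -2:18) {
  ev <- schedule$events
  og <- schedule$ori_grid
  sg <- schedule$sf_grid
  no <- length(og)
  ns <- length(sg) + 1
  out <- array(NA_real_, c(length(delays), no, ns))
  nf <- length(isr)
  keep <- ev$onset_frame + max(delays) <= nf &
    ev$onset_frame + min(delays) >= 1
  ev <- ev[keep, ]
  for (di in seq_along(delays)) {
    acc <- array(0, c(no, ns))
    cnt <- array(0, c(no, ns))
    for (e in seq_len(nrow(ev))) {
      oi <- if (ev$is_blank[e]) 1 else match(ev$orientation[e], og)
      si <- if (ev$is_blank[e]) ns else match(ev$sf[e], sg)
      acc[oi, si] <- acc[oi, si] + isr[ev$onset_frame[e] + delays[di]]
      cnt[oi, si] <- cnt[oi, si] + 1
    }
    m <- acc / cnt
    out[di, , ] <- m
  }
  out
}

test_that("reverse correlation matches a brute-force event loop", {
  for (k in 1:20) {
    sch <- make_stimulus_schedule(20, seed = 100 + k)
    nf <- sch$n_frames + 30
    set.seed(200 + k)
    isr <- pmax(rnorm(nf), 0)
    tens <- reverse_correlate(isr, sch)
    oracle <- revcorr_oracle(isr, sch)
    expect_equal(tens$mean_isr, oracle, tolerance = 1e-12)
  }
})

test_that("an all-zero ISR yields an all-zero tensor and undefined delay", {
  sch <- make_stimulus_schedule(30, seed = 5)
  tens <- reverse_correlate(rep(0, sch$n_frames + 30), sch)
  expect_true(all(tens$mean_isr[is.finite(tens$mean_isr)] == 0))
  od <- optimal_delay(tens)
  expect_true(is.na(od$delay))
  expect_false(od$time_locked)
})

test_that("a lone response lights the unique condition cell at its delay", {
  sch <- make_stimulus_schedule(30, seed = 6)
  ev <- sch$events
  target <- which(!ev$is_blank)[1]
  isr <- rep(0, sch$n_frames + 30)
  isr[ev$onset_frame[target] + 5] <- 1
  tens <- reverse_correlate(isr, sch)
  oi <- match(ev$orientation[target], sch$ori_grid)
  si <- match(ev$sf[target], sch$sf_grid)
  di <- match(5, tens$delays)
  expect_gt(tens$mean_isr[di, oi, si], 0)
})

test_that("optimal delay selects the argmax with smallest-delay tie-break", {
  mk_tensor <- function(vals_at) {
    m <- array(0, c(21, 6, 9))
    for (d in names(vals_at)) m[as.integer(d), 1, 1] <- vals_at[[d]]
    structure(list(delays = -2:18, ori_grid = seq(0, 150, 30),
                   sf_grid = build_sf_grid(), mean_isr = m, z = m,
                   n_pres = matrix(10, 6, 9), n_dropped = 0),
              class = "resp_tensor")
  }
  # delay d maps to array index d + 3
  expect_equal(optimal_delay(mk_tensor(list(`9` = 1)))$delay, 6)
  expect_true(optimal_delay(mk_tensor(list(`9` = 1)))$time_locked)
  od12 <- optimal_delay(mk_tensor(list(`15` = 1)))
  expect_equal(od12$delay, 12)
  expect_false(od12$time_locked)
  tie <- optimal_delay(mk_tensor(list(`8` = 1, `10` = 1)))
  expect_equal(tie$delay, 5)
})

test_that("SNR is the ratio of grid SDs in signal and noise windows", {
  m <- array(0, c(21, 6, 9))
  delays <- -2:18
  set.seed(3)
  base <- rnorm(48)
  for (di in seq_along(delays)) {
    scale <- if (delays[di] %in% 4:9) 3 else
      if (delays[di] %in% c(-2:0, 15:18)) 1 else 2
    m[di, , 1:8] <- base * scale
  }
  tens <- structure(list(delays = delays, ori_grid = seq(0, 150, 30),
                         sf_grid = build_sf_grid(), mean_isr = m, z = m,
                         n_pres = matrix(10, 6, 9), n_dropped = 0),
                    class = "resp_tensor")
  expect_equal(compute_snr(tens), 3, tolerance = 1e-12)
  m2 <- m
  for (di in which(delays %in% 4:9)) m2[di, , 1:8] <- base
  tens$mean_isr <- m2
  expect_equal(compute_snr(tens), 1, tolerance = 1e-12)
})

test_that("spike ratio is the percent of answered preferred presentations", {
  sch <- make_stimulus_schedule(120, seed = 9)
  ev <- sch$events
  cond <- !ev$is_blank & ev$orientation == 60 &
    abs(ev$sf - sch$sf_grid[4]) < 1e-12
  onsets <- ev$onset_frame[cond]
  isr <- rep(0, sch$n_frames + 30)
  expect_equal(compute_spike_ratio(isr, sch, 60, sch$sf_grid[4], 6), 0)
  isr[onsets + 6] <- 1
  expect_equal(compute_spike_ratio(isr, sch, 60, sch$sf_grid[4], 6), 100)
  isr[onsets + 6] <- 0
  isr[onsets[seq_len(length(onsets) %/% 2)] + 6] <- 1
  expect_equal(compute_spike_ratio(isr, sch, 60, sch$sf_grid[4], 6),
               100 * (length(onsets) %/% 2) / length(onsets))
  expect_error(compute_spike_ratio(isr, sch, 61, sch$sf_grid[4], 6),
               "never presented")
})

test_that("classification thresholds are linear-interpolation 75th percentiles", {
  df <- data.frame(
    id = 1:6, eye = "contra",
    time_locked = c(FALSE, FALSE, FALSE, FALSE, TRUE, TRUE),
    snr = c(1, 2, 3, 4, 5, 2), sr = c(10, 20, 30, 40, 50, 15))
  out <- classify_population(df)
  expect_equal(out$snr_75[1], 3.25)
  expect_equal(out$sr_75[1], 32.5)
  expect_true(out$responsive[5])   # locked, snr 5 > 3.25, sr 50 > 32.5
  expect_false(out$responsive[6])  # locked but below both thresholds
  # time-lock gates regardless of SNR
  df2 <- df
  df2$snr[4] <- 100
  out2 <- classify_population(df2)
  expect_false(out2$responsive[4])
  expect_error(classify_population(df[df$time_locked, ]), "spontaneously")
})

test_that("responsiveness is classified independently per eye", {
  a <- tiny_analyzed()
  st <- a$analysis$stats
  expect_setequal(unique(st$eye), c("contra", "ipsi"))
  thr <- unique(st[, c("eye", "snr_75", "sr_75")])
  expect_equal(nrow(thr), 2)
  # ground-truth contra-monocular neurons should never be ipsi-responsive
  mono_c <- a$pop$id[a$pop$category == "C"]
  ipsi_flags <- st$responsive[st$eye == "ipsi" & st$id %in% mono_c]
  expect_lt(mean(ipsi_flags), 0.25)
})
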