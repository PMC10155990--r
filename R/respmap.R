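#' Reverse-correlate an inferred spike rate to stimulus onsets
#'
#' For every delay d (frames, default -2..18 relative to onset) and every
#' stimulus condition (6 orientations x 8 SFs, plus the blank as a ninth SF
#' level), computes the mean ISR at `onset_frame + d` over all presentations
#' of that condition. Blank presentations occupy a single cell (row 1 of SF
#' column 9). Cell z-scores are formed against the mean and SD of the
#' non-blank mean-ISR cells over the noise delays {-2..0, 15..18}.
#' Presentations whose latest sampled frame falls beyond the trace end are
#' dropped and counted.
#'
#' @param isr Inferred spike-rate trace.
#' @param schedule A `stim_schedule` for the same eye/session.
#' @param delays Integer frame offsets; must cover -2..18.
#' @return A `resp_tensor`: list with `delays`, `ori_grid`, `sf_grid`,
#'   `mean_isr` (delays x 6 x 9 array), `z` (same shape), `n_pres`
#'   (6 x 9 matrix), `n_dropped`.
#' @export
reverse_correlate <- function(isr, schedule, delays = -2:18) {
  if (!all(-2:18 %in% delays))
    stop("delays must cover at least -2..18 (SNR noise windows)")
  ev <- schedule$events
  og <- schedule$ori_grid
  sg <- schedule$sf_grid
  no <- length(og)
  ns <- length(sg) + 1L  # ninth level = blank
  nd <- length(delays)
  nf <- length(isr)
  oi <- match(ev$orientation, og)
  si <- match(ev$sf, sg)
  oi[ev$is_blank] <- 1L
  si[ev$is_blank] <- ns
  cond <- (si - 1L) * no + oi
  fidx <- outer(ev$onset_frame, delays, `+`)
  keep <- ev$onset_frame + max(delays) <= nf & ev$onset_frame + min(delays) >= 1
  n_dropped <- sum(!keep)
  cond <- cond[keep]
  vals <- matrix(isr[fidx[keep, , drop = FALSE]], sum(keep), nd)
  sums <- rowsum(vals, cond)
  cnt <- tabulate(cond, nbins = no * ns)
  mean_isr <- array(NA_real_, c(nd, no, ns))
  present <- as.integer(rownames(sums))
  # mean over events per condition per delay
  m <- matrix(NA_real_, no * ns, nd)
  m[present, ] <- sums / cnt[present]
  for (d in seq_len(nd)) mean_isr[d, , ] <- matrix(m[, d], no, ns)
  n_pres <- matrix(cnt, no, ns)
  noise_d <- which(delays %in% c(-2:0, 15:18))
  noise_cells <- mean_isr[noise_d, , seq_len(ns - 1L), drop = FALSE]
  mu <- mean(noise_cells, na.rm = TRUE)
  sg2 <- stats::sd(noise_cells, na.rm = TRUE)
  z <- if (is.finite(sg2) && sg2 > 0) (mean_isr - mu) / sg2 else
    array(0, dim(mean_isr))
  structure(list(delays = delays, ori_grid = og, sf_grid = sg,
                 mean_isr = mean_isr, z = z, n_pres = n_pres,
                 n_dropped = n_dropped),
            class = "resp_tensor")
}

#' Optimal response delay of a neuron
#'
#' The delay whose best stimulus cell (blank excluded) has the highest mean
#' ISR; ties break toward the smallest delay. A neuron is time-locked when
#' the optimal delay falls in frames 4-9 after onset; otherwise it is
#' spontaneously active.
#'
#' @param tensor A `resp_tensor`.
#' @return List with `delay` (frame offset, `NA` if the tensor is all
#'   zero/empty) and `time_locked` (logical).
#' @export
optimal_delay <- function(tensor) {
  grid <- tensor$mean_isr[, , seq_along(tensor$sf_grid), drop = FALSE]
  per_delay <- apply(grid, 1, function(x) {
    x <- x[is.finite(x)]
    if (length(x)) max(x) else -Inf
  })
  if (!any(is.finite(per_delay)) || all(per_delay <= 0))
    return(list(delay = NA_integer_, time_locked = FALSE))
  d <- tensor$delays[which.max(per_delay)]  # which.max: first (smallest) wins
  list(delay = d, time_locked = d >= 4 && d <= 9)
}

#' Signal-to-noise ratio of a response tensor
#'
#' Signal: mean over delays 4-9 of the per-delay SD of mean ISR across the
#' orientation x SF grid (blank excluded). Noise: the same statistic
#' averaged over the flanking delays -2..0 before onset and 15..18 after.
#'
#' @param tensor A `resp_tensor`.
#' @return SNR (unitless); `Inf` with a warning when the noise term is 0.
#' @export
compute_snr <- function(tensor) {
  grid <- tensor$mean_isr[, , seq_along(tensor$sf_grid), drop = FALSE]
  per_delay_sd <- apply(grid, 1, stats::sd, na.rm = TRUE)
  sig <- mean(per_delay_sd[tensor$delays %in% 4:9])
  noi <- mean(per_delay_sd[tensor$delays %in% c(-2:0, 15:18)])
  if (!is.finite(noi) || noi == 0) {
    warning("zero noise SD; SNR reported as Inf")
    return(Inf)
  }
  sig / noi
}

#' Spike ratio: percent of preferred presentations answered
#'
#' The percentage of presentations of the preferred condition for which the
#' ISR is positive at `onset_frame + delay`.
#'
#' @param isr Inferred spike-rate trace.
#' @param schedule A `stim_schedule`.
#' @param pref_ori,pref_sf Preferred orientation (degrees) and SF (cpd),
#'   values on the schedule grids.
#' @param delay Optimal delay, frames.
#' @return SR in percent (0-100).
#' @export
compute_spike_ratio <- function(isr, schedule, pref_ori, pref_sf, delay) {
  ev <- schedule$events
  sel <- which(!ev$is_blank & ev$orientation == pref_ori & ev$sf == pref_sf)
  if (!length(sel)) stop("preferred condition never presented")
  fr <- ev$onset_frame[sel] + delay
  fr <- fr[fr >= 1 & fr <= length(isr)]
  if (!length(fr)) stop("no in-range presentations of preferred condition")
  100 * mean(isr[fr] > 0)
}

#' Classify neurons as visually responsive per eye
#'
#' Applies the three responsiveness criteria: (1) the optimal delay is
#' time-locked (4-9 frames after onset); (2) SNR exceeds the 75th percentile
#' of the spontaneously active neurons (optimal delay outside 4-9); (3) the
#' spike ratio exceeds the 75th percentile of the spontaneously active
#' neurons. Thresholds are computed per eye from that session's spontaneous
#' set using linear-interpolation percentiles.
#'
#' @param stats_df data.frame with columns `eye`, `time_locked`, `snr`,
#'   `sr` (one row per neuron per eye).
#' @return The input with added columns `snr_75`, `sr_75`, `responsive`.
#' @export
classify_population <- function(stats_df) {
  need <- c("eye", "time_locked", "snr", "sr")
  if (!all(need %in% names(stats_df))) stop("missing columns")
  out <- stats_df
  out$snr_75 <- NA_real_
  out$sr_75 <- NA_real_
  for (eye in unique(out$eye)) {
    sel <- out$eye == eye
    spont <- sel & !out$time_locked
    if (!any(spont))
      stop("no spontaneously active neurons for eye '", eye,
           "'; simulate a larger population")
    snr_75 <- stats::quantile(out$snr[spont][is.finite(out$snr[spont])],
                              0.75, names = FALSE)
    sr_75 <- stats::quantile(out$sr[spont], 0.75, names = FALSE)
    out$snr_75[sel] <- snr_75
    out$sr_75[sel] <- sr_75
  }
  out$responsive <- out$time_locked & out$snr > out$snr_75 &
    out$sr > out$sr_75
  out
}
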