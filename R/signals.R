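#' Extract a neuropil-corrected ROI trace from a movie
#'
#' Per frame: mean fluorescence over the ROI's pixels minus the median over
#' a surrounding neuropil annulus. The annulus is the set of pixels within
#' `annulus_width` pixels of the ROI (excluding the ROI itself and the
#' pixels of any other ROI). If every annulus pixel is occluded by other
#' ROIs, the nearest free pixels are used instead, with a warning.
#'
#' @param movie Array rows x cols x frames.
#' @param mask Logical matrix (rows x cols), the ROI.
#' @param other_masks Optional list of logical matrices for the remaining
#'   ROIs, excluded from the annulus.
#' @param annulus_width Annulus thickness in pixels.
#' @return Numeric trace of length frames.
#' @export
extract_roi_trace <- function(movie, mask, other_masks = NULL,
                              annulus_width = 6) {
  d <- dim(movie)
  if (length(d) != 3) stop("movie must be rows x cols x frames")
  if (!any(mask)) stop("mask is empty")
  if (any(dim(mask) != d[1:2])) stop("mask does not match frame size")
  px <- which(mask)
  occupied <- mask
  if (length(other_masks))
    for (m in other_masks) occupied <- occupied | m
  ann <- annulus_pixels(mask, annulus_width) & !occupied
  if (!any(ann)) {
    warning("annulus fully occluded; falling back to nearest free pixels")
    free <- which(!occupied)
    dmat <- pixel_distances(mask, free, d[1:2])
    ann_px <- free[order(dmat)][seq_len(min(50, length(free)))]
  } else {
    ann_px <- which(ann)
  }
  nf <- d[3]
  npix <- d[1] * d[2]
  vapply(seq_len(nf), function(t) {
    off <- (t - 1) * npix
    mean(movie[off + px]) - stats::median(movie[off + ann_px])
  }, numeric(1))
}

# pixels within `width` of the mask (chebyshev-euclidean hybrid via brute
# force over mask pixels; masks are small somata so this stays cheap)
annulus_pixels <- function(mask, width) {
  d <- dim(mask)
  idx <- which(mask, arr.ind = TRUE)
  out <- matrix(FALSE, d[1], d[2])
  w <- ceiling(width)
  rows <- max(1, min(idx[, 1]) - w):min(d[1], max(idx[, 1]) + w)
  cols <- max(1, min(idx[, 2]) - w):min(d[2], max(idx[, 2]) + w)
  for (r in rows) for (c in cols) {
    if (mask[r, c]) next
    if (min((idx[, 1] - r)^2 + (idx[, 2] - c)^2) <= width^2)
      out[r, c] <- TRUE
  }
  out
}

pixel_distances <- function(mask, free_idx, geom) {
  idx <- which(mask, arr.ind = TRUE)
  fr <- ((free_idx - 1) %% geom[1]) + 1
  fc <- ((free_idx - 1) %/% geom[1]) + 1
  vapply(seq_along(free_idx), function(i)
    min((idx[, 1] - fr[i])^2 + (idx[, 2] - fc[i])^2), numeric(1))
}

#' Normalized fluorescence change (dF/F) from a raw trace
#'
#' F0 is a rolling low percentile of the raw trace (evaluated on a strided
#' grid and linearly interpolated, which is equivalent to the dense rolling
#' percentile for slow baselines), floored at a small positive epsilon.
#'
#' @param raw Raw fluorescence trace.
#' @param frame_rate Imaging rate, Hz.
#' @param baseline_window Rolling window, seconds (>= 10).
#' @param baseline_percentile Percentile (0-100) defining F0.
#' @param eps Floor for F0.
#' @return dF/F trace, same length as `raw`.
#' @export
compute_dff <- function(raw, frame_rate = 15.5, baseline_window = 60,
                        baseline_percentile = 20, eps = 1e-6) {
  if (baseline_window * frame_rate < 10) stop("baseline window too short")
  n <- length(raw)
  if (all(raw == 0)) {
    warning("all-zero raw trace")
    return(numeric(n))
  }
  w <- min(n, round(baseline_window * frame_rate))
  stride <- max(1, floor(w / 4))
  centers <- unique(c(seq(1, n, by = stride), n))
  f0g <- vapply(centers, function(i) {
    lo <- max(1, i - w %/% 2); hi <- min(n, i + w %/% 2)
    stats::quantile(raw[lo:hi], baseline_percentile / 100, names = FALSE)
  }, numeric(1))
  f0 <- stats::approx(centers, f0g, xout = seq_len(n), rule = 2)$y
  f0 <- pmax(f0, eps)
  (raw - f0) / f0
}

#' Infer a nonnegative spike rate from a dF/F trace
#'
#' A causal first-difference deconvolver for slow indicators: the trace is
#' lightly smoothed with a trailing moving average, differenced, rectified
#' at zero, and thresholded at `threshold` robust standard deviations
#' (1.4826 * MAD) of the differenced trace. The output scale is arbitrary
#' but monotone in the underlying spike count, which is all the downstream
#' reverse-correlation analysis uses.
#'
#' @param dff dF/F trace (finite).
#' @param smoothing Trailing moving-average width, frames.
#' @param threshold Threshold in robust SDs of the differenced noise.
#' @return Inferred spike rate per frame (>= 0), same length as `dff`.
#' @export
infer_spike_rate <- function(dff, smoothing = 3, threshold = 2) {
  if (any(!is.finite(dff))) stop("dff contains non-finite samples")
  n <- length(dff)
  if (n == 0) return(numeric(0))
  sm <- if (smoothing > 1) {
    as.numeric(stats::filter(dff, rep(1 / smoothing, smoothing),
                             sides = 1))
  } else dff
  sm[is.na(sm)] <- dff[is.na(sm)]
  d <- c(0, diff(sm))
  d[d < 0] <- 0
  sdr <- stats::mad(diff(sm))
  if (sdr > 0) d[d < threshold * sdr] <- 0
  d
}

#' Inferred spike rates for every neuron of a session
#'
#' @param session A `synthetic_session` (or any list with `dff` matrices).
#' @param smoothing,threshold Passed to [infer_spike_rate()].
#' @return Named list of frames x neurons ISR matrices per eye.
#' @export
session_isr <- function(session, smoothing = 3, threshold = 2) {
  lapply(session$dff, function(m)
    apply(m, 2, infer_spike_rate, smoothing = smoothing,
          threshold = threshold))
}
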