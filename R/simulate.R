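#' Orientation tuning gain (von Mises on the doubled angle)
#'
#' Gain in [0, 1], equal to 1 at the preferred orientation. Orientation is a
#' 180-degree circular variable, so the angle is doubled before applying the
#' von Mises profile: exp(kappa * (cos(2 * dtheta) - 1)).
#'
#' @param ori,pref_ori Orientations in degrees.
#' @param kappa Concentration (unitless, >= 0).
#' @return Gain values in [0, 1].
#' @export
von_mises_gain <- function(ori, pref_ori, kappa) {
  exp(kappa * (cos(2 * (ori - pref_ori) * pi / 180) - 1))
}

#' Spatial-frequency tuning gain (log-Gaussian)
#'
#' Gain in [0, 1], equal to 1 at the preferred SF; width is measured in
#' octaves on the log2 axis.
#'
#' @param sf,pref_sf Spatial frequencies, cpd.
#' @param sigma_oct Tuning SD in octaves.
#' @return Gain values in [0, 1].
#' @export
log_gauss_gain <- function(sf, pref_sf, sigma_oct) {
  exp(-(log2(sf / pref_sf))^2 / (2 * sigma_oct^2))
}

#' Simulate a two-eye imaging session from a ground-truth population
#'
#' Forward model: for every presentation, a neuron emits Poisson spikes with
#' mean `a_eye * von_mises_gain(ori) * log_gauss_gain(sf)` (zero for blanks
#' and for the unresponsive eye), placed at a visual-response lag drawn
#' uniformly from 4-9 frames after stimulus onset. Baseline Poisson spikes
#' (`baseline_rate` per frame) are added, the spike train is convolved with
#' a single-exponential GCaMP6s-like calcium kernel (amplitude 1 dF/F per
#' spike, decay `kernel_tau`), and Gaussian trace noise of SD `noise_sd` is
#' superimposed. The ground truth is retained for parameter-recovery tests.
#'
#' @param pop Population from [sample_population()].
#' @param schedules Named list with elements `contra` and `ipsi`, each a
#'   [make_stimulus_schedule()] result with identical frame counts.
#' @param kernel_tau Calcium decay time constant, seconds.
#' @param seed Integer RNG seed.
#' @return A `synthetic_session`: list with `pop`, `schedules`, `dff`
#'   (named list of frames x neurons matrices per eye), `frame_rate`,
#'   `n_frames`, `seed`.
#' @export
simulate_session <- function(pop, schedules, kernel_tau = 1.6, seed) {
  if (!all(c("contra", "ipsi") %in% names(schedules)))
    stop("schedules must cover both eyes (contra, ipsi)")
  if (kernel_tau <= 0) stop("kernel_tau must be > 0")
  if (missing(seed)) stop("seed is required")
  nf_c <- schedules$contra$n_frames
  if (nf_c != schedules$ipsi$n_frames)
    stop("mismatched schedule frame counts")
  fr <- schedules$contra$frame_rate
  decay <- exp(-1 / (kernel_tau * fr))
  dff <- list()
  withr_seed(seed, {
    for (eye in c("contra", "ipsi")) {
      amp <- if (eye == "contra") pop$a_C else pop$a_I
      pref <- if (eye == "contra") pop$pref_ori else pop$pref_ori_I
      dff[[eye]] <- simulate_eye_dff(pop, amp, pref, schedules[[eye]],
                                     decay, nf_c)
    }
  })
  structure(list(pop = pop, schedules = schedules, dff = dff,
                 frame_rate = fr, n_frames = nf_c, seed = seed),
            class = "synthetic_session")
}

# one eye's dF/F matrix (frames x neurons); assumes RNG state is set
simulate_eye_dff <- function(pop, amp, pref_ori, schedule, decay, nf) {
  ev <- schedule$events
  n <- nrow(pop)
  ne <- nrow(ev)
  spikes <- matrix(0, nf, n)
  live <- which(amp > 0)
  if (length(live) && ne) {
    nb <- which(!ev$is_blank)
    ogain <- von_mises_gain(
      matrix(ev$orientation[nb], length(nb), length(live)),
      matrix(pref_ori[live], length(nb), length(live), byrow = TRUE),
      matrix(pop$kappa_ori[live], length(nb), length(live), byrow = TRUE))
    sgain <- log_gauss_gain(
      matrix(ev$sf[nb], length(nb), length(live)),
      matrix(pop$pref_sf[live], length(nb), length(live), byrow = TRUE),
      matrix(pop$sigma_sf[live], length(nb), length(live), byrow = TRUE))
    lam <- ogain * sgain *
      matrix(amp[live], length(nb), length(live), byrow = TRUE)
    cnt <- matrix(stats::rpois(length(lam), lam), nrow(lam), ncol(lam))
    lag <- matrix(sample(4:9, length(lam), replace = TRUE),
                  nrow(lam), ncol(lam))
    fidx <- matrix(ev$onset_frame[nb], length(nb), length(live)) + lag
    for (jj in seq_along(live)) {
      keep <- cnt[, jj] > 0 & fidx[, jj] <= nf
      if (!any(keep)) next
      agg <- rowsum(cnt[keep, jj], fidx[keep, jj])
      spikes[as.integer(rownames(agg)), live[jj]] <-
        spikes[as.integer(rownames(agg)), live[jj]] + agg
    }
  }
  base <- matrix(stats::rpois(nf * n, rep(pop$baseline_rate, each = nf)),
                 nf, n)
  spikes <- spikes + base
  dff <- apply(spikes, 2, function(s)
    as.numeric(stats::filter(s, decay, method = "recursive")))
  noise <- matrix(stats::rnorm(nf * n, 0, rep(pop$noise_sd, each = nf)),
                  nf, n)
  dff + noise
}

#' Circular disk ROI masks for a population
#'
#' @param pop Population with centroids `cx`, `cy`.
#' @param geometry Image size, c(rows, cols).
#' @param radius Disk radius in pixels.
#' @return List of logical matrices (one mask per neuron).
#' @export
population_masks <- function(pop, geometry = c(256, 256), radius = 3) {
  lapply(seq_len(nrow(pop)), function(i) {
    m <- matrix(FALSE, geometry[1], geometry[2])
    rr <- round(pop$cy[i]); cc <- round(pop$cx[i])
    for (dr in -radius:radius) for (dc in -radius:radius) {
      if (dr^2 + dc^2 <= radius^2) {
        r <- rr + dr; c <- cc + dc
        if (r >= 1 && r <= geometry[1] && c >= 1 && c <= geometry[2])
          m[r, c] <- TRUE
      }
    }
    m
  })
}

#' Render a toy movie from a synthetic session
#'
#' Builds a small frame stack in which each ROI's pixels carry that neuron's
#' dF/F trace (plus the ambient neuropil level and optional pixel noise) and
#' all other pixels carry the neuropil level alone. Exercises ROI trace
#' extraction end to end.
#'
#' @param session A `synthetic_session`.
#' @param eye Which eye's traces to render.
#' @param geometry Image size, c(rows, cols).
#' @param neuropil_level Constant neuropil signal added everywhere.
#' @param pixel_noise_sd Per-pixel Gaussian noise SD.
#' @param radius ROI disk radius, pixels.
#' @param frames Optional frame subset (indices) to render.
#' @param seed Integer RNG seed.
#' @return List with `movie` (array rows x cols x frames) and `masks`
#'   (list of logical matrices).
#' @export
render_toy_movie <- function(session, eye = "contra", geometry = c(64, 64),
                             neuropil_level = 0, pixel_noise_sd = 0,
                             radius = 3, frames = NULL, seed = 1) {
  masks <- population_masks(session$pop, geometry, radius)
  overlap <- Reduce(`+`, lapply(masks, function(m) m * 1L))
  if (any(overlap > 1L)) stop("ground-truth ROI masks overlap")
  if (is.null(frames)) frames <- seq_len(session$n_frames)
  tr <- session$dff[[eye]][frames, , drop = FALSE]
  nf <- length(frames)
  movie <- array(neuropil_level, c(geometry[1], geometry[2], nf))
  for (i in seq_along(masks)) {
    px <- which(masks[[i]])
    if (!length(px)) next
    for (t in seq_len(nf)) {
      movie[(t - 1) * prod(geometry) + px] <-
        neuropil_level + tr[t, i]
    }
  }
  if (pixel_noise_sd > 0) {
    withr_seed(seed, {
      movie <- movie + array(stats::rnorm(length(movie), 0, pixel_noise_sd),
                             dim(movie))
    })
  }
  list(movie = movie, masks = masks)
}
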