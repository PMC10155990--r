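#' Spatial-frequency grid on a logarithmic (half-octave) scale
#'
#' Builds the geometric sequence of spatial frequencies used for the grating
#' battery: `sf_min * step^k` for `k = 0 .. n_steps - 1`. The default battery
#' spans 0.028 to 0.48 cycles per degree (cpd) in 8 steps of x1.5
#' (half-octave spacing, since log2(1.5) ~ 0.585).
#'
#' @param sf_min Lowest spatial frequency, cpd.
#' @param n_steps Number of grid values (>= 1).
#' @param step Multiplicative step between successive values.
#' @return Numeric vector of length `n_steps`, in cpd.
#' @export
#' @examples
#' build_sf_grid()                 # the default 8-value battery
#' round(build_sf_grid()[8], 2)    # 0.48
build_sf_grid <- function(sf_min = 0.028, n_steps = 8, step = 1.5) {
  if (!is.numeric(sf_min) || sf_min <= 0) stop("sf_min must be > 0")
  if (n_steps < 1) stop("n_steps must be >= 1")
  if (!is.numeric(step) || step <= 0) stop("step must be > 0")
  sf_min * step^(seq_len(n_steps) - 1)
}

#' Default orientation grid: 0 to 150 degrees in 30-degree steps
#' @return Numeric vector of 6 orientations in degrees.
#' @export
ori_grid_default <- function() seq(0, 150, by = 30)

#' Default spatial-phase grid: 0 to 315 degrees in 45-degree steps
#' @return Numeric vector of 8 phases in degrees.
#' @export
phase_grid_default <- function() seq(0, 315, by = 45)

#' Random grating presentation schedule for one eye
#'
#' Draws `round(duration * stim_rate)` independent presentations, each a
#' uniformly random combination of orientation, spatial frequency, and phase.
#' The isoluminant grey screen (blank) is treated as a ninth level of the SF
#' axis with the same draw probability as each SF, so the draw space has
#' 6 orientations x 9 SF levels (x 8 phases for non-blank events). Event k
#' (1-based) onsets at frame `round(k * frame_rate / stim_rate)`, mirroring
#' hardware time-stamping of each stimulus transition to an acquisition
#' frame; at the defaults (15.5 Hz imaging, 4 Hz stimulation) successive
#' onsets are 3.875 frames apart before rounding.
#'
#' @param duration Session length in seconds.
#' @param stim_rate Presentation rate, Hz.
#' @param frame_rate Imaging frame rate, Hz.
#' @param eye `"contra"` or `"ipsi"`.
#' @param ori_grid,sf_grid,phase_grid Stimulus grids (degrees, cpd, degrees).
#' @param include_blank Include the grey-screen blank as a ninth SF level?
#' @param seed Integer RNG seed (required; schedules are reproducible).
#' @return A `stim_schedule`: list with `eye`, `frame_rate`, `stim_rate`,
#'   `duration`, `n_frames`, and `events` (data.frame with columns
#'   `onset_frame`, `orientation`, `sf`, `phase`, `is_blank`; orientation,
#'   sf and phase are `NA` for blank events).
#' @export
make_stimulus_schedule <- function(duration = 600, stim_rate = 4,
                                   frame_rate = 15.5, eye = c("contra", "ipsi"),
                                   ori_grid = ori_grid_default(),
                                   sf_grid = build_sf_grid(),
                                   phase_grid = phase_grid_default(),
                                   include_blank = TRUE, seed) {
  eye <- match.arg(eye)
  if (duration <= 0) stop("duration must be > 0")
  if (stim_rate <= 0 || frame_rate <= 0) stop("rates must be > 0")
  if (!length(ori_grid) || !length(sf_grid) || !length(phase_grid))
    stop("stimulus grids must be non-empty")
  if (missing(seed)) stop("seed is required")

  n_events <- round(duration * stim_rate)
  withr_seed(seed, {
    onset <- round(seq_len(n_events) * frame_rate / stim_rate)
    # blank is a ninth SF level with the same draw probability as each SF
    sf_lev <- sample.int(length(sf_grid) + include_blank, n_events,
                         replace = TRUE)
    blank <- include_blank & sf_lev > length(sf_grid)
    ori <- ori_grid[sample.int(length(ori_grid), n_events, replace = TRUE)]
    phs <- phase_grid[sample.int(length(phase_grid), n_events, replace = TRUE)]
    sf <- ifelse(blank, NA_real_, sf_grid[pmin(sf_lev, length(sf_grid))])
    ori[blank] <- NA_real_
    phs[blank] <- NA_real_
    events <- data.frame(onset_frame = onset, orientation = ori, sf = sf,
                         phase = phs, is_blank = blank)
  })
  structure(list(eye = eye, frame_rate = frame_rate, stim_rate = stim_rate,
                 duration = duration,
                 n_frames = ceiling(duration * frame_rate),
                 ori_grid = ori_grid, sf_grid = sf_grid, events = events),
            class = "stim_schedule")
}

#' @export
print.stim_schedule <- function(x, ...) {
  cat(sprintf("<stim_schedule> eye=%s, %d events, %.0f s @ %.1f Hz stim / %.1f Hz imaging\n",
              x$eye, nrow(x$events), x$duration, x$stim_rate, x$frame_rate))
  invisible(x)
}

#' Write/read a stimulus schedule as TSV
#'
#' Columns: onset_frame, eye, orientation_deg, sf_cpd, phase_deg, is_blank.
#' @param schedule A `stim_schedule`.
#' @param path Output file path.
#' @export
write_schedule_tsv <- function(schedule, path) {
  ev <- schedule$events
  out <- data.frame(onset_frame = ev$onset_frame, eye = schedule$eye,
                    orientation_deg = ev$orientation, sf_cpd = ev$sf,
                    phase_deg = ev$phase, is_blank = ev$is_blank)
  utils::write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

# run code under a local RNG seed without disturbing the caller's RNG state
withr_seed <- function(seed, code) {
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  eval.parent(substitute(code))
}
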