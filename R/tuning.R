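#' Preferred stimulus cell of a response tensor
#'
#' Argmax of mean ISR over the orientation x SF grid (blank excluded) at the
#' optimal delay; ties break toward the lower orientation index, then the
#' lower SF index.
#'
#' @param tensor A `resp_tensor`.
#' @param delay Optimal delay (frame offset).
#' @return List with `ori_idx`, `sf_idx`, `ori` (degrees), `sf` (cpd), or
#'   `NULL` when the grid carries no positive response (the neuron is then
#'   demoted to nonresponsive by callers).
#' @export
preferred_stimulus <- function(tensor, delay) {
  di <- match(delay, tensor$delays)
  grid <- tensor$mean_isr[di, , seq_along(tensor$sf_grid)]
  grid[!is.finite(grid)] <- -Inf
  if (all(grid <= 0)) {
    warning("all-zero response grid; neuron demoted to nonresponsive")
    return(NULL)
  }
  # column-major which.max: orientation index varies fastest -> lower
  # orientation, then lower SF, wins ties
  k <- which.max(grid)
  oi <- (k - 1L) %% nrow(grid) + 1L
  si <- (k - 1L) %/% nrow(grid) + 1L
  list(ori_idx = oi, sf_idx = si, ori = tensor$ori_grid[oi],
       sf = tensor$sf_grid[si])
}

#' Preferred orientation by complex vector average
#'
#' Half the argument of the resultant sum O_n * exp(i * 2 * pi * theta_n /
#' 180) over the six sampled orientations, converted to degrees and wrapped
#' into [0, 180). O_n is the z-score tuning row; negative entries are
#' floored at zero so the resultant is a proper weighted average.
#'
#' @param O_n Numeric weights (z-scores) at the sampled orientations.
#' @param theta_n Sampled orientations, degrees.
#' @return Preferred orientation in degrees, or `NA` when the resultant
#'   vector is (numerically) zero.
#' @export
preferred_orientation <- function(O_n, theta_n = ori_grid_default()) {
  if (length(O_n) != length(theta_n)) stop("O_n/theta_n length mismatch")
  if (any(!is.finite(O_n))) stop("O_n must be finite")
  w <- pmax(O_n, 0)
  v <- sum(w * exp(1i * 2 * pi * theta_n / 180))
  if (Mod(v) < 1e-12 * max(sum(w), 1)) return(NA_real_)
  wrap180(Arg(v) / 2 * 180 / pi)
}

#' Preferred spatial frequency by clipped log-weighted mean
#'
#' Tail entries of the SF tuning curve are clipped: walking outward from
#' the peak, entries are zeroed once they fall below `clip` times the peak
#' (interior dips above the clip level are retained). The preferred SF is
#' then 10^(sum(Sf_k * log10(omega_k)) / sum(Sf_k)) over the surviving
#' entries. Negative z-scores are floored at zero.
#'
#' @param Sf_k Numeric weights (z-scores) at the sampled SFs.
#' @param omega_k Sampled SFs, cpd.
#' @param clip Clip level as a fraction of the peak (default 0.25).
#' @return Preferred SF in cpd, or `NA` when everything is clipped.
#' @export
preferred_sf <- function(Sf_k, omega_k = build_sf_grid(), clip = 0.25) {
  if (length(Sf_k) != length(omega_k)) stop("Sf_k/omega_k length mismatch")
  if (any(!is.finite(Sf_k))) stop("Sf_k must be finite")
  w <- pmax(Sf_k, 0)
  if (max(w) <= 0) return(NA_real_)
  pk <- which.max(w)
  thr <- clip * w[pk]
  keep <- rep(TRUE, length(w))
  if (pk < length(w)) {
    below <- which(w < thr & seq_along(w) > pk)
    if (length(below)) keep[min(below):length(w)] <- FALSE
  }
  if (pk > 1) {
    below <- which(w < thr & seq_along(w) < pk)
    if (length(below)) keep[1:max(below)] <- FALSE
  }
  w[!keep] <- 0
  if (sum(w) <= 0) return(NA_real_)
  10^(sum(w * log10(omega_k)) / sum(w))
}

#' Full width at half maximum of an orientation tuning curve
#'
#' Linear interpolation between the six sampled orientations on the
#' circular 180-degree axis. When the curve never falls below half its
#' maximum the width is capped at 180 degrees and flagged.
#'
#' @param curve Tuning values (z-scores) at `theta`.
#' @param theta Sampled orientations, degrees.
#' @return List with `fwhm` (degrees) and `capped` (logical).
#' @export
orientation_fwhm <- function(curve, theta = ori_grid_default()) {
  w <- pmax(curve, 0)
  pk <- which.max(w)
  half <- w[pk] / 2
  n <- length(w)
  if (w[pk] <= 0 || all(w >= half)) return(list(fwhm = 180, capped = TRUE))
  step <- 180 / n
  cross <- function(dir) {
    # walk from the peak in direction dir until the curve crosses half-max
    for (k in seq_len(n)) {
      i0 <- (pk - 1 + dir * (k - 1)) %% n + 1
      i1 <- (pk - 1 + dir * k) %% n + 1
      if (w[i1] < half) {
        frac <- (w[i0] - half) / (w[i0] - w[i1])
        return((k - 1 + frac) * step)
      }
    }
    180 / 2
  }
  up <- cross(1L)
  dn <- cross(-1L)
  fwhm <- min(up + dn, 180)
  list(fwhm = fwhm, capped = fwhm >= 180)
}

#' Full width at half maximum of an SF tuning curve, in octaves
#'
#' As [orientation_fwhm()] but on the non-circular log2 SF axis; the width
#' is capped at the grid span when a flank never crosses half-max.
#'
#' @param curve Tuning values (z-scores) at `omega`.
#' @param omega Sampled SFs, cpd.
#' @return List with `fwhm` (octaves) and `capped` (logical).
#' @export
sf_fwhm <- function(curve, omega = build_sf_grid()) {
  w <- pmax(curve, 0)
  x <- log2(omega)
  pk <- which.max(w)
  half <- w[pk] / 2
  n <- length(w)
  span <- x[n] - x[1]
  if (w[pk] <= 0) return(list(fwhm = span, capped = TRUE))
  capped <- FALSE
  right <- {
    r <- x[n] - x[pk]
    found <- FALSE
    for (i in pk:(n - 1)) {
      if (pk == n) break
      if (w[i + 1] < half) {
        frac <- (w[i] - half) / (w[i] - w[i + 1])
        r <- (x[i] - x[pk]) + frac * (x[i + 1] - x[i])
        found <- TRUE
        break
      }
    }
    if (!found) capped <- TRUE
    r
  }
  left <- {
    l <- x[pk] - x[1]
    found <- FALSE
    for (i in pk:2) {
      if (pk == 1) break
      if (w[i - 1] < half) {
        frac <- (w[i] - half) / (w[i] - w[i - 1])
        l <- (x[pk] - x[i]) + frac * (x[i] - x[i - 1])
        found <- TRUE
        break
      }
    }
    if (!found) capped <- TRUE
    l
  }
  list(fwhm = min(left + right, span), capped = capped)
}

#' Per-SF response significance versus blank
#'
#' Kruskal-Wallis test across the 8 SF groups plus blank, followed by
#' Dunn's post-hoc comparison of each SF against the blank with a
#' Bonferroni-style correction for the 8 comparisons. An SF is significant
#' when its corrected P < `alpha`. Groups with fewer than `min_n`
#' presentations are marked not assessable (`NA`).
#'
#' @param sf_samples List of 8 numeric vectors: per-presentation ISR values
#'   at each SF (pooled over orientations).
#' @param blank_samples Numeric vector of per-presentation ISR values for
#'   the blank.
#' @param alpha Significance level on the corrected P value.
#' @param min_n Minimum presentations per group.
#' @return Logical vector of length 8 (`NA` where not assessable), with
#'   attribute `p_corrected`.
#' @export
sf_significance <- function(sf_samples, blank_samples, alpha = 0.01,
                            min_n = 5) {
  k <- length(sf_samples)
  ok <- vapply(sf_samples, length, integer(1)) >= min_n
  res <- rep(NA, k)
  pc <- rep(NA_real_, k)
  if (length(blank_samples) < min_n || !any(ok)) {
    attr(res, "p_corrected") <- pc
    return(res)
  }
  groups <- c(sf_samples[ok], list(blank = blank_samples))
  x <- unlist(groups, use.names = FALSE)
  g <- rep(seq_along(groups), lengths(groups))
  n_tot <- length(x)
  r <- rank(x)
  rbar <- tapply(r, g, mean)
  nn <- tabulate(g)
  # tie-corrected variance term of Dunn's z statistic
  ties <- table(x)
  tie_term <- sum(ties^3 - ties) / (12 * (n_tot - 1))
  v0 <- n_tot * (n_tot + 1) / 12 - tie_term
  nb <- length(groups)
  z <- (rbar[seq_len(nb - 1)] - rbar[nb]) /
    sqrt(v0 * (1 / nn[seq_len(nb - 1)] + 1 / nn[nb]))
  p <- 2 * stats::pnorm(-abs(z))
  pc[ok] <- pmin(1, p * 8)  # Dunn's correction for 8 comparisons
  res[ok] <- pc[ok] < alpha & rbar[seq_len(nb - 1)] > rbar[nb]
  attr(res, "p_corrected") <- pc
  res
}

#' Per-presentation ISR samples by SF (and for the blank)
#'
#' Pools, over all orientations, the ISR values at `onset + delay` for each
#' SF level, and separately for blank presentations.
#'
#' @param isr Inferred spike-rate trace.
#' @param schedule A `stim_schedule`.
#' @param delay Optimal delay, frames.
#' @return List with `sf_samples` (list of 8 vectors) and `blank_samples`.
#' @export
isr_samples_by_sf <- function(isr, schedule, delay) {
  ev <- schedule$events
  fr <- ev$onset_frame + delay
  inr <- fr >= 1 & fr <= length(isr)
  sf_samples <- lapply(schedule$sf_grid, function(s)
    isr[fr[inr & !ev$is_blank & ev$sf == s]])
  blank_samples <- isr[fr[inr & ev$is_blank]]
  list(sf_samples = sf_samples, blank_samples = blank_samples)
}

#' Mean baseline-corrected dF/F response to the preferred stimulus
#'
#' Average dF/F at `onset + delay` over presentations of the preferred
#' condition, minus the average dF/F over the pre-onset frames (-2..0) of
#' the same presentations; floored at zero. This is the response-strength
#' quantity entering the ocular dominance index.
#'
#' @param dff dF/F trace.
#' @param schedule A `stim_schedule`.
#' @param pref_ori,pref_sf Preferred condition (grid values).
#' @param delay Optimal delay, frames.
#' @return Mean evoked dF/F (>= 0).
#' @export
dff_at_preferred <- function(dff, schedule, pref_ori, pref_sf, delay) {
  ev <- schedule$events
  sel <- which(!ev$is_blank & ev$orientation == pref_ori & ev$sf == pref_sf)
  on <- ev$onset_frame[sel]
  on <- on[on + delay <= length(dff) & on - 2 >= 1]
  if (!length(on)) return(0)
  evoked <- mean(dff[on + delay])
  pre <- mean(dff[c(on - 2, on - 1, on)])
  max(evoked - pre, 0)
}
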