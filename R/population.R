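#' Default ocular-dominance category composition
#'
#' Category proportions for a simulated population including nonresponsive
#' (NR) neurons. The responsive portion follows the ratio 294:243:120 of
#' monocular-contralateral (C), binocular (B), and monocular-ipsilateral (I)
#' neurons in healthy critical-period binocular V1, and about half of all
#' segmented somata are taken to be visually nonresponsive.
#'
#' @param nr_fraction Fraction of the population that is nonresponsive.
#' @return Named numeric vector over c(C, B, I, NR) summing to 1.
#' @export
default_composition <- function(nr_fraction = 0.5) {
  resp <- c(C = 294, B = 243, I = 120) / (294 + 243 + 120)
  c(resp * (1 - nr_fraction), NR = nr_fraction)
}

#' Default tuning priors for simulated neurons
#'
#' @return List of prior parameters: log-normal response amplitude
#'   (`amp_meanlog`, `amp_sdlog`, in expected spikes per preferred
#'   presentation), von Mises orientation concentration `kappa_ori`,
#'   log-Gaussian SF tuning width `sigma_sf_oct` (octaves), baseline firing
#'   `baseline_rate` (spikes/frame), trace noise `noise_sd` (dF/F units),
#'   and `ipsi_ori_sd` / `recruit_ori_sd` (degrees), the circular scatter of
#'   a binocular neuron's ipsilateral orientation preference around its
#'   contralateral one, for developmentally matched and newly recruited
#'   binocular neurons respectively.
#' @export
default_tuning_priors <- function() {
  list(amp_meanlog = log(2), amp_sdlog = 0.35,
       kappa_ori = 2.5, sigma_sf_oct = 0.9,
       baseline_rate = 0.02, noise_sd = 0.08,
       ipsi_ori_sd = 30, recruit_ori_sd = 40)
}

#' Sample a ground-truth neuron population
#'
#' Each neuron receives a category drawn from `composition`, per-eye response
#' amplitudes consistent with that category, an orientation preference
#' uniform on [0, 180), and an SF preference log-uniform over the span of
#' `sf_grid`. Binocular neurons' ipsilateral orientation preference equals
#' the contralateral one plus wrapped Gaussian noise of SD
#' `priors$ipsi_ori_sd` degrees (binocular matching); the ipsilateral SF
#' preference is shared. Centroids are laid out on a jittered grid so that
#' ROI masks never overlap.
#'
#' @param n Number of neurons (>= 0).
#' @param composition Probabilities over c(C, B, I, NR); must sum to 1.
#' @param priors Tuning priors, see [default_tuning_priors()].
#' @param sf_grid SF battery, cpd.
#' @param seed Integer RNG seed.
#' @param fov Field-of-view size in pixels, c(rows, cols).
#' @return data.frame with one row per neuron: id, cx, cy, category, a_C,
#'   a_I, pref_ori, pref_ori_I, kappa_ori, pref_sf, sigma_sf, baseline_rate,
#'   noise_sd.
#' @export
sample_population <- function(n, composition = default_composition(),
                              priors = default_tuning_priors(),
                              sf_grid = build_sf_grid(), seed,
                              fov = c(256, 256)) {
  if (n < 0) stop("n must be >= 0")
  if (abs(sum(composition) - 1) > 1e-8) stop("composition must sum to 1")
  if (missing(seed)) stop("seed is required")
  cats <- c("C", "B", "I", "NR")
  if (is.null(names(composition))) names(composition) <- cats
  if (n == 0) {
    return(data.frame(id = integer(), cx = numeric(), cy = numeric(),
                      category = character(), a_C = numeric(),
                      a_I = numeric(), pref_ori = numeric(),
                      pref_ori_I = numeric(), kappa_ori = numeric(),
                      pref_sf = numeric(), sigma_sf = numeric(),
                      baseline_rate = numeric(), noise_sd = numeric()))
  }
  withr_seed(seed, {
    category <- sample(cats, n, replace = TRUE, prob = composition[cats])
    amp <- function(k) stats::rlnorm(k, priors$amp_meanlog, priors$amp_sdlog)
    a_C <- ifelse(category %in% c("C", "B"), amp(n), 0)
    a_I <- ifelse(category %in% c("I", "B"), amp(n), 0)
    pref_ori <- stats::runif(n, 0, 180)
    pref_ori_I <- ifelse(
      category == "B",
      wrap180(pref_ori + stats::rnorm(n, 0, priors$ipsi_ori_sd)),
      ifelse(category == "I", stats::runif(n, 0, 180), pref_ori))
    lsf <- range(log2(sf_grid))
    pref_sf <- 2^stats::runif(n, lsf[1], lsf[2])
    # jittered grid layout keeps masks disjoint
    side <- ceiling(sqrt(n))
    pitch <- floor(min(fov) / (side + 1))
    if (pitch < 8) pitch <- 8
    idx <- seq_len(n) - 1
    cx <- (idx %% side + 1) * pitch + stats::runif(n, -1, 1)
    cy <- (idx %/% side + 1) * pitch + stats::runif(n, -1, 1)
    pop <- data.frame(id = seq_len(n), cx = cx, cy = cy, category = category,
                      a_C = a_C, a_I = a_I, pref_ori = pref_ori,
                      pref_ori_I = pref_ori_I,
                      kappa_ori = priors$kappa_ori, pref_sf = pref_sf,
                      sigma_sf = priors$sigma_sf_oct,
                      baseline_rate = priors$baseline_rate,
                      noise_sd = priors$noise_sd)
  })
  pop
}

#' Wrap angles into [0, 180)
#' @param x Angles in degrees.
#' @return Angles wrapped into the half-circle.
#' @export
wrap180 <- function(x) ((x %% 180) + 180) %% 180
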