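#' Default monocular-deprivation transition model
#'
#' A 4x4 stochastic matrix over the ocular-dominance categories
#' {C, B, I, NR} describing category changes over 4 days of contralateral-eye
#' deprivation during the critical period, together with response-amplitude
#' rescaling and a matching-dependent binocular-to-monocular rule. The
#' matrix is calibrated so that, applied to a healthy critical-period
#' population (about 294 C : 243 B : 120 I responsive neurons plus an equal
#' number of nonresponsive ones), the post-deprivation marginals show the
#' hallmark collapse of the contralateral bias: C and I counts become nearly
#' equal while the binocular pool is roughly preserved.
#'
#' `amp_scale_C` models the depression of deprived-eye response strength;
#' `amp_scale_I = 1` leaves nondeprived-eye strength unchanged.
#' `matching_loss_slope` (per degree) tilts the split between losing the
#' ipsilateral eye (B to C) and losing the deprived contralateral eye
#' (B to I): binocular neurons that were better matched for orientation
#' before deprivation are more likely to lose the deprived eye.
#'
#' @param amp_scale_C Multiplier on contralateral amplitude after MD.
#' @param amp_scale_I Multiplier on ipsilateral amplitude after MD.
#' @param matching_loss_slope Shift of P(B->I) per degree of pre-MD
#'   orientation mismatch below/above the reference mismatch of 30 degrees.
#' @return An `md_model` list: `transition_probs` (rows C, B, I, NR),
#'   `amp_scale_C`, `amp_scale_I`, `matching_loss_slope`.
#' @export
default_md_model <- function(amp_scale_C = 0.65, amp_scale_I = 1,
                             matching_loss_slope = 0.004) {
  P <- rbind(
    C  = c(C = 135, B = 87, I = 40, NR = 32) / 294,
    B  = c(C = 46, B = 102, I = 62, NR = 33) / 243,
    I  = c(C = 2.4, B = 36, I = 63.6, NR = 18) / 120,
    NR = c(C = 15, B = 21, I = 28, NR = 592) / 656)
  md_model(P, amp_scale_C, amp_scale_I, matching_loss_slope)
}

#' Construct and validate an MD transition model
#' @param transition_probs 4x4 row-stochastic matrix over {C, B, I, NR}.
#' @param amp_scale_C,amp_scale_I Amplitude multipliers (>= 0).
#' @param matching_loss_slope Per-degree tilt of the B->I probability.
#' @return An `md_model` list.
#' @export
md_model <- function(transition_probs, amp_scale_C = 1, amp_scale_I = 1,
                     matching_loss_slope = 0) {
  cats <- c("C", "B", "I", "NR")
  P <- as.matrix(transition_probs)
  if (!all(dim(P) == c(4, 4))) stop("transition_probs must be 4x4")
  if (any(P < 0) || any(abs(rowSums(P) - 1) > 1e-9))
    stop("transition_probs rows must be stochastic")
  dimnames(P) <- list(cats, cats)
  if (amp_scale_C < 0 || amp_scale_I < 0) stop("amplitude scales must be >= 0")
  structure(list(transition_probs = P, amp_scale_C = amp_scale_C,
                 amp_scale_I = amp_scale_I,
                 matching_loss_slope = matching_loss_slope),
            class = "md_model")
}

#' Apply a monocular-deprivation perturbation to a population
#'
#' Each neuron's category is redrawn from its row of the transition matrix.
#' For binocular neurons the B->I probability is increased (and B->C
#' decreased) by `matching_loss_slope * (30 - delta_ori)` degrees of pre-MD
#' orientation mismatch, clamped so the row stays stochastic: well-matched
#' binocular neurons preferentially lose the deprived contralateral eye.
#' Amplitudes are rescaled by `amp_scale_C` / `amp_scale_I`; neurons whose
#' new category requires an eye they lacked receive a freshly drawn
#' amplitude for that eye, and newly binocular neurons draw a new
#' second-eye orientation preference with scatter `recruit_ori_sd` (worse
#' matching than developmentally binocular neurons).
#'
#' @param pop Population data.frame from [sample_population()].
#' @param model An `md_model`.
#' @param priors Tuning priors (amplitudes and recruit scatter).
#' @param seed Integer RNG seed.
#' @return Population data.frame with updated category, amplitudes and
#'   second-eye preferences.
#' @export
apply_md_transition <- function(pop, model = default_md_model(),
                                priors = default_tuning_priors(), seed) {
  if (!inherits(model, "md_model")) stop("model must be an md_model")
  if (missing(seed)) stop("seed is required")
  P <- model$transition_probs
  n <- nrow(pop)
  new <- pop
  if (n == 0) return(new)
  withr_seed(seed, {
    dori <- delta_ori(pop$pref_ori, pop$pref_ori_I)
    newcat <- character(n)
    for (i in seq_len(n)) {
      p <- P[pop$category[i], ]
      if (pop$category[i] == "B" && model$matching_loss_slope != 0) {
        shift <- model$matching_loss_slope * (30 - dori[i])
        shift <- max(-p["I"], min(p["C"], shift))
        p["I"] <- p["I"] + shift
        p["C"] <- p["C"] - shift
      }
      newcat[i] <- sample(colnames(P), 1, prob = p)
    }
    amp <- function(k) stats::rlnorm(k, priors$amp_meanlog, priors$amp_sdlog)
    a_C <- pop$a_C * model$amp_scale_C
    a_I <- pop$a_I * model$amp_scale_I
    need_C <- newcat %in% c("C", "B") & a_C <= 0
    need_I <- newcat %in% c("I", "B") & a_I <= 0
    a_C[need_C] <- amp(sum(need_C)) * model$amp_scale_C
    a_I[need_I] <- amp(sum(need_I)) * model$amp_scale_I
    a_C[!newcat %in% c("C", "B")] <- 0
    a_I[!newcat %in% c("I", "B")] <- 0
    # newly binocular neurons: fresh, more scattered second-eye preference
    new_B <- newcat == "B" & pop$category != "B"
    pref_I <- pop$pref_ori_I
    pref_C <- pop$pref_ori
    gained_I <- new_B & pop$category %in% c("C", "NR")
    gained_C <- new_B & pop$category == "I"
    pref_I[gained_I] <- wrap180(pref_C[gained_I] +
                                  stats::rnorm(sum(gained_I), 0,
                                               priors$recruit_ori_sd))
    pref_C[gained_C] <- wrap180(pref_I[gained_C] +
                                  stats::rnorm(sum(gained_C), 0,
                                               priors$recruit_ori_sd))
    new$category <- newcat
    new$a_C <- a_C
    new$a_I <- a_I
    new$pref_ori <- pref_C
    new$pref_ori_I <- pref_I
  })
  new
}
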