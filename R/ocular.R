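#' Neuronal ocular dominance index and category
#'
#' ODI = (C - I) / (C + I) on the mean dF/F for each eye's preferred
#' stimulus when the neuron is responsive to both eyes (binocular, B).
#' Neurons responsive to only one eye are monocular and assigned ODI 1
#' (contralateral, C) or -1 (ipsilateral, I); neurons responsive to neither
#' eye are nonresponsive (NR, ODI `NA`).
#'
#' @param C_dff,I_dff Mean dF/F at each eye's preferred stimulus.
#' @param responsive_C,responsive_I Per-eye responsiveness flags.
#' @return List with `odi` and `category`.
#' @export
neuron_odi <- function(C_dff, I_dff, responsive_C, responsive_I) {
  if (responsive_C && responsive_I) {
    tot <- C_dff + I_dff
    if (!is.finite(tot) || tot <= 0) {
      warning("non-positive total dF/F for a binocular neuron")
      return(list(odi = NA_real_, category = "B"))
    }
    return(list(odi = (C_dff - I_dff) / tot, category = "B"))
  }
  if (responsive_C) return(list(odi = 1, category = "C"))
  if (responsive_I) return(list(odi = -1, category = "I"))
  list(odi = NA_real_, category = "NR")
}

#' Per-mouse mean and summed ODI
#'
#' Mean ODI is the arithmetic mean of neuronal ODIs over responsive
#' neurons. Summed ODI first sums each eye's preferred-stimulus dF/F over
#' all neurons responsive to that eye and then forms (C - I) / (C + I)
#' from the two sums, weighting neurons by response strength.
#'
#' @param od data.frame with columns `odi`, `category`, `C_dff`, `I_dff`.
#' @return List with `mean_odi`, `summed_odi`, `n_responsive`.
#' @export
mouse_odi_summaries <- function(od) {
  resp <- od$category %in% c("C", "B", "I")
  if (!any(resp))
    return(list(mean_odi = NA_real_, summed_odi = NA_real_,
                n_responsive = 0L))
  mean_odi <- mean(od$odi[resp], na.rm = TRUE)
  cs <- sum(od$C_dff[od$category %in% c("C", "B")], na.rm = TRUE)
  is <- sum(od$I_dff[od$category %in% c("I", "B")], na.rm = TRUE)
  summed <- if (cs + is > 0) (cs - is) / (cs + is) else NA_real_
  list(mean_odi = mean_odi, summed_odi = summed,
       n_responsive = sum(resp))
}

#' Circular difference between two orientation preferences
#'
#' Absolute difference along the 180-degree cycle, in [0, 90].
#'
#' @param a,b Orientations in degrees; values outside [0, 180) are wrapped
#'   with a warning.
#' @return Difference in degrees.
#' @export
delta_ori <- function(a, b) {
  if (any(c(a, b) < 0 | c(a, b) >= 180, na.rm = TRUE)) {
    warning("orientations outside [0, 180) wrapped")
    a <- wrap180(a)
    b <- wrap180(b)
  }
  d <- abs(a - b)
  pmin(d, 180 - d)
}

#' ODI histogram and per-eye dF/F cumulative distributions
#'
#' Bins neuronal ODI with the monocular masses kept identifiable: interior
#' bins tile (-1, 1) and the exact values -1 and +1 occupy their own end
#' bins. Also returns the empirical CDFs of preferred-stimulus dF/F per
#' eye, ready for serialization.
#'
#' @param od data.frame with `odi`, `category`, `C_dff`, `I_dff`.
#' @param n_interior Number of interior bins on (-1, 1).
#' @return List with `breaks`, `counts` (length `n_interior + 2`), and
#'   `cdf` (list per eye of sorted dF/F values and cumulative fractions).
#' @export
odi_distributions <- function(od, n_interior = 7) {
  resp <- od$category %in% c("C", "B", "I")
  if (!any(resp)) stop("no responsive neurons")
  odi <- od$odi[resp]
  breaks <- seq(-1, 1, length.out = n_interior + 1)
  interior <- odi > -1 & odi < 1
  cnt_int <- tabulate(pmin(findInterval(odi[interior], breaks,
                                        rightmost.closed = TRUE),
                           n_interior), nbins = n_interior)
  counts <- c(`-1` = sum(odi == -1), stats::setNames(cnt_int,
              paste0("bin", seq_len(n_interior))), `+1` = sum(odi == 1))
  cdf_of <- function(x) {
    x <- sort(x[is.finite(x) & x > 0])
    list(value = x, cum_fraction = seq_along(x) / length(x))
  }
  list(breaks = breaks, counts = counts,
       cdf = list(contra = cdf_of(od$C_dff[od$category %in% c("C", "B")]),
                  ipsi = cdf_of(od$I_dff[od$category %in% c("I", "B")])))
}
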