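# Shared builders for small synthetic fixtures. Everything is generated in
# code at test time; seeds are fixed so runs are reproducible.

# a short two-eye schedule pair with matched frame counts
tiny_schedules <- function(duration = 120, seed = 1) {
  list(contra = make_stimulus_schedule(duration, eye = "contra",
                                       seed = seed),
       ipsi = make_stimulus_schedule(duration, eye = "ipsi",
                                     seed = seed + 1))
}

# strongly tuned, low-noise priors for recovery-style tests
strong_priors <- function() {
  p <- default_tuning_priors()
  p$amp_meanlog <- log(2.5)
  p$amp_sdlog <- 0.3
  p$noise_sd <- 0.05
  p
}

# a small analyzed session with known ground truth
tiny_analyzed <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      pop <- sample_population(40, c(C = .3, B = .3, I = .2, NR = .2),
                               strong_priors(), seed = 11)
      ses <- simulate_session(pop, tiny_schedules(300, seed = 21),
                              seed = 31)
      cache <<- list(pop = pop, session = ses,
                     analysis = analyze_session(ses))
    }
    cache
  }
})

# independent ray-casting point-in-polygon oracle (even-odd rule)
point_in_poly_oracle <- function(px, py, poly) {
  n <- nrow(poly)
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    if ((yi > py) != (yj > py) &&
        px < (xj - xi) * (py - yi) / (yj - yi) + xi)
      inside <- !inside
    j <- i
  }
  inside
}

# reference annulus for the outlier test: pixels within `width` of the mask
annulus_ref <- function(mask, width) {
  d <- dim(mask)
  idx <- which(mask, arr.ind = TRUE)
  out <- matrix(FALSE, d[1], d[2])
  for (r in seq_len(d[1])) for (c in seq_len(d[2])) {
    if (mask[r, c]) next
    if (min((idx[, 1] - r)^2 + (idx[, 2] - c)^2) <= width^2)
      out[r, c] <- TRUE
  }
  out
}
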