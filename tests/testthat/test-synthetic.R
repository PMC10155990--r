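test_that("sampled populations respect category-amplitude invariants", {
  pop <- sample_population(300, seed = 4)
  expect_true(all(pop$a_I[pop$category == "C"] == 0))
  expect_true(all(pop$a_C[pop$category == "I"] == 0))
  expect_true(all(pop$a_C[pop$category == "NR"] == 0 &
                    pop$a_I[pop$category == "NR"] == 0))
  expect_true(all(pop$a_C[pop$category == "B"] > 0 &
                    pop$a_I[pop$category == "B"] > 0))
  expect_true(all(pop$pref_ori >= 0 & pop$pref_ori < 180))
  expect_true(all(pop$pref_sf >= 0.028 & pop$pref_sf <= 0.48))
})

test_that("empty populations and fixed seeds behave deterministically", {
  expect_equal(nrow(sample_population(0, seed = 1)), 0)
  expect_identical(sample_population(50, seed = 9),
                   sample_population(50, seed = 9))
  expect_error(sample_population(10, c(C = .5, B = .6, I = 0, NR = 0),
                                 seed = 1), "sum to 1")
})

test_that("responsive-only composition reproduces the healthy C:B:I ratio", {
  comp <- c(C = 0.45, B = 0.37, I = 0.18, NR = 0)
  pop <- sample_population(657, comp, seed = 12)
  cnt <- table(factor(pop$category, c("C", "B", "I", "NR")))
  # expected ~296/243/118; allow 4 binomial SDs
  expect_lt(abs(cnt[["C"]] - 657 * 0.45), 4 * sqrt(657 * 0.45 * 0.55))
  expect_lt(abs(cnt[["B"]] - 657 * 0.37), 4 * sqrt(657 * 0.37 * 0.63))
  expect_lt(abs(cnt[["I"]] - 657 * 0.18), 4 * sqrt(657 * 0.18 * 0.82))
  expect_equal(cnt[["NR"]], 0)
})

test_that("a monocular-contra neuron's ipsi trace carries only baseline and noise", {
  pri <- default_tuning_priors()
  pri$noise_sd <- 0
  pop <- sample_population(4, c(C = 1, B = 0, I = 0, NR = 0), pri,
                           seed = 3)
  pop$baseline_rate <- 0
  ses <- simulate_session(pop, tiny_schedules(60, seed = 5), seed = 6)
  expect_true(all(ses$dff$ipsi == 0))
  expect_gt(max(ses$dff$contra), 0)
})

test_that("noiseless transients sit 4-9 frames after near-preferred presentations", {
  pri <- default_tuning_priors()
  pri$noise_sd <- 0
  pop <- sample_population(1, c(C = 1, B = 0, I = 0, NR = 0), pri,
                           seed = 7)
  pop$baseline_rate <- 0
  pop$a_C <- 8
  sch <- tiny_schedules(120, seed = 8)
  ses <- simulate_session(pop, sch, seed = 9)
  tr <- ses$dff$contra[, 1]
  onsets_of_rise <- which(diff(c(0, tr)) > 0.5)
  ev <- sch$contra$events
  ok <- vapply(onsets_of_rise, function(f) {
    lag <- f - ev$onset_frame
    any(lag >= 4 & lag <= 9 & !ev$is_blank)
  }, logical(1))
  expect_gt(length(onsets_of_rise), 3)
  expect_true(all(ok))
})

test_that("doubling the contra amplitude doubles the mean evoked response", {
  pri <- default_tuning_priors()
  pri$noise_sd <- 0.01
  mk <- function(a, seed) {
    pop <- sample_population(1, c(C = 1, B = 0, I = 0, NR = 0), pri,
                             seed = 2)
    pop$a_C <- a
    pop$baseline_rate <- 0
    pop$pref_ori <- 60
    pop$pref_sf <- 0.094
    sch <- tiny_schedules(600, seed = 14)
    ses <- simulate_session(pop, sch, seed = seed)
    ev <- sch$contra$events
    sel <- which(!ev$is_blank & ev$orientation == 60 &
                   abs(log2(ev$sf / 0.094)) < 0.3)
    mean(ses$dff$contra[ev$onset_frame[sel] + 6, 1])
  }
  m1 <- mean(vapply(1:4, function(s) mk(1, s * 11), numeric(1)))
  m2 <- mean(vapply(1:4, function(s) mk(2, s * 11), numeric(1)))
  expect_gt(m2 / m1, 1.6)
  expect_lt(m2 / m1, 2.4)
})

test_that("simulate_session rejects mismatched schedules and bad kernels", {
  pop <- sample_population(2, seed = 1)
  sch <- tiny_schedules(60, seed = 1)
  bad <- sch
  bad$ipsi <- make_stimulus_schedule(30, eye = "ipsi", seed = 2)
  expect_error(simulate_session(pop, bad, seed = 1), "frame counts")
  expect_error(simulate_session(pop, sch, kernel_tau = 0, seed = 1),
               "kernel_tau")
  expect_error(simulate_session(pop, list(contra = sch$contra), seed = 1),
               "both eyes")
})

test_that("identity MD model leaves the population unchanged", {
  pop <- sample_population(120, seed = 6)
  ident <- md_model(diag(4))
  out <- apply_md_transition(pop, ident, seed = 8)
  expect_identical(out$category, pop$category)
  expect_equal(out$a_C, pop$a_C)
  expect_equal(out$a_I, pop$a_I)
})

test_that("a forced C-to-B transition converts every contra-monocular neuron", {
  pop <- sample_population(150, seed = 16)
  P <- diag(4)
  dimnames(P) <- list(c("C", "B", "I", "NR"), c("C", "B", "I", "NR"))
  P["C", ] <- c(0, 1, 0, 0)
  out <- apply_md_transition(pop, md_model(P), seed = 17)
  wasC <- pop$category == "C"
  expect_true(all(out$category[wasC] == "B"))
  expect_true(all(out$a_I[wasC] > 0))
})

test_that("default MD model equalizes the post-MD C:I count ratio", {
  pop <- sample_population(1313, seed = 19)
  out <- apply_md_transition(pop, seed = 20)
  cnt <- table(factor(out$category, c("C", "B", "I", "NR")))
  ratio <- cnt[["C"]] / cnt[["I"]]
  expect_gt(ratio, 0.75)
  expect_lt(ratio, 1.45)
  # pre-MD contra bias was strong
  pre <- table(factor(pop$category, c("C", "B", "I", "NR")))
  expect_gt(pre[["C"]] / pre[["I"]], 2)
})

test_that("MD transition rows must be stochastic", {
  P <- diag(4) * 0.9
  expect_error(md_model(P), "stochastic")
})

test_that("toy movies round-trip traces exactly at zero noise", {
  pri <- default_tuning_priors()
  pri$noise_sd <- 0
  pop <- sample_population(3, c(C = 1, B = 0, I = 0, NR = 0), pri,
                           seed = 2, fov = c(64, 64))
  ses <- simulate_session(pop, tiny_schedules(20, seed = 3), seed = 4)
  rt <- render_toy_movie(ses, geometry = c(64, 64), neuropil_level = 0.3,
                         frames = 1:100)
  expect_equal(dim(rt$movie), c(64, 64, 100))
  expect_length(rt$masks, 3)
  expect_true(all(Reduce(`+`, lapply(rt$masks, function(m) m * 1)) <= 1))
  tr <- extract_roi_trace(rt$movie, rt$masks[[1]], rt$masks[-1])
  expect_equal(tr, ses$dff$contra[1:100, 1], tolerance = 1e-12)
})

test_that("neuropil level of zero leaves the annulus silent", {
  pri <- default_tuning_priors()
  pri$noise_sd <- 0
  pop <- sample_population(2, c(C = 1, B = 0, I = 0, NR = 0), pri,
                           seed = 2, fov = c(48, 48))
  ses <- simulate_session(pop, tiny_schedules(20, seed = 3), seed = 4)
  rt <- render_toy_movie(ses, geometry = c(48, 48), neuropil_level = 0,
                         frames = 1:10)
  occupied <- Reduce(`|`, rt$masks)
  expect_equal(median(rt$movie[, , 5][!occupied]), 0)
})
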