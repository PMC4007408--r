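make_series <- function(nf, debris, soma = TRUE, dt = 30) {
  d <- data.frame(time_min = (seq_along(nf) - 1) * dt,
                  debris_fraction = debris, n_fragments = as.integer(nf),
                  soma_alive = soma)
  class(d) <- c("event_series", "data.frame")
  d
}

test_that("lag is quantized up to the first frame after fragmentation", {
  tp <- timing_profile(100, 0, 60, 0, 4, sampling_interval = 30)
  k <- measure_wd(simulate_wd_timecourse(tp, seed = 1))
  expect_equal(k$lag_min, 120)   # first frame at or after 100 min
  # lag and clearance are always multiples of the sampling interval
  wt <- shipped_profiles$WT$timing
  for (r in 1:40) {
    k2 <- measure_wd(simulate_wd_timecourse(wt, seed = 400 + r))
    if (k2$censored) next
    expect_equal(k2$lag_min %% 30, 0)
    if (!is.na(k2$clearance_min)) expect_equal(k2$clearance_min %% 30, 0)
  }
})

test_that("gradual fragmentation is recognized as asynchronous", {
  s <- make_series(nf = c(1, 1, 3, 6, 9, 4, 0),
                   debris = c(1, 1, 0.9, 0.8, 0.6, 0.3, 0))
  k <- measure_wd(s)
  expect_false(k$synchronous)
  expect_equal(k$lag_min, 60)
  s2 <- make_series(nf = c(1, 1, 9, 5, 2, 0, 0),
                    debris = c(1, 1, 0.9, 0.6, 0.3, 0.02, 0))
  expect_true(measure_wd(s2)$synchronous)
})

test_that("an intact axon is reported as right-censored, not imputed", {
  s <- make_series(nf = rep(1, 10), debris = rep(1, 10))
  k <- measure_wd(s)
  expect_true(k$censored)
  expect_true(is.na(k$lag_min))
})

test_that("event ordering reports swelling before death but not fragmentation", {
  stages <- c(1, 1, 2, 2, 3, 3, 3, 5)
  soma <- c(rep(TRUE, 7), FALSE)
  o <- onset_ordering(stages, soma, times = (0:7) * 60)
  expect_true(o$swelling_before_death)
  expect_false(o$fragmentation_before_death)
  expect_equal(o$t_first_stage2, 120)
  expect_equal(o$t_soma_death, 420)
  # stage flat at 1 until the death frame
  o2 <- onset_ordering(c(1, 1, 1, 5), c(TRUE, TRUE, TRUE, FALSE))
  expect_false(o2$swelling_before_death)
  # survivor: orderings undefined-flagged
  o3 <- onset_ordering(c(1, 2, 3), rep(TRUE, 3))
  expect_true(o3$death_censored)
  expect_true(is.na(o3$swelling_before_death))
})

test_that("simulated aSyn-like series put axonopathy hours before death", {
  # onset lead of 4 h at 30-min sampling: stage >= 2 precedes death by 8 frames
  lead_frames <- shipped_profiles$aSyn$timing$axonopathy_onset_lead_hours * 2
  death_at <- 20
  stages <- c(rep(1, death_at - lead_frames - 1),
              rep(2, lead_frames), 5)
  soma <- c(rep(TRUE, death_at - 1), FALSE)
  o <- onset_ordering(stages, soma, times = (seq_along(stages) - 1) * 30)
  expect_true(o$swelling_before_death)
  expect_equal(o$t_soma_death - o$t_first_stage2,
               shipped_profiles$aSyn$timing$axonopathy_onset_lead_hours * 60)
})
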