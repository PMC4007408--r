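wt <- shipped_profiles$WT

test_that("movie geometry follows the acquisition settings", {
  mv <- simulate_transport_movie(wt$transport, sim_config(), n_mito = 3, seed = 1)
  expect_equal(dim(mv$stack$frames)[1], 360)   # ~1 Hz for 6 minutes
  expect_equal(mv$stack$frame_interval_s, 1)
  expect_equal(mv$trace$calibrated_length_um,
               (dim(mv$stack$frames)[3] - 1) * 0.2)
})

test_that("a fully stationary population never travels far", {
  prof <- transport_profile(0, 0.56, 0.1, 0.57, 0.1, 6, 4.213, 0.38, 0.4125)
  mv <- simulate_transport_movie(prof, sim_config(), n_mito = 12, seed = 2)
  disp <- tapply(mv$truth$position_um, mv$truth$mito_id,
                 function(p) diff(range(p)))
  expect_true(all(disp < 2))
})

test_that("a forced single anterograde run obeys constant-velocity kinematics", {
  prof <- transport_profile(1, 0.5, 0, 0.5, 0, 1e6, 1e-3, 0, 0)
  mv <- simulate_transport_movie(prof, sim_config(movie_duration_s = 60),
                                 n_mito = 1, seed = 5)
  d <- mv$truth[mv$truth$in_fov, ]
  expect_true(all(d$state == "anterograde"))
  expect_equal(diff(d$position_um), rep(0.5, nrow(d) - 1), tolerance = 1e-9)
})

test_that("identical seed and config reproduce stacks and tables bit for bit", {
  a <- simulate_transport_movie(wt$transport, sim_config(), n_mito = 6, seed = 11)
  b <- simulate_transport_movie(wt$transport, sim_config(), n_mito = 6, seed = 11)
  expect_identical(a$stack$frames, b$stack$frames)
  expect_identical(a$truth, b$truth)
  expect_false(identical(
    a$stack$frames,
    simulate_transport_movie(wt$transport, sim_config(), n_mito = 6,
                             seed = 12)$stack$frames))
})

test_that("every rendered mitochondrion is accounted for in the ground truth", {
  mv <- simulate_transport_movie(wt$transport, sim_config(noise_sigma = 0),
                                 n_mito = 8, seed = 3)
  fr <- mv$stack$frames[1, , ]
  prof1 <- apply(fr, 2, max)
  n <- length(prof1)
  peaks <- sum(prof1 > 60 & prof1 > c(-Inf, prof1[-n]) & prof1 >= c(prof1[-1], -Inf))
  expect_equal(peaks, sum(mv$truth$frame == 1 & mv$truth$in_fov))
})

test_that("morphology generator respects density and degenerate spreads", {
  m0 <- morphology_profile(0, 2, 0.5)
  im <- simulate_morphology_image(m0, morph_sim_config(), 100, seed = 1)
  expect_equal(nrow(im$truth), 0)
  m2 <- morphology_profile(20, 2, 0, swollen_fraction = 0)
  im2 <- simulate_morphology_image(m2, morph_sim_config(), 100, seed = 2)
  expect_true(nrow(im2$truth) > 0)
  expect_equal(im2$truth$ratio, rep(2, nrow(im2$truth)), tolerance = 1e-9)
})

test_that("WT morphology sample mean matches its target at large n", {
  ratios <- unlist(lapply(1:10, function(i)
    simulate_morphology_image(wt$morphology, morph_sim_config(), 200,
                              seed = 40 + i)$truth$ratio))
  expect_gt(length(ratios), 300)
  se <- sd(ratios) / sqrt(length(ratios))
  expect_lt(abs(mean(ratios) - 2.01), 3 * se + 0.02)
})

test_that("axon profile signatures match their stage by construction", {
  p1 <- simulate_axon_profile(1, sim_config(noise_sigma = 0), 50, seed = 1)
  expect_lt(sd(p1) / mean(p1), 0.3)
  p5 <- simulate_axon_profile(5, sim_config(noise_sigma = 0), 50, seed = 2)
  expect_lt(mean(p5 > 0.3 * max(p5)), 0.1)
  expect_error(simulate_axon_profile(6, sim_config(), 50), "stage")
})

test_that("stage-3 profiles exceed the mild-beading boundary for an independent peak finder", {
  skip_if_not_installed("pracma")
  thr <- staging_thresholds()
  for (s in 1:5) {
    p <- simulate_axon_profile(3, sim_config(noise_sigma = 0), 50, seed = 60 + s)
    pk <- pracma::findpeaks(as.numeric(p), minpeakheight = 150,
                            minpeakdistance = 5)
    expect_gt(100 * nrow(pk) / 50, thr$bead_density_mild_max)
  }
})

test_that("cohort simulation honors survival, novelty and monotone stages", {
  prof <- shipped_profiles$WT
  full <- condition_profile("x", prof$transport, prof$morphology,
                            prof$axonopathy, prof$timing,
                            survival_2to3dpf = 1, new_expression_rate = 0)
  co <- simulate_cohort(full, 40, seed = 1)
  expect_equal(survival_percent(co, "x")$pct_survival, 100)
  expect_true(all(co$stage_t2 >= co$stage_t1, na.rm = TRUE))
  # identity transitions freeze the stage distribution
  ax_id <- axonopathy_profile(c(0.5, 0.3, 0.2, 0, 0), diag(5))
  frozen <- condition_profile("y", prof$transport, prof$morphology, ax_id,
                              prof$timing, 1, 0)
  cf <- simulate_cohort(frozen, 300, seed = 2)
  expect_equal(cf$stage_t1, cf$stage_t2)
  # new expression pushes survival above 100%
  nov <- condition_profile("z", prof$transport, prof$morphology,
                           prof$axonopathy, prof$timing, 1, 0.03)
  cn <- simulate_cohort(nov, 3000, seed = 3)
  expect_gt(survival_percent(cn, "z")$pct_survival, 100)
})

test_that("degenerate timing profiles give exact lag and clearance", {
  tp <- timing_profile(120, 0, 60, 0, 4, sampling_interval = 30)
  s <- simulate_wd_timecourse(tp, seed = 1)
  k <- measure_wd(s)
  expect_equal(k$lag_min, 120)
  expect_equal(k$clearance_min, 60)
  expect_true(k$synchronous)
})

test_that("measured lags agree with the generator's own draw log", {
  tp <- shipped_profiles$WT$timing
  true_lag <- meas <- numeric(300)
  for (r in 1:300) {
    s <- simulate_wd_timecourse(tp, seed = 7000 + r)
    true_lag[r] <- attr(s, "truth")$lag_min
    meas[r] <- measure_wd(s)$lag_min
  }
  ok <- !is.na(meas)
  # measured = true rounded up to the next frame
  expect_true(all(meas[ok] >= true_lag[ok]))
  expect_true(all(meas[ok] - true_lag[ok] <= 30))
  se <- sd(true_lag) / sqrt(sum(ok))
  expect_lt(abs(mean(meas[ok] - wd_lag_bias_correction(30)) - mean(true_lag[ok])),
            3 * se + 1)
})
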