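crit <- motility_criterion()

test_that("non-crossing ridges are each recovered as one accurate track", {
  parked <- c(5, 15, 48)
  m1 <- function(f) 18 + 0.1 * (f - 1)        # anterograde, 18 -> 29.9
  m2 <- function(f) 44 - 0.1 * (f - 1)        # retrograde, 44 -> 32.1
  fns <- c(lapply(parked, function(cc) function(f) cc + 0.01 * sin(f / 10)),
           list(m1, m2))
  ky <- make_ridge_kymograph(fns, n_frames = 120)
  tk <- extract_tracks(ky)
  expect_equal(length(unique(tk$mito_id)), 5)
  for (fn in list(m1, m2)) {
    # match the extracted track to its generator by initial position
    start <- fn(1)
    first <- tk[tk$frame == 1, ]
    mid <- first$mito_id[which.min(abs(first$position_um - start))]
    tr <- tk[tk$mito_id == mid, ]
    truth <- vapply(tr$frame, fn, 0)
    expect_lt(sqrt(mean((tr$position_um - truth)^2)), 0.2)
  }
})

test_that("blank and static kymographs degenerate gracefully", {
  blank <- structure(list(matrix = matrix(10, 50, 100), bin_size_um = 0.2,
                          frame_interval_s = 1), class = "kymograph")
  expect_equal(nrow(extract_tracks(blank)), 0)
  static <- make_ridge_kymograph(list(function(f) 10), n_frames = 60)
  tk <- extract_tracks(static)
  expect_equal(length(unique(tk$mito_id)), 1)
  expect_lt(diff(range(tk$position_um)), 0.2)
})

test_that("run segmentation resolves the canonical three-phase track", {
  # 60 s at +0.5, 60 s still, 60 s at -0.5
  pos <- c(cumsum(rep(0.5, 60)), rep(30, 60), 30 - cumsum(rep(0.5, 60)))
  runs <- segment_runs(make_track(c(0.25, pos)), crit)
  states <- runs$state[runs$n_frames > 3]
  expect_equal(states, c("anterograde", "paused", "retrograde"))
  ant <- runs[runs$state == "anterograde", ]
  expect_equal(ant$speed_um_s[1], 0.5, tolerance = 0.01)
  expect_equal(ant$displacement_um[1], 30, tolerance = 0.6)
})

test_that("a single constant run is one anterograde segment at its true speed", {
  runs <- segment_runs(make_track(0.5 * (0:100)), crit)
  expect_equal(nrow(runs), 1)
  expect_equal(runs$state, "anterograde")
  expect_equal(runs$speed_um_s, 0.5, tolerance = 1e-6)
})

test_that("jitter below the speed threshold is one long pause", {
  with_seed(3, {
    runs <- segment_runs(make_track(10 + cumsum(rnorm(200, 0, 0.02))), crit)
  })
  expect_true(all(runs$state == "paused"))
})

test_that("the motility criterion separates movers from drifters", {
  # 3 um at 0.3 um/s: motile
  expect_true(classify_motile(make_track(c(rep(0, 20), 0.3 * (0:10), rep(3, 20))), crit))
  # 1.9 um at 0.5 um/s: fails the travel threshold
  expect_false(classify_motile(make_track(c(rep(0, 20), seq(0, 1.9, by = 0.475), rep(1.9, 20))), crit))
  # slow 2.5-um drift over 360 s never exceeds the speed threshold
  expect_false(classify_motile(make_track(2.5 / 359 * (0:359)), crit))
})

test_that("transport summaries do the motility arithmetic per organelle", {
  tracks <- do.call(rbind, lapply(1:20, function(i) {
    p <- if (i <= 4) c(0.3 * (0:30), rep(9, 50)) else rep(i, 81)
    d <- make_track(p, mito_id = i); d
  }))
  class(tracks) <- c("track_table", "data.frame")
  attr(tracks, "frame_interval_s") <- 1
  s <- summarize_transport(tracks, crit)
  expect_equal(s$n_total, 20)
  expect_equal(s$pct_motile, 20)
  # all-stationary input flags the per-state fields as undefined
  st <- tracks[tracks$mito_id > 4, ]
  class(st) <- c("track_table", "data.frame")
  attr(st, "frame_interval_s") <- 1
  s0 <- summarize_transport(st, crit)
  expect_equal(s0$pct_motile, 0)
  expect_true(is.na(s0$pct_time_paused))
})

test_that("time fractions sum to 100 and known durations are recovered", {
  pos <- c(0.25, cumsum(rep(0.5, 60)), rep(30, 60), 30 - cumsum(rep(0.5, 60)))
  tracks <- make_track(pos)
  s <- summarize_transport(tracks, crit)
  expect_equal(s$pct_time_anterograde + s$pct_time_retrograde +
                 s$pct_time_paused, 100, tolerance = 0.01)
  expect_equal(s$pct_time_paused, 100 * 60 / length(pos), tolerance = 3)
  expect_equal(s$pct_distance_retrograde, 50, tolerance = 3)
})

test_that("mirroring the position axis swaps anterograde and retrograde", {
  mv <- simulate_transport_movie(shipped_profiles$WT$transport, sim_config(),
                                 n_mito = 8, seed = 21)
  ky <- build_kymograph(mv$stack, mv$trace)
  tk <- extract_tracks(ky)
  s <- summarize_transport(tk, crit)
  flip <- tk
  flip$position_um <- 50 - flip$position_um
  sf <- summarize_transport(flip, crit)
  expect_equal(s$pct_time_anterograde, sf$pct_time_retrograde, tolerance = 1e-9)
  expect_equal(s$pct_motile, sf$pct_motile)
  # and a constant offset changes nothing
  off <- tk; off$position_um <- off$position_um + 7
  so <- summarize_transport(off, crit)
  expect_equal(so$mean_anterograde_speed, s$mean_anterograde_speed)
  expect_equal(so$pct_time_paused, s$pct_time_paused)
})

test_that("the full pipeline recovers the generator's motile fraction and speeds", {
  wt <- shipped_profiles$WT$transport
  n_tot <- 0; n_mot <- 0; true_mot <- 0; speeds <- c()
  for (m in 1:12) {
    mv <- simulate_transport_movie(wt, sim_config(), n_mito = 10, seed = 300 + m)
    ky <- build_kymograph(mv$stack, mv$trace)
    s <- summarize_transport(extract_tracks(ky), crit)
    n_tot <- n_tot + s$n_total; n_mot <- n_mot + s$n_motile
    true_mot <- true_mot + sum(tapply(mv$truth$motile, mv$truth$mito_id, any))
    if (!is.na(s$mean_anterograde_speed))
      speeds <- c(speeds, s$mean_anterograde_speed)
  }
  p_hat <- true_mot / 120
  ci_half <- 1.96 * sqrt(p_hat * (1 - p_hat) / 120)
  expect_lt(abs(n_mot / n_tot - p_hat), ci_half + 0.03)
  expect_lt(abs(mean(speeds) - 0.56), 0.05 * 0.56 + 0.03)
})
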