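test_that("TIFF stacks round-trip losslessly with their calibration", {
  mv <- simulate_transport_movie(shipped_profiles$WT$transport,
                                 sim_config(movie_duration_s = 20),
                                 n_mito = 4, seed = 1)
  path <- file.path(tempdir(), "stack.tif")
  write_stack(mv$stack, path)
  back <- read_stack(path)
  expect_equal(back$frames, mv$stack$frames)
  expect_equal(back$frame_interval_s, 1)
  expect_equal(back$pixel_size_um, 0.2)
  expect_equal(stack_duration_s(back), 19)
  unlink(c(path, paste0(path, ".json")))
})

test_that("a single-frame stack reads fine but cannot make a kymograph", {
  one <- image_stack(array(5, dim = c(1, 4, 6)), 1, 0.2)
  path <- file.path(tempdir(), "one.tif")
  write_stack(one, path)
  back <- read_stack(path)
  expect_equal(dim(back$frames)[1], 1)
  tr <- axon_trace(c(0, 5), c(1, 1), 0.2)
  expect_error(build_kymograph(back, tr), ">= 2 frames")
  unlink(c(path, paste0(path, ".json")))
})

test_that("missing calibration without a sidecar is an error", {
  path <- file.path(tempdir(), "nocal.tif")
  tiff::writeTIFF(matrix(0.5, 4, 4), path)
  expect_error(read_stack(path), "calibration")
  expect_error(read_stack(file.path(tempdir(), "does_not_exist.tif")),
               "no such file")
  unlink(path)
})

test_that("axon traces round-trip through CSV with calibrated arc length", {
  tr <- axon_trace(c(0, 3, 3), c(0, 4, 10), pixel_size_um = 0.5)
  expect_equal(tr$calibrated_length_um, (5 + 6) * 0.5)
  path <- file.path(tempdir(), "trace.csv")
  write_axon_trace(tr, path)
  back <- read_axon_trace(path, 0.5)
  expect_equal(back$x_px, tr$x_px)
  expect_equal(back$calibrated_length_um, tr$calibrated_length_um)
  unlink(path)
})

test_that("kymograph geometry and ridge slopes match the source stack", {
  # static bright spot -> vertical ridge with slope 0
  px <- 0.2
  n_frames <- 60; ny <- 9; nx <- 200
  arr <- array(10, dim = c(n_frames, ny, nx))
  spot_col <- round(10 / px)   # arc position 10 um
  for (f in seq_len(n_frames)) arr[f, 5, spot_col] <- 200
  st <- image_stack(arr, 1, px)
  tr <- axon_trace(c(0, nx - 1), c(4, 4), px)
  ky <- build_kymograph(st, tr)
  expect_equal(nrow(ky$matrix), n_frames)
  ridge <- apply(ky$matrix, 1, which.max)
  expect_lt(diff(range(ridge)), 2)
  # moving spot at 0.5 um/s advances 0.5 um per row
  arr2 <- array(10, dim = c(n_frames, ny, nx))
  for (f in seq_len(n_frames)) {
    cc <- round((5 + 0.5 * (f - 1)) / px + 0.5)
    arr2[f, 5, cc] <- 200
  }
  ky2 <- build_kymograph(image_stack(arr2, 1, px), tr)
  ridge2 <- (apply(ky2$matrix, 1, which.max) - 0.5) * px
  slope <- coef(lm(ridge2 ~ seq_len(n_frames)))[2]
  expect_equal(unname(slope), 0.5, tolerance = 0.05)
})

test_that("a 6-minute 1-Hz stack yields 360 kymograph rows", {
  mv <- simulate_transport_movie(shipped_profiles$WT$transport, sim_config(),
                                 n_mito = 3, seed = 4)
  ky <- build_kymograph(mv$stack, mv$trace)
  expect_equal(nrow(ky$matrix), 360)
})

test_that("time reversal and rigid translation behave as symmetries", {
  mv <- simulate_transport_movie(shipped_profiles$WT$transport,
                                 sim_config(movie_duration_s = 40),
                                 n_mito = 5, seed = 9)
  ky <- build_kymograph(mv$stack, mv$trace)
  rev_stack <- image_stack(mv$stack$frames[dim(mv$stack$frames)[1]:1, , ],
                           1, 0.2)
  ky_rev <- build_kymograph(rev_stack, mv$trace)
  expect_equal(ky_rev$matrix, ky$matrix[nrow(ky$matrix):1, ])
  # translate stack and trace together by 2 px in y
  d <- dim(mv$stack$frames)
  arr <- array(10, dim = d + c(0, 4, 0))
  arr[, 3:(d[2] + 2), ] <- mv$stack$frames
  tr2 <- axon_trace(mv$trace$x_px, mv$trace$y_px + 2, 0.2)
  ky_tr <- build_kymograph(image_stack(arr, 1, 0.2), tr2)
  expect_equal(rowSums(ky_tr$matrix), rowSums(ky$matrix))
})
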