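test_that("rendered ellipses are segmented with faithful aspect ratios", {
  prof <- morphology_profile(10, 2.2, 0.4, swollen_fraction = 0)
  im <- simulate_morphology_image(prof, morph_sim_config(noise_sigma = 0),
                                  axon_length_um = 150, seed = 8)
  shp <- segment_mitochondria(im$image, im$pixel_size_um)
  expect_equal(nrow(shp), nrow(im$truth))
  truth <- im$truth[order(im$truth$centroid_x_um), ]
  meas <- shp[order(shp$centroid_x_um), ]
  expect_true(all(abs(meas$ratio - truth$ratio) / truth$ratio < 0.15))
  expect_true(all(meas$length_um >= meas$width_um))
})

test_that("a circle scores a ratio of one and a blank image yields nothing", {
  img <- matrix(0, 40, 40)
  for (y in 1:40) for (x in 1:40)
    if ((x - 20.5)^2 + (y - 20.5)^2 <= 64) img[y, x] <- 200
  shp <- segment_mitochondria(img, 0.1)
  expect_equal(nrow(shp), 1)
  expect_equal(shp$ratio, 1, tolerance = 0.05)
  expect_equal(nrow(segment_mitochondria(matrix(0, 20, 20), 0.1)), 0)
})

test_that("morphology summaries do the density and histogram arithmetic", {
  shapes <- data.frame(ratio = rep(2, 11))
  s <- summarize_morphology(shapes, axon_length_um = 50)
  expect_equal(s$density_per_100um, 22)
  expect_equal(s$ratio_sem, 0)
  expect_equal(sum(s$histogram$counts), 11)
  s2 <- summarize_morphology(shapes, axon_length_um = 100)
  expect_equal(s2$density_per_100um, s$density_per_100um / 2)
  expect_error(summarize_morphology(shapes, 0), "axon_length")
})

test_that("ratios are invariant to rotation and intensity rescaling", {
  prof <- morphology_profile(8, 2.0, 0.3)
  im <- simulate_morphology_image(prof, morph_sim_config(noise_sigma = 0),
                                  100, seed = 12)
  a <- segment_mitochondria(im$image, 0.1)
  b <- segment_mitochondria(t(im$image)[rev(seq_len(ncol(im$image))), ], 0.1)
  expect_equal(sort(a$ratio), sort(b$ratio), tolerance = 1e-6)
  c2 <- segment_mitochondria(im$image * 0.37, 0.1)
  expect_equal(sort(a$ratio), sort(c2$ratio), tolerance = 1e-6)
})

test_that("higher swollen fractions raise the measured spherical fraction", {
  spherical_frac <- function(sf, seed) {
    prof <- morphology_profile(20, if (sf > 0.2) 1.48 else 2.01, 0.6,
                               swollen_fraction = sf)
    r <- unlist(lapply(1:4, function(i) {
      im <- simulate_morphology_image(prof, morph_sim_config(), 150,
                                      seed = seed + i)
      segment_mitochondria(im$image, im$pixel_size_um)$ratio
    }))
    mean(r < 1.25)
  }
  expect_gt(spherical_frac(0.25, 600), spherical_frac(0.05, 700))
})
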