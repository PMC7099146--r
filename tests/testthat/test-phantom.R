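# synthetic phantom generator: determinism, texture statistics, drift
# bounds, atlas warps and acquisition noise

test_that("identical seeds reproduce the phantom bit for bit", {
  spec <- phantom_spec(shape = c(6, 60, 80), radii = c(15, 20), seed = 7L)
  a <- make_phantom(spec)
  b <- make_phantom(spec)
  expect_identical(a$volume$data, b$volume$data)
  expect_identical(a$label$data, b$label$data)
})

test_that("with zero outside density every blob lands inside the region", {
  spec <- phantom_spec(shape = c(4, 80, 80), radii = c(25, 25),
                       cell_density_out = 0, seed = 3L)
  ph <- make_phantom(spec)
  expect_true(all(ph$meta$n_blobs_out == 0))
  # all texture (beyond base + pedestal) must sit inside a slightly grown
  # region: blob rendering windows reach at most ceiling(3 sigma) pixels
  # (Chebyshev) beyond a region pixel
  w <- ceiling(3 * spec$blob_radius / 2)
  grown <- ph$label$data
  for (s in seq_len(dim(grown)[1]))
    grown[s, , ] <- EBImage::dilate((ph$label$data[s, , ] != 0) * 1,
                                    matrix(1, 2 * w + 1, 2 * w + 1)) != 0
  outside <- ph$volume$data[grown == 0]
  expect_true(all(abs(outside - spec$base_intensity) < 1))
})

test_that("per-slice in-region blob counts follow the Poisson intensity", {
  # 200x200 slices, region area ~10,000 px^2, density 5 per 1000 px^2
  # -> per-slice count ~ Poisson(mean 50)
  r <- sqrt(10000 / pi)
  spec <- phantom_spec(shape = c(100, 200, 200), radii = c(r, r),
                       exponent = 2, d_max = 0, cell_density_in = 5,
                       cell_density_out = 0, seed = 17L)
  ph <- make_phantom(spec)
  area <- sum(ph$label$data[1, , ])
  mu <- 5 / 1000 * area
  expect_lt(abs(mean(ph$meta$n_blobs_in) - mu), 3 * sqrt(mu / 100))
})

test_that("region/background intensity ratio tracks the contrast parameter", {
  ph <- fix_phantom()
  ratio <- mean(ph$volume$data[ph$label$data == 1]) /
    mean(ph$volume$data[ph$label$data == 0])
  expect_lt(abs(ratio - fix_spec()$contrast) / fix_spec()$contrast, 0.10)
})

test_that("adjacent-slice boundary drift stays within d_max", {
  ph <- fix_phantom()
  d_max <- fix_spec()$d_max
  for (s in 1:(dim(ph$label$data)[1] - 1)) {
    h <- boundary_hausdorff(ph$label$data[s, , ], ph$label$data[s + 1, , ])
    expect_lte(h, d_max)
  }
})

test_that("a region that would not fit the image is rejected", {
  expect_error(phantom_spec(shape = c(5, 50, 50), radii = c(40, 40)),
               "exceeds image bounds")
})

test_that("zero warp amplitude returns the subject and an identity transform", {
  spec <- phantom_spec(shape = c(5, 60, 60), radii = c(18, 15), seed = 9L)
  subject <- make_phantom(spec)
  ap <- make_atlas_pair(spec, warp_amplitude = 0)
  expect_identical(ap$volume$data, subject$volume$data)
  expect_identical(ap$label$data, subject$label$data)
  expect_null(ap$transform$forward)
  expect_equal(ap$transform$affine, identity_affine())
})

test_that("the atlas warp respects its amplitude and stays diffeomorphic", {
  spec <- phantom_spec(shape = c(8, 80, 100), radii = c(22, 28), seed = 5L)
  ap <- make_atlas_pair(spec, warp_amplitude = 15, seed = 31L)
  u <- ap$transform$forward
  mag <- sqrt(u[[1]]^2 + u[[2]]^2 + u[[3]]^2)
  expect_lte(max(mag), 15 + 1e-8)
  expect_gt(max(mag), 14)  # amplitude is attained, not just bounded
  js <- dualpathseg:::cpp_jacobian_stats(u)
  expect_gt(js[1], 0)
  v <- validate_transform(ap$transform)
  expect_true(v$ok)
})

test_that("warping the atlas label through the ground-truth transform recovers the subject", {
  # region large enough that the sub-voxel boundary quantization of the
  # resampling does not dominate the overlap
  spec <- phantom_spec(shape = c(8, 160, 200), radii = c(50, 65), seed = 5L)
  subject <- make_phantom(spec)
  ap <- make_atlas_pair(spec, warp_amplitude = 15, seed = 31L)
  # direct resampling of the atlas region through the ground-truth forward
  # field (linear interpolation of the binary, re-thresholded)
  back <- dualpathseg:::cpp_warp_volume((ap$label$data != 0) * 1,
                                        identity_affine(),
                                        ap$transform$forward,
                                        dim(ap$label$data),
                                        nearest = FALSE) > 0.5
  m <- dice_precision_recall(back * 1, subject$label$data)
  expect_gte(m$dice, 0.99)
  # the package's own nearest-neighbour label mapping is close behind
  mapped <- map_label(ap$transform, ap$label, 1L)
  expect_gte(dice_precision_recall(mapped$data, subject$label$data)$dice, 0.985)
})

test_that("an over-strong warp that folds is rejected", {
  spec <- phantom_spec(shape = c(4, 60, 60), radii = c(15, 15), seed = 2L)
  expect_error(make_atlas_pair(spec, warp_amplitude = 40, wavelength = 30),
               "folds")
})

test_that("zero-strength noise is the identity", {
  ph <- fix_phantom()
  out <- add_noise(ph$volume, strength = 0)
  expect_identical(out$data, ph$volume$data)
})

test_that("vignetting darkens corners relative to the centre", {
  vol <- volume3d(array(100, c(2, 64, 64)))
  out <- add_noise(vol, stripes = FALSE, vignette = TRUE, strength = 0.5)
  sl <- out$data[1, , ]
  corners <- mean(sl[c(1, 64), c(1, 64)])
  centre <- mean(sl[30:34, 30:34])
  expect_lt(corners, centre)
})

test_that("stripe noise concentrates power at the stripe frequency", {
  vol <- volume3d(array(120, c(1, 8, 200)))
  out <- add_noise(vol, stripes = TRUE, vignette = FALSE, strength = 0.6,
                   period = 40, seed = 4L)
  profile <- out$data[1, 4, ]
  spec_pow <- Mod(stats::fft(profile - mean(profile)))^2
  # one-sided spectrum, frequency index k corresponds to k cycles / 200 px
  half <- spec_pow[2:100]
  expect_equal(which.max(half), 200 / 40)
})
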