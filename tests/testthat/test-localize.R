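# initial localization: mutual information, affine + symmetric nonlinear
# registration, label mapping and Mask-init

test_that("registering a volume to itself stays at the identity", {
  ph <- fix_phantom()
  tfm <- register_volumes(ph$volume, ph$volume, levels = 2L,
                          demons_iters = c(5L, 3L))
  # affine translation and scale near identity
  expect_lt(max(abs(tfm$affine[, 4])), 0.5)
  expect_lt(max(abs(tfm$affine[, 1:3] - diag(3))), 0.02)
  mag <- sqrt(tfm$forward[[1]]^2 + tfm$forward[[2]]^2 + tfm$forward[[3]]^2)
  expect_lt(max(mag), 0.5)
})

test_that("a pure translation is recovered within a voxel", {
  ph <- fix_phantom()
  fixed <- ph$volume$data
  # moving(y) = fixed(y - t) for t = (0, 10, 6): the transform T(x) = x + t
  # resamples moving back onto fixed
  moving <- array(fix_spec()$base_intensity, dim(fixed))
  moving[, 11:160, 7:160] <- fixed[, 1:150, 1:154]
  # oracle: exhaustive integer translation search maximizing MI
  mi_at <- function(dr, dc) {
    A <- identity_affine(); A[2, 4] <- dr; A[3, 4] <- dc
    w <- dualpathseg:::cpp_warp_volume(moving, A, NULL, dim(fixed),
                                       fill = fix_spec()$base_intensity)
    mutual_information(fixed, w)
  }
  grid <- expand.grid(dr = 8:12, dc = 4:8)
  vals <- mapply(mi_at, grid$dr, grid$dc)
  oracle <- unlist(grid[which.max(vals), ])
  expect_equal(unname(oracle), c(10, 6))  # sanity: the optimum is the shift
  tfm <- register_volumes(volume3d(fixed), volume3d(moving),
                          levels = 3L, affine_only = TRUE)
  expect_lt(abs(tfm$affine[2, 4] - 10), 1)
  expect_lt(abs(tfm$affine[3, 4] - 6), 1)
  expect_lt(abs(tfm$affine[1, 4]), 1)
})

test_that("mutual information never decreases across pyramid levels", {
  spec <- fix_spec()
  ap <- cached("atlas15", function() make_atlas_pair(spec, warp_amplitude = 15,
                                                     seed = 77L))
  ph <- fix_phantom()
  tfm <- cached("reg15", function()
    register_volumes(ph$volume, ap$volume, levels = 3L))
  expect_true(all(tfm$mi$mi_final >= tfm$mi$mi_affine - 1e-9))
  v <- validate_transform(tfm)
  expect_lt(v$residual, 0.5)
  expect_lte(v$frac_nonpositive, 0.01)
})

test_that("registration recovers a 15 px warp well enough to map the label", {
  spec <- fix_spec()
  ap <- cached("atlas15", function() make_atlas_pair(spec, warp_amplitude = 15,
                                                     seed = 77L))
  ph <- fix_phantom()
  tfm <- cached("reg15", function()
    register_volumes(ph$volume, ap$volume, levels = 3L))
  mapped <- map_label(tfm, ap$label, 1L)
  m <- dice_precision_recall(mapped$data, ph$label$data)
  expect_gte(m$dice, 0.90)
})

test_that("label mapping is exact for identity and pure translations", {
  ph <- fix_phantom()
  lab <- label_volume(ph$label$data)
  ident <- transform3d(domain = dim(lab$data))
  expect_identical(map_label(ident, lab, 1L)$data != 0, lab$data != 0)
  # a 10 px in-plane translation: out(x) = lab(x + t)
  A <- identity_affine(); A[2, 4] <- 10
  tfm <- transform3d(affine = A, domain = dim(lab$data))
  mapped <- map_label(tfm, lab, 1L)
  shifted <- array(0L, dim(lab$data))
  shifted[, 1:150, ] <- lab$data[, 11:160, ]
  expect_identical(mapped$data != 0, shifted != 0)
  # absent region id is rejected
  expect_error(map_label(ident, lab, 7L), "not present")
  # empty region maps to empty
  empty <- label_volume(array(0L, c(4, 10, 10)), region_ids = 2L)
  tfm2 <- transform3d(domain = c(4, 10, 10))
  expect_equal(sum(map_label(tfm2, empty, 2L)$data), 0)
})

test_that("the initial mask sits on the middle slice and dilates by a disk", {
  lab <- array(0L, c(100, 121, 121))
  lab[40:60, 61, 61] <- 1L  # single-pixel region spanning slices 40..60
  mk <- init_mask(label_volume(lab), radius = 50)
  expect_equal(mk$slice, 50L)  # midpoint rule
  expect_identical(mk$provenance, "init")
  # brute-force digital disk of radius 50
  brute <- sum(outer((-60:60)^2, (-60:60)^2, `+`) <= 50^2)
  expect_equal(sum(mk$mask), brute)
  # radius 0 returns the slice label unchanged
  mk0 <- init_mask(label_volume(lab), radius = 0)
  expect_identical(mk0$mask, lab[50, , ] != 0)
  expect_error(init_mask(label_volume(array(0L, c(5, 8, 8)))), "empty")
})

test_that("dilation is extensive: Mask-init always contains the mapped slice", {
  ph <- fix_phantom()
  mk <- init_mask(label_volume(ph$label$data), radius = 50)
  sl <- ph$label$data[mk$slice, , ] != 0
  expect_true(all(sl <= mk$mask))
})

test_that("registration rejects constant volumes", {
  flat <- volume3d(array(1, c(4, 10, 10)))
  ph <- volume3d(array(runif(400), c(4, 10, 10)))
  expect_error(register_volumes(flat, ph), "non-constant")
})
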