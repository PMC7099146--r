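# tracking localization: masked interval prediction, Mask-track dilation,
# bidirectional propagation and 3D postprocessing

test_that("an empty mask predicts nothing", {
  img <- matrix(runif(400), 20, 20)
  res <- predict_slice(function(image, centers) rep(1, nrow(centers)),
                       img, matrix(FALSE, 20, 20))
  expect_false(any(res$pred))
  expect_equal(res$n_visited, 0L)
})

test_that("a full mask at stride 2 visits a quarter of the pixels", {
  img <- matrix(runif(40 * 60), 40, 60)
  mask <- matrix(TRUE, 40, 60)
  res <- predict_slice(function(image, centers) rep(1, nrow(centers)),
                       img, mask, stride = 2L)
  expect_equal(res$n_visited, ceiling(40 / 2) * ceiling(60 / 2))
  expect_equal(res$reduction, 1 - res$n_visited / (40 * 60))
})

test_that("an oracle classifier recovers the slice up to stride quantization", {
  ph <- fix_phantom()
  s <- 15L
  lab <- ph$label$data[s, , ] != 0
  mask <- make_track_mask(lab, radius = 20, slice = s)
  res <- predict_slice(oracle_for_slice(ph$label$data[s, , ]),
                       ph$volume$data[s, , ], mask, stride = 2L)
  m <- dice_precision_recall(res$pred, lab)
  expect_gte(m$dice, 0.98)
  # with stride 1 the oracle is exact within the mask
  res1 <- predict_slice(oracle_for_slice(ph$label$data[s, , ]),
                        ph$volume$data[s, , ], mask, stride = 1L)
  expect_identical(res1$pred, lab & mask$mask)
  expect_identical(res1$pred, lab)  # mask contains the region
})

test_that("track masks are disk dilations: extensive, exact for a point", {
  m <- matrix(FALSE, 61, 61); m[31, 31] <- TRUE
  mk <- make_track_mask(m, radius = 20)
  # brute-force digital disk
  idx <- which(mk$mask, arr.ind = TRUE)
  d2 <- (idx[, 1] - 31)^2 + (idx[, 2] - 31)^2
  expect_true(all(d2 <= 20^2))
  expect_equal(sum(mk$mask), sum(outer((-30:30)^2, (-30:30)^2, `+`) <= 400))
  # extensivity on random shapes
  set.seed(3)
  for (i in 1:5) {
    r <- matrix(runif(900) < 0.2, 30, 30)
    expect_true(all(r <= make_track_mask(r, radius = 3)$mask))
  }
  # empty in, empty out (stop signal)
  expect_false(any(make_track_mask(matrix(FALSE, 10, 10), radius = 20)$mask))
})

test_that("the computation reduction follows the stride arithmetic", {
  full <- matrix(TRUE, 100, 100)
  expect_equal(compute_reduction(full, 2L), 0.75)
  expect_equal(compute_reduction(full, 1L), 0)
  full99 <- matrix(TRUE, 99, 99)
  expect_equal(compute_reduction(full99, 3L), 1 - 33^2 / 99^2)
  expect_message(r <- compute_reduction(matrix(FALSE, 5, 5), 2L), "empty")
  expect_true(is.na(r))
})

test_that("a single-slice volume reduces to one masked prediction", {
  ph <- fix_phantom()
  one <- volume3d(ph$volume$data[10, , , drop = FALSE])
  lab1 <- ph$label$data[10, , ]
  init <- mask2d(dilate_disk(lab1 != 0, 20), slice = 1L, provenance = "init",
                 radius = 20)
  res <- track_volume(oracle_for_slice(lab1), one, init, stride = 2L)
  direct <- predict_slice(oracle_for_slice(lab1), one$data[1, , ], init, 2L)
  expect_identical(res$seg[1, , ], direct$pred)
})

test_that("oracle-driven tracking recovers the drifting region and keeps it inside every mask", {
  ph <- fix_phantom()
  oracle <- oracle_volume_classifier(ph$volume, ph$label)
  mapped <- label_volume(ph$label$data)
  init <- init_mask(mapped, radius = 20)
  res <- track_volume(oracle, ph$volume, init, stride = 2L, track_radius = 20)
  m <- dice_precision_recall(res$seg, ph$label$data)
  expect_gte(m$dice, 0.98)
  for (s in seq_along(res$masks)) {
    if (is.null(res$masks[[s]])) next
    truth <- ph$label$data[s, , ] != 0
    # tracking guarantee: drift + no segmentation error < radius => recall 1
    expect_true(all(truth <= res$masks[[s]]$mask),
                label = sprintf("slice %d containment", s))
    # prediction never escapes its mask
    expect_true(all(res$seg[s, , ] <= res$masks[[s]]$mask))
  }
})

test_that("propagation halts when the region vanishes", {
  spec <- phantom_spec(shape = c(20, 100, 100), radii = c(20, 20),
                       center = c(50, 50), d_max = 5, slice_range = c(1L, 12L),
                       seed = 55L)
  ph <- make_phantom(spec)
  oracle <- oracle_volume_classifier(ph$volume, ph$label)
  init <- init_mask(label_volume(ph$label$data), radius = 20)
  res <- track_volume(oracle, ph$volume, init, stride = 2L, track_radius = 20)
  # region exists through slice 12; tracking may touch slice 13 then stop
  expect_lte(res$stopped[2], 13L)
  expect_false(any(res$seg[14:20, , ]))
})

test_that("postprocessing fills holes, drops satellites, and is idempotent", {
  arr <- array(FALSE, c(5, 40, 40))
  arr[2:4, 10:30, 10:30] <- TRUE
  arr[3, 20, 20] <- FALSE                 # interior hole
  arr[3, 36:37, 36:37] <- TRUE            # 4-voxel satellite (2x2 on 1 slice)
  out <- postprocess(arr, min_component = 20L, smooth_sigma = 1)
  expect_true(out[3, 20, 20])             # hole filled
  expect_false(any(out[, 35:40, 35:40]))  # satellite removed
  expect_identical(postprocess(out, min_component = 20L, smooth_sigma = 1), out)
})

test_that("postprocessing an oracle tracking result is idempotent too", {
  ph <- fix_phantom()
  oracle <- oracle_volume_classifier(ph$volume, ph$label)
  init <- init_mask(label_volume(ph$label$data), radius = 20)
  res <- track_volume(oracle, ph$volume, init, stride = 2L)
  post <- postprocess(res)
  expect_identical(postprocess(post)$seg, post$seg)
  # postprocessing trades at most a little overlap for regularity
  expect_gte(dice_precision_recall(post$seg, ph$label$data)$dice, 0.96)
})
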