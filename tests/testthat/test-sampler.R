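# patch sampling: stride-grid candidates, the class balance rule, intensity
# augmentation, and the stratified split

test_that("stride grids enumerate the expected candidate counts", {
  img <- matrix(0, 100, 100)
  lab <- matrix(0L, 100, 100)
  cand <- extract_candidates(img, lab, stride = 3L, small = 21L, large = 31L)
  expect_equal(nrow(cand$candidates), ceiling(100 / 3)^2)  # 34^2 = 1156
  cand1 <- extract_candidates(matrix(0, 12, 15), matrix(0L, 12, 15),
                              stride = 1L, small = 5L, large = 9L)
  expect_equal(nrow(cand1$candidates), 12 * 15)
})

test_that("an all-background label yields only class-A negatives", {
  cand <- extract_candidates(matrix(runif(900), 30, 30), matrix(0L, 30, 30),
                             stride = 2L, small = 7L, large = 11L)
  expect_true(all(cand$candidates$class == "negA"))
  expect_equal(cand$counts$N2, 0L)
  expect_equal(cand$counts$N3, 0L)
})

test_that("candidate classes agree with a direct window scan", {
  set.seed(20)
  lab <- matrix(0L, 40, 40)
  lab[15:25, 10:30] <- 1L
  img <- matrix(runif(1600), 40, 40)
  small <- 9L
  cand <- extract_candidates(img, lab, stride = 3L, small = small, large = 15L)
  hp <- (small - 1L) %/% 2L
  for (k in sample(nrow(cand$candidates), 50)) {
    r <- cand$candidates$row[k]; c <- cand$candidates$col[k]
    rows <- reflect_index((r - hp):(r + hp), 40L)
    cols <- reflect_index((c - hp):(c + hp), 40L)
    n_region <- sum(lab[rows, cols])
    expected <- if (lab[r, c] > 0) "pos" else if (n_region == 0) "negA" else "negB"
    expect_identical(cand$candidates$class[k], expected)
  }
})

test_that("the retention fraction solves the balance equation", {
  # 0.1*N1 + 3*x*N2 = 3*N3
  c1 <- solve_balance(sample_counts(3000, 500, 100))
  expect_equal(as.numeric(c1$x), 0)
  c2 <- solve_balance(sample_counts(30000, 2000, 1500))
  expect_equal(as.numeric(c2$x), 0.25)
  expect_warning(c3 <- solve_balance(sample_counts(1000, 400, 500)),
                 "clamped")
  expect_equal(as.numeric(c3$x), 1)
  expect_true(attr(c3$x, "clamped"))
  expect_error(solve_balance(sample_counts(100, 0, 50)), "unbalanced")
  expect_silent(c4 <- solve_balance(sample_counts(3000, 0, 100)))
  expect_equal(as.numeric(c4$x), 0)
})

test_that("exactly 10% of class-A negatives survive screening", {
  # a 100 x 40 all-background slice at stride 2 gives 50 * 20 = 1000
  # class-A candidates; screening must retain exactly 100
  img <- matrix(runif(4000, 0, 255), 100, 40)
  cand <- extract_candidates(img, matrix(0L, 100, 40), stride = 2L,
                             small = 9L, large = 15L)
  expect_equal(cand$counts$N1, 1000L)
  ss <- suppressWarnings(screen_and_augment(cand, seed = 1L))
  expect_equal(length(ss$label), 100L)
  expect_true(all(ss$manifest$factor == 1))  # class A is never augmented
})

test_that("intensity augmentation scales by +/-20% and clips to the range", {
  img <- matrix(100, 30, 30)
  lab <- matrix(1L, 30, 30)  # all positive -> every sample augmented x3
  cand <- extract_candidates(img, lab, stride = 10L, small = 9L, large = 15L)
  expect_warning(ss <- screen_and_augment(cand, seed = 1L), "not balance")
  means <- round(apply(ss$small, 3, mean), 6)
  expect_setequal(unique(means), c(100, 120, 80))
  # clipping: value 240 at factor 1.2 saturates at 255
  img2 <- matrix(240, 30, 30)
  cand2 <- extract_candidates(img2, lab, stride = 10L, small = 9L, large = 15L)
  expect_warning(ss2 <- screen_and_augment(cand2, seed = 1L), "not balance")
  expect_setequal(unique(round(apply(ss2$small, 3, mean), 6)),
                  c(240, 255, 192))
})

test_that("the screened set satisfies the balance identity within rounding", {
  ph <- fix_phantom()
  cand <- extract_candidates(ph$volume, ph$label, stride = 6L,
                             slices = c(5L, 15L, 25L))
  ss <- screen_and_augment(cand, seed = 3L)
  expect_false(attr(ss$counts$x, "clamped"))
  expect_lte(abs(ss$balance_gap), 3)
  # totals: retainedA + 3*retainedB negatives vs 3*N3 positives
  expect_equal(sum(ss$label == 1), 3L * ss$counts$N3)
  expect_lte(abs(sum(ss$label == 0) - sum(ss$label == 1)), 3)
})

test_that("every sample's label matches the ground truth at its centre", {
  ph <- fix_phantom()
  cand <- extract_candidates(ph$volume, ph$label, stride = 7L, slices = 10L)
  ss <- screen_and_augment(cand, seed = 5L)
  truth <- mapply(function(s, r, c) ph$label$data[s, r, c],
                  ss$manifest$slice, ss$manifest$row, ss$manifest$col)
  expect_identical(ss$label, as.integer(truth != 0))
})

test_that("augmentation rescales intensity without touching geometry", {
  ph <- fix_phantom()
  cand <- extract_candidates(ph$volume, ph$label, stride = 9L, slices = 12L)
  ss <- screen_and_augment(cand, seed = 5L)
  aug <- which(ss$manifest$factor == 1.2)
  for (k in head(aug, 5)) {
    base <- which(ss$manifest$factor == 1 &
                    ss$manifest$row == ss$manifest$row[k] &
                    ss$manifest$col == ss$manifest$col[k] &
                    ss$manifest$slice == ss$manifest$slice[k])[1]
    unclipped <- ss$small[, , base] * 1.2 <= 255
    expect_equal(ss$small[, , k][unclipped],
                 (ss$small[, , base] * 1.2)[unclipped], tolerance = 1e-12)
  }
})

test_that("the train/validation split is stratified, disjoint and exhaustive", {
  ph <- fix_phantom()
  cand <- extract_candidates(ph$volume, ph$label, stride = 8L, slices = 8L)
  ss <- screen_and_augment(cand, seed = 2L)
  sp <- split_train_val(ss, 0.8, seed = 1L)
  n <- length(ss$label)
  expect_equal(length(sp$train$label) + length(sp$val$label), n)
  key <- function(x) paste(x$manifest$slice, x$manifest$row, x$manifest$col,
                           x$manifest$factor)
  expect_length(intersect(key(sp$train), key(sp$val)), 0)
  for (cl in 0:1) {
    n_cl <- sum(ss$label == cl)
    expect_equal(sum(sp$train$label == cl), floor(0.8 * n_cl))
  }
})

test_that("small sample sets split by the floor rule", {
  ss <- local({
    arr <- array(runif(5 * 5 * 5, 0, 255), c(5, 5, 5))
    structure(list(small = arr, large = arr, label = rep(1L, 5),
                   manifest = data.frame(slice = 1, row = 1:5, col = 1,
                                         class = "pos", factor = 1),
                   counts = sample_counts(0, 0, 5, x = 0),
                   patch_sizes = c(5L, 9L), intensity_range = c(0, 255),
                   balance_gap = 0), class = "sample_set")
  })
  sp <- split_train_val(ss, 0.8, seed = 3L)
  expect_equal(length(sp$train$label), 4L)
  expect_equal(length(sp$val$label), 1L)
})
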