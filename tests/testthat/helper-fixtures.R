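# shared fixtures, built once per test session and cached

.fixtures <- new.env(parent = emptyenv())

cached <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

# small drifting phantom used across modules (30 slices, 160 x 160)
fix_spec <- function() phantom_spec(shape = c(30, 160, 160),
                                    radii = c(40, 30), center = c(80, 80),
                                    d_max = 8, seed = 101L)

fix_phantom <- function() cached("phantom", function() make_phantom(fix_spec()))

# held-out phantom with a different seed and drift path
fix_spec_holdout <- function() phantom_spec(shape = c(24, 160, 160),
                                            radii = c(38, 32),
                                            center = c(82, 78), d_max = 8,
                                            seed = 202L)

fix_phantom_holdout <- function()
  cached("phantom_holdout", function() make_phantom(fix_spec_holdout()))

# balanced two-scale samples from the training phantom, capped at the
# desk-scale budget of 5,000 patches
fix_samples <- function() cached("samples", function() {
  ph <- fix_phantom()
  cand <- extract_candidates(ph$volume, ph$label, stride = 5L,
                             slices = seq(1L, 30L, by = 2L))
  ss <- screen_and_augment(cand, seed = 11L)
  ss <- subsample_balanced(ss, 4800L, seed = 12L)
  split_train_val(ss, 0.8, seed = 2L)
})

# a reduced-schedule trained model (shared by network and pipeline tests)
fix_model <- function() cached("model", function() {
  sp <- fix_samples()
  train_network(sp$train, sp$val, network_spec(),
                train_config(epochs = 4L, seed = 5L))
})

# oracle classifier: returns the ground-truth label at each centre as the
# region probability (the perfect-classifier reference of the tracking
# contracts)
oracle_classifier <- function(label_vol) {
  lab <- if (inherits(label_vol, "label_volume")) label_vol$data else label_vol
  slice_env <- new.env(parent = emptyenv())
  slice_env$current <- NULL
  f <- function(image, centers) {
    sl <- slice_env$current
    stopifnot(!is.null(sl))
    as.numeric(lab[sl, , , drop = TRUE][centers] != 0)
  }
  attr(f, "set_slice") <- function(s) assign("current", s, envir = slice_env)
  f
}

# oracle over a single slice matrix
oracle_for_slice <- function(label_slice) {
  function(image, centers) as.numeric(label_slice[centers] != 0)
}

# tracking oracle that follows track_volume's slice order: predictions are
# looked up in the ground-truth volume by matching the image content
oracle_volume_classifier <- function(vol, label_vol) {
  imgs <- vol$data
  lab <- if (inherits(label_vol, "label_volume")) label_vol$data else label_vol
  function(image, centers) {
    # identify the slice by exact image match
    for (s in seq_len(dim(imgs)[1])) {
      if (identical(dim(image), dim(imgs[s, , , drop = TRUE])) &&
          all(image == imgs[s, , , drop = TRUE])) {
        return(as.numeric(lab[s, , , drop = TRUE][centers] != 0))
      }
    }
    stop("oracle could not identify the slice")
  }
}

# boundary Hausdorff distance between two binary masks (brute force over
# boundary pixels; fine for test-sized masks)
boundary_hausdorff <- function(a, b) {
  bd <- function(m) {
    er <- EBImage::erode(m * 1, matrix(1, 3, 3)) != 0
    which(m & !er, arr.ind = TRUE)
  }
  pa <- bd(a != 0); pb <- bd(b != 0)
  if (!nrow(pa) || !nrow(pb)) return(Inf)
  d2 <- function(p, q) {
    outer(p[, 1], q[, 1], `-`)^2 + outer(p[, 2], q[, 2], `-`)^2
  }
  m <- d2(pa, pb)
  sqrt(max(max(apply(m, 1, min)), max(apply(m, 2, min))))
}
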