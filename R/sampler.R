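# two-scale patch sampling: candidate extraction on a stride grid, negative
# screening balanced against the positive count, intensity augmentation,
# and the stratified train/validation split

#' Sample counts and the negative-retention fraction
#'
#' Bookkeeping record for the class balance rule. Negatives split into
#' class A (the small patch contains no region pixel) and class B (it
#' contains some); positives have a region pixel at the centre. The balance
#' keeps `0.1 * N1 + 3 * x * N2 = 3 * N3`: 10% of class-A negatives are
#' retained unaugmented, a solved fraction `x` of class-B negatives is
#' retained, and class-B negatives and positives are each tripled by
#' intensity augmentation.
#'
#' @param N1,N2,N3 class-A negative, class-B negative, and positive counts
#' @param x solved retention fraction for class-B negatives (in `[0, 1]`),
#'   `NA` until solved
#' @return a `sample_counts` object
#' @export
sample_counts <- function(N1, N2, N3, x = NA_real_) {
  stopifnot(N1 >= 0, N2 >= 0, N3 >= 0)
  structure(list(N1 = as.integer(N1), N2 = as.integer(N2), N3 = as.integer(N3),
                 x = x), class = "sample_counts")
}

#' @export
print.sample_counts <- function(x, ...) {
  cat(sprintf("<sample_counts> N1 = %d (neg-A), N2 = %d (neg-B), N3 = %d (pos), x = %s\n",
              x$N1, x$N2, x$N3,
              if (is.na(x$x)) "unsolved" else format(x$x, digits = 4)))
  invisible(x)
}

#' Solve the class-B negative retention fraction
#'
#' Solves `0.1 * N1 + 3 * x * N2 = 3 * N3` for `x` and clamps the result to
#' `[0, 1]`; a clamp is reported with a warning and recorded in the
#' `"clamped"` attribute of the returned fraction.
#'
#' @param counts a [sample_counts()]
#' @return the counts with `x` filled in
#' @export
solve_balance <- function(counts) {
  stopifnot(inherits(counts, "sample_counts"))
  if (counts$N2 == 0) {
    if (abs(3 * counts$N3 - 0.1 * counts$N1) > 1e-9)
      stop("unbalanced sample set: no class-B negatives to trade against ",
           "3*N3 - 0.1*N1 = ", 3 * counts$N3 - 0.1 * counts$N1)
    x_raw <- 0
  } else {
    x_raw <- (3 * counts$N3 - 0.1 * counts$N1) / (3 * counts$N2)
  }
  x <- min(max(x_raw, 0), 1)
  clamped <- x != x_raw
  if (clamped)
    warning(sprintf("retention fraction %.4f clamped to %.0f; the screened set will not balance exactly",
                    x_raw, x))
  counts$x <- structure(x, clamped = clamped)
  counts
}

#' Extract two-scale patch candidates on a stride grid
#'
#' Walks a stride-spaced grid over one or more coronal slices and
#' classifies each candidate centre as positive (region pixel at the
#' centre), class-A negative (no region pixel anywhere in the small patch)
#' or class-B negative (some region pixels in the small patch). Patches
#' crossing the border are completed by reflection padding. Patch pixel
#' data are materialised later, at screening time.
#'
#' @param image numeric matrix (one slice) or 3D array/[volume3d()] (many)
#' @param label matching 0/1 integer matrix or array/[label_volume()]
#' @param stride candidate grid spacing, px (>= 1)
#' @param small small patch edge, px (odd)
#' @param large large patch edge, px (odd, > small); captured at this size
#'   and later resampled to `small`
#' @param slices which slices to walk when `image` is 3D (default: all)
#' @return a `patch_candidates` object: per-candidate centres and classes
#'   plus a [sample_counts()]
#' @export
extract_candidates <- function(image, label, stride = 3L, small = 51L,
                               large = 77L, slices = NULL) {
  stopifnot(stride >= 1L, small < large, small %% 2 == 1, large %% 2 == 1)
  if (inherits(image, "volume3d")) image <- image$data
  if (inherits(label, "label_volume")) label <- label$data
  if (is.matrix(image)) {
    image <- array(image, c(1L, dim(image)))
    label <- array(label, c(1L, dim(label)))
    slices <- 1L
  }
  stopifnot(all(dim(image) == dim(label)))
  if (large > min(dim(image)[2:3]))
    stop("large patch exceeds the in-plane image size")
  if (is.null(slices)) slices <- seq_len(dim(image)[1])
  hp <- (small - 1L) %/% 2L

  per_slice <- lapply(slices, function(s) {
    img <- image[s, , , drop = TRUE]
    lab <- label[s, , , drop = TRUE] != 0
    h <- nrow(img); w <- ncol(img)
    gr <- seq(1L, h, by = stride); gc <- seq(1L, w, by = stride)
    # window content test via an integral image over the reflect-padded label
    ridx <- reflect_index((1L - hp):(h + hp), h)
    cidx <- reflect_index((1L - hp):(w + hp), w)
    padded <- lab[ridx, cidx, drop = FALSE]
    sat <- rbind(0, apply(padded, 2, cumsum))
    sat <- cbind(0, t(apply(sat, 1, cumsum)))
    # window around centre (r, c) spans padded rows r..r+2hp, cols c..c+2hp
    win <- function(r, c) sat[r + 2L * hp + 1L, c + 2L * hp + 1L] -
      sat[r, c + 2L * hp + 1L] - sat[r + 2L * hp + 1L, c] + sat[r, c]
    grid <- expand.grid(row = gr, col = gc, KEEP.OUT.ATTRS = FALSE)
    nreg <- mapply(win, grid$row, grid$col)
    pos <- lab[cbind(grid$row, grid$col)]
    cls <- ifelse(pos, "pos", ifelse(nreg == 0, "negA", "negB"))
    data.frame(slice = s, row = grid$row, col = grid$col, class = cls,
               stringsAsFactors = FALSE)
  })
  cand <- do.call(rbind, per_slice)
  counts <- sample_counts(sum(cand$class == "negA"), sum(cand$class == "negB"),
                          sum(cand$class == "pos"))
  structure(list(image = image, label = label, slices = slices,
                 stride = as.integer(stride), small = as.integer(small),
                 large = as.integer(large), candidates = cand,
                 counts = counts),
            class = "patch_candidates")
}

#' @export
print.patch_candidates <- function(x, ...) {
  cat(sprintf("<patch_candidates> %d candidates over %d slice(s), stride %d, patches %d/%d px\n",
              nrow(x$candidates), length(x$slices), x$stride, x$small, x$large))
  print(x$counts)
  invisible(x)
}

# materialise small + large (resampled) patches for 1-based centres on slices
materialise_patches <- function(image, centers, small, large) {
  n <- nrow(centers)
  out_s <- array(0, c(small, small, n))
  out_l <- array(0, c(small, small, n))
  for (s in unique(centers$slice)) {
    idx <- which(centers$slice == s)
    pp <- cpp_extract_patch_pairs(image[s, , , drop = TRUE],
                                  cbind(centers$row[idx], centers$col[idx]),
                                  small, large)
    out_s[, , idx] <- pp$small
    out_l[, , idx] <- pp$large
  }
  list(small = out_s, large = out_l)
}

#' Screen candidates and augment the survivors
#'
#' Applies the balance rule: retains a seeded uniform subsample of
#' `floor(0.1 * N1)` class-A negatives, `floor(x * N2)` class-B negatives,
#' and all positives; class-B negatives and positives are then tripled by
#' intensity scaling (unchanged, +20%, -20%, clipped to the storage
#' range). Class-A negatives are kept unaugmented. The retained totals
#' satisfy `retainedA + 3 * retainedB = 3 * N3` within rounding (when the
#' solved fraction needed no clamping).
#'
#' @param cand a [patch_candidates()] result
#' @param seed subsampling seed
#' @param factors intensity augmentation factors applied to class-B
#'   negatives and positives
#' @param intensity_range clipping bounds for augmented intensities
#' @return a `sample_set`: arrays `small` and `large` (edge x edge x n,
#'   large already resampled to the small edge), integer `label` (1 =
#'   region), a manifest data frame, and the solved counts
#' @export
screen_and_augment <- function(cand, seed = 1L, factors = c(1, 1.2, 0.8),
                               intensity_range = c(0, 255)) {
  stopifnot(inherits(cand, "patch_candidates"))
  counts <- cand$counts
  if (is.na(counts$x)) {
    if (counts$N2 == 0L) {
      # nothing to trade against: screening still applies the 10% rule to
      # class A, but the resulting set cannot balance
      if (abs(3 * counts$N3 - 0.1 * counts$N1) > 1e-9)
        warning("no class-B negatives: screened set will not balance")
      counts$x <- structure(0, clamped = FALSE)
    } else {
      counts <- solve_balance(counts)
    }
  }
  cdf <- cand$candidates
  idxA <- which(cdf$class == "negA")
  idxB <- which(cdf$class == "negB")
  idxP <- which(cdf$class == "pos")
  keepA <- floor(0.1 * counts$N1)
  keepB <- floor(as.numeric(counts$x) * counts$N2)
  with_seed(seed, {
    selA <- sort(idxA[sample.int(length(idxA), keepA)])
    selB <- sort(idxB[sample.int(length(idxB), keepB)])
  })
  sel <- rbind(
    if (keepA) data.frame(i = selA, augment = FALSE),
    if (keepB) data.frame(i = selB, augment = TRUE),
    if (length(idxP)) data.frame(i = idxP, augment = TRUE)
  )
  centers <- cdf[sel$i, ]
  pat <- materialise_patches(cand$image, centers, cand$small, cand$large)
  # expand augmented rows by the three intensity factors
  fac <- ifelse(sel$augment, list(factors), list(1))
  rep_idx <- rep(seq_len(nrow(sel)), lengths(fac))
  fvec <- unlist(fac)
  clip <- function(x) pmin(pmax(x, intensity_range[1]), intensity_range[2])
  n_out <- length(rep_idx)
  small <- array(0, c(cand$small, cand$small, n_out))
  large <- array(0, c(cand$small, cand$small, n_out))
  for (k in seq_len(n_out)) {
    src <- rep_idx[k]
    small[, , k] <- clip(pat$small[, , src] * fvec[k])
    large[, , k] <- clip(pat$large[, , src] * fvec[k])
  }
  manifest <- centers[rep_idx, ]
  manifest$factor <- fvec
  rownames(manifest) <- NULL
  label <- as.integer(manifest$class == "pos")
  balance_gap <- (keepA + 3 * keepB) - 3 * counts$N3
  structure(list(small = small, large = large, label = label,
                 manifest = manifest, counts = counts,
                 patch_sizes = c(cand$small, cand$large),
                 intensity_range = intensity_range,
                 balance_gap = balance_gap),
            class = "sample_set")
}

#' @export
print.sample_set <- function(x, ...) {
  cat(sprintf("<sample_set> %d samples (%d positive, %d negative), patches %d/%d px\n",
              length(x$label), sum(x$label == 1), sum(x$label == 0),
              x$patch_sizes[1], x$patch_sizes[2]))
  invisible(x)
}

# subset helper used by the split
sample_subset <- function(x, idx) {
  structure(list(small = x$small[, , idx, drop = FALSE],
                 large = x$large[, , idx, drop = FALSE],
                 label = x$label[idx], manifest = x$manifest[idx, ],
                 counts = x$counts, patch_sizes = x$patch_sizes,
                 intensity_range = x$intensity_range,
                 balance_gap = x$balance_gap),
            class = "sample_set")
}

#' Class-balanced subsample of a sample set
#'
#' Seeded stratified subsample to at most `n` samples, preserving the
#' class proportions (used for desk-scale training runs).
#'
#' @param samples a `sample_set`
#' @param n maximum number of samples to keep
#' @param seed subsampling seed
#' @return a `sample_set` with at most `n` samples
#' @export
subsample_balanced <- function(samples, n, seed = 1L) {
  stopifnot(inherits(samples, "sample_set"))
  total <- length(samples$label)
  if (total <= n) return(samples)
  frac <- n / total
  keep <- with_seed(seed, {
    unlist(lapply(unique(samples$label), function(cl) {
      idx <- which(samples$label == cl)
      idx[sample.int(length(idx), floor(frac * length(idx)))]
    }))
  })
  sample_subset(samples, sort(keep))
}

#' Stratified train/validation split
#'
#' Splits a sample set into disjoint, exhaustive train and validation
#' subsets, stratified by class: `floor(fraction * n_class)` of each class
#' goes to the train set.
#'
#' @param samples a [screen_and_augment()] result
#' @param fraction train fraction (default 0.8)
#' @param seed shuffling seed
#' @return list with `train` and `val` sample sets
#' @export
split_train_val <- function(samples, fraction = 0.8, seed = 1L) {
  stopifnot(inherits(samples, "sample_set"), length(samples$label) >= 2)
  train_idx <- with_seed(seed, {
    unlist(lapply(unique(samples$label), function(cl) {
      idx <- which(samples$label == cl)
      idx[sample.int(length(idx), floor(fraction * length(idx)))]
    }))
  })
  train_idx <- sort(train_idx)
  val_idx <- setdiff(seq_along(samples$label), train_idx)
  list(train = sample_subset(samples, train_idx),
       val = sample_subset(samples, val_idx))
}
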