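# alternating prediction and tracking localization through the volume:
# masked interval prediction per slice, dilation of each 2D result into the
# next slice's Mask-track, bidirectional propagation, and 3D postprocessing

#' Masked interval prediction on one slice
#'
#' Classifies only mask pixels that fall on a stride-spaced grid (rows and
#' columns `1, 1+stride, ...`), fills the remaining mask pixels from their
#' nearest predicted neighbour (multi-source breadth-first fill), sets
#' everything outside the mask to background, and binarizes at the
#' threshold (ties go to background).
#'
#' @param model a trained `dualpath_model`, or a function
#'   `f(image, centers)` returning region probabilities for 1-based
#'   `(row, col)` centre matrix rows (an oracle classifier for validation)
#' @param image numeric slice matrix
#' @param mask a [mask2d()] (or logical matrix) of the same shape
#' @param stride prediction grid spacing, px (2 skips three quarters of a
#'   full mask)
#' @param threshold probability threshold for the region class
#' @return list with `pred` (logical matrix), `n_visited` (classified
#'   pixel count) and `reduction` (fraction of mask pixels skipped)
#' @export
predict_slice <- function(model, image, mask, stride = 2L, threshold = 0.5) {
  m <- if (inherits(mask, "mask2d")) mask$mask else mask != 0
  if (!all(dim(m) == dim(image))) stop("mask shape must match the image")
  empty <- list(pred = matrix(FALSE, nrow(image), ncol(image)),
                n_visited = 0L, reduction = NA_real_)
  if (!any(m)) return(empty)
  h <- nrow(image); w <- ncol(image)
  on_grid <- matrix(FALSE, h, w)
  on_grid[seq(1L, h, by = stride), seq(1L, w, by = stride)] <- TRUE
  visited <- which(m & on_grid, arr.ind = TRUE)
  if (nrow(visited) == 0L) return(empty)
  probs <- if (is.function(model)) {
    model(image, visited)
  } else {
    pp <- cpp_extract_patch_pairs(image, visited, model$spec$input_size,
                                  model$spec$large_size)
    predict_on_arrays(model_ptr(model), model, pp$small, pp$large)
  }
  bin <- as.numeric(probs > threshold)
  filled <- cpp_bfs_fill(h, w, visited[, 1], visited[, 2], bin)
  filled[is.na(filled)] <- 0
  pred <- (filled > 0) & m
  list(pred = pred, n_visited = nrow(visited),
       reduction = compute_reduction(m, stride))
}

#' Dilate a 2D result into the adjacent slice's localization (Mask-track)
#'
#' @param prev_result logical matrix (previous slice's binary result)
#' @param radius dilation radius, px (default 20)
#' @param slice slice index the mask will constrain
#' @return a [mask2d()] with provenance `"track"`; empty input gives an
#'   empty mask (the propagation stop signal)
#' @export
make_track_mask <- function(prev_result, radius = 20, slice = 1L) {
  mask2d(dilate_disk(prev_result, radius), slice = slice,
         provenance = "track", radius = radius)
}

#' Fraction of mask pixels skipped by interval prediction
#'
#' `1 - visited / |mask|` where visited counts mask pixels on the
#' stride-spaced grid. A full-image mask at stride 2 gives 0.75 (the
#' three-quarters computation saving).
#'
#' @param mask logical matrix or [mask2d()]
#' @param stride grid spacing, px
#' @return the skipped fraction; `NA` (with a message) for an empty mask
#' @export
compute_reduction <- function(mask, stride) {
  stopifnot(stride >= 1)
  m <- if (inherits(mask, "mask2d")) mask$mask else mask != 0
  tot <- sum(m)
  if (tot == 0) {
    message("empty mask: reduction undefined")
    return(NA_real_)
  }
  on_grid <- matrix(FALSE, nrow(m), ncol(m))
  on_grid[seq(1L, nrow(m), by = stride), seq(1L, ncol(m), by = stride)] <- TRUE
  1 - sum(m & on_grid) / tot
}

#' Segment a volume by alternating prediction and tracking localization
#'
#' Predicts the initial slice inside Mask-init, then propagates toward
#' both volume ends: each next slice is constrained by the previous
#' slice's result dilated by `track_radius` (Mask-track). A direction
#' stops when the predicted foreground falls below `min_area` pixels or
#' the volume ends.
#'
#' @param model a trained `dualpath_model` or an oracle classifier
#'   function (see [predict_slice()])
#' @param vol a [volume3d()]
#' @param init a [mask2d()] from [init_mask()] (non-empty)
#' @param stride,threshold interval-prediction parameters
#' @param track_radius Mask-track dilation radius, px
#' @param min_area minimum foreground (px) to continue propagating
#' @param keep_masks retain each slice's mask (for containment checks)?
#' @return a `seg_result` object: binary volume `seg`, per-slice `report`
#'   data frame, the per-slice `masks` (if kept), and stop slices
#' @export
track_volume <- function(model, vol, init, stride = 2L, threshold = 0.5,
                         track_radius = 20, min_area = 20L,
                         keep_masks = TRUE) {
  stopifnot(inherits(vol, "volume3d"), inherits(init, "mask2d"))
  if (!any(init$mask)) stop("initial mask is empty; nothing to segment")
  d <- dim(vol$data)
  seg <- array(FALSE, d)
  masks <- if (keep_masks) vector("list", d[1]) else NULL
  rep_rows <- list()
  note <- function(s, res, prov) {
    rep_rows[[length(rep_rows) + 1L]] <<- data.frame(
      slice = s, provenance = prov, n_visited = res$n_visited,
      n_foreground = sum(res$pred), reduction = res$reduction)
  }
  s0 <- init$slice
  res0 <- predict_slice(model, vol$data[s0, , , drop = TRUE], init, stride,
                        threshold)
  seg[s0, , ] <- res0$pred
  if (keep_masks) masks[[s0]] <- init
  note(s0, res0, "init")
  if (sum(res0$pred) < min_area) {
    warning("initial slice prediction below min_area; returning empty result")
    return(seg_result(seg * 0 > 0, do.call(rbind, rep_rows), masks,
                      start_slice = s0, stopped = c(s0, s0)))
  }
  stopped <- c(s0, s0)
  for (dir in c(-1L, 1L)) {
    prev <- res0$pred
    s <- s0 + dir
    while (s >= 1L && s <= d[1]) {
      mk <- make_track_mask(prev, radius = track_radius, slice = s)
      if (!any(mk$mask)) break
      res <- predict_slice(model, vol$data[s, , , drop = TRUE], mk, stride,
                           threshold)
      seg[s, , ] <- res$pred
      if (keep_masks) masks[[s]] <- mk
      note(s, res, "track")
      if (dir < 0) stopped[1] <- s else stopped[2] <- s
      if (sum(res$pred) < min_area) break
      prev <- res$pred
      s <- s + dir
    }
  }
  report <- do.call(rbind, rep_rows)
  report <- report[order(report$slice), ]
  rownames(report) <- NULL
  seg_result(seg, report, masks, start_slice = s0, stopped = stopped)
}

seg_result <- function(seg, report, masks = NULL, start_slice = NA_integer_,
                       stopped = c(NA_integer_, NA_integer_)) {
  structure(list(seg = seg, report = report, masks = masks,
                 start_slice = start_slice, stopped = stopped),
            class = "seg_result")
}

#' @export
print.seg_result <- function(x, ...) {
  cat(sprintf("<seg_result> %s volume, %d foreground voxels over slices %d..%d (start %d)\n",
              paste(dim(x$seg), collapse = "x"), sum(x$seg),
              x$stopped[1], x$stopped[2], x$start_slice))
  invisible(x)
}

#' Postprocess a 3D segmentation
#'
#' Per-slice hole filling, removal of 3D connected components (26-
#' connectivity) smaller than `min_component` voxels, and 3D Gaussian
#' smoothing of the binary volume re-thresholded at 0.5. The three steps
#' are iterated to a fixed point (at most `max_iter` passes), which makes
#' the operation idempotent on its own output.
#'
#' @param result a `seg_result` or binary 3D array
#' @param min_component minimum component size, voxels
#' @param smooth_sigma Gaussian sigma, voxels (0 disables smoothing)
#' @param max_iter fixed-point iteration cap (smoothing a binary volume and
#'   re-thresholding acts like a curvature flow that settles within a few
#'   tens of passes on region-like shapes)
#' @return same type as the input, postprocessed
#' @export
postprocess <- function(result, min_component = 20L, smooth_sigma = 1,
                        max_iter = 50L) {
  arr <- as_vol_array(result)
  cur <- arr != 0
  for (it in seq_len(max_iter)) {
    prev <- cur
    for (s in seq_len(dim(cur)[1])) {
      sl <- cur[s, , , drop = TRUE]
      if (any(sl)) cur[s, , ] <- EBImage::fillHull(sl * 1) != 0
    }
    lab <- cpp_label3d(cur * 1)
    keep <- which(lab$sizes >= min_component)
    cur <- array(lab$labels %in% keep, dim(cur)) & cur
    if (smooth_sigma > 0) {
      sm <- cpp_gaussian3d(cur * 1, rep(smooth_sigma, 3))
      cur <- sm > 0.5
    }
    if (identical(cur, prev)) break
  }
  if (inherits(result, "seg_result")) {
    result$seg <- cur
    result
  } else cur
}
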