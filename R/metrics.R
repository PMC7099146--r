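# segmentation and localization evaluation: Dice, Precision and Recall on
# binary sets, and the localization Recall / Redundancy pair

#' Dice, Precision and Recall between two binary grids
#'
#' Exact set-count formulas on the automated set I and ground-truth set J:
#' `Dice = 2 |I ∩ J| / (|I| + |J|)`, `Precision = |I ∩ J| / |I|`,
#' `Recall = |I ∩ J| / |J|`. Degenerate denominators give `NA` (with
#' `dice(empty, empty)` defined as 1).
#'
#' @param I,J binary arrays/matrices of identical shape (automated,
#'   ground truth)
#' @return one-row data frame with `dice`, `precision`, `recall` and the
#'   raw counts
#' @export
dice_precision_recall <- function(I, J) {
  I <- as_vol_array_or_matrix(I); J <- as_vol_array_or_matrix(J)
  if (!identical(dim(I), dim(J))) stop("I and J must have the same shape")
  i <- I != 0; j <- J != 0
  ni <- sum(i); nj <- sum(j); nij <- sum(i & j)
  dice <- if (ni + nj == 0) 1 else 2 * nij / (ni + nj)
  precision <- if (ni == 0) NA_real_ else nij / ni
  recall <- if (nj == 0) NA_real_ else nij / nj
  data.frame(dice = dice, precision = precision, recall = recall,
             n_auto = ni, n_truth = nj, n_intersect = nij)
}

as_vol_array_or_matrix <- function(x) {
  if (is.matrix(x)) x
  else if (inherits(x, "mask2d")) x$mask
  else as_vol_array(x)
}

#' Localization quality of a mask against the true region
#'
#' Recall (`|mask ∩ truth| / |truth|`) measures how completely the mask
#' covers the region: it must be near 1 for the subsequent prediction to
#' see every region pixel. Redundancy (`|mask ∩ truth| / |mask|`, the mask
#' precision) measures how loose the mask is; small regions under a wide
#' dilation give low redundancy.
#'
#' @param mask a [mask2d()] or binary matrix
#' @param truth binary matrix of the true region on the same slice
#' @return one-row data frame with `recall` and `redundancy`
#' @export
localization_report <- function(mask, truth) {
  m <- if (inherits(mask, "mask2d")) mask$mask else mask != 0
  t <- truth != 0
  if (!identical(dim(m), dim(t))) stop("mask and truth must have the same shape")
  inter <- sum(m & t)
  if (sum(t) == 0) warning("empty truth: localization recall undefined")
  data.frame(recall = if (sum(t) == 0) NA_real_ else inter / sum(t),
             redundancy = if (sum(m) == 0) NA_real_ else inter / sum(m))
}

#' Evaluate a 3D segmentation against ground truth
#'
#' Volume-level and per-slice Dice / Precision / Recall.
#'
#' @param pred a `seg_result` or binary array
#' @param truth a [label_volume()] or binary array
#' @param region_id region to compare when `truth` carries labels
#' @return list with `volume` (one-row data frame) and `per_slice`
#' @export
evaluate_segmentation <- function(pred, truth, region_id = 1L) {
  p <- as_vol_array(pred) != 0
  t_arr <- as_vol_array(truth)
  t <- if (inherits(truth, "label_volume")) t_arr == region_id else t_arr != 0
  vol <- dice_precision_recall(p, t)
  per_slice <- do.call(rbind, lapply(seq_len(dim(p)[1]), function(s) {
    cbind(slice = s, dice_precision_recall(p[s, , , drop = TRUE],
                                           t[s, , , drop = TRUE]))
  }))
  list(volume = vol, per_slice = per_slice)
}
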