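# core containers: intensity volumes, label volumes, masks, transforms
#
# Convention throughout the package: volumes are 3D arrays indexed
# (slice, row, col), 0-based in C++ and 1-based in R; the first axis is the
# coronal (tracking) axis; voxel spacing is in micrometres and defaults to
# the nominal 10 um isotropic acquisition grid.

#' Intensity volume
#'
#' A 3D scalar grid with voxel spacing and an explicit slice axis. The
#' intensity range records the storage dynamic range (used for clipping by
#' intensity augmentation and for lossless TIFF round trips).
#'
#' @param data 3D numeric array, indexed (slice, row, col); all finite
#' @param spacing voxel size per axis in micrometres, length 3, all > 0
#' @param slice_axis index of the coronal axis (fixed to 1 in this package)
#' @param intensity_range storage range, length-2 numeric
#' @return a `volume3d` object
#' @export
volume3d <- function(data, spacing = c(10, 10, 10), slice_axis = 1L,
                     intensity_range = c(0, 255)) {
  if (length(dim(data)) != 3L) stop("volume data must be a 3D array")
  if (any(dim(data) < 1L)) stop("all volume dimensions must be >= 1")
  if (!all(is.finite(data))) stop("volume intensities must be finite")
  if (length(spacing) != 3L || any(spacing <= 0)) stop("spacing must be 3 positive values")
  if (slice_axis != 1L) stop("the slice axis must be axis 1 (slice, row, col)")
  structure(list(data = data, spacing = as.numeric(spacing),
                 slice_axis = 1L, intensity_range = as.numeric(intensity_range)),
            class = "volume3d")
}

#' @export
print.volume3d <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<volume3d> %d slices of %d x %d px, spacing %s um, range [%g, %g]\n",
              d[1], d[2], d[3], paste(x$spacing, collapse = "x"),
              min(x$data), max(x$data)))
  invisible(x)
}

#' @export
dim.volume3d <- function(x) dim(x$data)

#' Label volume
#'
#' Non-negative integer grid aligned voxel-for-voxel with an intensity
#' volume; 0 is background and `region_ids` lists the present regions.
#'
#' @param data 3D integer array (slice, row, col)
#' @param region_ids integer ids present (defaults to the nonzero values)
#' @return a `label_volume` object
#' @export
label_volume <- function(data, region_ids = NULL) {
  if (length(dim(data)) != 3L) stop("label data must be a 3D array")
  if (any(data < 0)) stop("labels must be non-negative")
  storage.mode(data) <- "integer"
  present <- sort(unique(data[data > 0L]))
  if (is.null(region_ids)) region_ids <- present
  if (!all(present %in% region_ids)) stop("labels outside {0} + region_ids present")
  structure(list(data = data, region_ids = as.integer(region_ids)),
            class = "label_volume")
}

#' @export
print.label_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<label_volume> %d x %d x %d, regions {%s}\n", d[1], d[2], d[3],
              paste(x$region_ids, collapse = ", ")))
  invisible(x)
}

#' @export
dim.label_volume <- function(x) dim(x$data)

# coerce to the underlying array (accepts arrays, volumes, labels, results)
as_vol_array <- function(x) {
  if (is.array(x)) x
  else if (inherits(x, c("volume3d", "label_volume"))) x$data
  else if (inherits(x, "seg_result")) x$seg
  else stop("cannot interpret object as a 3D volume")
}

#' Per-slice localization mask
#'
#' Binary in-plane mask constraining where the classifier is evaluated,
#' with its provenance: `init` for the dilated atlas-mapped middle-slice
#' label (Mask-init), `track` for the dilated previous-slice segmentation
#' (Mask-track).
#'
#' @param mask logical matrix (row, col)
#' @param slice 1-based slice index the mask applies to
#' @param provenance `"init"` or `"track"`
#' @param radius dilation radius (px) that produced the mask
#' @return a `mask2d` object
#' @export
mask2d <- function(mask, slice, provenance = c("init", "track"), radius = 0) {
  provenance <- match.arg(provenance)
  if (!is.matrix(mask)) stop("mask must be a matrix")
  if (radius < 0) stop("dilation radius must be >= 0")
  structure(list(mask = mask != 0, slice = as.integer(slice),
                 provenance = provenance, radius = as.numeric(radius)),
            class = "mask2d")
}

#' @export
print.mask2d <- function(x, ...) {
  cat(sprintf("<mask2d> slice %d, %s, radius %g px, %d foreground px\n",
              x$slice, x$provenance, x$radius, sum(x$mask)))
  invisible(x)
}

#' Spatial transform: affine plus dense displacement fields
#'
#' Maps fixed-grid (subject) voxel coordinates x to moving (atlas)
#' coordinates as T(x) = A [x + u(x); 1], with A a 3x4 affine and u the
#' forward displacement field. The inverse field v inverts x -> x + u(x),
#' so T^-1(y) = w + v(w) with w = A^-1 y.
#'
#' @param affine 3x4 matrix (0-based voxel coordinates)
#' @param forward,inverse displacement fields: lists of three arrays
#'   (per-axis components, voxels), or `NULL` for a purely affine transform
#' @param domain dimension of the fixed grid the fields live on
#' @return a `transform3d` object
#' @export
transform3d <- function(affine = identity_affine(), forward = NULL,
                        inverse = NULL, domain = NULL) {
  stopifnot(is.matrix(affine), nrow(affine) == 3L, ncol(affine) == 4L)
  if (!is.null(forward)) {
    stopifnot(is.list(forward), length(forward) == 3L)
    if (is.null(domain)) domain <- dim(forward[[1]])
  }
  structure(list(affine = affine, forward = forward, inverse = inverse,
                 domain = domain), class = "transform3d")
}

#' @export
print.transform3d <- function(x, ...) {
  cat("<transform3d> affine:\n")
  print(round(x$affine, 4))
  if (!is.null(x$forward)) {
    mx <- sqrt(x$forward[[1]]^2 + x$forward[[2]]^2 + x$forward[[3]]^2)
    cat(sprintf("  displacement field on %s grid, max |u| = %.2f vox\n",
                paste(dim(x$forward[[1]]), collapse = "x"), max(mx)))
  }
  invisible(x)
}

#' @rdname transform3d
#' @export
identity_affine <- function() cbind(diag(3), 0)

#' Check the diffeomorphism invariants of a transform
#'
#' Verifies that composing the forward and inverse displacement fields is
#' close to the identity (mean residual below `tol` voxels) and that the
#' Jacobian determinant of x -> x + u(x) is positive on at least 99% of the
#' grid.
#'
#' @param t a `transform3d`
#' @param tol mean composition residual allowed, voxels
#' @return named list with `residual`, `min_jacobian`, `frac_nonpositive`,
#'   `ok`
#' @export
validate_transform <- function(t, tol = 0.5) {
  stopifnot(inherits(t, "transform3d"))
  if (is.null(t$forward)) {
    return(list(residual = 0, min_jacobian = 1, frac_nonpositive = 0, ok = TRUE))
  }
  res <- cpp_field_residual(t$forward, t$inverse)
  js <- cpp_jacobian_stats(t$forward)
  list(residual = res, min_jacobian = js[1], frac_nonpositive = js[2],
       ok = res < tol && js[2] <= 0.01)
}

# apply a transform to a volume defined on the moving grid, resampling it
# onto the fixed grid (trilinear for intensities, nearest for labels)
apply_transform <- function(t, arr, out_dim, nearest = FALSE, fill = 0) {
  cpp_warp_volume(arr, t$affine, t$forward, as.integer(out_dim),
                  nearest = nearest, fill = fill)
}
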