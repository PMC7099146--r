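# volume readers and writers: multi-page TIFF (8/16-bit, lossless integer
# round trips) and NIfTI-1 (spacing recorded in the header, micrometres)

tiff_bits <- function(maxval) if (maxval <= 255) 8L else 16L

#' Write a volume to disk
#'
#' Multi-page TIFF (`.tif`/`.tiff`; one page per coronal slice, 8- or
#' 16-bit chosen from the intensity range) or NIfTI-1 (`.nii`/`.nii.gz`;
#' voxel spacing stored in the header pixdim, micrometres). Integer-valued
#' volumes round-trip losslessly.
#'
#' @param vol a [volume3d()] or [label_volume()]
#' @param path output path; the extension selects the format
#' @return the path, invisibly
#' @export
write_volume <- function(vol, path) {
  arr <- as_vol_array(vol)
  spacing <- if (inherits(vol, "volume3d")) vol$spacing else c(10, 10, 10)
  ext <- tolower(tools::file_ext(sub("\\.gz$", "", path)))
  if (ext %in% c("tif", "tiff")) {
    bits <- tiff_bits(max(arr, 1))
    scale <- 2^bits - 1
    pages <- lapply(seq_len(dim(arr)[1]),
                    function(s) arr[s, , , drop = TRUE] / scale)
    tiff::writeTIFF(pages, path, bits.per.sample = bits)
  } else if (ext == "nii") {
    img <- RNifti::asNifti(aperm(arr, c(2, 3, 1)))
    RNifti::pixdim(img) <- spacing[c(2, 3, 1)]
    RNifti::writeNifti(img, path)
  } else {
    stop("unsupported volume format: ", path)
  }
  invisible(path)
}

#' Read a volume from disk
#'
#' @param path a multi-page TIFF or NIfTI-1 file
#' @param spacing voxel spacing to record for TIFF input (TIFF headers do
#'   not carry it); NIfTI spacing comes from the header
#' @param label read as a [label_volume()]?
#' @return a [volume3d()] (or [label_volume()])
#' @export
read_volume <- function(path, spacing = c(10, 10, 10), label = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path)
  ext <- tolower(tools::file_ext(sub("\\.gz$", "", path)))
  if (ext %in% c("tif", "tiff")) {
    pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    arr <- array(0, c(length(pages), dim(pages[[1]])))
    for (s in seq_along(pages)) arr[s, , ] <- pages[[s]]
    rng <- c(0, if (max(arr) <= 255) 255 else 65535)
  } else if (ext == "nii") {
    img <- RNifti::readNifti(path)
    arr <- aperm(array(as.numeric(img), dim(img)[1:3]), c(3, 1, 2))
    pd <- RNifti::pixdim(img)
    spacing <- pd[c(3, 1, 2)]
    rng <- c(0, max(255, max(arr)))
  } else {
    stop("unsupported volume format: ", path)
  }
  if (label) label_volume(array(as.integer(round(arr)), dim(arr)))
  else volume3d(arr, spacing = spacing, intensity_range = rng)
}

#' Write a 2D mask as a single-slice image
#'
#' @param mask a [mask2d()]
#' @param path output TIFF path
#' @return the path, invisibly
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "mask2d"))
  tiff::writeTIFF(mask$mask * 1, path, bits.per.sample = 8L)
  invisible(path)
}

#' Persist / restore a trained model
#'
#' Weights, architecture and training configuration serialize together so
#' a restored model predicts identically.
#'
#' @param model a `dualpath_model`
#' @param path output `.rds` path
#' @return `save_model`: the path, invisibly; `load_model`: the model
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "dualpath_model"))
  slim <- model
  slim$ptr_env <- NULL
  saveRDS(slim, path)
  invisible(path)
}

#' @rdname save_model
#' @param path path written by `save_model`
#' @export
load_model <- function(path) {
  model <- readRDS(path)
  model$ptr_env <- new.env(parent = emptyenv())
  class(model) <- "dualpath_model"
  model
}
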