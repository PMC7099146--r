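# internal helpers shared across modules

# run code with a private RNG stream; the caller's .Random.seed is untouched
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

#' Disk structuring element
#'
#' Binary digital disk of the given radius: all pixels whose centre lies
#' within Euclidean distance `radius` of the central pixel. Used for the
#' Mask-init and Mask-track dilations.
#'
#' @param radius disk radius in pixels (>= 0)
#' @return a (2*radius+1) square 0/1 matrix
#' @export
disk_kernel <- function(radius) {
  stopifnot(radius >= 0)
  radius <- as.integer(radius)
  ix <- seq(-radius, radius)
  k <- outer(ix^2, ix^2, `+`) <= radius^2
  storage.mode(k) <- "double"
  k
}

# morphological dilation of a binary matrix by a disk (identity at radius 0)
dilate_disk <- function(x, radius) {
  x <- (x != 0) * 1
  if (radius == 0) return(x != 0)
  EBImage::dilate(x, disk_kernel(radius)) != 0
}

# reflect out-of-range 1-based indices into [1, n] (edge not duplicated)
reflect_index <- function(i, n) {
  if (n == 1) return(rep(1L, length(i)))
  period <- 2L * n - 2L
  i <- ((i - 1L) %% period + period) %% period
  ifelse(i < n, i + 1L, period - i + 1L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
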