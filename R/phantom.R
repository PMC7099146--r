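# synthetic phantom volumes: a single brain-region-like structure with
# cell-body texture, smooth slice-to-slice shape drift, a warped atlas pair,
# and acquisition-style noise (illumination stripes, vignetting)

#' Phantom specification
#'
#' Describes a synthetic subject volume: a superellipse region whose centre
#' and radii drift smoothly from slice to slice (total boundary drift
#' clamped to `d_max` px per slice — the slow slice-to-slice change the
#' tracking localization relies on), textured with Gaussian "cell body"
#' blobs scattered by a Poisson process at different densities inside and
#' outside the region. The region/background mean-intensity ratio is set by
#' `contrast`.
#'
#' @param shape volume dimensions (slices, rows, cols)
#' @param radii initial in-plane superellipse radii (row, col), px
#' @param center initial region centre (row, col); defaults to the slice centre
#' @param exponent superellipse exponent (2 = ellipse)
#' @param d_max maximum boundary drift between adjacent slices, px
#' @param cell_density_in,cell_density_out expected blobs per 1000 px^2
#'   inside / outside the region
#' @param blob_radius blob radius, px (Gaussian sigma = blob_radius / 2)
#' @param blob_amplitude peak intensity added by one blob
#' @param contrast target ratio of region mean intensity to background mean
#' @param base_intensity background pedestal intensity
#' @param intensity_range storage range (clipping bounds)
#' @param slice_range slices on which the region exists (default: all)
#' @param spacing voxel spacing, micrometres
#' @param seed integer seed making the phantom reproducible
#' @return a `phantom_spec` object
#' @export
phantom_spec <- function(shape = c(100, 200, 300), radii = c(45, 60),
                         center = NULL, exponent = 2.5, d_max = 10,
                         cell_density_in = 8, cell_density_out = 1,
                         blob_radius = 4, blob_amplitude = 90, contrast = 3,
                         base_intensity = 30, intensity_range = c(0, 255),
                         slice_range = NULL, spacing = c(10, 10, 10),
                         seed = 1L) {
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3L, all(shape >= 1L))
  if (is.null(center)) center <- c((shape[2] + 1) / 2, (shape[3] + 1) / 2)
  if (d_max < 0) stop("d_max must be >= 0")
  if (cell_density_in < 0 || cell_density_out < 0) stop("densities must be >= 0")
  if (blob_radius <= 0 || blob_radius >= min(shape[2:3]))
    stop("blob_radius must be in (0, min in-plane dimension)")
  if (is.null(slice_range)) slice_range <- c(1L, shape[1])
  slice_range <- as.integer(slice_range)
  stopifnot(slice_range[1] >= 1L, slice_range[2] <= shape[1],
            slice_range[1] <= slice_range[2])
  # reject regions that do not fit the image at the start
  if (center[1] - radii[1] < 1 || center[1] + radii[1] > shape[2] ||
      center[2] - radii[2] < 1 || center[2] + radii[2] > shape[3])
    stop("region exceeds image bounds")
  structure(list(shape = shape, radii = radii, center = center,
                 exponent = exponent, d_max = d_max,
                 cell_density_in = cell_density_in,
                 cell_density_out = cell_density_out,
                 blob_radius = blob_radius, blob_amplitude = blob_amplitude,
                 contrast = contrast, base_intensity = base_intensity,
                 intensity_range = intensity_range,
                 slice_range = slice_range, spacing = spacing,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# per-slice superellipse mask: |dr/a|^e + |dc/b|^e <= 1
superellipse_mask <- function(nr, nc, center, radii, exponent) {
  dr <- abs(seq_len(nr) - center[1]) / radii[1]
  dc <- abs(seq_len(nc) - center[2]) / radii[2]
  outer(dr^exponent, dc^exponent, `+`) <= 1
}

# add one Gaussian blob into a slice (in place value, returns slice)
add_blob <- function(slice, r0, c0, sigma, amp) {
  w <- ceiling(3 * sigma)
  rr <- max(1, round(r0) - w):min(nrow(slice), round(r0) + w)
  cc <- max(1, round(c0) - w):min(ncol(slice), round(c0) + w)
  g <- amp * exp(-outer((rr - r0)^2, (cc - c0)^2, `+`) / (2 * sigma^2))
  slice[rr, cc] <- slice[rr, cc] + g
  slice
}

# expected per-pixel intensity contributed by the blob field at a density
# (blobs per px^2): density * amplitude * 2*pi*sigma^2
blob_mean <- function(density_per_px, sigma, amp) density_per_px * amp * 2 * pi * sigma^2

#' Generate a synthetic subject volume and its ground-truth label
#'
#' Draws, per slice, a Poisson number of blob centres at `cell_density_in`
#' inside the region and `cell_density_out` outside, renders Gaussian blobs
#' over a background pedestal, and adds an in-region pedestal chosen so
#' that the region/background mean-intensity ratio equals `contrast`.
#' Region centre and radii follow a clamped random walk so adjacent-slice
#' boundary drift stays at or below `d_max` px. Identical seeds give
#' bit-identical output.
#'
#' @param spec a [phantom_spec()]
#' @return list with `volume` (a [volume3d()]), `label` (a
#'   [label_volume()]; region id 1), and `meta` (per-slice region
#'   parameters and blob counts)
#' @export
make_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  d <- spec$shape
  sigma <- spec$blob_radius / 2
  dens_in <- spec$cell_density_in / 1000
  dens_out <- spec$cell_density_out / 1000
  mean_out <- spec$base_intensity + blob_mean(dens_out, sigma, spec$blob_amplitude)
  pedestal <- spec$contrast * mean_out - spec$base_intensity -
    blob_mean(dens_in, sigma, spec$blob_amplitude)
  if (pedestal < 0) {
    warning("contrast target unreachable with these densities; pedestal clamped to 0")
    pedestal <- 0
  }
  # drift budget: |d center| + max |d radii| <= d_max (superellipse boundary
  # moves by at most the centre shift plus the largest radius change)
  step_c <- 0.6 * spec$d_max
  step_r <- 0.4 * spec$d_max

  vol <- array(0, d)
  lab <- array(0L, d)
  meta <- data.frame(slice = seq_len(d[1]), center_r = NA_real_,
                     center_c = NA_real_, radius_r = NA_real_,
                     radius_c = NA_real_, n_blobs_in = 0L, n_blobs_out = 0L)
  with_seed(spec$seed, {
    ctr <- spec$center
    rad <- spec$radii
    for (s in seq_len(d[1])) {
      slice <- matrix(spec$base_intensity, d[2], d[3])
      region <- NULL
      if (s >= spec$slice_range[1] && s <= spec$slice_range[2]) {
        region <- superellipse_mask(d[2], d[3], ctr, rad, spec$exponent)
        lab[s, , ] <- region * 1L
        meta[s, 2:5] <- c(ctr, rad)
        slice <- slice + pedestal * region
        area <- sum(region)
        n_in <- stats::rpois(1, dens_in * area)
        placed <- 0L
        while (placed < n_in) {
          r0 <- stats::runif(1, 1, d[2]); c0 <- stats::runif(1, 1, d[3])
          ir <- min(max(1L, round(r0)), d[2]); ic <- min(max(1L, round(c0)), d[3])
          if (region[ir, ic]) {
            slice <- add_blob(slice, r0, c0, sigma, spec$blob_amplitude)
            placed <- placed + 1L
          }
        }
        meta$n_blobs_in[s] <- n_in
      }
      out_area <- d[2] * d[3] - sum(lab[s, , ])
      n_out <- stats::rpois(1, dens_out * out_area)
      placed <- 0L
      while (placed < n_out) {
        r0 <- stats::runif(1, 1, d[2]); c0 <- stats::runif(1, 1, d[3])
        ir <- min(max(1L, round(r0)), d[2]); ic <- min(max(1L, round(c0)), d[3])
        if (is.null(region) || !region[ir, ic]) {
          slice <- add_blob(slice, r0, c0, sigma, spec$blob_amplitude)
          placed <- placed + 1L
        }
      }
      meta$n_blobs_out[s] <- n_out
      vol[s, , ] <- round(pmin(pmax(slice, spec$intensity_range[1]),
                               spec$intensity_range[2]))
      # drift the region for the next slice (clamped random walk)
      ang <- stats::runif(1, 0, 2 * pi)
      mag <- stats::runif(1, 0, step_c)
      ctr_new <- ctr + mag * c(cos(ang), sin(ang))
      rad_new <- rad + stats::runif(2, -step_r / 2, step_r / 2)
      rad_new <- pmax(rad_new, 5)
      # keep the region inside the image
      ctr_new[1] <- min(max(ctr_new[1], 1 + rad_new[1]), d[2] - rad_new[1])
      ctr_new[2] <- min(max(ctr_new[2], 1 + rad_new[2]), d[3] - rad_new[2])
      ctr <- ctr_new; rad <- rad_new
    }
  })
  list(volume = volume3d(vol, spacing = spec$spacing,
                         intensity_range = spec$intensity_range),
       label = label_volume(lab, region_ids = 1L),
       meta = meta)
}

#' Generate an atlas pair related to the subject phantom by a known warp
#'
#' Regenerates the subject phantom from `spec`, then deforms it by a
#' smooth, invertible sinusoidal displacement field with maximum voxel
#' displacement `warp_amplitude`, mimicking an average-intensity atlas plus
#' label volume whose true spatial relation to the subject is known. The
#' returned ground-truth transform maps subject grid coordinates to atlas
#' coordinates, so resampling the atlas label through it reproduces the
#' subject label.
#'
#' @param spec a [phantom_spec()] describing the subject
#' @param warp_amplitude maximum displacement, px (>= 0; 0 = identity)
#' @param seed seed for the warp phases (independent of the subject seed)
#' @param wavelength sinusoid wavelength, px; defaults to a multiple of the
#'   amplitude large enough to keep the warp fold-free
#' @return list with `volume`, `label` (the atlas pair) and `transform`
#'   (the ground-truth [transform3d()])
#' @export
make_atlas_pair <- function(spec, warp_amplitude = 15, seed = spec$seed + 1000L,
                            wavelength = NULL) {
  stopifnot(inherits(spec, "phantom_spec"), warp_amplitude >= 0)
  subject <- make_phantom(spec)
  d <- spec$shape
  if (warp_amplitude == 0) {
    return(list(volume = subject$volume, label = subject$label,
                transform = transform3d(domain = d)))
  }
  if (is.null(wavelength)) wavelength <- max(16 * warp_amplitude, 96)
  u <- with_seed(seed, {
    ph <- stats::runif(6, 0, 2 * pi)
    sgrid <- seq_len(d[1]); rgrid <- seq_len(d[2]); cgrid <- seq_len(d[3])
    # in-plane separable sinusoids, slowly modulated along the slice axis;
    # the slice-axis component gets its own amplitude bounded by the slice
    # count so the axial derivative stays well below 1 (no folding)
    mod_s <- 0.6 + 0.4 * sin(2 * pi * sgrid / (2 * d[1]) + ph[5])
    # cosine taper toward the in-plane borders: |u(d)| <= d at distance d
    # from the border, so no content is displaced out of the domain (keeps
    # the inverse field accurate everywhere)
    taper <- function(n, m) {
      dd <- pmin(seq_len(n) - 1, n - seq_len(n))
      ifelse(dd >= m, 1, 0.5 * (1 - cos(pi * dd / m)))
    }
    m_r <- min(4 * warp_amplitude, (d[2] - 1) / 2)
    m_c <- min(4 * warp_amplitude, (d[3] - 1) / 2)
    env2d <- outer(taper(d[2], m_r), taper(d[3], m_c))
    ur <- outer(mod_s, env2d * outer(sin(2 * pi * rgrid / wavelength + ph[1]),
                                     cos(2 * pi * cgrid / wavelength + ph[2])))
    uc <- outer(mod_s, env2d * outer(cos(2 * pi * rgrid / wavelength + ph[3]),
                                     sin(2 * pi * cgrid / wavelength + ph[4])))
    k <- 0.98 * warp_amplitude / max(sqrt(ur^2 + uc^2))
    ur <- ur * k; uc <- uc * k
    a_s <- min(0.2 * warp_amplitude, 0.15 * d[1])
    # axial component tapers to zero at the first/last slice so no content
    # is displaced out of the volume along the slice axis
    env_s <- if (d[1] > 1) sin(pi * (sgrid - 1) / (d[1] - 1)) else 0
    us <- a_s * outer(env_s * sin(2 * pi * sgrid / (2 * d[1]) + ph[6]),
                      outer(cos(2 * pi * rgrid / (2 * wavelength)),
                            cos(2 * pi * cgrid / (2 * wavelength))))
    tot <- max(sqrt(us^2 + ur^2 + uc^2))
    k2 <- if (tot > warp_amplitude) warp_amplitude / tot else 1
    list(us * k2, ur * k2, uc * k2)  # components along (slice, row, col)
  })
  js <- cpp_jacobian_stats(u)
  if (js[1] <= 0)
    stop("warp amplitude too large: the deformation folds (Jacobian <= 0)")
  uinv <- cpp_invert_field(u, iters = 10L)
  tfm <- transform3d(forward = u, inverse = uinv, domain = d)
  # atlas(y) = subject((id + u)^-1 (y)): warp the subject by the inverse field
  atlas_vol <- cpp_warp_volume(subject$volume$data, identity_affine(), uinv,
                               as.integer(d), nearest = FALSE,
                               fill = spec$base_intensity)
  # linear interpolation of the binary region, re-thresholded: keeps the
  # warped boundary at sub-voxel accuracy
  atlas_lab <- (cpp_warp_volume((subject$label$data != 0) * 1,
                                identity_affine(), uinv, as.integer(d),
                                nearest = FALSE, fill = 0) > 0.5) * 1L
  list(volume = volume3d(round(atlas_vol), spacing = spec$spacing,
                         intensity_range = spec$intensity_range),
       label = label_volume(atlas_lab, region_ids = 1L),
       transform = tfm)
}

#' Add acquisition-style noise to a volume
#'
#' Models two artefacts of long-term micro-optical imaging with uneven
#' illumination: periodic multiplicative stripes along one in-plane axis
#' and radial intensity falloff toward the slice corners (vignetting).
#' `strength = 0` returns the input unchanged.
#'
#' @param vol a [volume3d()]
#' @param stripes add multiplicative bands varying along the column axis?
#' @param vignette add radial corner darkening?
#' @param strength artefact strength in `[0, 1]`
#' @param period stripe period, px
#' @param seed seed for the per-slice stripe phases
#' @return a new [volume3d()]
#' @export
add_noise <- function(vol, stripes = TRUE, vignette = TRUE, strength = 0.3,
                      period = 40, seed = 1L) {
  stopifnot(inherits(vol, "volume3d"), strength >= 0, strength <= 1)
  if (strength == 0 || (!stripes && !vignette)) return(vol)
  d <- dim(vol$data)
  out <- vol$data
  rr <- seq_len(d[2]); cc <- seq_len(d[3])
  ctr <- c((d[2] + 1) / 2, (d[3] + 1) / 2)
  dmax2 <- (d[2] - ctr[1])^2 + (d[3] - ctr[2])^2
  vig <- 1 - strength * outer((rr - ctr[1])^2, (cc - ctr[2])^2, `+`) / dmax2
  with_seed(seed, {
    for (s in seq_len(d[1])) {
      f <- matrix(1, d[2], d[3])
      if (stripes) {
        phase <- stats::runif(1, 0, 2 * pi)
        band <- 1 + strength * 0.5 * sin(2 * pi * cc / period + phase)
        f <- f * matrix(band, d[2], d[3], byrow = TRUE)
      }
      if (vignette) f <- f * vig
      out[s, , ] <- round(pmin(pmax(out[s, , ] * f, vol$intensity_range[1]),
                               vol$intensity_range[2]))
    }
  })
  volume3d(out, spacing = vol$spacing, intensity_range = vol$intensity_range)
}
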