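# initial localization: multi-resolution mutual-information registration of
# the atlas to the subject (affine stage, then a symmetric diffeomorphic
# demons-style nonlinear stage maintaining opposing-direction fields with
# Gaussian regularization), label propagation, and the dilated middle-slice
# Mask-init

#' Histogram mutual information between two volumes
#'
#' Joint 32-bin (by default) histogram MI in nats, computed over the whole
#' grid with each volume binned over its own range.
#'
#' @param a,b numeric arrays of identical shape
#' @param bins histogram bins per axis
#' @return mutual information (nats)
#' @export
mutual_information <- function(a, b, bins = 32L) {
  a <- as.numeric(a); b <- as.numeric(b)
  bin <- function(x) {
    r <- range(x)
    if (r[1] == r[2]) return(rep(1L, length(x)))
    pmin(pmax(floor((x - r[1]) / (r[2] - r[1]) * bins) + 1L, 1L), bins)
  }
  ia <- bin(a); ib <- bin(b)
  joint <- tabulate((ia - 1L) * bins + ib, nbins = bins * bins) / length(a)
  pa <- tabulate(ia, bins) / length(a)
  pb <- tabulate(ib, bins) / length(b)
  ent <- function(p) { p <- p[p > 0]; -sum(p * log(p)) }
  ent(pa) + ent(pb) - ent(joint)
}

# build a 3x4 affine from 9 parameters (translation, rotation [rad],
# log-scale), rotating/scaling about the grid centre
params_to_affine <- function(par, dims) {
  t <- par[1:3]; r <- par[4:6]; s <- exp(par[7:9])
  cx <- (dims - 1) / 2
  Rx <- rbind(c(1, 0, 0), c(0, cos(r[1]), -sin(r[1])), c(0, sin(r[1]), cos(r[1])))
  Ry <- rbind(c(cos(r[2]), 0, sin(r[2])), c(0, 1, 0), c(-sin(r[2]), 0, cos(r[2])))
  Rz <- rbind(c(cos(r[3]), -sin(r[3]), 0), c(sin(r[3]), cos(r[3]), 0), c(0, 0, 1))
  M <- Rz %*% Ry %*% Rx %*% diag(s)
  cbind(M, cx - M %*% cx + t)
}

# rescale a full-resolution affine to a pyramid level (coordinates shrink by
# `factor`): A_f = S A S^-1 with S = diag(1/f)
affine_at_level <- function(A, factor) {
  M <- A[, 1:3]
  cbind(M, A[, 4] / factor)
}

# downsample a volume by an integer pyramid factor (Gaussian antialias +
# trilinear resize)
pyr_level <- function(arr, factor) {
  if (factor == 1) return(arr)
  sm <- cpp_gaussian3d(arr, rep(factor / 2, 3))
  nd <- pmax(as.integer(ceiling(dim(arr) / factor)), 1L)
  cpp_resize3d(sm, nd)
}

# normalize intensities to [0, 1] (demons force scaling)
norm01 <- function(x) {
  r <- range(x)
  if (r[1] == r[2]) return(x * 0)
  (x - r[1]) / (r[2] - r[1])
}

# one symmetric demons pass at a fixed resolution: returns the forward field
# (fixed -> moving, level coordinates) refined from `u`, plus the backward
# field. Opposing-direction updates, each smoothed (fluid), with diffusion
# smoothing of the fields; symmetrised by averaging each field with the
# inverse of its opposite.
demons_level <- function(fixed, moving, u, ub, iters, sigma_fluid = 1,
                         sigma_diffusion = 2, step_cap = 2) {
  f <- norm01(fixed); m <- norm01(moving)
  smooth_field <- function(v, s)
    lapply(v, function(comp) cpp_gaussian3d(comp, rep(s, 3)))
  demons_step <- function(tgt, src, disp) {
    warped <- cpp_warp_volume(src, identity_affine(), disp, dim(tgt), fill = 0)
    g <- cpp_gradient3d(warped)
    diffim <- tgt - warped
    g2 <- g[[1]]^2 + g[[2]]^2 + g[[3]]^2
    denom <- g2 + diffim^2
    scale <- ifelse(denom > 1e-9, diffim / denom, 0)
    step <- lapply(g, function(comp) {
      v <- comp * scale
      pmin(pmax(v, -step_cap), step_cap)
    })
    smooth_field(step, sigma_fluid)
  }
  add_fields <- function(a, b) Map(`+`, a, b)
  for (it in seq_len(iters)) {
    u <- smooth_field(add_fields(u, demons_step(f, m, u)), sigma_diffusion)
    ub <- smooth_field(add_fields(ub, demons_step(m, f, ub)), sigma_diffusion)
    # symmetrise: opposing fields should invert each other
    inv_ub <- cpp_invert_field(ub, iters = 2L)
    inv_u <- cpp_invert_field(u, iters = 2L)
    u <- Map(function(a, b) (a + b) / 2, u, inv_ub)
    ub <- Map(function(a, b) (a + b) / 2, ub, inv_u)
  }
  list(u = u, ub = ub)
}

#' Register a moving volume (atlas) to a fixed volume (subject)
#'
#' Multi-resolution pyramid (default factors 4, 2, 1). Each level runs an
#' affine stage maximizing 32-bin histogram mutual information
#' (derivative-free optimization over translation, rotation and log-scale,
#' seeded by a coarse translation scan at the lowest resolution) followed
#' by a symmetric nonlinear stage: demons-style opposing-direction field
#' updates with Gaussian fluid/diffusion regularization, symmetrised so
#' the two fields invert each other. A level whose nonlinear stage fails to
#' improve MI is reverted, so MI is non-decreasing per level. If more than
#' 1% of Jacobian determinants of the final field are non-positive the
#' field is re-smoothed.
#'
#' @param fixed,moving [volume3d()] objects (or arrays) on comparable grids
#' @param levels number of pyramid levels (factors `2^(levels-1) ... 1`)
#' @param affine_only skip the nonlinear stage?
#' @param demons_iters per-level nonlinear iteration counts (coarse to
#'   fine), recycled as needed
#' @param sigma_diffusion Gaussian smoothing (voxels) applied to the
#'   displacement fields each iteration
#' @param verbose print per-level MI?
#' @return a [transform3d()] mapping fixed-grid coordinates to moving
#'   coordinates, with an `mi` attribute tracing per-level MI
#' @export
register_volumes <- function(fixed, moving, levels = 3L, affine_only = FALSE,
                             demons_iters = c(30L, 15L, 5L),
                             sigma_diffusion = 2, verbose = FALSE) {
  F0 <- as_vol_array(if (inherits(fixed, "volume3d")) fixed$data else fixed)
  M0 <- as_vol_array(if (inherits(moving, "volume3d")) moving$data else moving)
  if (diff(range(F0)) == 0 || diff(range(M0)) == 0)
    stop("registration requires non-constant volumes")
  factors <- 2L^((levels - 1L):0L)
  par <- rep(0, 9)
  u <- ub <- NULL
  mi_trace <- list()
  demons_iters <- rep_len(demons_iters, levels)
  for (li in seq_along(factors)) {
    f <- factors[li]
    Fl <- pyr_level(F0, f); Ml <- pyr_level(M0, f)
    neg_mi <- function(p) {
      A <- affine_at_level(params_to_affine(p, dim(F0)), f)
      W <- cpp_warp_volume(Ml, A, NULL, dim(Fl), fill = min(Ml))
      v <- -mutual_information(Fl, W)
      if (!is.finite(v)) stop("registration metric became non-finite")
      v
    }
    if (li == 1L) {
      # coarse translation scan (full-resolution voxel units)
      span <- 6 * f
      grid <- expand.grid(t1 = seq(-span, span, by = 2 * f),
                          t2 = seq(-span, span, by = 2 * f),
                          t3 = seq(-span, span, by = 2 * f))
      vals <- apply(grid, 1, function(g) neg_mi(c(g, par[4:9])))
      par[1:3] <- as.numeric(grid[which.min(vals), ])
    }
    scale_par <- c(rep(2 * f, 3), rep(0.05, 3), rep(0.05, 3))
    opt <- stats::optim(par, neg_mi, method = "Nelder-Mead",
                        control = list(maxit = if (li == 1L) 300 else 120,
                                       parscale = scale_par))
    par <- opt$par
    A_full <- params_to_affine(par, dim(F0))
    A_lev <- affine_at_level(A_full, f)
    Ml_aff <- cpp_warp_volume(Ml, A_lev, NULL, dim(Fl), fill = min(Ml))
    mi_affine <- mutual_information(Fl, Ml_aff)
    if (is.null(u)) {
      zero <- array(0, dim(Fl))
      u <- list(zero, zero, zero); ub <- list(zero, zero, zero)
    } else {
      # upsample the fields from the previous level (coordinates double)
      u <- lapply(u, function(cmp) 2 * cpp_resize3d(cmp, dim(Fl)))
      ub <- lapply(ub, function(cmp) 2 * cpp_resize3d(cmp, dim(Fl)))
    }
    if (!affine_only && demons_iters[li] > 0) {
      res <- demons_level(Fl, Ml_aff, u, ub, demons_iters[li],
                          sigma_diffusion = sigma_diffusion)
      W <- cpp_warp_volume(Ml_aff, identity_affine(), res$u, dim(Fl), fill = 0)
      mi_nl <- mutual_information(Fl, W)
      if (mi_nl >= mi_affine) {
        u <- res$u; ub <- res$ub
      } else {
        mi_nl <- mi_affine  # revert: keep the pre-stage fields
      }
    } else mi_nl <- mi_affine
    mi_trace[[li]] <- data.frame(level = li, factor = f,
                                 mi_affine = mi_affine, mi_final = mi_nl)
    if (verbose)
      message(sprintf("level %d (x%d): MI affine %.4f -> nonlinear %.4f",
                      li, f, mi_affine, mi_nl))
  }
  # bring fields to the full-resolution grid
  ffin <- factors[length(factors)]
  if (ffin != 1L) {
    u <- lapply(u, function(cmp) ffin * cpp_resize3d(cmp, dim(F0)))
    ub <- lapply(ub, function(cmp) ffin * cpp_resize3d(cmp, dim(F0)))
  }
  js <- cpp_jacobian_stats(u)
  if (js[2] > 0.01) {
    warning("displacement field folds on >1% of the grid; re-regularizing")
    u <- lapply(u, function(cmp) cpp_gaussian3d(cmp, rep(2 * sigma_diffusion, 3)))
  }
  tfm <- transform3d(affine = params_to_affine(par, dim(F0)), forward = u,
                     inverse = cpp_invert_field(u, iters = 8L),
                     domain = dim(F0))
  tfm$mi <- do.call(rbind, mi_trace)
  tfm
}

#' Map an atlas region label onto the subject grid
#'
#' Nearest-neighbour resampling of the binary region through the
#' registration transform: `out(x) = atlas_label(T(x))`.
#'
#' @param transform a [transform3d()] from [register_volumes()] (fixed =
#'   subject, moving = atlas)
#' @param atlas_label a [label_volume()]
#' @param region_id region to map (must be present in the atlas label)
#' @return a binary [label_volume()] on the subject grid (values 0 /
#'   `region_id`)
#' @export
map_label <- function(transform, atlas_label, region_id = 1L) {
  stopifnot(inherits(transform, "transform3d"),
            inherits(atlas_label, "label_volume"))
  if (!(region_id %in% atlas_label$region_ids))
    stop(sprintf("region %d not present in the atlas label", region_id))
  bin <- (atlas_label$data == region_id) * 1
  out_dim <- transform$domain %||% dim(atlas_label$data)
  mapped <- apply_transform(transform, bin, out_dim, nearest = TRUE, fill = 0)
  label_volume(array(as.integer(mapped * region_id), out_dim),
               region_ids = as.integer(region_id))
}

#' Build the initial localization mask (Mask-init)
#'
#' Selects the middle slice of the mapped region's nonzero slice range
#' (lower median on ties) and dilates that slice's label by a disk. The
#' dilation absorbs residual registration error so that the true region on
#' the starting slice is contained in the mask.
#'
#' @param mapped a mapped [label_volume()] (nonzero somewhere)
#' @param radius dilation radius, px (default 50)
#' @return a [mask2d()] with provenance `"init"`
#' @export
init_mask <- function(mapped, radius = 50) {
  stopifnot(inherits(mapped, "label_volume"))
  nz <- which(apply(mapped$data != 0, 1, any))
  if (!length(nz)) stop("mapped region is empty; cannot localize")
  mid <- (min(nz) + max(nz)) %/% 2L
  sl <- mapped$data[mid, , , drop = TRUE] != 0
  mask2d(dilate_disk(sl, radius), slice = mid, provenance = "init",
         radius = radius)
}
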