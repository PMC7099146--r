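# end-to-end run: localize (register atlas -> map label -> Mask-init),
# track through the volume, postprocess, optionally evaluate; with a
# reproducible JSON-able run report

#' Pipeline run configuration
#'
#' Collects every tunable of the localization + tracking pipeline. Paths
#' may be given instead of in-memory objects; [run_pipeline()] loads them.
#'
#' @param volume subject [volume3d()] or path
#' @param atlas_volume,atlas_label atlas pair (objects or paths)
#' @param model trained `dualpath_model` or path to a saved model
#' @param truth optional ground-truth [label_volume()] or path (enables
#'   evaluation)
#' @param region_id region to localize and segment
#' @param init_radius Mask-init dilation radius, px
#' @param track_radius Mask-track dilation radius, px
#' @param stride interval-prediction grid spacing, px
#' @param threshold classifier probability threshold
#' @param min_area tracking stop threshold, px
#' @param min_component,smooth_sigma postprocessing parameters
#' @param levels registration pyramid levels
#' @param seed run seed
#' @return a `run_config` object
#' @export
run_config <- function(volume, atlas_volume, atlas_label, model,
                       truth = NULL, region_id = 1L, init_radius = 50,
                       track_radius = 20, stride = 2L, threshold = 0.5,
                       min_area = 20L, min_component = 20L, smooth_sigma = 1,
                       levels = 3L, seed = 1L) {
  stopifnot(init_radius >= 0, track_radius >= 0, stride >= 1)
  structure(list(volume = volume, atlas_volume = atlas_volume,
                 atlas_label = atlas_label, model = model, truth = truth,
                 region_id = as.integer(region_id),
                 init_radius = init_radius, track_radius = track_radius,
                 stride = as.integer(stride), threshold = threshold,
                 min_area = as.integer(min_area),
                 min_component = as.integer(min_component),
                 smooth_sigma = smooth_sigma, levels = as.integer(levels),
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose keys match the [run_config()] arguments
#' @return a `run_config`
#' @export
read_run_config <- function(path) {
  do.call(run_config, yaml::read_yaml(path))
}

resolve_input <- function(x, loader) {
  if (is.character(x)) loader(x) else x
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE))
}

#' Run the full segmentation pipeline
#'
#' Register the atlas to the subject, map the region label, build
#' Mask-init from the dilated middle slice, track-segment the volume,
#' postprocess in 3D, and (when ground truth is supplied) evaluate. Every
#' stage failure aborts with a stage-tagged diagnostic. The returned
#' report embeds the configuration and seed, so a run is reproducible from
#' its report alone.
#'
#' @param config a [run_config()]
#' @param verbose print stage progress?
#' @return list with `result` (a postprocessed `seg_result`), `metrics`
#'   (or `NULL`), `transform`, `init`, and `report`
#' @export
run_pipeline <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "run_config"))
  vol <- stage("load", resolve_input(config$volume, read_volume))
  atlas_vol <- stage("load", resolve_input(config$atlas_volume, read_volume))
  atlas_lab <- stage("load", resolve_input(
    config$atlas_label, function(p) read_volume(p, label = TRUE)))
  model <- stage("load", resolve_input(config$model, load_model))
  truth <- if (!is.null(config$truth))
    stage("load", resolve_input(config$truth,
                                function(p) read_volume(p, label = TRUE)))
  stage("localize", if (!(config$region_id %in% atlas_lab$region_ids))
    stop(sprintf("region %d not present in the atlas label", config$region_id)))
  if (verbose) message("localize: registering atlas to subject")
  tfm <- stage("localize", register_volumes(vol, atlas_vol,
                                            levels = config$levels))
  mapped <- stage("localize", map_label(tfm, atlas_lab, config$region_id))
  init <- stage("localize", init_mask(mapped, radius = config$init_radius))
  if (verbose) message(sprintf("track: start slice %d", init$slice))
  res <- stage("track", track_volume(model, vol, init,
                                     stride = config$stride,
                                     threshold = config$threshold,
                                     track_radius = config$track_radius,
                                     min_area = config$min_area))
  res <- stage("postprocess", postprocess(res,
                                          min_component = config$min_component,
                                          smooth_sigma = config$smooth_sigma))
  metrics <- NULL
  if (!is.null(truth))
    metrics <- stage("evaluate",
                     evaluate_segmentation(res, truth, config$region_id))
  cfg_record <- config
  for (f in c("volume", "atlas_volume", "atlas_label", "model", "truth"))
    if (!is.character(cfg_record[[f]])) cfg_record[[f]] <-
      if (is.null(cfg_record[[f]])) NULL else "<in-memory>"
  report <- list(config = unclass(cfg_record), seed = config$seed,
                 package_version = as.character(utils::packageVersion("dualpathseg")),
                 start_slice = init$slice, stopped = res$stopped,
                 per_slice = res$report,
                 volume_dice = if (!is.null(metrics)) metrics$volume$dice)
  list(result = res, metrics = metrics, transform = tfm, init = init,
       report = report)
}

#' Write a pipeline run report as JSON
#'
#' @param run a [run_pipeline()] result
#' @param path output JSON path
#' @return the path, invisibly
#' @export
write_run_report <- function(run, path) {
  jsonlite::write_json(run$report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Plot one slice with optional mask and segmentation overlays
#'
#' @param vol a [volume3d()]
#' @param slice slice index
#' @param mask optional [mask2d()] drawn as a contour
#' @param seg optional binary matrix / `seg_result` drawn as a contour
#' @param ... passed to [graphics::image()]
#' @return invisibly, `NULL`
#' @export
plot_slice <- function(vol, slice, mask = NULL, seg = NULL, ...) {
  img <- as_vol_array(vol)[slice, , , drop = TRUE]
  graphics::image(t(img)[, nrow(img):1], col = grDevices::gray.colors(256),
                  axes = FALSE, asp = nrow(img) / ncol(img), ...)
  add_contour <- function(m, col) {
    m <- if (inherits(m, "mask2d")) m$mask else if (inherits(m, "seg_result"))
      m$seg[slice, , , drop = TRUE] else m
    graphics::contour(x = seq(0, 1, length.out = ncol(m)),
                      y = seq(0, 1, length.out = nrow(m)),
                      z = t(m[nrow(m):1, ]) * 1, levels = 0.5, add = TRUE,
                      drawlabels = FALSE, col = col, lwd = 2)
  }
  if (!is.null(mask)) add_contour(mask, "yellow")
  if (!is.null(seg)) add_contour(seg, "red")
  invisible(NULL)
}
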