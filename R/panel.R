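# Panel configuration and the per-core quantification driver.

#' Build a marker-panel configuration
#'
#' Collects everything the quantification stage needs per core: channel
#' thresholds, size gates, the tissue-ROI settings, the combinations to
#' co-label, and the overlap rule. [default_panel()] derives a workable
#' config from an [image_spec()] (thresholds at 35% of the foreground mean,
#' comfortably above background, autofluorescence and bleed-through).
#'
#' @param channels marker channel names (DAPI excluded)
#' @param thresholds named numeric vector of per-channel intensity
#'   thresholds; a single unnamed value is recycled
#' @param um_per_px image scale
#' @param size_gate_um2 cell-label size gate
#' @param dapi_threshold,dapi_size_gate_um2 settings for nucleus labels
#' @param tissue_channel,tissue_threshold,min_hole_area_um2,closing_radius_px
#'   ROI settings (see [compute_tissue_roi()])
#' @param combinations list of character vectors (2-4 markers) to co-label
#' @param min_overlap,coloc_method,max_centroid_dist_um see [colocalize()]
#' @param dapi_center require labels to contain or touch a DAPI centroid
#' @return a `panel_config` list
#' @export
panel_config <- function(channels, thresholds, um_per_px,
                         size_gate_um2 = c(20, 400),
                         dapi_threshold = NULL,
                         dapi_size_gate_um2 = c(3, 400),
                         tissue_channel = "DAPI", tissue_threshold = 25,
                         min_hole_area_um2 = 400, closing_radius_px = 3,
                         combinations = list(), min_overlap = 0.5,
                         coloc_method = "overlap",
                         max_centroid_dist_um = 5,
                         dapi_center = TRUE) {
  if (length(thresholds) == 1L && is.null(names(thresholds)))
    thresholds <- setNames(rep(thresholds, length(channels)), channels)
  missing <- setdiff(channels, names(thresholds))
  if (length(missing))
    stop_input("no threshold for channel(s): %s",
               paste(missing, collapse = ", "))
  for (cmb in combinations) {
    bad <- setdiff(cmb, channels)
    if (length(bad))
      stop_input("combination references unknown marker(s): %s",
                 paste(bad, collapse = ", "))
  }
  structure(list(
    channels = channels, thresholds = thresholds, um_per_px = um_per_px,
    size_gate_um2 = size_gate_um2,
    dapi_threshold = dapi_threshold %||% thresholds[[1]],
    dapi_size_gate_um2 = dapi_size_gate_um2,
    tissue_channel = tissue_channel, tissue_threshold = tissue_threshold,
    min_hole_area_um2 = min_hole_area_um2,
    closing_radius_px = closing_radius_px,
    combinations = combinations, min_overlap = min_overlap,
    coloc_method = coloc_method,
    max_centroid_dist_um = max_centroid_dist_um,
    dapi_center = dapi_center), class = "panel_config")
}

#' @rdname panel_config
#' @param spec an `image_spec`
#' @param ... overrides passed on to [panel_config()]
#' @export
default_panel <- function(spec, ...) {
  thr <- 0.35 * spec$intensity_fg[["mean"]]
  panel_config(channels = names(spec$marker_prevalence),
               thresholds = thr, um_per_px = spec$um_per_px, ...)
}

#' Read / write a panel configuration as YAML
#' @param path YAML file
#' @export
read_panel_config <- function(path) {
  y <- yaml::read_yaml(path)
  y$thresholds <- unlist(y$thresholds)
  y$combinations <- lapply(y$combinations, unlist)
  do.call(panel_config, y)
}

#' @rdname read_panel_config
#' @param panel a `panel_config`
#' @export
write_panel_config <- function(panel, path) {
  p <- unclass(panel)
  p$thresholds <- as.list(p$thresholds)
  p$combinations <- lapply(p$combinations, as.list)
  yaml::write_yaml(p, path)
  invisible(path)
}

#' Quantify one core image under a panel configuration
#'
#' ROI, DAPI nuclei, per-marker labels (DAPI-centered), all configured
#' colocalizations, then [summarize_core()]. A core whose ROI is empty is
#' reported as `NULL` with a warning so the caller can exclude it.
#'
#' @param image a `core_image` or channel array
#' @param panel a `panel_config`
#' @param core_id identifier for the records
#' @return quantification records (see [summarize_core()]), or `NULL` for
#'   an empty-ROI core
#' @export
quantify_core <- function(image, panel, core_id = "core") {
  roi <- tryCatch(
    compute_tissue_roi(image, channel = panel$tissue_channel,
                       threshold = panel$tissue_threshold,
                       min_hole_area_um2 = panel$min_hole_area_um2,
                       um_per_px = panel$um_per_px,
                       closing_radius_px = panel$closing_radius_px,
                       core_id = core_id),
    error = function(e) {
      warning(sprintf("core %s excluded: %s", core_id, conditionMessage(e)))
      NULL
    })
  if (is.null(roi)) return(NULL)

  dapi <- detect_labels(image, "DAPI", panel$dapi_threshold,
                        size_gate_um2 = panel$dapi_size_gate_um2,
                        roi = roi, um_per_px = panel$um_per_px)
  label_sets <- lapply(panel$channels, function(m)
    detect_labels(image, m, panel$thresholds[[m]],
                  size_gate_um2 = panel$size_gate_um2, roi = roi,
                  dapi_labels = if (panel$dapi_center) dapi else NULL,
                  um_per_px = panel$um_per_px))
  names(label_sets) <- panel$channels

  co <- lapply(panel$combinations, function(cmb)
    colocalize(label_sets, cmb, min_overlap = panel$min_overlap,
               method = panel$coloc_method,
               max_centroid_dist_um = panel$max_centroid_dist_um))
  names(co) <- vapply(panel$combinations, combo_key, character(1))

  summarize_core(label_sets, co, roi, image, core_id = core_id)
}

#' Quantify a set of rendered cores
#'
#' @param images named list of `core_image`s (names become core ids) or a
#'   directory of TIFFs written by [write_core_tiff()]
#' @param panel a `panel_config`
#' @return row-bound quantification records; excluded (empty-ROI) core ids
#'   in `attr(, "excluded")`
#' @export
quantify_cores <- function(images, panel) {
  if (is.character(images) && length(images) == 1L && dir.exists(images)) {
    paths <- list.files(images, pattern = "\\.tiff?$", full.names = TRUE)
    images <- lapply(paths, read_core_tiff)
    names(images) <- sub("\\.tiff?$", "", basename(paths))
  }
  ids <- names(images) %||% sprintf("core%03d", seq_along(images))
  out <- vector("list", length(images))
  excluded <- character(0)
  for (i in seq_along(images)) {
    rec <- quantify_core(images[[i]], panel, core_id = ids[i])
    if (is.null(rec)) excluded <- c(excluded, ids[i]) else out[[i]] <- rec
  }
  res <- do.call(rbind, out)
  attr(res, "excluded") <- excluded
  res
}
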