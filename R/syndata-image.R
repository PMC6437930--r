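# Rendering of synthetic multichannel core images.
#
# Each cell is a Gaussian-profiled disk (sigma = r/1.5, clipped at r) in
# every channel it is positive for; DAPI renders the nucleus at 0.6x the
# cell radius. Tissue autofluorescence fills the core disk (minus holes) so
# that ROI detection sees a bright disk, background noise covers the whole
# canvas, and optional bleed-through mixes a fixed fraction of every other
# channel into each channel.

tissue_mask_impl <- function(geom, holes) {
  d2 <- outer((seq_len(geom$px) - geom$center)^2,
              (seq_len(geom$px) - geom$center)^2, `+`)
  mask <- d2 <= geom$radius_px^2
  for (i in seq_len(nrow(holes))) {
    h2 <- outer((seq_len(geom$px) - holes$x[i])^2,
                (seq_len(geom$px) - holes$y[i])^2, `+`)
    mask[h2 <= holes$r_px[i]^2] <- FALSE
  }
  mask
}

# stamp one Gaussian disk; returns nothing, modifies `layer` in caller via
# explicit return of the patch instead (R copy semantics)
disk_kernel <- function(r) {
  ir <- max(1L, ceiling(r))
  ax <- (-ir):ir
  d2 <- outer(ax^2, ax^2, `+`)
  k <- exp(-d2 / (2 * r^2))    # sigma = r: bright to the rim, soft shoulder
  k[d2 > r^2] <- 0
  k
}

render_impl <- function(ct, spec) {
  geom <- ct$geom
  px <- geom$px
  channels <- spec_channels(spec)
  mask <- tissue_mask_impl(geom, ct$holes)
  n_in <- sum(mask)

  bg <- spec$intensity_bg; af <- spec$intensity_af; fg <- spec$intensity_fg
  chans <- vector("list", length(channels))
  names(chans) <- channels
  for (ch in channels) {
    layer <- if (bg[["mean"]] > 0 || bg[["sd"]] > 0) {
      matrix(pmax(rnorm(px * px, bg[["mean"]], bg[["sd"]]), 0), px, px)
    } else matrix(0, px, px)
    if (af[["mean"]] > 0 || af[["sd"]] > 0)
      layer[mask] <- layer[mask] +
        pmax(rnorm(n_in, af[["mean"]], af[["sd"]]), 0)
    chans[[ch]] <- layer
  }

  cells <- ct$cells
  for (i in seq_len(nrow(cells))) {
    xi <- cells$x[i]; yi <- cells$y[i]
    pos_ch <- c("DAPI",
                channels[-1][unlist(cells[i, channels[-1]], use.names = FALSE)])
    for (ch in pos_ch) {
      r <- if (ch == "DAPI") cells$nucleus_radius_px[i] else cells$radius_px[i]
      k <- disk_kernel(r)
      ir <- (nrow(k) - 1L) %/% 2L
      x0 <- round(xi); y0 <- round(yi)
      rows <- (x0 - ir):(x0 + ir); cols <- (y0 - ir):(y0 + ir)
      okr <- rows >= 1L & rows <= px; okc <- cols >= 1L & cols <= px
      if (!any(okr) || !any(okc)) next
      intensity <- max(rnorm(1, fg[["mean"]], fg[["sd"]]), 0)
      chans[[ch]][rows[okr], cols[okc]] <-
        chans[[ch]][rows[okr], cols[okc]] + intensity * k[okr, okc]
    }
  }

  # spectral crosstalk: a fraction of each spectrally adjacent channel
  # (chain in panel order) leaks in, as in real multi-fluorophore panels;
  # all-to-all mixing would grow with panel size, which optics do not
  if (spec$bleedthrough > 0) {
    orig <- chans
    for (j in seq_along(channels)) {
      for (k in c(j - 1L, j + 1L)) {
        if (k >= 1L && k <= length(channels))
          chans[[j]] <- chans[[j]] + spec$bleedthrough * orig[[k]]
      }
    }
  }

  img <- array(0, c(px, px, length(channels)),
               dimnames = list(NULL, NULL, channels))
  for (j in seq_along(channels)) img[, , j] <- chans[[j]]
  list(image = img, mask = mask)
}

#' Generate one synthetic multichannel core image with ground truth
#'
#' Runs [generate_cell_table()] and renders the result. The same spec and
#' seed always produce a bit-identical image and table.
#'
#' @inheritParams generate_cell_table
#' @return a `core_image` list: `image` (H x W x channel array with channel
#'   dimnames), `cells` (ground-truth table), `mask` (tissue disk minus
#'   holes), `area_mm2`, `um_per_px`, `core_id`
#' @export
generate_core_image <- function(spec, profile = NULL, seed = NULL,
                                core_id = "core") {
  out <- with_seed_or_not(seed, {
    ct <- cell_table_impl(spec, profile, core_id = core_id, do_place = TRUE)
    r <- render_impl(ct, ct$spec)
    list(ct = ct, r = r)
  })
  structure(list(image = out$r$image, cells = out$ct$cells,
                 mask = out$r$mask, area_mm2 = out$ct$area_mm2,
                 um_per_px = spec$um_per_px, core_id = core_id),
            class = "core_image")
}

#' Write / read a core image as a multi-page TIFF
#'
#' One 32-bit float page per channel. Channel names and the intensity scale
#' go to a plain-text YAML sidecar (`<path>.channels.txt`); when the sidecar
#' is absent, `read_core_tiff()` falls back to channel order supplied by the
#' caller (typically from the panel config).
#'
#' @param image a `core_image` or a H x W x channel array with channel
#'   dimnames
#' @param path output TIFF path
#' @return `write_core_tiff()` returns `path` invisibly
#' @export
write_core_tiff <- function(image, path) {
  arr <- if (inherits(image, "core_image")) image$image else image
  channels <- dimnames(arr)[[3]]
  if (is.null(channels)) stop_input("image must carry channel dimnames")
  scale <- max(1, max(arr))
  pages <- lapply(seq_along(channels), function(j) arr[, , j] / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L,
                  compression = "deflate", reduce = FALSE)
  meta <- list(channels = as.list(channels), scale = scale)
  if (inherits(image, "core_image"))
    meta$um_per_px <- image$um_per_px
  yaml::write_yaml(meta, paste0(path, ".channels.txt"))
  invisible(path)
}

#' @rdname write_core_tiff
#' @param channels fallback channel names (in page order) when no sidecar
#'   is present
#' @return `read_core_tiff()` returns a H x W x channel array
#' @export
read_core_tiff <- function(path, channels = NULL) {
  pages <- tiff::readTIFF(path, all = TRUE)
  sidecar <- paste0(path, ".channels.txt")
  scale <- 1
  if (file.exists(sidecar)) {
    meta <- yaml::read_yaml(sidecar)
    channels <- unlist(meta$channels)
    scale <- meta$scale %||% 1
  }
  if (is.null(channels))
    stop_input("no channel sidecar found for %s; supply `channels` in page order",
               path)
  if (length(channels) != length(pages))
    stop_input("%d channel names for %d TIFF pages", length(channels),
               length(pages))
  px <- dim(pages[[1]])
  img <- array(0, c(px[1], px[2], length(channels)),
               dimnames = list(NULL, NULL, channels))
  for (j in seq_along(pages)) img[, , j] <- pages[[j]] * scale
  img
}
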