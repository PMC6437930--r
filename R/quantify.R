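# Image-analysis stage: tissue ROI with hole removal, thresholded and
# size-gated label detection, DAPI-centered colocalization, MFI, and
# core-size-normalized log densities.

# 8-connected labeling: EBImage::bwlabel is 4-connected, so labels that
# touch only diagonally are merged afterwards with a union-find pass.
bwlabel8 <- function(mask) {
  L <- EBImage::bwlabel(mask)
  L <- matrix(as.integer(L), nrow(mask), ncol(mask))
  mx <- max(L)
  if (mx < 2L) return(L)
  nr <- nrow(L); nc <- ncol(L)
  A <- L[-nr, -nc]; B <- L[-1, -1]       # down-right diagonal
  s1 <- which(A > 0L & B > 0L & A != B)
  C <- L[-1, -nc]; D <- L[-nr, -1]       # up-right diagonal
  s2 <- which(C > 0L & D > 0L & C != D)
  if (!length(s1) && !length(s2)) return(L)
  pairs <- unique(rbind(cbind(A[s1], B[s1]), cbind(C[s2], D[s2])))
  parent <- seq_len(mx)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (q in seq_len(nrow(pairs))) {
    a <- find(pairs[q, 1]); b <- find(pairs[q, 2])
    if (a != b) parent[max(a, b)] <- min(a, b)
  }
  root <- vapply(seq_len(mx), find, integer(1))
  relab <- match(root, sort(unique(root)))
  out <- L
  out[L > 0L] <- relab[L[L > 0L]]
  out
}

get_channel <- function(image, channel) {
  if (inherits(image, "core_image")) image <- image$image
  channels <- dimnames(image)[[3]]
  if (is.null(channels) || !channel %in% channels)
    stop_input("channel '%s' not present in image (panel: %s)", channel,
               paste(channels, collapse = ", "))
  image[, , channel]
}

#' Tissue region of interest with hole removal
#'
#' Thresholds a tissue-visible channel, morphologically closes the mask,
#' keeps the largest connected component, and fills its interior holes
#' except those larger than `min_hole_area_um2` (real holes stay excluded
#' from the area). The resulting area in mm2 is the normalization
#' denominator for all densities.
#'
#' @param image a `core_image` or channel array
#' @param channel channel to threshold for tissue (autofluorescence makes
#'   any channel usable; DAPI by default)
#' @param threshold intensity threshold (>= 0)
#' @param min_hole_area_um2 holes at least this large are excluded from the
#'   tissue area; smaller ones are filled
#' @param um_per_px image scale; taken from a `core_image` when omitted
#' @param closing_radius_px radius of the morphological closing brush
#' @param core_id identifier carried into the result
#' @return a `tissue_roi`: `mask` (logical), `area_mm2`, `n_holes`
#' @export
compute_tissue_roi <- function(image, channel = "DAPI", threshold = 25,
                               min_hole_area_um2 = 400, um_per_px = NULL,
                               closing_radius_px = 3, core_id = "core") {
  if (threshold < 0) stop_input("threshold must be >= 0")
  um_per_px <- um_per_px %||%
    (if (inherits(image, "core_image")) image$um_per_px else
      stop_input("um_per_px required when image is a bare array"))
  ch <- get_channel(image, channel)
  raw <- ch > threshold
  if (!any(raw))
    stop("empty ROI: no pixel above threshold", call. = FALSE)
  brush <- EBImage::makeBrush(2L * as.integer(closing_radius_px) + 1L,
                              shape = "disc")
  closed <- EBImage::closing(raw, brush) > 0
  L <- bwlabel8(closed)
  sizes <- tabulate(L[L > 0L])
  keep <- which.max(sizes)
  comp <- L == keep
  filled <- EBImage::fillHull(comp) > 0
  holes <- filled & !comp
  mask <- filled
  if (any(holes)) {
    HL <- bwlabel8(holes)
    hsizes <- tabulate(HL[HL > 0L])
    min_px <- min_hole_area_um2 / um_per_px^2
    big <- which(hsizes >= min_px)
    if (length(big)) mask[HL %in% big] <- FALSE
  }
  structure(list(core_id = core_id, mask = mask,
                 area_mm2 = sum(mask) * um_per_px^2 / 1e6,
                 n_holes = if (any(holes)) length(unique(HL[HL > 0L])) else 0L),
            class = "tissue_roi")
}

#' Detect marker-positive cell labels in one channel
#'
#' Connected components (8-connectivity) of above-threshold pixels inside
#' the ROI, filtered to a size gate in um2 and -- when DAPI labels are
#' supplied -- required to contain or touch a DAPI-label centroid
#' (DAPI-centered counting).
#'
#' @param image a `core_image` or channel array
#' @param marker channel name
#' @param threshold per-channel intensity threshold
#' @param size_gate_um2 `c(min, max)` label area gate in um2
#' @param roi optional `tissue_roi`; labels outside it are discarded
#' @param dapi_labels optional `label_set` of DAPI nuclei for centering
#' @param um_per_px image scale; taken from a `core_image` when omitted
#' @return a `label_set`: `labels` data.frame (label_id, x, y, area_px,
#'   area_um2), label `matrix`, `marker`, `threshold`
#' @export
detect_labels <- function(image, marker, threshold,
                          size_gate_um2 = c(20, 400), roi = NULL,
                          dapi_labels = NULL, um_per_px = NULL) {
  um_per_px <- um_per_px %||%
    (if (inherits(image, "core_image")) image$um_per_px else
      stop_input("um_per_px required when image is a bare array"))
  ch <- get_channel(image, marker)
  mask <- ch > threshold
  if (!is.null(roi)) mask <- mask & roi$mask
  L <- bwlabel8(mask)
  empty <- structure(list(
    labels = data.frame(label_id = integer(0), x = numeric(0),
                        y = numeric(0), area_px = integer(0),
                        area_um2 = numeric(0)),
    matrix = matrix(0L, nrow(ch), ncol(ch)), marker = marker,
    threshold = threshold, um_per_px = um_per_px), class = "label_set")
  if (max(L) == 0L) return(empty)

  idx <- which(L > 0L)
  lab <- L[idx]
  areas <- tabulate(lab)
  gate_px <- size_gate_um2 / um_per_px^2
  rows <- (idx - 1L) %% nrow(ch) + 1L
  cols <- (idx - 1L) %/% nrow(ch) + 1L
  cx <- rowsum(rows, lab)[, 1] / areas
  cy <- rowsum(cols, lab)[, 1] / areas
  keep <- which(areas >= gate_px[1] & areas <= gate_px[2])

  if (!is.null(dapi_labels) && length(keep)) {
    dl <- dapi_labels$labels
    ok <- logical(max(L))
    if (nrow(dl)) {
      xr <- pmin(pmax(round(dl$x), 1L), nrow(ch))
      yr <- pmin(pmax(round(dl$y), 1L), ncol(ch))
      for (dx in -1:1) for (dy in -1:1) {
        xs <- pmin(pmax(xr + dx, 1L), nrow(ch))
        ys <- pmin(pmax(yr + dy, 1L), ncol(ch))
        hits <- L[cbind(xs, ys)]
        ok[hits[hits > 0L]] <- TRUE
      }
    }
    keep <- keep[ok[keep]]
  }
  if (!length(keep)) return(empty)

  relab <- match(L, keep, nomatch = 0L)
  out <- matrix(as.integer(relab), nrow(ch), ncol(ch))
  structure(list(
    labels = data.frame(label_id = seq_along(keep), x = cx[keep],
                        y = cy[keep], area_px = areas[keep],
                        area_um2 = areas[keep] * um_per_px^2),
    matrix = out, marker = marker, threshold = threshold,
    um_per_px = um_per_px), class = "label_set")
}

#' Colocalization of 2-4 marker label sets
#'
#' A co-label is emitted wherever one label from every combination member
#' mutually overlaps: the shared pixel region must cover at least
#' `min_overlap` of the smallest participating label (default rule), or all
#' member centroids must lie within `max_centroid_dist_um` of each other
#' (`method = "centroid"`). Each member label joins at most one co-label,
#' so the co-count never exceeds the smallest member count.
#'
#' @param label_sets named list of `label_set`s (one per marker, same core,
#'   same thresholds as single-marker counting)
#' @param markers combination members (2-4 names present in `label_sets`)
#' @param min_overlap minimum pixel-overlap fraction of the smallest member
#' @param method `"overlap"` (default) or `"centroid"`
#' @param max_centroid_dist_um centroid tolerance for the centroid method
#' @return a `label_set` whose `marker` is the [combo_key()]
#' @export
colocalize <- function(label_sets, markers, min_overlap = 0.5,
                       method = c("overlap", "centroid"),
                       max_centroid_dist_um = 5) {
  method <- match.arg(method)
  if (length(markers) < 2L || length(markers) > 4L)
    stop_input("combinations must have 2-4 markers, got %d", length(markers))
  missing <- setdiff(markers, names(label_sets))
  if (length(missing))
    stop_input("no label set for: %s", paste(missing, collapse = ", "))
  ls <- label_sets[markers]
  um_per_px <- ls[[1]]$um_per_px
  key <- combo_key(markers)
  empty <- structure(list(
    labels = data.frame(label_id = integer(0), x = numeric(0),
                        y = numeric(0), area_px = integer(0),
                        area_um2 = numeric(0)),
    matrix = matrix(0L, nrow(ls[[1]]$matrix), ncol(ls[[1]]$matrix)),
    marker = key, threshold = NA_real_, um_per_px = um_per_px),
    class = "label_set")
  if (any(vapply(ls, function(s) nrow(s$labels) == 0L, logical(1))))
    return(empty)

  if (method == "centroid") {
    return(colocalize_centroid(ls, key, max_centroid_dist_um, empty))
  }

  inter <- Reduce(`&`, lapply(ls, function(s) s$matrix > 0L))
  if (!any(inter)) return(empty)
  CL <- bwlabel8(inter)
  idx <- which(CL > 0L)
  comp <- CL[idx]
  areas <- tabulate(comp)
  nr <- nrow(inter)
  rows <- (idx - 1L) %% nr + 1L
  cols <- (idx - 1L) %/% nr + 1L

  member_areas <- lapply(ls, function(s) s$labels$area_px)
  used <- lapply(ls, function(s) logical(nrow(s$labels)))
  ord <- order(areas, decreasing = TRUE)
  by_comp <- split(idx, comp)
  comp_rows <- split(rows, comp)
  comp_cols <- split(cols, comp)
  acc <- list()
  acc_px <- list()
  for (comp_id in ord) {
    in_comp <- by_comp[[comp_id]]
    ids <- vapply(seq_along(ls), function(m) {
      v <- ls[[m]]$matrix[in_comp]
      v <- v[v > 0L]
      if (!length(v)) return(0L)
      as.integer(names(sort(table(v), decreasing = TRUE))[1])
    }, integer(1))
    if (any(ids == 0L)) next
    smallest <- min(vapply(seq_along(ls), function(m)
      member_areas[[m]][ids[m]], numeric(1)))
    if (areas[comp_id] / smallest < min_overlap) next
    if (any(vapply(seq_along(ls), function(m) used[[m]][ids[m]],
                   logical(1)))) next
    for (m in seq_along(ls)) used[[m]][ids[m]] <- TRUE
    acc[[length(acc) + 1L]] <- c(
      x = mean(comp_rows[[comp_id]]), y = mean(comp_cols[[comp_id]]),
      area = areas[comp_id])
    acc_px[[length(acc_px) + 1L]] <- in_comp
  }
  if (!length(acc)) return(empty)
  M <- matrix(0L, nrow(inter), ncol(inter))
  for (j in seq_along(acc_px)) M[acc_px[[j]]] <- j
  df <- do.call(rbind, acc)
  structure(list(
    labels = data.frame(label_id = seq_along(acc), x = df[, "x"],
                        y = df[, "y"], area_px = as.integer(df[, "area"]),
                        area_um2 = df[, "area"] * um_per_px^2),
    matrix = M, marker = key, threshold = NA_real_,
    um_per_px = um_per_px), class = "label_set")
}

# greedy mutual-nearest-centroid matching (config-switch alternative)
colocalize_centroid <- function(ls, key, max_dist_um, empty) {
  um_per_px <- ls[[1]]$um_per_px
  max_px <- max_dist_um / um_per_px
  base <- ls[[1]]$labels
  used <- lapply(ls, function(s) logical(nrow(s$labels)))
  acc <- list()
  for (i in seq_len(nrow(base))) {
    ids <- integer(length(ls)); ids[1] <- i
    ok <- TRUE
    for (m in seq_along(ls)[-1]) {
      cand <- ls[[m]]$labels
      d <- sqrt((cand$x - base$x[i])^2 + (cand$y - base$y[i])^2)
      d[used[[m]]] <- Inf
      j <- which.min(d)
      if (!length(j) || d[j] > max_px) { ok <- FALSE; break }
      ids[m] <- j
    }
    if (!ok || used[[1]][i]) next
    for (m in seq_along(ls)) used[[m]][ids[m]] <- TRUE
    acc[[length(acc) + 1L]] <- c(x = base$x[i], y = base$y[i],
                                 area = base$area_px[i])
  }
  if (!length(acc)) return(empty)
  df <- do.call(rbind, acc)
  structure(list(
    labels = data.frame(label_id = seq_along(acc), x = df[, "x"],
                        y = df[, "y"], area_px = as.integer(df[, "area"]),
                        area_um2 = df[, "area"] * um_per_px^2),
    matrix = empty$matrix, marker = key, threshold = NA_real_,
    um_per_px = um_per_px), class = "label_set")
}

#' Summarize a core into normalized quantification records
#'
#' One record per label set: raw count, density per mm2 of tissue,
#' log10(density + 1), and -- for single markers -- the mean fluorescence
#' intensity of above-threshold pixels inside the labels. Zero counts give
#' density 0 and log value 0; MFI is undefined (NA) at zero count.
#'
#' @param label_sets named list of single-marker `label_set`s
#' @param co_label_sets named list of colocalization `label_set`s
#' @param roi the core's `tissue_roi`
#' @param image the `core_image` or array (for MFI)
#' @param core_id identifier for the records
#' @return tidy data.frame: core_id, combination_key, raw_count, area_mm2,
#'   density, log_value, mfi
#' @export
summarize_core <- function(label_sets, co_label_sets = list(), roi, image,
                           core_id = "core") {
  if (roi$area_mm2 <= 0) stop_input("ROI area must be positive")
  one <- function(s, single) {
    n <- nrow(s$labels)
    dens <- n / roi$area_mm2
    mfi <- NA_real_
    if (single && n > 0L) {
      ch <- get_channel(image, s$marker)
      px <- ch[s$matrix > 0L]
      mfi <- mean(px[px > s$threshold])
    }
    data.frame(core_id = core_id, combination_key = combo_key(s$marker),
               raw_count = n, area_mm2 = roi$area_mm2, density = dens,
               log_value = log10(dens + 1), mfi = mfi,
               stringsAsFactors = FALSE)
  }
  rows <- c(lapply(label_sets, one, single = TRUE),
            lapply(co_label_sets, one, single = FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
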