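# Ground-truth cell tables for synthetic TMA cores.
#
# Cells are placed by dart throwing with a minimum centre distance of
# r_i + r_j + 3 px: disks stay disjoint and non-adjacent (8-connectivity)
# even after stamp centres are rounded to the pixel grid. This keeps the
# noiseless rendering an exact oracle: every planted cell is one connected
# component in every channel it is positive for.

# merge a patient profile into an image spec: prevalences are overridden
# by name, co-expression entries are appended
apply_profile <- function(spec, profile) {
  if (is.null(profile)) return(spec)
  if (!is.null(profile$marker_prevalence)) {
    ov <- profile$marker_prevalence
    unknown <- setdiff(names(ov), names(spec$marker_prevalence))
    if (length(unknown))
      stop_input("profile overrides unknown marker(s): %s",
                 paste(unknown, collapse = ", "))
    spec$marker_prevalence[names(ov)] <- ov
  }
  if (!is.null(profile$coexpression))
    spec$coexpression <- c(spec$coexpression, profile$coexpression)
  validate_image_spec(spec)
}

# joint-group then residual-independent marker assignment (see image_spec)
assign_markers <- function(spec, is_leuk) {
  markers <- names(spec$marker_prevalence)
  n <- length(is_leuk)
  pos <- matrix(FALSE, n, length(markers), dimnames = list(NULL, markers))
  nl <- sum(is_leuk)
  groups <- spec$coexpression
  K <- length(groups)
  if (nl > 0L) {
    gidx <- integer(nl)
    if (K > 0L) {
      pg <- vapply(groups, function(g) g$joint, numeric(1))
      gidx <- sample.int(K + 1L, nl, replace = TRUE,
                         prob = c(1 - sum(pg), pg)) - 1L
    }
    for (m in seq_along(markers)) {
      in_group <- rep(FALSE, nl)
      if (K > 0L) {
        for (k in seq_len(K)) {
          if (markers[m] %in% groups[[k]]$markers)
            in_group <- in_group | (gidx == k)
        }
      }
      pos[is_leuk, m] <-
        in_group | (runif(nl) < spec$marker_prevalence[[m]])
    }
  }
  if (nl < n) {
    tp <- spec$tumor_marker_prevalence
    for (m in seq_along(markers)) {
      p <- if (markers[m] %in% names(tp)) tp[[markers[m]]] else 0
      if (p > 0) pos[!is_leuk, m] <- runif(n - nl) < p
    }
  }
  pos
}

# sample non-overlapping circular holes inside the core
sample_holes <- function(spec, geom) {
  lo <- min(spec$hole_n_range); hi <- max(spec$hole_n_range)
  n_holes <- if (hi > lo) sample(seq.int(lo, hi), 1L) else lo
  if (n_holes == 0L)
    return(data.frame(x = numeric(0), y = numeric(0), r_px = numeric(0)))
  r_px <- runif(n_holes, spec$hole_radius_range_um[1],
                spec$hole_radius_range_um[2]) / spec$um_per_px
  xs <- ys <- numeric(0)
  for (i in seq_len(n_holes)) {
    for (try in 1:200) {
      a <- runif(1, 0, 2 * pi)
      d <- sqrt(runif(1)) * max(geom$radius_px - r_px[i] - 2, 0)
      x <- geom$center + d * cos(a); y <- geom$center + d * sin(a)
      if (length(xs) == 0L ||
          all(sqrt((xs - x)^2 + (ys - y)^2) > r_px[seq_along(xs)] + r_px[i]))
        break
    }
    xs <- c(xs, x); ys <- c(ys, y)
  }
  data.frame(x = xs, y = ys, r_px = r_px)
}

# dart-throwing placement with pairwise spacing r_i + r_j + 3 px,
# inside the core disk and outside holes; returns kept indices + coords
place_cells <- function(radii_px, geom, holes) {
  n <- length(radii_px)
  s <- 2 * max(radii_px) + 3            # grid cell size >= max spacing
  ng <- max(1L, ceiling(geom$px / s))
  grid <- vector("list", ng * ng)
  xs <- ys <- numeric(n)
  kept <- logical(n)
  for (i in seq_len(n)) {
    r <- radii_px[i]
    placed <- FALSE
    for (try in 1:300) {
      a <- runif(1, 0, 2 * pi)
      d <- sqrt(runif(1)) * (geom$radius_px - r - 1)
      x <- geom$center + d * cos(a); y <- geom$center + d * sin(a)
      if (nrow(holes) &&
          any((holes$x - x)^2 + (holes$y - y)^2 <= (holes$r_px + r)^2))
        next
      gi <- min(ng, max(1L, ceiling(x / s)))
      gj <- min(ng, max(1L, ceiling(y / s)))
      ok <- TRUE
      for (ii in max(1L, gi - 1L):min(ng, gi + 1L)) {
        for (jj in max(1L, gj - 1L):min(ng, gj + 1L)) {
          nb <- grid[[(ii - 1L) * ng + jj]]
          if (length(nb) &&
              any((xs[nb] - x)^2 + (ys[nb] - y)^2 <
                  (radii_px[nb] + r + 3)^2)) {
            ok <- FALSE
            break
          }
        }
        if (!ok) break
      }
      if (ok) {
        xs[i] <- x; ys[i] <- y; kept[i] <- TRUE
        cell <- (gi - 1L) * ng + gj
        grid[[cell]] <- c(grid[[cell]], i)
        placed <- TRUE
        break
      }
    }
    if (!placed) kept[i] <- FALSE
  }
  list(x = xs, y = ys, kept = kept)
}

cell_table_impl <- function(spec, profile = NULL, core_id = "core",
                            do_place = TRUE) {
  spec <- apply_profile(spec, profile)
  geom <- spec_canvas(spec)
  holes <- sample_holes(spec, geom)
  area_px <- pi * geom$radius_px^2 - sum(pi * holes$r_px^2)
  area_mm2 <- area_px * spec$um_per_px^2 / 1e6

  n <- max(1L, as.integer(round(
    rnorm(1, spec$cells_per_core_mean, spec$cells_per_core_sd))))
  leuk_frac <- rnorm_trunc(1, spec$leukocyte_fraction_mean,
                           spec$leukocyte_fraction_sd, 0.02, 0.98)
  radii_um <- runif(n, spec$cell_radius_range_um[1],
                    spec$cell_radius_range_um[2])
  radii_px <- radii_um / spec$um_per_px

  if (do_place) {
    pl <- place_cells(radii_px, geom, holes)
    if (!all(pl$kept)) {
      warning(sprintf("core %s: %d of %d cells could not be placed and were dropped",
                      core_id, sum(!pl$kept), n))
    }
    keep <- which(pl$kept)
    x <- pl$x[keep]; y <- pl$y[keep]
    n <- length(keep)
    radii_px <- radii_px[keep]; radii_um <- radii_um[keep]
  } else {
    x <- y <- rep(NA_real_, n)
  }

  is_leuk <- runif(n) < leuk_frac
  pos <- assign_markers(spec, is_leuk)
  cells <- data.frame(
    cell_id = sprintf("%s_%04d", core_id, seq_len(n)),
    core_id = core_id,
    x = x, y = y,
    radius_px = radii_px,
    nucleus_radius_px = 0.6 * radii_px,
    class = ifelse(is_leuk, "leukocyte", "tumor"),
    stringsAsFactors = FALSE
  )
  cells <- cbind(cells, as.data.frame(pos, check.names = FALSE))
  list(cells = cells, holes = holes, area_mm2 = area_mm2,
       leukocyte_fraction = leuk_frac, spec = spec, geom = geom)
}

#' Generate a ground-truth cell table for one synthetic core
#'
#' Draws the number of cells, the leukocyte fraction, marker positivity
#' (joint co-expression groups plus residual independent rates), tissue
#' holes, and -- when `place = TRUE` -- non-overlapping cell positions
#' inside the tissue disk.
#'
#' @param spec an [image_spec()]
#' @param profile optional per-patient profile: a list with
#'   `$marker_prevalence` overrides and/or extra `$coexpression` entries
#' @param seed integer seed; fully determines the output
#' @param core_id identifier stamped into the table
#' @param place place cells spatially (needed for rendering; positivity
#'   and counts do not depend on it)
#' @return list with `cells` (one row per cell with one logical column per
#'   marker), `holes`, `area_mm2` and `leukocyte_fraction`
#' @export
generate_cell_table <- function(spec, profile = NULL, seed = NULL,
                                core_id = "core", place = TRUE) {
  with_seed_or_not(seed,
    cell_table_impl(spec, profile, core_id = core_id, do_place = place))
}

#' Ground-truth counts for single markers and combinations
#'
#' The oracle the image-quantification stage is tested against: counts are
#' read directly off the cell table.
#'
#' @param cells a cell table from [generate_cell_table()]
#' @param markers marker names (default: all marker columns present)
#' @param combinations list of character vectors of markers
#' @return named integer vector keyed by [combo_key()]
#' @export
ground_truth_counts <- function(cells, markers = NULL, combinations = list()) {
  cols <- setdiff(names(cells),
                  c("cell_id", "core_id", "x", "y", "radius_px",
                    "nucleus_radius_px", "class"))
  markers <- markers %||% cols
  out <- vapply(markers, function(m) sum(cells[[m]]), integer(1))
  names(out) <- markers
  for (cmb in combinations) {
    k <- combo_key(cmb)
    out[k] <- sum(Reduce(`&`, lapply(cmb, function(m) cells[[m]])))
  }
  out
}
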