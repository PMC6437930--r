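#' Specification of a synthetic tissue-microarray core image
#'
#' Describes one 0.6 mm TMA core as imaged by multiplex immunofluorescence:
#' how many cells it carries, what fraction are CD45+ leukocytes, the immune
#' marker panel with per-marker positivity rates, co-expression structure,
#' rendering intensities and tissue holes. The defaults emulate
#' immune-enriched NSCLC biopsy cores: 742 +/- 163 cells per core of which
#' 40 +/- 25% are leukocytes.
#'
#' `marker_prevalence` gives, per marker, the *residual independent*
#' positivity rate among leukocytes; co-expression groups add joint
#' positivity on top, so the marginal rate for marker m is
#' `g_m + (1 - g_m) * p_m` where `g_m` is the summed probability of groups
#' containing m. This construction guarantees every joint fraction is at
#' most each member's marginal.
#'
#' @param core_diameter_um tissue core diameter in micrometers
#' @param um_per_px image scale (micrometers per pixel)
#' @param cells_per_core_mean,cells_per_core_sd normal distribution of the
#'   number of cells per core (truncated at 1)
#' @param leukocyte_fraction_mean,leukocyte_fraction_sd per-core fraction of
#'   cells that are leukocytes (truncated to \[0.02, 0.98\])
#' @param cell_radius_range_um uniform range of cell radii; nuclei are drawn
#'   at 0.6x the cell radius for the DAPI channel
#' @param marker_prevalence named vector: residual independent positivity
#'   per marker among leukocytes (CD45 should be 1)
#' @param tumor_marker_prevalence named vector of positivity among
#'   non-leukocytes; markers absent from it default to 0
#' @param coexpression list of `list(markers = c(...), joint = p)` entries:
#'   a fraction `p` of leukocytes is jointly positive for all listed markers
#' @param intensity_fg,intensity_bg,intensity_af `c(mean=, sd=)` arbitrary
#'   units for stamped cell signal, background noise, and in-tissue
#'   autofluorescence (what makes the tissue disk visible for ROI detection)
#' @param bleedthrough spectral crosstalk: fraction of each spectrally
#'   adjacent channel's signal (chain in panel order) added to a channel
#'   (0 disables)
#' @param hole_n_range integer range of tissue holes per core
#' @param hole_radius_range_um uniform range of hole radii
#' @param canvas_margin_px blank margin around the core disk
#' @param canvas_px optional canvas override; must fit the core
#' @return an `image_spec` object (validated list)
#' @export
image_spec <- function(core_diameter_um = 600,
                       um_per_px = 0.3225,
                       cells_per_core_mean = 742,
                       cells_per_core_sd = 163,
                       leukocyte_fraction_mean = 0.40,
                       leukocyte_fraction_sd = 0.25,
                       cell_radius_range_um = c(3, 5),
                       marker_prevalence = c(
                         CD45 = 1.00, CD3 = 0.55, CD20 = 0.12,
                         `PD-1` = 0.18, `TIM-3` = 0.15, `LAG-3` = 0.12,
                         BTLA = 0.15, CD26 = 0.20
                       ),
                       tumor_marker_prevalence = NULL,
                       coexpression = list(),
                       intensity_fg = c(mean = 200, sd = 30),
                       intensity_bg = c(mean = 10, sd = 4),
                       intensity_af = c(mean = 30, sd = 5),
                       bleedthrough = 0.02,
                       hole_n_range = c(0, 2),
                       hole_radius_range_um = c(20, 60),
                       canvas_margin_px = 6,
                       canvas_px = NULL) {
  spec <- list(
    core_diameter_um = core_diameter_um, um_per_px = um_per_px,
    cells_per_core_mean = cells_per_core_mean,
    cells_per_core_sd = cells_per_core_sd,
    leukocyte_fraction_mean = leukocyte_fraction_mean,
    leukocyte_fraction_sd = leukocyte_fraction_sd,
    cell_radius_range_um = cell_radius_range_um,
    marker_prevalence = marker_prevalence,
    tumor_marker_prevalence = tumor_marker_prevalence %||%
      setNames(numeric(length(marker_prevalence)), names(marker_prevalence)),
    coexpression = coexpression,
    intensity_fg = intensity_fg, intensity_bg = intensity_bg,
    intensity_af = intensity_af,
    bleedthrough = bleedthrough,
    hole_n_range = hole_n_range,
    hole_radius_range_um = hole_radius_range_um,
    canvas_margin_px = canvas_margin_px,
    canvas_px = canvas_px
  )
  class(spec) <- "image_spec"
  validate_image_spec(spec)
}

#' @rdname image_spec
#' @param spec an `image_spec`
#' @export
validate_image_spec <- function(spec) {
  stopifnot(inherits(spec, "image_spec"))
  if (spec$core_diameter_um <= 0 || spec$um_per_px <= 0)
    stop_input("core diameter and scale must be positive")
  fr <- c(spec$leukocyte_fraction_mean, spec$marker_prevalence,
          spec$tumor_marker_prevalence, spec$bleedthrough)
  if (any(fr < 0 | fr > 1))
    stop_input("all fractions must lie in [0, 1]")
  if (is.null(names(spec$marker_prevalence)))
    stop_input("marker_prevalence must be a named vector")
  for (g in spec$coexpression) {
    if (is.null(g$markers) || is.null(g$joint))
      stop_input("coexpression entries need $markers and $joint")
    if (g$joint < 0 || g$joint > 1)
      stop_input("joint fractions must lie in [0, 1]")
    unknown <- setdiff(g$markers, names(spec$marker_prevalence))
    if (length(unknown))
      stop_input("coexpression references unknown marker(s): %s",
                 paste(unknown, collapse = ", "))
  }
  js <- sum(vapply(spec$coexpression, function(g) g$joint, numeric(1)))
  if (length(spec$coexpression) && js > 1)
    stop_input("coexpression joint fractions sum to %.3f > 1", js)
  need <- ceiling(spec$core_diameter_um / spec$um_per_px) +
    2L * spec$canvas_margin_px
  if (!is.null(spec$canvas_px) && spec$canvas_px < need)
    stop_input("canvas (%d px) too small for core diameter (needs %d px)",
               spec$canvas_px, need)
  spec
}

# canvas geometry: side length and core radius in pixels
spec_canvas <- function(spec) {
  r_px <- spec$core_diameter_um / 2 / spec$um_per_px
  px <- spec$canvas_px %||%
    (ceiling(spec$core_diameter_um / spec$um_per_px) +
       2L * spec$canvas_margin_px)
  list(px = as.integer(px), radius_px = r_px,
       center = (as.integer(px) + 1) / 2)
}

#' Channel names of a panel (DAPI plus every marker)
#' @param spec an `image_spec`
#' @export
spec_channels <- function(spec) c("DAPI", names(spec$marker_prevalence))

#' Specification of a synthetic patient cohort with planted survival effects
#'
#' Patients carry a latent Bernoulli status per planted marker combination;
#' status multiplies the baseline hazard by the planted hazard ratio and
#' simultaneously raises the joint positivity of the combination's markers
#' in that patient's cores, so that image-derived values are a noisy readout
#' of the latent truth. Survival is exponential by default (Weibull shape
#' exposed); censoring combines an administrative horizon with an
#' independent exponential dropout.
#'
#' @param n_patients cohort size
#' @param cores_per_patient integer range of replicate cores per patient
#' @param baseline_hazard events per month for combination-negative patients
#' @param weibull_shape Weibull shape (1 = exponential)
#' @param planted_effects list of [planted_effect()] entries
#' @param censor_horizon_months administrative censoring time
#' @param censor_rate independent censoring hazard (per month, 0 disables)
#' @param covariates logical: draw T-stage, subtype, sex, smoking,
#'   metastasis and treatment columns
#' @return a `cohort_spec` object
#' @export
cohort_spec <- function(n_patients = 81,
                        cores_per_patient = c(3, 5),
                        baseline_hazard = 0.045,
                        weibull_shape = 1,
                        planted_effects = list(),
                        censor_horizon_months = 72,
                        censor_rate = 0.01,
                        covariates = TRUE) {
  cs <- list(
    n_patients = as.integer(n_patients),
    cores_per_patient = as.integer(cores_per_patient),
    baseline_hazard = baseline_hazard,
    weibull_shape = weibull_shape,
    planted_effects = planted_effects,
    censor_horizon_months = censor_horizon_months,
    censor_rate = censor_rate,
    covariates = isTRUE(covariates)
  )
  class(cs) <- "cohort_spec"
  validate_cohort_spec(cs)
}

#' A planted prognostic marker combination
#'
#' @param markers markers forming the combination (2-4)
#' @param hr hazard ratio applied to latent-positive patients (must be > 0)
#' @param prevalence latent-positive fraction of the cohort
#' @param joint_positive,joint_negative joint positivity of the full
#'   combination among leukocytes for latent-positive / negative patients
#' @param pair_background constant joint positivity given to every pair
#'   subset of the combination in *all* patients (checkpoint co-expression
#'   is common irrespective of outcome, which makes the full combination the
#'   cleanest readout of the latent status)
#' @export
planted_effect <- function(markers, hr, prevalence = 0.4,
                           joint_positive = 0.25, joint_negative = 0.02,
                           pair_background = 0.10) {
  if (hr <= 0) stop_input("hazard ratios must be > 0")
  list(markers = as.character(markers), hr = hr, prevalence = prevalence,
       joint_positive = joint_positive, joint_negative = joint_negative,
       pair_background = pair_background)
}

#' @rdname cohort_spec
#' @param cspec a `cohort_spec`
#' @param ispec optional `image_spec` to check planted markers against
#' @export
validate_cohort_spec <- function(cspec, ispec = NULL) {
  stopifnot(inherits(cspec, "cohort_spec"))
  if (cspec$n_patients < 1) stop_input("n_patients must be >= 1")
  if (any(cspec$cores_per_patient < 1))
    stop_input("cores_per_patient must be >= 1")
  if (cspec$censor_horizon_months <= 0)
    stop_input("censoring horizon must be > 0")
  if (cspec$baseline_hazard <= 0) stop_input("baseline hazard must be > 0")
  for (pe in cspec$planted_effects) {
    if (pe$hr <= 0) stop_input("hazard ratios must be > 0")
    if (!is.null(ispec)) {
      unknown <- setdiff(pe$markers, names(ispec$marker_prevalence))
      if (length(unknown))
        stop_input("planted combination references unknown marker(s): %s",
                   paste(unknown, collapse = ", "))
    }
  }
  cspec
}
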