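# Synthetic patient cohorts with planted marker-dependent hazards.

draw_covariates <- function(n) {
  data.frame(
    T_stage = sample(c(2L, 3L, 4L), n, replace = TRUE,
                     prob = c(0.50, 0.25, 0.25)),
    subtype = sample(c("ADC", "SCC"), n, replace = TRUE,
                     prob = c(0.6, 0.4)),
    sex = sample(c("F", "M"), n, replace = TRUE),
    smoking = sample(c("ever", "never"), n, replace = TRUE,
                     prob = c(0.8, 0.2)),
    metastasis = sample(c(0L, 1L), n, replace = TRUE, prob = c(0.8, 0.2)),
    treatment = sample(c("chemo", "chemoradiation", "none"), n,
                       replace = TRUE, prob = c(0.45, 0.35, 0.2)),
    stringsAsFactors = FALSE
  )
}

# co-expression entries a patient's latent status implies: the full planted
# set at joint_positive/negative, plus a constant background joint for each
# strict pair subset (only meaningful for combinations of size >= 3)
profile_for_status <- function(effects, status_row) {
  entries <- list()
  seen_pairs <- character(0)
  for (k in seq_along(effects)) {
    pe <- effects[[k]]
    entries[[length(entries) + 1L]] <- list(
      markers = pe$markers,
      joint = if (status_row[k] == 1L) pe$joint_positive else pe$joint_negative
    )
    if (length(pe$markers) >= 3L && pe$pair_background > 0) {
      prs <- utils::combn(sort(pe$markers), 2L, simplify = FALSE)
      for (pr in prs) {
        key <- combo_key(pr)
        if (!key %in% seen_pairs) {
          seen_pairs <- c(seen_pairs, key)
          entries[[length(entries) + 1L]] <-
            list(markers = pr, joint = pe$pair_background)
        }
      }
    }
  }
  list(coexpression = entries)
}

#' Generate a synthetic patient cohort with planted survival effects
#'
#' Each patient gets a latent Bernoulli status per planted combination; the
#' status multiplies the baseline hazard by the planted hazard ratio and
#' selects the high or low joint co-expression level used when that
#' patient's cores are generated. Survival times are Weibull (exponential
#' when `weibull_shape = 1`), censored at an administrative horizon and by
#' an independent exponential dropout.
#'
#' @param cspec a [cohort_spec()]
#' @param ispec the [image_spec()] whose panel the planted combinations
#'   must reference
#' @param seed integer seed; fully determines the cohort
#' @return an `icp_cohort` list: `clinical` (patient_id, months, event,
#'   covariates), `core_map` (core_id, patient_id), `profiles` (named list
#'   of per-patient image profiles), `truth` (latent status per planted
#'   combination), plus the specs used
#' @export
generate_cohort <- function(cspec, ispec = image_spec(), seed = NULL) {
  validate_cohort_spec(cspec, ispec)
  with_seed_or_not(seed, {
    n <- cspec$n_patients
    pids <- sprintf("P%03d", seq_len(n))
    effects <- cspec$planted_effects
    keys <- vapply(effects, function(pe) combo_key(pe$markers), character(1))

    status <- matrix(0L, n, length(effects),
                     dimnames = list(pids, keys))
    for (k in seq_along(effects))
      status[, k] <- rbinom(n, 1L, effects[[k]]$prevalence)

    hazard <- rep(cspec$baseline_hazard, n)
    for (k in seq_along(effects))
      hazard <- hazard * effects[[k]]$hr^status[, k]

    shape <- cspec$weibull_shape
    t_event <- (-log(runif(n)) / hazard)^(1 / shape)
    t_cens <- if (cspec$censor_rate > 0) rexp(n, cspec$censor_rate) else
      rep(Inf, n)
    t_cens <- pmin(t_cens, cspec$censor_horizon_months)
    months <- pmin(t_event, t_cens)
    event <- as.integer(t_event <= t_cens)

    clinical <- data.frame(patient_id = pids, months = months,
                           event = event, stringsAsFactors = FALSE)
    if (cspec$covariates) clinical <- cbind(clinical, draw_covariates(n))

    lo <- min(cspec$cores_per_patient); hi <- max(cspec$cores_per_patient)
    n_cores <- if (hi > lo) sample(seq.int(lo, hi), n, replace = TRUE) else
      rep(lo, n)
    core_map <- data.frame(
      core_id = unlist(lapply(seq_len(n), function(i)
        sprintf("%s_C%d", pids[i], seq_len(n_cores[i])))),
      patient_id = rep(pids, n_cores),
      stringsAsFactors = FALSE
    )

    profiles <- lapply(seq_len(n), function(i)
      profile_for_status(effects, status[i, , drop = TRUE]))
    names(profiles) <- pids

    structure(list(clinical = clinical, core_map = core_map,
                   profiles = profiles,
                   truth = data.frame(patient_id = pids,
                                      as.data.frame(status,
                                                    check.names = FALSE),
                                      stringsAsFactors = FALSE,
                                      check.names = FALSE),
                   cspec = cspec, ispec = ispec),
              class = "icp_cohort")
  })
}

#' Quantify a synthetic cohort directly from ground-truth cell tables
#'
#' Generates every core's cell table (no pixel rendering) and reads single
#' marker and combination counts straight off it: the same generative cell
#' model the image path draws from, minus optics. Densities are normalized
#' to the core's tissue area (holes subtracted) and log10(x+1) transformed,
#' matching the image-quantification output contract.
#'
#' @param cohort an `icp_cohort`
#' @param combinations list of character vectors; defaults to the planted
#'   combinations plus all their pair subsets
#' @param markers single markers to report (default: full panel)
#' @param seed integer seed
#' @return a tidy data.frame: core_id, combination_key, raw_count,
#'   area_mm2, density, log_value, mfi (NA here)
#' @export
simulate_quant_matrix <- function(cohort, combinations = NULL,
                                  markers = NULL, seed = NULL) {
  stopifnot(inherits(cohort, "icp_cohort"))
  ispec <- cohort$ispec
  panel <- names(ispec$marker_prevalence)
  markers <- markers %||% panel
  if (is.null(combinations)) {
    combinations <- list()
    for (pe in cohort$cspec$planted_effects) {
      combinations <- c(combinations, list(pe$markers))
      if (length(pe$markers) >= 3L)
        combinations <- c(combinations,
                          utils::combn(sort(pe$markers), 2L, simplify = FALSE))
    }
    combinations <- combinations[!duplicated(vapply(combinations, combo_key,
                                                    character(1)))]
  }
  bad <- setdiff(unique(unlist(combinations)), panel)
  if (length(bad))
    stop_input("combination references marker(s) not in the panel: %s",
               paste(bad, collapse = ", "))

  # merge each patient's profile into the spec once, not per core
  merged <- lapply(cohort$profiles, function(pr) apply_profile(ispec, pr))

  with_seed_or_not(seed, {
    core_ids <- cohort$core_map$core_id
    pat <- cohort$core_map$patient_id
    n_cores <- length(core_ids)
    areas <- numeric(n_cores)
    pos_list <- vector("list", n_cores)
    for (i in seq_len(n_cores)) {
      sp <- merged[[pat[i]]]
      geom <- spec_canvas(sp)
      holes <- sample_holes(sp, geom)
      areas[i] <- (pi * geom$radius_px^2 - sum(pi * holes$r_px^2)) *
        sp$um_per_px^2 / 1e6
      nc <- max(1L, as.integer(round(
        rnorm(1, sp$cells_per_core_mean, sp$cells_per_core_sd))))
      lf <- rnorm_trunc(1, sp$leukocyte_fraction_mean,
                        sp$leukocyte_fraction_sd, 0.02, 0.98)
      pos_list[[i]] <- assign_markers(sp, runif(nc) < lf)
    }
    ncell <- vapply(pos_list, nrow, integer(1))
    POS <- do.call(rbind, pos_list)
    core_idx <- rep(seq_len(n_cores), ncell)

    # bit-pattern counting: every cell's positivity pattern is an integer,
    # a combination count is the number of cells whose pattern covers the
    # combination's bits
    bits <- 2^(seq_along(panel) - 1L)
    codes <- as.integer(POS %*% bits)
    code_levels <- sort(unique(codes))
    nlev <- length(code_levels)
    bin <- (core_idx - 1L) * nlev + match(codes, code_levels)
    cnt <- matrix(tabulate(bin, nbins = n_cores * nlev),
                  nrow = n_cores, byrow = TRUE)

    targets <- c(as.list(markers), combinations)
    keys <- vapply(targets, combo_key, character(1))
    tbits <- vapply(targets, function(m)
      sum(bits[match(m, panel)]), numeric(1))
    Z <- vapply(tbits, function(b)
      as.integer(bitwAnd(code_levels, as.integer(b)) == b),
      integer(length(code_levels)))
    Z <- matrix(Z, nrow = length(code_levels))
    counts <- cnt %*% Z          # cores x targets

    data.frame(
      core_id = rep(core_ids, times = length(keys)),
      combination_key = rep(keys, each = length(core_ids)),
      raw_count = as.vector(counts),
      area_mm2 = rep(areas, times = length(keys)),
      density = as.vector(counts) / rep(areas, times = length(keys)),
      log_value = log10(as.vector(counts) /
                          rep(areas, times = length(keys)) + 1),
      mfi = NA_real_,
      stringsAsFactors = FALSE
    )
  })
}
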