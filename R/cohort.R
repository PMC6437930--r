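# Patient-level assembly: replicate-core aggregation (both analysis
# methods), mean +/- SEM dichotomization, and ROC cutoff validation.

#' Assemble an analysis matrix from per-core quantification records
#'
#' `method = "average"` gives one row per patient: the arithmetic mean of
#' its cores' log values (missing cores dropped from the mean, not
#' zero-filled). `method = "per_core"` keeps one row per core, each
#' carrying its patient's survival data downstream -- the non-averaged
#' analysis route for markers with strong inter-core variability.
#'
#' @param quant tidy records from [quantify_cores()] or
#'   [simulate_quant_matrix()]
#' @param core_map data.frame core_id -> patient_id (every quantified core
#'   must be mapped)
#' @param method `"average"` or `"per_core"`
#' @param value which column to spread (log densities by default)
#' @return a `marker_matrix`: `values` (units x combination keys),
#'   `unit_id`, `patient_id` (per unit), `method`
#' @export
aggregate_cores <- function(quant, core_map,
                            method = c("average", "per_core"),
                            value = "log_value") {
  method <- match.arg(method)
  unmapped <- setdiff(unique(quant$core_id), core_map$core_id)
  if (length(unmapped))
    stop_input("cores not in core map: %s", paste(unmapped, collapse = ", "))
  ci <- factor(quant$core_id); ki <- factor(quant$combination_key)
  if (anyDuplicated(paste(quant$core_id, quant$combination_key)) == 0L) {
    wide <- matrix(NA_real_, nlevels(ci), nlevels(ki),
                   dimnames = list(levels(ci), levels(ki)))
    wide[cbind(as.integer(ci), as.integer(ki))] <- quant[[value]]
  } else {
    wide <- tapply(quant[[value]], list(ci, ki), mean)
  }
  patient <- core_map$patient_id[match(rownames(wide), core_map$core_id)]

  if (method == "per_core") {
    mm <- list(values = wide, unit_id = rownames(wide),
               patient_id = patient, method = method)
    class(mm) <- "marker_matrix"
    return(mm)
  }

  pf <- factor(patient, levels = unique(patient))
  num <- rowsum(ifelse(is.na(wide), 0, wide), pf, na.rm = FALSE)
  cnt <- rowsum((!is.na(wide)) * 1L, pf)
  avg <- num / cnt
  avg[cnt == 0L] <- NA
  empty <- rowSums(cnt) == 0L
  if (any(empty)) {
    warning(sprintf("patient(s) with no quantified core dropped: %s",
                    paste(rownames(avg)[empty], collapse = ", ")))
    avg <- avg[!empty, , drop = FALSE]
  }
  mm <- list(values = avg, unit_id = rownames(avg),
             patient_id = rownames(avg), method = method)
  class(mm) <- "marker_matrix"
  mm
}

#' Survival data aligned to the analysis units of a marker matrix
#'
#' @param mm a `marker_matrix`
#' @param clinical data.frame with patient_id, months, event
#' @return data.frame unit_id, patient_id, months, event (one row per unit)
#' @export
unit_survival <- function(mm, clinical) {
  i <- match(mm$patient_id, clinical$patient_id)
  if (anyNA(i))
    stop_input("patients missing from clinical table: %s",
               paste(unique(mm$patient_id[is.na(i)]), collapse = ", "))
  data.frame(unit_id = mm$unit_id, patient_id = mm$patient_id,
             months = clinical$months[i], event = clinical$event[i],
             stringsAsFactors = FALSE)
}

#' Dichotomize marker values at cohort mean +/- SEM
#'
#' Units strictly above mean + SEM are `hi`, strictly below mean - SEM are
#' `lo`, and the mid-band (boundaries included) is `excluded` -- which is
#' why classified group sizes sum below the cohort size. SEM uses the
#' sample SD (n - 1).
#'
#' @param values numeric vector (names become unit ids)
#' @param unit_id optional unit ids
#' @return a data.frame (unit_id, value, class) with attributes `mean`,
#'   `sem`, `cutoff_hi`, `cutoff_lo`, `n_hi`, `n_lo`, `n_excluded`
#' @export
dichotomize <- function(values, unit_id = NULL) {
  unit_id <- unit_id %||% names(values) %||% as.character(seq_along(values))
  ok <- !is.na(values)
  if (sum(ok) < 2L)
    stop_input("need at least 2 non-missing values, got %d", sum(ok))
  if (sum(ok) == 2L)
    warning("only 2 values: the SEM band is degenerate and excludes both")
  m <- mean(values[ok])
  sem <- sd(values[ok]) / sqrt(sum(ok))
  if (sem == 0)
    warning("all values identical: SEM is 0 and every unit is excluded")
  cls <- rep("excluded", length(values))
  cls[ok & values > m + sem] <- "hi"
  cls[ok & values < m - sem] <- "lo"
  out <- data.frame(unit_id = unit_id, value = values, class = cls,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "mean") <- m
  attr(out, "sem") <- sem
  attr(out, "cutoff_hi") <- m + sem
  attr(out, "cutoff_lo") <- m - sem
  attr(out, "n_hi") <- sum(cls == "hi")
  attr(out, "n_lo") <- sum(cls == "lo")
  attr(out, "n_excluded") <- sum(cls == "excluded")
  class(out) <- c("strat_label", "data.frame")
  out
}

#' ROC validation of marker cutoffs against the death outcome
#'
#' Full threshold sweep: sensitivity is the fraction of deaths with value
#' above the threshold, specificity the fraction of survivors at or below
#' it. The area under the curve is the trapezoidal integral, which equals
#' pairwise concordance with ties counted one half. Reports operating
#' points at the supplied cutoffs (e.g. the mean +/- SEM pair) and the
#' Youden-J-maximizing threshold.
#'
#' @param values marker values
#' @param outcome 0/1 death-during-follow-up flag
#' @param cutoffs optional named vector of cutoffs to report
#' @return list: `auc`, `roc` (threshold, sens, spec), `youden`
#'   (cutoff, sens, spec, j), `at_cutoffs` data.frame, `n_pos`, `n_neg`
#' @export
roc_validate <- function(values, outcome, cutoffs = NULL) {
  ok <- !is.na(values) & !is.na(outcome)
  values <- values[ok]; outcome <- outcome[ok]
  if (length(unique(outcome)) < 2L)
    stop_input("AUC undefined: only one outcome class present")
  pos <- values[outcome == 1]; neg <- values[outcome == 0]
  u <- sort(unique(values))
  ths <- c(-Inf, (u[-length(u)] + u[-1]) / 2, Inf)
  sens <- vapply(ths, function(t) mean(pos > t), numeric(1))
  spec <- vapply(ths, function(t) mean(neg <= t), numeric(1))
  fpr <- 1 - spec
  o <- order(fpr, sens)
  auc <- sum(diff(fpr[o]) * (sens[o][-1] + sens[o][-length(o)]) / 2)
  j <- sens + spec - 1
  jbest <- which.max(j)
  at <- NULL
  if (!is.null(cutoffs)) {
    at <- data.frame(
      cutoff = unname(cutoffs),
      name = names(cutoffs) %||% as.character(seq_along(cutoffs)),
      sens = vapply(cutoffs, function(t) mean(pos > t), numeric(1)),
      spec = vapply(cutoffs, function(t) mean(neg <= t), numeric(1)),
      stringsAsFactors = FALSE)
    rownames(at) <- NULL
  }
  list(auc = auc,
       roc = data.frame(threshold = ths, sens = sens, spec = spec),
       youden = list(cutoff = ths[jbest], sens = sens[jbest],
                     spec = spec[jbest], j = j[jbest]),
       at_cutoffs = at, n_pos = length(pos), n_neg = length(neg))
}
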