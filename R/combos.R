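# Discovery and ranking of prognostic marker combinations: colocalization
# and additive combination values, global checkpoint scores, exhaustive
# duplex/triplex scans, correlograms, and PCA coexpression groups.

#' Per-unit value of a marker combination
#'
#' Colocalization mode returns the combination's co-label log-density
#' column (the markers must have been co-labeled at quantification time);
#' additive mode sums the members' single-marker log values — an
#' alternative scoring that needs no co-labeling.
#'
#' @param mm a `marker_matrix`
#' @param markers combination members
#' @param mode `"colocalization"` or `"additive"`
#' @return named numeric vector (one value per analysis unit)
#' @export
combination_value <- function(mm, markers,
                              mode = c("colocalization", "additive")) {
  mode <- match.arg(mode)
  v <- mm$values
  if (mode == "additive") {
    missing <- setdiff(markers, colnames(v))
    if (length(missing))
      stop_input("marker column(s) missing: %s",
                 paste(missing, collapse = ", "))
    out <- rowSums(v[, markers, drop = FALSE])
  } else {
    key <- combo_key(markers)
    if (!key %in% colnames(v))
      stop_input(paste0(
        "no colocalization column '%s' in the matrix; re-run ",
        "quantification with this combination in the panel config"), key)
    out <- v[, key]
  }
  names(out) <- mm$unit_id
  out
}

#' Global immune-checkpoint scores per analysis unit
#'
#' Two variants of a per-patient summary over a checkpoint set: `sum_score`
#' is the summed log values; `count_score` is the number of checkpoints in
#' the set whose value exceeds its cohort mean (computed on the analysis
#' matrix itself).
#'
#' @param mm a `marker_matrix`
#' @param icp_set columns to summarize (non-empty subset of the matrix)
#' @return data.frame: unit_id, sum_score, count_score
#' @export
global_score <- function(mm, icp_set) {
  if (length(icp_set) == 0L) stop_input("icp_set must be non-empty")
  missing <- setdiff(icp_set, colnames(mm$values))
  if (length(missing))
    stop_input("column(s) missing: %s", paste(missing, collapse = ", "))
  v <- mm$values[, icp_set, drop = FALSE]
  mu <- colMeans(v, na.rm = TRUE)
  data.frame(unit_id = mm$unit_id,
             sum_score = rowSums(v),
             count_score = rowSums(sweep(v, 2, mu, `>`), na.rm = TRUE),
             stringsAsFactors = FALSE)
}

#' Exhaustive scan of prognostic marker combinations
#'
#' Every combination of `sizes` markers from `candidates` (plus the
#' optional anchor, e.g. CD3) is scored: combination value, mean +/- SEM
#' dichotomization, log-rank hi vs lo. Combinations whose dichotomization
#' leaves a group empty are skipped with a reason. The report is sorted by
#' p (ties broken by |log HR| descending) with Benjamini-Hochberg q-values.
#'
#' @param mm a `marker_matrix`
#' @param clinical clinical table (patient_id, months, event)
#' @param candidates candidate markers (anchor excluded automatically)
#' @param sizes combination sizes drawn from `candidates`
#' @param anchor optional marker prepended to every combination
#' @param mode passed to [combination_value()]
#' @return a `combination_report` data.frame: combination, mode, size,
#'   n_hi, n_lo, chi2, p, q, hr, ci_low, ci_high; skipped combinations in
#'   `attr(, "skipped")`
#' @export
rank_combinations <- function(mm, clinical, candidates, sizes = c(2, 3),
                              anchor = NULL,
                              mode = c("colocalization", "additive")) {
  mode <- match.arg(mode)
  candidates <- setdiff(candidates, anchor)
  if (max(sizes) + length(anchor) > 4L)
    stop_input("combinations are capped at 4 markers (anchor included)")
  surv <- unit_survival(mm, clinical)
  rows <- list(); skipped <- list()
  for (s in sizes) {
    if (s > length(candidates)) next
    sets <- utils::combn(candidates, s, simplify = FALSE)
    for (set in sets) {
      members <- c(anchor, set)
      key <- combo_key(members)
      val <- tryCatch(combination_value(mm, members, mode),
                      error = function(e) e)
      if (inherits(val, "error")) {
        skipped[[key]] <- conditionMessage(val)
        next
      }
      strat <- dichotomize(val, mm$unit_id)
      hi <- strat$class == "hi"; lo <- strat$class == "lo"
      if (!any(hi) || !any(lo)) {
        skipped[[key]] <- "degenerate dichotomization (empty group)"
        next
      }
      lr <- tryCatch(
        logrank_test(surv$months[hi], surv$event[hi],
                     surv$months[lo], surv$event[lo]),
        error = function(e) e)
      if (inherits(lr, "error")) {
        skipped[[key]] <- conditionMessage(lr)
        next
      }
      rows[[key]] <- data.frame(
        combination = key, mode = mode, size = length(members),
        n_hi = sum(hi), n_lo = sum(lo), chi2 = lr$chi2, p = lr$p,
        hr = lr$hr, ci_low = lr$ci95[1], ci_high = lr$ci95[2],
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    stop_input("no combination could be tested")
  report <- do.call(rbind, rows)
  report$q <- p.adjust(report$p, method = "BH")
  report <- report[order(report$p, -abs(log(report$hr))), ]
  report$rank <- seq_len(nrow(report))
  rownames(report) <- NULL
  attr(report, "skipped") <- skipped
  class(report) <- c("combination_report", "data.frame")
  report
}

#' Pairwise correlation structure of a marker set
#'
#' Full Pearson matrix with an average-linkage hierarchical ordering on
#' distance 1 - r, the basis of the coexpression correlograms.
#'
#' @param mm a `marker_matrix` or numeric matrix
#' @param markers columns to include (>= 3 after dropping constants)
#' @return list: `r` (correlation matrix), `order` (clustered marker
#'   order), `hclust`, `top_pair`
#' @export
correlogram <- function(mm, markers = NULL) {
  v <- if (inherits(mm, "marker_matrix")) mm$values else mm
  markers <- markers %||% colnames(v)
  v <- v[, markers, drop = FALSE]
  const <- apply(v, 2, function(col) sd(col, na.rm = TRUE) == 0 ||
                   all(is.na(col)))
  if (any(const)) {
    warning(sprintf("constant column(s) dropped: %s",
                    paste(markers[const], collapse = ", ")))
    v <- v[, !const, drop = FALSE]
  }
  if (ncol(v) < 3L) stop_input("need at least 3 non-constant markers")
  r <- cor(v, use = "pairwise.complete.obs")
  hc <- hclust(as.dist(1 - r), method = "average")
  up <- upper.tri(r)
  top <- which(r == max(r[up]) & up, arr.ind = TRUE)[1, ]
  list(r = r, order = colnames(r)[hc$order], hclust = hc,
       top_pair = sort(colnames(r)[top]))
}

#' PCA coexpression groups with oriented scores
#'
#' PCA on column-standardized log values. Each component's group contains
#' the markers whose |loading| reaches `loading_threshold` of the
#' component's maximum |loading|; the score sign is oriented so it
#' correlates positively with the mean standardized expression of the
#' group's members (PCA signs being arbitrary).
#'
#' @param mm a `marker_matrix` or numeric matrix
#' @param markers columns to analyze
#' @param n_components number of leading components to report
#' @param loading_threshold membership cut as a fraction of the max
#'   |loading|
#' @return list: `groups` (per component: members, loadings, orientation),
#'   `scores` (units x components, oriented), `variance_proportion`
#'   (descending, all components), `unit_id`
#' @export
pca_groups <- function(mm, markers = NULL, n_components = 2,
                       loading_threshold = 0.5) {
  v <- if (inherits(mm, "marker_matrix")) mm$values else mm
  unit_id <- if (inherits(mm, "marker_matrix")) mm$unit_id else rownames(v)
  markers <- markers %||% colnames(v)
  v <- v[, markers, drop = FALSE]
  keep <- apply(v, 2, function(col) !anyNA(col) && sd(col) > 0)
  if (sum(keep) < 2L)
    stop_input("need at least 2 complete, non-degenerate marker columns")
  v <- v[, keep, drop = FALSE]
  pr <- prcomp(v, center = TRUE, scale. = TRUE)
  n_components <- min(n_components, ncol(pr$rotation))
  z <- scale(v)
  groups <- vector("list", n_components)
  scores <- pr$x[, seq_len(n_components), drop = FALSE]
  for (k in seq_len(n_components)) {
    load <- pr$rotation[, k]
    members <- names(load)[abs(load) >= loading_threshold * max(abs(load))]
    mz <- rowMeans(z[, members, drop = FALSE])
    s <- sign(cor(scores[, k], mz))
    if (is.na(s) || s == 0) s <- 1
    scores[, k] <- s * scores[, k]
    groups[[k]] <- list(component = k, members = members,
                        loadings = s * load, orientation = s)
  }
  rownames(scores) <- unit_id
  list(groups = groups, scores = scores,
       variance_proportion = pr$sdev^2 / sum(pr$sdev^2),
       unit_id = unit_id)
}

#' Survival stratification on a principal-component score
#'
#' Mean +/- SEM dichotomization of the (oriented) PC score followed by a
#' log-rank test, reusing the cohort and survival machinery.
#'
#' @param scores named numeric vector of per-unit PC scores
#' @param mm the `marker_matrix` the scores were computed on (for the
#'   unit -> patient map)
#' @param clinical clinical table
#' @return a `surv_test` (see [logrank_test()]) with the stratification in
#'   `attr(, "strat")`
#' @export
pc_survival <- function(scores, mm, clinical) {
  surv <- unit_survival(mm, clinical)
  strat <- dichotomize(scores[mm$unit_id], mm$unit_id)
  hi <- strat$class == "hi"; lo <- strat$class == "lo"
  if (!any(hi) || !any(lo))
    stop_input("degenerate dichotomization of PC scores")
  out <- logrank_test(surv$months[hi], surv$event[hi],
                      surv$months[lo], surv$event[lo])
  attr(out, "strat") <- strat
  out
}
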