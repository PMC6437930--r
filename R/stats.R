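# Survival and correlation statistics. Standard machinery (product-limit
# estimator, Mantel-Cox risk sets, Cox partial likelihood) is delegated to
# the survival package; the log-rank hazard ratio is the O/E-ratio variant
# with CI exp(log HR +/- 1.96 * sqrt(1/E1 + 1/E2)).

#' Kaplan-Meier product-limit estimate
#'
#' @param months follow-up times (>= 0)
#' @param events 0/1 event flags
#' @return a `km_curve` data.frame: time, n_risk, n_event, n_censor, surv
#' @export
km_estimate <- function(months, events) {
  if (length(months) < 1L) stop_input("need at least one observation")
  if (any(months < 0)) stop_input("negative survival time")
  sf <- survival::survfit(survival::Surv(months, events) ~ 1)
  out <- data.frame(time = sf$time, n_risk = sf$n.risk,
                    n_event = sf$n.event, n_censor = sf$n.censor,
                    surv = sf$surv)
  class(out) <- c("km_curve", "data.frame")
  out
}

#' Log-rank (Mantel-Cox) test with log-rank hazard ratio
#'
#' Chi-square over pooled risk sets, two-sided p from chi-square with 1 df,
#' and the log-rank HR = (O_hi/E_hi) / (O_lo/E_lo) with
#' CI95 = exp(log HR +/- 1.96 * sqrt(1/E_hi + 1/E_lo)).
#'
#' @param months_hi,events_hi follow-up and event flags of the `hi` group
#' @param months_lo,events_lo follow-up and event flags of the `lo` group
#' @return a `surv_test` list: chi2, p, hr (hi vs lo), ci95, n_hi, n_lo,
#'   obs, exp
#' @export
logrank_test <- function(months_hi, events_hi, months_lo, events_lo) {
  if (length(months_hi) == 0L || length(months_lo) == 0L)
    stop_input("both groups must be non-empty")
  if (sum(events_hi) + sum(events_lo) == 0L)
    stop_input("degenerate test: no events in either group")
  g <- factor(rep(c("hi", "lo"), c(length(months_hi), length(months_lo))),
              levels = c("hi", "lo"))
  sd <- survival::survdiff(
    survival::Surv(c(months_hi, months_lo), c(events_hi, events_lo)) ~ g)
  O <- sd$obs; E <- sd$exp
  if (any(E <= 0))
    stop_input("degenerate test: a group contributes no expected events")
  hr <- (O[1] / E[1]) / (O[2] / E[2])
  se <- sqrt(1 / E[1] + 1 / E[2])
  chi2 <- sd$chisq
  structure(list(
    chi2 = unname(chi2),
    p = unname(pchisq(chi2, df = 1, lower.tail = FALSE)),
    hr = unname(hr),
    ci95 = unname(c(hr * exp(-1.96 * se), hr * exp(1.96 * se))),
    n_hi = length(months_hi), n_lo = length(months_lo),
    obs = unname(O), exp = unname(E)), class = "surv_test")
}

#' Univariate Cox proportional-hazards validation
#'
#' Partial-likelihood fit with the Efron tie correction; Wald p-value and
#' CI. Used as the cross-check for the log-rank HR, mirroring dual
#' reporting of both statistics.
#'
#' @param months,events follow-up and event flags
#' @param x covariate (non-constant; binary hi/lo indicator or continuous)
#' @return list: beta, hr, p, ci95, n, flagged (TRUE when the likelihood is
#'   monotone, i.e. perfect separation)
#' @export
cox_univariate <- function(months, events, x) {
  if (sum(events) < 2L) stop_input("need at least 2 events")
  if (length(unique(x[!is.na(x)])) < 2L) stop_input("covariate is constant")
  flagged <- FALSE
  fit <- withCallingHandlers(
    survival::coxph(survival::Surv(months, events) ~ x, ties = "efron",
                    control = survival::coxph.control(iter.max = 50)),
    warning = function(w) {
      if (grepl("infinite|converged", conditionMessage(w)))
        flagged <<- TRUE
      invokeRestart("muffleWarning")
    })
  if (is.na(coef(fit)))
    stop_input("Cox fit failed to produce a coefficient")
  s <- summary(fit)
  beta <- unname(coef(fit))
  se <- s$coefficients[1, "se(coef)"]
  list(beta = beta, hr = exp(beta),
       p = unname(s$coefficients[1, "Pr(>|z|)"]),
       ci95 = unname(exp(c(beta - 1.96 * se, beta + 1.96 * se))),
       n = length(months), flagged = flagged)
}

#' Pearson correlation with two-tailed p and Fisher-z CI
#'
#' @param x,y numeric vectors (n >= 3, finite, non-constant)
#' @return list: r, p, ci95, n
#' @export
pearson_corr <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop_input("need at least 3 finite pairs")
  if (sd(x) == 0 || sd(y) == 0)
    stop_input("correlation undefined: zero variance")
  ct <- cor.test(x, y, method = "pearson", conf.level = 0.95)
  list(r = unname(ct$estimate), p = ct$p.value,
       ci95 = unname(ct$conf.int), n = length(x))
}

#' Cumulative-correlation ranking of a marker set
#'
#' Each marker's cumulative correlation is its mean pairwise Pearson r with
#' every other marker in the set (self excluded); markers are returned in
#' descending order, alphabetical on ties. Constant columns are dropped
#' with a warning.
#'
#' @param x a `marker_matrix` or plain numeric matrix with marker columns
#' @param markers columns to rank (>= 3 after dropping constants)
#' @return data.frame: marker, cumulative_r, rank
#' @export
cumulative_correlation <- function(x, markers = NULL) {
  v <- if (inherits(x, "marker_matrix")) x$values else x
  markers <- markers %||% colnames(v)
  v <- v[, markers, drop = FALSE]
  const <- apply(v, 2, function(col) sd(col, na.rm = TRUE) == 0 ||
                   all(is.na(col)))
  if (any(const)) {
    warning(sprintf("constant column(s) excluded: %s",
                    paste(markers[const], collapse = ", ")))
    v <- v[, !const, drop = FALSE]
  }
  if (ncol(v) < 3L) stop_input("need at least 3 non-constant markers")
  C <- cor(v, use = "pairwise.complete.obs")
  cum <- (rowSums(C) - 1) / (ncol(C) - 1)
  ord <- order(-cum, colnames(C))
  data.frame(marker = colnames(C)[ord], cumulative_r = unname(cum[ord]),
             rank = seq_along(ord), stringsAsFactors = FALSE)
}

#' Schoenfeld asymptotic power of the two-sided log-rank test
#'
#' `power = Phi(delta - z) + Phi(-delta - z)` with
#' `delta = sqrt(d * a * (1 - a)) * |log hr|`, `d = n * event_fraction`,
#' allocation `a`, and `z` the two-sided normal quantile, so HR = 1 gives
#' exactly alpha.
#'
#' @param n total sample size
#' @param hr hazard ratio between the groups (> 0)
#' @param allocation fraction of patients in the first group
#' @param event_fraction expected fraction of patients with an event
#' @param alpha two-sided significance level
#' @export
schoenfeld_power <- function(n, hr, allocation = 0.5, event_fraction = 0.7,
                             alpha = 0.05) {
  if (hr <= 0) stop_input("hazard ratios must be > 0")
  d <- n * event_fraction
  delta <- sqrt(d * allocation * (1 - allocation)) * abs(log(hr))
  z <- qnorm(1 - alpha / 2)
  pnorm(delta - z) + pnorm(-delta - z)
}

#' Monte-Carlo power of the log-rank test
#'
#' Simulates exponential survival in two groups with the given hazard
#' ratio; an independent exponential censoring rate is solved numerically
#' so the expected overall event fraction matches `event_fraction`. Power
#' is the fraction of simulated cohorts with log-rank p below alpha; the
#' Schoenfeld closed form is reported alongside as a cross-check.
#'
#' @inheritParams schoenfeld_power
#' @param reps number of simulated cohorts (>= 100)
#' @param seed integer seed
#' @return list: power, se (binomial), schoenfeld, reps, n, hr
#' @export
logrank_power <- function(n, hr, allocation = 0.5, event_fraction = 0.7,
                          alpha = 0.05, reps = 500, seed = NULL) {
  if (hr <= 0) stop_input("hazard ratios must be > 0")
  if (reps < 100) stop_input("reps must be >= 100")
  lam1 <- 0.1 * hr          # first group; baseline scale is arbitrary
  lam2 <- 0.1
  n1 <- round(n * allocation); n2 <- n - n1
  crate <- if (event_fraction >= 1 - 1e-9) 0 else
    uniroot(function(c)
      allocation * lam1 / (lam1 + c) + (1 - allocation) * lam2 / (lam2 + c) -
        event_fraction,
      c(1e-9, 1e4))$root
  g <- factor(rep(c(1, 2), c(n1, n2)))
  pvals <- with_seed_or_not(seed, vapply(seq_len(reps), function(i) {
    t <- c(rexp(n1, lam1), rexp(n2, lam2))
    cens <- if (crate > 0) rexp(n, crate) else rep(Inf, n)
    obs <- pmin(t, cens)
    ev <- as.integer(t <= cens)
    if (sum(ev) == 0L) return(1)
    sd <- survival::survdiff(survival::Surv(obs, ev) ~ g)
    pchisq(sd$chisq, df = 1, lower.tail = FALSE)
  }, numeric(1)))
  power <- mean(pvals < alpha)
  list(power = power, se = sqrt(power * (1 - power) / reps),
       schoenfeld = schoenfeld_power(n, hr, allocation, event_fraction,
                                     alpha),
       reps = reps, n = n, hr = hr)
}
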