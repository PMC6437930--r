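# Independent oracles, written from first principles and never calling the
# package's (or the survival package's) code paths they are used to check.

# Mantel-Cox log-rank by explicit risk-set enumeration: at each distinct
# event time, observed and expected events in group 1 under the
# hypergeometric null, plus its variance.
brute_logrank <- function(time1, event1, time2, event2) {
  time <- c(time1, time2)
  event <- c(event1, event2)
  grp <- rep(c(1L, 2L), c(length(time1), length(time2)))
  ts <- sort(unique(time[event == 1]))
  O1 <- E1 <- V <- 0
  for (t in ts) {
    n1 <- sum(time >= t & grp == 1L)
    n2 <- sum(time >= t & grp == 2L)
    nt <- n1 + n2
    d1 <- sum(time == t & event == 1 & grp == 1L)
    d2 <- sum(time == t & event == 1 & grp == 2L)
    dt <- d1 + d2
    O1 <- O1 + d1
    E1 <- E1 + dt * n1 / nt
    if (nt > 1)
      V <- V + dt * (n1 / nt) * (1 - n1 / nt) * (nt - dt) / (nt - 1)
  }
  O <- sum(event[grp == 1L])
  E2 <- sum(event) - E1
  list(chi2 = (O1 - E1)^2 / V,
       hr = (O1 / E1) / ((sum(event) - O1) / E2),
       O1 = O1, E1 = E1, E2 = E2)
}

# Efron-corrected Cox log partial likelihood for one covariate, evaluated
# on a beta grid; the argmax is the oracle estimate.
efron_loglik <- function(beta, time, event, x) {
  ll <- 0
  for (t in sort(unique(time[event == 1]))) {
    risk <- which(time >= t)
    dead <- which(time == t & event == 1)
    d <- length(dead)
    ll <- ll + beta * sum(x[dead])
    sr <- sum(exp(beta * x[risk]))
    sd_ <- sum(exp(beta * x[dead]))
    for (l in seq_len(d) - 1L)
      ll <- ll - log(sr - (l / d) * sd_)
  }
  ll
}

grid_search_cox <- function(time, event, x, lower = -4, upper = 4,
                            tol = 1e-5) {
  grid <- seq(lower, upper, by = 0.01)
  ll <- vapply(grid, efron_loglik, numeric(1), time = time, event = event,
               x = x)
  b <- grid[which.max(ll)]
  fine <- seq(b - 0.02, b + 0.02, by = tol)
  llf <- vapply(fine, efron_loglik, numeric(1), time = time, event = event,
                x = x)
  fine[which.max(llf)]
}

# AUC as exhaustive pairwise concordance, ties counted one half
concordance_auc <- function(values, outcome) {
  pos <- values[outcome == 1]
  neg <- values[outcome == 0]
  tot <- 0
  for (p in pos) tot <- tot + sum(p > neg) + 0.5 * sum(p == neg)
  tot / (length(pos) * length(neg))
}

# product-limit estimator by hand (no ties assumptions beyond grouping)
hand_km <- function(time, event) {
  ts <- sort(unique(time[event == 1]))
  s <- 1
  out <- numeric(length(ts))
  for (i in seq_along(ts)) {
    n <- sum(time >= ts[i])
    d <- sum(time == ts[i] & event == 1)
    s <- s * (1 - d / n)
    out[i] <- s
  }
  data.frame(time = ts, surv = out)
}
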