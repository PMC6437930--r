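test_that("Kaplan-Meier estimates match hand product-limit results", {
  # all censored: survival stays at 1
  km <- km_estimate(c(2, 4, 6), c(0, 0, 0))
  expect_true(all(km$surv == 1))

  # times {1, 2+, 3}: S = 2/3 on [1, 3), 0 at 3
  km2 <- km_estimate(c(1, 2, 3), c(1, 0, 1))
  ev <- km2[km2$n_event > 0, ]
  expect_equal(ev$surv, c(2 / 3, 0))

  # two patients, events at distinct times: 1 -> 0.5 -> 0
  km3 <- km_estimate(c(5, 9), c(1, 1))
  expect_equal(km3$surv, c(0.5, 0))

  expect_error(km_estimate(c(-1, 2), c(1, 1)), "negative")
})

test_that("K-M equals one minus the empirical CDF without censoring", {
  withr::with_seed(11, {
    t <- round(rexp(40, 0.1), 1)
  })
  km <- km_estimate(t, rep(1, 40))
  hk <- hand_km(t, rep(1, 40))
  expect_equal(km$surv[km$n_event > 0], hk$surv, tolerance = 1e-12)
  ecdf_t <- ecdf(t)
  expect_equal(km$surv[km$n_event > 0], 1 - ecdf_t(hk$time),
               tolerance = 1e-12)
})

test_that("log-rank matches brute-force risk-set enumeration", {
  a <- list(t = c(1, 2, 3), e = c(1, 1, 1))
  b <- list(t = c(4, 5, 6), e = c(1, 1, 1))
  lr <- logrank_test(a$t, a$e, b$t, b$e)
  or <- brute_logrank(a$t, a$e, b$t, b$e)
  expect_equal(lr$chi2, or$chi2, tolerance = 1e-10)
  expect_equal(lr$hr, or$hr, tolerance = 1e-10)

  # with censoring and ties
  a2 <- list(t = c(2, 2, 5, 7, 9), e = c(1, 1, 0, 1, 0))
  b2 <- list(t = c(3, 4, 4, 8, 10), e = c(1, 1, 1, 0, 1))
  lr2 <- logrank_test(a2$t, a2$e, b2$t, b2$e)
  or2 <- brute_logrank(a2$t, a2$e, b2$t, b2$e)
  expect_equal(lr2$chi2, or2$chi2, tolerance = 1e-10)
  expect_equal(lr2$hr, or2$hr, tolerance = 1e-10)
  expect_true(lr2$ci95[1] < lr2$hr && lr2$hr < lr2$ci95[2])
})

test_that("log-rank is symmetric and null on identical groups", {
  t <- c(1, 3, 5, 7); e <- c(1, 0, 1, 1)
  same <- logrank_test(t, e, t, e)
  expect_equal(same$chi2, 0, tolerance = 1e-12)
  expect_equal(same$p, 1)
  expect_equal(same$hr, 1, tolerance = 1e-12)

  a <- list(t = c(2, 4, 9, 12), e = c(1, 1, 0, 1))
  b <- list(t = c(1, 3, 6, 14), e = c(1, 1, 1, 0))
  ab <- logrank_test(a$t, a$e, b$t, b$e)
  ba <- logrank_test(b$t, b$e, a$t, a$e)
  expect_equal(ab$chi2, ba$chi2, tolerance = 1e-12)
  expect_equal(ab$p, ba$p, tolerance = 1e-12)
  expect_equal(ab$hr, 1 / ba$hr, tolerance = 1e-12)

  expect_error(logrank_test(numeric(0), numeric(0), t, e), "non-empty")
  expect_error(logrank_test(c(1, 2), c(0, 0), c(3, 4), c(0, 0)),
               "degenerate")
})

test_that("null log-rank p-values are uniform", {
  ps <- withr::with_seed(21, vapply(1:1000, function(i) {
    t <- rexp(60, 0.1)
    e <- as.integer(t <= 25)
    t <- pmin(t, 25)
    g <- sample(rep(c(TRUE, FALSE), 30))
    logrank_test(t[g], e[g], t[!g], e[!g])$p
  }, numeric(1)))
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
  expect_lt(abs(mean(ps < 0.05) - 0.05), 0.02)
})

test_that("Cox beta matches grid-search partial-likelihood maximization", {
  t <- c(4, 3, 1, 1, 2, 2, 3, 5)
  e <- c(1, 1, 1, 0, 1, 1, 0, 1)
  x <- c(0, 2, 1, 1, 1, 0, 0, 2)
  fit <- cox_univariate(t, e, x)
  oracle <- grid_search_cox(t, e, x)
  expect_equal(fit$beta, oracle, tolerance = 1e-4)
})

test_that("Cox recovers a planted binary hazard ratio", {
  hits <- vapply(1:10, function(i) withr::with_seed(400 + i, {
    x <- rbinom(400, 1, 0.5)
    t <- rexp(400, 0.05 * 2^x)
    e <- as.integer(t <= 60); t <- pmin(t, 60)
    hr <- cox_univariate(t, e, x)$hr
    hr >= 1.6 && hr <= 2.5
  }), logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("Cox under the null gives small betas, and flags separation", {
  betas <- vapply(1:10, function(i) withr::with_seed(500 + i, {
    t <- rexp(100, 0.05)
    e <- rep(1L, 100)
    cox_univariate(t, e, rnorm(100))$beta
  }), numeric(1))
  expect_lt(abs(mean(betas)), 0.1)
  expect_error(cox_univariate(c(1, 2, 3), c(1, 1, 0), rep(2, 3)),
               "constant")
})

test_that("Cox and log-rank agree on effect direction", {
  for (i in 1:6) {
    withr::with_seed(600 + i, {
      x <- rbinom(120, 1, 0.5)
      t <- rexp(120, 0.05 * ifelse(x == 1, 0.5, 1))
      e <- as.integer(t <= 48); t <- pmin(t, 48)
    })
    lr <- logrank_test(t[x == 1], e[x == 1], t[x == 0], e[x == 0])
    cx <- cox_univariate(t, e, x)
    expect_equal(sign(log(lr$hr)), sign(cx$beta))
  }
})

test_that("Pearson wrapper matches the direct formula", {
  expect_equal(pearson_corr(1:10, 1:10)$r, 1)
  expect_equal(pearson_corr(1:10, -(1:10))$r, -1)
  withr::with_seed(31, {
    x <- rnorm(10); y <- x + rnorm(10)
  })
  pc <- pearson_corr(x, y)
  expect_equal(pc$r, cov(x, y) / (sd(x) * sd(y)), tolerance = 1e-12)
  expect_true(pc$ci95[1] < pc$r && pc$r < pc$ci95[2])
  expect_error(pearson_corr(rep(1, 5), 1:5), "zero variance")
})

test_that("cumulative correlation ranks coexpressed markers first", {
  withr::with_seed(41, {
    a <- rnorm(200)
    m <- cbind(A = a, B = a + rnorm(200, sd = 0.1), C = rnorm(200),
               D = rnorm(200))
  })
  cc <- cumulative_correlation(m)
  expect_setequal(cc$marker[1:2], c("A", "B"))
  expect_true(all(cc$marker[3:4] %in% c("C", "D")))
  expect_error(cumulative_correlation(m[, 1:2]), "at least 3")
  m2 <- cbind(m, E = rep(1, 200))
  expect_warning(cc2 <- cumulative_correlation(m2), "constant")
  expect_false("E" %in% cc2$marker)
})

test_that("simulated block members outrank noise markers", {
  wins <- vapply(1:20, function(i) withr::with_seed(700 + i, {
    f <- rnorm(200)
    m <- cbind(sapply(1:4, function(j) f + rnorm(200, sd = 0.8)),
               matrix(rnorm(200 * 2), 200))
    colnames(m) <- c(paste0("B", 1:4), "N1", "N2")
    cc <- cumulative_correlation(m)
    all(match(paste0("B", 1:4), cc$marker) < match(c("N1", "N2"),
                                                   cc$marker))
  }), logical(1))
  expect_gte(mean(wins), 0.95)
})

test_that("Monte-Carlo power agrees with the Schoenfeld closed form", {
  p1 <- logrank_power(80, 1, event_fraction = 0.7, reps = 400, seed = 1)
  expect_lt(abs(p1$power - 0.05), 3 * sqrt(0.05 * 0.95 / 400) + 0.01)
  p2 <- logrank_power(100, 0.5, event_fraction = 0.7, reps = 400, seed = 2)
  expect_lt(abs(p2$power - p2$schoenfeld), 3 * p2$se + 0.01)
  expect_error(logrank_power(100, -1, reps = 400), "> 0")
  expect_error(logrank_power(100, 0.5, reps = 50), ">= 100")
})

test_that("power increases with sample size", {
  lo <- logrank_power(40, 0.6, event_fraction = 0.7, reps = 300, seed = 3)
  hi <- logrank_power(200, 0.6, event_fraction = 0.7, reps = 300, seed = 4)
  expect_gt(hi$power, lo$power)
  expect_gt(schoenfeld_power(200, 0.6), schoenfeld_power(40, 0.6))
})
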