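toy_matrix <- function(n = 60, seed = 1) {
  withr::with_seed(seed, {
    v <- cbind(A = rnorm(n), B = rnorm(n), C = rnorm(n))
    v <- cbind(v, `A+B` = (v[, "A"] + v[, "B"]) / 2 + rnorm(n, sd = 0.1))
  })
  ids <- sprintf("P%03d", seq_len(n))
  rownames(v) <- ids
  structure(list(values = v, unit_id = ids, patient_id = ids,
                 method = "average"), class = "marker_matrix")
}

toy_clinical <- function(mm, seed = 2, hazard = 0.05) {
  withr::with_seed(seed, {
    t <- rexp(length(mm$unit_id), hazard)
  })
  data.frame(patient_id = mm$patient_id, months = pmin(t, 60),
             event = as.integer(t <= 60), stringsAsFactors = FALSE)
}

test_that("combination values reduce correctly in additive mode", {
  mm <- toy_matrix()
  expect_equal(combination_value(mm, "A", mode = "additive"),
               setNames(mm$values[, "A"], mm$unit_id))
  ab <- combination_value(mm, c("A", "B"), mode = "additive")
  expect_equal(unname(ab), unname(mm$values[, "A"] + mm$values[, "B"]))
  # two columns carrying identical values sum to exactly twice one of them
  mm2 <- mm
  mm2$values[, "B"] <- mm2$values[, "A"]
  dup <- combination_value(mm2, c("A", "B"), mode = "additive")
  expect_equal(unname(dup), unname(2 * mm2$values[, "A"]))
})

test_that("colocalization mode needs its co-label column", {
  mm <- toy_matrix()
  got <- combination_value(mm, c("B", "A"), mode = "colocalization")
  expect_equal(unname(got), unname(mm$values[, "A+B"]))  # key is sorted
  expect_error(combination_value(mm, c("A", "C"), mode = "colocalization"),
               "re-run")
})

test_that("global scores respect their bounds and zero floor", {
  mm <- toy_matrix()
  mm$values <- abs(mm$values) + 1
  mm$values[3, c("A", "B", "C")] <- 0
  gs <- global_score(mm, c("A", "B", "C"))
  expect_equal(gs$count_score[3], 0)
  expect_true(all(gs$count_score >= 0 & gs$count_score <= 3))
  expect_equal(gs$sum_score, unname(rowSums(mm$values[, c("A", "B", "C")])))
  expect_error(global_score(mm, character(0)), "non-empty")
})

test_that("planted global effects are recovered by the sum score", {
  hits <- vapply(1:10, function(i) {
    withr::with_seed(800 + i, {
      n <- 400
      latent <- rbinom(n, 1, 0.5)
      vals <- sapply(1:5, function(j) latent + rnorm(n, sd = 0.8))
      colnames(vals) <- paste0("M", 1:5)
      rownames(vals) <- sprintf("P%03d", 1:n)
      t <- rexp(n, 0.05 * 0.5^latent)
    })
    mm <- structure(list(values = vals, unit_id = rownames(vals),
                         patient_id = rownames(vals), method = "average"),
                    class = "marker_matrix")
    cl <- data.frame(patient_id = mm$patient_id, months = pmin(t, 60),
                     event = as.integer(t <= 60))
    gs <- global_score(mm, paste0("M", 1:5))
    st <- dichotomize(gs$sum_score, gs$unit_id)
    sv <- unit_survival(mm, cl)
    hi <- st$class == "hi"; lo <- st$class == "lo"
    lr <- logrank_test(sv$months[hi], sv$event[hi],
                       sv$months[lo], sv$event[lo])
    lr$hr < 1 && lr$p < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("size-1 scans reproduce the single-marker ranking", {
  mm <- toy_matrix()
  cl <- toy_clinical(mm)
  rep1 <- rank_combinations(mm, cl, c("A", "B", "C"), sizes = 1,
                            mode = "additive")
  manual <- vapply(c("A", "B", "C"), function(m) {
    st <- dichotomize(mm$values[, m], mm$unit_id)
    sv <- unit_survival(mm, cl)
    hi <- st$class == "hi"; lo <- st$class == "lo"
    logrank_test(sv$months[hi], sv$event[hi],
                 sv$months[lo], sv$event[lo])$p
  }, numeric(1))
  expect_equal(rep1$combination, names(sort(manual)))
  expect_equal(sort(rep1$p), unname(sort(manual)), tolerance = 1e-12)
})

test_that("BH q-values never undercut their p-values", {
  mm <- toy_matrix()
  cl <- toy_clinical(mm)
  rep <- rank_combinations(mm, cl, c("A", "B", "C"), sizes = c(1, 2),
                           mode = "additive")
  expect_true(all(rep$q >= rep$p - 1e-15))
  expect_true(!is.unsorted(rep$p))
})

test_that("anchored scans prepend the anchor to every combination", {
  mm <- toy_matrix()
  cl <- toy_clinical(mm)
  rep <- rank_combinations(mm, cl, c("B", "C"), sizes = 1, anchor = "A",
                           mode = "additive")
  expect_setequal(rep$combination, c("A+B", "A+C"))
  expect_error(rank_combinations(mm, cl, c("B", "C"), sizes = 4,
                                 anchor = "A", mode = "additive"),
               "capped")
})

test_that("correlograms recover planted block structure", {
  withr::with_seed(51, {
    f1 <- rnorm(150); f2 <- rnorm(150)
    m <- cbind(A1 = f1 + rnorm(150, sd = 0.4),
               A2 = f1 + rnorm(150, sd = 0.4),
               A3 = f1 + rnorm(150, sd = 0.4),
               B1 = f2 + rnorm(150, sd = 0.4),
               B2 = f2 + rnorm(150, sd = 0.4),
               B3 = f2 + rnorm(150, sd = 0.4))
  })
  cg <- correlogram(m)
  expect_equal(cg$r, t(cg$r))
  expect_equal(unname(diag(cg$r)), rep(1, 6))
  pos <- match(colnames(m), cg$order)
  expect_lt(max(abs(diff(sort(pos[1:3])))), 2)  # A block contiguous
  expect_lt(max(abs(diff(sort(pos[4:6])))), 2)  # B block contiguous
  # permuting input columns leaves block contiguity intact
  cg2 <- correlogram(m[, c(4, 1, 5, 2, 6, 3)])
  pos2 <- match(colnames(m), cg2$order)
  expect_lt(max(abs(diff(sort(pos2[1:3])))), 2)
  expect_lt(max(abs(diff(sort(pos2[4:6])))), 2)
})

test_that("PCA groups match planted two-factor structure", {
  # unequal block strengths keep the two leading eigenvalues apart, so
  # the components are identified (equal blocks would be rotation-
  # degenerate by symmetry)
  withr::with_seed(61, {
    f1 <- rnorm(200); f2 <- rnorm(200)
    f2 <- residuals(lm(f2 ~ f1))   # exactly independent planted factors
    m <- cbind(X1 = f1 + rnorm(200, sd = 0.2),
               X2 = f1 + rnorm(200, sd = 0.2),
               Y1 = f2 + rnorm(200, sd = 0.6),
               Y2 = f2 + rnorm(200, sd = 0.6))
    rownames(m) <- sprintf("U%03d", 1:200)
  })
  pg <- pca_groups(m, n_components = 2)
  vp <- pg$variance_proportion
  expect_true(all(diff(vp) <= 1e-12))
  expect_lte(sum(vp), 1 + 1e-12)
  mem <- lapply(pg$groups, `[[`, "members")
  expect_true(setequal(mem[[1]], c("X1", "X2")) ||
                setequal(mem[[1]], c("Y1", "Y2")))
  expect_true(setequal(c(mem[[1]], mem[[2]]), colnames(m)))
  # duplicated columns get equal-magnitude loadings
  md <- cbind(m[, c("X1", "X1", "Y1")])
  colnames(md) <- c("D1", "D2", "Z")
  pg2 <- pca_groups(md, n_components = 1)
  l <- pg2$groups[[1]]$loadings
  expect_equal(abs(l[["D1"]]), abs(l[["D2"]]), tolerance = 1e-10)
  # scores are oriented along their members' mean expression
  expect_gt(cor(pg$scores[, 1], rowMeans(scale(m[, mem[[1]]]))), 0)
})

test_that("PC-score stratification is sign-invariant up to HR inversion", {
  mm <- toy_matrix(n = 80, seed = 71)
  cl <- toy_clinical(mm, seed = 72)
  pg <- pca_groups(mm, markers = c("A", "B", "A+B"), n_components = 1)
  s <- pg$scores[, 1]
  a <- pc_survival(s, mm, cl)
  b <- pc_survival(-s, mm, cl)
  expect_equal(a$p, b$p, tolerance = 1e-12)
  expect_equal(a$hr, 1 / b$hr, tolerance = 1e-12)
})

test_that("additive and colocalization modes agree on planted directions", {
  planted <- c("TIM-3", "CD26", "CD39")
  cs <- cohort_spec(n_patients = 150, covariates = FALSE,
                    planted_effects = list(planted_effect(planted, hr = 0.5)))
  s <- test_spec(marker_prevalence = scan_prevalence())
  agree <- vapply(1:10, function(i) {
    coh <- generate_cohort(cs, s, seed = 900 + i)
    q <- simulate_quant_matrix(coh, seed = 950 + i)
    mm <- aggregate_cores(q, coh$core_map, method = "average")
    sv <- unit_survival(mm, coh$clinical)
    hrs <- vapply(c("colocalization", "additive"), function(md) {
      val <- combination_value(mm, planted, mode = md)
      st <- dichotomize(val, mm$unit_id)
      hi <- st$class == "hi"; lo <- st$class == "lo"
      logrank_test(sv$months[hi], sv$event[hi],
                   sv$months[lo], sv$event[lo])$hr
    }, numeric(1))
    sign(log(hrs[1])) == sign(log(hrs[2]))
  }, logical(1))
  expect_gte(mean(agree), 0.9)
})
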