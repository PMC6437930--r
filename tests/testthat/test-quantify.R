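# helpers to build bare test images: H x W x channel arrays with dimnames
blank_image <- function(px, channels) {
  array(0, c(px, px, length(channels)),
        dimnames = list(NULL, NULL, channels))
}

add_disk <- function(img, channel, cx, cy, r, value) {
  d2 <- outer((seq_len(dim(img)[1]) - cx)^2,
              (seq_len(dim(img)[2]) - cy)^2, `+`)
  layer <- img[, , channel]
  layer[d2 <= r^2] <- value
  img[, , channel] <- layer
  img
}

test_that("ROI area matches disk geometry and subtracts punched holes", {
  um <- 0.3225
  img <- blank_image(650, "DAPI")
  img <- add_disk(img, "DAPI", 325, 325, 300, 100)
  roi <- compute_tissue_roi(img, threshold = 50, um_per_px = um,
                            min_hole_area_um2 = 100)
  expected <- pi * (300 * um / 1000)^2
  expect_lt(abs(roi$area_mm2 - expected) / expected, 0.02)

  img2 <- add_disk(img, "DAPI", 325, 325, 50, 0)  # punch a hole
  roi2 <- compute_tissue_roi(img2, threshold = 50, um_per_px = um,
                             min_hole_area_um2 = 100)
  hole <- pi * (50 * um / 1000)^2
  expect_lt(abs((roi$area_mm2 - roi2$area_mm2) - hole) / hole, 0.02)
})

test_that("an all-zero image raises an empty-ROI error", {
  img <- blank_image(100, "DAPI")
  expect_error(compute_tissue_roi(img, threshold = 10, um_per_px = 1),
               "empty ROI")
})

test_that("label detection respects thresholds, gates and geometry", {
  um <- 1
  img <- blank_image(200, c("DAPI", "CD3"))
  img <- add_disk(img, "DAPI", 100, 100, 150, 30)  # tissue plateau
  roi <- compute_tissue_roi(img, threshold = 20, um_per_px = um)

  # blank channel: zero labels
  ls0 <- detect_labels(img, "CD3", 50, c(20, 400), roi, um_per_px = um)
  expect_equal(nrow(ls0$labels), 0)

  # one disk above threshold and inside the gates: exactly one label
  img1 <- add_disk(img, "CD3", 100, 100, 5, 200)
  ls1 <- detect_labels(img1, "CD3", 50, c(20, 400), roi, um_per_px = um)
  expect_equal(nrow(ls1$labels), 1)
  expect_lt(abs(ls1$labels$x - 100), 1)

  # unknown channel is a config error
  expect_error(detect_labels(img, "PD-1", 50, c(20, 400), roi,
                             um_per_px = um), "not present")
})

test_that("size gates drop sub-gate objects and keep centroid accuracy", {
  um <- 1
  img <- blank_image(300, c("DAPI", "CD3"))
  img <- add_disk(img, "DAPI", 150, 150, 140, 30)
  centers <- cbind(x = c(50, 110, 170, 230, 150, 90, 210, 150),
                   y = c(60, 60, 60, 60, 150, 220, 220, 260))
  for (i in 1:8) img <- add_disk(img, "CD3", centers[i, 1], centers[i, 2],
                                 4, 200)
  small <- cbind(x = c(70, 190, 150), y = c(120, 120, 40))
  for (i in 1:3) img <- add_disk(img, "CD3", small[i, 1], small[i, 2],
                                 1.4, 200)
  roi <- compute_tissue_roi(img, threshold = 20, um_per_px = um)
  # min gate 20 um2 excludes the radius-1.4 dots (area ~6 um2)
  ls <- detect_labels(img, "CD3", 50, c(20, 400), roi, um_per_px = um)
  expect_equal(nrow(ls$labels), 8)
  d <- sqrt(outer(ls$labels$x, centers[, 1], `-`)^2 +
              outer(ls$labels$y, centers[, 2], `-`)^2)
  expect_true(all(apply(d, 2, min) <= 2))
})

test_that("raising a threshold never increases the label count", {
  s <- test_spec()
  ci <- generate_core_image(s, seed = 21)
  roi <- compute_tissue_roi(ci)
  counts <- vapply(c(50, 70, 90, 120, 160), function(thr)
    nrow(detect_labels(ci, "CD3", thr, c(20, 400), roi)$labels),
    integer(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("DAPI centering drops labels without a nucleus", {
  um <- 1
  img <- blank_image(200, c("DAPI", "CD3"))
  img <- add_disk(img, "DAPI", 100, 100, 90, 30)
  img <- add_disk(img, "DAPI", 60, 60, 3, 200)    # nucleus for cell 1
  img <- add_disk(img, "CD3", 60, 60, 5, 200)     # cell 1: has nucleus
  img <- add_disk(img, "CD3", 140, 140, 5, 200)   # cell 2: no nucleus
  roi <- compute_tissue_roi(img, threshold = 20, um_per_px = um)
  dapi <- detect_labels(img, "DAPI", 50, c(3, 400), roi, um_per_px = um)
  ls <- detect_labels(img, "CD3", 50, c(20, 400), roi,
                      dapi_labels = dapi, um_per_px = um)
  expect_equal(nrow(ls$labels), 1)
  expect_lt(abs(ls$labels$x - 60), 1.5)
})

test_that("colocalization handles disjoint, identical and nested sets", {
  um <- 1
  img <- blank_image(200, c("DAPI", "A", "B", "C"))
  img <- add_disk(img, "DAPI", 100, 100, 90, 30)
  roi <- compute_tissue_roi(img, threshold = 20, um_per_px = um)
  # A and B identical at two spots, C disjoint
  for (ctr in list(c(60, 60), c(140, 140))) {
    img <- add_disk(img, "A", ctr[1], ctr[2], 5, 200)
    img <- add_disk(img, "B", ctr[1], ctr[2], 5, 200)
  }
  img <- add_disk(img, "C", 100, 160, 5, 200)
  ls <- lapply(c(A = "A", B = "B", C = "C"), function(m)
    detect_labels(img, m, 50, c(20, 400), roi, um_per_px = um))

  expect_equal(nrow(colocalize(ls, c("A", "B"))$labels), 2)  # identical
  expect_equal(nrow(colocalize(ls, c("A", "C"))$labels), 0)  # disjoint
  expect_equal(nrow(colocalize(ls, c("A", "B", "C"))$labels), 0)
  expect_error(colocalize(ls, "A"), "2-4")
  expect_error(colocalize(ls, c("A", "B", "C", "A", "B")), "2-4")
})

test_that("co-counts are monotone under combination growth", {
  s <- test_spec(coexpression = list(
    list(markers = c("CD3", "TIM-3"), joint = 0.15),
    list(markers = c("CD3", "TIM-3", "CD26"), joint = 0.10)))
  ci <- generate_core_image(s, seed = 31)
  roi <- compute_tissue_roi(ci)
  dapi <- detect_labels(ci, "DAPI", 70, c(3, 400), roi)
  ls <- lapply(c(CD3 = "CD3", `TIM-3` = "TIM-3", CD26 = "CD26"),
               function(m) detect_labels(ci, m, 70, c(20, 400), roi,
                                         dapi_labels = dapi))
  n2 <- nrow(colocalize(ls, c("CD3", "TIM-3"))$labels)
  n3 <- nrow(colocalize(ls, c("CD3", "TIM-3", "CD26"))$labels)
  expect_lte(n3, n2)
  expect_lte(n2, min(nrow(ls$CD3$labels), nrow(ls$`TIM-3`$labels)))
})

test_that("summaries normalize to core size with log10(x + 1)", {
  um <- 1
  img <- blank_image(600, c("DAPI", "CD3"))
  img <- add_disk(img, "DAPI", 300, 300, 290, 30)
  roi <- compute_tissue_roi(img, threshold = 20, um_per_px = um)
  # force the exact arithmetic example: count 100 at area 0.25 mm2
  roi$area_mm2 <- 0.25
  centers <- expand.grid(x = seq(120, 480, length.out = 10),
                         y = seq(120, 480, length.out = 10))
  for (i in 1:100) img <- add_disk(img, "CD3", centers$x[i], centers$y[i],
                                   4, 150)
  ls <- detect_labels(img, "CD3", 50, c(20, 400), roi, um_per_px = um)
  rec <- summarize_core(list(CD3 = ls), list(), roi, img)
  expect_equal(rec$raw_count, 100)
  expect_equal(rec$density, 400)
  expect_equal(rec$log_value, log10(401))
  expect_equal(rec$log_value, 2.6032, tolerance = 1e-4)
  expect_equal(rec$mfi, 150)   # uniform label intensity

  # zero count: density 0, log value 0, MFI undefined
  blank <- detect_labels(img, "DAPI", 1e6, c(3, 400), roi, um_per_px = um)
  rec0 <- summarize_core(list(DAPI = blank), list(), roi, img)
  expect_equal(rec0$density, 0)
  expect_equal(rec0$log_value, 0)
  expect_true(is.na(rec0$mfi))
})

test_that("density is invariant to joint scaling of counts and area", {
  a <- data.frame(raw = c(40, 80), area = c(0.2, 0.4))
  expect_equal(a$raw[1] / a$area[1], a$raw[2] / a$area[2])
  # and through the summarize path: same labels, doubled-area ROI halves
  # density but log values remain monotone transforms of density only
  um <- 1
  img <- blank_image(200, c("DAPI", "CD3"))
  img <- add_disk(img, "DAPI", 100, 100, 90, 30)
  img <- add_disk(img, "CD3", 100, 100, 5, 200)
  roi <- compute_tissue_roi(img, threshold = 20, um_per_px = um)
  ls <- detect_labels(img, "CD3", 50, c(20, 400), roi, um_per_px = um)
  r1 <- summarize_core(list(CD3 = ls), list(), roi, img)
  roi2 <- roi; roi2$area_mm2 <- roi$area_mm2 * 2
  r2 <- summarize_core(list(CD3 = ls), list(), roi2, img)
  expect_equal(r1$density, 2 * r2$density)
})

test_that("independent operator configs correlate above 0.75", {
  # two parameterizations +/-10% around the default thresholds
  s <- test_spec()
  pA <- default_panel(s); pB <- default_panel(s)
  pA$thresholds <- pA$thresholds * 0.9
  pA$dapi_threshold <- pA$dapi_threshold * 0.9
  pB$thresholds <- pB$thresholds * 1.1
  pB$dapi_threshold <- pB$dapi_threshold * 1.1
  counts <- lapply(1:4, function(i) {
    ci <- generate_core_image(s, seed = 40 + i)
    qa <- quantify_core(ci, pA)
    qb <- quantify_core(ci, pB)
    cbind(qa$raw_count, qb$raw_count)
  })
  m <- do.call(rbind, counts)
  expect_gt(cor(m[, 1], m[, 2]), 0.75)
})
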