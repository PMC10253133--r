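# Nucleus detection, cell expansion, measurement and positivity scoring.

test_that("uniform background yields zero detections", {
  d <- detect_nuclei(matrix(0, 200, 200), 0.5, detection_params())
  expect_equal(nrow(d$table), 0L)
  expect_equal(max(d$labels), 0L)
})

test_that("pixel size must be supplied", {
  expect_error(detect_nuclei(matrix(0, 10, 10), pixel_size = -1), "pixel_size")
})

test_that("well-separated discs are each detected with accurate area", {
  ctrs <- separated_centres()
  h <- disc_image(ctrs, radius_um = 3, od = 0.5)
  d <- detect_nuclei(h, 0.5, detection_params())
  expect_equal(nrow(d$table), 20L)
  true_area <- pi * 9
  expect_true(all(abs(d$table$nucleus_area - true_area) < 0.15 * true_area))
  # centroids recovered
  nn <- apply(d$table[, c("x_um", "y_um")], 1, function(p)
    min(sqrt((ctrs[, 1] - p[1])^2 + (ctrs[, 2] - p[2])^2)))
  expect_lt(max(nn), 1)
})

test_that("nuclei larger than the maximum area are excluded", {
  h <- disc_image(cbind(50, 50), radius_um = 12, od = 0.5,
                  dim_px = c(200, 200))
  d <- detect_nuclei(h, 0.5, detection_params())
  expect_equal(nrow(d$table), 0L)
})

test_that("a circular nucleus has circularity 1 within tolerance", {
  h <- disc_image(cbind(50, 50), radius_um = 6, od = 0.5,
                  dim_px = c(200, 200))
  d <- detect_nuclei(h, 0.5, detection_params())
  expect_equal(nrow(d$table), 1L)
  expect_equal(d$table$nucleus_circularity, 1, tolerance = 0.05)
})

test_that("shape splitting separates touching discs", {
  h <- matrix(0, 200, 200)
  for (cx in c(46, 54))
    h[ellipse_indices(dim(h), cx, 50, 4, 4, 0, 0.5)] <- 0.5
  on <- detect_nuclei(h, 0.5, detection_params(split_by_shape = TRUE))
  off <- detect_nuclei(h, 0.5, detection_params(split_by_shape = FALSE))
  expect_equal(nrow(on$table), 2L)
  expect_equal(nrow(off$table), 1L)
})

test_that("detection is translation invariant to whole-pixel shifts", {
  ctrs <- separated_centres(n = 8, lo = 20, hi = 120)
  h <- disc_image(ctrs, radius_um = 3, od = 0.5, dim_px = c(340, 340))
  shift_px <- 13
  h2 <- matrix(0, 340, 340)
  h2[(1 + shift_px):340, (1 + shift_px):340] <-
    h[1:(340 - shift_px), 1:(340 - shift_px)]
  d1 <- detect_nuclei(h, 0.5, detection_params())
  d2 <- detect_nuclei(h2, 0.5, detection_params())
  expect_equal(nrow(d1$table), nrow(d2$table))
  ord1 <- order(d1$table$x_um, d1$table$y_um)
  ord2 <- order(d2$table$x_um, d2$table$y_um)
  expect_equal(d2$table$x_um[ord2], d1$table$x_um[ord1] + shift_px * 0.5,
               tolerance = 1e-8)
  expect_equal(d2$table$y_um[ord2], d1$table$y_um[ord1] + shift_px * 0.5,
               tolerance = 1e-8)
  expect_equal(d2$table$nucleus_area[ord2], d1$table$nucleus_area[ord1])
})

test_that("cell expansion grows an isolated nucleus by the expected area", {
  h <- disc_image(cbind(50, 50), radius_um = 3, od = 0.5,
                  dim_px = c(200, 200))
  p <- detection_params()
  d <- detect_nuclei(h, 0.5, p)
  cl <- expand_cells(d$labels, 0.5, p)
  cell_area <- sum(cl > 0) * 0.25
  expect_equal(cell_area, pi * 64, tolerance = 0.2 * pi * 64)  # r = 3 + 5
  expect_true(all(cl[d$labels > 0] == d$labels[d$labels > 0]))
})

test_that("zero expansion leaves cells equal to nuclei", {
  h <- disc_image(cbind(50, 50), radius_um = 3, od = 0.5,
                  dim_px = c(200, 200))
  p0 <- detection_params(cell_expansion = 0)
  d <- detect_nuclei(h, 0.5, p0)
  expect_identical(expand_cells(d$labels, 0.5, p0), d$labels)
})

test_that("two nearby nuclei split expansion territory symmetrically", {
  h <- matrix(0, 200, 300)
  for (cx in c(60, 90)) h[ellipse_indices(dim(h), cx, 50, 3, 3, 0, 0.5)] <- 0.5
  p <- detection_params()
  d <- detect_nuclei(h, 0.5, p)
  expect_equal(nrow(d$table), 2L)
  cl <- expand_cells(d$labels, 0.5, p)
  a <- tabulate(cl[cl > 0], 2)
  expect_lt(abs(a[1] - a[2]) / mean(a), 0.1)
  # cells never overlap: each pixel carries exactly one label
  expect_true(all(cl %in% 0:2))
  expect_false(any(cl > 0 & d$labels > 0 & cl != d$labels))
})

test_that("compartment means are exact on constant fields and scale linearly", {
  h <- disc_image(cbind(50, 50), radius_um = 3, od = 0.5,
                  dim_px = c(200, 200))
  dab <- matrix(0.3, 200, 200)
  p <- detection_params()
  d <- detect_nuclei(h, 0.5, p)
  cl <- expand_cells(d$labels, 0.5, p)
  m1 <- measure_cells(d, cl, h, dab, 0.5)
  expect_equal(m1$nucleus_dab_od_mean, 0.3, tolerance = 1e-12)
  expect_equal(m1$cytoplasm_dab_od_mean, 0.3, tolerance = 1e-12)
  m2 <- measure_cells(d, cl, h, 2 * dab, 0.5)
  for (f in c("nucleus_dab_od_mean", "cell_dab_od_mean",
              "cytoplasm_dab_od_mean"))
    expect_equal(m2[[f]], 2 * m1[[f]], tolerance = 1e-12)
})

test_that("an empty compartment yields NA features but keeps the cell", {
  h <- disc_image(cbind(50, 50), radius_um = 3, od = 0.5,
                  dim_px = c(200, 200))
  p0 <- detection_params(cell_expansion = 0)
  d <- detect_nuclei(h, 0.5, p0)
  m <- measure_cells(d, expand_cells(d$labels, 0.5, p0), h, h * 0, 0.5)
  expect_equal(nrow(m), 1L)
  expect_true(is.na(m$cytoplasm_dab_od_mean))
  expect_false(is.na(m$nucleus_dab_od_mean))
})

test_that("positivity scoring is inclusive at the threshold", {
  cells <- data.frame(nucleus_dab_od_mean = c(0.25, 0.19, 0.2))
  out <- score_positive(cells, detection_params())
  expect_equal(out$base_class, c("Positive", "Negative", "Positive"))
  expect_equal(unname(attr(out, "counts")[c("Positive", "Negative")]),
               c(2L, 1L))
})

test_that("missing scores are flagged as unscored with a warning", {
  cells <- data.frame(nucleus_dab_od_mean = c(0.3, NA))
  expect_warning(out <- score_positive(cells, detection_params()), "unscored")
  expect_true(is.na(out$base_class[2]))
  expect_error(score_positive(data.frame(x = 1), detection_params()),
               "score compartment")
})

test_that("detection on simulator output recovers counts and base classes", {
  sm <- stain_matrix()
  rc <- render_core(separable_scenario(0.5), sm, pixel_size = 0.5, seed = 17)
  d <- detect_cells(rc$tile, 0.5, sm,
                    detection_params(requested_pixel_size = 0.5))
  truth <- rc$cells
  expect_lt(abs(nrow(d$cells) - nrow(truth)) / nrow(truth), 0.05)
  # match detections to truth and check base-class agreement
  nn <- vapply(seq_len(nrow(d$cells)), function(i)
    which.min((truth$x_um - d$cells$x_um[i])^2 +
                (truth$y_um - d$cells$y_um[i])^2), integer(1))
  dist <- sqrt((truth$x_um[nn] - d$cells$x_um)^2 +
                 (truth$y_um[nn] - d$cells$y_um)^2)
  matched <- dist < 3
  expect_gt(mean(matched), 0.9)
  acc <- mean(d$cells$base_class[matched] == truth$marker_status[nn[matched]])
  expect_gte(acc, 0.99)
})

test_that("no cell polygons overlap on a dense core", {
  sm <- stain_matrix()
  rc <- render_core(scenario_normal_proficient(), sm, pixel_size = 1,
                    seed = 3)
  d <- detect_cells(rc$tile, 1, sm, detection_params(requested_pixel_size = 1))
  # label masks partition space: every pixel has at most one cell label and
  # nucleus labels agree with cell labels where both are present
  nl <- d$nucleus_labels; cl <- d$cell_labels
  expect_true(all(cl[nl > 0] == nl[nl > 0]))
  expect_equal(sort(unique(as.integer(cl[cl > 0]))),
               seq_len(nrow(d$cells)))
})
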