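# Synthetic TMA generator: geometry, determinism, ground-truth consistency.

test_that("slide dimensions follow cols*spacing/pixel_size", {
  spec <- tma_sim_spec(scenarios = tma_study_layout(seed = 1))
  expect_equal(unname(tma_dimensions(spec)), c(32400L, 16200L))
  spec2 <- tma_sim_spec(rows = 2, cols = 3, pixel_size = 2, seed = 1,
                        scenarios = rep(list(scenario_blank()), 6))
  expect_equal(unname(tma_dimensions(spec2)), c(1350L, 900L))
  img <- render_tma(spec2)
  expect_equal(dim(tma_as_array(img))[2:1], unname(tma_dimensions(spec2)))
})

test_that("spec validation enforces the grid invariants", {
  expect_error(tma_sim_spec(scenarios = list(scenario_blank())), "scenarios")
  expect_error(tma_sim_spec(pixel_size = 0), "pixel_size")
  expect_error(tma_sim_spec(tissue_core_diameter = 1000), "smaller")
})

test_that("blank cores render within noise of the background with no cells", {
  spec <- tma_sim_spec(rows = 1, cols = 1, pixel_size = 2, noise_sd = 0.02,
                       scenarios = list(scenario_blank()), seed = 4)
  img <- render_tma(spec)
  expect_equal(nrow(img$truth$cells), 0L)
  tile <- img$tiles[[1]]
  # 1 sigma of OD noise is ~ bg * ln(10) * noise_sd grey levels near background
  sigma_grey <- max(spec$background_rgb) * log(10) * spec$noise_sd
  for (ch in 1:3) {
    dev <- abs(tile[, , ch] - spec$background_rgb[ch])
    expect_lt(max(dev), 6 * sigma_grey)
    expect_lt(mean(dev), sigma_grey)
  }
})

test_that("rendering is deterministic for a fixed seed", {
  spec <- tma_sim_spec(rows = 1, cols = 2, pixel_size = 2, seed = 9,
                       scenarios = list(scenario_normal_proficient(),
                                        scenario_tumour_deficient()))
  a <- render_tma(spec); b <- render_tma(spec)
  expect_identical(tma_as_array(a), tma_as_array(b))
  expect_identical(a$truth$cells, b$truth$cells)
  spec2 <- tma_sim_spec(rows = 1, cols = 2, pixel_size = 2, seed = 10,
                        scenarios = spec$scenarios)
  expect_false(identical(tma_as_array(a), tma_as_array(render_tma(spec2))))
})

test_that("cell counts follow density times tissue area", {
  sc <- core_scenario(density = 2000)
  counts <- vapply(1:8, function(s)
    nrow(render_core(sc, pixel_size = 4, seed = s)$cells), numeric(1))
  lambda <- 2000 * pi * 0.3^2     # 565.5 expected in a 0.6 mm disc
  expect_lt(abs(mean(counts) - lambda), 4 * sqrt(lambda / 8))
  expect_true(all(abs(counts - lambda) < 5 * sqrt(lambda)))
})

test_that("hard-core placement respects the minimum distance and the disc", {
  rc <- render_core(core_scenario(density = 1500), pixel_size = 4, seed = 2)
  cells <- rc$cells
  d <- as.matrix(dist(cbind(cells$x_um, cells$y_um)))
  diag(d) <- Inf
  mean_radius <- sum(core_scenario()$composition * core_scenario()$radius_mean)
  expect_gte(min(d), 1.5 * mean_radius - 1e-9)
  r2 <- (cells$x_um - 450)^2 + (cells$y_um - 450)^2
  expect_true(all(r2 <= 300^2))
})

test_that("infeasible densities fail with a diagnostic", {
  expect_error(render_core(core_scenario(density = 3e4), pixel_size = 4,
                           seed = 1),
               "hard-core placement infeasible")
})

test_that("marker fractions converge to the scenario fraction", {
  sc <- core_scenario(marker_positive_fraction = 1)
  rc <- render_core(sc, pixel_size = 4, seed = 6)
  expect_true(all(rc$cells$marker_status == "Positive"))
  sc2 <- core_scenario(marker_positive_fraction = 0.7)
  cells <- do.call(rbind, lapply(1:4, function(s)
    render_core(sc2, pixel_size = 4, seed = s)$cells))
  p <- mean(cells$marker_status == "Positive")
  se <- sqrt(0.7 * 0.3 / nrow(cells))
  expect_lt(abs(p - 0.7), 4 * se)
})

test_that("the study layout has 15 blanks and 162 positions", {
  layout <- tma_study_layout(seed = 3)
  expect_length(layout, 162L)
  ids <- vapply(layout, `[[`, character(1), "id")
  expect_equal(sum(ids == "blank"), 15L)
  expect_equal(sum(ids == "excluded_scant"), 48L)
  expect_equal(sum(grepl("^ambiguous", ids)), 25L)
  spec <- tma_sim_spec(scenarios = layout, pixel_size = 8, seed = 3)
  img <- render_tma(spec)
  blank_labels <- img$truth$cores$label[img$truth$cores$blank]
  expect_length(blank_labels, 15L)
  expect_false(any(img$truth$cells$core_label %in% blank_labels))
})

test_that("every truth cell lies inside its core disc", {
  spec <- tma_sim_spec(rows = 2, cols = 2, pixel_size = 4, seed = 5,
                       scenarios = list(scenario_normal_proficient(),
                                        scenario_scant_mixed(),
                                        scenario_tumour_deficient(),
                                        scenario_blank()))
  img <- render_tma(spec)
  cells <- img$truth$cells
  cores <- img$truth$cores
  m <- match(cells$core_label, cores$label)
  r2 <- (cells$x_um - cores$x_um[m])^2 + (cells$y_um - cores$y_um[m])^2
  expect_true(all(r2 <= 300^2 + 1e-6))
  # per-core truth counts match the cell table
  tab <- table(cells$core_label)
  expect_equal(unname(cores$n_cells[match(names(tab), cores$label)]),
               as.integer(tab))
})

test_that("scenario expected calls encode the certification outcomes", {
  expect_equal(scenario_expected_call(scenario_normal_proficient()),
               "MLH1ProficientNormal")
  expect_equal(scenario_expected_call(scenario_tumour_deficient()),
               "MLH1DeficientTumour")
  expect_equal(scenario_expected_call(scenario_patchy_stain()), "Flagged")
  expect_equal(scenario_expected_call(scenario_immune_rich()), "Flagged")
  expect_equal(scenario_expected_call(scenario_blank()), "Invalid")
  expect_equal(scenario_expected_call(scenario_excluded_scant()), "Invalid")
})

test_that("write_tma produces the slide TIFF and truth tables", {
  dir <- withr::local_tempdir()
  spec <- tma_sim_spec(rows = 1, cols = 2, pixel_size = 4, seed = 8,
                       scenarios = list(scenario_normal_proficient(),
                                        scenario_blank()))
  img <- render_tma(spec)
  write_tma(img, dir)
  expect_true(file.exists(file.path(dir, "slide.tif")))
  arr <- tiff::readTIFF(file.path(dir, "slide.tif"))
  expect_equal(dim(arr), c(225, 450, 3))
  cells <- read.csv(file.path(dir, "truth_cells.csv"))
  expect_setequal(names(cells),
                  c("x_um", "y_um", "core_label", "tissue_class",
                    "marker_status"))
  expect_equal(nrow(cells), nrow(img$truth$cells))
})
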