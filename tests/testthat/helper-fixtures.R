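# Shared fixtures, built in code and memoised across test files.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache))
    assign(name, builder(), envir = .fixture_cache)
  get(name, envir = .fixture_cache)
}

# Single-channel image with hard discs of given OD at (x, y) um positions.
disc_image <- function(centres, radius_um, od = 0.5, dim_px = c(400, 400),
                       pixel_size = 0.5) {
  h <- matrix(0, dim_px[1L], dim_px[2L])
  for (i in seq_len(nrow(centres)))
    h[ellipse_indices(dim_px, centres[i, 1L], centres[i, 2L],
                      radius_um, radius_um, 0, pixel_size)] <- od
  h
}

# 20 well-separated disc centres inside a box, minimum pairwise distance.
separated_centres <- function(n = 20, lo = 15, hi = 185, min_dist = 20,
                              seed = 3) {
  with_seed(seed, {
    ctrs <- matrix(numeric(0), 0, 2)
    while (nrow(ctrs) < n) {
      p <- runif(2, lo, hi)
      if (nrow(ctrs) == 0 ||
          min((ctrs[, 1] - p[1])^2 + (ctrs[, 2] - p[2])^2) > min_dist^2)
        ctrs <- rbind(ctrs, p)
    }
    ctrs
  })
}

# A separable core scenario: sparse, well-spaced, strongly stained nuclei
# with class OD means straddling the 0.2 positivity threshold by >= 0.15.
separable_scenario <- function(positive_fraction = 0.5) {
  core_scenario(
    composition = c(NormalEpithelium = 1, Tumour = 0, ImmuneInfiltrate = 0,
                    Stroma = 0),
    marker_positive_fraction = positive_fraction,
    dab_od = 0.6, hema_od = 0.6, density = 300,
    radius_mean = 3, radius_sd = 0.2, aspect = 1,
    id = "separable")
}

# Trained classifier on a reduced training set (6 regions), shared by the
# classifier and pipeline tests.
small_model <- function() fixture("small_model", function() {
  regions <- simulate_training_regions(7, stain_matrix(), pixel_size = 1,
                                       size_um = 400, seed = 5)
  train_pipeline_classifier(regions, 1,
                            pipeline_config(detection = detection_params(
                              requested_pixel_size = 1)))
})

# Detected + smoothed cells of one mixed core, shared across tests.
mixed_core_cells <- function() fixture("mixed_core_cells", function() {
  sm <- stain_matrix()
  rc <- render_core(scenario_tumour_proficient(), sm, pixel_size = 1, seed = 33)
  d <- detect_cells(rc$tile, 1, sm, detection_params(requested_pixel_size = 1))
  list(truth = rc$cells,
       cells = add_smoothed_features(d$cells, 25, TRUE))
})

# Small 3 x 4 grid image shared by the dearray/certification tests.
small_grid_image <- function(seed = 12) fixture("small_grid_image", function() {
  scen <- list(scenario_normal_proficient(), scenario_blank(),
               scenario_tumour_deficient(),
               scenario_tumour_proficient(), scenario_excluded_scant(),
               scenario_normal_proficient(),
               scenario_tumour_proficient(), scenario_normal_proficient(),
               scenario_tumour_deficient(),
               scenario_blank(), scenario_normal_proficient(),
               scenario_tumour_proficient())
  spec <- tma_sim_spec(rows = 3, cols = 4, pixel_size = 4, seed = seed,
                       scenarios = scen)
  render_tma(spec)
})
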