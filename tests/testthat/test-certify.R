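# Per-core certification decision tree.

mk_summary <- function(n_normal = 0, n_tumour = 0, n_immune = 0, n_stroma = 0,
                       n_epi_pos = 0, n_epi_neg = NULL, label = "A1") {
  if (is.null(n_epi_neg)) n_epi_neg <- n_normal + n_tumour - n_epi_pos
  structure(list(core_label = label, n_normal = n_normal, n_tumour = n_tumour,
                 n_immune = n_immune, n_stroma = n_stroma,
                 n_epi_pos = n_epi_pos, n_epi_neg = n_epi_neg,
                 n_total = n_normal + n_tumour + n_immune + n_stroma),
            class = "core_summary")
}

test_that("summarize_core counts composite classes exactly", {
  cells <- data.frame(
    tissue_class = c(rep("Tumour", 80), rep("Stroma", 20)),
    base_class = c(rep("Negative", 80), rep("Positive", 20)))
  s <- summarize_core(cells, "C3")
  expect_equal(s$n_tumour, 80L)
  expect_equal(s$n_stroma, 20L)
  expect_equal(s$n_epi_neg, 80L)
  expect_equal(s$n_epi_pos, 0L)
  expect_equal(s$n_total, 100L)
  empty <- summarize_core(cells[0, ])
  expect_equal(empty$n_total, 0L)
  # unscored cells are dropped
  cells$base_class[1] <- NA
  expect_equal(summarize_core(cells)$n_total, 99L)
})

test_that("clear deficient tumour certifies as MLH1DeficientTumour", {
  s <- mk_summary(n_tumour = 90, n_stroma = 10, n_epi_pos = 5, n_epi_neg = 85)
  out <- certify(s, certification_params())
  expect_equal(out$call, "MLH1DeficientTumour")
  expect_equal(out$flag_reason, "none")
  expect_equal(out$histology_fraction, 0.90)
  expect_equal(out$marker_fraction, 5 / 90)
})

test_that("mixed histology flags for histology even with certain marker", {
  s <- mk_summary(n_normal = 50, n_tumour = 50, n_epi_pos = 10,
                  n_epi_neg = 90)
  out <- certify(s, certification_params())
  expect_equal(out$call, "Flagged")
  expect_equal(out$flag_reason, "Histology")
})

test_that("intermediate marker fraction flags for MLH1", {
  s <- mk_summary(n_tumour = 80, n_stroma = 20, n_epi_pos = 56,
                  n_epi_neg = 24)
  out <- certify(s, certification_params())
  expect_equal(out$call, "Flagged")
  expect_equal(out$flag_reason, "MLH1")
  expect_equal(out$marker_fraction, 0.7)
})

test_that("the 75 percent boundary is inclusive", {
  # exactly 75% tumour histology and exactly 75% marker-positive epithelium
  s <- mk_summary(n_tumour = 75, n_normal = 5, n_stroma = 20,
                  n_epi_pos = 60, n_epi_neg = 20)
  out <- certify(s, certification_params())
  expect_equal(out$call, "MLH1ProficientTumour")
  # a hair below the threshold on either axis flags
  s2 <- mk_summary(n_tumour = 74, n_normal = 6, n_stroma = 20,
                   n_epi_pos = 60, n_epi_neg = 20)
  expect_equal(certify(s2, certification_params())$call, "Flagged")
})

test_that("cores below min_cells are invalid; no epithelium flags both", {
  expect_equal(certify(mk_summary(n_tumour = 5), certification_params())$call,
               "Invalid")
  s <- mk_summary(n_immune = 30, n_stroma = 30)
  out <- certify(s, certification_params())
  expect_equal(out$call, "Flagged")
  expect_equal(out$flag_reason, "Both")
  expect_true(is.na(out$marker_fraction))
})

test_that("deficient normal epithelium certifies with a warning", {
  s <- mk_summary(n_normal = 90, n_stroma = 10, n_epi_pos = 2,
                  n_epi_neg = 88)
  expect_warning(out <- certify(s, certification_params()),
                 "biologically unexpected")
  expect_equal(out$call, "MLH1DeficientNormal")
})

test_that("epithelial denominator changes the histology fraction", {
  s <- mk_summary(n_normal = 60, n_stroma = 40, n_epi_pos = 55, n_epi_neg = 5)
  all_cells <- certify(s, certification_params())
  epi <- certify(s, certification_params(
    histology_denominator = "epithelial_cells"))
  expect_equal(all_cells$call, "Flagged")      # 60% of all cells
  expect_equal(epi$call, "MLH1ProficientNormal")  # 100% of epithelium
})

test_that("raising the threshold never certifies a flagged core", {
  set.seed(14)
  for (i in 1:60) {
    counts <- as.integer(rmultinom(1, 120, runif(4)))
    pos <- as.integer(round(runif(1) * (counts[1] + counts[2])))
    s <- mk_summary(counts[1], counts[2], counts[3], counts[4],
                    n_epi_pos = pos)
    prev_flagged <- FALSE
    for (th in c(0.6, 0.75, 0.9)) {
      out <- suppressWarnings(certify(s, certification_params(threshold = th)))
      if (prev_flagged) expect_equal(out$call, "Flagged")
      prev_flagged <- out$call == "Flagged"
    }
    # at any threshold > 0.5 certification is unambiguous and pure
    out1 <- suppressWarnings(certify(s, certification_params()))
    out2 <- suppressWarnings(certify(s, certification_params()))
    expect_identical(out1, out2)
  }
})

test_that("certify_all covers every core and conserves tallies", {
  img <- small_grid_image()
  g <- dearray(img, rows = 3, cols = 4)
  cells <- img$truth$cells
  cells$base_class <- cells$marker_status
  calls <- certify_all(g, cells, certification_params())
  expect_equal(nrow(calls), 12L)
  t <- attr(calls, "tallies")
  expect_equal(sum(t[c("certified", "invalid")]) +
                 sum(t[grep("flagged", names(t))]), 12)
  expect_equal(sum(calls$call == "Invalid"), sum(!g$cores$valid))
  # with perfect tissue classes the expected calls are reproduced
  tr <- img$truth$cores
  m <- match(calls$core_label, tr$label)
  certified <- !calls$call %in% c("Flagged", "Invalid")
  expect_true(all(calls$call[certified] == tr$expected_call[m][certified]))
})
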