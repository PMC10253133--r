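# Training montage composition and random-forest tissue classification.

test_that("montage layout places 14 tiles in a 3 x 5 grid with gutters", {
  tiles <- replicate(14, array(100L, c(100, 100, 3)), simplify = FALSE)
  m <- compose_training_image(tiles, pixel_size = 1, gutter_um = 50)
  expect_equal(dim(m$image), c(3 * 100 + 2 * 50, 5 * 100 + 4 * 50, 3))
  expect_equal(nrow(m$offsets_um), 14L)
  # single tile: montage equals the tile
  one <- compose_training_image(tiles[1], pixel_size = 1)
  expect_identical(one$image, tiles[[1]])
})

test_that("annotation coordinates are remapped by the tile offset", {
  tiles <- replicate(2, array(100L, c(50, 50, 3)), simplify = FALSE)
  ann <- list(list(list(polygon = cbind(x = c(10, 20, 20, 10),
                                        y = c(10, 10, 20, 20)),
                        tissue_class = "Tumour")),
              list(list(polygon = cbind(x = c(5, 15, 15, 5),
                                        y = c(5, 5, 15, 15)),
                        tissue_class = "Stroma")))
  m <- compose_training_image(tiles, ann, pixel_size = 1, gutter_um = 10)
  expect_equal(m$annotations[[1]]$polygon[1, ], c(x = 10, y = 10))
  expect_equal(unname(m$annotations[[2]]$polygon[1, ]),
               unname(c(5, 5) + m$offsets_um[2, ]))
  expect_error(compose_training_image(list(array(0L, c(10, 10, 3)),
                                           array(0L, c(20, 20, 3))),
                                      pixel_size = 1), "same dimensions")
})

test_that("cells are labelled by the containing annotation polygon", {
  cells <- data.frame(x_um = c(15, 100, 1), y_um = c(15, 100, 1))
  ann <- list(list(polygon = cbind(c(10, 20, 20, 10), c(10, 10, 20, 20)),
                   tissue_class = "Tumour"))
  lab <- label_cells_by_annotation(cells, ann)
  expect_equal(lab, c("Tumour", NA, NA))
})

test_that("separable synthetic features are classified near-perfectly", {
  set.seed(21)
  n <- 200
  mk <- function(mu, cls) data.frame(f1 = rnorm(n, mu[1]), f2 = rnorm(n, mu[2]),
                                     cls = cls)
  df <- rbind(mk(c(0, 0), "NormalEpithelium"), mk(c(6, 0), "Tumour"),
              mk(c(0, 6), "ImmuneInfiltrate"), mk(c(6, 6), "Stroma"))
  model <- train_tissue_classifier(df, df$cls, features = c("f1", "f2"),
                                   seed = 1)
  expect_gte(model$oob_accuracy, 0.95)
  pred <- predict(model, df)
  expect_gte(mean(pred == df$cls), 0.99)
})

test_that("permuted labels give chance-level out-of-bag accuracy", {
  set.seed(33)
  n <- 150
  df <- data.frame(f1 = rnorm(4 * n), f2 = rnorm(4 * n))
  labs <- sample(rep(TISSUE_CLASSES, n))
  model <- train_tissue_classifier(df, labs, features = c("f1", "f2"),
                                   seed = 2)
  se <- sqrt(0.25 * 0.75 / (4 * n))
  expect_lt(abs(model$oob_accuracy - 0.25), 3 * se)
})

test_that("training is deterministic and rejects degenerate input", {
  set.seed(5)
  df <- data.frame(f1 = rnorm(100), f2 = rnorm(100))
  labs <- rep(c("Tumour", "Stroma"), 50)
  m1 <- train_tissue_classifier(df, labs, features = c("f1", "f2"), seed = 9)
  m2 <- train_tissue_classifier(df, labs, features = c("f1", "f2"), seed = 9)
  expect_identical(predict(m1, df), predict(m2, df))
  expect_error(train_tissue_classifier(df, rep("Tumour", 100),
                                       features = c("f1", "f2")),
               "two tissue classes")
  expect_warning(train_tissue_classifier(df, rep(c("Tumour", "Stroma"),
                                                 c(95, 5)),
                                         features = c("f1", "f2"), seed = 1),
                 "fewer than")
})

test_that("classification carries marker status through unchanged", {
  set.seed(2)
  df <- data.frame(f1 = c(rnorm(50), rnorm(50, 8)),
                   f2 = rnorm(100),
                   base_class = sample(c("Positive", "Negative"), 100, TRUE))
  labs <- rep(c("NormalEpithelium", "Tumour"), each = 50)
  model <- train_tissue_classifier(df, labs, features = c("f1", "f2"),
                                   seed = 3)
  out <- classify_cells(model, df)
  expect_equal(out$base_class, df$base_class)
  expect_equal(out$composite_class,
               paste(out$tissue_class, out$base_class, sep = ":"))
  empty <- classify_cells(model, df[0, ])
  expect_equal(nrow(empty), 0L)
  expect_error(predict(model, df[, "f2", drop = FALSE]), "f1")
})

test_that("serialise -> load -> predict is identical to direct predict", {
  model <- small_model()
  cells <- mixed_core_cells()$cells
  path <- withr::local_tempfile(fileext = ".rds")
  save_classifier(model, path)
  expect_true(file.exists(paste0(path, ".manifest.txt")))
  reloaded <- load_classifier(path)
  expect_identical(predict(reloaded, cells), predict(model, cells))
})

test_that("simulator cores are classified with at least 90 percent accuracy", {
  model <- small_model()
  fix <- mixed_core_cells()
  cells <- classify_cells(model, fix$cells)
  truth <- fix$truth
  nn <- vapply(seq_len(nrow(cells)), function(i)
    which.min((truth$x_um - cells$x_um[i])^2 +
                (truth$y_um - cells$y_um[i])^2), integer(1))
  matched <- sqrt((truth$x_um[nn] - cells$x_um)^2 +
                    (truth$y_um[nn] - cells$y_um)^2) < 4
  acc <- mean(cells$tissue_class[matched] == truth$tissue_class[nn[matched]])
  expect_gte(acc, 0.9)
})
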