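# Feature transforms, MLP training, prediction, and the evaluation protocol.

test_that("feature construction applies the declared transforms", {
  ds <- small_dataset()
  rrs <- filter_records(ds, "RRS")
  cfg <- full_band_config()
  tr_idx <- 1:200
  f <- make_features(rrs, "chl_a", cfg, train_idx = tr_idx)

  # standardization contract on the training rows
  Xtr <- f$X[tr_idx, ]
  expect_lt(max(abs(colMeans(Xtr))), 1e-9)
  expect_lt(max(abs(apply(Xtr, 2, stats::var) - 1)), 1e-6)

  # pigment target is log10: chl = 100 -> 2
  expect_equal(f$y, log10(pmax(rrs$meta$chl_a, 1e-3)))
  i <- which.min(abs(rrs$meta$chl_a - 100))
  expect_equal(f$y[i], log10(rrs$meta$chl_a[i]))

  # ratio target untouched
  f_car <- make_features(rrs, "car", cfg)
  expect_identical(f_car$y, rrs$meta$car)
  expect_false(f_car$transform$target_log)
  expect_true(f$transform$target_log)

  expect_error(make_features(rrs, "turbidity", cfg), "valid products")
  expect_error(make_features(ds, "chl_a", cfg), "single data type")
})

test_that("target transforms invert exactly", {
  ds <- small_dataset()
  rrs <- filter_records(ds, "RRS")
  f <- make_features(rrs, "pc", full_band_config())
  y_back <- inverse_target(f$transform, f$y)
  expect_equal(y_back, pmax(rrs$meta$pc, f$transform$target_floor),
               tolerance = 1e-9)
  expect_equal(forward_target(f$transform, y_back), f$y, tolerance = 1e-12)
})

test_that("training is deterministic and learns a noiseless map", {
  set.seed(10)
  X <- matrix(stats::rnorm(2000 * 4), 2000)
  y <- 3 * X[, 1]
  cfg <- train_config(max_epochs = 60)

  m1 <- train_model(X, y, cfg, seed = 13)
  m2 <- train_model(X, y, cfg, seed = 13)
  expect_equal(m1$best_val_mae, m2$best_val_mae, tolerance = 1e-7)
  expect_identical(m1$weights, m2$weights)

  # fixed architecture: five hidden layers of 100 units, single output
  expect_identical(m1$hidden, rep(100L, 5L))
  expect_equal(vapply(m1$weights, nrow, 0L), c(rep(100L, 5L), 1L))

  holdout <- matrix(stats::rnorm(500 * 4), 500)
  expect_gte(r_squared(3 * holdout[, 1], predict(m1, holdout)), 0.99)

  expect_error(train_model(X[1:50, ], y[1:50], cfg), "at least 100")
  Xb <- X; Xb[1, 1] <- NA
  expect_error(train_model(Xb, y, cfg), "non-finite")
  expect_error(predict(m1, X[, 1:2]), "feature count")
})

test_that("pigment predictions are strictly positive", {
  ds <- small_dataset()
  rrs <- filter_records(ds, "RRS")
  f <- make_features(rrs, "chl_a", full_band_config())
  m <- train_model(f$X, f$y, train_config(max_epochs = 15), seed = 2,
                   transform = f$transform)
  expect_true(all(predict(m, f$X) > 0))
})

test_that("the pipeline is feature-count agnostic", {
  ds <- small_dataset()
  rrs <- filter_records(ds, "RRS")
  grid <- wavelength_grid()
  tc <- train_config(max_epochs = 10)
  for (centers in list(c(548, 674, 704),
                       c(510, 548, 590, 620, 650, 674, 704, 730, 760),
                       cyanosat_centers()[seq(1, 300, 3)])) {
    cfg <- srf_matrix(centers, 12, grid)
    f <- make_features(rrs, "car", cfg)
    m <- train_model(f$X, f$y, tc, seed = 1, transform = f$transform)
    expect_length(predict(m, f$X), n_records(rrs))
  }
})

test_that("models round-trip through their persisted form", {
  set.seed(3)
  X <- matrix(stats::rnorm(300 * 3), 300)
  y <- X[, 2]
  m <- train_model(X, y, train_config(max_epochs = 5), seed = 4)
  path <- tempfile(fileext = ".rds")
  write_retrieval_model(m, path)
  back <- read_retrieval_model(path)
  expect_equal(predict(back, X), predict(m, X))
  expect_true(file.exists(paste0(path, ".json")))
  unlink(c(path, paste0(path, ".json")))
})

test_that("evaluation keeps holdout and folds disjoint and learns", {
  ds <- small_dataset(600, seed = 77)
  rrs <- filter_records(ds, "RRS")
  ev <- evaluate(rrs, "chl_a", full_band_config(),
                 train_config(max_epochs = 25), seed = 6, run_cv = TRUE)

  # outer partition property
  expect_length(intersect(ev$train_idx, ev$test_idx), 0)
  expect_setequal(c(ev$train_idx, ev$test_idx), seq_len(n_records(rrs)))
  expect_equal(length(ev$test_idx), round(0.2 * n_records(rrs)))

  # every training record in exactly one CV fold
  expect_length(ev$fold_id, length(ev$train_idx))
  expect_setequal(unique(ev$fold_id), 1:5)
  expect_equal(nrow(ev$cv$folds), 5)

  # holdout flag and learnability of the noiseless forward map
  expect_true(ev$report$holdout_only)
  expect_equal(ev$report$n_test, length(ev$test_idx))
  expect_gte(ev$report$r2, 0.9)

  expect_error(evaluate(filter_records(rrs, idx = 1:3), "chl_a",
                        full_band_config()), "fewer records")
})
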