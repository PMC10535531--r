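# Train/validation protocol: outer holdout, inner k-fold cross-validation.

#' Evaluate a retrieval for one product and band configuration
#'
#' Protocol: a seeded record-level 80/20 split reserves 20% of the records
#' as an untouched holdout. Within the 80%, optional 5-fold cross-validation
#' reports fold-metric means and standard deviations (a sampling-bias check);
#' a final model trained on the full 80% provides the holdout metrics
#' (R^2, MAPE, RMSELE). R^2 is computed on the model's target scale (log10
#' for pigments, raw for the ratio). Feature standardization is always
#' fitted on training rows only.
#'
#' @param dataset A `spectral_dataset` with records of a single data type
#'   (>= 500 records for a meaningful protocol).
#' @param product `"chl_a"`, `"pc"` or `"car"`.
#' @param config A `band_config`.
#' @param train_cfg A [train_config()].
#' @param seed Integer seed controlling split, folds and training.
#' @param cv_folds Number of cross-validation folds (default 5).
#' @param run_cv Whether to run the fold loop (the holdout metrics do not
#'   depend on it; skipping saves `cv_folds` trainings in large sweeps).
#' @param holdout_fraction Outer holdout fraction (default 0.2).
#' @param config_name Label recorded in the report (default `"Full"`).
#' @return An object of class `"retrieval_evaluation"`: the `metrics_report`,
#'   the fitted model, and the holdout features/targets for attribution.
#' @export
evaluate <- function(dataset, product, config, train_cfg = train_config(),
                     seed = 1L, cv_folds = 5L, run_cv = TRUE,
                     holdout_fraction = 0.2, config_name = "Full") {
  stopifnot(inherits(dataset, "spectral_dataset"))
  n <- n_records(dataset)
  if (n < cv_folds) {
    stop("fewer records than cross-validation folds", call. = FALSE)
  }

  split <- with_seed(as.integer(seed), {
    test_idx <- sort(sample.int(n, round(holdout_fraction * n)))
    train_idx <- setdiff(seq_len(n), test_idx)
    fold_id <- sample(rep_len(seq_len(cv_folds), length(train_idx)))
    list(test_idx = test_idx, train_idx = train_idx, fold_id = fold_id)
  })

  feats <- make_features(dataset, product, config,
                         train_idx = split$train_idx)
  X <- feats$X
  y <- feats$y

  cv <- NULL
  if (run_cv) {
    fold_rows <- lapply(seq_len(cv_folds), function(k) {
      tr <- split$train_idx[split$fold_id != k]
      te <- split$train_idx[split$fold_id == k]
      m <- train_model(X[tr, , drop = FALSE], y[tr], train_cfg,
                       seed = as.integer(seed) + k,
                       transform = feats$transform)
      pred_t <- predict_model_scale(m, X[te, , drop = FALSE])
      obs_raw <- feats$y_raw[te]
      pred_raw <- inverse_target(feats$transform, pred_t)
      ok <- obs_raw > 0.01
      data.frame(fold = k,
                 r2 = r_squared(y[te], pred_t),
                 mape_percent = if (any(ok)) mape(obs_raw[ok], pred_raw[ok])
                                else NA_real_,
                 rmsele = rmsele(obs_raw, pred_raw))
    })
    folds <- do.call(rbind, fold_rows)
    cv <- list(folds = folds,
               mean = colMeans(folds[, -1], na.rm = TRUE),
               sd = apply(folds[, -1], 2, stats::sd, na.rm = TRUE))
  }

  model <- train_model(X[split$train_idx, , drop = FALSE],
                       y[split$train_idx], train_cfg,
                       seed = as.integer(seed),
                       transform = feats$transform)

  X_test <- X[split$test_idx, , drop = FALSE]
  y_test <- y[split$test_idx]
  pred_t <- predict_model_scale(model, X_test)
  obs_raw <- feats$y_raw[split$test_idx]
  pred_raw <- inverse_target(feats$transform, pred_t)

  report <- metrics_report(
    product = product,
    data_type = dataset$meta$data_type[1],
    config_name = config_name,
    obs = obs_raw, pred = pred_raw,
    obs_model = y_test, pred_model = pred_t,
    cv_fold_means = if (is.null(cv)) NULL else as.list(cv$mean),
    seed = as.integer(seed)
  )

  structure(list(
    report = report, model = model, cv = cv,
    transform = feats$transform, config = config,
    test_idx = split$test_idx, train_idx = split$train_idx,
    fold_id = split$fold_id,
    X_test = X_test, y_test = y_test,
    obs_test = obs_raw, pred_test = pred_raw
  ), class = "retrieval_evaluation")
}

#' @export
print.retrieval_evaluation <- function(x, ...) {
  print(x$report)
  if (!is.null(x$cv)) {
    cat(sprintf("  CV fold means: R2=%.3f+/-%.3f, MAPE=%.1f%%, RMSELE=%.3f\n",
                x$cv$mean["r2"], x$cv$sd["r2"], x$cv$mean["mape_percent"],
                x$cv$mean["rmsele"]))
  }
  invisible(x)
}
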