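# Retrieval performance statistics.

#' Coefficient of determination
#'
#' R^2 = 1 - SS_res / SS_tot. Can be negative for predictions worse than the
#' observed mean (the convention the permutation-attribution error metric
#' relies on).
#'
#' @param obs Observed values (length >= 2, not all equal).
#' @param pred Predicted values.
#' @return Dimensionless score <= 1.
#' @export
r_squared <- function(obs, pred) {
  stopifnot(length(obs) == length(pred), length(obs) >= 2)
  ss_tot <- sum((obs - mean(obs))^2)
  if (ss_tot == 0) {
    stop("observations have zero variance; R^2 undefined", call. = FALSE)
  }
  1 - sum((pred - obs)^2) / ss_tot
}

#' Mean absolute percentage error
#'
#' 100 * mean(|pred - obs| / obs). Observations must be strictly positive;
#' near-zero targets (e.g. the cyanobacteria:algae ratio in purely algal
#' waters) must be filtered by the caller before calling.
#'
#' @param obs Observed values (> 0 elementwise).
#' @param pred Predicted values.
#' @return Error in percent.
#' @export
mape <- function(obs, pred) {
  stopifnot(length(obs) == length(pred))
  if (any(obs <= 0)) {
    stop("MAPE requires strictly positive observations", call. = FALSE)
  }
  100 * mean(abs(pred - obs) / obs)
}

#' Root mean square error of log-transformed values
#'
#' sqrt(mean((log10(pred + eps) - log10(obs + eps))^2)) with an additive
#' floor eps that keeps zero-containing targets finite. A value of 1 means
#' predictions are off by one decade on average.
#'
#' @param obs Observed values.
#' @param pred Predicted values.
#' @param floor Additive floor applied before the log (default 1e-3).
#'   Negative inputs (e.g. slight undershoot of a ratio regressor) are
#'   clamped to zero first, so the metric is total.
#' @return Dimensionless log-space error.
#' @export
rmsele <- function(obs, pred, floor = 1e-3) {
  stopifnot(length(obs) == length(pred))
  sqrt(mean((log10(pmax(pred, 0) + floor) - log10(pmax(obs, 0) + floor))^2))
}

#' Assemble a metrics report row
#'
#' Tidy one-row summary of a retrieval evaluation: the three statistics on
#' the untouched holdout plus the cross-validation fold means, tagged with
#' product, data type and configuration name.
#'
#' @param product `"chl_a"`, `"pc"` or `"car"`.
#' @param data_type `"RRS"`, `"TOAR"` or `"BRR"`.
#' @param config_name Label of the band configuration (e.g. `"Full"`).
#' @param obs,pred Observed and predicted values on the holdout, in physical
#'   units.
#' @param cv_fold_means Optional named list of per-fold metric means.
#' @param seed Seed used for the run.
#' @param mape_min_obs Observations at or below this value are excluded from
#'   MAPE (default 0.01, used for the ratio product).
#' @param obs_model,pred_model Optional observed/predicted values on the
#'   model's target scale (log10 for pigments); if supplied, R^2 is computed
#'   on that scale so decade-spanning concentrations do not reduce it to a
#'   bloom-only statistic. MAPE and RMSELE always use physical units.
#' @return An object of class `"metrics_report"` (also a data frame row via
#'   `as.data.frame`).
#' @export
metrics_report <- function(product, data_type, config_name, obs, pred,
                           cv_fold_means = NULL, seed = NA_integer_,
                           mape_min_obs = 0.01,
                           obs_model = NULL, pred_model = NULL) {
  ok <- obs > mape_min_obs
  r2 <- if (is.null(obs_model)) r_squared(obs, pred) else
    r_squared(obs_model, pred_model)
  structure(list(
    product = product, data_type = data_type, config_name = config_name,
    n_test = length(obs),
    r2 = r2,
    mape_percent = if (any(ok)) mape(obs[ok], pred[ok]) else NA_real_,
    rmsele = rmsele(obs, pred),
    cv_fold_means = cv_fold_means,
    seed = seed,
    holdout_only = TRUE
  ), class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf(
    "<metrics_report> %s / %s / %s (n=%d): R2=%.3f, MAPE=%.1f%%, RMSELE=%.3f\n",
    x$product, x$data_type, x$config_name, x$n_test, x$r2, x$mape_percent,
    x$rmsele
  ))
  invisible(x)
}

#' @export
as.data.frame.metrics_report <- function(x, ...) {
  data.frame(product = x$product, data_type = x$data_type,
             config = x$config_name, n_test = x$n_test, r2 = x$r2,
             mape_percent = x$mape_percent, rmsele = x$rmsele,
             seed = x$seed)
}

#' Append metrics report rows to a tidy CSV
#'
#' Long format: `product, data_type, config, metric, value`.
#'
#' @param reports A list of `metrics_report` objects.
#' @param path CSV path (created or appended to).
#' @return `path`, invisibly.
#' @export
write_metrics_csv <- function(reports, path) {
  rows <- do.call(rbind, lapply(reports, function(r) {
    data.frame(product = r$product, data_type = r$data_type,
               config = r$config_name,
               metric = c("r2", "mape_percent", "rmsele"),
               value = c(r$r2, r$mape_percent, r$rmsele))
  }))
  utils::write.table(rows, path, sep = ",", row.names = FALSE,
                     col.names = !file.exists(path), append = file.exists(path))
  invisible(path)
}
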