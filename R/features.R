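# Feature and target transforms for the retrieval models.

retrieval_products <- c("chl_a", "pc", "car")

#' Build model features and targets from a spectral dataset
#'
#' Resamples every spectrum through the band configuration, applies
#' log10(x + 1e-6) to the channel reflectances and standardizes each channel
#' (mean/scale fitted on the training rows only, then applied to all rows).
#' Pigment targets (chl_a, pc) are log10-transformed with a 1e-3 ug/L floor;
#' the cyanobacteria:algae ratio is left untransformed.
#'
#' @param dataset A `spectral_dataset` containing a single data type.
#' @param product `"chl_a"`, `"pc"` or `"car"`.
#' @param config A `band_config`.
#' @param train_idx Row indices the standardization is fitted on (default:
#'   all rows).
#' @param reflectance_floor Additive floor before the input log (default
#'   1e-6).
#' @return List with the standardized feature matrix `X`, the transformed
#'   target `y`, and the `transform` record needed to invert predictions.
#' @export
make_features <- function(dataset, product, config, train_idx = NULL,
                          reflectance_floor = 1e-6) {
  stopifnot(inherits(dataset, "spectral_dataset"))
  if (!product %in% retrieval_products) {
    stop(sprintf("unknown product '%s'; valid products: %s", product,
                 paste(retrieval_products, collapse = ", ")), call. = FALSE)
  }
  if (n_records(dataset) == 0) stop("empty dataset", call. = FALSE)
  if (length(unique(dataset$meta$data_type)) != 1) {
    stop("dataset must contain a single data type; use filter_records()",
         call. = FALSE)
  }
  if (is.null(train_idx)) train_idx <- seq_len(n_records(dataset))

  channels <- apply_srf(dataset$spectra, config)
  x_log <- log10(pmax(channels, 0) + reflectance_floor)
  means <- colMeans(x_log[train_idx, , drop = FALSE])
  scales <- apply(x_log[train_idx, , drop = FALSE], 2, stats::sd)
  scales[!is.finite(scales) | scales < 1e-12] <- 1  # constant channels
  X <- sweep(sweep(x_log, 2, means, "-"), 2, scales, "/")

  target_log <- product %in% c("chl_a", "pc")
  target_floor <- 1e-3
  y_raw <- dataset$meta[[product]]
  y <- if (target_log) log10(pmax(y_raw, target_floor)) else y_raw

  transform <- structure(list(
    input_log = TRUE,
    reflectance_floor = reflectance_floor,
    input_means = means,
    input_scales = scales,
    target_log = target_log,
    target_floor = target_floor,
    product = product,
    channel_centers = config$centers
  ), class = "transform_record")

  list(X = X, y = y, y_raw = y_raw, transform = transform)
}

#' Invert the target transform
#'
#' @param transform A `transform_record`.
#' @param z Values on the model (transformed) scale.
#' @return Values in physical units.
#' @export
inverse_target <- function(transform, z) {
  if (transform$target_log) 10^z else z
}

#' Apply the target transform
#'
#' @param transform A `transform_record`.
#' @param y Values in physical units.
#' @return Values on the model scale.
#' @export
forward_target <- function(transform, y) {
  if (transform$target_log) log10(pmax(y, transform$target_floor)) else y
}
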