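# Multilayer-perceptron retrieval models.

#' Training hyperparameters
#'
#' All values the optimizer needs in one record, so nothing is hard-coded in
#' the training routine: mini-batch size, Adam learning rate, the epoch cap,
#' and the inner validation split driving early stopping.
#'
#' @param batch_size Mini-batch size (default 256).
#' @param max_epochs Upper bound on training epochs (default 200).
#' @param early_stop_patience Epochs without inner-validation improvement
#'   before stopping (default 10).
#' @param learning_rate Adam step size (default 1e-3).
#' @param inner_val_fraction Fraction of the training rows held out for the
#'   early-stopping criterion (default 0.1).
#' @return A list of class `"train_config"`.
#' @export
train_config <- function(batch_size = 256L, max_epochs = 200L,
                         early_stop_patience = 10L, learning_rate = 1e-3,
                         inner_val_fraction = 0.1) {
  cfg <- list(batch_size = as.integer(batch_size),
              max_epochs = as.integer(max_epochs),
              early_stop_patience = as.integer(early_stop_patience),
              learning_rate = learning_rate,
              inner_val_fraction = inner_val_fraction)
  if (any(unlist(cfg) <= 0)) {
    stop("all training hyperparameters must be positive", call. = FALSE)
  }
  structure(cfg, class = "train_config")
}

#' Train a retrieval model
#'
#' Fits the fixed architecture -- five hidden layers of 100 rectified-linear
#' units and a single linear output -- with Adam on mean-absolute-error loss.
#' A seeded inner validation split drives early stopping; the weights with
#' the best inner-validation MAE are kept. Deterministic for a fixed seed
#' (and fixed BLAS thread count).
#'
#' @param X Standardized feature matrix (rows = records).
#' @param y Transformed target vector.
#' @param train_cfg A [train_config()].
#' @param seed Integer seed for weight initialization, batch shuffling and
#'   the inner split.
#' @param transform Optional `transform_record` attached to the model so
#'   predictions can be inverted to physical units.
#' @param hidden Hidden layer sizes (default `rep(100, 5)`).
#' @return An object of class `"retrieval_model"`.
#' @export
train_model <- function(X, y, train_cfg = train_config(), seed = 1L,
                        transform = NULL, hidden = rep(100L, 5L)) {
  X <- as.matrix(X)
  if (nrow(X) < 100) stop("need at least 100 training rows", call. = FALSE)
  if (any(!is.finite(X)) || any(!is.finite(y))) {
    stop("non-finite values in features or targets", call. = FALSE)
  }
  stopifnot(inherits(train_cfg, "train_config"), nrow(X) == length(y))

  n <- nrow(X)
  n_val <- max(1L, round(train_cfg$inner_val_fraction * n))
  val_idx <- with_seed(as.integer(seed),
                       sample.int(n, n_val))
  tr_idx <- setdiff(seq_len(n), val_idx)

  fit <- .mlp_train_cpp(X[tr_idx, , drop = FALSE], y[tr_idx],
                        X[val_idx, , drop = FALSE], y[val_idx],
                        hidden = as.integer(hidden),
                        batch_size = train_cfg$batch_size,
                        lr = train_cfg$learning_rate,
                        max_epochs = train_cfg$max_epochs,
                        patience = train_cfg$early_stop_patience,
                        seed = as.integer(seed))

  structure(list(
    weights = fit$weights,
    biases = fit$biases,
    hidden = as.integer(hidden),
    activation = "relu",
    transform = transform,
    product = if (is.null(transform)) NA_character_ else transform$product,
    train_seed = as.integer(seed),
    best_val_mae = fit$best_val_mae,
    epochs_run = fit$epochs_run,
    val_history = fit$val_history
  ), class = "retrieval_model")
}

#' @export
print.retrieval_model <- function(x, ...) {
  cat(sprintf(
    "<retrieval_model> %s: %d inputs -> [%s] -> 1, %d epochs, val MAE %.4g\n",
    ifelse(is.na(x$product), "generic", x$product),
    ncol(x$weights[[1]]), paste(x$hidden, collapse = ","),
    x$epochs_run, x$best_val_mae
  ))
  invisible(x)
}

# raw network output (model scale), no inverse target transform
predict_model_scale <- function(model, X) {
  X <- as.matrix(X)
  if (ncol(X) != ncol(model$weights[[1]])) {
    stop("feature count does not match the model", call. = FALSE)
  }
  as.numeric(.mlp_predict_cpp(model$weights, model$biases, X))
}

#' Predict in physical units
#'
#' Runs the network on already-transformed features and inverts the target
#' transform (10^z for log-transformed pigments), so pigment predictions are
#' strictly positive.
#'
#' @param object A `retrieval_model`.
#' @param X Standardized feature matrix (same transform as at training).
#' @param ... Unused.
#' @return Numeric vector of estimates in physical units.
#' @export
predict.retrieval_model <- function(object, X, ...) {
  z <- predict_model_scale(object, X)
  if (is.null(object$transform)) z else inverse_target(object$transform, z)
}

#' Save a retrieval model
#'
#' Weights go to an RDS file; a JSON sidecar carries the transform record,
#' product, seed and channel centers for auditability.
#'
#' @param model A `retrieval_model`.
#' @param path RDS path; sidecar written to `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_retrieval_model <- function(model, path) {
  saveRDS(model, path)
  meta <- list(product = model$product, train_seed = model$train_seed,
               hidden = model$hidden, epochs_run = model$epochs_run,
               best_val_mae = model$best_val_mae,
               channel_centers = model$transform$channel_centers,
               target_log = model$transform$target_log)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Load a retrieval model saved by [write_retrieval_model()]
#' @param path RDS path.
#' @return A `retrieval_model`.
#' @export
read_retrieval_model <- function(path) {
  model <- readRDS(path)
  stopifnot(inherits(model, "retrieval_model"))
  model
}
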