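# Permutation feature importance over spectral channels.

#' Permutation importance of each spectral channel
#'
#' Implements the standard permutation feature-importance procedure with
#' error measure L = 1 - R^2, so that larger scores mean more important:
#' the baseline error e_orig = L(y, f(X)) is computed once on the supplied
#' (test) partition; then each feature column is shuffled `n_repeats` times
#' with independent seeded permutations and the importance is
#' FI_j = mean(e_perm) - e_orig. A column with identical values in every row
#' has importance exactly zero (permutation is the identity on its values).
#'
#' @param model A `retrieval_model`, or any function `f(X) -> predictions`
#'   on the same scale as `y`.
#' @param X Feature matrix of the evaluation partition (rows disjoint from
#'   the model's training rows).
#' @param y Target vector on the model's output scale.
#' @param n_repeats Shuffles per column (default 5).
#' @param seed Integer seed for the permutations.
#' @param channel_centers Optional channel center wavelengths (nm) attached
#'   to the profile; defaults to the model's transform record when present.
#' @return An object of class `"attribution_profile"` with per-channel
#'   scores `fi`, the baseline `e_orig`, and a descending-sorted `ranking`.
#' @export
permutation_importance <- function(model, X, y, n_repeats = 5L, seed = 1L,
                                   channel_centers = NULL) {
  if (n_repeats < 1) stop("n_repeats must be >= 1", call. = FALSE)
  X <- as.matrix(X)
  stopifnot(nrow(X) == length(y))
  predict_fun <- if (inherits(model, "retrieval_model")) {
    if (ncol(X) != ncol(model$weights[[1]])) {
      stop("feature count does not match the model", call. = FALSE)
    }
    function(Xm) predict_model_scale(model, Xm)
  } else if (is.function(model)) {
    model
  } else {
    stop("model must be a retrieval_model or a prediction function",
         call. = FALSE)
  }
  if (is.null(channel_centers) && inherits(model, "retrieval_model") &&
      !is.null(model$transform)) {
    channel_centers <- model$transform$channel_centers
  }
  if (is.null(channel_centers)) channel_centers <- seq_len(ncol(X))

  loss <- function(obs, pred) 1 - r_squared(obs, pred)
  e_orig <- loss(y, predict_fun(X))
  p <- ncol(X)
  n <- nrow(X)

  fi <- with_seed(as.integer(seed), {
    vapply(seq_len(p), function(j) {
      col <- X[, j]
      if (max(col) == min(col)) return(0)  # constant feature: identity perm
      e_perm <- vapply(seq_len(n_repeats), function(r) {
        Xp <- X
        Xp[, j] <- col[sample.int(n)]
        loss(y, predict_fun(Xp))
      }, numeric(1))
      mean(e_perm) - e_orig
    }, numeric(1))
  })

  ord <- order(-fi, channel_centers)  # ties: lower wavelength first
  structure(list(
    channel_centers = as.numeric(channel_centers),
    fi = fi,
    metric = "one_minus_r2",
    n_repeats = as.integer(n_repeats),
    e_orig = e_orig,
    seed = as.integer(seed),
    ranking = data.frame(center_nm = channel_centers[ord], fi = fi[ord])
  ), class = "attribution_profile")
}

#' @export
print.attribution_profile <- function(x, ...) {
  top <- utils::head(x$ranking, 3)
  cat(sprintf(
    "<attribution_profile> %d channels, e_orig=%.4g; top: %s\n",
    length(x$fi), x$e_orig,
    paste(sprintf("%.0f nm (%.3g)", top$center_nm, top$fi), collapse = ", ")
  ))
  invisible(x)
}

#' Write an attribution profile to CSV with JSON metadata
#'
#' The CSV (`center_nm, fi`) is the input contract for the band-selection
#' step; the sidecar records metric, repeats, baseline error and seed.
#'
#' @param profile An `attribution_profile`.
#' @param path CSV path; sidecar written to `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_attribution_csv <- function(profile, path) {
  utils::write.csv(
    data.frame(center_nm = profile$channel_centers, fi = profile$fi),
    path, row.names = FALSE
  )
  meta <- list(metric = profile$metric, n_repeats = profile$n_repeats,
               e_orig = profile$e_orig, seed = profile$seed)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read an attribution profile written by [write_attribution_csv()]
#' @param path CSV path.
#' @return An `attribution_profile`.
#' @export
read_attribution_csv <- function(path) {
  df <- utils::read.csv(path)
  meta <- list(metric = NA_character_, n_repeats = NA_integer_,
               e_orig = NA_real_, seed = NA_integer_)
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    meta <- utils::modifyList(meta,
                              jsonlite::read_json(sidecar,
                                                  simplifyVector = TRUE))
  }
  ord <- order(-df$fi, df$center_nm)
  structure(list(
    channel_centers = df$center_nm, fi = df$fi, metric = meta$metric,
    n_repeats = meta$n_repeats, e_orig = meta$e_orig, seed = meta$seed,
    ranking = data.frame(center_nm = df$center_nm[ord], fi = df$fi[ord])
  ), class = "attribution_profile")
}
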