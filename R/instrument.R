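# Imager model: overlapping Gaussian spectral response functions, channel
# decimation and adjacent-channel binning.

#' Native channel centers of the CyanoSat-class imager
#'
#' 300 evenly spaced channel centers from 500 to 780 nm. The nominal 12 nm
#' FWHM response functions overlap heavily at the resulting ~0.94 nm spacing,
#' producing the characteristic spectral smoothing of the instrument.
#'
#' @return Numeric vector of 300 centers in nm.
#' @export
cyanosat_centers <- function() {
  seq(500, 780, length.out = 300)
}

#' Band configuration with discretized spectral response functions
#'
#' Builds the (channels x grid) spectral response matrix for Gaussian bands
#' of the given FWHM: row j is a bell curve with
#' sigma = FWHM / (2 * sqrt(2 * log(2))), truncated at +/- 3 sigma and
#' renormalized to unit sum on the grid, so a spectrally flat input is
#' preserved exactly.
#'
#' @param centers Strictly increasing channel centers in nm.
#' @param fwhm Full width at half maximum in nm (> 0).
#' @param grid Wavelength grid the responses are discretized on.
#' @return An object of class `"band_config"` with fields `centers`, `fwhm`,
#'   `grid` and the response matrix `srf`.
#' @export
srf_matrix <- function(centers, fwhm, grid = wavelength_grid()) {
  if (fwhm <= 0) stop("fwhm must be positive", call. = FALSE)
  grid <- as_wavelength_grid(grid)
  centers <- as.numeric(centers)
  if (any(diff(centers) <= 0)) {
    stop("centers must be strictly increasing", call. = FALSE)
  }
  wl <- as.numeric(grid)
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  # outer difference: rows = channels, cols = grid points
  d <- outer(centers, wl, `-`)
  srf <- exp(-d^2 / (2 * sigma^2))
  srf[abs(d) > 3 * sigma] <- 0
  rs <- rowSums(srf)
  if (any(rs <= 0)) {
    stop("grid does not cover some channel responses", call. = FALSE)
  }
  srf <- srf / rs
  structure(list(centers = centers, fwhm = fwhm, grid = grid, srf = srf),
            class = "band_config")
}

#' @export
print.band_config <- function(x, ...) {
  cat(sprintf("<band_config> %d channels, %.4g-%.4g nm, FWHM %.3g nm\n",
              length(x$centers), min(x$centers), max(x$centers), x$fwhm))
  invisible(x)
}

#' Resample spectra through a band configuration
#'
#' Matrix product of the spectral response matrix with the spectrum
#' (or with each row of a spectra matrix); exactly linear in the input.
#'
#' @param spectrum Numeric vector on the config's grid, or a matrix with one
#'   spectrum per row.
#' @param config A `band_config`.
#' @return Channel values: a vector, or a matrix (records x channels).
#' @export
apply_srf <- function(spectrum, config) {
  stopifnot(inherits(config, "band_config"))
  if (is.matrix(spectrum)) {
    if (ncol(spectrum) != length(config$grid)) {
      stop("spectrum length does not match the configuration grid",
           call. = FALSE)
    }
    out <- spectrum %*% t(config$srf)
    colnames(out) <- sprintf("ch_%0.1f", config$centers)
    return(out)
  }
  if (length(spectrum) != length(config$grid)) {
    stop("spectrum length does not match the configuration grid",
         call. = FALSE)
  }
  drop(config$srf %*% spectrum)
}

#' Keep every `step`-th channel of a band configuration
#'
#' Decimation used to trade the heavily oversampled native channels for
#' faster analysis: with 300 native channels and step 3 it yields the
#' 100-band working configuration at ~3 nm effective spacing.
#'
#' @param config A `band_config`.
#' @param step Positive integer stride (1 keeps all channels).
#' @return A `band_config` with channels at indices 1, 1+step, 1+2*step, ...
#' @export
decimate <- function(config, step = 3L) {
  stopifnot(inherits(config, "band_config"))
  if (step < 1) stop("step must be >= 1", call. = FALSE)
  keep <- seq(1L, length(config$centers), by = as.integer(step))
  structure(list(centers = config$centers[keep], fwhm = config$fwhm,
                 grid = config$grid,
                 srf = config$srf[keep, , drop = FALSE]),
            class = "band_config")
}

#' Bin adjacent channel values
#'
#' Replaces non-overlapping groups of `group` consecutive channels by their
#' arithmetic mean (the on-board SNR-enhancement binning). A trailing
#' remainder that does not fill a group is dropped with a warning.
#'
#' @param values Channel values (vector, or matrix with channels in columns).
#' @param group Positive integer group size.
#' @return Binned values.
#' @export
bin_adjacent <- function(values, group) {
  if (group < 1) stop("group must be >= 1", call. = FALSE)
  group <- as.integer(group)
  if (group == 1L) return(values)
  vec <- !is.matrix(values)
  m <- if (vec) matrix(values, nrow = 1) else values
  k <- ncol(m)
  n_groups <- k %/% group
  if (k %% group != 0L) {
    warning(sprintf("dropping %d trailing channel(s) not filling a group",
                    k %% group))
  }
  idx <- seq_len(n_groups * group)
  grp <- rep(seq_len(n_groups), each = group)
  out <- t(apply(m[, idx, drop = FALSE], 1,
                 function(r) tapply(r, grp, mean)))
  out <- matrix(out, nrow = nrow(m), ncol = n_groups)
  if (vec) drop(out) else out
}

#' Write a band configuration to CSV
#'
#' Stores one row per channel (`center_nm`, `fwhm_nm`); the response matrix
#' is regenerated on load, not stored.
#'
#' @param config A `band_config`.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_band_config <- function(config, path) {
  utils::write.csv(
    data.frame(center_nm = config$centers, fwhm_nm = config$fwhm),
    path, row.names = FALSE
  )
  invisible(path)
}

#' Read a band configuration from CSV
#'
#' @param path CSV written by [write_band_config()].
#' @param grid Wavelength grid to discretize the responses on.
#' @return A `band_config`.
#' @export
read_band_config <- function(path, grid = wavelength_grid()) {
  df <- utils::read.csv(path)
  srf_matrix(df$center_nm, fwhm = df$fwhm_nm[1], grid = grid)
}
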