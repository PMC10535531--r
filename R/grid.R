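#' Wavelength grid for spectral simulation
#'
#' Constructs and validates the wavelength grid that all simulated spectra,
#' inherent optical properties and spectral response functions share. The
#' default is the native simulation grid: 400 to 800 nm at 1 nm spacing
#' (401 points), covering the visible and the near-infrared red edge.
#'
#' @param wavelengths Numeric vector of wavelengths in nm. Must be strictly
#'   increasing and lie within 400--900 nm.
#' @return A numeric vector of class `"wavelength_grid"`.
#' @examples
#' grid <- wavelength_grid()
#' length(grid)  # 401
#' @export
wavelength_grid <- function(wavelengths = 400:800) {
  wavelengths <- as.numeric(wavelengths)
  if (length(wavelengths) < 2L) {
    stop("a wavelength grid needs at least two points", call. = FALSE)
  }
  if (any(!is.finite(wavelengths))) {
    stop("wavelengths must be finite", call. = FALSE)
  }
  if (any(diff(wavelengths) <= 0)) {
    stop("wavelengths must be strictly increasing", call. = FALSE)
  }
  if (min(wavelengths) < 400 || max(wavelengths) > 900) {
    stop("wavelengths must lie within [400, 900] nm", call. = FALSE)
  }
  structure(wavelengths, class = "wavelength_grid")
}

#' @export
print.wavelength_grid <- function(x, ...) {
  cat(sprintf(
    "<wavelength_grid> %d points, %.1f-%.1f nm\n",
    length(x), min(x), max(x)
  ))
  invisible(x)
}

as_wavelength_grid <- function(x) {
  if (inherits(x, "wavelength_grid")) x else wavelength_grid(x)
}

# Grid must span the full visible-NIR simulation window for IOP construction.
check_grid_covers <- function(grid, lo = 400, hi = 800) {
  if (min(grid) > lo || max(grid) < hi) {
    stop(sprintf("grid must cover %d-%d nm", lo, hi), call. = FALSE)
  }
  invisible(grid)
}
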