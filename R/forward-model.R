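# Water-leaving reflectance forward model.

#' Canonical vegetation red-edge reflectance
#'
#' Logistic red-edge shape used both for the adjacency (stray light from
#' vegetated shores) and for surface-scum blending:
#' rho_veg(lambda) = 0.05 + 0.45 / (1 + exp(-(lambda - 715)/10)).
#'
#' @param grid Wavelength grid (nm).
#' @return Dimensionless reflectance on the grid.
#' @export
vegetation_spectrum <- function(grid) {
  wl <- as.numeric(as_wavelength_grid(grid))
  0.05 + 0.45 / (1 + exp(-(wl - 715) / 10))
}

#' Sun-induced chlorophyll fluorescence emission
#'
#' Additive remote-sensing reflectance contribution of chlorophyll-a
#' fluorescence: two Gaussian emission bands at 685 nm (FWHM 25 nm) and
#' 730 nm (FWHM 50 nm) with a fixed secondary:primary amplitude ratio of 0.2.
#' The amplitude is proportional to chl_a * fluor_yield * (1 - 0.7 * car):
#' cyanobacteria hold most chlorophyll-a in weakly fluorescing photosystem I,
#' so a high cyanobacterial fraction suppresses the emission.
#'
#' @param state A `water_state`.
#' @param iops Matching `iop_set` (reserved for reabsorption refinements).
#' @param grid Wavelength grid (nm).
#' @param const Optical constants, see [optical_constants()].
#' @return Additive Rrs spectrum in 1/sr on the grid.
#' @export
fluorescence_term <- function(state, iops, grid = wavelength_grid(),
                              const = optical_constants()) {
  wl <- as.numeric(as_wavelength_grid(grid))
  amp <- const$fluor_scale * state$chl_a * state$fluor_yield *
    (1 - const$fluor_car_reduction * state$car)
  s1 <- const$fluor_fwhm1 / 2.354820045
  s2 <- const$fluor_fwhm2 / 2.354820045
  amp * (gauss_band(wl, const$fluor_center1, s1) +
           const$fluor_ratio * gauss_band(wl, const$fluor_center2, s2))
}

#' Remote-sensing reflectance of one simulated water
#'
#' Gordon-style elastic reflectance: u = bb/(a+bb), sub-surface
#' rrs = g0*u + g1*u^2, transferred above the surface as
#' Rrs = 0.52*rrs / (1 - 1.7*rrs), plus the fluorescence emission term.
#' For surface scums the water-column closure breaks down; the spectrum is
#' blended with the vegetation-like red-edge shape weighted by the state's
#' scum fraction.
#'
#' @param iops An `iop_set` built from `state` on `grid`.
#' @param state The `water_state`.
#' @param grid Wavelength grid (nm).
#' @param const Optical constants, see [optical_constants()].
#' @return A `spectrum_record` with `data_type = "RRS"` (values in 1/sr).
#' @export
rrs_forward <- function(iops, state, grid = wavelength_grid(),
                        const = optical_constants()) {
  stopifnot(inherits(iops, "iop_set"))
  a <- total_absorption(iops)
  bb <- iops$bb_w + iops$bb_p
  if (any(a < 0) || any(bb < 0)) {
    stop("IOPs must be non-negative", call. = FALSE)
  }
  u <- bb / (a + bb)
  rrs_sub <- const$g0 * u + const$g1 * u^2
  rrs <- 0.52 * rrs_sub / (1 - 1.7 * rrs_sub)
  rrs <- rrs + fluorescence_term(state, iops, grid, const)
  if (state$scum_fraction > 0) {
    veg <- vegetation_spectrum(grid) / pi  # reflectance -> Rrs units
    rrs <- (1 - state$scum_fraction) * rrs + state$scum_fraction * veg
  }
  spectrum_record("RRS", rrs, state, atmosphere = NULL, grid = grid)
}

#' One labeled spectrum
#'
#' Lightweight container pairing reflectance values with their water-state
#' labels and (for top-of-atmosphere types) the atmosphere state.
#'
#' @param data_type `"RRS"`, `"TOAR"` or `"BRR"`.
#' @param values Per-wavelength reflectance (1/sr for RRS, dimensionless
#'   otherwise).
#' @param state The `water_state` labels.
#' @param atmosphere An `atmosphere_state`, or `NULL` for RRS.
#' @param grid The wavelength grid.
#' @return An object of class `"spectrum_record"`.
#' @export
spectrum_record <- function(data_type, values, state, atmosphere, grid) {
  data_type <- match.arg(data_type, c("RRS", "TOAR", "BRR"))
  if (any(!is.finite(values))) {
    stop("spectrum values must be finite", call. = FALSE)
  }
  if (data_type == "RRS" && any(values < -1e-12)) {
    stop("Rrs values must be non-negative", call. = FALSE)
  }
  structure(list(
    data_type = data_type,
    values = as.numeric(values),
    labels = state,
    atmosphere = atmosphere,
    grid = as_wavelength_grid(grid)
  ), class = "spectrum_record")
}

#' @export
print.spectrum_record <- function(x, ...) {
  cat(sprintf("<spectrum_record> %s, %d wavelengths, max=%.4g\n",
              x$data_type, length(x$values), max(x$values)))
  invisible(x)
}
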