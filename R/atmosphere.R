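# Analytic single-scattering atmosphere: Rayleigh + aerosol path reflectance,
# vegetation adjacency, and the Rayleigh-only (bottom-of-Rayleigh) inversion.

#' Sample an atmosphere state
#'
#' Draws aerosol optical depth, Angstrom exponent, solar zenith and the
#' vegetation adjacency weight from the configured priors; view zenith is
#' nadir by default.
#'
#' @param config A [generator_config()] (its `atmosphere` priors are used).
#' @return An object of class `"atmosphere_state"`.
#' @export
sample_atmosphere <- function(config = generator_config()) {
  pr <- config$atmosphere
  structure(list(
    tau_a_550 = stats::runif(1, pr$tau_a_550[1], pr$tau_a_550[2]),
    angstrom = stats::runif(1, pr$angstrom[1], pr$angstrom[2]),
    theta_s = stats::runif(1, pr$theta_s[1], pr$theta_s[2]),
    theta_v = stats::runif(1, pr$theta_v[1], pr$theta_v[2]),
    adjacency_weight = stats::runif(1, pr$adjacency_weight[1],
                                    pr$adjacency_weight[2])
  ), class = "atmosphere_state")
}

#' Rayleigh optical thickness
#'
#' Standard closed form, wavelength in nm (converted to um internally):
#' tau_r = 0.008569 * lam^-4 * (1 + 0.0113 * lam^-2 + 0.00013 * lam^-4).
#'
#' @param wl_nm Wavelengths in nm.
#' @return Rayleigh optical thickness (dimensionless).
#' @export
rayleigh_optical_thickness <- function(wl_nm) {
  lam <- wl_nm / 1000
  0.008569 * lam^-4 * (1 + 0.0113 * lam^-2 + 0.00013 * lam^-4)
}

deg2rad <- function(x) x * pi / 180

# scattering angle for a sun-sensor geometry in the principal plane
scattering_cosine <- function(theta_s, theta_v) {
  -cos(deg2rad(theta_s)) * cos(deg2rad(theta_v)) -
    sin(deg2rad(theta_s)) * sin(deg2rad(theta_v))
}

rayleigh_phase <- function(cos_theta) 0.75 * (1 + cos_theta^2)

henyey_greenstein <- function(cos_theta, g = 0.7) {
  (1 - g^2) / (1 + g^2 - 2 * g * cos_theta)^1.5
}

# Rayleigh path reflectance and two-way Rayleigh transmittance on a grid
rayleigh_terms <- function(atm, grid) {
  wl <- as.numeric(as_wavelength_grid(grid))
  tau_r <- rayleigh_optical_thickness(wl)
  mu_s <- cos(deg2rad(atm$theta_s))
  mu_v <- cos(deg2rad(atm$theta_v))
  cth <- scattering_cosine(atm$theta_s, atm$theta_v)
  list(
    rho_r = tau_r * rayleigh_phase(cth) / (4 * mu_s * mu_v),
    t_r = exp(-0.5 * tau_r * (1 / mu_s + 1 / mu_v))
  )
}

aerosol_terms <- function(atm, grid, ssa = 0.95, g = 0.7) {
  wl <- as.numeric(as_wavelength_grid(grid))
  tau_a <- atm$tau_a_550 * (wl / 550)^(-atm$angstrom)
  mu_s <- cos(deg2rad(atm$theta_s))
  mu_v <- cos(deg2rad(atm$theta_v))
  cth <- scattering_cosine(atm$theta_s, atm$theta_v)
  list(
    rho_a = ssa * tau_a * henyey_greenstein(cth, g) / (4 * mu_s * mu_v),
    # forward-peaked aerosol scattering attenuates the diffuse beam weakly
    t_a = exp(-0.25 * tau_a * (1 / mu_s + 1 / mu_v))
  )
}

#' Propagate water-leaving reflectance to top of atmosphere
#'
#' Analytic single-scattering propagation:
#' rho_t = rho_r + rho_a + t * pi * Rrs + t * w_adj * rho_veg, where rho_r is
#' the Rayleigh path reflectance, rho_a the aerosol path reflectance
#' (Angstrom-law optical depth, Henyey-Greenstein phase with g = 0.7, single
#' scattering albedo 0.95), t the combined two-way diffuse transmittance and
#' the last term stray light from adjacent vegetated land.
#'
#' @param rrs A `spectrum_record` with `data_type = "RRS"`.
#' @param atm An `atmosphere_state`.
#' @param grid Wavelength grid (must match the record's grid).
#' @return A `spectrum_record` with `data_type = "TOAR"` (dimensionless).
#' @export
toa_forward <- function(rrs, atm, grid = rrs$grid) {
  stopifnot(inherits(rrs, "spectrum_record"), rrs$data_type == "RRS",
            inherits(atm, "atmosphere_state"))
  ray <- rayleigh_terms(atm, grid)
  aer <- aerosol_terms(atm, grid)
  t_total <- ray$t_r * aer$t_a
  veg <- vegetation_spectrum(grid)
  toar <- ray$rho_r + aer$rho_a + t_total * pi * rrs$values +
    t_total * atm$adjacency_weight * veg
  spectrum_record("TOAR", toar, rrs$labels, atmosphere = atm, grid = grid)
}

#' Bottom-of-Rayleigh reflectance from top-of-atmosphere reflectance
#'
#' Partial atmospheric correction that removes molecular scattering only:
#' BRR = (TOAR - rho_r) / t_r, with t_r the two-way Rayleigh transmittance.
#' Aerosol path reflectance and adjacency stray light are deliberately left
#' in, as in operational Rayleigh-corrected products.
#'
#' @param toar A `spectrum_record` with `data_type = "TOAR"`.
#' @param atm The same `atmosphere_state` used in the forward propagation.
#' @param grid Wavelength grid (must match the record's grid).
#' @return A `spectrum_record` with `data_type = "BRR"` (dimensionless).
#' @export
brr_from_toar <- function(toar, atm, grid = toar$grid) {
  stopifnot(inherits(toar, "spectrum_record"), toar$data_type == "TOAR",
            inherits(atm, "atmosphere_state"))
  ray <- rayleigh_terms(atm, grid)
  if (any(ray$t_r <= 0)) {
    stop("Rayleigh transmittance must be positive", call. = FALSE)
  }
  brr <- (toar$values - ray$rho_r) / ray$t_r
  spectrum_record("BRR", brr, toar$labels, atmosphere = atm, grid = grid)
}
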