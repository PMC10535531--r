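# Pure-water and pigment optical constants, and assembly of inherent optical
# properties (IOPs) for one simulated water.

# Pure-water absorption (m^-1) at 5 nm, 400-800 nm, literature-style values
# (visible from Pope & Fry-type measurements, NIR from Kou-type). The strong
# NIR rise (a_w > 2.5 m^-1 by 750 nm) drives the red-edge reflectance features
# that the band-selection analysis keys on.
.aw_table <- local({
  wl <- seq(400, 800, by = 5)
  aw <- c(
    # 400-495
    0.00663, 0.00530, 0.00473, 0.00444, 0.00454, 0.00478, 0.00495, 0.00530,
    0.00635, 0.00751, 0.00922, 0.00962, 0.00979, 0.01011, 0.01060, 0.01140,
    0.01270, 0.01360, 0.01500, 0.01730,
    # 500-595
    0.02040, 0.02560, 0.03250, 0.03960, 0.04090, 0.04170, 0.04340, 0.04520,
    0.04740, 0.05110, 0.05650, 0.05960, 0.06190, 0.06420, 0.06950, 0.07720,
    0.08960, 0.11000, 0.13510, 0.16720,
    # 600-695
    0.22240, 0.25770, 0.26440, 0.26780, 0.27550, 0.28340, 0.29160, 0.30120,
    0.31080, 0.32500, 0.34000, 0.37100, 0.41000, 0.42900, 0.43900, 0.44800,
    0.46500, 0.48600, 0.51600, 0.55900,
    # 700-795
    0.62400, 0.70400, 0.82700, 1.00700, 1.23100, 1.48900, 1.79900, 2.08000,
    2.38000, 2.47000, 2.55000, 2.78000, 2.85000, 2.92000, 2.95000, 2.85000,
    2.70000, 2.55000, 2.40000, 2.25000,
    # 800
    2.15000
  )
  stopifnot(length(aw) == length(wl))
  list(wl = wl, aw = aw)
})

.aw_cache <- new.env(parent = emptyenv())

#' Pure-water absorption spectrum
#'
#' Linear interpolation of a bundled 5 nm literature-style lookup table
#' (cached per grid, since the generator evaluates it for every water).
#'
#' @param grid Wavelength grid (nm).
#' @return Absorption coefficient a_w in 1/m on the grid.
#' @export
pure_water_absorption <- function(grid) {
  grid <- as_wavelength_grid(grid)
  key <- paste0(length(grid), ":", min(grid), ":", max(grid))
  cached <- .aw_cache[[key]]
  if (!is.null(cached)) return(cached)
  out <- stats::approx(.aw_table$wl, .aw_table$aw, xout = as.numeric(grid),
                       rule = 2)$y
  .aw_cache[[key]] <- out
  out
}

#' Pure-water backscattering spectrum
#'
#' Half of the molecular scattering coefficient of pure water, with the
#' standard steep power-law wavelength dependence.
#'
#' @param grid Wavelength grid (nm).
#' @return Backscattering coefficient bb_w in 1/m on the grid.
#' @export
pure_water_backscattering <- function(grid) {
  grid <- as_wavelength_grid(grid)
  0.5 * 0.00288 * (500 / as.numeric(grid))^4.32
}

# Unit-peak Gaussian absorption band.
gauss_band <- function(wl, center, sigma) {
  exp(-((wl - center)^2) / (2 * sigma^2))
}

#' Optical constants of the bio-optical forward model
#'
#' Central registry of the tunable constants of the emulator: pigment band
#' amplitudes and widths for the algal and cyanobacterial chlorophyll-specific
#' absorption bases, the phycocyanin decomposition constants, NAP and
#' fluorescence scale factors. Exposed so that every constant the phycocyanin
#' label and the forward model depend on can be overridden in one place.
#'
#' @param ... Named overrides of the default constants.
#' @return A named list of constants.
#' @export
optical_constants <- function(...) {
  defaults <- list(
    # Algal basis: chlorophyll-a Soret + red bands, carotenoid shoulder
    # (fucoxanthin/peridinin-type accessory pigments near 490 nm), and the
    # chl-b/c 620 nm shoulder. The 620 amplitude is set so that
    # a*(620) = 0.24 * a*(665) for the pure algal basis, i.e. the standard
    # chlorophyll correction removes the non-phycocyanin contribution
    # almost exactly.
    alg_bands = data.frame(
      center = c(440, 490, 620, 675),
      sigma  = c(20, 18, 20, 13),
      amp    = c(0.0260, 0.0140, 0.0029, 0.0160)  # m^2/mg
    ),
    # Cyanobacterial basis: chl-a bands plus phycocyanin 620 nm band (whose
    # amplitude is set per-water from the PC:Chl ratio), a weak 650 nm
    # phycocyanobilin shoulder, and the same chl 620 nm shoulder. Carotenoid
    # shoulder absent relative to algae, which shifts the green reflectance
    # peak.
    cy_bands = data.frame(
      center = c(440, 620, 650, 675),
      sigma  = c(18, 20, 10, 11),
      amp    = c(0.0200, 0.0029, 0.0040, 0.0160)
    ),
    pc_band_center = 620,
    pc_band_sigma  = 12,
    # PC decomposition: a_pc(620) = a_ph(620) - eps_chl * a_ph(665);
    # a*_pc(620) = pc_astar_base * (0.5 + 0.5 * CAR).
    eps_chl       = 0.24,
    pc_astar_base = 0.0095,       # m^2/mg
    # NAP absorption: a_nap(440) per g/m^3 and exponential slope.
    nap_astar_440 = 0.030,        # m^2/g
    nap_slope     = 0.011,        # 1/nm
    # Particulate backscattering at 550 nm from Chl and NAP.
    bbp_chl_coef  = 0.0040,       # (m^-1) per (ug/L)^0.63
    bbp_chl_exp   = 0.63,
    bbp_nap_coef  = 0.0050,       # m^2/g
    # Gordon-style reflectance model coefficients.
    g0 = 0.0949, g1 = 0.0794,
    # Fluorescence emission: primary 685 nm / secondary 730 nm pair.
    fluor_center1 = 685, fluor_fwhm1 = 25,
    fluor_center2 = 730, fluor_fwhm2 = 50,
    fluor_ratio   = 0.2,
    fluor_scale   = 5e-4,         # sr^-1 per (ug/L * unit yield)
    fluor_car_reduction = 0.7
  )
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(defaults))
  if (length(unknown)) {
    stop("unknown optical constant(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  utils::modifyList(defaults, overrides)
}

sum_bands <- function(wl, bands) {
  out <- numeric(length(wl))
  for (i in seq_len(nrow(bands))) {
    out <- out + bands$amp[i] * gauss_band(wl, bands$center[i], bands$sigma[i])
  }
  out
}

#' Chlorophyll-specific absorption basis spectra
#'
#' The algal basis mixes chlorophyll-a with carotenoid accessory pigments;
#' the cyanobacterial basis replaces the carotenoid shoulder with the
#' phycocyanin 620 nm band (amplitude proportional to the water's PC:Chl
#' ratio) and a weak 650 nm shoulder.
#'
#' @param grid Wavelength grid (nm).
#' @param pc_to_chl PC:Chl ratio scaling the 620 nm band of the
#'   cyanobacterial basis.
#' @param const Optical constants, see [optical_constants()].
#' @return A list with numeric vectors `alg` and `cy` (m^2/mg on the grid).
#' @export
pigment_bases <- function(grid, pc_to_chl = 1, const = optical_constants()) {
  wl <- as.numeric(as_wavelength_grid(grid))
  alg <- sum_bands(wl, const$alg_bands)
  cy <- sum_bands(wl, const$cy_bands) +
    const$pc_astar_base * pc_to_chl *
      gauss_band(wl, const$pc_band_center, const$pc_band_sigma)
  list(alg = alg, cy = cy)
}

#' Build the inherent optical properties of one simulated water
#'
#' Scales the chlorophyll-specific pigment bases by the cyanobacteria:algae
#' ratio (CAR), adds CDOM and non-algal-particle (NAP) exponentials and the
#' particulate backscattering power law, and records the phycocyanin
#' decomposition terms used by [phycocyanin_label()].
#'
#' The phytoplankton absorption mixes the two bases linearly:
#' a_ph(lambda) = chl * ((1 - car) * a*_alg(lambda) + car * a*_cy(lambda)).
#' Cyanobacteria-enhanced near-infrared backscattering multiplies the
#' particulate backscattering by (1 + car) beyond the red edge.
#'
#' @param state A `water_state`, see [sample_water_state()].
#' @param grid Wavelength grid covering 400--800 nm.
#' @param const Optical constants, see [optical_constants()].
#' @return An object of class `"iop_set"`: list of absorption and
#'   backscattering spectra (1/m) plus the PC decomposition terms.
#' @export
build_iops <- function(state, grid = wavelength_grid(),
                       const = optical_constants()) {
  grid <- as_wavelength_grid(grid)
  check_grid_covers(grid)
  stopifnot(inherits(state, "water_state"))
  wl <- as.numeric(grid)

  bases <- pigment_bases(grid, pc_to_chl = state$pc_to_chl, const = const)
  a_ph <- state$chl_a * ((1 - state$car) * bases$alg + state$car * bases$cy)
  a_cdom <- state$cdom_440 * exp(-state$cdom_slope * (wl - 440))
  a_nap <- state$nap * const$nap_astar_440 * exp(-const$nap_slope * (wl - 440))
  a_w <- pure_water_absorption(grid)

  bbp_550 <- const$bbp_chl_coef * state$chl_a^const$bbp_chl_exp +
    const$bbp_nap_coef * state$nap
  # smooth NIR enhancement: cyanobacterial gas vacuoles scatter strongly
  nir_weight <- 1 / (1 + exp(-(wl - 700) / 15))
  bb_p <- bbp_550 * (550 / wl)^state$bbp_exponent *
    (1 + state$car * nir_weight)
  bb_w <- pure_water_backscattering(grid)

  i620 <- which.min(abs(wl - 620))
  i665 <- which.min(abs(wl - 665))
  a_star_pc_620 <- const$pc_astar_base * (0.5 + 0.5 * state$car)
  a_pc_620 <- max(0, a_ph[i620] - const$eps_chl * a_ph[i665])

  structure(list(
    grid = grid,
    a_w = a_w, a_ph = a_ph, a_cdom = a_cdom, a_nap = a_nap,
    bb_w = bb_w, bb_p = bb_p,
    a_pc_620 = a_pc_620, a_star_pc_620 = a_star_pc_620
  ), class = "iop_set")
}

#' Total absorption of an IOP set
#' @param iops An `iop_set`.
#' @return Total absorption a_w + a_ph + a_cdom + a_nap (1/m).
#' @export
total_absorption <- function(iops) {
  stopifnot(inherits(iops, "iop_set"))
  iops$a_w + iops$a_ph + iops$a_cdom + iops$a_nap
}

#' Phycocyanin concentration label from phytoplankton absorption
#'
#' Decomposes the phytoplankton absorption at 620 nm into a phycocyanin part
#' by subtracting the chlorophyll contribution estimated from the 665 nm
#' absorption, then divides by the PC-specific absorption coefficient:
#' PC = (a_ph(620) - eps * a_ph(665)) / a*_pc(620), clamped at zero. The
#' specific absorption a*_pc(620) increases linearly with CAR, reflecting
#' higher phycocyanin packaging in cyanobacteria-dominated populations.
#'
#' @param state The `water_state` the IOPs were built from.
#' @param iops The matching `iop_set`.
#' @return Phycocyanin concentration in ug/L.
#' @export
phycocyanin_label <- function(state, iops) {
  stopifnot(inherits(iops, "iop_set"))
  if (iops$a_star_pc_620 <= 0) {
    stop("PC-specific absorption must be positive", call. = FALSE)
  }
  if (state$car == 0) {
    return(0)
  }
  iops$a_pc_620 / iops$a_star_pc_620
}
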