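# Water-type priors and sampling of biogeophysical water states.

#' Names of the seven optical water types
#' @return Character vector of the water-type names.
#' @export
water_types <- function() {
  c("oligotrophic", "mixed_eutrophic", "sediment_dominated",
    "cdom_dominated", "eukaryote_bloom", "cyano_bloom", "scum")
}

# run code with a private, restored RNG stream
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(code)
}

runif_log <- function(n, lo, hi) exp(stats::runif(n, log(lo), log(hi)))

#' Synthetic-dataset generator configuration
#'
#' Defaults define the study conditions: a uniform mixture over seven optical
#' water types spanning oligotrophic lakes to hypereutrophic scums, with
#' per-type concentration ranges (log-uniform unless noted) and atmosphere
#' priors for the top-of-atmosphere propagation.
#'
#' @param mixture Named numeric vector of water-type weights (must sum to 1).
#' @param ranges Named list of per-type parameter ranges; see defaults.
#' @param atmosphere List of atmosphere prior ranges.
#' @param const Optical constants, see [optical_constants()].
#' @return A list of class `"generator_config"`.
#' @export
generator_config <- function(mixture = NULL, ranges = NULL,
                             atmosphere = NULL,
                             const = optical_constants()) {
  types <- water_types()
  if (is.null(mixture)) {
    mixture <- stats::setNames(rep(1 / length(types), length(types)), types)
  }
  if (!setequal(names(mixture), types)) {
    stop("mixture must name exactly the seven water types", call. = FALSE)
  }
  mixture <- mixture[types]
  if (abs(sum(mixture) - 1) > 1e-9) {
    stop("mixture weights must sum to 1 (within 1e-9)", call. = FALSE)
  }
  defaults <- list(
    oligotrophic = list(chl = c(0.1, 3), cdom = c(0.01, 0.5),
                        nap = c(0.05, 2), car = c(0, 1)),
    mixed_eutrophic = list(chl = c(3, 30), cdom = c(0.1, 2),
                           nap = c(0.5, 10), car = c(0, 1)),
    sediment_dominated = list(chl = c(1, 20), cdom = c(0.1, 2),
                              nap = c(20, 200), car = c(0, 1)),
    cdom_dominated = list(chl = c(0.5, 10), cdom = c(1, 10),
                          nap = c(0.1, 5), car = c(0, 1)),
    eukaryote_bloom = list(chl = c(30, 1000), cdom = c(0.1, 3),
                           nap = c(0.5, 10), car = c(0, 0.3)),
    cyano_bloom = list(chl = c(30, 1000), cdom = c(0.1, 3),
                       nap = c(0.5, 10), car = c(0.7, 1)),
    scum = list(chl = c(1000, 10000), cdom = c(0.1, 3),
                nap = c(0.5, 10), car = c(0, 1),
                scum_fraction = c(0.3, 1))
  )
  if (!is.null(ranges)) {
    defaults <- utils::modifyList(defaults, ranges)
  }
  atm_defaults <- list(
    tau_a_550 = c(0.02, 0.30), angstrom = c(0.5, 2.0),
    theta_s = c(20, 60), theta_v = c(0, 0), adjacency_weight = c(0, 0.3)
  )
  if (!is.null(atmosphere)) {
    atm_defaults <- utils::modifyList(atm_defaults, atmosphere)
  }
  structure(list(
    mixture = mixture,
    ranges = defaults,
    # shared priors across types
    shared = list(
      pc_to_chl = c(0.1, 2),       # log-uniform
      fluor_yield = c(0, 0.02),    # uniform
      cdom_slope = c(0.010, 0.020),
      bbp_exponent = c(0.3, 1.5)
    ),
    atmosphere = atm_defaults,
    const = const
  ), class = "generator_config")
}

# draw one state from the current RNG stream
draw_water_state <- function(water_type, config, grid = wavelength_grid()) {
  types <- water_types()
  if (identical(water_type, "random")) {
    water_type <- sample(types, 1, prob = config$mixture)
  }
  if (!water_type %in% types) {
    stop(sprintf("unknown water type '%s'; valid types: %s", water_type,
                 paste(types, collapse = ", ")), call. = FALSE)
  }
  rng <- config$ranges[[water_type]]
  sh <- config$shared
  state <- structure(list(
    water_type = water_type,
    chl_a = runif_log(1, rng$chl[1], rng$chl[2]),
    car = stats::runif(1, rng$car[1], rng$car[2]),
    pc_to_chl = runif_log(1, sh$pc_to_chl[1], sh$pc_to_chl[2]),
    cdom_440 = runif_log(1, rng$cdom[1], rng$cdom[2]),
    nap = runif_log(1, rng$nap[1], rng$nap[2]),
    fluor_yield = stats::runif(1, sh$fluor_yield[1], sh$fluor_yield[2]),
    cdom_slope = stats::runif(1, sh$cdom_slope[1], sh$cdom_slope[2]),
    bbp_exponent = stats::runif(1, sh$bbp_exponent[1], sh$bbp_exponent[2]),
    scum_fraction = if (is.null(rng$scum_fraction)) 0 else
      stats::runif(1, rng$scum_fraction[1], rng$scum_fraction[2]),
    pc = NA_real_
  ), class = "water_state")
  # PC is defined by the state's own IOPs (620 nm decomposition), so the
  # label round-trips by construction.
  state$pc <- phycocyanin_label(state, build_iops(state, grid,
                                                  const = config$const))
  state
}

#' Sample one water state
#'
#' Draws the biogeophysical parameters of one simulated water from the
#' per-type priors. The phycocyanin concentration is not sampled directly:
#' it is computed from the state's own phytoplankton absorption via
#' [phycocyanin_label()], so label and optics are consistent by construction.
#'
#' @param seed Non-negative integer seed; the draw is deterministic given it.
#' @param water_type One of [water_types()], or `"random"` to draw from the
#'   configured mixture.
#' @param config A [generator_config()].
#' @param grid Wavelength grid used to derive the PC label.
#' @return An object of class `"water_state"`.
#' @export
sample_water_state <- function(seed, water_type = "random",
                               config = generator_config(),
                               grid = wavelength_grid()) {
  stopifnot(is.numeric(seed), length(seed) == 1, seed >= 0)
  with_seed(as.integer(seed), draw_water_state(water_type, config, grid))
}

#' @export
print.water_state <- function(x, ...) {
  cat(sprintf(
    "<water_state> %s: chl_a=%.3g ug/L, pc=%.3g ug/L, car=%.2f, cdom=%.2g, nap=%.2g\n",
    x$water_type, x$chl_a, x$pc, x$car, x$cdom_440, x$nap
  ))
  invisible(x)
}
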