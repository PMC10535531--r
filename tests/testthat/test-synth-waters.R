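# Synthetic water generator: state sampling, IOP construction, PC label,
# reflectance forward models and the dataset contract.

test_that("water-state sampling is seeded and respects per-type ranges", {
  a <- sample_water_state(7, "cyano_bloom")
  b <- sample_water_state(7, "cyano_bloom")
  expect_identical(a, b)

  draws <- lapply(1:200, function(i) sample_water_state(i))
  car <- vapply(draws, `[[`, numeric(1), "car")
  expect_true(all(car >= 0 & car <= 1))
  chl <- vapply(draws, `[[`, numeric(1), "chl_a")
  expect_true(all(chl > 0))

  blooms <- lapply(1:1000, function(i) sample_water_state(i, "cyano_bloom"))
  car_b <- vapply(blooms, `[[`, numeric(1), "car")
  expect_true(all(car_b >= 0.7))
  expect_gte(mean(car_b), 0.7)

  expect_error(sample_water_state(1, "turbid_swamp"), "unknown water type")
})

test_that("IOP construction mixes pigment bases and stays non-negative", {
  grid <- wavelength_grid()
  wl <- as.numeric(grid)

  # pure-water limit: no constituents
  st0 <- fixed_state(chl_a = 1e-12, car = 0, cdom_440 = 0, nap = 0)
  st0$chl_a <- 0
  iops0 <- build_iops(st0, grid)
  expect_equal(total_absorption(iops0), pure_water_absorption(grid))

  # hand evaluation of the mixing formula at 675 nm
  st <- fixed_state(chl_a = 10, car = 0.5, pc_to_chl = 1.3)
  iops <- build_iops(st, grid)
  const <- optical_constants()
  eval_bands <- function(bands, x) {
    sum(bands$amp * exp(-((x - bands$center)^2) / (2 * bands$sigma^2)))
  }
  a_alg_675 <- eval_bands(const$alg_bands, 675)
  a_cy_675 <- eval_bands(const$cy_bands, 675) +
    const$pc_astar_base * 1.3 *
      exp(-((675 - const$pc_band_center)^2) / (2 * const$pc_band_sigma^2))
  i675 <- which(wl == 675)
  expect_equal(iops$a_ph[i675], 10 * (0.5 * a_cy_675 + 0.5 * a_alg_675),
               tolerance = 1e-12)

  # non-negativity of every component for assorted states
  for (i in 1:25) {
    s <- sample_water_state(i)
    io <- build_iops(s, grid)
    for (f in c("a_w", "a_ph", "a_cdom", "a_nap", "bb_w", "bb_p")) {
      expect_true(all(io[[f]] >= 0), info = f)
    }
  }

  expect_error(build_iops(st, wavelength_grid(500:780)), "must cover")
})

test_that("monotone construction: pigments move their absorption bands", {
  grid <- wavelength_grid()
  wl <- as.numeric(grid)
  i620 <- which(wl == 620)
  i675 <- which(wl == 675)

  base <- fixed_state(chl_a = 20, car = 0.6, pc_to_chl = 0.5)
  more_pc <- fixed_state(chl_a = 20, car = 0.6, pc_to_chl = 1.5)
  expect_gt(more_pc$pc, base$pc)
  expect_gt(build_iops(more_pc, grid)$a_ph[i620],
            build_iops(base, grid)$a_ph[i620])

  more_chl <- fixed_state(chl_a = 60, car = 0.6, pc_to_chl = 0.5)
  expect_gt(build_iops(more_chl, grid)$a_ph[i675],
            build_iops(base, grid)$a_ph[i675])
})

test_that("phycocyanin label follows the 620 nm decomposition and round-trips", {
  # direct arithmetic: (0.5 - 0.24*0.4) / 0.007 = 57.714...
  io <- flat_iops(a_pc_620 = 0.5 - 0.24 * 0.4, a_star_pc_620 = 0.007)
  st <- fixed_state(car = 0.5)
  expect_equal(phycocyanin_label(st, io), (0.5 - 0.096) / 0.007,
               tolerance = 1e-12)

  # a_pc_620 recorded by build_iops equals the clamped decomposition
  grid <- wavelength_grid()
  wl <- as.numeric(grid)
  s <- fixed_state(chl_a = 50, car = 0.8, pc_to_chl = 1.2)
  io2 <- build_iops(s, grid)
  expect_equal(io2$a_pc_620,
               max(0, io2$a_ph[wl == 620] - 0.24 * io2$a_ph[wl == 665]),
               tolerance = 1e-12)

  # zero cyanobacteria -> zero PC
  s0 <- fixed_state(car = 0)
  expect_identical(phycocyanin_label(s0, build_iops(s0)), 0)
  expect_identical(s0$pc, 0)

  # round trip for generated states, all types
  for (i in seq_along(water_types())) {
    s <- sample_water_state(100 + i, water_types()[i])
    lab <- phycocyanin_label(s, build_iops(s))
    expect_equal(lab, s$pc, tolerance = 1e-6)
  }

  io_bad <- flat_iops(a_star_pc_620 = 0)
  expect_error(phycocyanin_label(st, io_bad), "positive")
})

test_that("reflectance model matches the quadratic closed form", {
  grid <- wavelength_grid()
  st <- fixed_state(fluor_yield = 0, scum_fraction = 0)
  # a=0.9, bb=0.1 -> u=0.1 -> rrs_sub=0.010284 -> Rrs=0.005443
  rec <- rrs_forward(flat_iops(a = 0.9, bb = 0.1), st, grid)
  expect_equal(unique(round(rec$values, 10)),
               round(0.52 * 0.010284 / (1 - 1.7 * 0.010284), 10))
  expect_equal(rec$values[1], 0.005443, tolerance = 1e-4)

  # vanishing backscattering -> vanishing reflectance
  rec0 <- rrs_forward(flat_iops(a = 0.9, bb = 1e-12), st, grid)
  expect_true(all(rec0$values < 1e-10))

  # non-negativity across sampled states
  for (i in 1:20) {
    s <- sample_water_state(i)
    r <- rrs_forward(build_iops(s), s)
    expect_true(all(r$values >= 0))
    expect_true(all(is.finite(r$values)))
  }
})

test_that("fluorescence term has the configured shape", {
  grid <- wavelength_grid()
  wl <- as.numeric(grid)
  io <- flat_iops()

  off <- fixed_state(fluor_yield = 0)
  expect_true(all(fluorescence_term(off, io, grid) == 0))

  on <- fixed_state(car = 0, fluor_yield = 0.01)
  term <- fluorescence_term(on, io, grid)
  expect_lte(abs(wl[which.max(term)] - 685), 1)

  # isolate the secondary emission by switching its amplitude off
  primary <- fluorescence_term(on, io, grid,
                               const = optical_constants(fluor_ratio = 0))
  secondary <- term - primary
  expect_equal(secondary[wl == 730] / primary[wl == 685], 0.2,
               tolerance = 1e-9)

  # cyanobacterial suppression
  cy <- fixed_state(car = 1, fluor_yield = 0.01)
  expect_equal(max(fluorescence_term(cy, io, grid)) / max(term), 0.3,
               tolerance = 1e-9)
})

test_that("top-of-atmosphere propagation and Rayleigh inversion close", {
  grid <- wavelength_grid()
  st <- fixed_state()
  rrs <- rrs_forward(build_iops(st), st, grid)
  atm0 <- structure(list(tau_a_550 = 0, angstrom = 1, theta_s = 30,
                         theta_v = 0, adjacency_weight = 0),
                    class = "atmosphere_state")

  # zero water signal, no aerosol -> pure Rayleigh path
  zero <- spectrum_record("RRS", rep(0, length(grid)), st, NULL, grid)
  toar0 <- toa_forward(zero, atm0, grid)
  tau_r <- rayleigh_optical_thickness(as.numeric(grid))
  rho_r <- tau_r * 0.75 * (1 + cos(pi - 30 * pi / 180)^2) /
    (4 * cos(30 * pi / 180))
  expect_equal(toar0$values, rho_r, tolerance = 1e-12)

  # single-wavelength Rayleigh hand case: tau_r=0.1, P=1.5, theta_s=30
  expect_equal(0.1 * 1.5 / (4 * cos(30 * pi / 180)), 0.0433, tolerance = 1e-3)

  # additivity: TOAR >= Rayleigh path
  atm <- structure(list(tau_a_550 = 0.2, angstrom = 1.3, theta_s = 40,
                        theta_v = 0, adjacency_weight = 0.2),
                   class = "atmosphere_state")
  toar <- toa_forward(rrs, atm, grid)
  rho_r40 <- rayleigh_optical_thickness(as.numeric(grid)) * 0.75 *
    (1 + cos(pi - 40 * pi / 180)^2) / (4 * cos(40 * pi / 180))
  expect_true(all(toar$values >= rho_r40 - 1e-12))

  # aerosol-free, adjacency-free inversion is exact
  toar_clean <- toa_forward(rrs, atm0, grid)
  brr <- brr_from_toar(toar_clean, atm0, grid)
  expect_lt(max(abs(brr$values - pi * rrs$values)), 1e-9)

  # pure Rayleigh sky -> zero BRR
  brr0 <- brr_from_toar(toar0, atm0, grid)
  expect_lt(max(abs(brr0$values)), 1e-12)

  # with aerosol, the residual equals (rho_a + t*adj*veg) / t_r at any band
  brr_a <- brr_from_toar(toa_forward(rrs, atm, grid), atm, grid)
  wl <- as.numeric(grid)
  j <- which(wl == 600)
  mu_s <- cos(40 * pi / 180)
  tau_a <- 0.2 * (600 / 550)^(-1.3)
  cth <- -mu_s
  p_hg <- (1 - 0.7^2) / (1 + 0.7^2 - 2 * 0.7 * cth)^1.5
  rho_a <- 0.95 * tau_a * p_hg / (4 * mu_s)
  t_r <- exp(-0.5 * rayleigh_optical_thickness(600) * (1 / mu_s + 1))
  t_a <- exp(-0.25 * tau_a * (1 / mu_s + 1))
  veg <- 0.05 + 0.45 / (1 + exp(-(600 - 715) / 10))
  resid <- (rho_a + t_r * t_a * 0.2 * veg) / t_r +
    (t_a - 1) * pi * rrs$values[j]
  expect_equal(brr_a$values[j] - pi * rrs$values[j], resid,
               tolerance = 1e-10)
})

test_that("dataset generation is deterministic with the 1:2:2 record contract", {
  ds <- generate_dataset(10, seed = 99)
  expect_equal(sum(ds$meta$data_type == "RRS"), 10)
  expect_equal(sum(ds$meta$data_type == "TOAR"), 20)
  expect_equal(sum(ds$meta$data_type == "BRR"), 20)

  ds2 <- generate_dataset(10, seed = 99)
  expect_identical(ds$meta, ds2$meta)
  expect_identical(ds$spectra, ds2$spectra)

  # all RRS spectra non-negative; everything finite
  expect_true(all(ds$spectra[ds$meta$data_type == "RRS", ] >= 0))
  expect_true(all(is.finite(ds$spectra)))

  bad_mix <- generator_config()
  bad_mix$mixture["scum"] <- bad_mix$mixture["scum"] + 0.01
  expect_error(generate_dataset(5, 1, config = do.call(
    generator_config, list(mixture = bad_mix$mixture))), "sum to 1")
})

test_that("water-type mixture sampling is close to uniform at scale", {
  ds <- small_dataset(700, seed = 31)
  types <- ds$meta$water_type[ds$meta$data_type == "RRS"]
  counts <- table(factor(types, levels = water_types()))
  n <- length(types)
  p <- 1 / 7
  sigma <- sqrt(n * p * (1 - p))
  expect_true(all(abs(counts - n * p) <= 4 * sigma))
})

test_that("dataset CSV round-trips through the sidecar format", {
  ds <- generate_dataset(4, seed = 3)
  path <- tempfile(fileext = ".csv")
  write_dataset_csv(ds, path)
  back <- read_dataset_csv(path)
  expect_equal(as.numeric(back$grid), as.numeric(ds$grid))
  expect_equal(back$spectra, ds$spectra, tolerance = 1e-12)
  expect_equal(back$meta$chl_a, ds$meta$chl_a, tolerance = 1e-12)
  expect_identical(back$seed, ds$seed)
  expect_identical(back$config_hash, ds$config_hash)
  unlink(c(path, paste0(path, ".json")))
})
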