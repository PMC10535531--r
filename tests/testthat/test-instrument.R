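# Imager model: channel grid, spectral response functions, decimation,
# binning.

test_that("native channel grid spans 500-780 nm with 300 uniform centers", {
  centers <- cyanosat_centers()
  expect_length(centers, 300)
  expect_equal(centers[1], 500)
  expect_equal(centers[300], 780)
  spacing <- diff(centers)
  expect_equal(spacing, rep(280 / 299, 299), tolerance = 1e-9)
})

test_that("SRF rows are unit-sum bells with sigma = FWHM/2.35482", {
  grid <- wavelength_grid()
  cfg <- srf_matrix(cyanosat_centers(), fwhm = 12, grid = grid)
  expect_equal(rowSums(cfg$srf), rep(1, 300), tolerance = 1e-6)

  sigma <- 12 / (2 * sqrt(2 * log(2)))
  expect_equal(sigma, 12 / 2.35482, tolerance = 1e-5)

  # independent recomputation of one interior row (on-grid center)
  wl <- as.numeric(grid)
  cfg600 <- srf_matrix(c(550, 600, 650), fwhm = 12, grid = grid)
  row <- cfg600$srf[2, ]
  expected <- exp(-((wl - 600)^2) / (2 * sigma^2))
  expected[abs(wl - 600) > 3 * sigma] <- 0
  expected <- expected / sum(expected)
  expect_equal(row, expected, tolerance = 1e-12)

  # symmetric about an on-grid center
  i600 <- which(wl == 600)
  k <- 1:15
  expect_equal(row[i600 + k], row[i600 - k], tolerance = 1e-9)

  # row maximum sits at the grid point nearest each center
  peak_idx <- apply(cfg$srf, 1, which.max)
  nearest <- vapply(cfg$centers, function(c) which.min(abs(wl - c)), 0L)
  expect_equal(peak_idx, nearest)

  expect_error(srf_matrix(cyanosat_centers(), fwhm = 0), "positive")
  expect_error(srf_matrix(c(600, 550), fwhm = 12), "increasing")
})

test_that("SRF application is linear and preserves flat spectra", {
  grid <- wavelength_grid()
  cfg <- decimate(srf_matrix(cyanosat_centers(), 12, grid), 3)

  flat <- rep(0.3, length(grid))
  expect_equal(apply_srf(flat, cfg), rep(0.3, 100), tolerance = 1e-9)

  set.seed(4)
  s1 <- stats::runif(length(grid))
  s2 <- stats::runif(length(grid))
  lin <- apply_srf(2.5 * s1 - 0.7 * s2, cfg)
  expect_equal(lin, 2.5 * apply_srf(s1, cfg) - 0.7 * apply_srf(s2, cfg),
               tolerance = 1e-12)

  # matrix form agrees with the per-spectrum form
  m <- rbind(s1, s2)
  dimnames(m) <- NULL
  out <- apply_srf(m, cfg)
  expect_equal(out[1, ], apply_srf(s1, cfg), ignore_attr = TRUE)

  # hand quadrature of a triangular spectrum at one channel
  tri <- pmax(0, 1 - abs(as.numeric(grid) - 650) / 40)
  j <- which.min(abs(cfg$centers - 650))
  expect_equal(apply_srf(tri, cfg)[j], sum(cfg$srf[j, ] * tri),
               tolerance = 1e-9)

  expect_error(apply_srf(rep(1, 10), cfg), "does not match")
})

test_that("narrow responses approach nearest-grid-point sampling", {
  grid <- wavelength_grid()
  wl <- as.numeric(grid)
  smooth <- 0.01 * (1 + sin(wl / 60))           # gentle curvature
  cfg1 <- srf_matrix(cyanosat_centers(), fwhm = 1, grid = grid)
  nearest <- vapply(cfg1$centers,
                    function(c) smooth[which.min(abs(wl - c))], 0)
  expect_lt(max(abs(apply_srf(smooth, cfg1) - nearest)), 1e-3)
})

test_that("decimation keeps every step-th channel and commutes with SRF build", {
  grid <- wavelength_grid()
  cfg <- srf_matrix(cyanosat_centers(), 12, grid)
  d3 <- decimate(cfg, 3)
  expect_length(d3$centers, 100)
  expect_true(all(d3$centers %in% cfg$centers))
  expect_identical(decimate(cfg, 1)$centers, cfg$centers)
  expect_identical(decimate(cfg, 1)$srf, cfg$srf)

  direct <- srf_matrix(cyanosat_centers()[seq(1, 300, 3)], 12, grid)
  expect_equal(d3$srf, direct$srf, tolerance = 1e-12)
  expect_error(decimate(cfg, 0), ">= 1")
})

test_that("adjacent binning averages consecutive groups", {
  expect_equal(bin_adjacent(c(1, 2, 3, 4, 5, 6), 3), c(2, 5))
  expect_identical(bin_adjacent(c(1, 2, 3), 1), c(1, 2, 3))
  expect_equal(bin_adjacent(rep(7, 12), 4), rep(7, 3))
  expect_warning(out <- bin_adjacent(1:7, 3), "trailing")
  expect_equal(out, c(2, 5))
  m <- rbind(1:6, 7:12)
  expect_equal(bin_adjacent(m, 3), rbind(c(2, 5), c(8, 11)))
  expect_error(bin_adjacent(1:6, 0), ">= 1")
})

test_that("band configurations round-trip through CSV", {
  grid <- wavelength_grid()
  cfg <- srf_matrix(c(548, 626, 680), 12, grid)
  path <- tempfile(fileext = ".csv")
  write_band_config(cfg, path)
  back <- read_band_config(path, grid)
  expect_equal(back$centers, cfg$centers)
  expect_equal(back$srf, cfg$srf, tolerance = 1e-12)
  unlink(path)
})
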