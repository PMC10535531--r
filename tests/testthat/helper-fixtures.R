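# Shared fixtures, all built in code at test time.

# minimal hand-built IOP set: constant absorption/backscattering
flat_iops <- function(a = 0.9, bb = 0.1, grid = wavelength_grid(),
                      a_pc_620 = 0, a_star_pc_620 = 0.0095) {
  n <- length(grid)
  structure(list(
    grid = grid,
    a_w = rep(a, n), a_ph = rep(0, n), a_cdom = rep(0, n), a_nap = rep(0, n),
    bb_w = rep(bb, n), bb_p = rep(0, n),
    a_pc_620 = a_pc_620, a_star_pc_620 = a_star_pc_620
  ), class = "iop_set")
}

# water state with every field pinned (bypasses the priors)
fixed_state <- function(chl_a = 10, car = 0.5, pc_to_chl = 1, cdom_440 = 0.5,
                        nap = 1, fluor_yield = 0.01, cdom_slope = 0.015,
                        bbp_exponent = 1, scum_fraction = 0,
                        water_type = "mixed_eutrophic", pc = NA_real_) {
  st <- structure(list(
    water_type = water_type, chl_a = chl_a, car = car, pc_to_chl = pc_to_chl,
    cdom_440 = cdom_440, nap = nap, fluor_yield = fluor_yield,
    cdom_slope = cdom_slope, bbp_exponent = bbp_exponent,
    scum_fraction = scum_fraction, pc = pc
  ), class = "water_state")
  if (is.na(st$pc)) st$pc <- phycocyanin_label(st, build_iops(st))
  st
}

# synthetic attribution profile made of Gaussian bumps with known apexes
bump_profile <- function(apexes, heights, width = 6,
                         centers = seq(500, 780, length.out = 100)) {
  fi <- numeric(length(centers))
  for (i in seq_along(apexes)) {
    # place each apex exactly on the nearest channel so it is the argmax
    fi <- fi + heights[i] * exp(-((centers - apexes[i])^2) / (2 * width^2))
  }
  structure(list(
    channel_centers = centers, fi = fi, metric = "one_minus_r2",
    n_repeats = 1L, e_orig = 0, seed = 0L,
    ranking = data.frame(center_nm = centers[order(-fi)],
                         fi = sort(fi, decreasing = TRUE))
  ), class = "attribution_profile")
}

# small cached dataset shared by expensive tests within one run
.test_cache <- new.env(parent = emptyenv())
small_dataset <- function(n_waters = 300, seed = 421) {
  key <- paste0("ds_", n_waters, "_", seed)
  if (is.null(.test_cache[[key]])) {
    .test_cache[[key]] <- generate_dataset(n_waters, seed = seed)
  }
  .test_cache[[key]]
}
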