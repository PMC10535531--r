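# Peak finding, P1/P2 selection and configuration merging.

test_that("peak finding returns apexes ranked by attribution", {
  # single triangular bump -> exactly its apex (placed on a channel center)
  centers <- seq(500, 780, length.out = 100)
  apex <- centers[50]
  fi <- pmax(0, 1 - abs(centers - apex) / 30)
  prof <- bump_profile(apex, 1, width = 15, centers = centers)
  prof$fi <- fi
  pk <- find_peaks(prof, min_sep_nm = 9, smooth_window = 1)
  expect_equal(nrow(pk), 1)
  expect_equal(pk$center_nm, apex)

  # two bumps 10 nm apart, wide separation: only the taller survives
  close_prof <- bump_profile(c(640, 650), c(1, 0.6), width = 3,
                             centers = centers)
  pk2 <- find_peaks(close_prof, min_sep_nm = 30)
  expect_equal(nrow(pk2), 1)
  expect_lt(abs(pk2$center_nm - 640), 3)

  # ranking is by descending attribution
  multi <- bump_profile(c(540, 620, 700), c(0.4, 1, 0.7), width = 5,
                        centers = centers)
  pk3 <- find_peaks(multi, min_sep_nm = 9)
  expect_true(all(diff(pk3$fi) <= 0))
  expect_lt(abs(pk3$center_nm[1] - 620), 3)

  expect_error(find_peaks(multi, min_sep_nm = 0), "positive")
})

test_that("nine-band selection returns the tallest apexes in ascending order", {
  apexes <- seq(510, 775, length.out = 12)
  heights <- c(0.9, 0.2, 0.8, 0.15, 0.7, 0.6, 0.1, 0.5, 0.95, 0.4, 0.3, 0.85)
  prof <- bump_profile(apexes, heights, width = 4)
  sel <- select_p1(prof, source = list(product = "pc", data_type = "RRS"))
  expect_s3_class(sel, "band_selection")
  expect_length(sel$centers, 9)
  expect_true(!is.unsorted(sel$centers, strictly = TRUE))

  # brute-force expectation: the 9 tallest bump apexes (snapped to channels)
  top9 <- sort(apexes[order(-heights)][1:9])
  snapped <- vapply(top9, function(a) {
    prof$channel_centers[which.min(abs(prof$channel_centers - a))]
  }, 0)
  expect_lt(max(abs(sel$centers - snapped)), 3)

  # subset of the unconstrained peak list
  pk <- find_peaks(prof, min_sep_nm = 9)
  expect_true(all(sel$centers %in% pk$center_nm))

  too_few <- bump_profile(c(560, 660), c(1, 0.5), width = 8)
  expect_error(select_p1(too_few), "short by")
})

test_that("three-band selection enforces the broad-region separation", {
  prof <- bump_profile(c(548, 560, 620, 650, 680, 704),
                       c(1.0, 0.9, 0.8, 0.75, 0.7, 0.6), width = 4)
  sel <- select_p2(prof)
  expect_length(sel$centers, 3)
  gaps <- diff(sel$centers)
  expect_true(all(gaps >= 30))

  # three well-separated bumps are all selected regardless of height order
  spaced <- bump_profile(c(548, 650, 730), c(0.2, 1, 0.5), width = 5)
  sel2 <- select_p2(spaced)
  snapped2 <- vapply(c(548, 650, 730), function(a) {
    spaced$channel_centers[which.min(abs(spaced$channel_centers - a))]
  }, 0)
  expect_lt(max(abs(sel2$centers - snapped2)), 3)
})

test_that("merging selections reproduces the published synthesis exactly", {
  expected <- list(
    TOAR = c(548, 572, 614, 632, 650, 686, 710, 722),
    BRR = c(548, 560, 614, 632, 680, 686, 716, 722),
    RRS = c(548, 590, 626, 674, 680, 704, 749)
  )
  for (dt in names(expected)) {
    merged <- merge_configs(unname(reference_selections("P2", dt)))
    expect_equal(merged$centers, expected[[dt]])
  }
  # repeated bands across products are flagged by their source count
  m_rrs <- merge_configs(unname(reference_selections("P2", "RRS")))
  expect_equal(m_rrs$n_sources[m_rrs$centers == 548], 2L)
  expect_equal(m_rrs$n_sources[m_rrs$centers == 674], 2L)
})

test_that("merging is idempotent, commutative and size-bounded", {
  sels <- unname(reference_selections("P2", "TOAR"))
  m1 <- merge_configs(sels)
  expect_equal(merge_configs(list(m1))$centers, m1$centers)

  m_rev <- merge_configs(rev(sels))
  expect_equal(m_rev$centers, m1$centers)
  expect_lte(length(m1$centers),
             sum(vapply(sels, function(s) length(s$centers), 0L)))

  # self-merge is the same selection
  solo <- merge_configs(list(sels[[1]], sels[[1]]))
  expect_equal(solo$centers, sels[[1]]$centers)

  # tolerance collapses near-duplicates
  a <- merge_configs(sels, tol_nm = 15)
  expect_lt(length(a$centers), length(m1$centers))
})

test_that("selections serialize to CSV and Markdown", {
  sels <- reference_selections("P2", "RRS")
  path <- tempfile(fileext = ".csv")
  write_selection_csv(unname(sels), path)
  df <- utils::read.csv(path)
  expect_equal(nrow(df), 9)
  expect_named(df, c("name", "center_nm", "n_sources"))
  unlink(path)

  md <- selection_markdown(list(sels$chl_a, merge_configs(unname(sels))))
  expect_match(md, "\\| Band \\|")
  expect_match(md, "\\*\\*548\\*\\*")  # repeated band rendered bold
})

test_that("the published reference table is internally consistent", {
  ref <- cyanosat_reference_selections()
  counts <- table(ref$config, paste(ref$product, ref$data_type))
  expect_true(all(counts["P2", ] == 3))
  expect_true(all(counts["P1", ] == 9))
  # every center lies in the plausible spectral window
  expect_true(all(ref$center_nm >= 500 & ref$center_nm <= 790))
})
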