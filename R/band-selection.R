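# Reduction of attribution profiles to P1/P2 band configurations and their
# merged minimum-viable / optimal syntheses.

#' Ranked attribution peaks
#'
#' Light moving-average smoothing (window in channels, edges truncated),
#' local maxima (strictly greater than both immediate neighbors; endpoints
#' qualify against their single neighbor), then greedy selection by
#' descending attribution that discards any candidate closer than
#' `min_sep_nm` to an already accepted peak. Ties in attribution break
#' toward the lower wavelength for determinism.
#'
#' @param profile An `attribution_profile` (>= 3 channels).
#' @param min_sep_nm Minimum separation between accepted peaks in nm (> 0).
#' @param smooth_window Moving-average window in channels (default 3).
#' @return Data frame of accepted peaks (`center_nm`, `fi`) ranked by
#'   descending attribution.
#' @export
find_peaks <- function(profile, min_sep_nm, smooth_window = 3L) {
  stopifnot(inherits(profile, "attribution_profile"))
  if (min_sep_nm <= 0) stop("min_sep_nm must be positive", call. = FALSE)
  centers <- profile$channel_centers
  fi <- profile$fi
  k <- length(fi)
  if (k < 3) stop("profile needs at least 3 channels", call. = FALSE)

  half <- (as.integer(smooth_window) - 1L) %/% 2L
  smooth <- vapply(seq_len(k), function(i) {
    lo <- max(1L, i - half)
    hi <- min(k, i + half)
    mean(fi[lo:hi])
  }, numeric(1))

  is_peak <- vapply(seq_len(k), function(i) {
    left_ok <- i == 1L || smooth[i] > smooth[i - 1L]
    right_ok <- i == k || smooth[i] > smooth[i + 1L]
    left_ok && right_ok
  }, logical(1))
  cand <- which(is_peak)
  if (!length(cand)) {
    return(data.frame(center_nm = numeric(0), fi = numeric(0)))
  }
  cand <- cand[order(-smooth[cand], centers[cand])]

  accepted <- integer(0)
  for (i in cand) {
    if (!length(accepted) ||
        all(abs(centers[i] - centers[accepted]) >= min_sep_nm)) {
      accepted <- c(accepted, i)
    }
  }
  data.frame(center_nm = centers[accepted], fi = smooth[accepted])
}

new_band_selection <- function(name, centers, source, attribution = NULL) {
  centers <- as.numeric(centers)
  ord <- order(centers)
  structure(list(name = name, centers = centers[ord],
                 attribution = if (is.null(attribution)) NULL else
                   attribution[ord],
                 source = source), class = "band_selection")
}

#' @export
print.band_selection <- function(x, ...) {
  cat(sprintf("<band_selection> %s (%d bands): %s nm\n", x$name,
              length(x$centers),
              paste(round(x$centers), collapse = ", ")))
  invisible(x)
}

select_top_peaks <- function(profile, n, min_sep_nm, smooth_window, name,
                             source) {
  peaks <- find_peaks(profile, min_sep_nm, smooth_window)
  if (nrow(peaks) < n) {
    stop(sprintf(
      "%s selection needs %d peaks but only %d found at %g nm separation (short by %d)",
      name, n, nrow(peaks), min_sep_nm, n - nrow(peaks)), call. = FALSE)
  }
  top <- peaks[seq_len(n), ]
  new_band_selection(name, top$center_nm, source, top$fi)
}

#' Nine-band (near-optimal) configuration from an attribution profile
#'
#' The nine top-ranked attribution peaks under a 9 nm separation constraint,
#' reported in ascending wavelength: the configuration that retrieves
#' products with almost full-spectrum accuracy using few bands.
#'
#' @param profile An `attribution_profile`.
#' @param n Number of bands (default 9).
#' @param min_sep_nm Minimum peak separation (default 9 nm).
#' @param smooth_window Smoothing window for [find_peaks()].
#' @param source Provenance, e.g. `list(product = "pc", data_type = "RRS")`.
#' @return A `band_selection` named `"P1"`.
#' @export
select_p1 <- function(profile, n = 9L, min_sep_nm = 9, smooth_window = 3L,
                      source = NULL) {
  select_top_peaks(profile, n, min_sep_nm, smooth_window, "P1", source)
}

#' Three-band (minimum viable) configuration from an attribution profile
#'
#' The three top peaks under a wide 30 nm separation, one per broad region
#' of importance: the minimum viable configuration for product estimation.
#'
#' @inheritParams select_p1
#' @param n Number of bands (default 3).
#' @param min_sep_nm Minimum peak separation (default 30 nm).
#' @return A `band_selection` named `"P2"`.
#' @export
select_p2 <- function(profile, n = 3L, min_sep_nm = 30, smooth_window = 3L,
                      source = NULL) {
  select_top_peaks(profile, n, min_sep_nm, smooth_window, "P2", source)
}

#' Merge band selections into a synthesis configuration
#'
#' Union of the selections' centers in ascending order, with centers closer
#' than `tol_nm` collapsed to one; the per-center duplicate count records
#' how many input selections contributed each band (the analogue of bolding
#' repeated bands in a configuration table). Commutative and idempotent.
#'
#' @param selections List of `band_selection` objects.
#' @param tol_nm Collapse tolerance in nm (default 0: exact duplicates).
#' @param name Name of the merged selection (default `"merged"`).
#' @return A `band_selection` with an extra `n_sources` field.
#' @export
merge_configs <- function(selections, tol_nm = 0, name = "merged") {
  if (!length(selections)) stop("no selections to merge", call. = FALSE)
  if (inherits(selections, "band_selection")) selections <- list(selections)
  all_centers <- sort(unlist(lapply(selections, `[[`, "centers")))
  groups <- cumsum(c(TRUE, diff(all_centers) > tol_nm))
  centers <- as.numeric(tapply(all_centers, groups, function(g) g[1]))
  counts <- as.integer(tapply(all_centers, groups, length))
  source <- lapply(selections, `[[`, "source")
  out <- new_band_selection(name, centers, source)
  out$n_sources <- counts[order(centers)]
  out
}

#' Write band selections to CSV
#'
#' One row per band: `name, center_nm, n_sources` (1 when the selection is
#' not a merge), mirroring the layout of published configuration tables.
#'
#' @param selections A `band_selection` or list of them.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_selection_csv <- function(selections, path) {
  if (inherits(selections, "band_selection")) selections <- list(selections)
  rows <- do.call(rbind, lapply(selections, function(s) {
    data.frame(name = s$name, center_nm = s$centers,
               n_sources = if (is.null(s$n_sources)) 1L else s$n_sources)
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' Render band selections as a Markdown table
#'
#' @param selections Named list of `band_selection` objects (columns).
#' @return Character scalar of Markdown.
#' @export
selection_markdown <- function(selections) {
  if (inherits(selections, "band_selection")) selections <- list(selections)
  nm <- vapply(selections, `[[`, "", "name")
  n_max <- max(vapply(selections, function(s) length(s$centers), 0L))
  header <- paste0("| Band | ", paste(nm, collapse = " | "), " |")
  sep <- paste0("|---", paste(rep("|---", length(nm)), collapse = ""), "|")
  rows <- vapply(seq_len(n_max), function(i) {
    cells <- vapply(selections, function(s) {
      if (i <= length(s$centers)) {
        v <- sprintf("%g", s$centers[i])
        if (!is.null(s$n_sources) && s$n_sources[i] > 1) {
          v <- paste0("**", v, "**")
        }
        v
      } else ""
    }, "")
    paste0("| ", i, " | ", paste(cells, collapse = " | "), " |")
  }, "")
  paste(c(header, sep, rows), collapse = "\n")
}

#' Published reference band configurations of the CyanoSat study design
#'
#' The P1 (nine-band) and P2 (three-band) configurations reported for the
#' CyanoSat imager per product (chl_a, pc, car) and data type (RRS, TOAR,
#' BRR) at 12 nm FWHM. These serve as fixed inputs for synthesizing the
#' merged minimum-viable and optimal configurations and for comparing the
#' emulator's selections against the published ones.
#'
#' @return Data frame with columns `config` ("P1"/"P2"), `product`,
#'   `data_type`, `center_nm`.
#' @export
cyanosat_reference_selections <- function() {
  p2 <- list(
    chl_a = list(RRS = c(590, 674, 749), TOAR = c(614, 686, 722),
                 BRR = c(614, 686, 722)),
    pc = list(RRS = c(548, 626, 680), TOAR = c(548, 632, 710),
              BRR = c(548, 632, 716)),
    car = list(RRS = c(548, 674, 704), TOAR = c(572, 650, 722),
               BRR = c(560, 680, 722))
  )
  p1 <- list(
    chl_a = list(RRS = c(536, 590, 599, 614, 623, 674, 695, 749, 761),
                 TOAR = c(506, 530, 566, 614, 656, 686, 722, 764, 782),
                 BRR = c(512, 572, 614, 638, 674, 686, 722, 764, 782)),
    pc = list(RRS = c(548, 578, 626, 680, 698, 728, 746, 764, 776),
              TOAR = c(548, 608, 632, 662, 698, 710, 740, 758, 770),
              BRR = c(512, 548, 560, 596, 632, 644, 680, 716, 746)),
    car = list(RRS = c(548, 560, 614, 632, 674, 704, 722, 740, 758),
               TOAR = c(548, 572, 614, 632, 650, 674, 722, 752, 788),
               BRR = c(560, 590, 638, 656, 680, 698, 722, 770, 782))
  )
  rows <- list()
  for (cfg in c("P2", "P1")) {
    src <- if (cfg == "P2") p2 else p1
    for (product in names(src)) {
      for (dt in names(src[[product]])) {
        rows[[length(rows) + 1L]] <- data.frame(
          config = cfg, product = product, data_type = dt,
          center_nm = src[[product]][[dt]]
        )
      }
    }
  }
  do.call(rbind, rows)
}

#' Reference selections as `band_selection` objects
#'
#' @param config `"P1"` or `"P2"`.
#' @param data_type `"RRS"`, `"TOAR"` or `"BRR"`.
#' @return Named list of `band_selection` objects, one per product.
#' @export
reference_selections <- function(config = c("P2", "P1"),
                                 data_type = c("RRS", "TOAR", "BRR")) {
  config <- match.arg(config)
  data_type <- match.arg(data_type)
  ref <- cyanosat_reference_selections()
  ref <- ref[ref$config == config & ref$data_type == data_type, ]
  out <- lapply(split(ref, ref$product), function(df) {
    new_band_selection(config, df$center_nm,
                       source = list(product = df$product[1],
                                     data_type = data_type))
  })
  out[c("chl_a", "pc", "car")]
}
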