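# Labeled spectral dataset: generation, container, and on-disk format.

label_fields <- c("chl_a", "pc", "car", "pc_to_chl", "water_type", "cdom_440",
                  "nap", "fluor_yield", "cdom_slope", "bbp_exponent",
                  "scum_fraction")
atm_fields <- c("tau_a_550", "angstrom", "theta_s", "theta_v",
                "adjacency_weight")

state_row <- function(state) {
  out <- state[label_fields]
  as.data.frame(out, stringsAsFactors = FALSE)
}

atm_row <- function(atm) {
  if (is.null(atm)) {
    as.data.frame(stats::setNames(as.list(rep(NA_real_, length(atm_fields))),
                                  atm_fields))
  } else {
    as.data.frame(atm[atm_fields])
  }
}

#' Spectral dataset container
#'
#' N spectra on a shared wavelength grid with per-record labels. Spectra are
#' stored as a numeric matrix (records x wavelengths) and labels as a
#' data frame with one row per record; `data_type` tags each record as
#' water-leaving (`RRS`), top-of-atmosphere (`TOAR`) or bottom-of-Rayleigh
#' (`BRR`).
#'
#' @param grid Wavelength grid.
#' @param spectra Numeric matrix, one row per record.
#' @param meta Data frame with columns `water_id`, `data_type`, the water
#'   labels and the atmosphere parameters (`NA` for RRS records).
#' @param seed The generator seed (or `NA` for external data).
#' @param config_hash Hash of the generating configuration.
#' @return An object of class `"spectral_dataset"`.
#' @export
spectral_dataset <- function(grid, spectra, meta, seed = NA_integer_,
                             config_hash = NA_character_) {
  grid <- as_wavelength_grid(grid)
  spectra <- as.matrix(spectra)
  stopifnot(ncol(spectra) == length(grid), nrow(spectra) == nrow(meta))
  if (!all(meta$data_type %in% c("RRS", "TOAR", "BRR"))) {
    stop("data_type must be RRS, TOAR or BRR", call. = FALSE)
  }
  structure(list(grid = grid, spectra = spectra, meta = meta,
                 seed = seed, config_hash = config_hash),
            class = "spectral_dataset")
}

#' @export
print.spectral_dataset <- function(x, ...) {
  tab <- table(x$meta$data_type)
  cat(sprintf("<spectral_dataset> %d records on %d wavelengths (%s)\n",
              nrow(x$spectra), length(x$grid),
              paste(sprintf("%s: %d", names(tab), tab), collapse = ", ")))
  invisible(x)
}

#' Number of records in a spectral dataset
#' @param dataset A `spectral_dataset`.
#' @return Integer record count.
#' @export
n_records <- function(dataset) nrow(dataset$spectra)

#' Subset a spectral dataset
#'
#' @param dataset A `spectral_dataset`.
#' @param data_type Optional data type to keep (`"RRS"`, `"TOAR"`, `"BRR"`).
#' @param idx Optional row indices to keep (applied after the type filter).
#' @return A `spectral_dataset`.
#' @export
filter_records <- function(dataset, data_type = NULL, idx = NULL) {
  keep <- seq_len(n_records(dataset))
  if (!is.null(data_type)) {
    data_type <- match.arg(data_type, c("RRS", "TOAR", "BRR"))
    keep <- keep[dataset$meta$data_type[keep] == data_type]
  }
  if (!is.null(idx)) keep <- keep[idx]
  spectral_dataset(dataset$grid, dataset$spectra[keep, , drop = FALSE],
                   dataset$meta[keep, , drop = FALSE],
                   seed = dataset$seed, config_hash = dataset$config_hash)
}

# polynomial rolling hash over the JSON encoding: cheap config fingerprint
config_hash <- function(config) {
  txt <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA,
                          force = TRUE)
  bytes <- utf8ToInt(as.character(txt))
  h <- 216613626
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' Generate a labeled synthetic spectral dataset
#'
#' For each of `n_waters` simulated waters (types drawn from the configured
#' mixture) the generator emits one water-leaving reflectance record and, for
#' each of two independently sampled atmospheres, one top-of-atmosphere and
#' one bottom-of-Rayleigh record: 5 records per water in total. The whole
#' draw is a pure function of `(n_waters, seed, config)`.
#'
#' @param n_waters Number of simulated waters (>= 1).
#' @param seed Integer seed controlling every random draw.
#' @param config A [generator_config()].
#' @param grid Wavelength grid (default 400--800 nm at 1 nm).
#' @param n_atmospheres Atmospheres sampled per water (default 2).
#' @return A `spectral_dataset` with `n_waters * (1 + 2 * n_atmospheres)`
#'   records.
#' @export
generate_dataset <- function(n_waters, seed, config = generator_config(),
                             grid = wavelength_grid(), n_atmospheres = 2L) {
  stopifnot(n_waters >= 1)
  grid <- as_wavelength_grid(grid)
  n_rec <- n_waters * (1L + 2L * n_atmospheres)
  with_seed(as.integer(seed), {
    spectra <- matrix(NA_real_, nrow = n_rec, ncol = length(grid))
    meta_list <- vector("list", n_rec)
    row <- 0L
    for (w in seq_len(n_waters)) {
      state <- draw_water_state("random", config, grid)
      iops <- build_iops(state, grid, const = config$const)
      rrs <- rrs_forward(iops, state, grid, const = config$const)
      srow <- state_row(state)
      row <- row + 1L
      spectra[row, ] <- rrs$values
      meta_list[[row]] <- cbind(water_id = w, data_type = "RRS",
                                srow, atm_row(NULL))
      for (k in seq_len(n_atmospheres)) {
        atm <- sample_atmosphere(config)
        toar <- toa_forward(rrs, atm, grid)
        brr <- brr_from_toar(toar, atm, grid)
        row <- row + 1L
        spectra[row, ] <- toar$values
        meta_list[[row]] <- cbind(water_id = w, data_type = "TOAR",
                                  srow, atm_row(atm))
        row <- row + 1L
        spectra[row, ] <- brr$values
        meta_list[[row]] <- cbind(water_id = w, data_type = "BRR",
                                  srow, atm_row(atm))
      }
    }
    meta <- do.call(rbind, meta_list)
    rownames(meta) <- NULL
    spectral_dataset(grid, spectra, meta, seed = as.integer(seed),
                     config_hash = config_hash(config))
  })
}

#' Write a spectral dataset to CSV with a JSON sidecar
#'
#' One row per record: `data_type`, the label and atmosphere columns, then
#' one column per wavelength named `wl_<nm>`. The sidecar records the grid,
#' the seed and the configuration hash.
#'
#' @param dataset A `spectral_dataset`.
#' @param path CSV path; the sidecar is written to `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_dataset_csv <- function(dataset, path) {
  wl_names <- sprintf("wl_%g", as.numeric(dataset$grid))
  wide <- cbind(dataset$meta,
                stats::setNames(as.data.frame(dataset$spectra), wl_names))
  utils::write.csv(wide, path, row.names = FALSE)
  sidecar <- list(wavelengths = as.numeric(dataset$grid),
                  seed = dataset$seed, config_hash = dataset$config_hash)
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a spectral dataset from CSV
#'
#' Inverse of [write_dataset_csv()]; the grid is taken from the `wl_<nm>`
#' column names, and the sidecar (if present) restores seed and config hash.
#'
#' @param path CSV path.
#' @return A `spectral_dataset`.
#' @export
read_dataset_csv <- function(path) {
  wide <- utils::read.csv(path, stringsAsFactors = FALSE)
  wl_cols <- grep("^wl_", names(wide), value = TRUE)
  grid <- wavelength_grid(as.numeric(sub("^wl_", "", wl_cols)))
  meta <- wide[, setdiff(names(wide), wl_cols), drop = FALSE]
  spectra <- as.matrix(wide[, wl_cols, drop = FALSE])
  dimnames(spectra) <- NULL
  seed <- NA_integer_
  hash <- NA_character_
  sidecar_path <- paste0(path, ".json")
  if (file.exists(sidecar_path)) {
    sidecar <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
    seed <- as.integer(sidecar$seed)
    hash <- sidecar$config_hash
  }
  spectral_dataset(grid, spectra, meta, seed = seed, config_hash = hash)
}
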