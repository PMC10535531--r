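# End-to-end experiment orchestration: generate -> resample -> train
# Full/P1/P2 per product per data type -> attribute -> select -> report.

#' Experiment configuration
#'
#' Everything a full run needs, with validation up front so a bad value is
#' rejected before any compute. Serializable to/from YAML.
#'
#' @param n_waters Simulated waters in the dataset.
#' @param seed Master seed; every stage seed is derived from it.
#' @param generator A [generator_config()].
#' @param fwhm FWHM values in nm (first is the working configuration; a
#'   second is used by [compare_fwhm()]).
#' @param decimation_step Channel stride for the working configuration
#'   (default 3: 300 native channels -> 100).
#' @param products Subset of `c("chl_a", "pc", "car")`.
#' @param data_types Subset of `c("RRS", "TOAR", "BRR")`.
#' @param train A [train_config()].
#' @param attribution List with `n_repeats` (default 5).
#' @param selection List with `p1_n`, `p1_min_sep_nm`, `p2_n`,
#'   `p2_min_sep_nm`, `smooth_window`.
#' @param run_cv Whether [evaluate()] runs the inner fold loop.
#' @param out_dir Output directory, or `NULL` to skip writing artifacts.
#' @return A list of class `"experiment_config"`.
#' @export
experiment_config <- function(n_waters = 3000L, seed = 1L,
                              generator = generator_config(),
                              fwhm = c(12, 8), decimation_step = 3L,
                              products = c("chl_a", "pc", "car"),
                              data_types = c("RRS", "TOAR", "BRR"),
                              train = train_config(),
                              attribution = list(n_repeats = 5L),
                              selection = list(p1_n = 9L, p1_min_sep_nm = 9,
                                               p2_n = 3L, p2_min_sep_nm = 30,
                                               smooth_window = 3L),
                              run_cv = FALSE, out_dir = NULL) {
  bad <- setdiff(products, retrieval_products)
  if (length(bad)) {
    stop(sprintf("unknown product(s) %s; valid products: %s",
                 paste(bad, collapse = ", "),
                 paste(retrieval_products, collapse = ", ")), call. = FALSE)
  }
  bad <- setdiff(data_types, c("RRS", "TOAR", "BRR"))
  if (length(bad)) {
    stop(sprintf("unknown data type(s) %s; valid types: RRS, TOAR, BRR",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  if (!length(fwhm)) stop("fwhm list must be non-empty", call. = FALSE)
  structure(list(
    n_waters = as.integer(n_waters), seed = as.integer(seed),
    generator = generator, fwhm = as.numeric(fwhm),
    decimation_step = as.integer(decimation_step),
    products = products, data_types = data_types, train = train,
    attribution = attribution, selection = selection,
    run_cv = isTRUE(run_cv), out_dir = out_dir
  ), class = "experiment_config")
}

#' Load an experiment configuration from YAML
#'
#' Scalar fields override the defaults of [experiment_config()]; nested
#' generator/train/selection blocks are merged into their default records.
#'
#' @param path YAML file.
#' @return An `experiment_config`.
#' @export
experiment_config_from_yaml <- function(path) {
  raw <- yaml::read_yaml(path)
  args <- list()
  for (f in c("n_waters", "seed", "fwhm", "decimation_step", "products",
              "data_types", "run_cv", "out_dir")) {
    if (!is.null(raw[[f]])) args[[f]] <- raw[[f]]
  }
  if (!is.null(raw$train)) args$train <- do.call(train_config, raw$train)
  if (!is.null(raw$generator)) {
    gargs <- raw$generator
    if (!is.null(gargs$mixture)) gargs$mixture <- unlist(gargs$mixture)
    args$generator <- do.call(generator_config, gargs)
  }
  if (!is.null(raw$attribution)) args$attribution <- raw$attribution
  if (!is.null(raw$selection)) {
    args$selection <- utils::modifyList(
      formals(experiment_config)$selection |> eval(), raw$selection)
  }
  do.call(experiment_config, args)
}

# stage seeds derived deterministically from the master seed (kept < 2^31)
derive_seed <- function(master, ...) {
  tag <- paste(c(master, ...), collapse = "/")
  bytes <- utf8ToInt(tag)
  h <- 216613626
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  as.integer(h)
}

#' Full decimated working band configuration
#'
#' @param fwhm FWHM in nm (default 12).
#' @param step Decimation stride (default 3).
#' @param grid Wavelength grid.
#' @return A `band_config` (100 channels at the defaults).
#' @export
full_band_config <- function(fwhm = 12, step = 3L, grid = wavelength_grid()) {
  decimate(srf_matrix(cyanosat_centers(), fwhm, grid), step)
}

#' Run the full band-selection experiment
#'
#' For every (product, data type) pair: trains the Full (decimated
#' 100-channel) retrieval, computes the permutation-attribution profile on
#' the holdout, derives the P1 and P2 selections, retrains models on the
#' selected channels, and collects metrics for all three configurations.
#' Per data type the P2 selections across products are merged into the
#' minimum-viable synthesis and the P1 selections into the optimal
#' synthesis. Deterministic given the master seed.
#'
#' @param config An [experiment_config()].
#' @param dataset Optional pre-generated `spectral_dataset` (it must match
#'   the config's generator settings; by default one is generated).
#' @return A list with `metrics` (one row per product x data type x
#'   configuration), `profiles`, `selections`, `merged`, and a run
#'   `manifest`; artifacts are written to `config$out_dir` when set.
#' @export
run_experiment <- function(config = experiment_config(), dataset = NULL) {
  stopifnot(inherits(config, "experiment_config"))
  t0 <- Sys.time()
  grid <- wavelength_grid()
  if (is.null(dataset)) {
    dataset <- generate_dataset(config$n_waters,
                                seed = derive_seed(config$seed, "data"),
                                config = config$generator, grid = grid)
  }
  full_cfg <- full_band_config(config$fwhm[1], config$decimation_step, grid)
  sel_cfg <- config$selection

  metrics <- list()
  profiles <- list()
  selections <- list()
  log_lines <- character(0)
  say <- function(fmt, ...) {
    line <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"),
                    sprintf(fmt, ...))
    log_lines <<- c(log_lines, line)
    message(line)
  }

  for (dt in config$data_types) {
    ds_t <- filter_records(dataset, data_type = dt)
    for (product in config$products) {
      key <- paste(product, dt, sep = ".")
      say("Full retrieval: %s / %s", product, dt)
      ev_full <- evaluate(ds_t, product, full_cfg, config$train,
                          seed = derive_seed(config$seed, product, dt),
                          run_cv = config$run_cv, config_name = "Full")
      metrics[[paste0(key, ".Full")]] <- ev_full$report

      say("Attribution: %s / %s", product, dt)
      profile <- permutation_importance(
        ev_full$model, ev_full$X_test, ev_full$y_test,
        n_repeats = config$attribution$n_repeats,
        seed = derive_seed(config$seed, product, dt, "perm")
      )
      profiles[[key]] <- profile

      source <- list(product = product, data_type = dt)
      for (cfg_name in c("P1", "P2")) {
        sel <- tryCatch({
          if (cfg_name == "P1") {
            select_p1(profile, sel_cfg$p1_n, sel_cfg$p1_min_sep_nm,
                      sel_cfg$smooth_window, source = source)
          } else {
            select_p2(profile, sel_cfg$p2_n, sel_cfg$p2_min_sep_nm,
                      sel_cfg$smooth_window, source = source)
          }
        }, error = function(e) {
          say("WARNING: %s selection failed for %s/%s: %s", cfg_name,
              product, dt, conditionMessage(e))
          NULL
        })
        if (is.null(sel)) next
        selections[[paste0(key, ".", cfg_name)]] <- sel
        band_cfg <- srf_matrix(sel$centers, config$fwhm[1], grid)
        say("%s retrieval (%d bands): %s / %s", cfg_name,
            length(sel$centers), product, dt)
        ev <- evaluate(ds_t, product, band_cfg, config$train,
                       seed = derive_seed(config$seed, product, dt),
                       run_cv = config$run_cv, config_name = cfg_name)
        metrics[[paste0(key, ".", cfg_name)]] <- ev$report
      }
    }
  }

  merged <- list()
  for (dt in config$data_types) {
    for (cfg_name in c("P2", "P1")) {
      keys <- paste(config$products, dt, cfg_name, sep = ".")
      sels <- selections[keys[keys %in% names(selections)]]
      if (length(sels)) {
        nm <- if (cfg_name == "P2") "minimum_viable" else "optimal"
        merged[[paste(dt, nm, sep = ".")]] <-
          merge_configs(unname(sels), name = paste(nm, dt, sep = "_"))
      }
    }
  }

  metrics_df <- do.call(rbind, lapply(metrics, as.data.frame))
  rownames(metrics_df) <- NULL
  manifest <- list(
    seed = config$seed, n_waters = config$n_waters,
    fwhm = config$fwhm[1], decimation_step = config$decimation_step,
    products = config$products, data_types = config$data_types,
    config_hash = config_hash(unclass(config)[setdiff(names(config),
                                                      "out_dir")]),
    r_version = as.character(getRversion()),
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs"))
  )

  result <- list(metrics = metrics_df, profiles = profiles,
                 selections = selections, merged = merged,
                 manifest = manifest, log = log_lines, dataset = dataset)

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(metrics_df,
                     file.path(config$out_dir, "metrics.csv"),
                     row.names = FALSE)
    for (key in names(profiles)) {
      write_attribution_csv(profiles[[key]],
                            file.path(config$out_dir,
                                      paste0("profile_", key, ".csv")))
    }
    if (length(selections)) {
      write_selection_csv(unname(selections),
                          file.path(config$out_dir, "selections.csv"))
    }
    if (length(merged)) {
      write_selection_csv(unname(merged),
                          file.path(config$out_dir, "merged_configs.csv"))
    }
    jsonlite::write_json(manifest, file.path(config$out_dir,
                                             "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
    writeLines(log_lines, file.path(config$out_dir, "run.log"))
  }
  result
}

#' Compare retrieval performance across FWHM configurations
#'
#' Runs the Full-configuration water-leaving retrieval for each FWHM on the
#' same generated waters (identical seed), one row per product per FWHM,
#' with the per-product metric deltas reported alongside. No ordering is
#' asserted: the table reports the differences.
#'
#' @param config An [experiment_config()] whose `fwhm` has at least two
#'   values.
#' @param dataset Optional pre-generated dataset (shared across FWHMs).
#' @return A list with the comparison `table` and the per-product `deltas`.
#' @export
compare_fwhm <- function(config = experiment_config(), dataset = NULL) {
  stopifnot(inherits(config, "experiment_config"))
  if (length(config$fwhm) < 2) {
    stop("compare_fwhm needs at least two FWHM values", call. = FALSE)
  }
  grid <- wavelength_grid()
  if (is.null(dataset)) {
    dataset <- generate_dataset(config$n_waters,
                                seed = derive_seed(config$seed, "data"),
                                config = config$generator, grid = grid)
  }
  ds_rrs <- filter_records(dataset, data_type = "RRS")
  rows <- list()
  for (fwhm in config$fwhm) {
    band_cfg <- full_band_config(fwhm, config$decimation_step, grid)
    for (product in config$products) {
      ev <- evaluate(ds_rrs, product, band_cfg, config$train,
                     seed = derive_seed(config$seed, product, "RRS"),
                     run_cv = config$run_cv,
                     config_name = sprintf("Full_%gnm", fwhm))
      df <- as.data.frame(ev$report)
      df$fwhm <- fwhm
      rows[[length(rows) + 1L]] <- df
    }
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  # deltas: narrowest minus widest FWHM (e.g. 8 nm minus 12 nm)
  deltas <- do.call(rbind, lapply(split(tab, tab$product), function(d) {
    d <- d[order(-d$fwhm), ]
    n <- nrow(d)
    data.frame(product = d$product[1],
               fwhm_pair = paste(d$fwhm[c(n, 1)], collapse = " vs "),
               abs_delta_r2 = abs(d$r2[n] - d$r2[1]),
               delta_mape = d$mape_percent[n] - d$mape_percent[1],
               delta_rmsele = d$rmsele[n] - d$rmsele[1])
  }))
  rownames(deltas) <- NULL
  list(table = tab, deltas = deltas)
}
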