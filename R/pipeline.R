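#' Pipeline configuration
#'
#' Bundles every stage's parameters with the seed into one serializable
#' object. All defaults are the pipeline's canonical values: 200-3000 Hz
#' passband, 4.5 x noise SD threshold, strict >10 spikes/min activity rule,
#' 5-spike bursts merged under 100 ms, 50 ms STTC window, 0.7 CorSE map
#' threshold and 3 principal components.
#'
#' @param detection A [detection_params()].
#' @param burst A [burst_params()].
#' @param sttc An [sttc_params()].
#' @param corse A [corse_params()].
#' @param n_components Principal components to retain.
#' @param corse_enabled Run the (raw-trace) CorSE stage.
#' @param data_label Label prefix for output files
#'   (`<cellType>_<ddmyy>_<plateID>_DIV<n>` style).
#' @param seed Integer seed for any simulated input.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(detection = detection_params(),
                            burst = burst_params(),
                            sttc = sttc_params(),
                            corse = corse_params(),
                            n_components = 3L,
                            corse_enabled = TRUE,
                            data_label = "synthetic_MEA1_DIV21",
                            seed = 1L) {
  structure(list(detection = detection, burst = burst, sttc = sttc,
                 corse = corse, n_components = as.integer(n_components),
                 corse_enabled = isTRUE(corse_enabled),
                 data_label = data_label, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Write / read a pipeline configuration file
#'
#' Flat YAML serialization of a [pipeline_config()]; reading reconstructs
#' the typed parameter objects through their constructors, so invalid values
#' are rejected at load time.
#'
#' @param config A `pipeline_config`.
#' @param path YAML file path.
#' @return `write_config` returns `path` invisibly; `read_config` a
#'   `pipeline_config`.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(lapply(unclass(config), function(x)
    if (is.list(x)) unclass(x) else x), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  pipeline_config(
    detection = do.call(detection_params, raw$detection),
    burst = do.call(burst_params, raw$burst),
    sttc = do.call(sttc_params, raw$sttc),
    corse = do.call(corse_params, raw$corse),
    n_components = raw$n_components,
    corse_enabled = raw$corse_enabled,
    data_label = raw$data_label,
    seed = raw$seed
  )
}

#' Detect spikes on every electrode of a plate
#'
#' @param plate An [mea_plate()].
#' @param params A [detection_params()].
#' @param verbose Log per-electrode counts and noise estimates.
#' @return A [spike_table()] of all detected spikes.
#' @export
detect_plate_spikes <- function(plate, params = detection_params(),
                                verbose = FALSE) {
  md <- plate$metadata
  rows <- list()
  for (w in names(plate$wells)) {
    for (e in names(plate$wells[[w]])) {
      tr <- detect_spikes(plate$wells[[w]][[e]], md$sampling_frequency_hz,
                          params, well = w, electrode = e)
      if (verbose) {
        message(sprintf("%s/%s: %d spikes (sigma %.2f uV)", w, e,
                        length(tr$times_s), 1e6 * attr(tr, "sigma_v")))
      }
      if (length(tr$times_s)) {
        rows[[paste(w, e)]] <- data.frame(well = w, electrode = e,
                                          time_s = tr$times_s,
                                          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows)) return(spike_table(duration_s = md$duration_s))
  df <- do.call(rbind, rows)
  spike_table(df$well, df$electrode, df$time_s, duration_s = md$duration_s)
}

# Split a spike table into per-well lists of spike_train objects, creating
# empty trains for electrodes present on the plate but silent in the table.
spikes_to_trains <- function(spikes, duration_s, wells, electrodes,
                             noisy = NULL) {
  out <- list()
  for (w in wells) {
    keep_e <- electrodes
    if (!is.null(noisy)) {
      keep_e <- setdiff(keep_e, noisy$electrode[noisy$well == w])
    }
    out[[w]] <- lapply(stats::setNames(keep_e, keep_e), function(e) {
      t <- spikes$time_s[spikes$well == w & spikes$electrode == e]
      spike_train(t, duration_s, well = w, electrode = e)
    })
  }
  out
}

#' Run the full analysis pipeline
#'
#' Orchestrates simulate (optional) -> spike detection -> burst analysis ->
#' STTC / CorSE -> PCA, writing every stage's outputs and a JSON run
#' manifest into `out_dir`. Stages are isolated: burst and firing features
#' depend only on the spike table, STTC only on spikes + its window, CorSE
#' only on the raw traces.
#'
#' @param input Path to a plate HDF5 file, an [mea_plate()], or `NULL` when
#'   `scenario` is given.
#' @param out_dir Output directory (created if needed).
#' @param config A [pipeline_config()].
#' @param scenario Optional [plate_scenario()] simulated (with
#'   `config$seed`) instead of reading `input`.
#' @param noisy Optional noisy-electrode data frame (columns `well`,
#'   `electrode`) or path to its CSV.
#' @return Invisibly, a named list of written file paths.
#' @export
run_pipeline <- function(input = NULL, out_dir, config = pipeline_config(),
                         scenario = NULL, noisy = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  label <- config$data_label
  files <- list()
  if (!is.null(scenario)) {
    sim <- generate_plate(scenario, seed = config$seed)
    plate <- sim$plate
    files$raw_h5 <- file.path(out_dir, paste0(label, ".h5"))
    write_plate(plate, files$raw_h5)
    files$truth_spikes <- file.path(out_dir, paste0(label, "_truth_spikes.csv"))
    write_spike_csv(sim$truth$spikes, files$truth_spikes)
  } else if (is.character(input)) {
    plate <- read_plate(input)
  } else if (inherits(input, "mea_plate")) {
    plate <- input
  } else {
    stop("provide an input plate (path or mea_plate) or a scenario")
  }
  if (is.character(noisy)) noisy <- read_noisy_electrodes(noisy)
  md <- plate$metadata

  spikes <- detect_plate_spikes(plate, config$detection)
  files$spikes <- file.path(out_dir, paste0(label, "_spikes.csv"))
  write_spike_csv(spikes, files$spikes)

  wells <- names(plate$wells)
  electrodes <- electrode_labels(md$plate_type)
  trains <- spikes_to_trains(spikes, md$duration_s, wells, electrodes, noisy)

  ws <- list()
  for (w in wells) {
    sm <- sttc_matrix(trains[[w]], config$sttc, active_only = TRUE,
                      detection = config$detection)
    files[[paste0("sttc_matrix_", w)]] <-
      file.path(out_dir, paste0(label, "_STTC_matrix_", w, ".csv"))
    write.csv(as.data.frame(unclass(sm)), files[[paste0("sttc_matrix_", w)]])
    ws[[w]] <- well_stats(trains[[w]], md$duration_s, config$burst,
                          config$detection, sttc = attr(sm, "well_mean"))
  }

  div_col <- paste0("DIV", md$div)
  feat_map <- c(meanfiringrate_by_active_electrodes = "mfr_by_active_electrodes",
                nae = "nae", STTC = "sttc", bursts_per_min = "bursts_per_min",
                mean_dur = "mean_dur_s", mean_freq_in_burst = "mean_freq_in_burst",
                per_spikes_in_burst = "per_spikes_in_burst",
                mean_spikes_in_burst = "mean_spikes_in_burst")
  for (feat in names(feat_map)) {
    vals <- matrix(vapply(ws, function(s) as.numeric(s[[feat_map[[feat]]]]), 0),
                   ncol = 1, dimnames = list(names(ws), div_col))
    files[[paste0("feature_", feat)]] <-
      write_feature_table(vals, feat, label, out_dir)
  }

  if (config$corse_enabled) {
    corse_means <- rep(NA_real_, length(wells))
    names(corse_means) <- wells
    for (w in wells) {
      cm <- well_corse(plate$wells[[w]], md$sampling_frequency_hz, config$corse)
      files[[paste0("corse_matrix_", w)]] <-
        file.path(out_dir, paste0(label, "_CorSE_matrix_", w, ".csv"))
      write.csv(as.data.frame(unclass(cm)), files[[paste0("corse_matrix_", w)]])
      edges <- connectivity_map(cm, config$corse$map_threshold)
      files[[paste0("corse_map_", w)]] <-
        file.path(out_dir, paste0(label, "_CorSE_map_", w, ".csv"))
      write.csv(edges, files[[paste0("corse_map_", w)]], row.names = FALSE)
      corse_means[w] <- attr(cm, "well_mean")
    }
    files$corse_means <- file.path(out_dir, paste0(label, "_CorSE.csv"))
    write.csv(data.frame(well = wells, CorSE = corse_means),
              files$corse_means, row.names = FALSE)
  }

  stats_table <- data.frame(
    well = names(ws), div = md$div,
    mfr_by_active_electrodes = vapply(ws, `[[`, 0, "mfr_by_active_electrodes"),
    bursts_per_min = vapply(ws, `[[`, 0, "bursts_per_min"),
    mean_dur_s = vapply(ws, `[[`, 0, "mean_dur_s"),
    mean_freq_in_burst = vapply(ws, `[[`, 0, "mean_freq_in_burst"),
    mean_spikes_in_burst = vapply(ws, `[[`, 0, "mean_spikes_in_burst"),
    per_spikes_in_burst = vapply(ws, `[[`, 0, "per_spikes_in_burst"),
    sttc = vapply(ws, `[[`, 0, "sttc"),
    stringsAsFactors = FALSE
  )
  files$well_stats <- file.path(out_dir, paste0(label, "_well_stats.csv"))
  write.csv(stats_table, files$well_stats, row.names = FALSE)

  n_complete <- sum(rowSums(is.na(stats_table[, PCA_FEATURES])) == 0)
  if (n_complete >= max(3L, config$n_components)) {
    feats <- suppressMessages(assemble_features(stats_table))
    pc <- mea_pca(zscore(feats), config$n_components)
    sc <- cbind(attr(feats, "labels"), as.data.frame(pc$scores))
    files$pca_scores <- file.path(out_dir, paste0(label, "_pca_scores.csv"))
    write.csv(sc, files$pca_scores, row.names = FALSE)
  }

  manifest <- list(
    package = "meapipe",
    version = as.character(utils::packageVersion("meapipe")),
    data_label = label,
    seed = config$seed,
    config = lapply(unclass(config), function(x) if (is.list(x)) unclass(x) else x),
    plate_type = md$plate_type,
    wells = wells,
    n_spikes = nrow(spikes),
    outputs = unname(unlist(files))
  )
  files$manifest <- file.path(out_dir, paste0(label, "_manifest.json"))
  jsonlite::write_json(manifest, files$manifest, auto_unbox = TRUE, pretty = TRUE)
  invisible(files)
}
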