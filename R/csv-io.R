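#' Spike time tables
#'
#' A spike table is the long-format exchange table between the spike
#' detector and everything downstream: one row per detected spike, columns
#' `well`, `electrode`, `time_s` (seconds from recording start), sorted by
#' well, electrode, time.
#'
#' @param well,electrode Character vectors.
#' @param time_s Numeric spike times in seconds.
#' @param duration_s Optional recording duration; times must lie in
#'   `[0, duration_s]`.
#' @return Data frame of class `spike_table`.
#' @export
spike_table <- function(well = character(), electrode = character(),
                        time_s = numeric(), duration_s = NULL) {
  df <- data.frame(well = as.character(well),
                   electrode = as.character(electrode),
                   time_s = as.numeric(time_s), stringsAsFactors = FALSE)
  if (any(df$time_s < 0)) stop("negative spike times")
  if (!is.null(duration_s) && any(df$time_s > duration_s)) {
    stop("spike times beyond recording duration")
  }
  df <- df[order(df$well, df$electrode, df$time_s), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("spike_table", "data.frame")
  if (!is.null(duration_s)) attr(df, "duration_s") <- duration_s
  df
}

#' Write / read spike time CSV files
#'
#' Long-format CSV with header `well,electrode,time_s`; times are written
#' with 6-decimal precision (microsecond resolution), which round trips
#' losslessly at MEA sampling rates.
#'
#' @param spikes A `spike_table`.
#' @param path CSV file path.
#' @return `write_spike_csv` returns `path` invisibly; `read_spike_csv`
#'   returns a `spike_table`.
#' @export
write_spike_csv <- function(spikes, path) {
  df <- as.data.frame(spikes)[c("well", "electrode", "time_s")]
  df$time_s <- sprintf("%.6f", df$time_s)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_spike_csv
#' @export
read_spike_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  need <- c("well", "electrode", "time_s")
  if (!all(need %in% names(df))) {
    stop("spike CSV must have columns: ", paste(need, collapse = ", "))
  }
  t <- suppressWarnings(as.numeric(df$time_s))
  if (anyNA(t) && nrow(df)) {
    stop("unparseable time_s at line ", which(is.na(t))[1] + 1L)
  }
  spike_table(df$well, df$electrode, t)
}

#' Read a noisy-electrode list
#'
#' Electrodes flagged as artifact-ridden during acquisition; downstream
#' analysis discards them automatically. Duplicated rows are collapsed.
#'
#' @param path CSV with columns `well`, `electrode`.
#' @param plate_type Optional; if given, well labels are validated.
#' @return Data frame with columns `well`, `electrode` (unique rows).
#' @export
read_noisy_electrodes <- function(path, plate_type = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  if (nrow(df) == 0L || ncol(df) == 0L) {
    return(data.frame(well = character(), electrode = character(),
                      stringsAsFactors = FALSE))
  }
  if (!all(c("well", "electrode") %in% names(df))) {
    stop("noisy-electrode CSV must have columns well, electrode")
  }
  df <- unique(df[c("well", "electrode")])
  rownames(df) <- NULL
  if (!is.null(plate_type)) check_well_labels(df$well, plate_type, "noisy-electrode well")
  df
}

#' Read an experiment log
#'
#' The experiment log lists the wells of one plate with their group /
#' pharmacological-treatment labels.
#'
#' @param path CSV with columns `well`, `treatment`.
#' @param plate_type Optional; if given, well labels are validated.
#' @return Data frame with columns `well`, `treatment`.
#' @export
read_explog <- function(path, plate_type = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  if (!all(c("well", "treatment") %in% names(df))) {
    stop("experiment log must have columns well, treatment")
  }
  if (!is.null(plate_type)) check_well_labels(df$well, plate_type, "experiment-log well")
  df[c("well", "treatment")]
}

#' Write a per-well feature table
#'
#' One CSV per output feature, rows = wells, columns = recording days (DIV);
#' the file is named `<data_label>_<feature>.csv`. Valid feature names are
#' `meanfiringrate_by_active_electrodes`, `nae`, `STTC`, `bursts_per_min`,
#' `mean_dur`, `mean_freq_in_burst`, `per_spikes_in_burst` and
#' `mean_spikes_in_burst`. Wells whose every electrode was eliminated (no
#' value at any DIV) are omitted from the file.
#'
#' @param values Numeric matrix, rows named by well, columns by DIV.
#' @param feature Feature name (one of the list above).
#' @param data_label Recording label used as the file-name prefix.
#' @param dir Output directory.
#' @return The written file path, invisibly.
#' @export
write_feature_table <- function(values, feature, data_label, dir = ".") {
  if (!feature %in% FEATURE_NAMES) {
    stop("unknown feature '", feature, "'; valid names: ",
         paste(FEATURE_NAMES, collapse = ", "))
  }
  values <- as.matrix(values)
  keep <- rowSums(!is.na(values)) > 0L
  values <- values[keep, , drop = FALSE]
  df <- data.frame(well = rownames(values), values, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df) <- c("well", colnames(values))
  path <- file.path(dir, paste0(data_label, "_", feature, ".csv"))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @param path Path of a feature CSV to read back.
#' @export
read_feature_table <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$well
  m
}
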