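#' Recording metadata
#'
#' Acquisition metadata stored alongside the voltage traces: sampling
#' frequency, recording duration, units, culture age (days in vitro) and the
#' plate geometry, plus the lists of wells excluded from the experiment and
#' single malfunctioning electrodes that were not recorded.
#'
#' @param sampling_frequency_hz Sampling rate in Hz (default 12500, the
#'   acquisition rate of the recordings this dialect was designed for).
#' @param duration_s Recording duration in seconds.
#' @param recording_units Unit string; must be "Volts".
#' @param div Days in vitro (non-negative integer).
#' @param plate_type 12 or 48 wells per plate.
#' @param excluded_wells Character vector of well labels not recorded.
#' @param inactive_channels Data frame with columns `well`, `electrode`
#'   listing single channels absent from their wells.
#' @return An object of class `recording_metadata`.
#' @export
recording_metadata <- function(sampling_frequency_hz = 12500,
                               duration_s,
                               recording_units = "Volts",
                               div = 0L,
                               plate_type = 12L,
                               excluded_wells = character(),
                               inactive_channels = NULL) {
  plate_type <- check_plate_type(plate_type)
  if (!is.numeric(duration_s) || length(duration_s) != 1L || duration_s <= 0) {
    stop("duration_s must be a positive scalar")
  }
  if (!is.numeric(sampling_frequency_hz) || sampling_frequency_hz <= 0) {
    stop("sampling_frequency_hz must be positive")
  }
  if (!identical(recording_units, "Volts")) {
    warning("recording_units is not 'Volts': ", recording_units)
  }
  excluded_wells <- as.character(excluded_wells)
  check_well_labels(excluded_wells, plate_type, "excluded well")
  if (is.null(inactive_channels)) {
    inactive_channels <- data.frame(well = character(), electrode = character(),
                                    stringsAsFactors = FALSE)
  }
  stopifnot(all(c("well", "electrode") %in% names(inactive_channels)))
  check_well_labels(inactive_channels$well, plate_type, "inactive-channel well")
  bad <- setdiff(inactive_channels$electrode, electrode_labels(plate_type))
  if (length(bad)) stop("invalid electrode label(s): ", paste(bad, collapse = ", "))
  structure(list(
    sampling_frequency_hz = as.numeric(sampling_frequency_hz),
    duration_s = as.numeric(duration_s),
    recording_units = recording_units,
    div = as.integer(div),
    plate_type = plate_type,
    excluded_wells = excluded_wells,
    inactive_channels = inactive_channels[c("well", "electrode")]
  ), class = "recording_metadata")
}

#' Multiwell plate recording
#'
#' Container for a full plate recording: per-well, per-electrode voltage
#' traces (volts) plus acquisition metadata. Traces for excluded wells and
#' inactive channels must be absent, and every trace must span the full
#' recording duration.
#'
#' @param wells Named list (by well label) of named lists (by electrode
#'   label) of numeric voltage traces.
#' @param metadata A [recording_metadata()] object.
#' @return An object of class `mea_plate`.
#' @export
mea_plate <- function(wells, metadata) {
  plate <- structure(list(wells = wells, metadata = metadata), class = "mea_plate")
  validate_plate(plate)
  plate
}

#' Validate a plate recording against its invariants
#'
#' @param plate An `mea_plate` object.
#' @return The plate, invisibly; stops with the offending well/electrode on
#'   violation.
#' @export
validate_plate <- function(plate) {
  md <- plate$metadata
  n_expected <- round(md$duration_s * md$sampling_frequency_hz)
  valid_wells <- well_labels(md$plate_type)
  check_well_labels(names(plate$wells), md$plate_type)
  for (w in intersect(names(plate$wells), md$excluded_wells)) {
    stop("well ", w, " is listed in excluded_wells but has traces")
  }
  valid_el <- electrode_labels(md$plate_type)
  for (w in names(plate$wells)) {
    el <- plate$wells[[w]]
    bad <- setdiff(names(el), valid_el)
    if (length(bad)) stop("well ", w, ": invalid electrode label(s) ",
                          paste(bad, collapse = ", "))
    inact <- md$inactive_channels$electrode[md$inactive_channels$well == w]
    hit <- intersect(names(el), inact)
    if (length(hit)) stop("well ", w, ": inactive electrode(s) present: ",
                          paste(hit, collapse = ", "))
    for (e in names(el)) {
      if (length(el[[e]]) != n_expected) {
        stop("well ", w, " electrode ", e, ": trace length ", length(el[[e]]),
             " != round(duration_s * fs) = ", n_expected)
      }
    }
  }
  invisible(plate)
}

#' @export
print.mea_plate <- function(x, ...) {
  md <- x$metadata
  cat("mea_plate:", md$plate_type, "-well recording,", md$duration_s, "s at",
      md$sampling_frequency_hz, "Hz, DIV", md$div, "\n")
  cat("  wells present:", length(x$wells),
      " excluded:", length(md$excluded_wells),
      " inactive channels:", nrow(md$inactive_channels), "\n")
  invisible(x)
}

#' Write a plate recording to HDF5
#'
#' Writes the plate in a dialect with two top-level groups: `/Data` holds one
#' subgroup per recorded well (e.g. `/Data/A3`) each containing one dataset
#' per electrode (e.g. `/Data/A3/22`, a voltage time series stored as 32-bit
#' float); `/DataInfo` holds the datasets `ExcludedWells` and
#' `InactiveChannels` and the attributes `SamplingFrequencyInHz`,
#' `DurationInSec`, `RecordingUnits`, `DIV` and `Plate type`. All HDF5 paths
#' use forward slashes.
#'
#' @param plate An `mea_plate` object.
#' @param path Output file path (overwritten if present).
#' @return `path`, invisibly.
#' @export
write_plate <- function(plate, path) {
  validate_plate(plate)
  md <- plate$metadata
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  rhdf5::h5createGroup(path, "Data")
  for (w in names(plate$wells)) {
    rhdf5::h5createGroup(path, paste0("Data/", w))
    for (e in names(plate$wells[[w]])) {
      ds <- paste0("Data/", w, "/", e)
      rhdf5::h5createDataset(path, ds, dims = length(plate$wells[[w]][[e]]),
                             H5type = "H5T_IEEE_F32LE", level = 0)
      rhdf5::h5write(plate$wells[[w]][[e]], path, ds)
    }
  }
  rhdf5::h5createGroup(path, "DataInfo")
  rhdf5::h5write(md$excluded_wells, path, "DataInfo/ExcludedWells")
  ic <- md$inactive_channels
  rhdf5::h5write(paste(ic$well, ic$electrode, sep = "/"),
                 path, "DataInfo/InactiveChannels")
  fid <- rhdf5::H5Fopen(path)
  gid <- rhdf5::H5Gopen(fid, "DataInfo")
  rhdf5::h5writeAttribute(md$sampling_frequency_hz, gid, "SamplingFrequencyInHz")
  rhdf5::h5writeAttribute(md$duration_s, gid, "DurationInSec")
  rhdf5::h5writeAttribute(md$recording_units, gid, "RecordingUnits")
  rhdf5::h5writeAttribute(md$div, gid, "DIV")
  rhdf5::h5writeAttribute(md$plate_type, gid, "Plate type")
  rhdf5::H5Gclose(gid)
  rhdf5::H5Fclose(fid)
  invisible(path)
}

#' Read a plate recording from HDF5
#'
#' Reads a file written in the dialect of [write_plate()]. A file missing the
#' `/Data` or `/DataInfo` group, or any of the five metadata attributes, is
#' rejected with an error naming the missing piece. A `RecordingUnits`
#' attribute other than "Volts" produces a warning, not a failure.
#'
#' @param path Path to the HDF5 file.
#' @return An `mea_plate` object.
#' @export
read_plate <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  ls <- rhdf5::h5ls(path)
  top <- ls$name[ls$group == "/"]
  for (g in c("Data", "DataInfo")) {
    if (!g %in% top) stop("not a plate recording: missing '/", g, "' group")
  }
  at <- rhdf5::h5readAttributes(path, "DataInfo")
  for (a in c("SamplingFrequencyInHz", "DurationInSec", "RecordingUnits",
              "DIV", "Plate type")) {
    if (is.null(at[[a]])) stop("missing '/DataInfo' attribute: ", a)
  }
  excluded <- read_string_dataset(path, "DataInfo/ExcludedWells")
  ic_raw <- read_string_dataset(path, "DataInfo/InactiveChannels")
  parts <- strsplit(ic_raw, "/", fixed = TRUE)
  ic <- data.frame(
    well = vapply(parts, `[`, "", 1L),
    electrode = vapply(parts, `[`, "", 2L),
    stringsAsFactors = FALSE
  )
  md <- recording_metadata(
    sampling_frequency_hz = as.numeric(at$SamplingFrequencyInHz),
    duration_s = as.numeric(at$DurationInSec),
    recording_units = as.character(at$RecordingUnits),
    div = as.integer(at$DIV),
    plate_type = as.integer(at[["Plate type"]]),
    excluded_wells = excluded,
    inactive_channels = ic
  )
  wells_present <- ls$name[ls$group == "/Data" & ls$otype == "H5I_GROUP"]
  wells <- list()
  for (w in sort(wells_present)) {
    el_names <- sort(ls$name[ls$group == paste0("/Data/", w)])
    wells[[w]] <- lapply(stats::setNames(el_names, el_names), function(e) {
      as.numeric(rhdf5::h5read(path, paste0("Data/", w, "/", e)))
    })
  }
  mea_plate(wells, md)
}

read_string_dataset <- function(path, name) {
  x <- tryCatch(as.character(rhdf5::h5read(path, name)), error = function(e) character())
  x[!is.na(x) & nzchar(x)]
}

#' Extract one electrode trace from a plate
#'
#' Mirrors direct HDF5 addressing: asking for a well listed in
#' `ExcludedWells`, or an electrode listed in `InactiveChannels`, raises a
#' lookup error, just as reading the absent dataset from the file would.
#'
#' @param plate An `mea_plate`.
#' @param well,electrode Labels.
#' @return Numeric voltage trace.
#' @export
plate_trace <- function(plate, well, electrode) {
  md <- plate$metadata
  if (well %in% md$excluded_wells) {
    stop("well ", well, " is excluded from this recording")
  }
  ic <- md$inactive_channels
  if (any(ic$well == well & ic$electrode == electrode)) {
    stop("electrode ", well, "/", electrode, " is listed as inactive")
  }
  tr <- plate$wells[[well]][[electrode]]
  if (is.null(tr)) stop("no trace for ", well, "/", electrode)
  tr
}
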