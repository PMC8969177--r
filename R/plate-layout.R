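#' Well labels for a plate type
#'
#' Multiwell MEA plates come in two geometries: a 12-well plate (3 x 4 wells,
#' 64 recording electrodes per well) and a 48-well plate (6 x 8 wells, 16
#' electrodes per well). Wells are labelled row letter + column number
#' ("A1" ... "C4" or "A1" ... "F8").
#'
#' @param plate_type Integer, 12 or 48.
#' @return Character vector of well labels in row-major order.
#' @export
well_labels <- function(plate_type) {
  plate_type <- check_plate_type(plate_type)
  if (plate_type == 12L) {
    rows <- LETTERS[1:3]; cols <- 1:4
  } else {
    rows <- LETTERS[1:6]; cols <- 1:8
  }
  as.vector(t(outer(rows, cols, paste0)))
}

#' Electrode labels for a plate type
#'
#' Electrodes are addressed by two-digit row-column strings on a square grid:
#' "11".."88" for the 64-electrode wells of a 12-well plate, "11".."44" for
#' the 16-electrode wells of a 48-well plate.
#'
#' @inheritParams well_labels
#' @return Character vector of electrode labels.
#' @export
electrode_labels <- function(plate_type) {
  plate_type <- check_plate_type(plate_type)
  n <- if (plate_type == 12L) 8L else 4L
  as.vector(t(outer(seq_len(n), seq_len(n), paste0)))
}

#' Electrode grid coordinates
#'
#' Maps electrode labels to (column, row) positions on the physical grid,
#' used for laying out connectivity maps.
#'
#' @param labels Character vector of two-digit electrode labels.
#' @return Data frame with columns `electrode`, `x` (column), `y` (row).
#' @export
electrode_positions <- function(labels) {
  data.frame(
    electrode = labels,
    x = as.integer(substr(labels, 2, 2)),
    y = as.integer(substr(labels, 1, 1)),
    stringsAsFactors = FALSE
  )
}

check_plate_type <- function(plate_type) {
  pt <- suppressWarnings(as.integer(plate_type))
  if (length(pt) != 1L || is.na(pt) || !pt %in% c(12L, 48L)) {
    stop("plate_type must be 12 or 48, got: ", paste(plate_type, collapse = ","))
  }
  pt
}

check_well_labels <- function(wells, plate_type, what = "well") {
  valid <- well_labels(plate_type)
  bad <- setdiff(wells, valid)
  if (length(bad)) {
    stop("invalid ", what, " label(s) for ", plate_type, "-well plate: ",
         paste(bad, collapse = ", "))
  }
  invisible(wells)
}
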