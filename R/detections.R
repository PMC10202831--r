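#' Detected fluorescent objects
#'
#' A detection table holds one row per diffraction-limited fluorescent object
#' (an RNP or a reporter molecule) with its position in micrometers, raw
#' intensity, channel, compartment and specimen of origin. This is the
#' contract input of the pipeline: spot segmentation happens upstream.
#'
#' @section Columns:
#' \describe{
#'   \item{id}{opaque object identifier (unique within a specimen/channel)}
#'   \item{specimen_id}{opaque specimen identifier}
#'   \item{channel}{`"rna"` or `"reporter"`}
#'   \item{x, y, z}{coordinates in µm (`z` optional, `NA` for 2D data)}
#'   \item{intensity}{raw fluorescence, arbitrary units, >= 0}
#'   \item{compartment}{`"nurse_cell"`, `"oocyte"`, `"follicle_cell"` or
#'     `"excluded"`}
#'   \item{stage}{ordinal stage label, e.g. `"5-7"`, `"9"` (may be `NA`)}
#' }
#' @name detections
NULL

.channels <- c("rna", "reporter")
.compartments <- c("nurse_cell", "oocyte", "follicle_cell", "excluded")
.det_required <- c("id", "specimen_id", "channel", "x", "y", "intensity",
                   "compartment")

#' Construct and validate a detection table
#'
#' @param df data.frame with at least the required columns (see
#'   [detections]); `z` and `stage` are added as `NA` when absent. Unknown
#'   compartment labels are mapped to `"excluded"` with a warning.
#' @return The validated data.frame with class `rnp_detections`.
#' @examples
#' d <- as_detections(data.frame(
#'   id = 1:2, specimen_id = "s1", channel = c("rna", "reporter"),
#'   x = c(0, 1), y = c(0, 0), intensity = c(100, 50),
#'   compartment = "oocyte"))
#' @export
as_detections <- function(df) {
  if (!is.data.frame(df)) {
    stop_rnp("detections must be a data.frame", class = "rnp_schema_error")
  }
  missing_cols <- setdiff(.det_required, names(df))
  if (length(missing_cols)) {
    stop_rnp("missing required column(s): %s",
             paste(missing_cols, collapse = ", "),
             class = "rnp_schema_error")
  }
  if (!"z" %in% names(df)) df$z <- rep(NA_real_, nrow(df))
  if (!"stage" %in% names(df)) df$stage <- rep(NA_character_, nrow(df))
  df$channel <- as.character(df$channel)
  df$compartment <- as.character(df$compartment)
  df$stage <- as.character(df$stage)

  if (nrow(df) > 0) {
    for (col in c("x", "y", "intensity")) {
      v <- df[[col]]
      if (!is.numeric(v) || any(!is.finite(v))) {
        bad <- if (is.numeric(v)) which(!is.finite(v)) else seq_len(nrow(df))
        stop_rnp("non-finite or non-numeric '%s' in row(s) %s", col,
                 paste(head(bad, 5), collapse = ", "),
                 class = "rnp_parse_error")
      }
    }
    if (any(df$intensity < 0)) {
      stop_rnp("intensity must be >= 0 (row %d)", which(df$intensity < 0)[1],
               class = "rnp_validation_error")
    }
    bad_chan <- !df$channel %in% .channels
    if (any(bad_chan)) {
      stop_rnp("unknown channel '%s'; must be one of: %s",
               df$channel[bad_chan][1], paste(.channels, collapse = ", "),
               class = "rnp_validation_error")
    }
    bad_comp <- !df$compartment %in% .compartments
    if (any(bad_comp)) {
      warning(sprintf(
        "%d detection(s) with unknown compartment label(s) (%s) mapped to 'excluded'",
        sum(bad_comp),
        paste(unique(df$compartment[bad_comp]), collapse = ", ")))
      df$compartment[bad_comp] <- "excluded"
    }
  }
  canonical <- c(.det_required[1:5], "z", "intensity", "compartment", "stage")
  df <- df[, c(canonical, setdiff(names(df), canonical))]
  class(df) <- c("rnp_detections", "data.frame")
  df
}

#' Read a detection table from CSV
#'
#' The CSV dialect is comma-separated with a header row, UTF-8, `.` decimal.
#'
#' @param path path to a CSV file with the columns documented in
#'   [detections].
#' @return an `rnp_detections` data.frame (possibly with zero rows).
#' @seealso [write_detections()]
#' @export
read_detections <- function(path) {
  if (!file.exists(path)) {
    stop_rnp("file not found: %s", path, class = "rnp_io_error")
  }
  df <- read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  as_detections(df)
}

#' Write a detection table to CSV
#'
#' Round-trips with [read_detections()]: all fields are preserved.
#'
#' @param detections an `rnp_detections` data.frame.
#' @param path output CSV path.
#' @export
write_detections <- function(detections, path) {
  detections <- as_detections(detections)
  write.csv(detections, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

# Drop detections in the 'excluded' compartment; all downstream analyses
# operate on the remaining compartments only.
drop_excluded <- function(detections) {
  detections[detections$compartment != "excluded", , drop = FALSE]
}
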