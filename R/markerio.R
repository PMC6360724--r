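# Marker-trajectory IO: trial container, TRC-like TSV reader/writer,
# marker-set schema and validation.

#' Marker trajectory trial
#'
#' Container for a labelled block of 3D marker trajectories.
#'
#' @param data Numeric array, frames x markers x 3 (XYZ), millimetres. `NA`
#'   entries are treated as gaps and flagged.
#' @param markers Character vector of marker names (length = dim 2 of `data`).
#' @param rate Sampling rate in Hz.
#' @param label Condition tag, one of `trial_labels()`.
#' @param units Coordinate units of `data`; `"m"` is converted to mm.
#' @param up_axis Which lab axis is vertical, `"x"`, `"y"` or `"z"`.
#' @param side Instrumented limb, `"right"` or `"left"`.
#' @return An object of class `"trial"`: list with elements `label`, `rate`,
#'   `markers`, `data` (mm, gaps as 0), `gaps` (frames x markers logical),
#'   `units` (always `"mm"`), `up_axis`, `side`.
#' @export
trial <- function(data, markers, rate, label = "natural", units = "mm",
                  up_axis = "z", side = "right") {
  if (!label %in% trial_labels())
    stop("unknown trial label '", label, "'", call. = FALSE)
  if (!is.numeric(rate) || length(rate) != 1L || !is.finite(rate) || rate <= 0)
    stop("rate must be a single positive number (Hz)", call. = FALSE)
  if (length(dim(data)) != 3L || dim(data)[3] != 3L)
    stop("data must be a frames x markers x 3 array", call. = FALSE)
  if (length(markers) != dim(data)[2])
    stop("marker names (", length(markers), ") do not match data columns (",
         dim(data)[2], ")", call. = FALSE)
  if (anyDuplicated(markers))
    stop("duplicate marker names: ",
         paste(unique(markers[duplicated(markers)]), collapse = ", "),
         call. = FALSE)
  if (!up_axis %in% c("x", "y", "z"))
    stop("up_axis must be 'x', 'y' or 'z'", call. = FALSE)
  if (!side %in% c("right", "left"))
    stop("side must be 'right' or 'left'", call. = FALSE)
  units <- match.arg(units, c("mm", "m"))
  if (units == "m") data <- data * 1000
  gaps <- apply(is.na(data), c(1, 2), any)
  data[is.na(data)] <- 0
  if (!all(is.finite(data)))
    stop("coordinates must be finite (gaps are encoded as NA)", call. = FALSE)
  dimnames(data) <- list(NULL, markers, c("X", "Y", "Z"))
  structure(list(label = label, rate = rate, markers = as.character(markers),
                 data = data, gaps = gaps, units = "mm",
                 up_axis = up_axis, side = side),
            class = "trial")
}

#' Recognised trial condition labels
#' @return Character vector of valid labels.
#' @export
trial_labels <- function() {
  c("natural", "functional_turnout", "forced_turnout", "saute", "lunge",
    "squat_circumduction", "seated_passive_er", "seated_active_er")
}

#' @export
print.trial <- function(x, ...) {
  cat("<trial>", x$label, "|", dim(x$data)[1], "frames x",
      dim(x$data)[2], "markers @", x$rate, "Hz |", x$side, "side, up =",
      x$up_axis, "\n")
  ngap <- sum(x$gaps)
  if (ngap > 0) cat("  gaps:", ngap, "marker-frames flagged\n")
  invisible(x)
}

#' Number of frames in a trial
#' @param trial A [trial()] object.
#' @export
n_frames <- function(trial) dim(trial$data)[1]

#' Extract one marker's trajectory
#' @param trial A [trial()] object.
#' @param name Marker name.
#' @return frames x 3 matrix (mm); gap frames are `NA`.
#' @export
marker_xyz <- function(trial, name) {
  if (!name %in% trial$markers) stop("marker '", name, "' not in trial", call. = FALSE)
  m <- trial$data[, name, , drop = FALSE]
  m <- matrix(m, ncol = 3, dimnames = list(NULL, c("X", "Y", "Z")))
  m[trial$gaps[, match(name, trial$markers)], ] <- NA_real_
  m
}

#' Vertical coordinate of a marker
#' @inheritParams marker_xyz
#' @return Numeric vector (mm) along the trial's declared up axis.
#' @export
marker_height <- function(trial, name) {
  marker_xyz(trial, name)[, c(x = 1L, y = 2L, z = 3L)[trial$up_axis]]
}

# ---------------------------------------------------------------------------
# Marker-set schema

#' Default marker-set schema
#'
#' Names the anatomical (calibration) and technical (tracking cluster) markers
#' per segment, and the virtual markers with their owning segment. The
#' hindfoot carries CAL/SUS/HDL, the first metatarsal MTB1/MTS1/MTS2 with MT1
#' as a calibrated head marker, the forefoot MT2/MT5/FFM, the midfoot the
#' navicular tuberosity NAV plus CUB/MFM, the hallux a single HAL marker.
#'
#' @param side `"right"` or `"left"` instrumented limb.
#' @return An object of class `"marker_schema"`.
#' @export
default_marker_schema <- function(side = "right") {
  side <- match.arg(side, c("right", "left"))
  segments <- list(
    pelvis           = list(anatomical = character(0),
                            technical = c("PELV1", "PELV2", "PELV3")),
    thigh            = list(anatomical = c("LFC", "MFC"),
                            technical = c("THI1", "THI2", "THI3")),
    tibia            = list(anatomical = c("LMAL", "MMAL"),
                            technical = c("TIB1", "TIB2", "TIB3")),
    hindfoot         = list(anatomical = c("CAL", "SUS", "HDL", "CALe"),
                            technical = c("CAL", "SUS", "HDL")),
    midfoot          = list(anatomical = c("NAV"),
                            technical = c("NAV", "CUB", "MFM")),
    forefoot         = list(anatomical = c("MT5"),
                            technical = c("MT2", "MT5", "FFM")),
    first_metatarsal = list(anatomical = c("MTB1", "MT1", "MTS1", "MTS2"),
                            technical = c("MTB1", "MTS1", "MTS2")),
    hallux           = list(anatomical = c("HAL"),
                            technical = c("HAL"))
  )
  virtual <- c(LMAL = "tibia", MMAL = "tibia", CALe = "hindfoot",
               MT1 = "first_metatarsal", MidMet = "first_metatarsal",
               X_MET = "first_metatarsal", FTML = "forefoot", KJC = "thigh")
  structure(list(segments = segments, virtual_markers = virtual, side = side),
            class = "marker_schema")
}

#' @export
print.marker_schema <- function(x, ...) {
  cat("<marker_schema>", length(x$segments), "segments,",
      length(x$virtual_markers), "virtual markers,", x$side, "side\n")
  invisible(x)
}

#' Markers a schema requires on disk
#'
#' Physical (non-virtual) markers per segment. Virtual markers (reconstructed
#' by CAST) are excluded except in calibration trials, where the calibration
#' markers are physically present.
#'
#' @param schema A [default_marker_schema()] object.
#' @param calibration If `TRUE`, include calibration-only markers
#'   (malleoli, CALe, MT1, femoral condyles).
#' @return Character vector of marker names.
#' @export
schema_required_markers <- function(schema, calibration = FALSE) {
  tech <- unique(unlist(lapply(schema$segments, `[[`, "technical")))
  if (!calibration) return(tech)
  anat <- unique(unlist(lapply(schema$segments, `[[`, "anatomical")))
  unique(c(tech, anat))
}

#' Validate a trial against a marker schema
#'
#' Report-only check: lists missing required markers per segment and the gap
#' fraction per marker. Passes iff no required marker is missing and every
#' required marker's gap fraction is at or below `gap_threshold`.
#'
#' @param trial A [trial()] object.
#' @param schema A [default_marker_schema()] object.
#' @param gap_threshold Maximum tolerated gap fraction per marker.
#' @param calibration Validate against the calibration marker set (see
#'   [schema_required_markers()]).
#' @return List with `pass`, `missing` (character), `gap_fraction` (named
#'   numeric for required markers present), `warnings` (character).
#' @export
validate_trial <- function(trial, schema, gap_threshold = 0.05,
                           calibration = FALSE) {
  required <- schema_required_markers(schema, calibration = calibration)
  missing <- setdiff(required, trial$markers)
  present <- intersect(required, trial$markers)
  gf <- colMeans(trial$gaps)[match(present, trial$markers)]
  names(gf) <- present
  warnings <- character(0)
  over <- gf[gf > gap_threshold]
  if (length(over))
    warnings <- paste0("gap fraction above threshold for ",
                       paste(names(over), collapse = ", "))
  partial <- gf[gf > 0 & gf <= gap_threshold]
  if (length(partial))
    warnings <- c(warnings,
                  paste0("gaps present (within threshold) for ",
                         paste(names(partial), collapse = ", ")))
  list(pass = length(missing) == 0L && all(gf <= gap_threshold),
       missing = missing, gap_fraction = gf, warnings = warnings)
}

# ---------------------------------------------------------------------------
# TRC-like tab-separated on-disk format.
#
# Header (key<TAB>value): rate_hz, units, up_axis, label, side; then a column
# row `frame  time  <M>_X <M>_Y <M>_Z ...`; gaps are written as NA.

#' Write a trial to the canonical TSV format
#'
#' Tab-separated, '.' decimal, header keys `rate_hz`, `units`, `up_axis`,
#' `label`, `side`; coordinates at 1e-9 mm precision; gaps as `NA`.
#'
#' @param trial A [trial()] object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trial <- function(trial, path) {
  con <- tryCatch(file(path, open = "wt"),
                  error = function(e) stop("cannot open '", path,
                                           "' for writing", call. = FALSE))
  on.exit(close(con))
  writeLines(c(paste0("rate_hz\t", format(trial$rate, digits = 15)),
               "units\tmm",
               paste0("up_axis\t", trial$up_axis),
               paste0("label\t", trial$label),
               paste0("side\t", trial$side)), con)
  cols <- as.vector(t(outer(trial$markers, c("X", "Y", "Z"), paste, sep = "_")))
  writeLines(paste(c("frame", "time", cols), collapse = "\t"), con)
  nf <- n_frames(trial)
  flat <- matrix(aperm(trial$data, c(3, 2, 1)), nrow = 3 * length(trial$markers))
  flat <- t(flat)  # frames x (3*markers), X,Y,Z grouped per marker
  gap3 <- trial$gaps[, rep(seq_along(trial$markers), each = 3), drop = FALSE]
  body <- matrix(sprintf("%.9f", flat), nrow = nf)
  body[gap3] <- "NA"
  lines <- paste(0:(nf - 1),
                 sprintf("%.9f", (0:(nf - 1)) / trial$rate),
                 apply(body, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(lines, con)
  invisible(path)
}

#' Read a trial from disk
#'
#' @param path File path.
#' @param format `"tsv"` (canonical format, see [write_trial()]). `"c3d"` is
#'   not supported by this build and raises an error.
#' @return A [trial()] object.
#' @export
read_trial <- function(path, format = "tsv") {
  format <- match.arg(format, c("tsv", "c3d"))
  if (format == "c3d")
    stop("C3D input is not supported; convert to the canonical TSV format",
         call. = FALSE)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  hdr <- list()
  i <- 1L
  while (i <= length(lines) && !startsWith(lines[i], "frame\t")) {
    kv <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(kv) == 2L) hdr[[kv[1]]] <- kv[2]
    i <- i + 1L
  }
  for (key in c("rate_hz", "units", "up_axis"))
    if (is.null(hdr[[key]]))
      stop("format error: missing header field '", key, "'", call. = FALSE)
  if (i > length(lines)) stop("format error: no column header row", call. = FALSE)
  cols <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
  coord_cols <- cols[-(1:2)]
  if (length(coord_cols) %% 3L != 0L)
    stop("format error: coordinate columns not in X/Y/Z triples", call. = FALSE)
  markers <- sub("_X$", "", coord_cols[seq(1, length(coord_cols), by = 3)])
  if (anyDuplicated(markers))
    stop("schema error: duplicate marker names in header", call. = FALSE)
  body <- lines[-seq_len(i)]
  body <- body[nzchar(body)]
  toks <- unlist(strsplit(body, "\t", fixed = TRUE))
  toks[toks == "NA"] <- NA_character_
  vals <- matrix(as.numeric(toks), nrow = length(body), byrow = TRUE)
  coords <- vals[, -(1:2), drop = FALSE]
  arr <- aperm(array(t(coords), dim = c(3, length(markers), nrow(coords))),
               c(3, 2, 1))
  trial(arr, markers,
        rate = as.numeric(hdr$rate_hz),
        label = if (is.null(hdr$label)) "natural" else hdr$label,
        units = hdr$units,
        up_axis = hdr$up_axis,
        side = if (is.null(hdr$side)) "right" else hdr$side)
}
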