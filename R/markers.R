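#' Marker trajectory sets
#'
#' A `marker_set` is a tibble holding one row per captured frame with a
#' `frame` index, a `time` column (seconds) and three coordinate columns per
#' marker named `<LABEL>_x`, `<LABEL>_y`, `<LABEL>_z` (metres, lab axes).
#' Attributes carry the sampling `rate` (Hz) and an `axis_map` naming which
#' lab axis is medio-lateral (`ml`), antero-posterior (`ap`) and vertical
#' (`vert`). Invisible markers are recorded as `NA` coordinates.
#'
#' @param data A data frame with `time` and `<LABEL>_x/_y/_z` columns.
#'   A `frame` column is added when absent.
#' @param rate Sampling frequency in Hz (must be positive).
#' @param axis_map Named character vector with entries `ml`, `ap`, `vert`
#'   mapping the three body directions onto distinct lab axes
#'   (`"x"`, `"y"`, `"z"`). Default: lab x is medio-lateral, y is the
#'   direction of travel, z is vertical.
#' @return A `marker_set` tibble.
#' @examples
#' tr <- simulate_marker_gait(zeta = 0.1, cadence = 50, n_trials = 1, seed = 1)
#' tr$trials[[1]]
#' @export
marker_set <- function(data, rate,
                       axis_map = c(ml = "x", ap = "y", vert = "z")) {
  if (!is.data.frame(data)) {
    stop_validation("`data` must be a data frame of marker coordinates.")
  }
  if (!is_scalar_number(rate) || rate <= 0) {
    stop_validation("`rate` must be a single positive number (Hz).")
  }
  axis_map <- validate_axis_map(axis_map)
  data <- as_tibble(data)
  if (!"time" %in% names(data)) {
    stop_validation("marker data must contain a `time` column (seconds).")
  }
  if (!"frame" %in% names(data)) {
    data <- dplyr::mutate(data, frame = dplyr::row_number(), .before = 1L)
  }
  labels <- marker_labels_from_names(names(data))
  if (length(labels) == 0L) {
    stop_validation("no `<LABEL>_x/_y/_z` marker columns found.")
  }
  coord_cols <- as.vector(t(outer(labels, c("x", "y", "z"), paste, sep = "_")))
  out <- data[, c("frame", "time", coord_cols)]
  structure(out,
            class = c("marker_set", class(tibble())),
            rate = rate, axis_map = axis_map, labels = labels)
}

validate_axis_map <- function(axis_map) {
  axis_map <- unlist(axis_map)
  need <- c("ml", "ap", "vert")
  if (!all(need %in% names(axis_map))) {
    stop_validation("`axis_map` must name the `ml`, `ap` and `vert` axes.")
  }
  axis_map <- axis_map[need]
  if (!all(axis_map %in% c("x", "y", "z")) || anyDuplicated(axis_map)) {
    stop_validation("`axis_map` must assign three distinct lab axes x/y/z.")
  }
  axis_map
}

marker_labels_from_names <- function(nms) {
  hits <- grep("_[xyz]$", nms, value = TRUE)
  unique(sub("_[xyz]$", "", hits))
}

#' @export
print.marker_set <- function(x, ...) {
  cat(sprintf("<marker_set> %d frames at %g Hz, %d markers (%s)\n",
              nrow(x), attr(x, "rate"), length(attr(x, "labels")),
              paste(attr(x, "labels"), collapse = ", ")))
  NextMethod()
}

#' @rdname marker_set
#' @param x A `marker_set`.
#' @export
marker_rate <- function(x) attr(x, "rate")

#' @rdname marker_set
#' @export
marker_names <- function(x) attr(x, "labels")

#' @rdname marker_set
#' @export
axis_map <- function(x) attr(x, "axis_map")

# Coordinate vector of one marker along one body axis ("ml", "ap", "vert").
marker_axis <- function(mts, label, axis) {
  lab_axis <- attr(mts, "axis_map")[[axis]]
  col <- paste0(label, "_", lab_axis)
  if (!col %in% names(mts)) {
    stop_validation(sprintf("marker `%s` not present in this marker set.",
                            label))
  }
  mts[[col]]
}

check_markers_present <- function(mts, required, context = "this operation") {
  missing <- setdiff(required, marker_names(mts))
  if (length(missing) > 0L) {
    stop_validation(sprintf("missing required marker(s) for %s: %s",
                            context, paste(missing, collapse = ", ")),
                    missing_markers = missing)
  }
  invisible(mts)
}

# Default alias table: lab naming conventions vary, so common synonyms are
# folded onto the canonical labels. Matching is case-insensitive.
default_marker_aliases <- function() {
  list(
    RHEE = c("RHEE", "R_HEEL", "RHEEL", "RIGHT_HEEL"),
    LHEE = c("LHEE", "L_HEEL", "LHEEL", "LEFT_HEEL"),
    RPSI = c("RPSI", "R_PSIS", "RPSIS"),
    LPSI = c("LPSI", "L_PSIS", "LPSIS"),
    RASI = c("RASI", "R_ASIS", "RASIS"),
    LASI = c("LASI", "L_ASIS", "LASIS")
  )
}

canonicalize_label <- function(label, aliases) {
  up <- toupper(label)
  for (canon in names(aliases)) {
    if (up %in% toupper(aliases[[canon]])) {
      return(canon)
    }
  }
  up
}

#' Read marker trajectories from a TRC or wide-CSV file
#'
#' Supported dialects are the tab-delimited TRC format used by motion-capture
#' software and a wide CSV with a `time` column plus `<MARKER>_X`,
#' `<MARKER>_Y`, `<MARKER>_Z` columns. Marker labels are matched
#' case-insensitively through an alias table and renamed to the canonical
#' labels (RHEE, LHEE, RPSI, LPSI, RASI, LASI, ...). Coordinates are converted
#' to metres (TRC files declare their units; CSV defaults to metres).
#'
#' @param path Path to the file.
#' @param format `"auto"` (by extension), `"trc"` or `"csv"`.
#' @param rate Sampling rate in Hz. For TRC it defaults to the file's
#'   `DataRate`; for CSV it is inferred from the `time` column when omitted.
#' @param units `"m"` or `"mm"`; overrides file metadata when given.
#' @param axis_map See [marker_set()].
#' @param aliases Named list mapping canonical labels to accepted synonyms.
#' @param required Marker labels that must be present; a validation error
#'   naming the absent labels is raised otherwise. Use `character()` to skip.
#' @return A [marker_set()].
#' @export
read_marker_file <- function(path, format = c("auto", "trc", "csv"),
                             rate = NULL, units = NULL,
                             axis_map = c(ml = "x", ap = "y", vert = "z"),
                             aliases = default_marker_aliases(),
                             required = REQUIRED_MARKERS) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    stop_format(sprintf("file not found: %s", path))
  }
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(path)),
                     trc = "trc", csv = "csv",
                     stop_format(sprintf(
                       "cannot infer format from extension of `%s`;
 pass `format` explicitly.", basename(path))))
  }
  mts <- switch(format,
                trc = read_marker_trc(path, rate, units, axis_map, aliases),
                csv = read_marker_csv(path, rate, units, axis_map, aliases))
  if (length(required) > 0L) {
    check_markers_present(mts, required, context = basename(path))
  }
  mts
}

read_marker_csv <- function(path, rate, units, axis_map, aliases) {
  dat <- tryCatch(
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE),
    error = function(e) stop_format(sprintf(
      "failed to parse CSV `%s`: %s", basename(path), conditionMessage(e))))
  names(dat) <- sub("^Time$", "time", names(dat), ignore.case = TRUE)
  if (!"time" %in% names(dat)) {
    stop_format(sprintf("CSV `%s` has no `time` column.", basename(path)))
  }
  coord_cols <- grep("_[XYZxyz]$", names(dat), value = TRUE)
  if (length(coord_cols) == 0L) {
    stop_format(sprintf("CSV `%s` has no `<MARKER>_X/_Y/_Z` columns.",
                        basename(path)))
  }
  lab <- sub("_[XYZxyz]$", "", coord_cols)
  ax <- tolower(sub("^.*_", "", coord_cols))
  canon <- vapply(lab, canonicalize_label, character(1), aliases = aliases)
  out <- dat[c("time", coord_cols)]
  names(out) <- c("time", paste0(canon, "_", ax))
  if (is.null(rate)) {
    dt <- median(diff(out$time))
    if (!is.finite(dt) || dt <= 0) {
      stop_format("cannot infer sampling rate from the `time` column.")
    }
    rate <- 1 / dt
  }
  scale <- unit_scale(units %||% "m")
  out[-1] <- lapply(out[-1], function(v) v * scale)
  marker_set(out, rate = rate, axis_map = axis_map)
}

unit_scale <- function(units) {
  switch(units,
         m = 1, mm = 1e-3, cm = 1e-2,
         stop_validation(sprintf("unsupported units `%s`.", units)))
}

read_marker_trc <- function(path, rate, units, axis_map, aliases) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 6L) {
    stop_format(sprintf("TRC `%s` is truncated.", basename(path)))
  }
  meta_keys <- strsplit(lines[2], "\t")[[1]]
  meta_vals <- strsplit(lines[3], "\t")[[1]]
  meta <- setNames(as.list(meta_vals), meta_keys)
  file_rate <- suppressWarnings(as.numeric(meta[["DataRate"]]))
  file_units <- meta[["Units"]] %||% "mm"
  header <- strsplit(lines[4], "\t")[[1]]
  labels <- header[-(1:2)]
  labels <- labels[nzchar(labels)]
  if (length(labels) == 0L) {
    stop_format(sprintf("TRC `%s`: no marker labels on header line 4.",
                        basename(path)))
  }
  canon <- vapply(labels, canonicalize_label, character(1), aliases = aliases)
  data_lines <- lines[-(1:5)]
  data_lines <- data_lines[nzchar(trimws(data_lines))]
  fields <- strsplit(data_lines, "\t")
  ncol_expected <- 2L + 3L * length(labels)
  mat <- t(vapply(fields, function(f) {
    f <- f[seq_len(ncol_expected)]
    suppressWarnings(as.numeric(f))
  }, numeric(ncol_expected)))
  scale <- unit_scale(units %||% tolower(file_units))
  coords <- mat[, -(1:2), drop = FALSE] * scale
  out <- tibble(frame = as.integer(mat[, 1]), time = mat[, 2])
  for (j in seq_along(canon)) {
    out[[paste0(canon[j], "_x")]] <- coords[, 3 * j - 2]
    out[[paste0(canon[j], "_y")]] <- coords[, 3 * j - 1]
    out[[paste0(canon[j], "_z")]] <- coords[, 3 * j]
  }
  rate <- rate %||% file_rate
  if (is.null(rate) || !is.finite(rate)) {
    stop_format(sprintf("TRC `%s`: no usable DataRate; pass `rate`.",
                        basename(path)))
  }
  marker_set(out, rate = rate, axis_map = axis_map)
}

#' Write a marker set to disk
#'
#' `write_marker_csv()` writes the wide-CSV dialect ([read_marker_file()]),
#' `write_marker_trc()` the TRC dialect. Round-tripping preserves positions
#' to well under 1e-6 m and the rate exactly.
#'
#' @param mts A [marker_set()].
#' @param path Output path.
#' @param units Coordinate units to write (`"m"` or `"mm"`).
#' @return `path`, invisibly.
#' @export
write_marker_csv <- function(mts, path, units = "m") {
  scale <- 1 / unit_scale(units)
  labels <- marker_names(mts)
  out <- tibble(time = mts$time)
  for (l in labels) {
    for (a in c("x", "y", "z")) {
      out[[paste0(l, "_", toupper(a))]] <- mts[[paste0(l, "_", a)]] * scale
    }
  }
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_marker_csv
#' @export
write_marker_trc <- function(mts, path, units = "mm") {
  labels <- marker_names(mts)
  rate <- marker_rate(mts)
  scale <- 1 / unit_scale(units)
  n <- nrow(mts)
  hdr <- c(
    sprintf("PathFileType\t4\t(X/Y/Z)\t%s", basename(path)),
    "DataRate\tCameraRate\tNumFrames\tNumMarkers\tUnits\tOrigDataRate\tOrigDataStartFrame\tOrigNumFrames",
    sprintf("%g\t%g\t%d\t%d\t%s\t%g\t1\t%d", rate, rate, n, length(labels),
            units, rate, n),
    paste(c("Frame#", "Time",
            as.vector(rbind(labels, "", ""))), collapse = "\t"),
    paste(c("", "", paste0(rep(c("X", "Y", "Z"), length(labels)),
                           rep(seq_along(labels), each = 3))),
          collapse = "\t"))
  coord_cols <- as.vector(t(outer(labels, c("x", "y", "z"), paste, sep = "_")))
  mat <- as.matrix(mts[coord_cols]) * scale
  rows <- vapply(seq_len(n), function(i) {
    paste(c(format(mts$frame[i]), sprintf("%.6f", mts$time[i]),
            sprintf("%.8f", mat[i, ])), collapse = "\t")
  }, character(1))
  writeLines(c(hdr, "", rows), path)
  invisible(path)
}

#' Drop frames with incomplete marker data
#'
#' Removes frames where any of the `required` markers has a missing or
#' non-finite coordinate (poor marker visibility). Original frame indices and
#' times are retained so downstream timing uses true elapsed time. The
#' operation is idempotent.
#'
#' @param mts A [marker_set()].
#' @param required Labels that must be visible in every retained frame.
#' @param min_frames Minimum number of retained frames; defaults to roughly
#'   two strides of data at typical overground cadence (4 s of samples).
#' @return A `marker_set` containing only complete frames.
#' @export
drop_invalid_frames <- function(mts, required = REQUIRED_MARKERS,
                                min_frames = NULL) {
  check_markers_present(mts, required, "drop_invalid_frames")
  min_frames <- min_frames %||% round(4 * marker_rate(mts))
  cols <- as.vector(t(outer(required, c("x", "y", "z"), paste, sep = "_")))
  ok <- rowSums(!is.finite(as.matrix(mts[cols]))) == 0L
  out <- mts[ok, , drop = FALSE]
  if (nrow(out) < min_frames) {
    stop_insufficient(sprintf(
      "only %d complete frames remain (< %d, about two strides).",
      nrow(out), min_frames))
  }
  structure(out, class = class(mts), rate = marker_rate(mts),
            axis_map = attr(mts, "axis_map"), labels = marker_names(mts))
}

#' Participant tables and metrics tables
#'
#' `read_participant_table()` reads the per-participant demographic/clinical
#' CSV with header `id,group,age,sex,height_m,mass_kg,psprs,psprs_gm`;
#' clinical severity scores (PSPRS and its gait-midline subscore) are allowed
#' only for the PSP group. `write_metrics_table()` writes the per-participant
#' stability metrics in a stable column order, and `read_metrics_table()`
#' reads it back (round-trips to better than 1e-9).
#'
#' @param path CSV path.
#' @return A tibble.
#' @export
read_participant_table <- function(path) {
  dat <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("id", "group", "age", "sex", "height_m", "mass_kg",
            "psprs", "psprs_gm")
  missing <- setdiff(need, names(dat))
  if (length(missing) > 0L) {
    stop_format(sprintf("participant table lacks column(s): %s",
                        paste(missing, collapse = ", ")))
  }
  if (!all(dat$group %in% c("Control", "PSP"))) {
    stop_validation("`group` must be `Control` or `PSP`.")
  }
  if (any(dat$age <= 0, na.rm = TRUE)) {
    stop_validation("`age` must be positive.")
  }
  bad <- dat$group == "Control" & (!is.na(dat$psprs) | !is.na(dat$psprs_gm))
  if (any(bad)) {
    stop_validation("severity scores present for Control participant(s).")
  }
  dat$group <- factor(dat$group, levels = c("Control", "PSP"))
  dat$sex <- factor(dat$sex, levels = c("F", "M"))
  dat
}

metrics_column_order <- function() {
  c("id", "group", "age", "sex", "height_m", "mass_kg", "cadence",
    "mean_FM", "max_LE_L", "max_LE_S", "psprs", "psprs_gm",
    "stride_time_s", "n_strides", "embed_tau", "embed_n",
    "condition_number", "rosenstein_r2", "stable_fm", "stable_le")
}

#' @rdname read_participant_table
#' @param metrics A data frame of per-participant metric rows.
#' @param json_path Optional path for a JSON copy (requires jsonlite).
#' @export
write_metrics_table <- function(metrics, path, json_path = NULL) {
  metrics <- as_tibble(metrics)
  known <- intersect(metrics_column_order(), names(metrics))
  metrics <- metrics[c(known, setdiff(names(metrics), known))]
  readr::write_csv(metrics, path, progress = FALSE)
  if (!is.null(json_path)) {
    if (!requireNamespace("jsonlite", quietly = TRUE)) {
      stop_validation("jsonlite is required to write the JSON copy.")
    }
    jsonlite::write_json(metrics, json_path, dataframe = "rows",
                         auto_unbox = TRUE, digits = NA, na = "null")
  }
  invisible(path)
}

#' @rdname read_participant_table
#' @export
read_metrics_table <- function(path) {
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}
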