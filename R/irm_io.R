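# Movie, annotation, config and trace I/O; coordinate and time conventions.

#' Construct an IRM sequence
#'
#' Wraps a numeric `H x W x T` array of raw IRM intensities (higher = brighter
#' = farther from the substrate) together with its acquisition timing.
#'
#' @param frames numeric array, `H x W x T` with `T >= 2`; all values finite.
#' @param frame_interval seconds per frame (> 0). Default 5, the usual IRM
#'   time-lapse acquisition interval.
#' @param origin_time seconds offset of frame 1.
#' @param source_id free-text provenance label.
#' @return An object of class `irm_sequence`.
#' @export
irm_sequence <- function(frames, frame_interval = 5, origin_time = 0,
                         source_id = "") {
  if (!is.array(frames) || length(dim(frames)) != 3L)
    stop("`frames` must be an H x W x T array")
  if (dim(frames)[3] < 2L)
    stop("an IRM sequence needs at least 2 frames, got ", dim(frames)[3])
  if (!all(is.finite(frames)))
    stop("non-finite intensities in `frames`")
  if (!is.numeric(frame_interval) || length(frame_interval) != 1L ||
      !is.finite(frame_interval) || frame_interval <= 0)
    stop("`frame_interval` must be a single positive number of seconds")
  structure(
    list(frames = frames, frame_interval = frame_interval,
         origin_time = origin_time, source_id = as.character(source_id)),
    class = "irm_sequence")
}

#' @export
print.irm_sequence <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("irm_sequence: %d x %d pixels, %d frames @ %g s/frame\n",
              d[1], d[2], d[3], x$frame_interval))
  cat(sprintf("  intensity range [%g, %g]%s\n",
              min(x$frames), max(x$frames),
              if (nzchar(x$source_id)) paste0("  source: ", x$source_id) else ""))
  invisible(x)
}

#' @export
dim.irm_sequence <- function(x) dim(x$frames)

#' Acquisition times of an IRM sequence
#'
#' @param seq an [irm_sequence()].
#' @return Numeric vector, seconds: `(frame - 1) * frame_interval + origin_time`.
#' @export
frame_times <- function(seq) {
  stopifnot(inherits(seq, "irm_sequence"))
  (seq_len(dim(seq$frames)[3]) - 1L) * seq$frame_interval + seq$origin_time
}

#' Rectangular platelet region of interest
#'
#' A per-platelet bounding box plus the frame range over which it is analysed.
#' Indices are 1-based and inclusive.
#'
#' @param platelet_id free-text identifier.
#' @param box integer vector `c(row_min, col_min, row_max, col_max)`.
#' @param frame_range integer vector `c(first, last)`; `NULL` means the whole
#'   sequence (resolved against the sequence at use time).
#' @return An object of class `platelet_roi`.
#' @export
platelet_roi <- function(platelet_id, box, frame_range = NULL) {
  box <- as.integer(box)
  if (length(box) != 4L || anyNA(box))
    stop("`box` must be c(row_min, col_min, row_max, col_max)")
  if (box[3] < box[1] || box[4] < box[2])
    stop("empty bounding box for platelet ", platelet_id)
  if (!is.null(frame_range)) {
    frame_range <- as.integer(frame_range)
    if (length(frame_range) != 2L || anyNA(frame_range) ||
        frame_range[2] < frame_range[1])
      stop("invalid frame_range for platelet ", platelet_id)
  }
  structure(list(platelet_id = as.character(platelet_id), box = box,
                 frame_range = frame_range),
            class = "platelet_roi")
}

#' Background region: an empty patch near the platelet
#'
#' @param box as in [platelet_roi()].
#' @return An object of class `background_roi`.
#' @export
background_roi <- function(box) {
  r <- platelet_roi("background", box)
  structure(list(box = r$box), class = "background_roi")
}

#' Manually annotated phase time points for one platelet
#'
#' Frame indices (1-based) of the characterized spreading stages. Present
#' indices must be non-decreasing in the order onset, filopodia,
#' lamellipodia, spread; absent stages are `NA`.
#'
#' @param platelet_id identifier matching the ROI.
#' @param onset_frame frame of first appearance.
#' @param filopodia_onset_frame,lamellipodia_onset_frame,spread_frame frame
#'   indices or `NA`.
#' @param endpoint_class one of `"no_attach"`, `"filopodial"`, `"fully_spread"`.
#' @return An object of class `phase_annotation`.
#' @export
phase_annotation <- function(platelet_id, onset_frame,
                             filopodia_onset_frame = NA,
                             lamellipodia_onset_frame = NA,
                             spread_frame = NA,
                             endpoint_class = c("no_attach", "filopodial",
                                                "fully_spread")) {
  endpoint_class <- match.arg(endpoint_class)
  idx <- c(onset_frame, filopodia_onset_frame, lamellipodia_onset_frame,
           spread_frame)
  present <- idx[!is.na(idx)]
  if (length(present) && any(diff(present) < 0))
    stop("phase frames out of order for platelet ", platelet_id,
         " (must be non-decreasing: onset, filopodia, lamellipodia, spread)")
  structure(list(platelet_id = as.character(platelet_id),
                 onset_frame = as.integer(onset_frame),
                 filopodia_onset_frame = as.integer(filopodia_onset_frame),
                 lamellipodia_onset_frame = as.integer(lamellipodia_onset_frame),
                 spread_frame = as.integer(spread_frame),
                 endpoint_class = endpoint_class),
            class = "phase_annotation")
}

# --- internal geometry helpers ----------------------------------------------

validate_roi <- function(roi, seq) {
  d <- dim(seq$frames)
  b <- roi$box
  if (b[1] < 1L || b[2] < 1L || b[3] > d[1] || b[4] > d[2])
    stop("box (", paste(b, collapse = ","), ") outside image bounds ",
         d[1], " x ", d[2])
  fr <- roi$frame_range
  if (!is.null(fr) && (fr[1] < 1L || fr[2] > d[3]))
    stop("frame_range outside [1, ", d[3], "]")
  invisible(TRUE)
}

boxes_disjoint <- function(a, b) {
  a[3] < b[1] || b[3] < a[1] || a[4] < b[2] || b[4] < a[2]
}

# Crop a sequence to an ROI's box and frame range; returns an irm_sequence.
crop_sequence <- function(seq, roi = NULL) {
  stopifnot(inherits(seq, "irm_sequence"))
  if (is.null(roi)) return(seq)
  b <- if (inherits(roi, "background_roi")) roi$box else {
    validate_roi(roi, seq); roi$box
  }
  fr <- if (!is.null(roi$frame_range)) roi$frame_range else
    c(1L, dim(seq$frames)[3])
  frames <- seq$frames[b[1]:b[3], b[2]:b[4], fr[1]:fr[2], drop = FALSE]
  irm_sequence(frames, seq$frame_interval,
               origin_time = seq$origin_time + (fr[1] - 1L) * seq$frame_interval,
               source_id = seq$source_id)
}

# --- movie I/O ---------------------------------------------------------------

#' Read a single-channel multi-page TIFF time-lapse
#'
#' Intensities are preserved bit-exactly for integer TIFFs (no rescaling):
#' segmentation and event thresholds act on raw camera units.
#'
#' @param path path to a multi-page TIFF (8/16-bit integer or float), one
#'   channel per page.
#' @param frame_interval seconds per frame.
#' @param ... passed to [irm_sequence()] (`origin_time`, `source_id`).
#' @return An [irm_sequence()].
#' @export
load_sequence <- function(path, frame_interval = 5, ...) {
  if (!file.exists(path)) stop("file not found: ", path)
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (length(pages) < 2L)
    stop("movie must have at least 2 frames, got ", length(pages),
         " (page 1)")
  for (i in seq_along(pages)) {
    if (length(dim(pages[[i]])) != 2L)
      stop("multi-channel input: page ", i, " has ",
           dim(pages[[i]])[3], " channels; expected single-channel IRM")
    if (i > 1L && !identical(dim(pages[[i]]), dim(pages[[1]])))
      stop("non-uniform page shape at page ", i)
  }
  frames <- array(0, dim = c(dim(pages[[1]]), length(pages)))
  for (i in seq_along(pages)) frames[, , i] <- pages[[i]]
  irm_sequence(frames, frame_interval, source_id = path, ...)
}

#' Write an IRM sequence as a multi-page TIFF
#'
#' Integer-valued data round-trips exactly through [load_sequence()] at the
#' given bit depth.
#'
#' @param seq an [irm_sequence()].
#' @param path output path.
#' @param bits_per_sample 8 or 16; values must lie in `[0, 2^bits - 1]`.
#' @return `path`, invisibly.
#' @export
write_sequence <- function(seq, path, bits_per_sample = 16L) {
  stopifnot(inherits(seq, "irm_sequence"), bits_per_sample %in% c(8L, 16L))
  top <- 2^bits_per_sample - 1
  if (min(seq$frames) < 0 || max(seq$frames) > top)
    stop("intensities outside [0, ", top, "] cannot be written at ",
         bits_per_sample, " bits")
  pages <- lapply(seq_len(dim(seq$frames)[3]),
                  function(t) seq$frames[, , t] / top)
  tiff::writeTIFF(pages, path, bits.per.sample = bits_per_sample,
                  compression = "none")
  invisible(path)
}

# --- annotations -------------------------------------------------------------

annotation_columns <- c(
  "platelet_id", "row_min", "col_min", "row_max", "col_max",
  "frame_first", "frame_last", "onset", "filopodia_onset",
  "lamellipodia_onset", "spread", "endpoint_class",
  "bg_row_min", "bg_col_min", "bg_row_max", "bg_col_max", "index_base")

#' Read per-platelet annotations and validate them against a sequence
#'
#' Accepts a CSV (fixed header, see Details) or a JSON array of records.
#' Records carry the platelet bounding box, frame range, phase time points,
#' endpoint class, and the empty background box used for event calibration.
#' An `index_base` of 0 marks 0-based half-open indices (converted on load);
#' 1 marks 1-based inclusive indices.
#'
#' @details CSV columns: `platelet_id, row_min, col_min, row_max, col_max,
#' frame_first, frame_last, onset, filopodia_onset, lamellipodia_onset,
#' spread, endpoint_class, bg_row_min, bg_col_min, bg_row_max, bg_col_max,
#' index_base`. Empty cells mean "absent".
#'
#' @param path annotation file (.csv or .json).
#' @param seq the [irm_sequence()] the annotations refer to.
#' @return A list of records, each `list(roi, phases, background)`.
#' @export
load_annotations <- function(path, seq) {
  stopifnot(inherits(seq, "irm_sequence"))
  if (!file.exists(path)) stop("file not found: ", path)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    tab <- jsonlite::fromJSON(path)
    tab <- as.data.frame(tab, stringsAsFactors = FALSE)
  } else {
    tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  }
  missing_cols <- setdiff(annotation_columns, names(tab))
  if (length(missing_cols))
    stop("annotation file lacks columns: ", paste(missing_cols, collapse = ", "))
  if (anyDuplicated(tab$platelet_id))
    stop("duplicate platelet_id: ",
         paste(unique(tab$platelet_id[duplicated(tab$platelet_id)]),
               collapse = ", "))
  lapply(seq_len(nrow(tab)), function(i) {
    rec <- tab[i, ]
    base <- rec$index_base
    if (is.na(base) || !base %in% c(0L, 1L))
      stop("index_base must be 0 or 1 for platelet ", rec$platelet_id)
    # 0-based half-open -> 1-based inclusive: mins shift by +1, exclusive
    # maxima become inclusive as-is.
    shift <- if (base == 0L) 1L else 0L
    to_min <- function(v) if (is.na(v)) NA_integer_ else as.integer(v) + shift
    to_max <- function(v) if (is.na(v)) NA_integer_ else
      as.integer(v) + if (base == 0L) 0L else 0L
    box <- c(to_min(rec$row_min), to_min(rec$col_min),
             to_max(rec$row_max), to_max(rec$col_max))
    fr <- c(to_min(rec$frame_first), to_max(rec$frame_last))
    roi <- platelet_roi(rec$platelet_id, box, fr)
    validate_roi(roi, seq)
    bgbox <- c(to_min(rec$bg_row_min), to_min(rec$bg_col_min),
               to_max(rec$bg_row_max), to_max(rec$bg_col_max))
    bg <- background_roi(bgbox)
    validate_roi(bg, seq)
    if (!boxes_disjoint(roi$box, bg$box))
      stop("background box overlaps platelet box for ", rec$platelet_id)
    ph <- phase_annotation(rec$platelet_id,
                           onset_frame = to_min(rec$onset),
                           filopodia_onset_frame = to_min(rec$filopodia_onset),
                           lamellipodia_onset_frame = to_min(rec$lamellipodia_onset),
                           spread_frame = to_min(rec$spread),
                           endpoint_class = rec$endpoint_class)
    idx <- c(ph$onset_frame, ph$filopodia_onset_frame,
             ph$lamellipodia_onset_frame, ph$spread_frame)
    if (any(!is.na(idx) & (idx < fr[1] | idx > fr[2])))
      stop("phase frame outside frame_range for platelet ", rec$platelet_id)
    list(roi = roi, phases = ph, background = bg)
  })
}

#' Write per-platelet annotations
#'
#' Inverse of [load_annotations()]; always writes 1-based inclusive indices
#' (`index_base = 1`).
#'
#' @param records list of `list(roi, phases, background)` records.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(records, path) {
  rows <- lapply(records, function(r) {
    data.frame(platelet_id = r$roi$platelet_id,
               row_min = r$roi$box[1], col_min = r$roi$box[2],
               row_max = r$roi$box[3], col_max = r$roi$box[4],
               frame_first = r$roi$frame_range[1],
               frame_last = r$roi$frame_range[2],
               onset = r$phases$onset_frame,
               filopodia_onset = r$phases$filopodia_onset_frame,
               lamellipodia_onset = r$phases$lamellipodia_onset_frame,
               spread = r$phases$spread_frame,
               endpoint_class = r$phases$endpoint_class,
               bg_row_min = r$background$box[1],
               bg_col_min = r$background$box[2],
               bg_row_max = r$background$box[3],
               bg_col_max = r$background$box[4],
               index_base = 1L, stringsAsFactors = FALSE)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE, na = "")
  invisible(path)
}

# --- traces and config -------------------------------------------------------

#' Export named per-frame series as a CSV with a time column
#'
#' All series must share length; the first column is `time_seconds`
#' (`(frame - 1) * frame_interval + origin_time`); values are written at full
#' precision in a deterministic column order (order given).
#'
#' @param traces named list of equal-length numeric vectors, or a data.frame.
#' @param path output CSV path.
#' @param frame_interval seconds per frame.
#' @param origin_time seconds of the first row.
#' @return `path`, invisibly.
#' @export
export_traces <- function(traces, path, frame_interval, origin_time = 0) {
  traces <- as.list(traces)
  if (is.null(names(traces)) || any(!nzchar(names(traces))))
    stop("all series must be named")
  lens <- vapply(traces, length, integer(1))
  if (length(unique(lens)) != 1L)
    stop("series length mismatch: ", paste(lens, collapse = ", "))
  n <- lens[[1]]
  out <- data.frame(time_seconds = (seq_len(n) - 1) * frame_interval + origin_time)
  for (nm in names(traces)) out[[nm]] <- traces[[nm]]
  # full precision: format numerics explicitly at 17 significant digits
  fmt <- out
  for (nm in names(fmt)) if (is.double(fmt[[nm]]))
    fmt[[nm]] <- formatC(fmt[[nm]], digits = 17, format = "g")
  utils::write.csv(fmt, path, row.names = FALSE, quote = FALSE, na = "NA")
  invisible(path)
}

#' Read a trace CSV written by [export_traces()]
#'
#' @param path CSV path.
#' @return data.frame with `time_seconds` plus one column per series.
#' @export
read_traces <- function(path) utils::read.csv(path)

#' Read a pipeline configuration file
#'
#' YAML with keys `frame_interval`, `active_sd_multiplier`, `bin_size`,
#' `seed`; absent keys take the package defaults.
#'
#' @param path YAML path, or `NULL` for pure defaults.
#' @return Named list of settings.
#' @export
load_config <- function(path = NULL) {
  cfg <- list(frame_interval = 5, active_sd_multiplier = 1,
              bin_size = 3L, seed = 1L)
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config not found: ", path)
    user <- yaml::read_yaml(path)
    unknown <- setdiff(names(user), names(cfg))
    if (length(unknown))
      stop("unknown config keys: ", paste(unknown, collapse = ", "))
    cfg[names(user)] <- user
  }
  if (cfg$frame_interval <= 0) stop("frame_interval must be > 0")
  if (cfg$active_sd_multiplier <= 0) stop("active_sd_multiplier must be > 0")
  if (cfg$bin_size < 1) stop("bin_size must be >= 1")
  cfg
}
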