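# Domain types and file I/O: IMU sequences, segments, templates,
# time-series CSV and template JSON.

IMU_CHANNELS <- c("ax", "ay", "az", "gx", "gy", "gz")
GESTURES <- c("nod", "tilt_up", "shake_left", "shake_right",
              "tilt_left", "tilt_right")

#' The six recognized head-gesture classes
#'
#' @return Character vector of the six class labels: nod, tilt_up,
#'   shake_left, shake_right, tilt_left, tilt_right.
#' @export
gesture_classes <- function() GESTURES

#' Construct a six-channel IMU sequence
#'
#' An `imu_sequence` is a numeric matrix with one row per sample and the six
#' columns `ax, ay, az` (acceleration, g) and `gx, gy, gz` (angular
#' velocity, rad/s), plus a sampling rate in Hz.
#'
#' @param samples Numeric matrix or data frame with 6 columns (or 0 rows);
#'   columns are taken in `ax, ay, az, gx, gy, gz` order (matched by name
#'   when named).
#' @param fs Sampling rate in Hz (> 0). Default 100.
#' @return An object of class `imu_sequence`.
#' @export
imu_sequence <- function(samples, fs = 100) {
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0)
    stop("`fs` must be a single positive number (Hz)")
  m <- as.matrix(samples)
  if (length(m) == 0L) m <- matrix(numeric(0), nrow = 0, ncol = 6)
  if (ncol(m) != 6L)
    stop("an IMU sequence needs exactly 6 channels, got ", ncol(m))
  if (!is.null(colnames(m)) && all(IMU_CHANNELS %in% colnames(m)))
    m <- m[, IMU_CHANNELS, drop = FALSE]
  storage.mode(m) <- "double"
  if (nrow(m) > 0 && !all(is.finite(m)))
    stop("all IMU samples must be finite")
  colnames(m) <- IMU_CHANNELS
  rownames(m) <- NULL
  structure(m, fs = fs, class = c("imu_sequence", "matrix", "array"))
}

#' @export
print.imu_sequence <- function(x, ...) {
  cat(sprintf("<imu_sequence> %d samples @ %g Hz (%.3f s)\n",
              nrow(x), attr(x, "fs"), nrow(x) / attr(x, "fs")))
  if (nrow(x) > 0) {
    utils::head(`attributes<-`(x, list(dim = dim(x),
                                       dimnames = dimnames(x)))) |> print()
    if (nrow(x) > 6) cat("...\n")
  }
  invisible(x)
}

#' Number of samples and sampling rate of an IMU sequence
#' @param x An `imu_sequence`.
#' @return `n_samples()`: integer row count; `sampling_rate()`: Hz.
#' @export
n_samples <- function(x) nrow(x)

#' @rdname n_samples
#' @export
sampling_rate <- function(x) attr(x, "fs")

#' Half-open sample-index interval into an IMU sequence
#'
#' Sample indexing is 0-based and the interval is half-open: a segment
#' `[start, end)` covers samples `start, ..., end - 1` and has duration
#' `(end - start) / fs` seconds.
#'
#' @param start First sample index (0-based, inclusive).
#' @param end One past the last sample index (exclusive); must exceed `start`.
#' @param fs Sampling rate (Hz) of the source sequence.
#' @return An object of class `gesture_segment`.
#' @export
segment <- function(start, end, fs = 100) {
  start <- as.integer(start); end <- as.integer(end)
  if (is.na(start) || is.na(end) || start < 0L || end <= start)
    stop("need 0 <= start < end")
  if (fs <= 0) stop("`fs` must be positive")
  structure(list(start = start, end = end, fs = fs),
            class = "gesture_segment")
}

#' @export
print.gesture_segment <- function(x, ...) {
  cat(sprintf("<segment> [%d, %d) @ %g Hz = [%.3f, %.3f) s, %.3f s\n",
              x$start, x$end, x$fs, x$start / x$fs, x$end / x$fs,
              segment_duration(x)))
  invisible(x)
}

#' Segment duration in seconds
#' @param seg A `gesture_segment`.
#' @return `(end - start) / fs`.
#' @export
segment_duration <- function(seg) (seg$end - seg$start) / seg$fs

#' A labeled gesture segment
#'
#' @param data An `imu_sequence` holding the extracted segment.
#' @param label One of [gesture_classes()].
#' @return An object of class `labeled_segment`.
#' @export
labeled_segment <- function(data, label) {
  if (!inherits(data, "imu_sequence")) stop("`data` must be an imu_sequence")
  label <- match.arg(label, GESTURES)
  structure(list(data = data, label = label), class = "labeled_segment")
}

#' A per-class gesture template
#'
#' The element-wise average of the training segments of one class, truncated
#' to the median training-segment length `m`; all six channels share length
#' `m`.
#'
#' @param label Gesture class.
#' @param channels Numeric `m x 6` matrix of averaged channel values.
#' @param n_sources Number of training segments averaged (>= 1).
#' @return An object of class `gesture_template`.
#' @export
gesture_template <- function(label, channels, n_sources) {
  label <- match.arg(label, GESTURES)
  channels <- as.matrix(channels)
  if (ncol(channels) != 6L || nrow(channels) < 1L)
    stop("template channels must form an m x 6 matrix with m >= 1")
  if (n_sources < 1L) stop("`n_sources` must be >= 1")
  colnames(channels) <- IMU_CHANNELS
  structure(list(label = label, channels = channels,
                 m = nrow(channels), n_sources = as.integer(n_sources)),
            class = "gesture_template")
}

#' @export
print.gesture_template <- function(x, ...) {
  cat(sprintf("<gesture_template> %s: m = %d samples, averaged from %d segments\n",
              x$label, x$m, x$n_sources))
  invisible(x)
}

#' A set of gesture templates, at most one per class
#'
#' @param templates List of `gesture_template` objects, no duplicated labels.
#' @param preprocess Preprocessing fingerprint (see
#'   [preprocess_fingerprint()]) recording how the training segments were
#'   filtered/normalized; classification enforces the same preprocessing.
#' @return An object of class `template_set`.
#' @seealso [build_template_set()], [is_complete()]
#' @export
template_set <- function(templates, preprocess = NULL) {
  labels <- vapply(templates, function(t) t$label, character(1))
  if (anyDuplicated(labels)) stop("duplicate class label in template set")
  names(templates) <- labels
  structure(list(templates = templates, preprocess = preprocess),
            class = "template_set")
}

#' Does a template set cover all six classes?
#' @param x A `template_set`.
#' @return TRUE iff one template is present for every class.
#' @export
is_complete <- function(x) {
  stopifnot(inherits(x, "template_set"))
  all(GESTURES %in% names(x$templates))
}

#' @export
print.template_set <- function(x, ...) {
  cat(sprintf("<template_set> %d/6 classes%s\n", length(x$templates),
              if (is_complete(x)) "" else " (incomplete)"))
  for (t in x$templates)
    cat(sprintf("  %-12s m = %3d  n_sources = %d\n", t$label, t$m, t$n_sources))
  invisible(x)
}

#' Convert a time in seconds to a sample count
#'
#' Rounds `t * fs` to the nearest integer, except that any strictly positive
#' duration maps to at least one sample; zero maps to zero. All time-valued
#' thresholds are converted to samples once via this function so rounding
#' happens at a single point.
#'
#' @param t Time(s) in seconds, >= 0.
#' @param fs Sampling rate in Hz, > 0.
#' @return Integer sample count(s): `max(1, round(t * fs))` for `t > 0`,
#'   0 for `t = 0`.
#' @examples
#' seconds_to_samples(0.5, 100)   # 50
#' seconds_to_samples(0.004, 100) # 1, never 0 for positive t
#' @export
seconds_to_samples <- function(t, fs) {
  if (any(!is.finite(t)) || any(t < 0)) stop("`t` must be finite and >= 0")
  if (!is.finite(fs) || fs <= 0) stop("`fs` must be positive")
  as.integer(ifelse(t == 0, 0L, pmax(1, round(t * fs))))
}

#' Read a six-channel IMU time series from CSV
#'
#' The file must have a header naming the six channels `ax,ay,az,gx,gy,gz`;
#' an optional leading time column `t` is checked for monotonicity and
#' dropped.
#'
#' @param path Path to the CSV file.
#' @param fs Sampling rate in Hz to attach.
#' @return An `imu_sequence`.
#' @export
read_imu_csv <- function(path, fs = 100) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  missing <- setdiff(IMU_CHANNELS, names(df))
  if (length(missing))
    stop("format error: missing channel column(s): ",
         paste(missing, collapse = ", "))
  if ("t" %in% names(df) && nrow(df) > 1) {
    tv <- suppressWarnings(as.numeric(df$t))
    if (anyNA(tv) || any(diff(tv) < 0))
      stop("format error: time column `t` is not monotone")
  }
  mat <- matrix(NA_real_, nrow = nrow(df), ncol = 6,
                dimnames = list(NULL, IMU_CHANNELS))
  for (ch in IMU_CHANNELS) {
    v <- suppressWarnings(as.numeric(df[[ch]]))
    bad <- which(!is.finite(v))
    if (length(bad))
      stop(sprintf("parse error: non-numeric value in column `%s`, data row %d",
                   ch, min(bad)))
    mat[, ch] <- v
  }
  imu_sequence(mat, fs = fs)
}

#' Write an IMU sequence to CSV
#'
#' Writes the six channel columns with 17 significant digits so that a
#' read/write round trip reproduces the values exactly.
#'
#' @param x An `imu_sequence`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_imu_csv <- function(x, path) {
  stopifnot(inherits(x, "imu_sequence"))
  con <- file(path, "w"); on.exit(close(con))
  writeLines(paste(IMU_CHANNELS, collapse = ","), con)
  if (nrow(x) > 0) {
    rows <- apply(x, 1, function(r) paste(sprintf("%.17g", r), collapse = ","))
    writeLines(rows, con)
  }
  invisible(path)
}

#' Write / read a set of gesture templates as JSON
#'
#' The file is a top-level map from class label to
#' `{"m": int, "n_sources": int, "channels": [6 arrays of length m]}`, with
#' channel values serialized at full (17 significant digit) precision so the
#' round trip is bit-exact. A reserved `"_preprocess"` entry records the
#' preprocessing fingerprint of the training segments.
#'
#' @param x A `template_set`.
#' @param path Output path.
#' @return `path` invisibly (write); a `template_set` (read). A file missing
#'   some classes is readable; completeness is queried with [is_complete()].
#'   Duplicate class labels in a file are a format error.
#' @export
write_templates_json <- function(x, path) {
  stopifnot(inherits(x, "template_set"))
  out <- lapply(x$templates, function(t) {
    list(m = t$m, n_sources = t$n_sources,
         channels = lapply(seq_len(6), function(j) t$channels[, j]))
  })
  if (!is.null(x$preprocess)) out[["_preprocess"]] <- x$preprocess
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' @rdname write_templates_json
#' @export
read_templates_json <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  labs <- names(raw)
  labs <- labs[labs != "_preprocess"]
  if (anyDuplicated(labs))
    stop("format error: duplicate class label in template file: ",
         paste(unique(labs[duplicated(labs)]), collapse = ", "))
  bad <- setdiff(labs, GESTURES)
  if (length(bad)) stop("format error: unknown class label: ", bad[[1]])
  templates <- lapply(labs, function(lab) {
    e <- raw[[lab]]
    ch <- vapply(e$channels, function(v) as.numeric(unlist(v)),
                 numeric(e$m))
    gesture_template(lab, matrix(ch, ncol = 6), e$n_sources)
  })
  pp <- raw[["_preprocess"]]
  if (!is.null(pp)) pp <- list(t_win_s = pp$t_win_s, normalize = pp$normalize)
  template_set(templates, preprocess = pp)
}

#' Write / read a labeled segment dataset as a directory of CSVs
#'
#' One CSV per segment plus a `manifest.csv` with columns `file,label`.
#'
#' @param segments List of `labeled_segment` objects.
#' @param dir Directory path (created if needed).
#' @param fs Sampling rate used when reading back.
#' @return The directory path invisibly (write); a list of
#'   `labeled_segment` (read).
#' @export
write_gesture_dataset <- function(segments, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- sprintf("seg_%04d.csv", seq_along(segments))
  for (i in seq_along(segments))
    write_imu_csv(segments[[i]]$data, file.path(dir, files[i]))
  manifest <- data.frame(
    file = files,
    label = vapply(segments, function(s) s$label, character(1)))
  write.table(manifest, file.path(dir, "manifest.csv"), sep = ",",
              row.names = FALSE, quote = FALSE)
  invisible(dir)
}

#' @rdname write_gesture_dataset
#' @export
read_gesture_dataset <- function(dir, fs = 100) {
  manifest <- read.csv(file.path(dir, "manifest.csv"),
                       stringsAsFactors = FALSE)
  if (!all(c("file", "label") %in% names(manifest)))
    stop("format error: manifest must have columns `file,label`")
  lapply(seq_len(nrow(manifest)), function(i)
    labeled_segment(read_imu_csv(file.path(dir, manifest$file[i]), fs = fs),
                    manifest$label[i]))
}
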