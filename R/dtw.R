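# Template construction, DTW alignment, and minimum-distance
# classification.

as_channel_matrix <- function(x) {
  if (inherits(x, "gesture_template")) return(x$channels)
  if (inherits(x, "imu_sequence"))
    return(`attributes<-`(x, list(dim = dim(x), dimnames = dimnames(x))))
  m <- as.matrix(x)
  storage.mode(m) <- "double"
  m
}

#' Build a per-class template by element-wise averaging
#'
#' Given the start-anchored training segments of one class (index 0 = the
#' detected start), the template length `m` is the median of the segment
#' lengths (for an even count, the mean of the two middle lengths rounded
#' half down so `m` stays a valid sample index). For each channel
#' independently, the template value at position `i` (1..m) is the mean over
#' the segments whose length is at least `i` — shorter segments simply do
#' not contribute at positions they do not reach.
#'
#' @param segments Non-empty list of `imu_sequence` (6 channels each),
#'   already preprocessed if the templates are to be used that way.
#' @param label Gesture class of these segments.
#' @return A `gesture_template` of length `m`.
#' @export
build_template <- function(segments, label) {
  if (length(segments) == 0L) stop("build_template: no segments")
  mats <- lapply(segments, as_channel_matrix)
  nch <- ncol(mats[[1]])
  if (any(vapply(mats, ncol, integer(1)) != nch))
    stop("dimension error: segments disagree on channel count")
  lens <- vapply(mats, nrow, integer(1))
  if (any(lens < 1L)) stop("build_template: empty segment")
  m <- as.integer(floor(median(lens)))  # half-down for even counts
  acc <- matrix(0, nrow = m, ncol = nch)
  cnt <- integer(m)
  for (s in mats) {
    k <- min(nrow(s), m)
    acc[seq_len(k), ] <- acc[seq_len(k), , drop = FALSE] +
      s[seq_len(k), , drop = FALSE]
    cnt[seq_len(k)] <- cnt[seq_len(k)] + 1L
  }
  gesture_template(label, acc / cnt, n_sources = length(segments))
}

#' Pairwise pointwise distance matrix between two multichannel sequences
#'
#' Entry (i, j) is the Euclidean distance in channel space between sample i
#' of `s` and position j of `t` (or its square when `squared = TRUE`).
#'
#' @param s,t Sequences: `imu_sequence`, `gesture_template`, or plain
#'   numeric matrices with one column per channel (channel counts must
#'   match; a numeric vector is taken as a single channel).
#' @param squared Skip the square root (the squared-distance variant).
#' @return An `n x m` matrix of non-negative values.
#' @export
dtw_distance_matrix <- function(s, t, squared = FALSE) {
  S <- as_channel_matrix(s); T_ <- as_channel_matrix(t)
  if (nrow(S) == 0L || nrow(T_) == 0L)
    stop("dtw_distance_matrix: empty sequence")
  if (ncol(S) != ncol(T_))
    stop("dimension error: channel counts differ (", ncol(S), " vs ",
         ncol(T_), ")")
  d2 <- matrix(0, nrow(S), nrow(T_))
  for (k in seq_len(ncol(S)))
    d2 <- d2 + outer(S[, k], T_[, k], "-")^2
  d2[d2 < 0] <- 0
  if (squared) d2 else sqrt(d2)
}

#' Dynamic-time-warping alignment of two multichannel sequences
#'
#' Fills the cumulative-distance grid by the recursion
#' `r(i, j) = d(i, j) + min(r(i-1, j), r(i-1, j-1), r(i, j-1))` with
#' `r(1, 1) = d(1, 1)` and out-of-grid neighbours treated as +Inf, and
#' recovers the optimal warp path by backtracking the argmin choices
#' (ties preferring the diagonal, then the vertical, then the horizontal
#' predecessor — this affects only the reported path, never the distance).
#' The path runs from (1, 1) to (n, m), moves by steps in
#' {(+1, 0), (+1, +1), (0, +1)}, and its length k satisfies
#' `max(n, m) <= k <= n + m - 1`. No global path band is imposed: the full
#' `n x m` grid is computed.
#'
#' @inheritParams dtw_distance_matrix
#' @return An object of class `dtw_result`: a list with `distance`
#'   (`r(n, m)`, the classification score), `normalized_distance`
#'   (`distance / k`), `path` (k x 2 integer matrix of 1-based (i, j)
#'   pairs), `k`, `cumulative` (the r grid) and `distance_matrix` (d).
#' @export
dtw_align <- function(s, t, squared = FALSE) {
  d <- dtw_distance_matrix(s, t, squared = squared)
  core <- dtw_core(d)
  path <- cbind(i = core$path_i, j = core$path_j)
  structure(list(distance = core$distance,
                 normalized_distance = core$distance / nrow(path),
                 path = path, k = nrow(path),
                 cumulative = core$cumulative, distance_matrix = d),
            class = "dtw_result")
}

#' @export
print.dtw_result <- function(x, ...) {
  cat(sprintf(
    "<dtw_result> %d x %d grid: distance = %.6g, path length k = %d, distance/k = %.6g\n",
    nrow(x$distance_matrix), ncol(x$distance_matrix), x$distance, x$k,
    x$normalized_distance))
  invisible(x)
}

#' Shorthand for the DTW distance between two sequences
#'
#' @inheritParams dtw_align
#' @param normalize_by_path_length Divide by the warp-path length k.
#' @return A single non-negative number.
#' @export
dtw_distance <- function(s, t, squared = FALSE,
                         normalize_by_path_length = FALSE) {
  r <- dtw_align(s, t, squared = squared)
  if (normalize_by_path_length) r$normalized_distance else r$distance
}

#' Build the six-class template set from labeled training segments
#'
#' Preprocesses every training segment (median filter, then arctangent
#' normalization per `pp`), groups by label, and averages each group with
#' [build_template()]. The preprocessing fingerprint is stored in the set so
#' [classify_gesture()] can refuse mismatched preprocessing.
#'
#' @param train List of `labeled_segment` (raw, as extracted by detection).
#' @param pp A `preprocess_config`.
#' @return A `template_set` (complete iff every class is represented).
#' @export
build_template_set <- function(train, pp = preprocess_config()) {
  labels <- vapply(train, function(s) s$label, character(1))
  templates <- lapply(intersect(GESTURES, unique(labels)), function(lab) {
    segs <- lapply(train[labels == lab],
                   function(s) preprocess_sequence(s$data, pp))
    build_template(segs, lab)
  })
  template_set(templates, preprocess = preprocess_fingerprint(pp))
}

#' Classify a segment by minimum DTW distance to the templates
#'
#' Preprocesses the query segment exactly as the templates' training
#' segments were (verified against the stored fingerprint), computes the
#' DTW distance to each of the six class templates, and returns the label
#' of the smallest. By default the unnormalized cumulative distance
#' `r(n, m)` is the score; exact ties are broken toward the
#' lexicographically smallest class label.
#'
#' @param x An `imu_sequence` — a raw extracted segment.
#' @param templates A complete `template_set`.
#' @param pp The `preprocess_config` to apply; must match the fingerprint
#'   stored in `templates`.
#' @param normalize_by_path_length Score with `r(n, m)/k` instead.
#' @param squared Use squared pointwise distances.
#' @return An object of class `gesture_classification`: list with `label`
#'   and `distances` (named numeric of length 6, lexicographic label
#'   order).
#' @export
classify_gesture <- function(x, templates, pp = preprocess_config(),
                             normalize_by_path_length = FALSE,
                             squared = FALSE) {
  stopifnot(inherits(x, "imu_sequence"), inherits(templates, "template_set"))
  if (!is_complete(templates))
    stop("config error: template set is incomplete (",
         length(templates$templates), "/6 classes)")
  if (!is.null(templates$preprocess) &&
      !isTRUE(all.equal(templates$preprocess, preprocess_fingerprint(pp))))
    stop("config error: preprocessing config does not match the ",
         "fingerprint stored with the templates")
  q <- preprocess_sequence(x, pp)
  labs <- sort(names(templates$templates))  # lexicographic => ties resolved
  distances <- vapply(labs, function(lab)
    dtw_distance(q, templates$templates[[lab]], squared = squared,
                 normalize_by_path_length = normalize_by_path_length),
    numeric(1))
  structure(list(label = labs[which.min(distances)], distances = distances),
            class = "gesture_classification")
}

#' @export
print.gesture_classification <- function(x, ...) {
  cat("<gesture_classification>", x$label, "\n")
  print(round(x$distances, 4))
  invisible(x)
}
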