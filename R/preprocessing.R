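# Preprocessing: arctangent amplitude normalization and sliding median
# filtering.

#' Preprocessing configuration
#'
#' @param t_win_s Median-filter window length in seconds. Default 0.3 s
#'   (the value selected by the detector parameter sweep; 0.2 s is the other
#'   documented choice and remains selectable).
#' @param normalize Apply arctangent normalization to all six channels
#'   before template building and DTW matching. Default TRUE.
#' @param normalize_for_detection Apply arctangent normalization before
#'   endpoint detection as well. Default FALSE: the detection threshold is
#'   stated in rad/s, which is inconsistent with thresholding
#'   arctan-compressed values, so detection runs on filtered, unnormalized
#'   angular velocities.
#' @return An object of class `preprocess_config`.
#' @export
preprocess_config <- function(t_win_s = 0.3, normalize = TRUE,
                              normalize_for_detection = FALSE) {
  if (!is.finite(t_win_s) || t_win_s <= 0) stop("`t_win_s` must be > 0")
  structure(list(t_win_s = t_win_s,
                 normalize = isTRUE(normalize),
                 normalize_for_detection = isTRUE(normalize_for_detection)),
            class = "preprocess_config")
}

#' Fingerprint of the preprocessing applied to DTW inputs
#'
#' Stored inside a [template_set()] so that classification can verify the
#' query segment is preprocessed the same way as the training segments were.
#'
#' @param pp A `preprocess_config`.
#' @return A list with elements `t_win_s` and `normalize`.
#' @export
preprocess_fingerprint <- function(pp) {
  list(t_win_s = pp$t_win_s, normalize = pp$normalize)
}

#' Arctangent amplitude normalization
#'
#' Maps each value through `y = atan(x) * 2 / pi`, compressing every channel
#' into the open interval (-1, 1) while preserving sign and order. Used on
#' all six channels before template construction and DTW matching.
#'
#' @param x Numeric vector (all values finite).
#' @return Numeric vector of the same length with |y| < 1.
#' @examples
#' normalize_arctan(c(0, 1, tan(pi / 3))) # 0, 0.5, 2/3
#' @export
normalize_arctan <- function(x) {
  if (length(x) && !all(is.finite(x)))
    stop("normalize_arctan: input must be finite")
  atan(x) * 2 / pi
}

#' Sliding median filter with edge replication
#'
#' For odd window length `l` the output at position `t` is the median of the
#' window of length `l` centered at `t`; for even `l` the window is
#' `x[t - l/2 : t + l/2 - 1]` and the output is the mean of the two middle
#' values. Boundaries are handled by replicating the first/last sample, so
#' the output has the same length as the input. Its purpose in the pipeline
#' is suppressing salt-and-pepper (single-sample impulse) sensor noise.
#'
#' @param x Numeric vector, non-empty.
#' @param l Window length in samples, >= 1. `l = 1` is the identity.
#' @return Filtered vector, same length as `x`.
#' @examples
#' median_filter(c(1, 9, 2, 8, 3), 3) # 1 2 8 3 3
#' median_filter(c(1, 9, 2, 8), 2)    # 1 5 5.5 5
#' @export
median_filter <- function(x, l) {
  n <- length(x)
  if (n == 0L) stop("median_filter: empty series")
  l <- as.integer(l)
  if (is.na(l) || l < 1L) stop("median_filter: window length must be >= 1")
  if (l == 1L) return(x)
  if (l %% 2L == 1L) {
    pad_l <- (l - 1L) %/% 2L; pad_r <- pad_l
  } else {
    pad_l <- l %/% 2L; pad_r <- l %/% 2L - 1L
  }
  xp <- c(rep(x[1], pad_l), x, rep(x[n], pad_r))
  vapply(seq_len(n), function(t) median(xp[t:(t + l - 1L)]), numeric(1))
}

#' Preprocess a six-channel IMU sequence
#'
#' Median-filters each channel with a window of
#' `seconds_to_samples(t_win_s, fs)` samples, then (if `pp$normalize`)
#' applies arctangent normalization. Filtering precedes normalization.
#'
#' @param x An `imu_sequence`.
#' @param pp A `preprocess_config`.
#' @return The preprocessed `imu_sequence`.
#' @export
preprocess_sequence <- function(x, pp = preprocess_config()) {
  stopifnot(inherits(x, "imu_sequence"))
  fs <- sampling_rate(x)
  l <- seconds_to_samples(pp$t_win_s, fs)
  out <- apply(x, 2, median_filter, l = l)
  if (nrow(x) == 1L) out <- matrix(out, nrow = 1)
  if (pp$normalize) out <- normalize_arctan(out)
  imu_sequence(out, fs = fs)
}
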