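# End-to-end pipeline orchestration and evaluation: train/test splitting,
# template building + classification, confusion matrices, stream pipeline.

#' Bundle the pipeline configuration
#'
#' @param preprocess A [preprocess_config()].
#' @param detect A [detection_config()].
#' @param generator A [generator_config()].
#' @param train_fraction Stratified train fraction, in (0, 1). Default 0.82,
#'   mirroring a 1914-train / 419-test split of 2333 segments.
#' @param normalize_by_path_length,squared DTW scoring options, passed to
#'   [classify_gesture()].
#' @param seed Master seed.
#' @return An object of class `run_config`.
#' @export
run_config <- function(preprocess = preprocess_config(),
                       detect = detection_config(),
                       generator = generator_config(),
                       train_fraction = 0.82,
                       normalize_by_path_length = FALSE,
                       squared = FALSE,
                       seed = 1) {
  if (!is.finite(train_fraction) || train_fraction <= 0 || train_fraction >= 1)
    stop("`train_fraction` must lie strictly in (0, 1)")
  structure(list(preprocess = preprocess, detect = detect,
                 generator = generator, train_fraction = train_fraction,
                 normalize_by_path_length = isTRUE(normalize_by_path_length),
                 squared = isTRUE(squared), seed = seed),
            class = "run_config")
}

#' Stratified train/test split of a labeled dataset
#'
#' Within each class, `round(train_fraction * n_c)` segments go to training
#' (capped at `n_c - 1` and floored at 1, so neither side of any class is
#' ever empty); assignment is a seeded random permutation.
#'
#' @param data List of `labeled_segment`.
#' @param train_fraction In (0, 1).
#' @param seed Integer seed.
#' @return List with elements `train` and `test` (disjoint, exhaustive).
#' @export
split_dataset <- function(data, train_fraction, seed = 1) {
  if (length(data) == 0L) stop("empty dataset")
  if (train_fraction <= 0 || train_fraction >= 1)
    stop("`train_fraction` must lie strictly in (0, 1)")
  labels <- vapply(data, function(s) s$label, character(1))
  tr_idx <- with_rng_seed(seed, {
    unlist(lapply(unique(labels), function(lab) {
      idx <- which(labels == lab)
      n_c <- length(idx)
      if (n_c < 2L)
        stop("stratification error: class `", lab, "` has < 2 segments")
      n_tr <- max(1L, min(as.integer(round(train_fraction * n_c)), n_c - 1L))
      sample(idx, n_tr)
    }))
  })
  list(train = data[sort(tr_idx)], test = data[sort(setdiff(seq_along(data), tr_idx))])
}

#' Train on one split, classify the other, and tabulate the results
#'
#' Builds one template per class from the training segments only, then
#' classifies every test segment by minimum DTW distance. The report
#' carries the 6 x 6 confusion matrix (rows = truth, columns = predicted),
#' overall and per-class accuracy in percent (2 decimals), and the per-class
#' train/test counts.
#'
#' @param train,test Lists of `labeled_segment`; `train` must contain every
#'   class.
#' @param cfg A `run_config`.
#' @return An object of class `evaluation_report`.
#' @export
evaluate_classifier <- function(train, test, cfg = run_config()) {
  tr_labels <- vapply(train, function(s) s$label, character(1))
  missing <- setdiff(GESTURES, tr_labels)
  if (length(missing))
    stop("config error: class(es) missing from training set: ",
         paste(missing, collapse = ", "))
  templates <- build_template_set(train, cfg$preprocess)
  te_labels <- vapply(test, function(s) s$label, character(1))
  predicted <- vapply(test, function(s)
    classify_gesture(s$data, templates, cfg$preprocess,
                     normalize_by_path_length = cfg$normalize_by_path_length,
                     squared = cfg$squared)$label,
    character(1))
  confusion <- table(factor(te_labels, levels = GESTURES),
                     factor(predicted, levels = GESTURES))
  confusion <- matrix(as.integer(confusion), 6, 6,
                      dimnames = list(truth = GESTURES, predicted = GESTURES))
  total <- length(test)
  correct <- sum(diag(confusion))
  per_class <- 100 * diag(confusion) / pmax(1L, rowSums(confusion))
  structure(list(
    confusion = confusion,
    accuracy_pct = round(100 * correct / total, 2),
    per_class_pct = round(per_class, 2),
    n_correct = correct, n_test = total,
    n_train_per_class = table(factor(tr_labels, levels = GESTURES)),
    n_test_per_class = rowSums(confusion),
    templates = templates, config = cfg),
    class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report> accuracy %.2f%% (%d/%d correct)\n",
              x$accuracy_pct, x$n_correct, x$n_test))
  cat("confusion matrix (rows = truth, cols = predicted):\n")
  print(x$confusion)
  cat("per-class accuracy (%):\n")
  print(x$per_class_pct)
  invisible(x)
}

#' Run the full pipeline on a continuous stream
#'
#' detect -> extract -> preprocess -> classify, stage by stage, against an
#' existing complete template set. Output rows are aligned with the detected
#' segments in stream order.
#'
#' @param stream An `imu_sequence`.
#' @param templates A complete `template_set`.
#' @param cfg A `run_config`.
#' @return Data frame with one row per detected segment: `start`, `end`
#'   (0-based half-open sample indices), `start_s`, `end_s`, `label`, and
#'   the six per-class distances (`d_<class>`, lexicographic order). Zero
#'   rows when nothing is detected.
#' @export
run_pipeline <- function(stream, templates, cfg = run_config()) {
  fs <- sampling_rate(stream)
  segs <- tryCatch(detect_segments(stream, cfg$detect, cfg$preprocess),
                   error = function(e) stop("detect stage: ",
                                            conditionMessage(e)))
  pieces <- tryCatch(extract_segments(stream, segs),
                     error = function(e) stop("extract stage: ",
                                              conditionMessage(e)))
  dist_names <- paste0("d_", sort(GESTURES))
  out <- data.frame(start = integer(0), end = integer(0),
                    start_s = numeric(0), end_s = numeric(0),
                    label = character(0), stringsAsFactors = FALSE)
  for (nm in dist_names) out[[nm]] <- numeric(0)
  for (i in seq_along(pieces)) {
    cls <- tryCatch(
      classify_gesture(pieces[[i]], templates, cfg$preprocess,
                       normalize_by_path_length = cfg$normalize_by_path_length,
                       squared = cfg$squared),
      error = function(e) stop("classify stage: ", conditionMessage(e)))
    row <- data.frame(start = segs[[i]]$start, end = segs[[i]]$end,
                      start_s = segs[[i]]$start / fs,
                      end_s = segs[[i]]$end / fs,
                      label = cls$label, stringsAsFactors = FALSE)
    for (j in seq_along(dist_names)) row[[dist_names[j]]] <- cls$distances[j]
    out <- rbind(out, row)
  }
  out
}
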