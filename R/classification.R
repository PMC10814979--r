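#' Confusion counts for binary predictions
#'
#' Tallies true/false positives and negatives, with class 1 taken as the
#' positive class.
#'
#' @param truth Integer vector of true labels (0/1).
#' @param pred Integer vector of predicted labels (0/1), same length.
#' @return A one-row tibble with columns `tp`, `tn`, `fp`, `fn`.
#' @export
confusion_counts <- function(truth, pred) {
  if (length(truth) != length(pred)) {
    stop("`truth` and `pred` must have the same length", call. = FALSE)
  }
  check_labels(truth, "truth")
  check_labels(pred, "pred", both_classes = FALSE)
  tibble::tibble(
    tp = sum(truth == 1L & pred == 1L),
    tn = sum(truth == 0L & pred == 0L),
    fp = sum(truth == 0L & pred == 1L),
    fn = sum(truth == 1L & pred == 0L)
  )
}

check_labels <- function(labels, arg = "labels", both_classes = FALSE) {
  if (!all(labels %in% c(0L, 1L))) {
    stop(sprintf("`%s` must contain only 0/1 class labels", arg), call. = FALSE)
  }
  if (both_classes && length(unique(labels)) < 2L) {
    stop(sprintf("`%s` must contain both classes", arg), call. = FALSE)
  }
  invisible(labels)
}

#' Classification accuracy from confusion counts
#'
#' The proportion of correctly classified instances,
#' `(tp + tn) / (tp + tn + fp + fn)`.
#'
#' @param counts A data frame or list with fields `tp`, `tn`, `fp`, `fn`.
#' @return A number in `[0, 1]`.
#' @examples
#' classification_accuracy(list(tp = 3, tn = 4, fp = 1, fn = 2))  # 0.7
#' @export
classification_accuracy <- function(counts) {
  need <- c("tp", "tn", "fp", "fn")
  if (!all(need %in% names(counts))) {
    stop("`counts` must have fields tp, tn, fp, fn", call. = FALSE)
  }
  v <- vapply(need, function(f) as.double(counts[[f]][1L]), 0)
  if (any(!is.finite(v)) || any(v < 0)) {
    stop("confusion counts must be nonnegative finite numbers", call. = FALSE)
  }
  total <- sum(v)
  if (total == 0) stop("confusion counts are all zero; no instances classified", call. = FALSE)
  (v[["tp"]] + v[["tn"]]) / total
}

#' Fit the accuracy-maximising threshold on a single feature
#'
#' Learns the one-dimensional threshold rule that best separates the two
#' classes on a scalar feature (here, per-series SlpEn). Every achievable
#' split is tried: candidate cuts are the midpoints between consecutive
#' distinct sorted feature values plus the two infinite cuts, in both
#' directions (class 1 above or below the cut). Ties in accuracy are broken
#' by the smallest cut, then by the class-1-above direction, so the fit is
#' fully deterministic.
#'
#' @param data A data frame with one row per series.
#' @param value Column holding the scalar feature (default `slpen`).
#' @param label Column holding the 0/1 class labels (default `label`).
#' @return An object of class `slpen_threshold` with elements `cut`,
#'   `direction` (`"above"` means values above the cut are predicted class 1),
#'   `accuracy`, and the training confusion `counts`.
#' @examples
#' d <- tibble::tibble(slpen = c(1, 3, 2, 4), label = c(0, 0, 1, 1))
#' fit_threshold(d)
#' @export
fit_threshold <- function(data, value = "slpen", label = "label") {
  value <- tidyselect_col(data, rlang::enquo(value), "value")
  labl <- tidyselect_col(data, rlang::enquo(label), "label")
  fit_threshold_values(value[labl == 0L], value[labl == 1L])
}

# Resolve a column given either bare name or string, defaulting sensibly.
tidyselect_col <- function(data, quo, what) {
  expr <- rlang::quo_get_expr(quo)
  nm <- if (is.character(expr)) expr else rlang::as_name(expr)
  if (!nm %in% names(data)) {
    stop(sprintf("column `%s` (for %s) not found in `data`", nm, what), call. = FALSE)
  }
  data[[nm]]
}

#' Threshold fit from two value vectors
#'
#' Lower-level interface to [fit_threshold()]: the class-0 and class-1 feature
#' values are passed directly.
#'
#' @param values0,values1 Finite numeric feature values for class 0 and
#'   class 1; both nonempty.
#' @return An `slpen_threshold` object (see [fit_threshold()]).
#' @export
fit_threshold_values <- function(values0, values1) {
  if (length(values0) == 0L || length(values1) == 0L) {
    stop("both classes must contribute at least one value", call. = FALSE)
  }
  if (!all(is.finite(values0)) || !all(is.finite(values1))) {
    stop("feature values must all be finite", call. = FALSE)
  }
  vals <- c(values0, values1)
  labs <- c(rep.int(0L, length(values0)), rep.int(1L, length(values1)))
  u <- sort(unique(vals))
  cuts <- c(-Inf, if (length(u) > 1L) (u[-length(u)] + u[-1L]) / 2)
  if (length(u) > 1L) cuts <- c(cuts, Inf)

  best <- list(accuracy = -1)
  n <- length(vals)
  for (cut in cuts) {
    for (dir in c("above", "below")) {
      pred <- predict_threshold(vals, cut, dir)
      acc <- sum(pred == labs) / n
      if (acc > best$accuracy) {
        best <- list(cut = cut, direction = dir, accuracy = acc, pred = pred)
      }
    }
  }
  counts <- confusion_counts(labs, best$pred)
  structure(
    list(cut = best$cut, direction = best$direction, accuracy = best$accuracy,
         counts = counts, n = n),
    class = "slpen_threshold"
  )
}

predict_threshold <- function(values, cut, direction) {
  if (direction == "above") as.integer(values > cut) else as.integer(values < cut)
}

#' @export
print.slpen_threshold <- function(x, ...) {
  cat(sprintf("<slpen_threshold> class 1 when value %s %g; training accuracy %.4f (n = %d)\n",
              if (x$direction == "above") ">" else "<", x$cut, x$accuracy, x$n))
  invisible(x)
}

#' Predict class labels with a fitted threshold rule
#'
#' @param object An `slpen_threshold` from [fit_threshold()].
#' @param newdata A numeric vector of feature values, or a data frame with a
#'   `slpen` column.
#' @param ... Unused.
#' @return Integer vector of 0/1 predictions.
#' @export
predict.slpen_threshold <- function(object, newdata, ...) {
  values <- if (is.data.frame(newdata)) newdata[["slpen"]] else newdata
  if (!is.numeric(values)) stop("`newdata` must supply numeric feature values", call. = FALSE)
  predict_threshold(values, object$cut, object$direction)
}

#' @export
tidy.slpen_threshold <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(cut = x$cut, direction = x$direction, accuracy = x$accuracy),
    x$counts
  )
}

#' @export
glance.slpen_threshold <- function(x, ...) {
  tibble::tibble(accuracy = x$accuracy, n = x$n)
}
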