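#' Repeated stratified train--validation evaluation
#'
#' Emulates a realistic deployment of the SlpEn classifier: on each repeat a
#' stratified random fraction of each class is used to run the grid search
#' (selecting both the SlpEn configuration and the threshold rule), and the
#' frozen classifier is then scored on the held-out series. The split is
#' stratified per class with `floor(train_fraction * n_class)` training series
#' (at least one), so both classes appear on both sides.
#'
#' @param data A dataset tibble (columns `id`, `label`, `series`).
#' @param spec A [grid_spec()] searched on each training subset.
#' @param train_fraction Fraction of each class used for training, in (0, 1).
#'   Default 0.3.
#' @param repeats Number of random repetitions. Default 10.
#' @param seed Integer seed; the whole procedure is reproducible given the
#'   seed and leaves the global RNG state untouched.
#' @inheritParams dataset_slpen
#' @return An object of class `slpen_validation` holding the per-repeat
#'   results (`tidy()`), and the mean and population standard deviation of the
#'   validation accuracy (`glance()`).
#' @export
train_validate <- function(data, spec, train_fraction = 0.3, repeats = 10L,
                           seed = 1L, normalize = FALSE) {
  check_dataset(data)
  if (!is.numeric(train_fraction) || train_fraction <= 0 || train_fraction >= 1) {
    stop("`train_fraction` must lie strictly between 0 and 1", call. = FALSE)
  }
  repeats <- as.integer(repeats)
  if (repeats < 1L) stop("`repeats` must be at least 1", call. = FALSE)

  idx_by_class <- split(seq_len(nrow(data)), data$label)
  n_train <- vapply(idx_by_class, function(idx) {
    k <- max(1L, as.integer(floor(train_fraction * length(idx))))
    if (k >= length(idx)) {
      stop(sprintf("degenerate split: a class with %d series leaves no validation series at train_fraction = %g",
                   length(idx), train_fraction), call. = FALSE)
    }
    k
  }, 0L)

  rows <- withr::with_seed(seed, {
    lapply(seq_len(repeats), function(r) {
      train_idx <- sort(unlist(mapply(function(idx, k) sample(idx, k),
                                      idx_by_class, n_train, SIMPLIFY = FALSE),
                               use.names = FALSE))
      train <- data[train_idx, ]
      valid <- data[-train_idx, ]
      gs <- grid_search(train, spec, normalize = normalize)
      cfg <- row_config(gs$best_config)
      scored <- dataset_slpen(valid, cfg, normalize = normalize)
      pred <- predict(gs$classifier, scored$slpen)
      acc <- classification_accuracy(confusion_counts(scored$label, pred))
      dplyr::mutate(gs$best_config,
                    repetition = r, train_accuracy = .data$accuracy,
                    accuracy = acc)
    })
  })
  results <- dplyr::bind_rows(rows)
  results <- dplyr::relocate(results, "repetition")
  mu <- mean(results$accuracy)
  sdev <- sqrt(mean((results$accuracy - mu)^2))   # population SD over repeats

  structure(
    list(results = results, mean_accuracy = mu, sd_accuracy = sdev,
         spec = spec, train_fraction = train_fraction, repeats = repeats,
         seed = seed, normalize = normalize),
    class = "slpen_validation"
  )
}

#' @export
print.slpen_validation <- function(x, ...) {
  cat(sprintf(
    "<slpen_validation> %d repeats, train fraction %.2f (%s grid)\nvalidation accuracy: %.4f +/- %.4f\n",
    x$repeats, x$train_fraction, x$spec$variant, x$mean_accuracy, x$sd_accuracy))
  invisible(x)
}

#' @export
tidy.slpen_validation <- function(x, ...) x$results

#' @export
glance.slpen_validation <- function(x, ...) {
  tibble::tibble(mean_accuracy = x$mean_accuracy, sd_accuracy = x$sd_accuracy,
                 repeats = x$repeats, train_fraction = x$train_fraction,
                 variant = x$spec$variant)
}

#' Plot per-repeat validation accuracies
#'
#' @param object An `slpen_validation` from [train_validate()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.slpen_validation <- function(object, ...) {
  df <- object$results
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$repetition), y = .data$accuracy)) +
    ggplot2::geom_point(size = 2, colour = "steelblue") +
    ggplot2::geom_hline(yintercept = object$mean_accuracy, linetype = "dashed") +
    ggplot2::labs(x = "repetition", y = "validation accuracy") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}
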