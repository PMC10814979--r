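#' Assemble a labelled two-class dataset
#'
#' Builds the tibble representation used throughout the package: one row per
#' series, with an identifier, a 0/1 class label and the series itself in a
#' list-column.
#'
#' @param series A list of numeric vectors (each a time series of length at
#'   least 2, all samples finite).
#' @param labels Integer vector of 0/1 class labels, one per series; both
#'   classes must be represented.
#' @param ids Optional character identifiers; generated when missing.
#' @param name Optional dataset name, stored as attribute `dataset_name`.
#' @return A tibble with columns `id`, `label`, `series`.
#' @export
labeled_dataset <- function(series, labels, ids = NULL, name = NULL) {
  if (!is.list(series)) stop("`series` must be a list of numeric vectors", call. = FALSE)
  if (length(series) != length(labels)) {
    stop("`labels` must have one entry per series", call. = FALSE)
  }
  labels <- as.integer(labels)
  check_labels(labels, both_classes = TRUE)
  if (is.null(ids)) ids <- sprintf("series_%03d", seq_along(series))
  for (i in seq_along(series)) check_series(series[[i]], arg = ids[i])
  out <- tibble::tibble(id = as.character(ids), label = labels, series = series)
  attr(out, "dataset_name") <- name
  out
}

check_dataset <- function(data) {
  need <- c("id", "label", "series")
  if (!is.data.frame(data) || !all(need %in% names(data))) {
    stop("`data` must be a dataset tibble with columns id, label, series",
         call. = FALSE)
  }
  check_labels(data$label, both_classes = TRUE)
  invisible(data)
}

#' Per-series Slope Entropy over a dataset
#'
#' Computes SlpEn for every series in a labelled dataset under one
#' configuration, returning the dataset with an `slpen` column appended.
#'
#' @param data A dataset tibble (columns `id`, `label`, `series`), e.g. from
#'   [generate_synth()] or [load_dataset()].
#' @param cfg An [slpen_config()].
#' @param normalize If `TRUE`, each series is passed through
#'   [normalize_series()] before symbolisation, putting all series on the
#'   unit-amplitude scale that gradient thresholds in `[0.05, 1]` presume.
#'   Default `FALSE` (raw amplitudes).
#' @return `data` with a numeric `slpen` column added.
#' @export
dataset_slpen <- function(data, cfg, normalize = FALSE) {
  check_dataset(data)
  check_config(cfg)
  short <- lengths(data$series) < cfg$m
  if (any(short)) {
    stop(sprintf("series %s shorter than embedding dimension m = %d",
                 paste(data$id[short], collapse = ", "), cfg$m), call. = FALSE)
  }
  xs <- if (normalize) lapply(data$series, normalize_series) else data$series
  dplyr::mutate(data, slpen = purrr::map_dbl(
    xs, function(x) slpen_from_diffs(diff(x), cfg$m, cfg$gamma_pos, cfg$gamma_neg, cfg$delta)
  ))
}

#' Resubstitution accuracy of one SlpEn configuration
#'
#' Computes SlpEn for every series, fits the accuracy-maximising threshold on
#' the full dataset, and reports the resulting accuracy together with the
#' fitted rule. This is the "full dataset" evaluation used when reporting a
#' configuration's separating power.
#'
#' @inheritParams dataset_slpen
#' @return A one-row tibble with the configuration (`m`, `gamma_pos`,
#'   `gamma_neg`, `delta`; `delta` is `NA` for the delta-omitted variant), the
#'   `accuracy`, and the fitted `cut` and `direction`.
#' @examples
#' ds <- generate_fixture("separable_pair", seed = 1)
#' evaluate_config(ds, slpen_config(3, 0.5))
#' @export
evaluate_config <- function(data, cfg, normalize = FALSE) {
  scored <- dataset_slpen(data, cfg, normalize = normalize)
  fit <- fit_threshold_values(scored$slpen[scored$label == 0L],
                              scored$slpen[scored$label == 1L])
  tibble::tibble(
    m = cfg$m, gamma_pos = cfg$gamma_pos, gamma_neg = cfg$gamma_neg,
    delta = if (is.null(cfg$delta)) NA_real_ else cfg$delta,
    accuracy = fit$accuracy, cut = fit$cut, direction = fit$direction
  )
}
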