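#' Specify a SlpEn parameter grid
#'
#' Describes the exhaustive search space over SlpEn configurations. Three
#' variants are supported: `"asymmetric_with_delta"` (independent positive and
#' negative gamma thresholds plus a symmetric delta), `"asymmetric_no_delta"`
#' (the delta-omitted symbolisation), and `"symmetric"` (the classical form,
#' enumerating only `gamma_neg = -gamma_pos` pairs).
#'
#' The defaults mirror the conventional search ranges: `m` from 3 to 9 in
#' steps of 1 and thresholds from 0.05 to 1.00 in steps of 0.05.
#' `constrain_delta` optionally drops configurations whose delta exceeds
#' either gamma magnitude; it is off by default so that optima with
#' `delta > gamma` remain reachable.
#'
#' @param variant One of `"asymmetric_with_delta"`, `"asymmetric_no_delta"`,
#'   `"symmetric"`.
#' @param m_values Integer embedding dimensions (all >= 2).
#' @param gamma_pos_values Positive thresholds for positive slopes.
#' @param gamma_neg_values Negative thresholds for negative slopes (ignored by
#'   the symmetric variant, which pairs each `gamma_pos` with its negative).
#' @param delta_values Nonnegative tie thresholds (ignored by
#'   `"asymmetric_no_delta"`).
#' @param constrain_delta If `TRUE`, skip configurations with
#'   `delta > min(gamma_pos, abs(gamma_neg))`.
#' @return An object of class `grid_spec`.
#' @export
grid_spec <- function(variant = c("asymmetric_with_delta", "asymmetric_no_delta", "symmetric"),
                      m_values = 3:9,
                      gamma_pos_values = seq(0.05, 1, by = 0.05),
                      gamma_neg_values = -seq(0.05, 1, by = 0.05),
                      delta_values = seq(0.05, 1, by = 0.05),
                      constrain_delta = FALSE) {
  variant <- match.arg(variant)
  m_values <- sort(unique(as.integer(m_values)))
  if (length(m_values) == 0L || any(m_values < 2L)) {
    stop("`m_values` must be a nonempty set of integers >= 2", call. = FALSE)
  }
  gamma_pos_values <- sort(unique(as.double(gamma_pos_values)))
  if (length(gamma_pos_values) == 0L || any(gamma_pos_values <= 0)) {
    stop("`gamma_pos_values` must be nonempty and strictly positive", call. = FALSE)
  }
  gamma_neg_values <- sort(unique(as.double(gamma_neg_values)))
  if (variant != "symmetric" &&
      (length(gamma_neg_values) == 0L || any(gamma_neg_values >= 0))) {
    stop("`gamma_neg_values` must be nonempty and strictly negative", call. = FALSE)
  }
  if (variant != "asymmetric_no_delta") {
    delta_values <- sort(unique(as.double(delta_values)))
    if (length(delta_values) == 0L || any(delta_values < 0)) {
      stop("`delta_values` must be nonempty and nonnegative", call. = FALSE)
    }
  } else {
    delta_values <- NULL
  }
  structure(
    list(variant = variant, m_values = m_values,
         gamma_pos_values = gamma_pos_values,
         gamma_neg_values = gamma_neg_values,
         delta_values = delta_values,
         constrain_delta = isTRUE(constrain_delta)),
    class = "grid_spec"
  )
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> variant = %s; %d configurations\n",
              x$variant, nrow(enumerate_grid(x))))
  invisible(x)
}

#' Enumerate every configuration in a grid
#'
#' Expands a [grid_spec()] into its full, duplicate-free configuration table
#' in a fixed deterministic order: `m` ascending, then `gamma_pos` ascending,
#' then `abs(gamma_neg)` ascending, then `delta` ascending. The delta-omitted
#' variant carries `delta = NA`.
#'
#' @param spec A [grid_spec()].
#' @return A tibble with columns `m`, `gamma_pos`, `gamma_neg`, `delta`.
#' @examples
#' nrow(enumerate_grid(grid_spec("asymmetric_no_delta")))  # 2800
#' @export
enumerate_grid <- function(spec) {
  if (!inherits(spec, "grid_spec")) stop("`spec` must be a grid_spec", call. = FALSE)
  gp <- spec$gamma_pos_values
  if (spec$variant == "symmetric") {
    pairs <- tibble::tibble(gamma_pos = gp, gamma_neg = -gp)
  } else {
    pairs <- tidyr::expand_grid(gamma_pos = gp, gamma_neg = spec$gamma_neg_values)
  }
  grid <- tidyr::expand_grid(
    m = spec$m_values,
    pairs,
    delta = if (is.null(spec$delta_values)) NA_real_ else spec$delta_values
  )
  if (spec$constrain_delta && !is.null(spec$delta_values)) {
    grid <- dplyr::filter(grid, .data$delta <= pmin(.data$gamma_pos, abs(.data$gamma_neg)))
  }
  grid <- dplyr::distinct(grid)
  grid <- dplyr::arrange(grid, .data$m, .data$gamma_pos, abs(.data$gamma_neg), .data$delta)
  if (nrow(grid) == 0L) stop("grid specification yields no configurations", call. = FALSE)
  grid
}

row_config <- function(row) {
  slpen_config(row$m, row$gamma_pos, row$gamma_neg,
               delta = if (is.na(row$delta)) NULL else row$delta)
}

#' Exhaustive grid search for the best SlpEn configuration
#'
#' Evaluates the resubstitution accuracy of every configuration in the grid
#' (per-series SlpEn, then the optimal single-feature threshold) and returns
#' the maximiser. Ties are broken deterministically by taking the first
#' maximiser in enumeration order (smallest `m`, then thresholds ascending),
#' so repeated runs on identical inputs give identical results.
#'
#' @param data A dataset tibble (columns `id`, `label`, `series`).
#' @param spec A [grid_spec()].
#' @inheritParams dataset_slpen
#' @return An object of class `slpen_grid` with the full accuracy `surface`
#'   (one row per configuration), the `best_config` row, `best_accuracy`, and
#'   the threshold `classifier` refitted at the best configuration. Use
#'   [tidy()] for the surface, [glance()] for the optimum, and [autoplot()]
#'   for a heatmap.
#' @export
grid_search <- function(data, spec, normalize = FALSE) {
  check_dataset(data)
  grid <- enumerate_grid(spec)
  max_m <- max(grid$m)
  short <- lengths(data$series) < max_m
  if (any(short)) {
    stop(sprintf("series %s shorter than the largest embedding dimension m = %d",
                 paste(data$id[short], collapse = ", "), max_m), call. = FALSE)
  }
  xs <- if (normalize) lapply(data$series, normalize_series) else data$series
  diffs <- lapply(xs, diff)
  lab0 <- data$label == 0L

  accs <- vapply(seq_len(nrow(grid)), function(i) {
    m <- grid$m[i]; gp <- grid$gamma_pos[i]; gn <- grid$gamma_neg[i]
    dl <- if (is.na(grid$delta[i])) NULL else grid$delta[i]
    vals <- vapply(diffs, slpen_from_diffs, 0, m = m,
                   gamma_pos = gp, gamma_neg = gn, delta = dl)
    fit_threshold_values(vals[lab0], vals[!lab0])$accuracy
  }, 0)

  surface <- dplyr::mutate(grid, accuracy = accs)
  best_i <- which.max(accs)                 # first maximiser in enumeration order
  best <- surface[best_i, ]
  cfg <- row_config(best)
  scored <- dataset_slpen(data, cfg, normalize = normalize)
  classifier <- fit_threshold_values(scored$slpen[lab0], scored$slpen[!lab0])

  structure(
    list(best_config = best, best_accuracy = best$accuracy,
         classifier = classifier, surface = surface, spec = spec,
         normalize = normalize),
    class = "slpen_grid"
  )
}

#' @export
print.slpen_grid <- function(x, ...) {
  b <- x$best_config
  cat(sprintf(
    "<slpen_grid> %d configurations (%s)\nbest: m=%d, gamma_pos=%.2f, gamma_neg=%.2f, delta=%s -> accuracy %.4f\n",
    nrow(x$surface), x$spec$variant, b$m, b$gamma_pos, b$gamma_neg,
    if (is.na(b$delta)) "omitted" else sprintf("%.2f", b$delta), x$best_accuracy))
  invisible(x)
}

#' @export
tidy.slpen_grid <- function(x, ...) x$surface

#' @export
glance.slpen_grid <- function(x, ...) {
  dplyr::mutate(x$best_config,
                n_configurations = nrow(x$surface),
                variant = x$spec$variant)
}

#' Plot a grid-search accuracy surface
#'
#' Heatmap of accuracy over the two gamma thresholds, faceted by embedding
#' dimension. When several delta values were searched, the best accuracy over
#' delta is shown for each `(m, gamma_pos, gamma_neg)` cell.
#'
#' @param object An `slpen_grid` from [grid_search()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.slpen_grid <- function(object, ...) {
  surf <- object$surface
  surf <- dplyr::summarise(
    dplyr::group_by(surf, .data$m, .data$gamma_pos, .data$gamma_neg),
    accuracy = max(.data$accuracy), .groups = "drop"
  )
  ggplot2::ggplot(surf, ggplot2::aes(x = .data$gamma_pos, y = .data$gamma_neg,
                                     fill = .data$accuracy)) +
    ggplot2::geom_tile() +
    ggplot2::facet_wrap(~m, labeller = ggplot2::label_both) +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = expression(gamma[1]), y = expression(gamma[2]),
                  fill = "accuracy") +
    ggplot2::theme_minimal()
}
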