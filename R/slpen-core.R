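#' Slope Entropy configuration
#'
#' Bundles the parameters of the Slope Entropy (SlpEn) symbolisation: the
#' embedding dimension `m`, the gradient thresholds `gamma_pos` (for positive
#' slopes) and `gamma_neg` (for negative slopes, stored with its sign), and the
#' tie half-width `delta`. The classical symmetric form is the special case
#' `gamma_neg = -gamma_pos`; setting `delta = NULL` selects the delta-omitted
#' variant, in which the near-zero tie region is absorbed into the +1/-1
#' regions with the boundary at zero slope.
#'
#' `delta` larger than `gamma_pos` or `abs(gamma_neg)` is deliberately
#' permitted: the symbolisation rules are applied in a fixed order (see
#' [assign_symbols()]) and remain well defined in that regime.
#'
#' @param m Integer embedding dimension, at least 2. Each length-`m`
#'   subsequence yields a pattern of `m - 1` slope symbols.
#' @param gamma_pos Positive threshold separating large from moderate positive
#'   slopes.
#' @param gamma_neg Negative threshold separating large from moderate negative
#'   slopes. Defaults to `-gamma_pos` (symmetric form).
#' @param delta Nonnegative tie threshold: differences with `|d| <= delta` map
#'   to symbol 0. `NULL` selects the delta-omitted variant.
#' @return An object of class `slpen_config`.
#' @examples
#' slpen_config(4, 2.5)                   # symmetric, delta = 0.001
#' slpen_config(8, 0.70, -0.75, 0.05)     # asymmetric gamma
#' slpen_config(8, 0.65, -0.70, NULL)     # delta-omitted
#' @export
slpen_config <- function(m, gamma_pos, gamma_neg = -gamma_pos, delta = 0.001) {
  if (length(m) != 1L || !is.numeric(m) || !is.finite(m) || m != as.integer(m) || m < 2) {
    stop("`m` must be a single integer >= 2", call. = FALSE)
  }
  if (length(gamma_pos) != 1L || !is.finite(gamma_pos) || gamma_pos <= 0) {
    stop("`gamma_pos` must be a single positive finite number", call. = FALSE)
  }
  if (length(gamma_neg) != 1L || !is.finite(gamma_neg) || gamma_neg >= 0) {
    stop("`gamma_neg` must be a single negative finite number", call. = FALSE)
  }
  if (!is.null(delta)) {
    if (length(delta) != 1L || !is.finite(delta) || delta < 0) {
      stop("`delta` must be NULL or a single nonnegative finite number", call. = FALSE)
    }
  }
  structure(
    list(m = as.integer(m), gamma_pos = as.double(gamma_pos),
         gamma_neg = as.double(gamma_neg),
         delta = if (is.null(delta)) NULL else as.double(delta)),
    class = "slpen_config"
  )
}

#' @export
print.slpen_config <- function(x, ...) {
  cat(sprintf(
    "<slpen_config> m = %d, gamma_pos = %g, gamma_neg = %g, delta = %s%s\n",
    x$m, x$gamma_pos, x$gamma_neg,
    if (is.null(x$delta)) "omitted" else format(x$delta),
    if (abs(x$gamma_pos + x$gamma_neg) < .Machine$double.eps^0.5) " (symmetric)" else ""
  ))
  invisible(x)
}

is_slpen_config <- function(x) inherits(x, "slpen_config")

check_config <- function(cfg) {
  if (!is_slpen_config(cfg)) {
    stop("`cfg` must be an `slpen_config` object; see slpen_config()", call. = FALSE)
  }
  cfg
}

# Validate a univariate series: numeric, length >= 2, all finite.
check_series <- function(x, arg = "x") {
  if (!is.numeric(x)) stop(sprintf("`%s` must be a numeric vector", arg), call. = FALSE)
  if (length(x) < 2L) {
    stop(sprintf("`%s` must contain at least 2 samples (got %d)", arg, length(x)),
         call. = FALSE)
  }
  if (!all(is.finite(x))) {
    stop(sprintf("`%s` contains non-finite samples (NaN/Inf/NA)", arg), call. = FALSE)
  }
  invisible(x)
}

#' Consecutive-sample differences of a time series
#'
#' The slope sequence underlying SlpEn: element `k` is `x[k + 1] - x[k]`.
#'
#' @param x Numeric time series of length at least 2; all samples finite.
#' @return Numeric vector of length `length(x) - 1`.
#' @examples
#' delta_encode(c(4, 7, 9, 10, 6, 11, 3))  # 3 2 1 -4 5 -8
#' @export
delta_encode <- function(x) {
  check_series(x)
  diff(x)
}

#' Map slope differences to the five-symbol alphabet
#'
#' Assigns each consecutive-sample difference a symbol from `{-2, -1, 0, +1,
#' +2}`. With `delta` present the rules are applied in this fixed order:
#' `d > gamma_pos` gives +2; otherwise `d > delta` gives +1; otherwise
#' `|d| <= delta` gives 0; otherwise `d >= gamma_neg` gives -1; anything
#' remaining gives -2. Because the order is fixed, configurations with
#' `delta > gamma_pos` remain well defined (the +2 rule wins inside the
#' overlap). With `delta` omitted there is no 0 region: `d > gamma_pos` gives
#' +2, `gamma_pos >= d >= 0` gives +1, `0 > d >= gamma_neg` gives -1, and
#' `d < gamma_neg` gives -2; a zero difference sits on the non-negative side
#' (+1).
#'
#' All boundary comparisons are exactly as stated: a difference equal to
#' `gamma_pos` is +1, one equal to `delta` (in magnitude) is 0, and one equal
#' to `gamma_neg` is -1.
#'
#' @param d Numeric vector of finite differences.
#' @param cfg An [slpen_config()].
#' @return Integer vector of symbols, same length as `d`.
#' @examples
#' cfg <- slpen_config(4, 2.5)
#' assign_symbols(c(3, 2, 1, -4, 5, -8), cfg)
#' @export
assign_symbols <- function(d, cfg) {
  check_config(cfg)
  if (!is.numeric(d) || !all(is.finite(d))) {
    stop("`d` must be a numeric vector of finite differences", call. = FALSE)
  }
  symbols_impl(d, cfg$gamma_pos, cfg$gamma_neg, cfg$delta)
}

# Rule chain, vectorised. Assignments run from lowest- to highest-priority
# rule so that each later assignment overrides the earlier ones exactly as the
# sequential if/else chain would.
symbols_impl <- function(d, gamma_pos, gamma_neg, delta) {
  s <- rep.int(-2L, length(d))
  if (is.null(delta)) {
    s[d >= gamma_neg] <- -1L
    s[d >= 0] <- 1L
    s[d > gamma_pos] <- 2L
  } else {
    s[d >= gamma_neg] <- -1L
    s[abs(d) <= delta] <- 0L
    s[d > delta] <- 1L
    s[d > gamma_pos] <- 2L
  }
  s
}

#' Symbolic patterns of every overlapping subsequence
#'
#' Slides a window of length `m` over the series and encodes each window's
#' `m - 1` consecutive differences with [assign_symbols()], yielding the
#' `N - m + 1` symbolic patterns whose histogram defines SlpEn.
#'
#' @inheritParams assign_symbols
#' @param x Numeric time series with `length(x) >= cfg$m`.
#' @return Integer matrix with `N - m + 1` rows and `m - 1` columns; row `j`
#'   is the pattern of the subsequence starting at position `j`.
#' @examples
#' symbolize(c(4, 7, 9, 10, 6, 11, 3), slpen_config(4, 2.5))
#' @export
symbolize <- function(x, cfg) {
  check_config(cfg)
  check_series(x)
  n <- length(x)
  m <- cfg$m
  if (n < m) {
    stop(sprintf("series length N = %d is shorter than embedding dimension m = %d",
                 n, m), call. = FALSE)
  }
  s <- symbols_impl(diff(x), cfg$gamma_pos, cfg$gamma_neg, cfg$delta)
  if (m == 2L) {
    mat <- matrix(s, ncol = 1L)
  } else {
    # embed() lists each window right-to-left; flip columns back to time order
    mat <- stats::embed(s, m - 1L)[, (m - 1L):1L, drop = FALSE]
  }
  colnames(mat) <- paste0("s", seq_len(m - 1L))
  mat
}

# Base-5 code of each pattern row; exact in doubles for m <= 9 (5^8 < 2^53).
pattern_codes <- function(mat) {
  as.vector((mat + 2L) %*% 5^(seq_len(ncol(mat)) - 1L))
}

#' Relative-frequency distribution of symbolic patterns
#'
#' Counts the occurrences of each distinct pattern and normalises by the total
#' number of subsequences, so the relative frequencies sum to one. Patterns
#' that never occur are not stored.
#'
#' @param patterns Integer matrix of symbolic patterns as returned by
#'   [symbolize()] (one row per pattern, symbols in `{-2, ..., +2}`).
#' @return A tibble of class `slpen_distribution` with columns `pattern`
#'   (comma-separated signed symbols), `count` and `p`, ordered
#'   deterministically; the total number of subsequences is in attribute
#'   `total_subsequences`.
#' @examples
#' pattern_distribution(symbolize(c(4, 7, 9, 10, 6, 11, 3), slpen_config(4, 2.5)))
#' @export
pattern_distribution <- function(patterns) {
  if (!is.matrix(patterns) || nrow(patterns) == 0L) {
    stop("`patterns` must be a nonempty pattern matrix from symbolize()", call. = FALSE)
  }
  codes <- pattern_codes(patterns)
  u <- sort(unique(codes))
  counts <- tabulate(match(codes, u), nbins = length(u))
  first <- match(u, codes)
  labels <- apply(patterns[first, , drop = FALSE], 1L, function(row) {
    paste(sprintf("%+d", row), collapse = ",")
  })
  out <- tibble::tibble(pattern = labels, count = as.integer(counts),
                        p = counts / nrow(patterns))
  out <- dplyr::arrange(out, dplyr::desc(.data$count), .data$pattern)
  attr(out, "total_subsequences") <- nrow(patterns)
  class(out) <- c("slpen_distribution", class(out))
  out
}

#' @export
print.slpen_distribution <- function(x, ...) {
  cat(sprintf("# Pattern distribution over %d subsequences (%d distinct patterns)\n",
              attr(x, "total_subsequences"), nrow(x)))
  NextMethod()
}

#' Plot a pattern distribution
#'
#' Bar chart of the relative frequency of each observed symbolic pattern.
#'
#' @param object An `slpen_distribution` from [pattern_distribution()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.slpen_distribution <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$pattern <- stats::reorder(df$pattern, df$p)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pattern, y = .data$p)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = "symbolic pattern", y = "relative frequency") +
    ggplot2::theme_minimal()
}

# Fast path shared by the dataset-level evaluators: SlpEn straight from a
# precomputed difference vector.
slpen_from_diffs <- function(d, m, gamma_pos, gamma_neg, delta) {
  s <- symbols_impl(d, gamma_pos, gamma_neg, delta)
  if (m == 2L) {
    codes <- s
  } else {
    codes <- as.vector(stats::embed(s + 2L, m - 1L) %*% 5^(0:(m - 2L)))
  }
  counts <- tabulate(match(codes, unique(codes)))
  p <- counts / length(codes)
  -sum(p * log(p))
}

#' Slope Entropy of a time series
#'
#' Computes SlpEn: the Shannon entropy (natural logarithm, so in nats) of the
#' relative-frequency histogram of the symbolic slope patterns produced by
#' [symbolize()]. The result lies in `[0, log(min(N - m + 1, 5^(m - 1)))]`.
#'
#' @inheritParams symbolize
#' @return A single nonnegative number (nats).
#' @examples
#' slope_entropy(c(4, 7, 9, 10, 6, 11, 3), slpen_config(4, 2.5))  # 1.3863
#' @export
slope_entropy <- function(x, cfg) {
  check_config(cfg)
  check_series(x)
  if (length(x) < cfg$m) {
    stop(sprintf("series length N = %d is shorter than embedding dimension m = %d",
                 length(x), cfg$m), call. = FALSE)
  }
  slpen_from_diffs(diff(x), cfg$m, cfg$gamma_pos, cfg$gamma_neg, cfg$delta)
}

#' Scale a series to unit amplitude
#'
#' Centers a series and divides by its sample standard deviation. Slope
#' symbols are invariant to the centering; the scaling puts every series on
#' the unit-amplitude scale that gradient thresholds in the conventional
#' `[0.05, 1.00]` range presume. A constant series (zero standard deviation)
#' is returned centered but unscaled.
#'
#' @param x Numeric time series.
#' @return Numeric vector of the same length.
#' @export
normalize_series <- function(x) {
  check_series(x)
  s <- stats::sd(x)
  if (s == 0) x - mean(x) else (x - mean(x)) / s
}
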