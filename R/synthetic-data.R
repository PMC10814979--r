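#' Generate a synthetic Gaussian-vs-uniform benchmark dataset
#'
#' Builds the two-class synthetic benchmark used throughout the package:
#' class 0 contains independent Gaussian white-noise series and class 1
#' contains independent uniform white-noise series. The defaults follow the
#' benchmark design of 20 series per class, 3000 samples each, Gaussian mean
#' 0, and a uniform class on \[-1, 1\]; the three standard variants differ
#' only in the Gaussian standard deviation (5, 10 or 20).
#'
#' Reproducibility: the master `seed` is expanded into one sub-seed per series
#' (drawn once via `sample.int`), and each series is generated under its own
#' sub-seed, so series are independent and the dataset is identical for a
#' given seed regardless of how many series are generated before or after.
#' The global RNG state is left untouched.
#'
#' @param seed Integer master seed.
#' @param gaussian_sd Standard deviation of the Gaussian class (5, 10 and 20
#'   give the Synth1/Synth2/Synth3 variants).
#' @param gaussian_mean Mean of the Gaussian class. Default 0.
#' @param n_per_class Series per class. Default 20.
#' @param length Samples per series. Default 3000.
#' @param uniform_low,uniform_high Support of the uniform class. Default
#'   \[-1, 1\].
#' @param name Optional dataset name attribute.
#' @return A dataset tibble with columns `id`, `label` (0 = Gaussian,
#'   1 = uniform) and `series`.
#' @examples
#' ds <- generate_synth(seed = 1, gaussian_sd = 5, n_per_class = 2, length = 100)
#' @export
generate_synth <- function(seed, gaussian_sd = 5, gaussian_mean = 0,
                           n_per_class = 20L, length = 3000L,
                           uniform_low = -1, uniform_high = 1, name = NULL) {
  if (!is.finite(gaussian_sd) || gaussian_sd <= 0) {
    stop("`gaussian_sd` must be positive", call. = FALSE)
  }
  if (!is.finite(uniform_low) || !is.finite(uniform_high) || uniform_low >= uniform_high) {
    stop("`uniform_low` must be smaller than `uniform_high`", call. = FALSE)
  }
  n_per_class <- as.integer(n_per_class)
  length <- as.integer(length)
  if (n_per_class < 1L) stop("`n_per_class` must be at least 1", call. = FALSE)
  if (length < 2L) stop("`length` must be at least 2", call. = FALSE)

  sub <- derive_subseeds(seed, 2L * n_per_class)
  gauss <- lapply(seq_len(n_per_class), function(i) {
    withr::with_seed(sub[i], stats::rnorm(length, mean = gaussian_mean, sd = gaussian_sd))
  })
  unif <- lapply(seq_len(n_per_class), function(i) {
    withr::with_seed(sub[n_per_class + i],
                     stats::runif(length, min = uniform_low, max = uniform_high))
  })
  labeled_dataset(
    series = c(gauss, unif),
    labels = rep(c(0L, 1L), each = n_per_class),
    ids = c(sprintf("gauss_%03d", seq_len(n_per_class)),
            sprintf("unif_%03d", seq_len(n_per_class))),
    name = name
  )
}

#' The three standard synthetic benchmark datasets
#'
#' Convenience wrapper around [generate_synth()] selecting the Gaussian
#' standard deviation of the named variant: `"synth1"` uses SD 5, `"synth2"`
#' SD 10 and `"synth3"` SD 20; the uniform class is \[-1, 1\] in all three.
#'
#' @param which One of `"synth1"`, `"synth2"`, `"synth3"`.
#' @param seed Integer master seed.
#' @param ... Passed on to [generate_synth()].
#' @return A dataset tibble.
#' @export
synth_dataset <- function(which = c("synth1", "synth2", "synth3"), seed, ...) {
  which <- match.arg(which)
  sd <- c(synth1 = 5, synth2 = 10, synth3 = 20)[[which]]
  generate_synth(seed = seed, gaussian_sd = sd, name = which, ...)
}

# One sub-seed per series, derived once from the master seed.
derive_subseeds <- function(seed, n) {
  withr::with_seed(as.integer(seed), sample.int(.Machine$integer.max, n))
}

#' Deterministic test fixtures
#'
#' Small labelled datasets with known behaviour, used to exercise the
#' classification and search machinery:
#' \describe{
#'   \item{`constant`}{every series is constant, so SlpEn is 0 for any valid
#'     configuration and the classes are indistinguishable;}
#'   \item{`separable_pair`}{class 0 series are constant (SlpEn 0) and class 1
#'     series are Gaussian white noise (SlpEn > 0), so the SlpEn supports are
#'     disjoint by construction;}
#'   \item{`null_pair`}{both classes are drawn from the same standard Gaussian,
#'     so no configuration should separate them beyond chance.}
#' }
#'
#' @param kind One of `"constant"`, `"separable_pair"`, `"null_pair"`.
#' @param seed Integer master seed.
#' @param n_per_class Series per class. Default 10.
#' @param length Samples per series. Default 200.
#' @return A dataset tibble.
#' @export
generate_fixture <- function(kind = c("constant", "separable_pair", "null_pair"),
                             seed, n_per_class = 10L, length = 200L) {
  kind <- match.arg(kind)
  n_per_class <- as.integer(n_per_class)
  length <- as.integer(length)
  sub <- derive_subseeds(seed, 2L * n_per_class)
  noise <- function(i) withr::with_seed(sub[i], stats::rnorm(length))
  series <- switch(
    kind,
    constant = lapply(seq_len(2L * n_per_class), function(i) rep(as.double(i), length)),
    separable_pair = c(
      lapply(seq_len(n_per_class), function(i) rep(as.double(i), length)),
      lapply(n_per_class + seq_len(n_per_class), noise)
    ),
    null_pair = lapply(seq_len(2L * n_per_class), noise)
  )
  labeled_dataset(series,
                  labels = rep(c(0L, 1L), each = n_per_class),
                  name = kind)
}
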