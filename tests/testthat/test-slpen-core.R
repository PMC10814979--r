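test_that("consecutive differences are computed correctly", {
  expect_equal(delta_encode(example_series), c(3, 2, 1, -4, 5, -8))
  expect_equal(delta_encode(c(5, 5, 5, 5)), c(0, 0, 0))
  expect_equal(delta_encode(c(0, 1, 0, 1)), c(1, -1, 1))
  expect_error(delta_encode(c(1)), "at least 2")
  expect_error(delta_encode(c(1, NaN, 2)), "non-finite")
  expect_error(delta_encode(c(1, Inf)), "non-finite")
})

test_that("symbol assignment follows the five-region rule chain", {
  cfg <- slpen_config(4, 2.5, -2.5, 0.001)
  expect_identical(assign_symbols(3, cfg), 2L)
  expect_identical(assign_symbols(-4, cfg), -2L)
  expect_identical(assign_symbols(c(3, 2, 1, -4, 5, -8), cfg),
                   c(2L, 1L, 1L, -2L, 2L, -2L))
  # boundaries are strict exactly as stated
  expect_identical(assign_symbols(2.5, cfg), 1L)    # d == gamma_pos -> +1
  expect_identical(assign_symbols(-2.5, cfg), -1L)  # d == gamma_neg -> -1
  cfg2 <- slpen_config(3, 1, -1, 0.1)
  expect_identical(assign_symbols(0, cfg2), 0L)
  expect_identical(assign_symbols(c(0.1, -0.1), cfg2), c(0L, 0L))  # |d| == delta -> 0
})

test_that("delta larger than gamma is accepted and resolved in rule order", {
  # the +2 rule is checked first, so gamma_pos < d <= delta still maps to +2
  cfg <- slpen_config(5, 0.20, -0.20, 0.50)
  expect_identical(assign_symbols(c(0.3, 0.1, -0.3, -0.6), cfg),
                   c(2L, 0L, 0L, -2L))
})

test_that("delta-omitted variant splits at the zero-slope line", {
  cfg <- slpen_config(3, 2, -2, delta = NULL)
  expect_identical(assign_symbols(c(3, 1, 0, -1, -3), cfg),
                   c(2L, 1L, 1L, -1L, -2L))
  expect_identical(symbolize(c(0, 1, 0), cfg),
                   matrix(c(1L, -1L), nrow = 1, dimnames = list(NULL, c("s1", "s2"))))
})

test_that("symbolize reproduces the worked example's four patterns", {
  pats <- symbolize(example_series, slpen_config(4, 2.5, -2.5, 0.001))
  expect_identical(nrow(pats), 4L)
  expect_identical(unname(pats),
                   matrix(c( 2L,  1L,  1L,
                             1L,  1L, -2L,
                             1L, -2L,  2L,
                            -2L,  2L, -2L), nrow = 4, byrow = TRUE))
})

test_that("symbolize handles constant series and rejects short ones", {
  cfg <- slpen_config(3, 1, -1, 0.01)
  pats <- symbolize(rep(7, 10), cfg)
  expect_identical(dim(pats), c(8L, 2L))
  expect_true(all(pats == 0L))
  expect_error(symbolize(c(1, 2), slpen_config(4, 1)), "N = 2.*m = 4")
})

test_that("pattern distribution counts by total subsequences and sums to one", {
  dist <- pattern_distribution(symbolize(example_series, slpen_config(4, 2.5)))
  expect_equal(dist$p, rep(0.25, 4))
  expect_equal(sum(dist$p), 1, tolerance = 1e-12)
  expect_equal(attr(dist, "total_subsequences"), 4L)

  one <- pattern_distribution(symbolize(rep(1, 9), slpen_config(3, 1)))
  expect_identical(nrow(one), 1L)
  expect_equal(one$p, 1)

  # counts 3 and 1 over two patterns -> 0.75 / 0.25
  mixed <- matrix(c(1L, 1L,  1L, 1L,  1L, 1L,  -1L, 2L), ncol = 2, byrow = TRUE)
  d <- pattern_distribution(mixed)
  expect_equal(sort(d$p), c(0.25, 0.75))
  expect_error(pattern_distribution(matrix(integer(0), ncol = 2)), "nonempty")
})

test_that("slope entropy reproduces the worked example and trivial cases", {
  expect_equal(slope_entropy(example_series, slpen_config(4, 2.5, -2.5, 0.001)),
               1.3863, tolerance = 5e-5)
  expect_equal(slope_entropy(example_series, slpen_config(4, 2.5)), log(4))
  expect_equal(slope_entropy(rep(3.2, 50), slpen_config(5, 0.4, -0.9, 0.05)), 0)
})

test_that("slope entropy matches the naive reference on a seeded Gaussian series", {
  x <- withr::with_seed(42, rnorm(200))
  cfg <- slpen_config(3, 0.7, -0.5, 0.05)
  expect_equal(slope_entropy(x, cfg), naive_slpen(x, 3, 0.7, -0.5, 0.05),
               tolerance = 1e-12)
})

test_that("configuration validation rejects malformed parameters", {
  expect_error(slpen_config(1, 1), "m")
  expect_error(slpen_config(3, -1), "gamma_pos")
  expect_error(slpen_config(3, 1, 0.5), "gamma_neg")
  expect_error(slpen_config(3, 1, -1, -0.1), "delta")
  expect_error(slope_entropy(c(1, 2, 3), "not a config"), "slpen_config")
})

test_that("normalize_series gives unit scale and handles constants", {
  x <- withr::with_seed(1, rnorm(500, 10, 4))
  z <- normalize_series(x)
  expect_equal(sd(z), 1)
  expect_equal(mean(z), 0, tolerance = 1e-12)
  expect_equal(normalize_series(rep(2, 10)), rep(0, 10))
  # slopes are offset-invariant: shifting the series never changes SlpEn
  cfg <- slpen_config(4, 0.5, -0.4, 0.05)
  expect_equal(slope_entropy(x + 100, cfg), slope_entropy(x, cfg))
})
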