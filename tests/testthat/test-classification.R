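test_that("accuracy from confusion counts follows (tp+tn)/total", {
  expect_equal(classification_accuracy(list(tp = 2, tn = 2, fp = 0, fn = 0)), 1.0)
  expect_equal(classification_accuracy(list(tp = 1, tn = 1, fp = 1, fn = 1)), 0.5)
  expect_equal(classification_accuracy(list(tp = 3, tn = 4, fp = 1, fn = 2)), 0.7)
  expect_error(classification_accuracy(list(tp = 0, tn = 0, fp = 0, fn = 0)), "zero")
  cc <- confusion_counts(truth = c(1, 1, 0, 0, 1), pred = c(1, 0, 0, 1, 1))
  expect_identical(as.integer(c(cc$tp, cc$tn, cc$fp, cc$fn)), c(2L, 1L, 1L, 1L))
})

test_that("threshold fit handles separable, degenerate and interleaved values", {
  perfect <- fit_threshold_values(c(1, 2), c(3, 4))
  expect_equal(perfect$accuracy, 1.0)
  expect_identical(predict(perfect, c(1.5, 3.5)), c(0L, 1L))

  tied <- fit_threshold_values(c(5, 5), c(5, 5))
  expect_equal(tied$accuracy, 0.5)

  inter <- fit_threshold_values(c(1, 3), c(2, 4))
  expect_equal(inter$accuracy, 0.75)

  expect_error(fit_threshold_values(numeric(0), c(1)), "both classes")
  expect_error(fit_threshold_values(c(1, NA), c(2)), "finite")
})

test_that("threshold accuracy never falls below the majority baseline", {
  withr::with_seed(31, {
    for (i in 1:25) {
      n0 <- sample(1:15, 1); n1 <- sample(1:15, 1)
      fit <- fit_threshold_values(rnorm(n0), rnorm(n1))
      expect_gte(fit$accuracy, max(n0, n1) / (n0 + n1))
    }
  })
})

test_that("threshold fit equals exhaustive brute force on small instances", {
  withr::with_seed(23, {
    for (i in 1:30) {
      v0 <- round(rnorm(sample(2:20, 1)), 1)  # rounding forces ties across classes
      v1 <- round(rnorm(sample(2:20, 1)), 1)
      expect_equal(fit_threshold_values(v0, v1)$accuracy,
                   brute_force_threshold_accuracy(v0, v1))
    }
  })
})

test_that("threshold accuracy is invariant to strictly increasing transforms", {
  withr::with_seed(29, {
    v0 <- rnorm(12); v1 <- rnorm(12, 0.8)
    base <- fit_threshold_values(v0, v1)$accuracy
    for (f in list(function(v) exp(v), function(v) v^3 + 2 * v, function(v) atan(v))) {
      expect_equal(fit_threshold_values(f(v0), f(v1))$accuracy, base)
    }
  })
})

test_that("fit_threshold on a data frame agrees with the vector interface", {
  df <- tibble::tibble(slpen = c(1, 3, 2, 4), label = c(0L, 0L, 1L, 1L))
  fit <- fit_threshold(df)
  expect_equal(fit$accuracy, fit_threshold_values(c(1, 3), c(2, 4))$accuracy)
  td <- tidy(fit)
  expect_true(all(c("cut", "direction", "accuracy", "tp", "tn", "fp", "fn") %in% names(td)))
  expect_equal(glance(fit)$n, 4L)
})

test_that("evaluate_config composes per-series SlpEn with the threshold fit", {
  ds <- generate_fixture("separable_pair", seed = 5)
  cfg <- slpen_config(3, 0.5)
  res <- evaluate_config(ds, cfg)
  expect_equal(res$accuracy, 1.0)

  scored <- dataset_slpen(ds, cfg)
  direct <- fit_threshold_values(scored$slpen[scored$label == 0],
                                 scored$slpen[scored$label == 1])
  expect_equal(res$accuracy, direct$accuracy)
  expect_equal(res$cut, direct$cut)

  # permutation invariance in series order
  perm <- withr::with_seed(8, ds[sample(nrow(ds)), ])
  expect_equal(evaluate_config(perm, cfg)$accuracy, res$accuracy)

  # constant classes are indistinguishable: majority baseline for balanced data
  const <- generate_fixture("constant", seed = 1)
  expect_equal(evaluate_config(const, cfg)$accuracy, 0.5)

  short <- labeled_dataset(list(c(1, 2), rnorm(50), rnorm(50)), c(0L, 0L, 1L),
                           ids = c("tiny", "a", "b"))
  expect_error(evaluate_config(short, slpen_config(5, 1)), "tiny")
})

test_that("train_validate is deterministic, separates separable data, and reports both moments", {
  ds <- generate_fixture("separable_pair", seed = 2)
  spec <- grid_spec("symmetric", m_values = 3:4, gamma_pos_values = c(0.3, 0.6),
                    delta_values = 0.001)
  tv1 <- train_validate(ds, spec, train_fraction = 0.3, repeats = 5, seed = 123)
  tv2 <- train_validate(ds, spec, train_fraction = 0.3, repeats = 5, seed = 123)
  expect_identical(tidy(tv1), tidy(tv2))
  expect_equal(tv1$mean_accuracy, 1.0)
  expect_equal(tv1$sd_accuracy, 0.0)
  g <- glance(tv1)
  expect_identical(g$repeats, 5L)
  lone <- labeled_dataset(list(rnorm(60), rnorm(60), rnorm(60), rnorm(60)),
                          c(0L, 1L, 1L, 1L))
  expect_error(train_validate(lone, spec, train_fraction = 0.5),
               "degenerate split")
})

test_that("identically distributed classes validate near chance", {
  ds <- generate_fixture("null_pair", seed = 21, n_per_class = 12, length = 120)
  spec <- grid_spec("symmetric", m_values = 3, gamma_pos_values = c(0.3, 0.7),
                    delta_values = 0.05)
  tv <- train_validate(ds, spec, train_fraction = 0.3, repeats = 10, seed = 77)
  # mean over repeats should sit within 3 standard errors of 0.5
  n_val <- 18  # 12 - floor(0.3 * 12) = 9 validation series per class
  se <- sqrt(0.25 / n_val) / sqrt(10)
  expect_lt(abs(tv$mean_accuracy - 0.5), 3 * se)
})
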