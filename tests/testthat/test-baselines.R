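# Gain-ratio scoring and the uniform baseline fit/predict contract.

test_that("gain ratio matches hand-computed entropy cases", {
  expect_equal(gain_ratio(c("a", "a", "b", "b"), c(1, 1, 0, 0)), 1)
  expect_equal(gain_ratio(c("a", "a", "b", "b"), c(1, 0, 1, 0)), 0)
  # three-way split of a uniform binary target, still perfectly aligned:
  # gain = 1 bit, split info = log2(3)
  f <- c("x", "x", "y", "y", "z", "z")
  h <- function(p) ifelse(p %in% c(0, 1), 0, -p * log2(p) -
                            (1 - p) * log2(1 - p))
  expect_equal(gain_ratio(f, c(1, 1, 0, 0, 0, 0)),
               (h(1 / 3) - 0) / log2(3))
  expect_warning(r0 <- gain_ratio(rep("a", 4), c(1, 0, 1, 0)),
                 "split information")
  expect_equal(r0, 0)
  expect_error(gain_ratio("a", 1), "length")
})

test_that("gain ratio lies in [0, 1] and ignores category labels", {
  set.seed(3)
  for (i in 1:25) {
    f <- sample(letters[1:4], 40, replace = TRUE)
    y <- sample(0:2, 40, replace = TRUE)
    g <- gain_ratio(f, y)
    expect_gte(g, 0); expect_lte(g, 1)
    relab <- c(a = "Q", b = "R", c = "S", d = "T")[f]
    expect_equal(gain_ratio(relab, y), g)
    expect_equal(gain_ratio(f, c("lo", "mid", "hi")[y + 1]), g)
  }
})

test_that("every baseline honours the uniform fit/predict contract", {
  ds <- ann_dataset(fixture_table, coding = "fuzzy")
  for (id in c("DT-GE", "SVR-LNR", "SVR-POLY", "RBF-S", "RBF-N")) {
    bf <- suppressWarnings(fit_baseline(id, ds, seed = 1))
    pred <- predict(bf, ds)
    expect_identical(length(pred), nrow(ds$X))
    expect_true(all(is.finite(pred)), info = id)
    bf2 <- suppressWarnings(fit_baseline(id, ds, seed = 1))
    expect_identical(predict(bf2, ds), pred, info = id)
  }
  expect_error(baseline_spec("DT-XX"), "unknown")
})

test_that("a decision tree reproduces a constant target exactly", {
  tab <- fixture_table
  tab$prevalence <- 12.5
  tab$base_rate <- 12.5
  ds <- ann_dataset(tab, coding = "fuzzy")
  bf <- fit_baseline("DT-GE", ds, seed = 1)
  expect_equal(mmre(ds$y, predict(bf, ds)), 0)
  bs <- suppressWarnings(fit_baseline("SVR-LNR", ds, seed = 1))
  expect_lt(mmre(ds$y, predict(bs, ds)), 0.5)
})

test_that("linear-kernel SVR interpolates exactly linear data to
           under 1% MMRE", {
  tab <- fixture_table
  # target exactly linear in the model's base-rate logit feature
  f8 <- stats::qlogis(0.05 + 0.9 * tab$base_rate / 100)
  tab$prevalence <- 10 + 2 * f8
  ds <- ann_dataset(tab, coding = "fuzzy")
  spec <- baseline_spec("SVR-LNR",
                        hyperparameters = list(cost = 100, epsilon = 1e-3))
  bf <- suppressWarnings(fit_baseline(spec, ds, seed = 1))
  expect_lt(mmre(ds$y, predict(bf, ds)), 1)
})

test_that("baselines and ANN-L36 share one evaluation path", {
  ex <- run_experiment(codings = "fuzzy", baselines = c("DT-GE"),
                       config = search_config(seed = 1))
  expect_setequal(unique(ex$report$model), c("ANN-L36-Fuzzy", "DT-GE"))
  expect_true(all(c("model", "phase", "year", "mmre") %in%
                    names(ex$report)))
  expect_true(all(is.finite(ex$report$mmre)))
  expect_true(all(c("pearson", "spearman", "r2_cubic_2013",
                    "r2_cubic_2019") %in% names(ex$correlations)))
})
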