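# Synthetic cohort generation, aggregation and contingency statistics.

test_that("the printed survey composition reproduces its shares", {
  params <- serbia_stratum_params()
  m <- params$margins
  total <- sum(m$count[m$margin == "year"])
  expect_identical(total, 27801L)
  expect_identical(m$count[m$level == "2013"], 14623L)
  expect_identical(m$count[m$level == "2019"], 13178L)

  share <- function(level) {
    100 * m$count[m$level == level] / total
  }
  expect_equal(round_half_up(share("2013")), 52.6)
  expect_equal(round_half_up(share("Belgrade")), 24.3)
  expect_equal(round_half_up(share("55-64")), 18.9)
  expect_equal(round_half_up(share("female")), 52.6)
})

test_that("largest-remainder allocation is exact and proportional", {
  expect_identical(sum(allocate_counts(1000, c(1, 1, 1))), 1000L)
  expect_identical(allocate_counts(10, c(3, 3, 4)), c(3L, 3L, 4L))
  set.seed(1)
  for (i in 1:20) {
    sh <- runif(6)
    n <- sample(10:5000, 1)
    al <- allocate_counts(n, sh)
    expect_identical(sum(al), as.integer(n))
    expect_true(all(abs(al - n * sh / sum(sh)) < 1))
  }
})

test_that("cohort generation honours counts, seeds and probabilities", {
  co <- generate_cohort(seed = 9, years = 2013, n = 1500)
  expect_identical(nrow(co), 1500L)
  expect_true(all(co$year == 2013))
  expect_identical(nrow(generate_cohort(seed = 9, years = 2013, n = 1500)),
                   1500L)
  expect_identical(generate_cohort(seed = 9, years = 2013, n = 1500), co)

  pr <- stats::setNames(rep(0, 17), ncd_diseases())
  pr["Hypertension"] <- 1
  co0 <- generate_cohort(seed = 1, years = 2019, n = 300,
                         disease_prob = pr)
  expect_true(all(co0$hypertension == 1L))
  expect_true(all(co0$asthma == 0L))
})

test_that("aggregation computes percent prevalence with conserved totals", {
  co <- generate_cohort(seed = 4, n = 2000)
  overall <- aggregate_prevalence(co)
  expect_true(all(overall$prevalence >= 0 & overall$prevalence <= 100))

  by_reg <- aggregate_prevalence(co, by = "region")
  for (yr in c(2013, 2019)) {
    for (d in c("hypertension", "depression")) {
      dd <- ncd_diseases()[match(d, gsub("[^A-Za-z0-9]+", "_",
                                         tolower(ncd_diseases())))]
      sub <- by_reg[by_reg$year == yr & by_reg$disease == dd, ]
      pooled <- overall[overall$year == yr & overall$disease == dd, ]
      # sum of per-stratum positives equals pooled positives
      expect_equal(sum(sub$prevalence * sub$n / 100),
                   pooled$prevalence * pooled$n / 100, tolerance = 1e-9)
    }
  }
  expect_error(aggregate_prevalence(co, by = "height"), "unknown")
})

test_that("a four-record stratum with one positive is 25%", {
  co <- generate_cohort(seed = 1, n = 4,
                        disease_prob = stats::setNames(rep(0, 17),
                                                       ncd_diseases()))
  co$hypertension <- c(1L, 0L, 0L, 0L)
  agg <- aggregate_prevalence(co)
  hyp <- agg[agg$disease == "Hypertension", ]
  expect_equal(sum(hyp$prevalence * hyp$n) / sum(hyp$n), 25)
})

test_that("generator recovers planted prevalence within binomial error", {
  # per-stratum parameter recovery over many seeds at reduced size
  p <- 0.34; n <- 600
  se <- sqrt(p * (1 - p) / n)
  pr <- stats::setNames(rep(0.1, 17), ncd_diseases())
  pr["Hypertension"] <- p
  hits <- vapply(1:100, function(s) {
    co <- generate_cohort(seed = s, years = 2013, n = n,
                          disease_prob = pr)
    abs(mean(co$hypertension) - p) <= 4 * se
  }, logical(1))
  expect_gte(mean(hits), 0.99)
})

test_that("odds ratio matches its closed form, interval and symmetries", {
  expect_equal(odds_ratio(10, 10, 10, 10)$or, 1)
  res <- odds_ratio(20, 10, 10, 20)
  expect_equal(res$or, 4)
  # oracle: direct evaluation of the Woolf formula
  se <- sqrt(1 / 20 + 1 / 10 + 1 / 10 + 1 / 20)
  z <- stats::qnorm(0.975)
  expect_equal(res$ci_low, exp(log(4) - z * se))
  expect_equal(res$ci_high, exp(log(4) + z * se))
  expect_equal(res$ci_low, 1.365, tolerance = 5e-3)
  expect_equal(res$ci_high, 11.72, tolerance = 5e-3)
  expect_equal(res$p_value, 2 * stats::pnorm(-log(4) / se))

  # swap both rows and both columns simultaneously: invariant
  expect_equal(odds_ratio(20, 10, 10, 20)$or, odds_ratio(20, 10, 10, 20)$or)
  expect_equal(odds_ratio(7, 3, 11, 13)$or, odds_ratio(13, 11, 3, 7)$or)
  # swap exposure labels: reciprocal
  expect_equal(odds_ratio(7, 3, 11, 13)$or,
               1 / odds_ratio(11, 13, 7, 3)$or)

  expect_error(odds_ratio(0, 5, 5, 5), "continuity correction")
  expect_silent(odds_ratio(0, 5, 5, 5, correct = TRUE))
})

test_that("pooled two-proportion z agrees with prop.test", {
  expect_equal(two_proportion_test(50, 100, 50, 100)$z, 0)
  expect_equal(two_proportion_test(50, 100, 50, 100)$p_value, 1)

  res <- two_proportion_test(340, 1000, 300, 1000)
  ref <- stats::prop.test(c(340, 300), c(1000, 1000), correct = FALSE)
  expect_equal(res$z^2, unname(ref$statistic))
  expect_equal(res$p_value, ref$p.value)
  # frozen oracle value: 0.04 / sqrt(0.32 * 0.68 * 2/1000)
  expect_equal(res$z, 1.9174126, tolerance = 1e-6)

  expect_error(two_proportion_test(0, 10, 0, 10), "degenerate")
  expect_error(two_proportion_test(11, 10, 5, 10), "require")
})
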