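# Orthogonal array and factorial-plan arithmetic.

test_that("full factorial size is exact and multiplicative", {
  plan <- factorial_plan(c(rep(2, 11), rep(3, 12)))
  expect_identical(full_factorial_size(plan), 2^11 * 3^12)
  expect_identical(full_factorial_size(plan), 1088391168)
  expect_identical(full_factorial_size(factorial_plan(2)), 2)
  expect_identical(full_factorial_size(factorial_plan(c(2, 2, 3))), 12)

  # multiplicative over plan concatenation
  a <- c(2, 3, 3); b <- c(2, 2)
  expect_identical(full_factorial_size(factorial_plan(c(a, b))),
                   full_factorial_size(factorial_plan(a)) *
                     full_factorial_size(factorial_plan(b)))

  expect_error(factorial_plan(integer()), "at least one factor")
  expect_error(factorial_plan(c(2, 1)), "at least 2 levels")
})

test_that("reduction fraction follows its formula and is monotone", {
  plan <- factorial_plan(c(rep(2, 11), rep(3, 12)))
  expect_equal(reduction_fraction(plan, 36), 1 - 36 / 1088391168,
               tolerance = 0)
  # the printed percentage with an extra digit is a misprint; the formula
  # value begins 0.9999999669, not 0.999999999669
  expect_false(isTRUE(all.equal(reduction_fraction(plan, 36),
                                0.999999999669, tolerance = 1e-11)))
  expect_identical(reduction_fraction(factorial_plan(2), 2), 0)
  expect_identical(reduction_fraction(factorial_plan(2), 1), 0.5)
  expect_error(reduction_fraction(factorial_plan(2), 3), "exceeds")

  runs <- c(1, 10, 36, 1000, 1e6)
  fr <- vapply(runs, function(n) reduction_fraction(plan, n), numeric(1))
  expect_true(all(diff(fr) < 0))
})

test_that("the embedded L36 array matches the printed patterns", {
  expect_identical(l36$n_rows, 36L)
  expect_identical(sum(l36$n_levels == 2L), 11L)
  expect_identical(sum(l36$n_levels == 3L), 12L)
  expect_true(all(l36$cells["ANN1", ] == 1L))
  expect_identical(unname(l36$cells["ANN2", ]),
                   c(rep(1L, 11), rep(2L, 12)))
  expect_identical(unname(l36$cells["ANN3", ]),
                   c(rep(1L, 11), rep(3L, 12)))
})

test_that("the array passes every balance invariant", {
  rep_ <- oa_balance(l36)
  expect_identical(nrow(rep_$violations), 0L)
  expect_identical(unname(rep_$column_counts$W1), c(18L, 18L))
  expect_identical(unname(rep_$column_counts$W12), c(12L, 12L, 12L))
  # every (2-level, 3-level) pair shows each of the 6 combinations 6 times
  pw <- rep_$pair_counts
  w1w12 <- pw[pw$factor_a == "W1" & pw$factor_b == "W12", ]
  expect_identical(w1w12$min_count, 6L)
  expect_identical(w1w12$max_count, 6L)
  expect_true(all(pw$min_count == pw$expected))
  expect_true(all(pw$max_count == pw$expected))
})

test_that("array CSV round trip is bit-exact and validation bites", {
  path <- withr::local_tempfile(fileext = ".csv")
  write_oa_csv(l36, path)
  back <- read_oa_csv(path)
  expect_identical(back$cells, l36$cells)

  # corrupt one cell: balance validation must name the failure
  broken <- l36$cells
  broken[1L, 1L] <- 2L
  df <- as.data.frame(broken)
  path2 <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(df, path2, row.names = FALSE, quote = FALSE)
  expect_error(read_oa_csv(path2), "integrity failure")
})
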