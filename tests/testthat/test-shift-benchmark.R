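# Regression scaling of shieldings to shifts and CMAE scoring.

toy_records <- function(sigma, delta, nucleus = "1H") {
  tibble::tibble(
    compound_id = "cmpd01", nucleus = nucleus,
    site = paste0("s", seq_along(sigma)),
    sigma_calc = sigma, delta_exp = delta, n_equivalent = 1L
  )
}

test_that("OLS slope and intercept are recovered on exact data", {
  m <- fit_shift_model(toy_records(c(0, 1), c(1, 3)))
  expect_equal(m$A, 2, tolerance = 1e-12)
  expect_equal(m$B, 1, tolerance = 1e-12)
  # noise-free inversion of a realistic proton map
  sigma <- seq(22, 31, length.out = 40)
  m2 <- fit_shift_model(toy_records(sigma, -1.05 * sigma + 31.2))
  expect_equal(m2$A, -1.05, tolerance = 1e-10)
  expect_equal(m2$B, 31.2, tolerance = 1e-8)
})

test_that("degenerate regressions are errors", {
  expect_error(fit_shift_model(toy_records(c(2, 2), c(1, 3))),
               "degenerate")
  expect_error(fit_shift_model(toy_records(2, 1)), "degenerate")
  mixed <- dplyr::bind_rows(toy_records(c(1, 2), c(1, 2), "1H"),
                            toy_records(c(10, 20), c(1, 2), "13C"))
  expect_error(fit_shift_model(mixed), "one kind at a time")
  expect_identical(fit_shift_model(mixed, nucleus = "13C")$nucleus, "13C")
})

test_that("estimated slope sits within three closed-form standard errors", {
  A <- -1.05; B <- 31.2; sd <- 0.1; n <- 500
  withr::with_seed(123, {
    sigma <- stats::runif(n, 20, 32)
    delta <- A * sigma + B + stats::rnorm(n, 0, sd)
  })
  m <- fit_shift_model(toy_records(sigma, delta))
  # closed-form OLS sampling sd of the slope with known noise sd
  se <- sd / sqrt(sum((sigma - mean(sigma))^2))
  expect_lt(abs(m$A - A), 3 * se)
  # the model's own standard error agrees with the closed form
  expect_equal(tidy(m)$std.error[2], se, tolerance = 0.15)
})

test_that("scaled shifts are the fitted line, and kinds must match", {
  rec <- toy_records(c(25, 26, 27), c(5, 4, 3))
  m <- fit_shift_model(rec)
  scored <- scale_shifts(rec, m)
  expect_equal(scored$delta_scaled, m$A * rec$sigma_calc + m$B,
               tolerance = 1e-12)
  # identity model passes sigma through
  ident <- m; ident$A <- 1; ident$B <- 0
  expect_equal(scale_shifts(rec, ident)$delta_scaled, rec$sigma_calc,
               tolerance = 1e-12)
  carbon <- toy_records(c(100, 120), c(30, 50), nucleus = "13C")
  expect_error(scale_shifts(carbon, m), "fitted for 1H")
})

test_that("CMAE is zero iff the data are collinear, and bounded by the worst residual", {
  perfect <- toy_records(c(25, 26, 27), c(6.5, 5.45, 4.4))
  expect_equal(cmae(perfect)$cmae, 0, tolerance = 1e-12)
  noisy <- toy_records(c(25, 26, 27, 28), c(6.5, 5.0, 4.8, 3.1))
  st <- cmae(noisy)
  expect_gt(st$cmae, 0)
  expect_lte(st$cmae, max(abs(st$records$delta_scaled - st$records$delta_exp)))
})

test_that("CMAE is invariant under affine transforms of the shieldings", {
  rec <- make_shift_dataset(synthetic_shift_spec("1H", seed = 7,
                                                 n_shifts = 200))
  base <- cmae(rec)$cmae
  withr::with_seed(31, {
    for (i in 1:5) {
      a <- stats::runif(1, -3, 3)
      while (abs(a) < 0.05) a <- stats::runif(1, -3, 3)
      b <- stats::runif(1, -50, 50)
      tr <- dplyr::mutate(rec, sigma_calc = a * .data$sigma_calc + b)
      expect_lt(abs(cmae(tr)$cmae - base), 1e-10)
    }
  })
})

test_that("per-compound breakdown and outlier ranking are consistent", {
  spec <- synthetic_shift_spec("1H", seed = 3, n_shifts = 300,
                               outlier_fraction = 0.05)
  st <- cmae(make_shift_dataset(spec))
  expect_identical(sum(st$per_compound$n), st$n)
  expect_equal(sum(st$per_compound$mae * st$per_compound$n) / st$n,
               st$cmae, tolerance = 1e-12)
  if (nrow(st$outliers) > 1) {
    expect_true(all(diff(st$outliers$abs_error) <= 0))
  }
  expect_true(all(st$outliers$abs_error > st$outlier_threshold))
  g <- glance(st)
  expect_identical(g$n, st$n)
})

test_that("shift tables round-trip through csv and tsv with validation", {
  rec <- make_shift_dataset(synthetic_shift_spec("13C", seed = 5,
                                                 n_shifts = 50))
  csv <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(rec, csv)
  expect_equal(read_shift_table(csv)$sigma_calc, rec$sigma_calc,
               tolerance = 1e-12)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(rec, tsv)
  expect_identical(nrow(read_shift_table(tsv)), nrow(rec))
  bad <- rec
  bad$nucleus[17] <- "15N"
  badfile <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(bad, badfile)
  expect_error(read_shift_table(badfile), "row 17")
})

test_that("equivalent nuclei collapse to averaged shieldings", {
  rec <- tibble::tibble(
    compound_id = "cmpd01", nucleus = "1H",
    site = c("Me", "Me", "Me", "H5"),
    sigma_calc = c(29.0, 29.2, 29.4, 26.0),
    delta_exp = c(1.2, 1.2, 1.2, 5.0),
    n_equivalent = 1L
  )
  col <- collapse_equivalent(rec)
  expect_identical(nrow(col), 2L)
  me <- col[col$site == "Me", ]
  expect_equal(me$sigma_calc, 29.2, tolerance = 1e-12)
  expect_identical(me$n_equivalent, 3L)
})

test_that("cost ratios follow the cubic scaling law", {
  expect_identical(cost_ratio(100, 100), 1)
  expect_identical(cost_ratio(200, 100), 8)
  expect_error(cost_ratio(10, 0), "positive")
  # recount oracle on ethylene: level-2 vs level-1 schemes
  mols <- fixture_molecules()
  n1 <- count_molecular_functions(mols$ethylene, pecs_synthetic(1))
  n2 <- count_molecular_functions(mols$ethylene, pecs_synthetic(2))
  expect_identical(n1, 2L * 18L + 4L * 5L)
  expect_identical(n2, 2L * 34L + 4L * 14L)
  expect_equal(cost_ratio(n2, n1), (124 / 56)^3, tolerance = 1e-12)
})
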