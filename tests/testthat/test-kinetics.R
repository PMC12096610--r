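test_that("curve validation accepts monotone data and flags dips", {
  ok <- validate_curve(glucose_curve(c(0, 12, 30)))
  expect_length(ok$warnings, 0)

  dip <- validate_curve(glucose_curve(c(0, 30, 28),
                                      time_min = c(0, 240, 360)))
  expect_length(dip$warnings, 1)
  expect_match(dip$warnings, "240-360")

  expect_error(glucose_curve(c(0, -1, 5)), ">= 0")
  expect_error(glucose_curve(c(0, 1, 2), time_min = c(0, 20, 20)),
               "duplicate|increasing")
  expect_error(glucose_curve(c(0, 1, 2), time_min = c(20, 0, 60)),
               "increasing")
})

test_that("interval rates follow the direct-difference formula", {
  cv <- glucose_curve(c(0, 12, 30))
  expect_equal(interval_rate(cv, 0, 20), 0.6)
  expect_equal(interval_rate(cv, 20, 60), 0.45)

  flat <- glucose_curve(c(3, 5, 5), time_min = c(0, 20, 60))
  expect_equal(interval_rate(flat, 20, 60), 0)

  # measured baseline, not assumed zero
  nonzero0 <- glucose_curve(c(4, 14), time_min = c(0, 20))
  expect_equal(interval_rate(nonzero0, 0, 20), 0.5)

  dip <- glucose_curve(c(0, 30, 28), time_min = c(0, 240, 360))
  expect_warning(k <- interval_rate(dip, 240, 360),
                 class = "cnsync_negative_rate")
  expect_equal(k, -2 / 120)

  expect_error(interval_rate(cv, 20, 20), "strictly less")
  expect_error(suppressWarnings(interval_rate(cv, 0, 30)), "grid")
  expect_equal(interval_rate(cv, 0, 30, interpolate = TRUE),
               (12 + 10 * 18 / 40) / 30)
  # phases keep separate clocks: no cross-phase rate
  expect_error(interval_rate(glucose_curve(c(1, 2), time_min = c(60, 120),
                                           phase = "gastric"),
                             60, 120),
               "no points in the intestinal")
})

test_that("rate series preserves order, flags negatives, telescopes", {
  cv <- glucose_curve(c(0, 12, 30))
  rs <- rate_series(cv, c(0, 20, 60))
  expect_equal(rs$rate, c(0.6, 0.45))
  expect_equal(rs$t1, c(0, 20))
  expect_false(any(rs$flag_negative))

  one <- rate_series(cv, c(0, 20))
  expect_equal(nrow(one), 1)

  const <- glucose_curve(c(7, 7, 7))
  expect_true(all(rate_series(const, c(0, 20, 60))$rate == 0))

  expect_error(rate_series(cv, c(0, 25)), "subset")

  dip <- glucose_curve(c(0, 30, 28), time_min = c(0, 240, 360))
  expect_true(rate_series(dip, c(0, 240, 360))$flag_negative[2])

  # telescoping: sum K_i * dt_i recovers the net release, exactly
  set.seed(11)
  for (i in 1:20) {
    tt <- sort(sample(seq(0, 480, 10), 6))
    dd <- cumsum(abs(rnorm(6, 5)))
    cv <- glucose_curve(dd, time_min = tt)
    rs <- rate_series(cv, tt)
    expect_equal(sum(rs$rate * (rs$t2 - rs$t1)), dd[6] - dd[1],
                 tolerance = 1e-12)
  }
})

test_that("swapping interval endpoint values negates the rate", {
  set.seed(7)
  for (i in 1:10) {
    d <- abs(rnorm(2, 10))
    a <- glucose_curve(c(d[1], d[2]), time_min = c(0, 20))
    b <- glucose_curve(c(d[2], d[1]), time_min = c(0, 20))
    expect_equal(suppressWarnings(interval_rate(a, 0, 20)),
                 -suppressWarnings(interval_rate(b, 0, 20)))
  }
})

test_that("replicate summaries give pointwise mean and SEM", {
  reps <- lapply(1:3, function(r) {
    glucose_curve(c(0, c(9, 10, 11)[r], 30), rep = r)
  })
  sm <- summarize_replicates(reps)
  expect_equal(sm$mean[sm$time_min == 20], 10)
  expect_equal(sm$sem[sm$time_min == 20], 1 / sqrt(3),
               tolerance = 1e-10)
  expect_equal(sm$sem[sm$time_min == 0], 0)

  same <- lapply(1:3, function(r) glucose_curve(c(0, 10, 30), rep = r))
  sm2 <- summarize_replicates(same)
  expect_equal(sm2$mean, c(0, 10, 30))
  expect_true(all(sm2$sem == 0))

  expect_error(summarize_replicates(same[1]), "at least 2")
  bad <- c(same[1], list(glucose_curve(c(0, 10), time_min = c(0, 20),
                                       rep = 2)))
  expect_error(summarize_replicates(bad), "grids")
})

test_that("unit conversion scales by 10 and round-trips exactly", {
  cv <- glucose_curve(c(0, 5, 8), unit = "g/100g")
  conv <- convert_units(cv, "g/kg")
  expect_equal(conv$data$cumulative, c(0, 50, 80))
  expect_equal(conv$unit, "g/kg")
  back <- convert_units(conv, "g/100g")
  expect_identical(back$data$cumulative, cv$data$cumulative)

  aa <- release_curve("d1", "total_amino_acids", 1, "intestinal",
                      c(0, 20), c(0, 5), "mmol/kg")
  expect_error(convert_units(aa, "g/kg"), "no defined conversion")

  # converting units commutes with taking rates
  k_then_scale <- interval_rate(cv, 0, 20) * 10
  scale_then_k <- interval_rate(conv, 0, 20)
  expect_equal(k_then_scale, scale_then_k, tolerance = 1e-12)
})

test_that("long-format CSV round-trips through curve objects", {
  df <- curves_to_df(list(glucose_curve(c(0, 12, 30)),
                          glucose_curve(c(0, 10, 25), rep = 2)))
  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(df, path)
  curves <- read_release_curves(path)
  expect_length(curves, 2)
  expect_equal(curves_to_df(curves), df)

  expect_error(curves_from_df(df[, -3]), "missing required columns")
  mixed <- df
  mixed$unit[1] <- "g/100g"
  expect_error(curves_from_df(mixed), "mixes units")
})
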