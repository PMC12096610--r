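test_that("first-order curves match the closed form and are deterministic", {
  rc <- simulate_release_curve("d1", "glucose",
                               kinetic_params(A = 150, k = 0.02),
                               n_rep = 1, seed = 9)[[1]]
  d20 <- 150 * (1 - exp(-0.02 * 20))
  expect_equal(rc$data$cumulative[rc$data$time_min == 20], d20)
  expect_equal(d20, 49.45199, tolerance = 1e-6)
  expect_equal(interval_rate(rc, 0, 20), d20 / 20) # 2.4726 g/kg/min

  zero <- simulate_release_curve("d1", "glucose", kinetic_params(150, 0),
                                 n_rep = 1)[[1]]
  expect_true(all(zero$data$cumulative == 0))

  a <- simulate_release_curve("d1", "glucose", kinetic_params(150, 0.02),
                              n_rep = 3, seed = 5)
  b <- simulate_release_curve("d1", "glucose", kinetic_params(150, 0.02),
                              n_rep = 3, seed = 5)
  expect_identical(curves_to_df(a), curves_to_df(b))
  noisy1 <- simulate_release_curve("d1", "glucose",
                                   kinetic_params(150, 0.02, sigma = 5),
                                   n_rep = 3, seed = 5)
  noisy2 <- simulate_release_curve("d1", "glucose",
                                   kinetic_params(150, 0.02, sigma = 5),
                                   n_rep = 3, seed = 5)
  expect_identical(curves_to_df(noisy1), curves_to_df(noisy2))
  expect_false(identical(curves_to_df(noisy1), curves_to_df(a)))

  expect_error(simulate_release_curve("d1", "glucose",
                                      kinetic_params(150, 0.02),
                                      schedule = list(intestinal = numeric(0))),
               "schedule")
  expect_error(kinetic_params(-1, 0.02), ">= 0")
})

test_that("noiseless curves saturate below A with decreasing rates", {
  lag_par <- kinetic_params(A = 100, k = 0.03, lag = 30)
  rc <- simulate_release_curve("d1", "glucose", lag_par, n_rep = 1)[[1]]
  expect_true(all(diff(rc$data$cumulative) >= 0))
  expect_true(all(rc$data$cumulative <= 100))
  expect_equal(rc$data$cumulative[rc$data$time_min == 20], 0) # within lag

  nolag <- simulate_release_curve("d1", "glucose",
                                  kinetic_params(100, 0.03),
                                  n_rep = 1)[[1]]
  rs <- rate_series(nolag, c(0, 20, 60, 90, 120, 240, 360, 480))
  expect_true(all(rs$rate > 0))
  expect_true(all(diff(rs$rate) < 0)) # first-order: rates decay over time
})

test_that("diet panel orders glucose release by waxy fraction", {
  df <- simulate_diet_panel(sigma_frac = 0, seed = 2)
  st <- sync_table(df, letters = FALSE)
  ord <- c("RGR_HGR", "MRGR_MHGR", "MGR_MGR", "MSGR_MLGR", "SGR_LGR")
  relg <- st$rel_gaa_mean[match(ord, st$diet)]
  expect_true(all(diff(relg) < 0)) # higher waxy fraction, faster glucose

  # identical endpoints make every diet the panel average
  same <- simulate_diet_panel(
    glucose = list(fast = list(A = 400, k = 0.02),
                   slow = list(A = 400, k = 0.02)),
    sigma_frac = 0, seed = 2)
  st2 <- sync_table(same, letters = FALSE)
  expect_equal(st2$rel_gaa_mean, rep(1, 5), tolerance = 1e-9)
  expect_true(all(st2$class == "Syn"))

  expect_warning(
    simulate_diet_panel(glucose = list(fast = list(A = 100, k = 0.03),
                                       slow = list(A = 400, k = 0.008)),
                        sigma_frac = 0, seed = 1),
    "smaller asymptote")

  # fixed seed reproduces the dataset byte for byte
  expect_identical(simulate_diet_panel(seed = 17),
                   simulate_diet_panel(seed = 17))
})

test_that("designed amplitudes hit Relative G/AA targets exactly", {
  targets <- c(1.3, 1.2, 1.6, 0.4, 0.7)
  dp <- design_panel_params(targets)
  df <- simulate_diet_panel(glucose_A = dp$glucose_A, aa_A = dp$aa_A,
                            sigma_frac = 0, seed = 1)
  st <- sync_table(df, letters = FALSE)
  ord <- c("RGR_HGR", "MRGR_MHGR", "MGR_MGR", "MSGR_MLGR", "SGR_LGR")
  expect_equal(st$rel_gaa_mean[match(ord, st$diet)], targets,
               tolerance = 1e-9)
  expect_error(design_panel_params(c(2, 2, 2)), "equal 1")
  expect_equal(design_panel_params(c(1, 1, 1))$aa_A, rep(900, 3))
})

test_that("ingredient archetypes map to distinct dominant curve shapes", {
  arch <- tibble::tibble(rate = c("rapid", "slow"),
                         level = c("high", "low"),
                         duration = c("persistent", "transient"))
  curves <- simulate_ingredient_panel(arch, seed = 3)
  expect_length(curves, 6)
  expect_true(all(vapply(curves, function(cv) cv$unit == "g/100g",
                         logical(1))))
  strong <- curves[[1]]$data # rapid/high/persistent, rep 1
  weak <- curves[[4]]$data   # slow/low/transient, rep 1
  gt0 <- strong$time_min > 0
  expect_true(all(strong$cumulative[gt0] > weak$cumulative[gt0]))

  single <- simulate_ingredient_panel(tibble::tibble(
    rate = "rapid", level = "high", duration = "transient"))
  expect_length(single, 3)

  many <- do.call(rbind, replicate(23, arch[1, ], simplify = FALSE))
  expect_length(simulate_ingredient_panel(many, seed = 1), 69)

  expect_error(simulate_ingredient_panel(tibble::tibble(
    rate = "medium", level = "high", duration = "transient")),
    "unknown rate")
})

test_that("trial simulation is reproducible and rejects impossible truths", {
  a <- simulate_trial(trial_config(n_per_diet = 2), seed = 4)
  b <- simulate_trial(trial_config(n_per_diet = 2), seed = 4)
  expect_identical(a$digesta_assay, b$digesta_assay)
  expect_identical(a$balance, b$balance)

  expect_error(trial_config(true_aid = matrix(101, 5, 5)), "exceed 100")
  expect_error(trial_config(n_per_diet = 1), ">= 2")

  # truth table pairs AID with its endogenous-corrected SID
  expect_true(all(a$truth_digestibility$sid_true >=
                    a$truth_digestibility$aid_true))
})

test_that("AID recovery at n = 200 simulated animals per diet", {
  tr <- simulate_trial(trial_config(n_per_diet = 200), seed = 11)
  res <- aid_sid_table(tr$diet_assay, tr$digesta_assay)
  est <- res$per_animal |>
    dplyr::group_by(diet_id, analyte) |>
    dplyr::summarise(aid_hat = mean(aid),
                     se = sd(aid) / sqrt(dplyr::n()), .groups = "drop") |>
    dplyr::left_join(tr$truth_digestibility, by = c("diet_id", "analyte"))
  expect_true(all(abs(est$aid_hat - est$aid_true) <= 3 * est$se))
})
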