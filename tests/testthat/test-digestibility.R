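test_that("total tract digestibility follows the intake-fecal formula", {
  expect_equal(attd(40, 14.4), 64)
  expect_equal(attd(20, 0), 100)
  expect_equal(attd(20, 20), 0)
  expect_error(attd(0, 1), "> 0")
  expect_warning(neg <- attd(10, 12), "exceeds intake")
  expect_equal(neg, -20)
  # complement identity, exact
  set.seed(31)
  for (i in 1:20) {
    fi <- runif(1, 10, 30); fe <- runif(1, 0, fi)
    expect_equal(attd(fi, fe) + 100 * fe / fi, 100, tolerance = 1e-12)
  }
})

test_that("marker-ratio AID matches hand values and ratio invariances", {
  expect_equal(aid(5, 10, 2, 4), 75)
  expect_equal(aid(0, 10, 2, 4), 100)
  expect_equal(aid(5, 10, 2, 1), 0) # digesta/diet equals marker dilution
  expect_error(aid(5, 0, 2, 4), "basal_endogenous_loss")
  expect_warning(aid(30, 10, 2, 4), "negative AID")

  set.seed(32)
  for (i in 1:10) {
    x <- runif(4, 0.5, 10) # aa_digesta, aa_diet, cr_diet, cr_digesta
    c1 <- runif(1, 0.1, 5); c2 <- runif(1, 0.1, 5)
    base <- suppressWarnings(aid(x[1], x[2], x[3], x[4]))
    expect_equal(suppressWarnings(aid(x[1], x[2], x[3] * c1, x[4] * c1)),
                 base, tolerance = 1e-12)
    expect_equal(suppressWarnings(aid(x[1] * c2, x[2] * c2, x[3], x[4])),
                 base, tolerance = 1e-12)
  }
})

test_that("basal endogenous losses pool per-animal marker-scaled flows", {
  dig <- tibble::tibble(
    animal_id = c("p1", "p2"),
    analyte = "lysine",
    value = c(5, 5),
    cr_digesta = c(4, 2.5)
  )
  out <- basal_endogenous_loss(dig, cr_diet = 2)
  expect_equal(out$iaa, mean(c(5 * 2 / 4, 5 * 2 / 2.5))) # (2.5 + 4)/2
  expect_equal(out$n, 2)

  zero <- basal_endogenous_loss(
    tibble::tibble(animal_id = "p1", analyte = "lysine", value = 0,
                   cr_digesta = 4), cr_diet = 2)
  expect_equal(zero$iaa, 0)

  expect_error(basal_endogenous_loss(dig[0, ], 2), "no nitrogen-free")
  med <- basal_endogenous_loss(dig, 2, fun = stats::median)
  expect_equal(med$iaa, stats::median(c(2.5, 4)))
})

test_that("SID adds the endogenous correction and never drops below AID", {
  expect_equal(sid(75, 0.5, 10), 80)
  expect_equal(sid(75, 0, 10), 75)
  expect_error(sid(75, 0.5, 0), "> 0")
  expect_error(sid(75, -1, 10), ">= 0")
  set.seed(33)
  for (i in 1:20) {
    a <- runif(1, -10, 95); iaa <- runif(1, 0, 3); cc <- runif(1, 1, 20)
    s <- sid(a, iaa, cc)
    expect_gte(s, a)
    expect_equal(s - a, 100 * iaa / cc, tolerance = 1e-12)
    if (iaa == 0) expect_identical(s, a)
  }
})

test_that("balance fractions complement ATTD and handle edge intakes", {
  fr <- balance_fractions(20, 8.76, 0.4, 40, 14.4, 5)
  expect_equal(fr$fe_fige, 43.8)
  expect_equal(fr$fn_fin, 36)
  expect_equal(fr$fe_fige + attd(20, 8.76), 100, tolerance = 1e-12)
  expect_equal(balance_fractions(20, 0, 0, 40, 0, 0)$fe_fige, 0)
  expect_error(balance_fractions(0, 1, 1, 40, 1, 1), "> 0")
})

test_that("growth metrics divide by days on test", {
  gp <- growth_performance(28.0, 33.22, 9, 11.16)
  expect_equal(gp$adg, 0.58)
  expect_equal(gp$adfi, 1.24)
  expect_equal(growth_performance(30, 30, 9, 9)$adg, 0)
  expect_error(growth_performance(30, 31, 0, 9), "days")
})

test_that("balance_table computes all per-animal metrics at once", {
  bal <- tibble::tibble(
    animal_id = "p1", diet_id = "d1",
    fi_ge = 20, fe_ge = 7.34, ue_ge = 0.376,
    fi_n = 19, fe_n = 6.0, un_n = 2.7,
    bw_start = 28.0, bw_end = 33.22, days = 9, feed_total = 11.16
  )
  tab <- balance_table(bal)
  expect_equal(tab$attd_ge, attd(20, 7.34))
  expect_equal(tab$attd_ge + tab$fe_fige, 100, tolerance = 1e-12)
  expect_equal(tab$attd_n + tab$fn_fin, 100, tolerance = 1e-12)
  expect_equal(tab$adg, 0.58)
  expect_error(balance_table(bal[, -3]), "missing balance columns")
})

test_that("noiseless trial inverts exactly through the AID/SID pipeline", {
  cfg <- trial_config(conc_cv = 0, balance_cv = 0, adfi_sd = 0,
                      n_per_diet = 2)
  tr <- simulate_trial(cfg, seed = 2)
  res <- aid_sid_table(tr$diet_assay, tr$digesta_assay)
  est <- res$per_animal |>
    dplyr::group_by(diet_id, analyte) |>
    dplyr::summarise(aid = mean(aid), sid = mean(sid), .groups = "drop") |>
    dplyr::left_join(tr$truth_digestibility, by = c("diet_id", "analyte"))
  expect_lt(max(abs(est$aid - est$aid_true)), 1e-9)
  expect_lt(max(abs(est$sid - est$sid_true)), 1e-9)
  # NF animals return the configured endogenous losses exactly
  expect_equal(
    res$endogenous$iaa[match(names(cfg$true_iaa),
                             res$endogenous$analyte)],
    unname(cfg$true_iaa), tolerance = 1e-12)
  # balance records are exactly consistent with the balance truths
  bt <- balance_table(tr$balance) |>
    dplyr::group_by(diet_id) |>
    dplyr::summarise(attd_ge = mean(attd_ge), adg = mean(adg),
                     .groups = "drop") |>
    dplyr::left_join(tr$truth_balance, by = "diet_id")
  expect_lt(max(abs(bt$attd_ge.x - bt$attd_ge.y)), 1e-9)
  expect_lt(max(abs(bt$adg.x - bt$adg.y)), 1e-9)
})

test_that("estimated AID recovers truth within sampling error at n = 6", {
  tr <- simulate_trial(trial_config(), seed = 7)
  res <- aid_sid_table(tr$diet_assay, tr$digesta_assay)
  est <- res$per_animal |>
    dplyr::group_by(diet_id, analyte) |>
    dplyr::summarise(aid_hat = mean(aid),
                     se = sd(aid) / sqrt(dplyr::n()), .groups = "drop") |>
    dplyr::left_join(tr$truth_digestibility, by = c("diet_id", "analyte"))
  expect_true(all(abs(est$aid_hat - est$aid_true) <= 3 * est$se))
})
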