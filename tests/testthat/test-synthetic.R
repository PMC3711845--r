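test_that("synthetic cost records reproduce the generating means", {
  spec <- default_spec()
  rec <- generate_cost_records(stage_mix = c(local = 1),
                               gamma_specs = spec$costs$treatment,
                               n = 68, seed = 21,
                               eol_spec = spec$costs$end_of_life)
  expect_equal(nrow(rec), 68)
  expect_true(all(rec$stage == "local"))
  tot <- rec$cost_m1_6 + rec$cost_m7_12 + rec$cost_m13_18
  expect_true(all(tot >= 0))
  # sample mean within 3 standard errors of the published mean
  expect_lt(abs(mean(tot) - 10940), 3 * sd(tot) / sqrt(68))
  # deaths carry end-of-life costs over their last three intervals
  if (any(rec$died)) {
    expect_true(all(rowSums(rec[rec$died, c("eol_m1_6", "eol_m7_12",
                                            "eol_m13_18")]) > 0))
  }
  expect_true(all(rec[!rec$died, c("eol_m1_6", "eol_m7_12",
                                   "eol_m13_18")] == 0))
})

test_that("cost-record generation is reproducible and handles n = 1", {
  spec <- default_spec()
  a <- generate_cost_records(gamma_specs = spec$costs$treatment, n = 40,
                             seed = 5)
  b <- generate_cost_records(gamma_specs = spec$costs$treatment, n = 40,
                             seed = 5)
  expect_identical(a, b)
  one <- generate_cost_records(gamma_specs = spec$costs$treatment, n = 1,
                               seed = 5)
  expect_equal(nrow(one), 1)
})

test_that("gamma MLE recovers generating parameters at n = 10,000", {
  spec <- default_spec()
  gen <- spec$costs$treatment$local
  rec <- generate_cost_records(stage_mix = c(local = 1),
                               gamma_specs = spec$costs$treatment,
                               n = 10000, seed = 31, p_death = 0)
  fit <- fit_gamma_mle(rec, "local")
  expect_equal(dist_mean(fit), dist_mean(gen), tolerance = 0.02)
  expect_equal(unname(fit$params[["shape"]]),
               unname(gen$params[["shape"]]), tolerance = 0.10)
})

test_that("gamma MLE at the study's n = 68 is unbiased but imprecise", {
  spec <- default_spec()
  set.seed(41)
  means <- replicate(30, {
    rec <- generate_cost_records(stage_mix = c(local = 1),
                                 gamma_specs = spec$costs$treatment,
                                 n = 68, seed = sample.int(1e6, 1),
                                 p_death = 0)
    dist_mean(fit_gamma_mle(rec, "local"))
  })
  expect_equal(mean(means), 10940, tolerance = 0.15 * 10940)
  expect_gt(sd(means), 0.04 * 10940)  # wide sampling spread at n = 68
})

test_that("degenerate cost samples are rejected", {
  rec <- data.frame(stage = "local", cost_m1_6 = rep(5, 5),
                    cost_m7_12 = 0, cost_m13_18 = 0)
  expect_error(fit_gamma_mle(rec, "local"), "degenerate")
  expect_error(fit_gamma_mle(rec[1, ], "local"), "at least 2")
})

test_that("synthetic survival records match the generating curve", {
  ps <- calibrated_ps()
  rec <- generate_survival_records(ps$weibull["local"], censor_time = 15,
                                   n = 10000, seed = 51)
  km <- survival::survfit(survival::Surv(time, event) ~ 1, data = rec)
  s5 <- summary(km, times = 5)$surv
  expect_lt(abs(s5 - 0.968), 3 * sqrt(0.968 * 0.032 / 10000))
  # administrative censoring and the degenerate in-situ spec
  tiny <- generate_survival_records(ps$weibull["local"],
                                    censor_time = 1e-3, n = 50, seed = 52)
  expect_true(all(tiny$event == 0))
  insitu <- generate_survival_records(ps$weibull["in_situ"],
                                      censor_time = 15, n = 50, seed = 53)
  expect_true(all(insitu$event == 0))
  expect_true(all(insitu$time == 15))
  expect_identical(
    generate_survival_records(ps$weibull["local"], 15, 100, seed = 54),
    generate_survival_records(ps$weibull["local"], 15, 100, seed = 54))
})

test_that("censoring-aware Weibull MLE recovers generating parameters", {
  ps <- calibrated_ps()
  # distant stage: low censoring at a 15-year window
  rec <- generate_survival_records(ps$weibull["distant"], censor_time = 15,
                                   n = 10000, seed = 61)
  expect_lt(mean(rec$event == 0), 0.5)
  fit <- fit_weibull_mle(rec, "distant")
  gen <- ps$weibull$distant
  expect_equal(fit$shape, gen$shape, tolerance = 0.05)
  expect_equal(fit$scale, gen$scale, tolerance = 0.05)
  expect_lt(abs(weibull_survival(fit, 5) - weibull_survival(gen, 5)), 0.01)
  expect_lt(abs(weibull_survival(fit, 10) - weibull_survival(gen, 10)),
            0.01)

  # exponential special case, essentially uncensored
  expo <- list(exp = structure(list(shape = 1, scale = 8, stage = "exp",
                                    degenerate = FALSE),
                               class = "weibull_spec"))
  rec2 <- generate_survival_records(expo, censor_time = 200, n = 10000,
                                    seed = 62)
  fit2 <- fit_weibull_mle(rec2, "exp")
  expect_equal(fit2$shape, 1, tolerance = 0.05)

  # no observed events: cannot fit
  insitu <- generate_survival_records(ps$weibull["in_situ"], 15, 100,
                                      seed = 63)
  expect_error(fit_weibull_mle(insitu, "in_situ"), "events")
})

test_that("heavy censoring degrades recovery but stays unbiased in S(5)", {
  ps <- calibrated_ps()
  # local stage at a 15-year window is ~83% censored; S(5) is still
  # well-estimated because events before 5 years are observed
  rec <- generate_survival_records(ps$weibull["local"], censor_time = 15,
                                   n = 10000, seed = 71)
  expect_gt(mean(rec$event == 0), 0.5)
  fit <- fit_weibull_mle(rec, "local")
  expect_lt(abs(weibull_survival(fit, 5) - 0.968), 0.01)
})
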