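test_that("conditional sensitivities solve the joint-detection identity", {
  # MRI 77%, mammography 39%, either 94% -> printed 90% / 74%
  cs <- derive_conditional_sensitivities(0.77, 0.39, 0.94)
  expect_equal(unname(cs[1]), 0.55 / 0.61, tolerance = 1e-12)
  expect_equal(unname(cs[2]), 0.17 / 0.23, tolerance = 1e-12)
  expect_equal(round(100 * unname(cs)), c(90, 74))

  # combined no better than either: detections coincide
  expect_equal(unname(derive_conditional_sensitivities(0.5, 0.5, 0.5)),
               c(0, 0))
  # independence: conditionals equal marginals
  expect_equal(unname(derive_conditional_sensitivities(0.6, 0.3, 0.72)),
               c(0.6, 0.3), tolerance = 1e-12)
})

test_that("reconstructing se_either from the conditionals is exact", {
  set.seed(5)
  for (i in 1:200) {
    se_a <- runif(1, 0.05, 0.99)
    se_b <- runif(1, 0.05, 0.99)
    joint <- runif(1, max(0, se_a + se_b - 1), min(se_a, se_b))
    se_either <- se_a + se_b - joint
    cs <- derive_conditional_sensitivities(se_a, se_b, se_either)
    expect_equal(se_b + (1 - se_b) * cs[["se_a_given_b_neg"]], se_either,
                 tolerance = 1e-12)
    expect_equal(se_a + (1 - se_a) * cs[["se_b_given_a_neg"]], se_either,
                 tolerance = 1e-12)
  }
})

test_that("inconsistent sensitivity triples are rejected with the triple", {
  expect_error(derive_conditional_sensitivities(0.8, 0.7, 0.6), "0.6")
  expect_error(derive_conditional_sensitivities(0.3, 0.2, 0.6),
               "inconsistent")
})

test_that("band risk converts to a compounding-exact per-cycle probability", {
  p <- band_risk_to_cycle_prob(0.015, 20)
  expect_equal(1 - (1 - p)^20, 0.015, tolerance = 1e-14)
  expect_equal(p, 1 - (1 - 0.015)^(1 / 20), tolerance = 1e-14)
  expect_equal(band_risk_to_cycle_prob(0, 20), 0)
  expect_equal(1 - (1 - band_risk_to_cycle_prob(0.20, 20))^20, 0.20,
               tolerance = 1e-14)
  expect_error(band_risk_to_cycle_prob(1, 20), "risk10")
})

test_that("per-cycle probability is monotone in risk and cycle count", {
  risks <- seq(0.01, 0.9, by = 0.05)
  p <- band_risk_to_cycle_prob(risks, 20)
  expect_true(all(diff(p) > 0))
  for (r in c(0.05, 0.5)) {
    pc <- vapply(c(2, 5, 10, 20, 40), band_risk_to_cycle_prob,
                 numeric(1), risk10 = r)
    expect_true(all(diff(pc) < 0))
  }
})

test_that("the packaged configuration reproduces the published inputs", {
  ps <- mean_parameter_set(default_spec())
  expect_equal(ps$screening$se_mri, 0.77)
  expect_equal(ps$screening$se_mam, 0.39)
  expect_equal(ps$screening$se_combined, 0.94)
  expect_equal(round(100 * ps$screening$se_mri_given_mam_fn), 90)
  expect_equal(round(100 * ps$screening$se_mam_given_mri_fn), 74)
  expect_equal(ps$incidence$risk10, c(0.015, 0.086, 0.18, 0.20, 0.18))
  expect_equal(unname(ps$costs$treatment),
               c(3427, 10940, 23612, 15645))
  expect_equal(ps$costs$mri, 277)
  expect_equal(unname(ps$utilities$treatment),
               c(0.965, 0.860, 0.675, 0.380))
  expect_equal(ps$utilities$remission, 0.965)
  expect_equal(ps$model$discount_rate, 0.035)
  # stage rows renormalised from rows printed as 101%
  expect_equal(sum(ps$stages$mri_detected), 1, tolerance = 1e-12)
  expect_equal(unname(ps$stages$mam_detected),
               c(0.27, 0.49, 0.22, 0.02), tolerance = 1e-12)
})

test_that("loading the same configuration twice is deterministic", {
  expect_identical(load_parameter_spec(), load_parameter_spec())
})

test_that("invalid configurations fail with the offending path", {
  cfg <- yaml::read_yaml(system.file("extdata", "config_default.yaml",
                                     package = "brcascreen"))
  bad <- cfg
  bad$stages$mam_detected$p <- c(0.40, 0.40, 0.20, 0.10)
  f <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(bad, f)
  expect_error(load_parameter_spec(f), "mam_detected")

  bad2 <- cfg
  bad2$costs$mri <- NULL
  f2 <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(bad2, f2)
  expect_error(load_parameter_spec(f2), "mri")
})

test_that("parameter-set invariants catch corrupted values", {
  ps <- mean_parameter_set(default_spec())
  ps$utilities$treatment[["local"]] <- 1.4
  expect_error(validate_parameter_set(ps), "utilities")
  ps2 <- mean_parameter_set(default_spec())
  ps2$stages$non_screen[2] <- ps2$stages$non_screen[2] + 0.2
  expect_error(validate_parameter_set(ps2), "simplex")
})
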