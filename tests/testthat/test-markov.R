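test_that("screening schedules follow the programme design", {
  m <- default_spec()$model
  sc <- build_screening_schedule("combined", m)
  # first event: MRI at age 25
  expect_identical(sc$events[1], "mri")
  expect_equal(sc$ages[1], 25)
  # ages 30-64.5: strict MRI/mammogram alternation every cycle
  alt <- sc$events[sc$ages >= 30 & sc$ages < 65]
  expect_true(all(alt != "none"))
  expect_true(all(alt[seq(1, length(alt), 2)] == "mri"))
  expect_true(all(alt[seq(2, length(alt), 2)] == "mammogram"))
  # 25-29: annual MRI only
  young <- sc$events[sc$ages < 30]
  expect_true(all(young %in% c("mri", "none")))
  expect_equal(sum(young == "mri"), 5)
  # 65-79: annual mammography only
  old <- sc$events[sc$ages >= 65 & sc$ages < 80]
  expect_true(all(old %in% c("mammogram", "none")))
  expect_equal(sum(old == "mammogram"), 15)
  expect_true(all(sc$events[sc$ages >= 80] == "none"))

  sm <- build_screening_schedule("mammography_only", m)
  expect_true(all(sm$events[sm$ages < 30] == "none"))     # e.g. age 27
  expect_equal(sum(sm$events == "mammogram"), 50)          # annual 30-79
  expect_true(all(sm$ages[sm$events == "mammogram"] %% 1 == 0))
})

test_that("detection probabilities follow the conditional-sensitivity rules", {
  ps <- mean_parameter_set(default_spec())
  expect_equal(detection_probability("mri", "mam", 40, ps, "combined"),
               0.55 / 0.61, tolerance = 1e-12)
  expect_equal(detection_probability("mammogram", "mri", 40, ps, "combined"),
               0.17 / 0.23, tolerance = 1e-12)
  expect_equal(detection_probability("mri", "none", 40, ps, "combined"),
               0.77)
  expect_equal(detection_probability("none", "none", 40, ps, "combined"), 0)
  # age-specific mammography in the comparator arm
  expect_equal(detection_probability("mammogram", "none", 45, ps,
                                     "mammography_only"), 0.70)
  expect_equal(detection_probability("mammogram", "none", 75, ps,
                                     "mammography_only"), 0.84)
  # combined arm falls back to age-specific mammography once MRI stops
  expect_equal(detection_probability("mammogram", "none", 70, ps,
                                     "combined"), 0.84)
})

test_that("false-positive flow matches direct arithmetic", {
  ps <- mean_parameter_set(default_spec())
  f <- false_positive_flow(0.86, ps)
  expect_equal(unname(f["cost"]), 0.14 * 187, tolerance = 1e-12)
  expect_equal(unname(f["qaly_decrement"]),
               0.14 * (1 - 0.987) * 14 / 365.25, tolerance = 1e-12)
  expect_equal(unname(false_positive_flow(1, ps)), c(0, 0))
})

test_that("post-diagnosis value matches an independent summation", {
  # in-situ disease, no background mortality: closed-form stream
  ps <- calibrated_ps()
  ps$background$gompertz_a <- 0
  cache <- make_engine_cache(ps)
  d <- 60
  v <- post_diagnosis_value("in_situ", d, ps, cache)
  gam <- 1.035^(-0.5)
  n <- cache$n
  j <- seq_len(n - d)
  u_j <- ifelse(j <= 20, 0.965, 1)          # treatment = remission utility
  expect_equal(v$qalys, 0.5 * sum(u_j * gam^(d + j)), tolerance = 1e-9)
  expect_equal(v$cost, sum((3427 / 3) * gam^(d + (1:3))), tolerance = 1e-9)

  # zero discount, no background mortality, no cancer death: plain sums
  ps0 <- calibrated_ps()
  ps0$model$discount_rate <- 0
  ps0$background$gompertz_a <- 0
  cache0 <- make_engine_cache(ps0)
  v0 <- post_diagnosis_value("in_situ", d, ps0, cache0)
  expect_equal(v0$qalys,
               3 * 0.5 * 0.965 + 17 * 0.5 * 0.965 + (n - d - 20) * 0.5 * 1,
               tolerance = 1e-9)

  # distant stage: end-of-life cost accrues for deaths in cycles 4-20 and
  # treatment thirds for cycles survived, matching direct enumeration
  vd <- post_diagnosis_value("distant", d, ps0, cache0)
  pD <- death_density_by_cycle(ps0$weibull$distant, 20, 0.5)
  p_surv <- 1 - sum(pD)
  exp_treat <- p_surv * 3
  exp_eol <- 0
  for (D in 1:20) {
    prog <- terminal_pathway_allocation(D)$progressive_cycles
    exp_eol <- exp_eol + pD[D] * length(prog) / 3 * 26704
    exp_treat <- exp_treat + pD[D] * length(setdiff(seq_len(min(3, D - 1)),
                                                    prog))
  }
  expect_equal(vd$cost, exp_treat / 3 * 15645 + exp_eol, tolerance = 1e-9)
  # cancer mortality within 10 years is 1 - S(10)
  expect_equal(sum(pD), 1 - 0.102, tolerance = 1e-12)
})

test_that("cohort occupancies are conserved every cycle", {
  bc <- base_case()
  comps <- c("well", "undetected", "diagnosed_new", "treatment",
             "remission", "progressive", "cured", "dead_cancer",
             "dead_other")
  for (arm in c("combined", "mammography_only")) {
    tot <- rowSums(bc[[arm]]$trace[, comps])
    expect_lt(max(abs(tot - 1)), 1e-10)
    expect_true(all(as.matrix(bc[[arm]]$trace[, comps]) >= -1e-12))
  }
})

test_that("with zero incidence the arms differ only by screening burden", {
  spec <- default_spec()
  lv <- brcascreen:::mean_leaves(spec)
  lv$incidence <- rep(0, 5)
  ps <- brcascreen:::assemble_parameter_set(spec, lv)
  ps$background <- calibrated_ps()$background
  cache <- make_engine_cache(ps)
  rc <- run_cohort("combined", ps, keep_trace = FALSE, cache = cache)
  rm_ <- run_cohort("mammography_only", ps, keep_trace = FALSE,
                    cache = cache)
  expect_equal(sum(rc$stats$onsets), 0)
  expect_equal(sum(rc$stats$md), 0)
  # combined arm strictly costlier, and (through extra false-positive
  # work-ups) at most as effective
  expect_gt(rc$cost - rm_$cost, 0)
  expect_lte(rc$qalys - rm_$qalys, 0)
})

test_that("perfect screening detects every cancer arising in-programme", {
  spec <- default_spec()
  lv <- brcascreen:::mean_leaves(spec)
  lv$se_mri <- 1; lv$se_mam <- 1; lv$se_combined <- 1
  lv$sp_mri <- 1; lv$sp_mam <- 1; lv$sp_combined <- 1
  lv$mam_alone_se <- rep(1, 4); lv$mam_alone_sp <- rep(1, 4)
  ps <- brcascreen:::assemble_parameter_set(spec, lv)
  ps$background <- calibrated_ps()$background
  rc <- run_cohort("combined", ps, keep_trace = FALSE)
  expect_equal(rc$stats$program_sensitivity_by(65), 1, tolerance = 1e-12)
})

test_that("discounting reduces totals and vanishes at rate zero", {
  ps <- calibrated_ps()
  ps0 <- ps
  ps0$model$discount_rate <- 0
  r <- run_cohort("combined", ps, keep_trace = FALSE)
  r0 <- run_cohort("combined", ps0, keep_trace = FALSE)
  expect_gt(r0$cost, r$cost)
  expect_gt(r0$qalys, r$qalys)
  # at rate zero the discount weights are identically 1
  cache0 <- make_engine_cache(ps0)
  expect_true(all(cache0$disc == 1))
})

test_that("incremental summaries label dominance correctly", {
  lab <- brcascreen:::icer_label
  expect_identical(lab(100, -0.1)$label, "dominated")
  expect_identical(lab(-100, 0.1)$label, "dominant")
  expect_identical(lab(0, 0)$label, "equivalent")
  expect_identical(lab(100, 0.01)$label, "icer")
  expect_equal(lab(100, 0.01)$value, 10000)

  bc <- base_case()
  s_eq <- summarize_cea(bc$combined, bc$combined)
  expect_identical(s_eq$icer_label, "equivalent")
  expect_equal(s_eq$delta_cost, 0)
})

test_that("program sensitivity is higher with MRI for any performance draw", {
  spec <- default_spec()
  bg <- calibrated_ps()$background
  cache <- engine_cache_fx()
  set.seed(9)
  for (i in 1:5) {
    ps <- sample_parameter_set(spec, bg)
    rc <- run_cohort("combined", ps, keep_trace = FALSE, cache = cache)
    rm_ <- run_cohort("mammography_only", ps, keep_trace = FALSE,
                      cache = cache)
    expect_gte(rc$stats$program_sensitivity_by(65),
               rm_$stats$program_sensitivity_by(65))
  }
})
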