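# Independent individual-level microsimulation of one strategy arm.
#
# This is the primary correctness oracle for the cohort engine: it
# simulates women one by one (vectorised) through onset, screening,
# detection, staging, cancer death, background death and accrual, using
# only the parameter set and elementary formulas, and estimates the same
# per-arm totals the expected-value engine computes.
microsim_arm <- function(arm, ps, n_women, seed) {
  m <- ps$model
  h <- m$cycle_length_years
  n <- round((m$horizon_age - m$start_age) / h)
  ages <- m$start_age + (seq_len(n) - 1) * h
  gamma <- (1 + m$discount_rate)^(-h)
  disc <- gamma^seq_len(n)

  # schedule (re-derived here, independently of build_screening_schedule)
  whole <- abs(ages - round(ages)) < 1e-9
  ev <- rep("none", n)
  if (arm == "combined") {
    ev[whole & ages >= m$mri_ages[1] & ages <= m$mri_ages[2]] <- "mri"
    ev[!whole & ages > m$mam_ages_combined[1] &
         ages < m$mam_ages_combined[2] + 1] <- "mam"
  } else {
    ev[whole & ages >= m$mam_ages_alone[1] &
         ages <= m$mam_ages_alone[2]] <- "mam"
  }

  sc <- ps$screening
  band <- pmin(pmax(findInterval(ages, sc$mam_alone$age_lo), 1L),
               nrow(sc$mam_alone))
  sens_of <- function(event_t, hist, t) {
    if (event_t == "none") return(0)
    if (arm == "mammography_only") return(sc$mam_alone$se[band[t]])
    if (event_t == "mri") {
      if (hist == "mam") sc$se_mri_given_mam_fn else sc$se_mri
    } else {
      if (hist == "mri") sc$se_mam_given_mri_fn
      else if (ages[t] >= m$mri_ages[2] + 1) sc$mam_alone$se[band[t]]
      else sc$se_mam
    }
  }
  spec_t <- vapply(seq_len(n), function(t) {
    if (ev[t] == "none") return(1)
    if (arm == "mammography_only" ||
        (ev[t] == "mam" && ages[t] >= m$mri_ages[2] + 1)) {
      sc$mam_alone$sp[band[t]]
    } else if (ev[t] == "mri") sc$sp_mri else sc$sp_mam
  }, numeric(1))
  cost_t <- ifelse(ev == "mri", ps$costs$mri,
                   ifelse(ev == "mam", ps$costs$mammogram, 0))

  inc <- ps$incidence
  bi <- pmin(pmax(findInterval(ages, inc$age_lo), 1L), nrow(inc))
  p_on <- 1 - (1 - inc$risk10[bi])^(h / (inc$age_hi[1] - inc$age_lo[1]))
  p_on[ages < inc$age_lo[1]] <- 0

  a <- ps$background$gompertz_a
  b <- ps$background$gompertz_b
  q <- 1 - exp(-(a / b) * (exp(b * (ages + h)) - exp(b * ages)))

  set.seed(seed)
  F_bg <- 1 - cumprod(1 - q)
  t_bg <- findInterval(stats::runif(n_women), F_bg) + 1L  # n+1 = never
  F_on <- 1 - cumprod(1 - p_on)
  t_on <- findInterval(stats::runif(n_women), F_on) + 1L
  has_ca <- t_on <= n & t_on < t_bg

  # detection path (two screening chances at onset cycle and the next),
  # vectorised via per-cycle sensitivity lookups
  se1_t <- vapply(seq_len(n), function(t) sens_of(ev[t], "none", t),
                  numeric(1))
  se2_t <- vapply(seq_len(n), function(t) {
    c(none = sens_of(ev[t], "none", t),
      mri = sens_of(ev[t], "mri", t),
      mam = sens_of(ev[t], "mam", t))
  }, numeric(3))
  dx_cycle <- rep(NA_integer_, n_women)
  dx_mode <- rep(NA_character_, n_women)
  u1 <- stats::runif(n_women)
  u2 <- stats::runif(n_women)
  t1 <- pmin(t_on, n)
  det1 <- has_ca & u1 < se1_t[t1]
  dx_cycle[det1] <- t_on[det1]
  dx_mode[det1] <- ev[t1[det1]]
  second <- has_ca & !det1 & (t_on + 1L <= n) & (t_bg > t_on + 1L)
  t2 <- pmin(t_on + 1L, n)
  hist <- match(ev[t1], c("none", "mri", "mam"))
  p2 <- se2_t[cbind(hist, t2)]
  det2 <- second & u2 < p2
  dx_cycle[second] <- t_on[second] + 1L
  dx_mode[second] <- ifelse(det2[second], ev[t2[second]], "ns")
  diagnosed <- !is.na(dx_cycle)

  # stage and cancer-death cycle, vectorised within mode / stage groups
  stage <- rep(NA_character_, n_women)
  d_ca <- rep(Inf, n_women)  # cycles since diagnosis of cancer death
  u3 <- stats::runif(n_women)
  u4 <- stats::runif(n_women)
  rowfor <- list(mri = ps$stages$mri_detected,
                 mam = ps$stages$mam_detected,
                 ns = ps$stages$non_screen)
  cure <- m$cure_cycles
  pD_stage <- lapply(ps$weibull, function(w) {
    if (w$degenerate) rep(0, cure)
    else {
      t <- seq_len(cure) * h
      s <- exp(-(c(0, t) / w$scale)^w$shape)
      s[-length(s)] - s[-1]
    }
  })
  for (mo in names(rowfor)) {
    g <- which(diagnosed & dx_mode == mo)
    if (!length(g)) next
    stage[g] <- STAGES_MS[findInterval(u3[g], cumsum(rowfor[[mo]])) + 1L]
  }
  for (s in STAGES_MS) {
    g <- which(diagnosed & stage == s)
    if (!length(g)) next
    cd <- cumsum(pD_stage[[s]])
    died <- u4[g] < cd[cure]
    d_ca[g[died]] <- findInterval(u4[g[died]], cd) + 1L
  }

  # --- accrual -----------------------------------------------------------
  cumdisc <- cumsum(disc)
  cumcost <- cumsum(cost_t * disc)
  wd_dec <- (1 - ps$utilities$workup) * m$workup_duration_days / 365.25

  # end of the screening phase (last cycle accrued in screening states)
  scr_end <- pmin(ifelse(diagnosed, dx_cycle, n), t_bg - 1L, n)
  # undiagnosed onset (death before resolution): accrue as well until death
  alive0 <- scr_end >= 1L
  qaly <- ifelse(alive0, h * cumdisc[pmax(scr_end, 1L)], 0)
  cost <- ifelse(alive0, cumcost[pmax(scr_end, 1L)], 0)
  # diagnosis work-up for all diagnosed (screen- or clinically detected)
  dxed <- diagnosed & dx_cycle <= scr_end
  cost[dxed] <- cost[dxed] + ps$costs$workup * disc[dx_cycle[dxed]]
  qaly[dxed] <- qaly[dxed] - wd_dec * disc[dx_cycle[dxed]]

  # false-positive work-ups while alive and cancer free
  fp_end <- pmin(t_on - 1L, t_bg - 1L, n)
  for (t in which(ev != "none")) {
    at_risk <- which(fp_end >= t)
    if (!length(at_risk)) next
    hit <- at_risk[stats::runif(length(at_risk)) < 1 - spec_t[t]]
    cost[hit] <- cost[hit] + ps$costs$workup * disc[t]
    qaly[hit] <- qaly[hit] - wd_dec * disc[t]
  }

  # post-diagnosis streams, grouped by (stage, cancer-death cycle)
  u <- ps$utilities
  co <- ps$costs
  tc <- m$treatment_cycles
  groups <- split(which(dxed), paste(stage[dxed], d_ca[dxed]))
  for (g in groups) {
    s <- stage[g[1]]
    D <- d_ca[g[1]]
    u_j <- numeric(n)
    k_j <- numeric(n)
    lastj <- if (is.finite(D)) D - 1L else n
    for (j in seq_len(min(lastj, n))) {
      if (is.finite(D) && D >= 4 && j >= D - 3 && j <= D - 1) {
        u_j[j] <- u$progression
        k_j[j] <- co$end_of_life / m$terminal_cycles
      } else if (j <= tc) {
        u_j[j] <- u$treatment[[s]]
        k_j[j] <- co$treatment[[s]] / tc
      } else if (j <= cure) {
        u_j[j] <- u$remission
      } else {
        u_j[j] <- 1
      }
    }
    Gq <- cumsum(u_j * gamma^seq_len(n))
    Gk <- cumsum(k_j * gamma^seq_len(n))
    d <- dx_cycle[g]
    L <- pmin(lastj, t_bg[g] - 1L - d, n - d)
    ok <- L >= 1L
    qaly[g[ok]] <- qaly[g[ok]] + h * disc[d[ok]] * Gq[L[ok]]
    cost[g[ok]] <- cost[g[ok]] + disc[d[ok]] * Gk[L[ok]]
  }

  t65 <- round((65 - m$start_age) / h)
  dead_by65 <- (t_bg <= t65) |
    (is.finite(d_ca) & dxed & (dx_cycle + d_ca) <= t65)
  onset65 <- has_ca & ages[pmin(t_on, n)] < 65

  list(n = n_women,
       mean_cost = mean(cost), se_cost = stats::sd(cost) / sqrt(n_women),
       mean_qaly = mean(qaly), se_qaly = stats::sd(qaly) / sqrt(n_women),
       survival65 = mean(!dead_by65),
       cum_incidence65 = mean(onset65),
       prog_sens65 = {
         det <- dxed & onset65
         sum(det & dx_mode != "ns") / sum(det)
       })
}

STAGES_MS <- c("in_situ", "local", "regional", "distant")
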