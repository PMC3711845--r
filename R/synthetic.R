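#' Generate synthetic patient-level treatment-cost records
#'
#' Emulates an administrative extract of per-patient treatment costs over
#' the first 18 months after diagnosis: each patient's total is drawn from
#' the stage's Gamma distribution and split over the three 6-month
#' intervals by a front-loaded Dirichlet share (most cost falls in months
#' 1-6). A subset of patients are flagged as having died of breast
#' cancer; they additionally carry end-of-life costs over their last three
#' 6-month intervals, split by a back-loaded Dirichlet share.
#'
#' @param stage_mix Named probabilities over stages (defaults to equal).
#' @param gamma_specs Named list of `dist_spec` gamma objects per stage
#'   (e.g. from a `parameter_spec`'s `costs$treatment`).
#' @param n Number of patients.
#' @param seed Integer seed (records are reproducible from it).
#' @param p_death Fraction flagged as cancer deaths.
#' @param eol_spec Gamma `dist_spec` for the end-of-life total.
#' @param split_alpha,eol_alpha Dirichlet concentrations for the interval
#'   shares.
#' @return Data frame: `patient`, `stage`, `cost_m1_6`, `cost_m7_12`,
#'   `cost_m13_18`, `died`, `eol_m1_6`, `eol_m7_12`, `eol_m13_18`.
#' @export
generate_cost_records <- function(stage_mix = NULL, gamma_specs, n, seed,
                                  p_death = 10 / 68, eol_spec = NULL,
                                  split_alpha = c(6, 4, 2),
                                  eol_alpha = c(2, 3, 5)) {
  stopifnot(n >= 1)
  if (is.null(stage_mix)) {
    stage_mix <- stats::setNames(rep(1 / length(gamma_specs),
                                     length(gamma_specs)),
                                 names(gamma_specs))
  }
  set.seed(seed)
  stage <- sample(names(stage_mix), n, replace = TRUE,
                  prob = as.numeric(stage_mix))
  total <- vapply(stage, function(s) dist_draw(gamma_specs[[s]], 1L),
                  numeric(1))
  share <- rdirichlet(n, split_alpha)
  died <- stats::runif(n) < p_death
  eol <- matrix(0, n, 3)
  if (any(died) && !is.null(eol_spec)) {
    ne <- sum(died)
    eol[died, ] <- dist_draw(eol_spec, ne) * rdirichlet(ne, eol_alpha)
  }
  data.frame(patient = seq_len(n), stage = unname(stage),
             cost_m1_6 = total * share[, 1],
             cost_m7_12 = total * share[, 2],
             cost_m13_18 = total * share[, 3],
             died = died,
             eol_m1_6 = eol[, 1], eol_m7_12 = eol[, 2],
             eol_m13_18 = eol[, 3])
}

#' Maximum-likelihood Gamma fit to treatment-cost records
#'
#' Fits a Gamma distribution to the per-patient 18-month totals of one
#' stage by maximum likelihood.
#'
#' @param records Data frame from [generate_cost_records()] (or real
#'   records with the same columns).
#' @param stage Stage to fit.
#' @return A `dist_spec` (family gamma) whose `source` records the sample
#'   mean and the fitted 95% interval.
#' @export
fit_gamma_mle <- function(records, stage) {
  tot <- with(records[records$stage == stage, ],
              cost_m1_6 + cost_m7_12 + cost_m13_18)
  if (length(tot) < 2L) stop("need at least 2 records for stage ", stage)
  if (stats::sd(tot) == 0) stop("degenerate sample: all totals equal")
  fit <- fitdistrplus::fitdist(as.numeric(tot), "gamma", method = "mle",
                               lower = c(1e-8, 1e-12),
                               start = list(shape = mean(tot)^2 /
                                              stats::var(tot),
                                            rate = mean(tot) /
                                              stats::var(tot)))
  k <- unname(fit$estimate["shape"])
  th <- 1 / unname(fit$estimate["rate"])
  q <- stats::qgamma(c(0.025, 0.975), shape = k, scale = th)
  new_dist_spec("gamma", c(shape = k, scale = th),
                source = c(mean = k * th, lo = q[1], hi = q[2]),
                fitted_q = q, label = paste0("c_treat_", stage, "_mle"))
}

#' Generate synthetic registry-style survival records
#'
#' Event times are drawn from each stage's Weibull survival model and
#' administratively right-censored at a fixed follow-up horizon
#' (mirroring a registry window). A degenerate (no-death) spec yields
#' all-censored records.
#'
#' @param weibull_specs Named list of `weibull_spec` objects.
#' @param censor_time Administrative censoring time in years (> 0).
#' @param n Records per stage.
#' @param seed Integer seed.
#' @return Data frame: `patient`, `stage`, `time` (years), `event`
#'   (1 = cancer death, 0 = censored).
#' @export
generate_survival_records <- function(weibull_specs, censor_time, n, seed) {
  stopifnot(n >= 1, censor_time > 0)
  set.seed(seed)
  rows <- lapply(names(weibull_specs), function(s) {
    w <- weibull_specs[[s]]
    t <- if (w$degenerate) rep(Inf, n)
         else stats::rweibull(n, shape = w$shape, scale = w$scale)
    ev <- t <= censor_time
    data.frame(stage = s, time = pmin(t, censor_time),
               event = as.integer(ev))
  })
  out <- do.call(rbind, rows)
  out$patient <- seq_len(nrow(out))
  out[, c("patient", "stage", "time", "event")]
}

#' Censoring-aware maximum-likelihood Weibull fit to survival records
#'
#' Fits a Weibull survival model to right-censored event times of one
#' stage via [survival::survreg()].
#'
#' @param records Data frame from [generate_survival_records()].
#' @param stage Stage to fit.
#' @return A `weibull_spec` with the fitted shape and scale.
#' @export
fit_weibull_mle <- function(records, stage) {
  d <- records[records$stage == stage, ]
  if (sum(d$event) < 2L) {
    stop("need at least 2 observed events for stage ", stage)
  }
  fit <- survival::survreg(survival::Surv(time, event) ~ 1, data = d,
                           dist = "weibull")
  structure(list(shape = 1 / fit$scale,
                 scale = unname(exp(stats::coef(fit)[1])),
                 stage = stage, degenerate = FALSE),
            class = "weibull_spec")
}
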