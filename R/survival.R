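#' Fit a Weibull survival model through two survival anchors
#'
#' Two survival probabilities at two times identify a Weibull exactly:
#' `k = log(log(s2)/log(s1)) / log(t2/t1)` and
#' `lambda = t1 / (-log(s1))^(1/k)`, so that
#' `S(t) = exp(-(t/lambda)^k)` passes through both anchors.
#'
#' @param s1,s2 Survival probabilities at `t1` and `t2`, with
#'   `0 < s2 < s1 < 1`.
#' @param t1,t2 Anchor times in years, `0 < t1 < t2`.
#' @param stage Optional stage label carried in the result.
#' @return A `weibull_spec` list with `shape`, `scale` (years), `stage`.
#' @export
fit_weibull_two_points <- function(s1, s2, t1, t2, stage = NULL) {
  if (!(t1 > 0 && t2 > t1)) stop("need 0 < t1 < t2")
  if (!(s2 > 0 && s2 < s1 && s1 < 1)) {
    stop("survival anchors must satisfy 0 < s2 < s1 < 1; got S(", t1, ")=",
         s1, ", S(", t2, ")=", s2,
         " (use the degenerate no-death spec only for in-situ disease)")
  }
  k <- log(log(s2) / log(s1)) / log(t2 / t1)
  lambda <- t1 / (-log(s1))^(1 / k)
  structure(list(shape = k, scale = lambda, stage = stage,
                 degenerate = FALSE), class = "weibull_spec")
}

#' Degenerate no-death survival spec (in-situ disease)
#' @param stage Stage label.
#' @return A `weibull_spec` whose survival is identically 1.
#' @export
weibull_degenerate <- function(stage = "in_situ") {
  structure(list(shape = NA_real_, scale = NA_real_, stage = stage,
                 degenerate = TRUE), class = "weibull_spec")
}

#' Survival function of a fitted Weibull spec
#' @param w A `weibull_spec`.
#' @param t Times in years.
#' @return `S(t)`.
#' @export
weibull_survival <- function(w, t) {
  if (w$degenerate) return(rep(1, length(t)))
  exp(-(t / w$scale)^w$shape)
}

#' @export
print.weibull_spec <- function(x, ...) {
  if (x$degenerate) {
    cat("<weibull_spec>", x$stage, "- degenerate (no cancer death)\n")
  } else {
    cat(sprintf("<weibull_spec> %s: shape %.4f, scale %.2f yr; S(5)=%.4f, S(10)=%.4f\n",
                if (is.null(x$stage)) "" else x$stage, x$shape, x$scale,
                weibull_survival(x, 5), weibull_survival(x, 10)))
  }
  invisible(x)
}

#' Per-cycle unconditional cancer-death probabilities since diagnosis
#'
#' Discretises a fitted survival curve into cycle-wise death
#' probabilities: entry `j` is `S((j-1) h) - S(j h)` for cycle length `h`.
#' Under the 10-year cure rule only the first 20 cycles carry cancer
#' mortality; patients alive 10 years after diagnosis stop being at risk
#' of cancer death.
#'
#' @param w A `weibull_spec`.
#' @param n_cycles Number of cycles to discretise (typically 20).
#' @param cycle_len Cycle length in years.
#' @return Vector of length `n_cycles`; entries are non-negative and sum to
#'   `1 - S(n_cycles * cycle_len)`.
#' @export
death_density_by_cycle <- function(w, n_cycles, cycle_len) {
  if (n_cycles < 1) stop("n_cycles must be >= 1")
  if (w$degenerate) return(rep(0, n_cycles))
  t <- seq_len(n_cycles) * cycle_len
  s <- weibull_survival(w, c(0, t))
  s[-length(s)] - s[-1]
}

#' Terminal-pathway allocation for a cancer death at a given cycle
#'
#' Deaths within 18 months (3 cycles) of diagnosis go straight to the dead
#' state; later deaths spend the final 3 cycles before death in the
#' progressive-disease state (where the progression utility and end-of-life
#' costs apply, overriding treatment/remission bookkeeping).
#'
#' @param death_cycle Cycle since diagnosis at which cancer death occurs
#'   (>= 1).
#' @return List with `death_cycle` and `progressive_cycles` (possibly
#'   empty integer vector).
#' @export
terminal_pathway_allocation <- function(death_cycle) {
  if (death_cycle < 1) stop("death_cycle must be >= 1")
  if (death_cycle <= 3) {
    list(death_cycle = death_cycle, progressive_cycles = integer(0))
  } else {
    list(death_cycle = death_cycle,
         progressive_cycles = (death_cycle - 3L):(death_cycle - 1L))
  }
}

# --- background (competing) mortality ------------------------------------

# Gompertz hazard h(age) = a * exp(b * age). Per-cycle death probability
# for the cycle covering [age, age + h): 1 - exp(-integral of hazard).
gompertz_cycle_probs <- function(a, b, ages_start, cycle_len) {
  ch <- (a / b) * (exp(b * (ages_start + cycle_len)) - exp(b * ages_start))
  1 - exp(-ch)
}

# Background survival from cohort entry to the end of each cycle.
# Returns vector of length n_cycles + 1 (entry 1 = survival 1 at entry).
background_survival_curve <- function(background, start_age, cycle_len,
                                      n_cycles) {
  q <- gompertz_cycle_probs(background$gompertz_a, background$gompertz_b,
                            start_age + (seq_len(n_cycles) - 1) * cycle_len,
                            cycle_len)
  cumprod(c(1, 1 - q))
}

#' Calibrate the level of background (competing) mortality
#'
#' Background mortality is modelled as a Gompertz hazard
#' `h(age) = a exp(b age)` with a fixed slope `b`; the level `a` is solved
#' by bisection so that the full cohort model (mammography-alone arm, mean
#' parameters) reproduces a target all-cause cumulative mortality by a
#' target age. This anchors competing mortality to the published
#' validation figure for the modelled population rather than to an
#' external life table.
#'
#' @param ps A `parameter_set` (its `background$gompertz_a` may be `NA`).
#' @param target Optional `c(cum_mortality, by_age)`; defaults to the
#'   target stored in `ps$background$target`.
#' @param tol Calibration tolerance on cumulative mortality.
#' @return The parameter set with `background$gompertz_a` set.
#' @export
calibrate_background_mortality <- function(ps, target = NULL, tol = 1e-6) {
  if (is.null(target)) target <- ps$background$target
  p_target <- target[[1]]
  age_target <- target[[2]]
  if (!(p_target > 0 && p_target < 1)) {
    stop("target cumulative mortality must be in (0, 1)")
  }
  death_at <- function(a) {
    ps$background$gompertz_a <- a
    tr <- run_cohort("mammography_only", ps, keep_trace = FALSE)
    1 - tr$stats$survival_at_age(age_target)
  }
  lo <- 0
  hi <- 1e-4
  d_lo <- death_at(lo)
  if (d_lo > p_target) {
    stop("calibration infeasible: cancer mortality alone (",
         signif(d_lo, 3), ") already exceeds the target ", p_target)
  }
  while (death_at(hi) < p_target) {
    hi <- hi * 4
    if (hi > 1) stop("background-mortality bisection failed to bracket ",
                     "the target ", p_target, " by age ", age_target)
  }
  mid <- (lo + hi) / 2
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    d <- death_at(mid)
    if (d < p_target) lo <- mid else hi <- mid
    if (abs(d - p_target) < tol) break
  }
  ps$background$gompertz_a <- mid
  ps
}
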