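# Mean values of every uncertain leaf, in the documented sampling order.
mean_leaves <- function(spec) {
  list(
    incidence = vapply(spec$incidence, function(b) dist_mean(b$risk10),
                       numeric(1)),
    se_combined = dist_mean(spec$screening$se_combined),
    sp_combined = dist_mean(spec$screening$sp_combined),
    se_mri = dist_mean(spec$screening$se_mri),
    sp_mri = dist_mean(spec$screening$sp_mri),
    se_mam = dist_mean(spec$screening$se_mam),
    sp_mam = dist_mean(spec$screening$sp_mam),
    mam_alone_se = vapply(spec$mam_alone, function(b) dist_mean(b$se),
                          numeric(1)),
    mam_alone_sp = vapply(spec$mam_alone, function(b) dist_mean(b$sp),
                          numeric(1)),
    stages = lapply(spec$stages, function(s) s$p),
    c_mri = dist_mean(spec$costs$mri),
    c_mam = dist_mean(spec$costs$mammogram),
    c_workup = dist_mean(spec$costs$workup),
    c_treat = vapply(spec$costs$treatment, dist_mean, numeric(1)),
    c_eol = dist_mean(spec$costs$end_of_life),
    u_workup = dist_mean(spec$utilities$workup),
    u_treat = vapply(spec$utilities$treatment, dist_mean, numeric(1)),
    u_progression = dist_mean(spec$utilities$progression),
    u_remission = dist_mean(spec$utilities$remission),
    surv = lapply(spec$survival, function(s) {
      c(s5 = dist_mean(s$s5), s10 = dist_mean(s$s10))
    }))
}

#' Draw one concrete parameter set from the uncertain specification
#'
#' Samples every uncertain leaf from its calibrated distribution (Beta,
#' Gamma or Dirichlet; fixed leaves stay at their value) using the current
#' RNG state, in a fixed documented order so results are reproducible
#' given a seed. Leaves whose joint draw violates a structural invariant
#' (the sensitivity triple must admit a joint detection probability;
#' 10-year survival must be below 5-year survival) are redrawn together,
#' up to `max_retry` times.
#'
#' @param spec A `parameter_spec`.
#' @param background Calibrated background-mortality list to insert
#'   (`gompertz_a`, `gompertz_b`, `target`); background mortality is not
#'   sampled.
#' @param max_retry Bounded retry count for invariant-violating draws.
#' @return A `parameter_set`.
#' @export
sample_parameter_set <- function(spec, background = NULL, max_retry = 100L) {
  leaves <- sample_leaves(spec, max_retry)
  ps <- assemble_parameter_set(spec, leaves)
  if (!is.null(background)) ps$background <- background
  ps
}

# Sample every uncertain leaf in the documented order (internal).
sample_leaves <- function(spec, max_retry = 100L) {
  draw1 <- function(d) dist_draw(d, 1L)
  leaves <- list()
  leaves$incidence <- vapply(spec$incidence,
                             function(b) draw1(b$risk10), numeric(1))
  sc <- spec$screening
  ok <- FALSE
  for (i in seq_len(max_retry)) {
    tri <- c(draw1(sc$se_mri), draw1(sc$se_mam), draw1(sc$se_combined))
    feasible <- tri[3] >= max(tri[1], tri[2]) &&
      tri[3] <= min(1, tri[1] + tri[2]) &&
      (tri[1] + tri[2] - tri[3]) >= max(0, tri[1] + tri[2] - 1)
    if (feasible) { ok <- TRUE; break }
  }
  if (!ok) stop("sampling error: sensitivity triple (se_mri, se_mam, ",
                "se_combined) infeasible after ", max_retry, " retries")
  leaves$se_mri <- tri[1]
  leaves$se_mam <- tri[2]
  leaves$se_combined <- tri[3]
  leaves$sp_combined <- draw1(sc$sp_combined)
  leaves$sp_mri <- draw1(sc$sp_mri)
  leaves$sp_mam <- draw1(sc$sp_mam)
  leaves$mam_alone_se <- vapply(spec$mam_alone, function(b) draw1(b$se),
                                numeric(1))
  leaves$mam_alone_sp <- vapply(spec$mam_alone, function(b) draw1(b$sp),
                                numeric(1))
  leaves$stages <- lapply(spec$stages, function(s) {
    if (is.infinite(s$ess)) s$p else drop(rdirichlet(1, s$alpha))
  })
  leaves$c_mri <- draw1(spec$costs$mri)
  leaves$c_mam <- draw1(spec$costs$mammogram)
  leaves$c_workup <- draw1(spec$costs$workup)
  leaves$c_treat <- vapply(spec$costs$treatment, draw1, numeric(1))
  leaves$c_eol <- draw1(spec$costs$end_of_life)
  leaves$u_workup <- draw1(spec$utilities$workup)
  leaves$u_treat <- vapply(spec$utilities$treatment, draw1, numeric(1))
  leaves$u_progression <- draw1(spec$utilities$progression)
  leaves$u_remission <- draw1(spec$utilities$remission)
  leaves$surv <- lapply(spec$survival, function(s) {
    for (i in seq_len(max_retry)) {
      a <- c(s5 = draw1(s$s5), s10 = draw1(s$s10))
      if (a[["s10"]] < a[["s5"]]) return(a)
    }
    stop("sampling error: survival anchors s10 < s5 unattainable for a ",
         "stage after ", max_retry, " retries")
  })
  leaves
}

#' Probabilistic sensitivity analysis over the parameter specification
#'
#' Draws `n_draws` parameter sets, evaluates both strategy arms on each
#' (paired draws), and collects per-draw incremental cost and QALYs plus
#' the screening-effectiveness diagnostics. Background mortality is
#' calibrated once at the mean parameters and held fixed across draws.
#'
#' @param spec A `parameter_spec`.
#' @param n_draws Number of Monte Carlo draws (the analysis design uses
#'   10,000).
#' @param seed Integer seed; the whole analysis is reproducible from
#'   `(spec, n_draws, seed)`.
#' @param ps_mean Optional pre-calibrated mean `parameter_set` (saves the
#'   calibration step).
#' @param progress Print a progress message every 1000 draws.
#' @return A `psa_result`: `draws` (data frame, one row per draw),
#'   `summary` (means, ratio-of-means ICER, percentile intervals, fraction
#'   of draws with negative incremental QALYs), `seed`, `n_draws`.
#' @export
run_psa <- function(spec, n_draws = 1000L, seed = 1L, ps_mean = NULL,
                    progress = FALSE) {
  stopifnot(n_draws >= 1)
  if (is.null(ps_mean)) {
    ps_mean <- calibrate_background_mortality(mean_parameter_set(spec))
  }
  background <- ps_mean$background
  cache <- make_engine_cache(ps_mean)
  set.seed(seed)
  cols <- c("cost_combined", "cost_mammo", "qaly_combined", "qaly_mammo",
            "delta_cost", "delta_qalys", "cum_incidence",
            "prog_sens_combined", "prog_sens_mammo",
            "surv_combined", "surv_mammo")
  out <- matrix(NA_real_, n_draws, length(cols),
                dimnames = list(NULL, cols))
  failures <- 0L
  for (i in seq_len(n_draws)) {
    res <- NULL
    for (attempt in 1:3) {
      res <- tryCatch({
        ps <- sample_parameter_set(spec, background)
        rc <- run_cohort("combined", ps, keep_trace = FALSE, cache = cache)
        rm_ <- run_cohort("mammography_only", ps, keep_trace = FALSE,
                          cache = cache)
        list(rc = rc, rm = rm_)
      }, error = function(e) NULL)
      if (!is.null(res)) break
      failures <- failures + 1L
      if (failures > max(10, 0.01 * n_draws)) {
        stop("more than 1% of PSA draws failed; aborting")
      }
    }
    rc <- res$rc; rm_ <- res$rm
    out[i, ] <- c(rc$cost, rm_$cost, rc$qalys, rm_$qalys,
                  rc$cost - rm_$cost, rc$qalys - rm_$qalys,
                  rc$stats$cum_incidence_by(65),
                  rc$stats$program_sensitivity_by(65),
                  rm_$stats$program_sensitivity_by(65),
                  rc$stats$survival_at_age(65),
                  rm_$stats$survival_at_age(65))
    if (progress && i %% 1000 == 0) {
      message("PSA draw ", i, "/", n_draws)
    }
  }
  draws <- as.data.frame(out)
  qi <- function(x) stats::quantile(x, c(0.025, 0.975), names = FALSE)
  summ <- list(
    mean_delta_cost = mean(draws$delta_cost),
    mean_delta_qalys = mean(draws$delta_qalys),
    icer = mean(draws$delta_cost) / mean(draws$delta_qalys),
    ci_delta_cost = qi(draws$delta_cost),
    ci_delta_qalys = qi(draws$delta_qalys),
    mean_cost = c(combined = mean(draws$cost_combined),
                  mammography_only = mean(draws$cost_mammo)),
    mean_qalys = c(combined = mean(draws$qaly_combined),
                   mammography_only = mean(draws$qaly_mammo)),
    frac_negative_qalys = mean(draws$delta_qalys < 0),
    n_resampled = failures)
  structure(list(draws = draws, summary = summ, seed = seed,
                 n_draws = n_draws), class = "psa_result")
}

#' @export
print.psa_result <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<psa_result> %d draws (seed %d)\n", x$n_draws, x$seed))
  cat(sprintf("  mean incremental cost  $%.0f (95%% CI %.0f, %.0f)\n",
              s$mean_delta_cost, s$ci_delta_cost[1], s$ci_delta_cost[2]))
  cat(sprintf("  mean incremental QALYs %.3f (95%% CI %.3f, %.3f)\n",
              s$mean_delta_qalys, s$ci_delta_qalys[1], s$ci_delta_qalys[2]))
  cat(sprintf("  ICER (ratio of means)  $%.0f/QALY\n", s$icer))
  cat(sprintf("  draws with negative incremental QALYs: %.1f%%\n",
              100 * s$frac_negative_qalys))
  invisible(x)
}

#' Cost-effectiveness acceptability curve
#'
#' For each willingness-to-pay value, the probability that the combined
#' strategy is cost-effective under the net-monetary-benefit rule
#' `lambda * dE - dC >= 0` (ties count as cost-effective).
#'
#' @param psa A `psa_result`.
#' @param wtp_grid Willingness-to-pay values ($ per QALY).
#' @return Data frame with columns `wtp` and `prob_cost_effective`.
#' @export
compute_ceac <- function(psa, wtp_grid) {
  if (!length(wtp_grid)) stop("wtp_grid must be non-empty")
  de <- psa$draws$delta_qalys
  dc <- psa$draws$delta_cost
  data.frame(
    wtp = wtp_grid,
    prob_cost_effective = vapply(wtp_grid, function(l) {
      mean(l * de - dc >= 0)
    }, numeric(1)))
}

# Replace one scalar (or vector) leaf in the mean-leaf list / model.
set_leaf <- function(leaves, model, path, value) {
  parts <- strsplit(path, ".", fixed = TRUE)[[1]]
  if (identical(parts[1], "discount_rate")) {
    model$discount_rate <- value
    return(list(leaves = leaves, model = model))
  }
  valid <- c(names(leaves), "discount_rate")
  if (!parts[1] %in% names(leaves)) {
    stop("unknown parameter '", path, "'; valid roots: ",
         paste(valid, collapse = ", "))
  }
  node <- leaves
  for (p in parts[-length(parts)]) {
    if (is.null(node[[p]])) stop("unknown parameter path '", path, "'")
    node <- node[[p]]
  }
  last <- parts[length(parts)]
  if (length(parts) == 1L) {
    if (length(value) != length(leaves[[last]])) {
      stop("replacement for '", path, "' must have length ",
           length(leaves[[last]]))
    }
    if (!is.null(names(leaves[[last]]))) {
      value <- stats::setNames(as.numeric(value), names(leaves[[last]]))
    }
    leaves[[last]] <- value
  } else {
    expr <- paste0("leaves", paste0("[['", parts, "']]", collapse = ""))
    cur <- eval(parse(text = expr))
    if (is.null(cur)) stop("unknown parameter path '", path, "'")
    if (!is.null(names(cur)) && length(value) == length(cur)) {
      value <- stats::setNames(as.numeric(value), names(cur))
    }
    eval(parse(text = paste0(expr, " <- value")))
  }
  list(leaves = leaves, model = model)
}

# Evaluate both arms deterministically for given leaves/model overrides.
eval_deterministic <- function(spec, leaves, model, background) {
  spec$model <- model
  ps <- assemble_parameter_set(spec, leaves)
  ps$background <- background
  cache <- make_engine_cache(ps)
  rc <- run_cohort("combined", ps, keep_trace = FALSE, cache = cache)
  rm_ <- run_cohort("mammography_only", ps, keep_trace = FALSE,
                    cache = cache)
  summarize_cea(rc, rm_)
}

#' Deterministic one-way sensitivity analysis
#'
#' Evaluates the model at the mean parameter set with a single named leaf
#' replaced by each value in turn, and returns the resulting ICERs.
#' Parameter paths address the mean-leaf tree, e.g. `"c_mri"`,
#' `"se_mri"`, `"sp_mri"`, `"u_remission"`, `"c_treat.local"`,
#' `"stages.mri_detected"` (4-vector) or `"discount_rate"`.
#'
#' @param spec A `parameter_spec`.
#' @param param Parameter path (see details).
#' @param values Vector of values (or list, for vector-valued leaves).
#' @param ps_mean Optional pre-calibrated mean `parameter_set`.
#' @return Data frame with `value` (or index for vector leaves), `icer`,
#'   `icer_label`, `delta_cost`, `delta_qalys`.
#' @export
one_way_sensitivity <- function(spec, param, values, ps_mean = NULL) {
  if (is.null(ps_mean)) {
    ps_mean <- calibrate_background_mortality(mean_parameter_set(spec))
  }
  leaves0 <- mean_leaves(spec)
  rows <- lapply(seq_along(values), function(i) {
    v <- if (is.list(values)) values[[i]] else values[i]
    mod <- set_leaf(leaves0, spec$model, param, v)
    s <- eval_deterministic(spec, mod$leaves, mod$model, ps_mean$background)
    data.frame(value = if (length(v) == 1L) v else NA_real_,
               icer = s$icer, icer_label = s$icer_label,
               delta_cost = s$delta_cost, delta_qalys = s$delta_qalys)
  })
  out <- do.call(rbind, rows)
  attr(out, "param") <- param
  out
}

#' Tornado analysis: one-way ICER swings over parameter ranges
#'
#' Each parameter is evaluated at the low and high end of its plausible
#' range (by default the 95% CI of its calibrated distribution) with all
#' other inputs at their means; entries are ordered by descending ICER
#' swing.
#'
#' @param spec A `parameter_spec`.
#' @param params Named list mapping parameter paths to `c(lo, hi)` ranges,
#'   or `NULL` for the default set (MRI cost, MRI sensitivity and
#'   specificity, stage distribution of MRI-detected cancers, discount
#'   rate).
#' @param ps_mean Optional pre-calibrated mean `parameter_set`.
#' @return Data frame (one row per parameter) with low/high inputs, the
#'   ICER at each, and the absolute swing, sorted by descending swing.
#' @export
tornado <- function(spec, params = NULL, ps_mean = NULL) {
  if (is.null(ps_mean)) {
    ps_mean <- calibrate_background_mortality(mean_parameter_set(spec))
  }
  if (is.null(params)) {
    ci <- function(d) d$fitted_q
    # the MRI-detected stage row is varied through the 95% interval of its
    # local-stage component, other components scaled proportionally
    srow <- spec$stages$mri_detected
    loc_ci <- stats::qbeta(c(0.025, 0.975), srow$alpha[2],
                           sum(srow$alpha) - srow$alpha[2])
    shift_row <- function(p_local) {
      p <- srow$p
      p[-2] <- p[-2] * (1 - p_local) / (1 - p[2])
      p[2] <- p_local
      p
    }
    params <- list(
      c_mri = ci(spec$costs$mri),
      se_mri = ci(spec$screening$se_mri),
      sp_mri = ci(spec$screening$sp_mri),
      stages.mri_detected = list(shift_row(loc_ci[1]), shift_row(loc_ci[2])),
      discount_rate = c(0, 0.05))
  }
  leaves0 <- mean_leaves(spec)
  rows <- lapply(names(params), function(pm) {
    rg <- params[[pm]]
    icers <- vapply(1:2, function(k) {
      v <- if (is.list(rg)) rg[[k]] else rg[k]
      mod <- set_leaf(leaves0, spec$model, pm, v)
      s <- eval_deterministic(spec, mod$leaves, mod$model,
                              ps_mean$background)
      if (s$icer_label == "icer") s$icer else NA_real_
    }, numeric(1))
    data.frame(parameter = pm,
               low = if (is.list(rg)) NA_real_ else rg[1],
               high = if (is.list(rg)) NA_real_ else rg[2],
               icer_low = icers[1], icer_high = icers[2],
               swing = abs(icers[2] - icers[1]))
  })
  out <- do.call(rbind, rows)
  out[order(-out$swing), ]
}
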