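#' Calibrate a Beta distribution from a published mean and 95% CI
#'
#' Finds the Beta distribution whose mean equals `mean` exactly and whose
#' 2.5%/97.5% quantiles match the published interval `(lo, hi)` as closely
#' as possible, by a one-dimensional search over the concentration
#' (alpha + beta). This is the standard way to attach sampling uncertainty
#' to a probability for which only a point estimate and confidence interval
#' are published.
#'
#' @param mean Published mean, strictly between 0 and 1.
#' @param lo,hi Published 95% interval endpoints, `0 <= lo < mean < hi <= 1`.
#' @param label Optional name recorded in the returned spec.
#' @return A `dist_spec` object with `family = "beta"`, `params = c(shape1,
#'   shape2)`, the source triple, and the achieved quantiles (goodness of
#'   fit). A warning flag is recorded when the fitted 95% interval misses
#'   either published endpoint by more than 10% relative error; this
#'   happens when the published interval is incompatible with any Beta of
#'   that mean (e.g. an upper limit exactly at 1).
#' @export
beta_from_mean_ci <- function(mean, lo, hi, label = NULL) {
  if (!(mean > 0 && mean < 1)) {
    stop("beta_from_mean_ci: mean must be in (0, 1), got ", mean)
  }
  if (!(lo >= 0 && lo < mean && mean < hi && hi <= 1)) {
    stop("beta_from_mean_ci: need 0 <= lo < mean < hi <= 1, got (",
         lo, ", ", mean, ", ", hi, ")")
  }
  obj <- function(log_s) {
    s <- exp(log_s)
    a <- mean * s
    b <- (1 - mean) * s
    (stats::qbeta(0.025, a, b) - lo)^2 + (stats::qbeta(0.975, a, b) - hi)^2
  }
  opt <- stats::optimize(obj, lower = log(0.2), upper = log(1e7))
  s <- exp(opt$minimum)
  a <- mean * s
  b <- (1 - mean) * s
  q <- stats::qbeta(c(0.025, 0.975), a, b)
  new_dist_spec("beta", c(shape1 = a, shape2 = b),
                source = c(mean = mean, lo = lo, hi = hi),
                fitted_q = q, label = label)
}

#' Calibrate a Gamma distribution from a published mean and 95% CI
#'
#' As [beta_from_mean_ci()] but for non-negative quantities (costs): the
#' mean `shape * scale` is held at the published mean exactly while the
#' shape is searched so the 2.5%/97.5% quantiles match the published
#' interval in least squares.
#'
#' @param mean Published mean, positive.
#' @param lo,hi Published 95% interval endpoints, `0 < lo < mean < hi`.
#' @param label Optional name recorded in the returned spec.
#' @return A `dist_spec` with `family = "gamma"` and
#'   `params = c(shape, scale)`.
#' @export
gamma_from_mean_ci <- function(mean, lo, hi, label = NULL) {
  if (!(mean > 0)) stop("gamma_from_mean_ci: mean must be positive")
  if (!(lo > 0 && lo < mean && mean < hi)) {
    stop("gamma_from_mean_ci: need 0 < lo < mean < hi, got (",
         lo, ", ", mean, ", ", hi, ")")
  }
  obj <- function(log_k) {
    k <- exp(log_k)
    th <- mean / k
    (stats::qgamma(0.025, shape = k, scale = th) - lo)^2 +
      (stats::qgamma(0.975, shape = k, scale = th) - hi)^2
  }
  opt <- stats::optimize(obj, lower = log(1e-2), upper = log(1e6))
  k <- exp(opt$minimum)
  th <- mean / k
  q <- stats::qgamma(c(0.025, 0.975), shape = k, scale = th)
  new_dist_spec("gamma", c(shape = k, scale = th),
                source = c(mean = mean, lo = lo, hi = hi),
                fitted_q = q, label = label)
}

#' Build a Dirichlet stage-at-diagnosis distribution from a published row
#'
#' Published stage-at-diagnosis rows give the mean proportion of cancers in
#' each of four stages (in situ, local, regional, distant) plus a 95%
#' interval per component. The Dirichlet concentration is `ess * p` where
#' `p` is the (renormalised) mean vector and the effective sample size
#' `ess` is chosen by matching the published interval of the component with
#' the widest CI (published rows give per-component intervals but not
#' concentrations). Rows summing to 101% due to rounding are
#' renormalised; sums outside [0.98, 1.02] are rejected.
#'
#' @param p Numeric 4-vector of mean stage proportions.
#' @param ci Optional 4x2 matrix (lo, hi per component) used to choose the
#'   effective sample size; if `NULL`, `ess` must be given.
#' @param ess Effective sample size; overrides `ci` if supplied.
#' @param mode Detection mode label: one of `"mri_detected"`,
#'   `"mam_detected"`, `"non_screen"`.
#' @return A `stage_distribution` list with `mode`, `p` (normalised), `ess`,
#'   and `alpha = ess * p`.
#' @export
dirichlet_from_stage_row <- function(p, ci = NULL, ess = NULL,
                                     mode = c("mri_detected", "mam_detected",
                                              "non_screen")) {
  mode <- match.arg(mode)
  if (length(p) != 4L || any(p < 0)) {
    stop("stage row must be 4 non-negative proportions")
  }
  s <- sum(p)
  if (s < 0.98 || s > 1.02) {
    stop("stage row '", mode, "' sums to ", signif(s, 4),
         "; outside the rounding band [0.98, 1.02]")
  }
  p <- p / s
  if (is.null(ess)) {
    if (is.null(ci)) stop("either ci or ess must be supplied")
    ci <- as.matrix(ci)
    # component marginals are Beta(ess*p_i, ess*(1-p_i)); match the widest CI
    widest <- which.max(ci[, 2] - ci[, 1])
    pi <- p[widest]
    obj <- function(log_e) {
      e <- exp(log_e)
      ql <- stats::qbeta(0.025, e * pi, e * (1 - pi))
      qh <- stats::qbeta(0.975, e * pi, e * (1 - pi))
      (ql - ci[widest, 1])^2 + (qh - ci[widest, 2])^2
    }
    ess <- exp(stats::optimize(obj, lower = log(2), upper = log(1e5))$minimum)
  }
  if (ess <= 0) stop("ess must be positive")
  structure(list(mode = mode, p = p, ess = ess, alpha = ess * p),
            class = "stage_distribution")
}

#' Fixed (degenerate) distribution spec
#' @param value The constant value.
#' @param label Optional name.
#' @return A `dist_spec` with `family = "fixed"`.
#' @export
fixed_spec <- function(value, label = NULL) {
  new_dist_spec("fixed", c(value = value),
                source = c(mean = value, lo = value, hi = value),
                fitted_q = c(value, value), label = label)
}

new_dist_spec <- function(family, params, source, fitted_q, label = NULL) {
  rel <- function(fit, target) {
    if (target == 0) abs(fit) else abs(fit - target) / abs(target)
  }
  cov_ok <- family == "fixed" ||
    (rel(fitted_q[1], source[["lo"]]) <= 0.10 &&
     rel(fitted_q[2], source[["hi"]]) <= 0.10)
  structure(list(family = family, params = params,
                 source = source, fitted_q = unname(fitted_q),
                 coverage_ok = cov_ok, label = label),
            class = "dist_spec")
}

#' @export
print.dist_spec <- function(x, ...) {
  cat(sprintf("<dist_spec %s%s> mean %.4g, 95%% CI (%.4g, %.4g)",
              x$family,
              if (is.null(x$label)) "" else paste0(" '", x$label, "'"),
              x$source[["mean"]], x$source[["lo"]], x$source[["hi"]]))
  if (x$family != "fixed") {
    cat(sprintf("\n  params: %s\n  fitted 95%%: (%.4g, %.4g)%s\n",
                paste(sprintf("%s=%.4g", names(x$params), x$params),
                      collapse = ", "),
                x$fitted_q[1], x$fitted_q[2],
                if (x$coverage_ok) "" else "  [coverage warning]"))
  } else cat("\n")
  invisible(x)
}

#' Mean of a distribution spec
#' @param spec A `dist_spec`.
#' @return The analytic mean (equals the published mean by construction).
#' @export
dist_mean <- function(spec) {
  switch(spec$family,
         fixed = unname(spec$params[["value"]]),
         beta  = unname(spec$params[["shape1"]] /
                          (spec$params[["shape1"]] + spec$params[["shape2"]])),
         gamma = unname(spec$params[["shape"]] * spec$params[["scale"]]),
         stop("unknown family ", spec$family))
}

#' Draw from a distribution spec
#' @param spec A `dist_spec`.
#' @param n Number of draws.
#' @return Numeric vector of draws (uses the current RNG state).
#' @export
dist_draw <- function(spec, n = 1L) {
  switch(spec$family,
         fixed = rep(unname(spec$params[["value"]]), n),
         beta  = stats::rbeta(n, spec$params[["shape1"]],
                              spec$params[["shape2"]]),
         gamma = stats::rgamma(n, shape = spec$params[["shape"]],
                               scale = spec$params[["scale"]]),
         stop("unknown family ", spec$family))
}

#' Draw from a Dirichlet distribution
#'
#' @param n Number of draws.
#' @param alpha Concentration vector.
#' @return An `n x length(alpha)` matrix of simplex points.
#' @export
rdirichlet <- function(n, alpha) {
  k <- length(alpha)
  x <- matrix(stats::rgamma(n * k, shape = rep(alpha, each = n)), nrow = n)
  x / rowSums(x)
}
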