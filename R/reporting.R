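#' Run the base-case analysis and (optionally) write its outputs
#'
#' Loads a configuration, calibrates background mortality, evaluates both
#' strategy arms at the mean parameters, and returns (and optionally
#' writes) the per-cycle traces, the incremental summary, and a run
#' manifest sufficient to reproduce the result.
#'
#' @param config Path to a YAML configuration, or `NULL` for the packaged
#'   default.
#' @param output_dir Directory for outputs (`trace_<arm>.csv`,
#'   `summary.json`, `manifest.json`); `NULL` writes nothing.
#' @return List with `ps` (calibrated mean parameter set), `combined` and
#'   `mammography_only` cohort results, and `summary`.
#' @export
run_analysis <- function(config = NULL, output_dir = NULL) {
  spec <- load_parameter_spec(config)
  ps <- calibrate_background_mortality(mean_parameter_set(spec))
  cache <- make_engine_cache(ps)
  rc <- run_cohort("combined", ps, keep_trace = TRUE, cache = cache)
  rm_ <- run_cohort("mammography_only", ps, keep_trace = TRUE,
                    cache = cache)
  summ <- summarize_cea(rc, rm_)
  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(rc$trace,
                     file.path(output_dir, "trace_combined.csv"),
                     row.names = FALSE)
    utils::write.csv(rm_$trace,
                     file.path(output_dir, "trace_mammography_only.csv"),
                     row.names = FALSE)
    jsonlite::write_json(summary_as_list(summ),
                         file.path(output_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    write_manifest(file.path(output_dir, "manifest.json"), config, ps)
  }
  list(ps = ps, combined = rc, mammography_only = rm_, summary = summ)
}

summary_as_list <- function(s) {
  list(currency = "2008 CAD",
       cost = as.list(s$cost), qalys = as.list(s$qalys),
       delta_cost = s$delta_cost, delta_qalys = s$delta_qalys,
       icer = s$icer, icer_label = s$icer_label,
       cum_incidence = as.list(s$cum_incidence),
       program_sensitivity = as.list(s$program_sensitivity),
       survival = as.list(s$survival),
       stage_distribution = list(
         combined = as.numeric(s$stage_distribution["combined", ]),
         mammography_only =
           as.numeric(s$stage_distribution["mammography_only", ])),
       by_age = s$by_age)
}

#' Write a machine-readable run manifest
#'
#' Records the configuration fingerprint, package version, calibrated
#' quantities (Weibull fits, conditional sensitivities, Gompertz level)
#' and the seed(s) so any result can be reproduced bit-identically.
#'
#' @param path Output JSON path.
#' @param config Configuration path used (`NULL` for the packaged
#'   default).
#' @param ps Calibrated `parameter_set`.
#' @param seed Optional seed(s) used downstream.
#' @return The manifest list, invisibly.
#' @export
write_manifest <- function(path, config, ps, seed = NULL) {
  cfg_path <- if (is.null(config)) {
    system.file("extdata", "config_default.yaml", package = "brcascreen")
  } else config
  man <- list(
    package = "brcascreen",
    version = as.character(utils::packageVersion("brcascreen")),
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE),
    currency = "2008 CAD",
    config = cfg_path,
    config_md5 = unname(tools::md5sum(cfg_path)),
    seed = seed,
    calibration = list(
      conditional_sensitivities = c(
        se_mri_given_mam_fn = ps$screening$se_mri_given_mam_fn,
        se_mam_given_mri_fn = ps$screening$se_mam_given_mri_fn),
      weibull = lapply(ps$weibull, function(w) {
        list(stage = w$stage, shape = w$shape, scale = w$scale,
             degenerate = w$degenerate)
      }),
      background = list(gompertz_a = ps$background$gompertz_a,
                        gompertz_b = ps$background$gompertz_b,
                        target = as.list(ps$background$target))))
  jsonlite::write_json(man, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(man)
}

#' Validate the calibrated model against the packaged reference values
#'
#' Recomputes cumulative incidence by 65, program sensitivity per arm and
#' survival to 65 per arm at the mean parameters and compares them to the
#' packaged reference values (the published model-validation figures),
#' with pass/fail at documented tolerances (percentage points).
#'
#' @param config Configuration path or `NULL` for the default.
#' @param tolerances Named vector of tolerances in percentage points.
#' @return Data frame `check`, `value`, `reference`, `tolerance`, `pass`.
#' @export
validate_model <- function(config = NULL,
                           tolerances = c(incidence = 1.5,
                                          program_sensitivity = 2,
                                          survival = 1.5)) {
  res <- run_analysis(config)
  s <- res$summary
  ref <- reference_values()
  rows <- data.frame(
    check = c("cum_incidence_by_65", "program_sensitivity_combined",
              "program_sensitivity_mammography", "survival_to_65_combined",
              "survival_to_65_mammography"),
    value = 100 * c(s$cum_incidence["combined"],
                    s$program_sensitivity["combined"],
                    s$program_sensitivity["mammography_only"],
                    s$survival["combined"],
                    s$survival["mammography_only"]),
    reference = c(ref$cum_incidence, ref$program_sensitivity_combined,
                  ref$program_sensitivity_mammography,
                  ref$survival_combined, ref$survival_mammography),
    tolerance = unname(tolerances[c("incidence", "program_sensitivity",
                                    "program_sensitivity", "survival",
                                    "survival")]))
  rows$pass <- abs(rows$value - rows$reference) <= rows$tolerance
  rows
}

# Published validation figures the calibrated model is checked against
# (percent).
reference_values <- function() {
  list(cum_incidence = 42.7,
       program_sensitivity_combined = 93.9,
       program_sensitivity_mammography = 71.7,
       survival_combined = 80.1,
       survival_mammography = 79.1,
       icer = 50911,
       delta_cost = 4692,
       delta_qalys = 0.092)
}

need_ggplot <- function() {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting")
  }
}

#' Cost-effectiveness plane scatter of PSA draws
#' @param psa A `psa_result`.
#' @return A ggplot object.
#' @export
plot_ce_plane <- function(psa) {
  need_ggplot()
  d <- psa$draws
  ggplot2::ggplot(d, ggplot2::aes(x = .data$delta_qalys,
                                  y = .data$delta_cost)) +
    ggplot2::geom_point(alpha = 0.2, size = 0.4) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::stat_ellipse(level = 0.95, colour = "red") +
    ggplot2::labs(x = "Incremental QALYs",
                  y = "Incremental cost (2008 CAD)",
                  title = "Cost-effectiveness plane, MRI + mammography vs mammography")
}

#' Cost-effectiveness acceptability curve plot
#' @param ceac Data frame from [compute_ceac()].
#' @return A ggplot object.
#' @export
plot_ceac <- function(ceac) {
  need_ggplot()
  ggplot2::ggplot(ceac, ggplot2::aes(x = .data$wtp,
                                     y = .data$prob_cost_effective)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "Willingness to pay ($/QALY)",
                  y = "P(MRI screening cost-effective)",
                  title = "Cost-effectiveness acceptability curve")
}

#' Tornado diagram of one-way ICER swings
#' @param entries Data frame from [tornado()].
#' @param base_icer Base-case ICER (vertical reference).
#' @return A ggplot object.
#' @export
plot_tornado <- function(entries, base_icer = NULL) {
  need_ggplot()
  e <- entries
  e$parameter <- factor(e$parameter, levels = rev(e$parameter))
  p <- ggplot2::ggplot(e, ggplot2::aes(y = .data$parameter)) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$icer_low,
                                       xend = .data$icer_high,
                                       yend = .data$parameter),
                          linewidth = 5, colour = "steelblue") +
    ggplot2::labs(x = "ICER ($/QALY)", y = NULL,
                  title = "One-way sensitivity of the ICER")
  if (!is.null(base_icer)) {
    p <- p + ggplot2::geom_vline(xintercept = base_icer, linetype = 2)
  }
  p
}
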