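# Shared fixtures, computed lazily once per test run.
.fx <- new.env(parent = emptyenv())

default_spec <- function() {
  if (is.null(.fx$spec)) .fx$spec <- load_parameter_spec()
  .fx$spec
}

# Mean parameter set with calibrated background mortality.
calibrated_ps <- function() {
  if (is.null(.fx$ps)) {
    .fx$ps <- calibrate_background_mortality(mean_parameter_set(default_spec()))
  }
  .fx$ps
}

engine_cache_fx <- function() {
  if (is.null(.fx$cache)) .fx$cache <- make_engine_cache(calibrated_ps())
  .fx$cache
}

base_case <- function() {
  if (is.null(.fx$base)) {
    ps <- calibrated_ps()
    cache <- engine_cache_fx()
    rc <- run_cohort("combined", ps, keep_trace = TRUE, cache = cache)
    rm_ <- run_cohort("mammography_only", ps, keep_trace = TRUE,
                      cache = cache)
    .fx$base <- list(combined = rc, mammography_only = rm_,
                     summary = summarize_cea(rc, rm_))
  }
  .fx$base
}

# The shared full-size PSA used by the decision-uncertainty checks.
shared_psa <- function(n = 10000L, seed = 20260901L) {
  key <- paste0("psa_", n, "_", seed)
  if (is.null(.fx[[key]])) {
    .fx[[key]] <- run_psa(default_spec(), n_draws = n, seed = seed,
                          ps_mean = calibrated_ps())
  }
  .fx[[key]]
}

# A spec with every distribution collapsed to its mean (for the
# PSA-collapse identity).
collapsed_spec <- function() {
  spec <- default_spec()
  fix <- function(d) fixed_spec(dist_mean(d), d$label)
  spec$incidence <- lapply(spec$incidence, function(b) {
    b$risk10 <- fix(b$risk10); b
  })
  spec$screening <- lapply(spec$screening, fix)
  spec$mam_alone <- lapply(spec$mam_alone, function(b) {
    b$se <- fix(b$se); b$sp <- fix(b$sp); b
  })
  spec$stages <- lapply(spec$stages, function(s) { s$ess <- Inf; s })
  spec$costs$treatment <- lapply(spec$costs$treatment, fix)
  for (nm in c("mri", "mammogram", "workup", "end_of_life")) {
    spec$costs[[nm]] <- fix(spec$costs[[nm]])
  }
  spec$utilities$treatment <- lapply(spec$utilities$treatment, fix)
  for (nm in c("workup", "progression", "remission")) {
    spec$utilities[[nm]] <- fix(spec$utilities[[nm]])
  }
  spec$survival <- lapply(spec$survival, function(s) {
    list(s5 = fix(s$s5), s10 = fix(s$s10))
  })
  spec
}
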