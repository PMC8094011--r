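# Parameter handling: distribution specs for every model input, validation,
# and loading from the JSON parameter / run-configuration files.

#' Construct a distribution specification
#'
#' @param name Parameter identifier.
#' @param mean Point value (2020 USD for costs, utility units, or probability).
#' @param sd Standard deviation; if `NULL` it is filled by [default_sd()].
#' @param ci95 Optional length-2 vector (low, high) on the same scale.
#' @param kind One of `"gamma"`, `"beta"`, `"fixed"`.
#' @return A validated `dist_spec` list.
#' @export
dist_spec <- function(name, mean, sd = NULL, ci95 = NULL,
                      kind = c("gamma", "beta", "fixed")) {
  kind <- match.arg(kind)
  if (!is.finite(mean) || mean < 0) {
    stop("dist_spec '", name, "': mean must be nonnegative, got ", mean,
         call. = FALSE)
  }
  if (is.null(sd)) sd <- default_sd(mean)
  if (!is.finite(sd) || sd < 0) {
    stop("dist_spec '", name, "': sd must be nonnegative", call. = FALSE)
  }
  if (kind == "gamma" && mean == 0 && sd > 0) {
    stop("dist_spec '", name, "': gamma requires mean > 0", call. = FALSE)
  }
  if (kind == "beta") {
    if (mean < 0 || mean > 1) {
      stop("dist_spec '", name, "': beta requires mean in [0, 1], got ",
           mean, call. = FALSE)
    }
    if (mean > 0 && mean < 1 && sd > 0 && sd^2 >= mean * (1 - mean)) {
      stop(sprintf(
        "dist_spec '%s': sd^2 = %.6g violates the beta bound mean*(1-mean) = %.6g",
        name, sd^2, mean * (1 - mean)), call. = FALSE)
    }
  }
  if (!is.null(ci95)) {
    if (length(ci95) != 2L || any(!is.finite(ci95))) {
      stop("dist_spec '", name, "': ci95 must be a finite (low, high) pair",
           call. = FALSE)
    }
    if (!(ci95[1] < mean && mean < ci95[2])) {
      stop(sprintf("dist_spec '%s': ci95 (%g, %g) must bracket the mean %g",
                   name, ci95[1], ci95[2], mean), call. = FALSE)
    }
  }
  structure(list(name = name, mean = mean, sd = sd,
                 ci95 = if (is.null(ci95)) NULL else as.numeric(ci95),
                 kind = kind),
            class = "dist_spec")
}

#' Base-case model parameters
#'
#' Returns the full set of distribution specifications for the base-case
#' model: per-cycle drug costs, second-line costs, disease-state costs, the
#' one-time palliative-care/death cost, weighted toxicity costs and
#' disutilities per arm, societal per-cycle components, health utilities,
#' second-line uptake proportions, and the overall-survival hazard ratio
#' with its 95% CI. Costs carry gamma specs, utilities and probabilities
#' beta specs; SDs are filled by the 20%-of-mean rule. All costs are in
#' 2020 USD. Per-cycle drug costs already include infusion ($143) and
#' follow-up/monitoring ($433).
#'
#' @param sd_fraction Fraction of the mean used for unreported SDs
#'   (default 0.2; accepted range 0.1-0.4).
#' @return A named list of `dist_spec` objects.
#' @export
base_case_parameters <- function(sd_fraction = 0.2) {
  g <- function(name, mean, lo, hi) {
    dist_spec(name, mean, sd = default_sd(mean, sd_fraction),
              ci95 = c(lo, hi), kind = "gamma")
  }
  b <- function(name, mean, lo, hi) {
    dist_spec(name, mean, sd = default_sd(mean, sd_fraction),
              ci95 = c(lo, hi), kind = "beta")
  }
  specs <- list(
    g("cost_nivolumab",          14975,  9703, 21417),
    g("cost_ipilimumab",         11450,  7413, 16296),
    g("cost_combo",              26425, 17089, 37662),
    g("cost_pemetrexed",          7990,  5182, 11395),
    g("cost_gemcitabine",          118,    76,   169),
    g("cost_cisplatin",             94,    61,   134),
    g("cost_carboplatin",          163,   105,   233),
    g("cost_chemo_total",         7929,  5151, 11331),
    g("cost_second_line_nivo_ipi", 8908,  5764, 12735),
    g("cost_second_line_chemo",  12093,  7824, 17255),
    g("cost_toxicity_nivo_ipi",   1185,   767,  1695),
    g("cost_toxicity_chemo",      6384,  4139,  9127),
    g("cost_stable",              2166,  1397,  3098),
    g("cost_progressed",          4000,  2575,  5712),
    g("cost_death",              15957, 10335, 22818),
    g("cost_patient_time",         534,   345,   763),
    g("cost_transport_nivo_ipi",    91,    59,   130),
    g("cost_transport_chemo",       61,    39,    87),
    g("cost_caregiver",            619,   401,   882),
    g("cost_productivity",         854,   553,  1219),
    b("utility_stable",           0.754, 0.407, 0.970),
    b("utility_progression_decrement", 0.180, 0.115, 0.367),
    b("disutility_toxicity_nivo_ipi",  0.017, 0.011, 0.024),
    b("disutility_toxicity_chemo",     0.019, 0.012, 0.027),
    dist_spec("utility_death", 0, sd = 0, kind = "fixed"),
    dist_spec("second_line_uptake_nivo_ipi", 0.377,
              sd = default_sd(0.377, sd_fraction), kind = "beta"),
    dist_spec("second_line_uptake_chemo", 0.537,
              sd = default_sd(0.537, sd_fraction), kind = "beta"),
    # HR enters the deterministic sensitivity analysis through its CI;
    # survival uncertainty in the PSA is handled by per-curve hazard
    # multipliers instead, so the HR spec is fixed there.
    dist_spec("os_hazard_ratio", 0.73, sd = default_sd(0.73, sd_fraction),
              ci95 = c(0.64, 0.84), kind = "fixed")
  )
  names(specs) <- vapply(specs, `[[`, character(1), "name")
  specs
}

#' Default strategy configurations
#'
#' Immunotherapy: nivolumab-ipilimumab for up to 24 monthly cycles, 37.7%
#' second-line uptake at treatment stop. Chemotherapy: platinum doublet for
#' up to 3 monthly cycles (4 chemotherapy administrations), 53.7% uptake.
#'
#' @param nonsquamous_proportion Proportion of nonsquamous histology used by
#'   the maintenance-pemetrexed scenario.
#' @return A list of two `strategy_config` lists, named `nivo_ipi`, `chemo`.
#' @export
default_strategies <- function(nonsquamous_proportion = 0.7) {
  list(
    nivo_ipi = strategy_config(
      name = "nivo_ipi", max_treatment_cycles = 24,
      drug_cost_param = "cost_combo",
      second_line_cost_param = "cost_second_line_nivo_ipi",
      second_line_uptake_param = "second_line_uptake_nivo_ipi",
      toxicity_cost_param = "cost_toxicity_nivo_ipi",
      toxicity_disutility_param = "disutility_toxicity_nivo_ipi",
      transport_cost_param = "cost_transport_nivo_ipi"),
    chemo = strategy_config(
      name = "chemo", max_treatment_cycles = 3,
      drug_cost_param = "cost_chemo_total",
      second_line_cost_param = "cost_second_line_chemo",
      second_line_uptake_param = "second_line_uptake_chemo",
      toxicity_cost_param = "cost_toxicity_chemo",
      toxicity_disutility_param = "disutility_toxicity_chemo",
      transport_cost_param = "cost_transport_chemo",
      nonsquamous_proportion = nonsquamous_proportion)
  )
}

#' Construct a strategy configuration
#'
#' @param name Strategy identifier.
#' @param max_treatment_cycles Maximum first-line treatment duration in
#'   monthly cycles; may be fractional, in which case the final cycle's drug
#'   cost is prorated.
#' @param drug_cost_param,second_line_cost_param,second_line_uptake_param,toxicity_cost_param,toxicity_disutility_param,transport_cost_param
#'   Names of the parameters carrying this strategy's inputs.
#' @param maintenance_pemetrexed If `TRUE`, nonsquamous patients accrue
#'   pemetrexed cost in stable states beyond the treatment cap.
#' @param nonsquamous_proportion Proportion used by that scenario.
#' @param continue_past_progression If `TRUE`, first-line drug cost continues
#'   in the progressed state through cycle 24.
#' @return A `strategy_config` list.
#' @export
strategy_config <- function(name, max_treatment_cycles,
                            drug_cost_param, second_line_cost_param,
                            second_line_uptake_param,
                            toxicity_cost_param, toxicity_disutility_param,
                            transport_cost_param,
                            maintenance_pemetrexed = FALSE,
                            nonsquamous_proportion = 0,
                            continue_past_progression = FALSE) {
  if (!is.finite(max_treatment_cycles) || max_treatment_cycles < 1) {
    stop("strategy_config '", name,
         "': max_treatment_cycles must be >= 1", call. = FALSE)
  }
  if (nonsquamous_proportion < 0 || nonsquamous_proportion > 1) {
    stop("strategy_config '", name,
         "': nonsquamous_proportion must lie in [0, 1]", call. = FALSE)
  }
  structure(list(
    name = name,
    max_treatment_cycles = max_treatment_cycles,
    drug_cost_param = drug_cost_param,
    second_line_cost_param = second_line_cost_param,
    second_line_uptake_param = second_line_uptake_param,
    toxicity_cost_param = toxicity_cost_param,
    toxicity_disutility_param = toxicity_disutility_param,
    transport_cost_param = transport_cost_param,
    maintenance_pemetrexed = isTRUE(maintenance_pemetrexed),
    nonsquamous_proportion = nonsquamous_proportion,
    continue_past_progression = isTRUE(continue_past_progression)),
    class = "strategy_config")
}

#' Construct a run configuration
#'
#' @param horizon_cycles Model horizon in monthly cycles (default 120,
#'   i.e. 10 years).
#' @param annual_discount_rate Annual discount rate applied to costs and
#'   QALYs (default 0.03).
#' @param perspective `"healthcare"` (base case) or `"societal"`.
#' @param wtp_per_qaly Willingness-to-pay threshold in USD/QALY.
#' @param extrapolation_mode `"conditional_survival"` (base case) or
#'   `"cure_life_table"` for survival beyond trial follow-up.
#' @param trial_followup_cycles Months of trial follow-up (default 42).
#' @param half_cycle_correction Apply half-cycle correction to state accrual
#'   (off by default; the trial-calibrated round-trip validation assumes
#'   start-of-cycle occupancy).
#' @param start_age_years Cohort age at model entry, used by life-table
#'   extrapolation.
#' @param post_progression_hazard_multiplier Multiplier on the marginal OS
#'   hazard applied in the progressed state (default 1 preserves the
#'   trace-vs-input OS identity).
#' @param transition_sd_fraction SD of the per-curve PSA hazard-multiplier
#'   draw, as a fraction of the curve's mean monthly event probability
#'   (default 0.2, the 20\%-of-mean rule; 0 disables transition-probability
#'   sampling, making the PSA degenerate in the curves).
#' @param seed Integer RNG seed for stochastic analyses.
#' @return A `run_config` list.
#' @export
run_config <- function(horizon_cycles = 120,
                       annual_discount_rate = 0.03,
                       perspective = c("healthcare", "societal"),
                       wtp_per_qaly = 100000,
                       extrapolation_mode = c("conditional_survival",
                                              "cure_life_table"),
                       trial_followup_cycles = 42,
                       half_cycle_correction = FALSE,
                       start_age_years = 64,
                       post_progression_hazard_multiplier = 1,
                       transition_sd_fraction = 0.2,
                       seed = 1L) {
  if (transition_sd_fraction < 0 || transition_sd_fraction > 0.4) {
    stop("run_config: transition_sd_fraction must lie in [0, 0.4]",
         call. = FALSE)
  }
  perspective <- match.arg(perspective)
  extrapolation_mode <- match.arg(extrapolation_mode)
  if (horizon_cycles < trial_followup_cycles) {
    stop("run_config: horizon_cycles (", horizon_cycles,
         ") must be >= trial_followup_cycles (", trial_followup_cycles, ")",
         call. = FALSE)
  }
  if (annual_discount_rate < 0 || annual_discount_rate > 0.2) {
    stop("run_config: annual_discount_rate must lie in [0, 0.2]",
         call. = FALSE)
  }
  structure(list(
    cycle_length_months = 1,
    horizon_cycles = as.integer(horizon_cycles),
    annual_discount_rate = annual_discount_rate,
    perspective = perspective,
    wtp_per_qaly = wtp_per_qaly,
    extrapolation_mode = extrapolation_mode,
    trial_followup_cycles = as.integer(trial_followup_cycles),
    half_cycle_correction = isTRUE(half_cycle_correction),
    start_age_years = start_age_years,
    post_progression_hazard_multiplier = post_progression_hazard_multiplier,
    transition_sd_fraction = transition_sd_fraction,
    seed = as.integer(seed)),
    class = "run_config")
}

#' Assemble and validate a parameter set
#'
#' @param params Named list of `dist_spec` objects.
#' @param strategies List of `strategy_config` objects.
#' @param config A `run_config`.
#' @return A `parameter_set` list.
#' @export
parameter_set <- function(params = base_case_parameters(),
                          strategies = default_strategies(),
                          config = run_config()) {
  stopifnot(is.list(params), length(params) > 0)
  if (is.null(names(params)) || any(names(params) == "")) {
    stop("parameter_set: 'params' must be a named list", call. = FALSE)
  }
  ps <- structure(list(params = params, strategies = strategies,
                       config = config),
                  class = "parameter_set")
  validate_parameter_set(ps)
  ps
}

#' @keywords internal
validate_parameter_set <- function(ps) {
  us <- param_mean(ps, "utility_stable")
  ud <- param_mean(ps, "utility_progression_decrement")
  if (us - ud < 0) {
    stop("parameter_set: progressed-state utility would be negative (",
         us, " - ", ud, ")", call. = FALSE)
  }
  for (s in ps$strategies) {
    for (p in c(s$drug_cost_param, s$second_line_cost_param,
                s$second_line_uptake_param, s$toxicity_cost_param,
                s$toxicity_disutility_param, s$transport_cost_param)) {
      if (is.null(ps$params[[p]])) {
        stop("parameter_set: strategy '", s$name,
             "' references missing parameter '", p, "'", call. = FALSE)
      }
    }
    u <- param_mean(ps, s$second_line_uptake_param)
    if (u < 0 || u > 1) {
      stop("parameter_set: second-line uptake for '", s$name,
           "' must lie in [0, 1], got ", u, call. = FALSE)
    }
  }
  invisible(ps)
}

#' Point value of a named parameter
#' @param ps A `parameter_set`.
#' @param name Parameter name.
#' @return The parameter's mean.
#' @export
param_mean <- function(ps, name) {
  sp <- ps$params[[name]]
  if (is.null(sp)) stop("unknown parameter '", name, "'", call. = FALSE)
  sp$mean
}

#' Replace the point value of a named parameter
#'
#' Used by the deterministic sensitivity analysis and threshold searches;
#' the distribution kind and CI are left untouched, the sd is rescaled by
#' the 20% rule unless `keep_sd = TRUE`.
#'
#' @param ps A `parameter_set`.
#' @param name Parameter name.
#' @param value New mean.
#' @param keep_sd Keep the existing sd instead of rescaling.
#' @return The modified `parameter_set`.
#' @export
set_param <- function(ps, name, value, keep_sd = FALSE) {
  sp <- ps$params[[name]]
  if (is.null(sp)) stop("unknown parameter '", name, "'", call. = FALSE)
  sp$mean <- value
  if (!keep_sd) sp$sd <- default_sd(value)
  sp$ci95 <- NULL
  ps$params[[name]] <- sp
  validate_parameter_set(ps)
  ps
}

# ---------------------------------------------------------------------------
# File I/O

#' Load a parameter set from JSON files
#'
#' The parameter file holds one entry per model input:
#' `{name, mean, sd (optional), ci95 (optional), kind}`; missing SDs are
#' filled with the 20%-of-mean rule. The configuration file mirrors
#' [run_config()] plus a list of strategy blocks.
#'
#' @param parameter_file Path to the JSON parameter file.
#' @param config_file Optional path to the JSON run-configuration file; when
#'   omitted the defaults of [run_config()] and [default_strategies()] apply.
#' @return A validated `parameter_set`.
#' @export
load_parameters <- function(parameter_file, config_file = NULL) {
  if (!file.exists(parameter_file)) {
    stop("load_parameters: parameter file not found: ", parameter_file,
         call. = FALSE)
  }
  raw <- jsonlite::read_json(parameter_file, simplifyVector = FALSE)
  if (!is.null(raw$parameters)) raw <- raw$parameters
  specs <- lapply(raw, function(e) {
    for (f in c("name", "mean", "kind")) {
      if (is.null(e[[f]])) {
        stop("load_parameters: entry missing required field '", f, "'",
             if (!is.null(e$name)) paste0(" (parameter '", e$name, "')"),
             call. = FALSE)
      }
    }
    tryCatch(
      dist_spec(e$name, parse_money(e$mean),
                sd = if (is.null(e$sd)) NULL else parse_money(e$sd),
                ci95 = if (is.null(e$ci95)) NULL else
                  vapply(e$ci95, parse_money, numeric(1)),
                kind = e$kind),
      error = function(err) {
        stop("load_parameters: parameter '", e$name, "': ",
             conditionMessage(err), call. = FALSE)
      })
  })
  names(specs) <- vapply(specs, `[[`, character(1), "name")

  strategies <- default_strategies()
  config <- run_config()
  if (!is.null(config_file)) {
    if (!file.exists(config_file)) {
      stop("load_parameters: config file not found: ", config_file,
           call. = FALSE)
    }
    cf <- jsonlite::read_json(config_file, simplifyVector = TRUE)
    rc_fields <- intersect(names(cf), names(formals(run_config)))
    config <- do.call(run_config, cf[rc_fields])
    if (!is.null(cf$strategies)) {
      strategies <- lapply(seq_len(nrow(cf$strategies)), function(i) {
        row <- as.list(cf$strategies[i, ])
        do.call(strategy_config,
                row[intersect(names(row), names(formals(strategy_config)))])
      })
      names(strategies) <- vapply(strategies, `[[`, character(1), "name")
    }
  }
  parameter_set(specs, strategies, config)
}

#' Write a parameter set's specs to a JSON parameter file
#' @param params Named list of `dist_spec` objects.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_parameters <- function(params, path) {
  entries <- lapply(unname(params), function(sp) {
    e <- list(name = sp$name, mean = sp$mean, sd = sp$sd, kind = sp$kind)
    if (!is.null(sp$ci95)) e$ci95 <- sp$ci95
    e
  })
  jsonlite::write_json(entries, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

# Normalizes printed money: thin/regular/no-break spaces and commas as
# thousands separators ("26 425" -> 26425).
#' @keywords internal
parse_money <- function(x) {
  if (is.numeric(x)) return(as.numeric(x))
  x <- gsub("[,\u00a0\u2009\u202f ]", "", as.character(x))
  x <- sub("^\\$", "", x)
  v <- suppressWarnings(as.numeric(x))
  if (is.na(v)) stop("cannot parse numeric value '", x, "'", call. = FALSE)
  v
}
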