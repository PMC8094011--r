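# Incremental cost-effectiveness, deterministic sensitivity analyses,
# threshold searches, and scenario orchestration.

#' Bundle model inputs for a two-strategy analysis
#'
#' @param curves Named list (one entry per strategy, names matching the
#'   strategy configs) of lists with `os` and `pfs` `survival_curve`s
#'   covering at least the trial follow-up.
#' @param params A `parameter_set` (carries strategies and run config).
#' @param cs_table Conditional-survival data.frame (`year`, `cs`).
#' @param life_table Life-table data.frame (`age`, `qx`).
#' @param comparator Name of the comparator strategy (default `"chemo"`);
#'   the other strategy is the intervention.
#' @return A `cea_inputs` list.
#' @export
cea_inputs <- function(curves, params, cs_table = NULL, life_table = NULL,
                       comparator = "chemo") {
  stopifnot(inherits(params, "parameter_set"))
  missing <- setdiff(names(params$strategies), names(curves))
  if (length(missing)) {
    stop("cea_inputs: no curves supplied for strategy '", missing[1], "'",
         call. = FALSE)
  }
  if (!comparator %in% names(params$strategies)) {
    stop("cea_inputs: comparator '", comparator,
         "' is not a configured strategy", call. = FALSE)
  }
  structure(list(curves = curves, params = params, cs_table = cs_table,
                 life_table = life_table, comparator = comparator),
            class = "cea_inputs")
}

# Extend one strategy's OS and PFS curves to the horizon under the
# configured extrapolation regime. Both curves get the same extender; the
# base case applies conditional survival to both.
#' @keywords internal
extend_strategy_curves <- function(pair, inputs) {
  cfg <- inputs$params$config
  H <- cfg$horizon_cycles
  b <- cfg$trial_followup_cycles
  ext <- function(curve) {
    if (max(curve$times) >= H) return(curve_through(curve, H))
    if (cfg$extrapolation_mode == "conditional_survival") {
      if (is.null(inputs$cs_table)) {
        stop("conditional-survival extrapolation requested but no table given",
             call. = FALSE)
      }
      extend_conditional(curve, inputs$cs_table, boundary = b, horizon = H)
    } else {
      if (is.null(inputs$life_table)) {
        stop("cure extrapolation requested but no life table given",
             call. = FALSE)
      }
      extend_life_table(curve, inputs$life_table, cfg$start_age_years,
                        boundary = b, horizon = H)
    }
  }
  list(os = ext(pair$os), pfs = ext(pair$pfs))
}

#' Run both strategies and compute the incremental comparison
#'
#' @param inputs A `cea_inputs`.
#' @return A `cea_result`: per-strategy `strategy_result`s plus
#'   `delta_cost`, `delta_qalys`, `icer` (number or dominance label), and
#'   `icer_rounded`.
#' @export
run_cea <- function(inputs) {
  ps <- inputs$params
  results <- lapply(names(ps$strategies), function(nm) {
    strat <- ps$strategies[[nm]]
    cur <- extend_strategy_curves(inputs$curves[[nm]], inputs)
    sched <- build_schedule(cur$os, cur$pfs, strat, ps$config, params = ps)
    run_cohort(sched, ps, strat, ps$config)
  })
  names(results) <- names(ps$strategies)
  comp <- results[[inputs$comparator]]
  int_name <- setdiff(names(results), inputs$comparator)[1]
  intv <- results[[int_name]]
  dc <- intv$cost - comp$cost
  dq <- intv$qalys - comp$qalys
  ic <- icer(dc, dq)
  structure(list(
    strategies = results,
    intervention = int_name, comparator = inputs$comparator,
    delta_cost = dc, delta_qalys = dq,
    icer = ic,
    icer_rounded = if (is.numeric(ic)) round_icer(ic) else ic),
    class = "cea_result")
}

#' Incremental cost-effectiveness ratio or dominance label
#'
#' @param delta_cost Incremental cost (intervention minus comparator), USD.
#' @param delta_qalys Incremental effectiveness, QALYs.
#' @return The ratio in USD/QALY when the signs agree, otherwise
#'   `"dominant"` (cheaper, at least as effective), `"dominated"` (costlier,
#'   less effective), or `"indifferent"` (both zero).
#' @export
icer <- function(delta_cost, delta_qalys) {
  if (delta_cost == 0 && delta_qalys == 0) return("indifferent")
  if (delta_cost <= 0 && delta_qalys >= 0) return("dominant")
  if (delta_cost >= 0 && delta_qalys < 0) return("dominated")
  if (delta_qalys == 0) return("dominated")  # costlier, no gain
  delta_cost / delta_qalys
}

#' Round an ICER to the nearest $100 (half-up)
#' @param x Finite ICER.
#' @return Nearest multiple of 100.
#' @export
round_icer <- function(x) {
  stopifnot(is.finite(x))
  sign(x) * floor(abs(x) / 100 + 0.5) * 100
}

#' Net monetary benefit
#' @param cost Discounted cost, USD.
#' @param qalys Discounted QALYs.
#' @param wtp Willingness-to-pay, USD/QALY (>= 0).
#' @return `wtp * qalys - cost`.
#' @export
nmb <- function(cost, qalys, wtp) {
  stopifnot(wtp >= 0)
  wtp * qalys - cost
}

# ---------------------------------------------------------------------------
# One-way deterministic sensitivity analysis

# Applies a single-parameter change to the inputs. The OS hazard ratio is
# special-cased: the intervention OS curve is regenerated from the
# comparator anchor, S_int = S_comp^hr.
#' @keywords internal
apply_param_value <- function(inputs, name, value) {
  if (name == "os_hazard_ratio") {
    int_name <- setdiff(names(inputs$params$strategies), inputs$comparator)[1]
    inputs$curves[[int_name]]$os <-
      apply_hazard_ratio(inputs$curves[[inputs$comparator]]$os, value)
    inputs$params <- set_param(inputs$params, name, value)
  } else {
    inputs$params <- set_param(inputs$params, name, value)
  }
  inputs
}

#' One-way deterministic sensitivity analysis
#'
#' Re-runs the full two-strategy comparison with each parameter at its low
#' and high value (default range: the printed 95% CI where available,
#' otherwise mean +/- 20%), all other parameters at base. Entries are
#' sorted by ICER spread, descending — the tornado ordering. A model
#' failure at an extreme is flagged in the `error` column rather than
#' dropped.
#'
#' @param inputs A `cea_inputs`.
#' @param ranges Optional named list of `c(low, high)` overrides; names must
#'   be parameter names (`"os_hazard_ratio"` allowed). When `NULL`, every
#'   non-fixed parameter plus the OS hazard ratio is varied.
#' @return A data.frame with columns `parameter`, `low`, `high`,
#'   `icer_low`, `icer_high`, `spread`, `error`.
#' @export
one_way_dsa <- function(inputs, ranges = NULL) {
  ps <- inputs$params
  if (is.null(ranges)) {
    ranges <- list()
    for (sp in ps$params) {
      if (sp$mean == 0) next
      if (sp$kind == "fixed" && sp$name != "os_hazard_ratio") next
      ranges[[sp$name]] <- if (!is.null(sp$ci95)) sp$ci95 else
        c(0.8, 1.2) * sp$mean
    }
  }
  if (length(ranges) == 0L) {
    return(data.frame(parameter = character(), low = numeric(),
                      high = numeric(), icer_low = numeric(),
                      icer_high = numeric(), spread = numeric(),
                      error = character()))
  }
  rows <- lapply(names(ranges), function(nm) {
    rg <- ranges[[nm]]
    base <- if (nm %in% names(ps$params)) ps$params[[nm]]$mean else NA_real_
    if (!is.na(base) && !(rg[1] <= base && base <= rg[2])) {
      stop("one_way_dsa: range for '", nm, "' (", rg[1], ", ", rg[2],
           ") does not bracket the base value ", base, call. = FALSE)
    }
    eval_at <- function(v) {
      tryCatch({
        r <- run_cea(apply_param_value(inputs, nm, v))
        list(icer = if (is.numeric(r$icer)) r$icer else NA_real_, err = "")
      }, error = function(e) list(icer = NA_real_,
                                  err = conditionMessage(e)))
    }
    lo <- eval_at(rg[1]); hi <- eval_at(rg[2])
    data.frame(parameter = nm, low = rg[1], high = rg[2],
               icer_low = lo$icer, icer_high = hi$icer,
               spread = abs(hi$icer - lo$icer),
               error = paste(c(lo$err, hi$err)[c(lo$err, hi$err) != ""],
                             collapse = "; "),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(-out$spread, out$parameter), , drop = FALSE]
}

# ---------------------------------------------------------------------------
# Threshold searches

#' Bisection threshold search on drug price or treatment duration
#'
#' Finds the value of the intervention's monthly drug price or maximum
#' treatment duration at which the ICER meets the willingness-to-pay
#' target. The price search varies the combined monthly drug cost of the
#' intervention arm only; the duration search supports fractional months by
#' prorating the final cycle's drug cost. The ICER must be monotone in the
#' variable over the bracket (it is, by construction: both variables scale
#' intervention drug spend without touching QALYs).
#'
#' @param inputs A `cea_inputs`.
#' @param target_wtp Target willingness-to-pay, USD/QALY.
#' @param variable `"monthly_price"` or `"max_duration"`.
#' @param bracket `c(low, high)` for the variable; the ICERs at the
#'   endpoints must straddle the target.
#' @param tol Absolute tolerance on the variable ($1 for price, 0.1 month
#'   for duration by default).
#' @return The threshold value of the variable.
#' @export
threshold_search <- function(inputs, target_wtp,
                             variable = c("monthly_price", "max_duration"),
                             bracket, tol = NULL) {
  variable <- match.arg(variable)
  if (is.null(tol)) tol <- if (variable == "monthly_price") 1 else 0.1
  int_name <- setdiff(names(inputs$params$strategies), inputs$comparator)[1]
  eval_icer <- function(v) {
    ii <- inputs
    if (variable == "monthly_price") {
      ii$params <- set_param(ii$params,
                             ii$params$strategies[[int_name]]$drug_cost_param,
                             v)
    } else {
      ii$params$strategies[[int_name]]$max_treatment_cycles <- v
    }
    r <- run_cea(ii)
    if (!is.numeric(r$icer)) {
      # dominance: treat as signed infinity so bisection can proceed
      return(if (identical(r$icer, "dominant")) -Inf else Inf)
    }
    r$icer
  }
  bisect_threshold(eval_icer, target_wtp, bracket, tol)
}

#' Bisection on a monotone ICER function
#'
#' Generic core used by [threshold_search()]; exposed so the bisection can
#' be checked against a brute-force grid scan on toy models.
#'
#' @param icer_fn Function of the variable returning an ICER (may return
#'   +/-Inf for dominance).
#' @param target Target ICER (willingness-to-pay).
#' @param bracket `c(low, high)`; `icer_fn` at the endpoints must straddle
#'   the target.
#' @param tol Absolute tolerance on the variable.
#' @return The variable value at which the ICER crosses the target.
#' @export
bisect_threshold <- function(icer_fn, target, bracket, tol) {
  stopifnot(length(bracket) == 2L, bracket[1] < bracket[2], tol > 0)
  f_lo <- icer_fn(bracket[1]) - target
  f_hi <- icer_fn(bracket[2]) - target
  if (is.na(f_lo) || is.na(f_hi) || f_lo * f_hi > 0) {
    stop(sprintf(
      "threshold bracket does not straddle the target (ICER(%g) = %.0f, ICER(%g) = %.0f, target %g)",
      bracket[1], f_lo + target, bracket[2], f_hi + target, target),
      call. = FALSE)
  }
  lo <- bracket[1]; hi <- bracket[2]
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    fm <- icer_fn(mid) - target
    if (fm == 0) return(mid)
    if (sign(fm) == sign(f_lo)) {
      lo <- mid; f_lo <- fm
    } else {
      hi <- mid
    }
  }
  (lo + hi) / 2
}

# ---------------------------------------------------------------------------
# Scenario orchestration

#' Built-in scenario definitions
#'
#' `base` (healthcare perspective, conditional-survival extrapolation);
#' `societal` (adds per-cycle patient-time, transport, caregiver and
#' productivity costs); `continue_past_progression` (intervention drug cost
#' continues in the progressed state through 24 months);
#' `maintenance_pemetrexed` (nonsquamous chemotherapy patients accrue
#' pemetrexed in stable states beyond the chemotherapy cap); `cure`
#' (life-table extrapolation beyond trial follow-up).
#'
#' @return Named list of scenario modifier functions
#'   (`cea_inputs -> cea_inputs`).
#' @export
default_scenarios <- function() {
  list(
    base = identity,
    societal = function(ii) {
      ii$params$config$perspective <- "societal"; ii
    },
    continue_past_progression = function(ii) {
      int <- setdiff(names(ii$params$strategies), ii$comparator)[1]
      ii$params$strategies[[int]]$continue_past_progression <- TRUE; ii
    },
    maintenance_pemetrexed = function(ii) {
      ii$params$strategies[[ii$comparator]]$maintenance_pemetrexed <- TRUE; ii
    },
    cure = function(ii) {
      ii$params$config$extrapolation_mode <- "cure_life_table"; ii
    }
  )
}

#' Run a list of named scenarios
#'
#' @param inputs A `cea_inputs`.
#' @param scenarios Named list of modifier functions as in
#'   [default_scenarios()]; each scenario applies its configuration change
#'   to the shared base inputs and nothing else. A scenario may also be a
#'   list with a `curves` element (e.g. a PD-L1 subgroup's curve set) and an
#'   optional `modify` function.
#' @return A data.frame with one row per scenario: per-strategy cost and
#'   QALYs, increments, `icer` and `icer_rounded` (NA when a dominance
#'   label applies, reported in `label`).
#' @export
run_scenarios <- function(inputs, scenarios = default_scenarios()) {
  if (length(scenarios) == 0L) {
    return(data.frame(scenario = character()))
  }
  if (is.null(names(scenarios)) || any(names(scenarios) == "")) {
    stop("run_scenarios: scenarios must be named", call. = FALSE)
  }
  rows <- lapply(names(scenarios), function(nm) {
    sc <- scenarios[[nm]]
    ii <- inputs
    if (is.function(sc)) {
      ii <- sc(ii)
    } else if (is.list(sc)) {
      if (!is.null(sc$curves)) ii$curves <- sc$curves
      if (!is.null(sc$modify)) ii <- sc$modify(ii)
    } else {
      stop("run_scenarios: scenario '", nm,
           "' must be a function or a list", call. = FALSE)
    }
    r <- run_cea(ii)
    ic_num <- if (is.numeric(r$icer)) r$icer else NA_real_
    data.frame(
      scenario = nm,
      cost_intervention = r$strategies[[r$intervention]]$cost,
      qalys_intervention = r$strategies[[r$intervention]]$qalys,
      cost_comparator = r$strategies[[r$comparator]]$cost,
      qalys_comparator = r$strategies[[r$comparator]]$qalys,
      delta_cost = r$delta_cost, delta_qalys = r$delta_qalys,
      icer = ic_num,
      icer_rounded = if (is.na(ic_num)) NA_real_ else round_icer(ic_num),
      label = if (is.numeric(r$icer)) "" else r$icer,
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' @export
print.cea_result <- function(x, ...) {
  for (r in x$strategies) print(r)
  cat(sprintf("incremental: $%.0f / %.3f QALYs -> ICER %s\n",
              x$delta_cost, x$delta_qalys,
              if (is.numeric(x$icer)) sprintf("$%.0f/QALY (rounded $%.0f)",
                                              x$icer, x$icer_rounded)
              else x$icer))
  invisible(x)
}
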