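# Four-state monthly cohort engine. States: stable disease on first-line
# treatment (S1), stable disease on second-line treatment (S2), progressed
# disease (P), dead (D). D is absorbing; the cohort enters in S1.

STATE_NAMES <- c("STABLE_FIRST_LINE", "STABLE_SECOND_LINE", "PROGRESSED",
                 "DEAD")

#' Discount factor for a monthly cycle index
#'
#' @param cycle Month index (0-based), vectorized.
#' @param annual_rate Annual discount rate (>= 0).
#' @return `(1 + annual_rate)^(-cycle/12)`.
#' @export
discount_factor <- function(cycle, annual_rate) {
  if (any(cycle < 0)) stop("discount_factor: cycle must be >= 0",
                           call. = FALSE)
  if (annual_rate < 0) stop("discount_factor: rate must be >= 0",
                            call. = FALSE)
  (1 + annual_rate)^(-cycle / 12)
}

#' Build the per-cycle transition schedule for one strategy
#'
#' For each cycle the stable states exit to death with the OS-curve monthly
#' probability and to progression with the excess-PFS-hazard probability
#' from [split_progression_death()]; the progressed state exits to death
#' with the OS monthly hazard scaled by
#' `config$post_progression_hazard_multiplier` (default 1, which makes every
#' alive state face the marginal OS hazard and preserves the trace-vs-input
#' OS identity). At the treatment-stop transition (entering cycle
#' `ceiling(max_treatment_cycles)`) the non-progressing, surviving
#' first-line mass routes to the second-line state with probability
#' `second_line_uptake`.
#'
#' @param os,pfs `survival_curve` objects covering months
#'   `0..config$horizon_cycles`.
#' @param strategy A `strategy_config`.
#' @param config A `run_config`.
#' @param uptake Second-line uptake probability; defaults to the strategy's
#'   parameter in `params`.
#' @param params Optional `parameter_set` used to resolve `uptake`.
#' @return A `transition_schedule`: list of `horizon_cycles` row-stochastic
#'   4x4 matrices.
#' @export
build_schedule <- function(os, pfs, strategy, config, uptake = NULL,
                           params = NULL) {
  H <- config$horizon_cycles
  os <- curve_through(os, H)
  pfs <- curve_through(pfs, H)
  if (is.null(uptake)) {
    if (is.null(params)) {
      stop("build_schedule: supply 'uptake' or 'params'", call. = FALSE)
    }
    uptake <- param_mean(params, strategy$second_line_uptake_param)
  }
  stopifnot(uptake >= 0, uptake <= 1)
  mult <- config$post_progression_hazard_multiplier
  stop_cycle <- ceiling(strategy$max_treatment_cycles)  # 1-based matrix index

  ts <- 0:(H - 1L)
  s0 <- surv_at(os, ts)
  alive_in <- s0 > 0
  p_die <- p_prog <- p_pp_die <- rep(1, H)
  pfs_alive <- surv_at(pfs, ts) > 0
  split_ok <- alive_in & pfs_alive
  if (any(split_ok)) {
    tt <- ts[split_ok]
    sp <- split_progression_death(pfs, os, tt)
    p_die[split_ok] <- sp$p_die
    p_prog[split_ok] <- sp$p_progress
  }
  if (any(alive_in & !pfs_alive)) {
    # PFS exhausted while OS persists: stable states are empty by then,
    # but keep the schedule well-defined with death-only exits
    tt <- ts[alive_in & !pfs_alive]
    p_die[alive_in & !pfs_alive] <- 1 - surv_at(os, tt + 1L) / s0[alive_in & !pfs_alive]
    p_prog[alive_in & !pfs_alive] <- 0
  }
  if (any(alive_in)) {
    tt <- ts[alive_in]
    p_pp_die[alive_in] <- 1 - (surv_at(os, tt + 1L) / s0[alive_in])^mult
  }
  if (any(alive_in & p_die + p_prog >= 1 + 1e-12)) {
    stop("build_schedule: p_progress + p_die >= 1 at cycle ",
         ts[alive_in & p_die + p_prog >= 1 + 1e-12][1], call. = FALSE)
  }
  p_prog[!alive_in] <- 0  # extinct cohort: absorb straight to death

  schedule <- vector("list", H)
  for (t in ts) {
    i <- t + 1L
    stay <- 1 - p_die[i] - p_prog[i]
    # S1 row, with one-cycle second-line routing at the treatment stop
    route <- if (i == stop_cycle) uptake else 0
    m <- matrix(c(
      stay * (1 - route), stay * route, p_prog[i], p_die[i],
      0, stay, p_prog[i], p_die[i],
      0, 0, 1 - p_pp_die[i], p_pp_die[i],
      0, 0, 0, 1), 4, 4, byrow = TRUE,
      dimnames = list(STATE_NAMES, STATE_NAMES))
    if (any(abs(rowSums(m) - 1) > 1e-12)) {
      stop("build_schedule: non-stochastic row at cycle ", t, call. = FALSE)
    }
    schedule[[i]] <- m
  }
  structure(schedule, class = "transition_schedule")
}

#' Run the cohort simulation and accrue discounted costs and QALYs
#'
#' The cohort starts as (1, 0, 0, 0). Per cycle `t` (start-of-cycle
#' occupancy, no half-cycle correction unless configured):
#' \itemize{
#'   \item first-line drug cost accrues in S1 while `t < max_treatment_cycles`
#'     (a fractional cap prorates the final cycle);
#'   \item second-line drug cost accrues in S2; stable-state management cost
#'     in S1 and S2; progressed-state cost in P;
#'   \item under the societal perspective, patient-time, transport,
#'     caregiver and productivity-loss components accrue in all alive states;
#'   \item the one-time palliative-care/death cost applies to each cycle's
#'     new entrants to D, discounted at their cycle of death;
#'   \item the one-time weighted toxicity cost and the 1-month toxicity
#'     disutility apply to the full cohort at cycle 0;
#'   \item utilities accrue at annual value / 12 per alive cycle (stable
#'     utility in S1/S2; stable minus the progression decrement in P).
#' }
#' Everything is discounted by [discount_factor()].
#'
#' @param schedule A `transition_schedule` from [build_schedule()].
#' @param params A `parameter_set`.
#' @param strategy A `strategy_config`.
#' @param config A `run_config`.
#' @return A `strategy_result`: list with `cost`, `qalys`,
#'   `undiscounted_cost`, `undiscounted_qalys`, `life_months`, `trace`
#'   (matrix, cycles 0..horizon by state), and `cost_breakdown`.
#' @export
run_cohort <- function(schedule, params, strategy, config) {
  H <- length(schedule)
  pm <- function(name) param_mean(params, name)

  drug1 <- pm(strategy$drug_cost_param)
  drug2 <- pm(strategy$second_line_cost_param)
  c_stable <- pm("cost_stable")
  c_prog <- pm("cost_progressed")
  c_death <- pm("cost_death")
  c_tox <- pm(strategy$toxicity_cost_param)
  u_stable <- pm("utility_stable")
  u_prog <- u_stable - pm("utility_progression_decrement")
  du_tox <- pm(strategy$toxicity_disutility_param)
  societal <- config$perspective == "societal"
  c_soc <- if (societal) {
    pm("cost_patient_time") + pm(strategy$transport_cost_param) +
      pm("cost_caregiver") + pm("cost_productivity")
  } else 0
  cap <- strategy$max_treatment_cycles
  pem <- if (strategy$maintenance_pemetrexed) {
    strategy$nonsquamous_proportion * pm("cost_pemetrexed")
  } else 0
  pp_cap <- 24  # months of continued first-line drug past progression

  trace <- matrix(0, H + 1L, 4, dimnames = list(0:H, STATE_NAMES))
  trace[1, 1] <- 1
  for (t in 1:H) {
    x <- trace[t, ] %*% schedule[[t]]
    if (abs(sum(x) - 1) > 1e-9) {
      stop("run_cohort: occupancy does not sum to 1 at cycle ", t,
           call. = FALSE)
    }
    trace[t + 1L, ] <- x
  }
  if (any(diff(trace[, 4]) < -1e-12)) {
    stop("run_cohort: DEAD occupancy decreased", call. = FALSE)
  }

  ts <- 0:(H - 1L)
  disc <- discount_factor(ts, config$annual_discount_rate)
  occ <- trace[1:H, , drop = FALSE]
  if (config$half_cycle_correction) {
    occ <- (occ + trace[2:(H + 1L), , drop = FALSE]) / 2
  }
  s1 <- occ[, 1]; s2 <- occ[, 2]; pr <- occ[, 3]
  alive <- s1 + s2 + pr

  drug_frac <- pmin(1, pmax(0, cap - ts))          # first-line proration
  pp_frac <- if (strategy$continue_past_progression) {
    pmin(1, pmax(0, pp_cap - ts))
  } else rep(0, H)
  maint_frac <- 1 - drug_frac                       # beyond the cap

  comp_undisc <- c(
    first_line_drug = sum(s1 * drug1 * drug_frac) +
      sum(pr * drug1 * pp_frac),
    second_line_drug = sum(s2 * drug2),
    maintenance_pemetrexed = sum((s1 + s2) * pem * maint_frac),
    state_management = sum((s1 + s2) * c_stable) + sum(pr * c_prog),
    societal = sum(alive * c_soc),
    death = (trace[H + 1L, 4] - trace[1, 4]) * c_death,
    toxicity = c_tox)
  newdead <- diff(trace[, 4])
  comp_disc <- c(
    first_line_drug = sum(disc * (s1 * drug1 * drug_frac +
                                    pr * drug1 * pp_frac)),
    second_line_drug = sum(disc * s2 * drug2),
    maintenance_pemetrexed = sum(disc * (s1 + s2) * pem * maint_frac),
    state_management = sum(disc * ((s1 + s2) * c_stable + pr * c_prog)),
    societal = sum(disc * alive * c_soc),
    death = sum(discount_factor(1:H, config$annual_discount_rate) *
                  newdead * c_death),
    toxicity = c_tox)  # cycle 0, factor 1

  q_cycle <- (s1 + s2) * u_stable / 12 + pr * u_prog / 12
  qalys_undisc <- sum(q_cycle) - du_tox / 12
  qalys_disc <- sum(disc * q_cycle) - du_tox / 12

  structure(list(
    strategy = strategy$name,
    cost = sum(comp_disc),
    qalys = qalys_disc,
    undiscounted_cost = sum(comp_undisc),
    undiscounted_qalys = qalys_undisc,
    life_months = sum(trace[1:H, 1] + trace[1:H, 2] + trace[1:H, 3]),
    trace = trace,
    cost_breakdown = comp_disc,
    cost_breakdown_undiscounted = comp_undisc),
    class = "strategy_result")
}

#' Overall survival implied by a cohort trace
#'
#' `S(t) = 1 - occupancy(DEAD, t)`; with the default post-progression hazard
#' multiplier this reproduces the input OS curve exactly, the package's
#' analog of validating model-predicted survival against the trial curve.
#'
#' @param trace Trace matrix from a `strategy_result` (cycles 0..H by state).
#' @return A `survival_curve`.
#' @export
trace_overall_survival <- function(trace) {
  survival_curve(1 - trace[, "DEAD"])
}

#' @export
print.strategy_result <- function(x, ...) {
  cat(sprintf("strategy '%s': discounted cost $%.0f, %.3f QALYs, %.1f life-months\n",
              x$strategy, x$cost, x$qalys, x$life_months))
  invisible(x)
}
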