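# Shared fixtures. Everything is generated in code; nothing is read from
# outside the temp directory.

# One synthetic input bundle per test run, cached.
local_inputs <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      d <- file.path(tempdir(), "nsclccea-bundle")
      synth_bundle(d, synthetic_trial_spec(seed = 1L))
      cache <<- load_cea_inputs(file.path(d, "bundle.json"))
    }
    cache
  }
})

# Flat survival curve at 1 over 0..n months.
flat_curve <- function(n) survival_curve(rep(1, n + 1))

# Exponential curve with constant monthly event probability p.
expo_curve <- function(p, n) survival_curve((1 - p)^(0:n))

# A minimal run_config for toy horizons (no extrapolation needed).
toy_config <- function(horizon, rate = 0, ...) {
  run_config(horizon_cycles = horizon, trial_followup_cycles = horizon,
             annual_discount_rate = rate, ...)
}

# ---------------------------------------------------------------------------
# Independent oracle: individual-level microsimulation. Mirrors the stated
# accrual rules directly from the curves, without build_schedule/run_cohort.
microsim <- function(os, pfs, params, strategy, config, n_patients, seed) {
  set.seed(seed)
  H <- config$horizon_cycles
  pm <- function(nm) param_mean(params, nm)
  drug1 <- pm(strategy$drug_cost_param)
  drug2 <- pm(strategy$second_line_cost_param)
  uptake <- pm(strategy$second_line_uptake_param)
  c_stable <- pm("cost_stable"); c_prog <- pm("cost_progressed")
  c_death <- pm("cost_death"); c_tox <- pm(strategy$toxicity_cost_param)
  u_stable <- pm("utility_stable")
  u_prog <- u_stable - pm("utility_progression_decrement")
  du_tox <- pm(strategy$toxicity_disutility_param)
  c_soc <- if (config$perspective == "societal") {
    pm("cost_patient_time") + pm(strategy$transport_cost_param) +
      pm("cost_caregiver") + pm("cost_productivity")
  } else 0
  cap <- strategy$max_treatment_cycles
  pem <- if (strategy$maintenance_pemetrexed) {
    strategy$nonsquamous_proportion * pm("cost_pemetrexed")
  } else 0
  stop_cycle <- ceiling(cap)
  mult <- config$post_progression_hazard_multiplier

  state <- rep(1L, n_patients)  # 1 S1, 2 S2, 3 P, 4 D
  cost <- rep(0, n_patients); qaly <- rep(0, n_patients)
  life <- rep(0, n_patients)
  r <- config$annual_discount_rate
  for (t in 0:(H - 1L)) {
    disc <- (1 + r)^(-t / 12)
    s1 <- state == 1L; s2 <- state == 2L; p3 <- state == 3L
    alive <- state != 4L
    dfrac <- min(1, max(0, cap - t))
    ppfrac <- if (strategy$continue_past_progression) {
      min(1, max(0, 24 - t))
    } else 0
    cost[s1] <- cost[s1] + disc * (c_stable + drug1 * dfrac +
                                     pem * (1 - dfrac) + c_soc)
    cost[s2] <- cost[s2] + disc * (c_stable + drug2 + pem * (1 - dfrac) +
                                     c_soc)
    cost[p3] <- cost[p3] + disc * (c_prog + drug1 * ppfrac + c_soc)
    qaly[s1 | s2] <- qaly[s1 | s2] + disc * u_stable / 12
    qaly[p3] <- qaly[p3] + disc * u_prog / 12
    life[alive] <- life[alive] + 1
    if (t == 0L) {
      cost <- cost + c_tox
      qaly <- qaly - du_tox / 12
    }
    # transitions, straight from the curves
    os0 <- surv_at(os, t); os1 <- surv_at(os, t + 1L)
    pf0 <- surv_at(pfs, t); pf1 <- surv_at(pfs, t + 1L)
    p_die <- 1 - os1 / os0
    excess <- max(0, -log(pf1 / pf0) + log(os1 / os0))
    p_prog <- min(1 - exp(-excess), 1 - p_die)
    p_pp_die <- 1 - (os1 / os0)^mult
    u <- stats::runif(n_patients)
    new_state <- state
    die_s <- (s1 | s2) & u < p_die
    prog_s <- (s1 | s2) & u >= p_die & u < p_die + p_prog
    new_state[die_s] <- 4L
    new_state[prog_s] <- 3L
    die_p <- p3 & u < p_pp_die
    new_state[die_p] <- 4L
    if (t + 1L == stop_cycle) {
      staying <- s1 & !die_s & !prog_s
      route <- staying & stats::runif(n_patients) < uptake
      new_state[route] <- 2L
    }
    newly_dead <- alive & new_state == 4L
    cost[newly_dead] <- cost[newly_dead] +
      c_death * (1 + r)^(-(t + 1) / 12)
    state <- new_state
  }
  list(cost = mean(cost), qalys = mean(qaly), life_months = mean(life),
       se_cost = stats::sd(cost) / sqrt(n_patients),
       se_qalys = stats::sd(qaly) / sqrt(n_patients))
}
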