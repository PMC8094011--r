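# Cohort engine: schedules, traces, accrual, discounting, round trips.

test_that("discount_factor matches the closed form", {
  expect_equal(discount_factor(0, 0.03), 1)
  expect_equal(discount_factor(12, 0.03), 1 / 1.03)
  expect_equal(discount_factor(120, 0.03), 1.03^-10)
  expect_equal(discount_factor(120, 0.03), 0.744094, tolerance = 1e-6)
  expect_equal(discount_factor(7, 0), 1)
  expect_error(discount_factor(-1, 0.03), ">= 0")
})

test_that("build_schedule produces stochastic matrices with the stated topology", {
  cfg <- toy_config(12)
  strat <- default_strategies()$chemo  # cap 3
  os <- expo_curve(0.05, 12)
  sched <- build_schedule(os, os, strat, cfg, uptake = 0.537)
  expect_length(sched, 12)
  for (i in seq_along(sched)) {
    m <- sched[[i]]
    expect_equal(rowSums(m), rep(1, 4), tolerance = 1e-12,
                 ignore_attr = TRUE)
    expect_true(all(m >= 0 & m <= 1))
    expect_equal(m["DEAD", ], c(0, 0, 0, 1), ignore_attr = TRUE)
    # PFS == OS: no progression anywhere, death prob 0.05 in every state
    expect_equal(m["STABLE_FIRST_LINE", "PROGRESSED"], 0)
    expect_equal(m["STABLE_FIRST_LINE", "DEAD"], 0.05, tolerance = 1e-12)
    expect_equal(m["PROGRESSED", "DEAD"], 0.05, tolerance = 1e-12)
    # second-line routing mass only at the treatment-stop transition
    routed <- m["STABLE_FIRST_LINE", "STABLE_SECOND_LINE"]
    if (i == 3) expect_equal(routed, 0.95 * 0.537) else expect_equal(routed, 0)
  }
  # zero-hazard curves: identity apart from the routing cycle
  sched0 <- build_schedule(flat_curve(12), flat_curve(12), strat, cfg,
                           uptake = 0.537)
  for (i in seq_along(sched0)) {
    if (i == 3) {
      expect_equal(sched0[[i]]["STABLE_FIRST_LINE", ],
                   c(1 - 0.537, 0.537, 0, 0), ignore_attr = TRUE)
    } else {
      expect_equal(sched0[[i]], diag(4), ignore_attr = TRUE)
    }
  }
})

test_that("run_cohort accrues the closed-form trivial cases", {
  ps <- parameter_set(config = toy_config(12))
  cfg <- ps$config
  strat <- default_strategies()$nivo_ipi

  # no death, no progression, 12 cycles, no discounting
  sched <- build_schedule(flat_curve(12), flat_curve(12), strat, cfg,
                          params = ps)
  res <- run_cohort(sched, ps, strat, cfg)
  du <- param_mean(ps, strat$toxicity_disutility_param)
  expect_equal(res$qalys, 0.754 - du / 12, tolerance = 1e-12)
  expect_equal(res$life_months, 12)

  # all dead at cycle 1: cycle-0 costs plus the one-time death cost
  dead1 <- survival_curve(c(1, rep(0, 12)))
  schedD <- build_schedule(dead1, dead1, strat, cfg, params = ps)
  resD <- run_cohort(schedD, ps, strat, cfg)
  expected <- param_mean(ps, "cost_stable") + param_mean(ps, "cost_combo") +
    param_mean(ps, strat$toxicity_cost_param) + param_mean(ps, "cost_death")
  expect_equal(resD$cost, expected, tolerance = 1e-9)
  expect_equal(resD$life_months, 1)
  expect_equal(unname(resD$trace[2, "DEAD"]), 1)

  # constant-hazard survival: truncated geometric life months
  cfg120 <- toy_config(120)
  ps120 <- parameter_set(config = cfg120)
  ec <- expo_curve(0.05, 120)
  schedE <- build_schedule(ec, ec, strat, cfg120, params = ps120)
  resE <- run_cohort(schedE, ps120, strat, cfg120)
  expect_equal(resE$life_months, sum(0.95^(0:119)), tolerance = 1e-9)
})

test_that("trace conservation, absorbing death, and OS round trip hold", {
  inputs <- local_inputs()
  res <- run_cea(inputs)
  for (nm in names(res$strategies)) {
    tr <- res$strategies[[nm]]$trace
    expect_equal(rowSums(tr), rep(1, nrow(tr)), tolerance = 1e-9,
                 ignore_attr = TRUE)
    expect_true(all(diff(tr[, "DEAD"]) >= -1e-12))
    # round trip: model-implied OS equals the (extended) input OS curve
    ext <- nsclcCEA:::extend_strategy_curves(inputs$curves[[nm]], inputs)
    rec <- trace_overall_survival(tr)
    expect_lt(max(abs(rec$surv - ext$os$surv)), 1e-9)
  }
})

test_that("discounting strictly reduces accruals; zero inputs zero out", {
  inputs <- local_inputs()
  r3 <- run_cea(inputs)
  inputs0 <- inputs
  inputs0$params$config$annual_discount_rate <- 0
  r0 <- run_cea(inputs0)
  for (nm in names(r3$strategies)) {
    expect_lt(r3$strategies[[nm]]$cost, r0$strategies[[nm]]$cost)
    expect_lt(r3$strategies[[nm]]$qalys, r0$strategies[[nm]]$qalys)
    expect_lte(r3$strategies[[nm]]$cost,
               r3$strategies[[nm]]$undiscounted_cost)
  }

  zc <- inputs
  for (nm in names(zc$params$params)) {
    if (startsWith(nm, "cost_")) {
      zc$params$params[[nm]]$mean <- 0
      zc$params$params[[nm]]$sd <- 0
    }
  }
  rz <- run_cea(zc)
  expect_equal(rz$strategies$nivo_ipi$cost, 0)
  expect_equal(rz$strategies$chemo$cost, 0)

  zu <- inputs
  for (nm in c("utility_stable", "utility_progression_decrement",
               "disutility_toxicity_nivo_ipi", "disutility_toxicity_chemo")) {
    zu$params$params[[nm]]$mean <- 0
  }
  ru <- run_cea(zu)
  expect_equal(ru$strategies$nivo_ipi$qalys, 0)
  expect_equal(ru$strategies$chemo$qalys, 0)
})

test_that("scenario accrual rules change costs the way they should", {
  inputs <- local_inputs()
  base <- run_cea(inputs)

  soc <- inputs
  soc$params$config$perspective <- "societal"
  rsoc <- run_cea(soc)
  for (nm in names(base$strategies)) {
    # societal: strictly higher costs, identical QALYs and trace
    expect_gt(rsoc$strategies[[nm]]$cost, base$strategies[[nm]]$cost)
    expect_equal(rsoc$strategies[[nm]]$qalys, base$strategies[[nm]]$qalys)
    expect_equal(rsoc$strategies[[nm]]$trace, base$strategies[[nm]]$trace)
  }

  cpp <- inputs
  cpp$params$strategies$nivo_ipi$continue_past_progression <- TRUE
  rcpp <- run_cea(cpp)
  expect_gt(rcpp$strategies$nivo_ipi$cost, base$strategies$nivo_ipi$cost)
  expect_equal(rcpp$strategies$nivo_ipi$qalys, base$strategies$nivo_ipi$qalys)
  expect_equal(rcpp$strategies$chemo$cost, base$strategies$chemo$cost)

  pem <- inputs
  pem$params$strategies$chemo$maintenance_pemetrexed <- TRUE
  rpem <- run_cea(pem)
  expect_gt(rpem$strategies$chemo$cost, base$strategies$chemo$cost)
  expect_equal(rpem$strategies$nivo_ipi$cost, base$strategies$nivo_ipi$cost)
})

test_that("half-cycle correction averages adjacent occupancies", {
  ps <- parameter_set(config = toy_config(12))
  strat <- default_strategies()$nivo_ipi
  ec <- expo_curve(0.1, 12)
  sched <- build_schedule(ec, ec, strat, ps$config, params = ps)
  r0 <- run_cohort(sched, ps, strat, ps$config)
  ps2 <- ps
  ps2$config$half_cycle_correction <- TRUE
  r1 <- run_cohort(sched, ps2, strat, ps2$config)
  # shrinking occupancy: half-cycle correction lowers QALYs
  expect_lt(r1$qalys, r0$qalys)
  du <- param_mean(ps, strat$toxicity_disutility_param)
  q_expect <- sum((0.9^(0:11) + 0.9^(1:12)) / 2) * 0.754 / 12 - du / 12
  expect_equal(r1$qalys, q_expect, tolerance = 1e-12)
})
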