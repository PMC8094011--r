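# Curve construction, file I/O, hazard algebra, and extrapolation.

test_that("survival_curve enforces its invariants", {
  expect_error(survival_curve(c(0.9, 0.8)), "S\\(0\\)")
  expect_error(survival_curve(c(1, 1.05)), "out of \\[0, 1\\]")
  expect_error(survival_curve(c(1, 0.8, 0.9)), "nonincreasing")
  sc <- survival_curve(c(1, 0.95, 0.90))
  expect_equal(surv_at(sc, 0:2), c(1, 0.95, 0.90))
  expect_error(surv_at(sc, 3), "domain")
})

test_that("read_survival_points validates and interpolates log-linearly", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("month\tsurvival", "0\t1.0", "1\t0.95", "2\t0.90"), f)
  sc <- read_survival_points(f)
  expect_length(sc$surv, 3)
  expect_equal(sc$surv, c(1, 0.95, 0.90))

  writeLines(c("month\tsurvival", "0\t1.0", "2\t0.81"), f)
  sc <- read_survival_points(f)
  expect_equal(surv_at(sc, 1), sqrt(0.81), tolerance = 1e-12)
  expect_equal(surv_at(sc, 2), 0.81)

  writeLines(c("month\tsurvival", "0\t1.0", "1\t1.05"), f)
  expect_error(read_survival_points(f), "out of \\[0, 1\\]")
  writeLines(c("month\tsurvival", "1\t0.9"), f)
  expect_error(read_survival_points(f), "month 0")

  # write/read round trip
  sc <- expo_curve(0.05, 24)
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_survival_points(sc, f2)
  expect_equal(read_survival_points(f2)$surv, sc$surv, tolerance = 1e-12)
})

test_that("monthly_event_probability is the conditional event risk", {
  sc <- survival_curve(c(1, 0.95, 0.95, 0.90, 0.81, 0.70, 0.50, 0.40))
  expect_equal(monthly_event_probability(sc, 3), 1 - 0.81 / 0.90)
  expect_equal(monthly_event_probability(sc, 1), 0)     # flat segment
  expect_equal(monthly_event_probability(sc, 6), 0.20)  # 0.50 -> 0.40
  # constant for exponential curves
  ec <- expo_curve(0.07, 60)
  expect_equal(monthly_event_probability(ec, 0:59), rep(0.07, 60),
               tolerance = 1e-9)
  z <- survival_curve(c(1, 0, 0))
  expect_error(monthly_event_probability(z, 1), "degenerate")
})

test_that("split_progression_death decomposes cause-specific hazards", {
  s_os <- survival_curve(c(1, 0.90, 0.81))
  s_pfs <- survival_curve(c(1, 0.80, 0.64))
  sp <- split_progression_death(s_pfs, s_os, 1)
  expect_equal(sp$p_die, 0.100, tolerance = 1e-12)
  expect_equal(sp$p_progress, 1 - exp(-(log(0.8 / 0.64) - log(0.9 / 0.81))),
               tolerance = 1e-12)
  expect_equal(sp$p_progress, 0.11111, tolerance = 1e-4)

  # identical curves: no excess progression hazard
  sp <- split_progression_death(s_os, s_os, 0:1)
  expect_equal(sp$p_progress, c(0, 0))

  # crossing hazards are floored at zero
  s_pfs2 <- survival_curve(c(1, 0.95, 0.95))
  sp <- split_progression_death(s_pfs2, s_os, 1)
  expect_equal(sp$p_progress, 0)

  # probabilities always compatible: p_progress + p_die < 1 under finite
  # hazards (property over random monotone curves)
  set.seed(7)
  for (i in 1:25) {
    os <- survival_curve(cumprod(c(1, runif(30, 0.85, 1))))
    ex <- cumprod(c(1, runif(30, 0.85, 1)))
    pfs <- survival_curve(os$surv * ex)
    sp <- split_progression_death(pfs, os, 0:29)
    expect_true(all(sp$p_progress + sp$p_die < 1))
    expect_true(all(sp$p_progress >= 0 & sp$p_die >= 0))
  }
})

test_that("conditional-survival extension compounds monthly", {
  sc <- survival_curve(seq(1, 0.40, length.out = 43))  # S(42) = 0.40
  cs <- data.frame(year = 1:7, cs = c(0.70, 0.75, 0.80, 0.85, 0.90, 0.90,
                                      0.90))
  ext <- extend_conditional(sc, cs, boundary = 42, horizon = 120)
  expect_length(ext$surv, 121)
  expect_equal(surv_at(ext, 43), 0.40 * 0.70^(1 / 12), tolerance = 1e-12)
  expect_equal(surv_at(ext, 43), 0.38829, tolerance = 1e-4)
  expect_equal(surv_at(ext, 54), 0.40 * 0.70)  # one full year compounds
  # cs = 1 leaves the curve flat
  flat <- extend_conditional(sc, data.frame(year = 1:7, cs = rep(1, 7)),
                             42, 120)
  expect_equal(surv_at(flat, 120), 0.40)
  # boundary = horizon is the identity
  expect_equal(extend_conditional(sc, cs, 42, 42)$surv, sc$surv)
  expect_error(extend_conditional(sc, cs[1:2, ], 42, 120), "covers")
})

test_that("life-table extension applies age-specific background mortality", {
  sc <- survival_curve(seq(1, 0.40, length.out = 43))
  lt <- data.frame(age = 50:100, qx = rep(0.12, 51))
  ext <- extend_life_table(sc, lt, start_age = 64, boundary = 42,
                           horizon = 60)
  expect_equal(surv_at(ext, 43), 0.40 * 0.88^(1 / 12), tolerance = 1e-12)
  expect_equal(surv_at(ext, 43), 0.39576, tolerance = 1e-4)
  # agreement of the two extenders when cs = 1 - q
  cs <- data.frame(year = 1:7, cs = 1 - 0.12)
  ext2 <- extend_conditional(sc, cs, 42, 60)
  expect_equal(ext$surv, ext2$surv, tolerance = 1e-12)
  expect_error(extend_life_table(sc, lt[lt$age < 66, ], 64, 42, 120),
               "not covered")
})

test_that("apply_hazard_ratio is proportional hazards on the grid", {
  ec <- expo_curve(1 - exp(-0.05), 60)  # S(t) = exp(-0.05 t)
  expect_equal(apply_hazard_ratio(ec, 1)$surv, ec$surv)
  hr2 <- apply_hazard_ratio(ec, 2)
  expect_equal(hr2$surv, exp(-0.10 * (0:60)), tolerance = 1e-12)
  sc <- survival_curve(c(rep(1, 12), rep(0.5, 5)))
  expect_equal(surv_at(apply_hazard_ratio(sc, 0.73), 12), 0.5^0.73)
  expect_equal(0.5^0.73, 0.60286, tolerance = 1e-4)
  expect_error(apply_hazard_ratio(ec, 0), "positive")
})

test_that("every transform preserves monotone nonincreasing output", {
  set.seed(11)
  base <- survival_curve(cumprod(c(1, runif(42, 0.9, 1))))
  cs <- data.frame(year = 1:10, cs = runif(10, 0.5, 1))
  lt <- make_life_table()
  outs <- list(
    apply_hazard_ratio(base, 0.73),
    apply_hazard_ratio(base, 1.8),
    extend_conditional(base, cs, 42, 120),
    extend_life_table(base, lt, 64, 42, 120))
  for (o in outs) {
    expect_equal(o$surv[1], 1)
    expect_true(all(diff(o$surv) <= 1e-12))
  }
})
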