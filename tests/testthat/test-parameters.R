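# Distribution parameterizations, the SD rule, weighted aggregation, and
# parameter-file loading.

test_that("gamma_from_mean_sd matches method-of-moments algebra", {
  cases <- list(
    list(mean = 26425, sd = 5285, shape = 25, scale = 1057),
    list(mean = 100, sd = 100, shape = 1, scale = 100),
    list(mean = 6384, sd = 1276.8, shape = 25, scale = 255.36))
  for (cs in cases) {
    g <- gamma_from_mean_sd(cs$mean, cs$sd)
    expect_equal(g$shape, cs$shape, tolerance = 1e-12)
    expect_equal(g$scale, cs$scale, tolerance = 1e-12)
    # analytic round trip
    expect_equal(g$shape * g$scale, cs$mean)
    expect_equal(sqrt(g$shape) * g$scale, cs$sd)
  }
  expect_error(gamma_from_mean_sd(0, 1), "positive")
  expect_error(gamma_from_mean_sd(1, -1), "positive")
})

test_that("beta_from_mean_sd matches method-of-moments algebra", {
  b <- beta_from_mean_sd(0.5, sqrt(1 / 12))
  expect_equal(b$alpha, 1, tolerance = 1e-9)
  expect_equal(b$beta, 1, tolerance = 1e-9)

  b <- beta_from_mean_sd(0.754, 0.1508)
  nu <- 0.754 * (1 - 0.754) / 0.1508^2 - 1
  expect_equal(b$alpha, 0.754 * nu)
  expect_equal(b$beta, (1 - 0.754) * nu)
  expect_equal(b$alpha, 5.396, tolerance = 1e-3)
  expect_equal(b$beta, 1.761, tolerance = 1e-3)

  expect_error(beta_from_mean_sd(0.754, 0.9), "feasibility")
  expect_error(beta_from_mean_sd(1.2, 0.1), "\\(0, 1\\)")
})

test_that("moment round-trip holds empirically on seeded draws", {
  set.seed(101)
  g <- gamma_from_mean_sd(26425, 5285)
  x <- rgamma(1e5, shape = g$shape, scale = g$scale)
  expect_equal(mean(x), 26425, tolerance = 0.01)
  expect_equal(sd(x), 5285, tolerance = 0.01)
  b <- beta_from_mean_sd(0.754, 0.1508)
  y <- rbeta(1e5, b$alpha, b$beta)
  expect_equal(mean(y), 0.754, tolerance = 0.01)
  expect_equal(sd(y), 0.1508, tolerance = 0.01)
})

test_that("default_sd applies the 20% rule and is linear", {
  expect_equal(default_sd(26425), 5285)
  expect_equal(default_sd(0), 0)
  expect_equal(default_sd(0.754), 0.1508)
  for (m in c(0.5, 7, 4000)) {
    for (k in c(2, 10)) {
      expect_equal(default_sd(k * m), k * default_sd(m))
    }
  }
  expect_equal(default_sd(100, fraction = 0.4), 40)
  expect_error(default_sd(100, fraction = 0.5), "fraction")
})

test_that("weighted_event_average is the expected per-patient burden", {
  expect_equal(weighted_event_average(c(0.1, 0.2), c(1000, 2000)), 500)
  expect_equal(weighted_event_average(numeric(0), numeric(0)), 0)
  f <- c(0.05, 0.05, 0.10); v <- c(3000, 1000, 500)
  expect_equal(weighted_event_average(f, v), sum(f * v))
  expect_equal(weighted_event_average(f, v), 250)
  expect_error(weighted_event_average(c(0.1), c(1, 2)), "length")
  expect_error(weighted_event_average(c(1.5), c(1)), "\\[0, 1\\]")
  expect_error(weighted_event_average(c(0.5), c(-1)), "nonnegative")
})

test_that("base-case parameters carry the printed values and kinds", {
  p <- base_case_parameters()
  expect_equal(p$cost_combo$mean, 26425)
  expect_equal(p$cost_combo$mean,
               p$cost_nivolumab$mean + p$cost_ipilimumab$mean)
  expect_equal(p$cost_progressed$mean, 4000)
  expect_equal(p$cost_toxicity_chemo$mean, 6384)
  expect_equal(p$cost_stable$mean, 2166)
  expect_equal(p$cost_death$mean, 15957)
  expect_equal(p$utility_stable$mean, 0.754)
  expect_equal(p$utility_stable$ci95, c(0.407, 0.970))
  expect_equal(p$utility_progression_decrement$mean, 0.180)
  expect_equal(p$disutility_toxicity_nivo_ipi$mean, 0.017)
  expect_equal(p$second_line_uptake_nivo_ipi$mean, 0.377)
  expect_equal(p$second_line_uptake_chemo$mean, 0.537)
  expect_equal(p$os_hazard_ratio$ci95, c(0.64, 0.84))
  for (sp in p) {
    if (startsWith(sp$name, "cost_")) expect_equal(sp$kind, "gamma")
    if (startsWith(sp$name, "utility_") && sp$mean > 0) {
      expect_equal(sp$kind, "beta")
    }
    # unreported SDs: 20% of the mean throughout
    expect_equal(sp$sd, 0.2 * sp$mean)
  }
})

test_that("the bundled fixture loads unmodified with the printed values", {
  f <- system.file("extdata", "table1_parameters.json", package = "nsclcCEA")
  ps <- load_parameters(f)
  base <- base_case_parameters()
  for (nm in names(base)) {
    expect_equal(ps$params[[nm]]$mean, base[[nm]]$mean, label = nm)
    expect_equal(ps$params[[nm]]$ci95, base[[nm]]$ci95, label = nm)
  }
})

test_that("parameter files round-trip and validate", {
  f <- withr::local_tempfile(fileext = ".json")
  make_parameter_fixture(f)
  ps <- load_parameters(f)
  expect_s3_class(ps, "parameter_set")
  expect_equal(param_mean(ps, "cost_combo"), 26425)
  base <- base_case_parameters()
  for (nm in names(base)) {
    expect_equal(ps$params[[nm]]$mean, base[[nm]]$mean, label = nm)
    expect_equal(ps$params[[nm]]$kind, base[[nm]]$kind, label = nm)
  }

  # thin-space thousands separators normalize at parse time
  f2 <- withr::local_tempfile(fileext = ".json")
  writeLines(c('[{"name":"cost_x","mean":"26 425","kind":"gamma"},',
               '{"name":"cost_y","mean":4000,"kind":"gamma"}]'), f2)
  raw <- jsonlite::read_json(f2)
  expect_equal(nsclcCEA:::parse_money(raw[[1]]$mean), 26425)

  # sd omitted -> filled by the 20% rule
  f3 <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(
    list(list(name = "cost_progressed", mean = 4000, kind = "gamma")),
    f3, auto_unbox = TRUE)
  raw3 <- jsonlite::read_json(f3)
  sp <- nsclcCEA:::dist_spec(raw3[[1]]$name, raw3[[1]]$mean,
                             kind = raw3[[1]]$kind)
  expect_equal(sp$sd, 800)

  # invariant violations are loud and name the field
  expect_error(dist_spec("utility_stable", 1.2, kind = "beta"),
               "utility_stable")
})

test_that("set_param rescales the sd and enforces utility ordering", {
  ps <- parameter_set()
  ps2 <- set_param(ps, "cost_combo", 5058)
  expect_equal(param_mean(ps2, "cost_combo"), 5058)
  expect_equal(ps2$params$cost_combo$sd, 0.2 * 5058)
  expect_error(set_param(ps, "utility_progression_decrement", 0.9),
               "negative")
  expect_error(param_mean(ps, "no_such_param"), "unknown parameter")
})
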