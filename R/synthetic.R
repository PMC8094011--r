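# Synthetic trial-data generator: stands in for digitized two-arm OS/PFS
# Kaplan-Meier curves, the SEER-style conditional-survival table, the
# actuarial life table, and the parameter file, so every stage of the
# pipeline runs without external data.

#' Specification for a synthetic two-arm trial
#'
#' Curves are piecewise exponential on the monthly grid: the comparator OS
#' hazard is a base rate times knot multipliers (a hazard increase after
#' month 24 by default gives trial-like late convexity), scaled to hit the
#' target median exactly. PFS adds a constant excess progression hazard
#' chosen to hit the PFS median, which enforces S_pfs <= S_os by
#' construction. The intervention arm applies proportional hazards:
#' S_int = S_comp^hr per endpoint. Medians are placeholder values typical
#' of advanced NSCLC trials, not estimates of any particular trial.
#'
#' @param chemo_median_os Comparator median OS in months.
#' @param chemo_median_pfs Comparator median PFS in months (< median OS).
#' @param os_hazard_ratio Intervention vs comparator OS hazard ratio
#'   (default 0.73).
#' @param pfs_hazard_ratio PFS hazard ratio (default 0.82).
#' @param followup_months Length of the generated curves (default 42).
#' @param knot_months,knot_multipliers Piecewise-hazard knots: from each
#'   knot month onward the base hazard is scaled by the matching multiplier.
#' @param seed Stored for provenance; generation is deterministic.
#' @return A `synthetic_trial_spec` list.
#' @export
synthetic_trial_spec <- function(chemo_median_os = 14,
                                 chemo_median_pfs = 5.5,
                                 os_hazard_ratio = 0.73,
                                 pfs_hazard_ratio = 0.82,
                                 followup_months = 42,
                                 knot_months = 24,
                                 knot_multipliers = 1.4,
                                 seed = 1L) {
  stopifnot(chemo_median_os > 0, chemo_median_pfs > 0,
            chemo_median_pfs <= chemo_median_os,
            os_hazard_ratio > 0, pfs_hazard_ratio > 0,
            length(knot_months) == length(knot_multipliers),
            all(knot_multipliers > 0))
  structure(list(chemo_median_os = chemo_median_os,
                 chemo_median_pfs = chemo_median_pfs,
                 os_hazard_ratio = os_hazard_ratio,
                 pfs_hazard_ratio = pfs_hazard_ratio,
                 followup_months = as.integer(followup_months),
                 knot_months = knot_months,
                 knot_multipliers = knot_multipliers,
                 seed = as.integer(seed)),
            class = "synthetic_trial_spec")
}

# Cumulative hazard shape M(t) = integral of the knot multiplier function;
# the base hazard is scaled so exp(-h0 * M(median)) = 0.5 exactly.
#' @keywords internal
hazard_shape_integral <- function(t, knot_months, knot_multipliers) {
  vapply(t, function(x) {
    bounds <- c(0, knot_months, Inf)
    mults <- c(1, knot_multipliers)
    total <- 0
    for (i in seq_along(mults)) {
      lo <- bounds[i]; hi <- min(x, bounds[i + 1])
      if (hi > lo) total <- total + mults[i] * (hi - lo)
    }
    total
  }, numeric(1))
}

#' Generate the four synthetic survival curves
#'
#' @param spec A `synthetic_trial_spec`.
#' @param dir Optional directory; when given, the four curves are written
#'   as two-column text files (`os_chemo.tsv`, `pfs_chemo.tsv`,
#'   `os_nivo_ipi.tsv`, `pfs_nivo_ipi.tsv`).
#' @return A named list of curve pairs,
#'   `list(chemo = list(os, pfs), nivo_ipi = list(os, pfs))`, with a
#'   `files` attribute when `dir` was given.
#' @export
make_trial_curves <- function(spec = synthetic_trial_spec(), dir = NULL) {
  grid <- 0:spec$followup_months
  M <- hazard_shape_integral(grid, spec$knot_months, spec$knot_multipliers)
  M_med_os <- hazard_shape_integral(spec$chemo_median_os, spec$knot_months,
                                    spec$knot_multipliers)
  h0 <- log(2) / M_med_os
  s_os_chemo <- exp(-h0 * M)

  # constant excess progression hazard calibrated to the PFS median
  M_med_pfs <- hazard_shape_integral(spec$chemo_median_pfs, spec$knot_months,
                                     spec$knot_multipliers)
  e0 <- (log(2) - h0 * M_med_pfs) / spec$chemo_median_pfs
  if (e0 < -1e-12) {
    stop("make_trial_curves: PFS median implies S_pfs > S_os; choose ",
         "chemo_median_pfs below chemo_median_os", call. = FALSE)
  }
  e0 <- max(0, e0)
  s_pfs_chemo <- exp(-(h0 * M + e0 * grid))

  s_os_int <- s_os_chemo^spec$os_hazard_ratio
  s_pfs_int <- s_pfs_chemo^spec$pfs_hazard_ratio
  if (any(s_pfs_int > s_os_int + 1e-12)) {
    stop("make_trial_curves: intervention PFS exceeds OS; ",
         "pfs_hazard_ratio is too small relative to os_hazard_ratio",
         call. = FALSE)
  }
  s_pfs_int <- pmin(s_pfs_int, s_os_int)

  curves <- list(
    chemo = list(os = survival_curve(s_os_chemo),
                 pfs = survival_curve(s_pfs_chemo)),
    nivo_ipi = list(os = survival_curve(s_os_int),
                    pfs = survival_curve(s_pfs_int)))
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    files <- character(0)
    for (arm in names(curves)) {
      for (which in c("os", "pfs")) {
        f <- file.path(dir, paste0(which, "_", arm, ".tsv"))
        write_survival_points(curves[[arm]][[which]], f)
        files[paste0(which, "_", arm)] <- f
      }
    }
    attr(curves, "files") <- files
  }
  curves
}

#' Generate a synthetic life table
#'
#' Gompertz-like annual death probabilities,
#' `q(age) = min(0.7, base * exp(slope * (age - 50)))` — a smooth stand-in
#' for an actuarial general-population table (synthetic, not SSA data).
#'
#' @param min_age,max_age Age range covered (years).
#' @param base,slope Gompertz parameters.
#' @param file Optional output path (headered two-column text).
#' @return A data.frame (`age`, `qx`).
#' @export
make_life_table <- function(min_age = 50, max_age = 110, base = 0.005,
                            slope = 0.085, file = NULL) {
  age <- min_age:max_age
  qx <- pmin(0.7, base * exp(slope * (age - 50)))
  d <- data.frame(age = age, qx = qx)
  if (!is.null(file)) {
    utils::write.table(d, file, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  d
}

#' Generate a synthetic conditional-survival table
#'
#' Annual conditional survival of long-term advanced-NSCLC survivors,
#' rising with time since the extrapolation boundary — a synthetic stand-in
#' for a registry-derived (SEER-style) table.
#'
#' @param cs Vector of annual conditional survival probabilities in (0, 1],
#'   one per year beyond the boundary.
#' @param file Optional output path (headered two-column text).
#' @return A data.frame (`year`, `cs`).
#' @export
make_conditional_survival <- function(cs = c(0.70, 0.75, 0.80, 0.83, 0.85,
                                             0.87, 0.88, 0.89, 0.90, 0.90),
                                      file = NULL) {
  stopifnot(all(cs > 0), all(cs <= 1))
  d <- data.frame(year = seq_along(cs), cs = cs)
  if (!is.null(file)) {
    utils::write.table(d, file, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  d
}

#' Write the parameter fixture file
#'
#' Emits every base-case parameter (drug, state, toxicity, death and
#' societal costs; utilities and disutilities; second-line uptake
#' proportions; the OS hazard ratio) with means, 20%-rule SDs, 95% CIs and
#' distribution kinds, in the JSON parameter-file format consumed by
#' [load_parameters()].
#'
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
make_parameter_fixture <- function(file) {
  write_parameters(base_case_parameters(), file)
}

#' Generate the complete synthetic input bundle
#'
#' Writes the four curve files, the life table, the conditional-survival
#' table, the parameter fixture, and a run-configuration JSON wired to all
#' of them, into `dir`.
#'
#' @param dir Output directory (created if needed).
#' @param spec A `synthetic_trial_spec`.
#' @param config A `run_config` recorded in the bundle.
#' @return Path of the bundle configuration JSON, invisibly.
#' @export
synth_bundle <- function(dir, spec = synthetic_trial_spec(),
                         config = run_config(seed = spec$seed)) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  curves <- make_trial_curves(spec, dir = dir)
  files <- attr(curves, "files")
  lt <- file.path(dir, "life_table.tsv")
  cs <- file.path(dir, "conditional_survival.tsv")
  pf <- file.path(dir, "parameters.json")
  make_life_table(file = lt)
  make_conditional_survival(file = cs)
  make_parameter_fixture(pf)
  cfg <- list(
    parameters = basename(pf),
    curves = list(
      nivo_ipi = list(os = basename(files[["os_nivo_ipi"]]),
                      pfs = basename(files[["pfs_nivo_ipi"]])),
      chemo = list(os = basename(files[["os_chemo"]]),
                   pfs = basename(files[["pfs_chemo"]]))),
    life_table = basename(lt),
    conditional_survival = basename(cs),
    comparator = "chemo",
    run = unclass(config),
    synthetic_trial = unclass(spec))
  out <- file.path(dir, "bundle.json")
  jsonlite::write_json(cfg, out, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(out)
}

#' Load a bundle configuration into model inputs
#'
#' @param bundle_file Path to a `bundle.json` written by [synth_bundle()];
#'   relative paths inside it resolve against its directory.
#' @return A `cea_inputs`.
#' @export
load_cea_inputs <- function(bundle_file) {
  if (!file.exists(bundle_file)) {
    stop("load_cea_inputs: file not found: ", bundle_file, call. = FALSE)
  }
  cfg <- jsonlite::read_json(bundle_file, simplifyVector = TRUE)
  root <- dirname(bundle_file)
  resolve <- function(p) if (file.exists(p)) p else file.path(root, p)
  params <- load_parameters(resolve(cfg$parameters))
  rc_fields <- intersect(names(cfg$run), names(formals(run_config)))
  params$config <- do.call(run_config, cfg$run[rc_fields])
  curves <- lapply(cfg$curves, function(pair) {
    list(os = read_survival_points(resolve(pair$os)),
         pfs = read_survival_points(resolve(pair$pfs)))
  })
  cea_inputs(curves, params,
             cs_table = read_conditional_survival(
               resolve(cfg$conditional_survival)),
             life_table = read_life_table(resolve(cfg$life_table)),
             comparator = if (is.null(cfg$comparator)) "chemo"
                          else cfg$comparator)
}
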