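#' Gamma distribution parameters from a mean and standard deviation
#'
#' Method-of-moments parameterization used for all cost inputs in the
#' probabilistic sensitivity analysis: `shape = (mean/sd)^2`,
#' `scale = sd^2/mean`, so the resulting gamma has exactly the requested
#' first two moments.
#'
#' @param mean Positive mean (2020 USD for costs).
#' @param sd Positive standard deviation, same units.
#' @return A list with elements `shape` and `scale`.
#' @examples
#' gamma_from_mean_sd(26425, 5285) # shape 25, scale 1057
#' @export
gamma_from_mean_sd <- function(mean, sd) {
  if (!is.finite(mean) || mean <= 0) {
    stop("gamma_from_mean_sd: 'mean' must be a positive finite number, got ",
         mean, call. = FALSE)
  }
  if (!is.finite(sd) || sd <= 0) {
    stop("gamma_from_mean_sd: 'sd' must be a positive finite number, got ",
         sd, call. = FALSE)
  }
  list(shape = (mean / sd)^2, scale = sd^2 / mean)
}

#' Beta distribution parameters from a mean and standard deviation
#'
#' Method-of-moments parameterization used for utilities and
#' transition-scale probabilities: with
#' `nu = mean * (1 - mean) / sd^2 - 1`, `alpha = mean * nu` and
#' `beta = (1 - mean) * nu`. Feasibility requires `sd^2 < mean * (1 - mean)`.
#'
#' @param mean Mean in (0, 1).
#' @param sd Positive standard deviation; must satisfy the feasibility bound.
#' @return A list with elements `alpha` and `beta`.
#' @examples
#' beta_from_mean_sd(0.754, 0.1508)
#' @export
beta_from_mean_sd <- function(mean, sd) {
  if (!is.finite(mean) || mean <= 0 || mean >= 1) {
    stop("beta_from_mean_sd: 'mean' must lie strictly in (0, 1), got ",
         mean, call. = FALSE)
  }
  if (!is.finite(sd) || sd <= 0) {
    stop("beta_from_mean_sd: 'sd' must be positive, got ", sd, call. = FALSE)
  }
  vmax <- mean * (1 - mean)
  if (sd^2 >= vmax) {
    stop(sprintf(
      "beta_from_mean_sd: sd^2 = %.6g exceeds the feasibility bound mean*(1-mean) = %.6g",
      sd^2, vmax), call. = FALSE)
  }
  nu <- vmax / sd^2 - 1
  list(alpha = mean * nu, beta = (1 - mean) * nu)
}

#' Default standard deviation rule
#'
#' When a parameter's SD is not reported it is set to a fixed fraction of the
#' mean (20% in the base case; the tested range is 10%-40%).
#'
#' @param mean Nonnegative mean.
#' @param fraction Fraction of the mean to use; default 0.2.
#' @return `fraction * mean`.
#' @export
default_sd <- function(mean, fraction = 0.2) {
  if (!is.finite(mean) || mean < 0) {
    stop("default_sd: 'mean' must be nonnegative, got ", mean, call. = FALSE)
  }
  if (!is.finite(fraction) || fraction < 0.1 || fraction > 0.4) {
    stop("default_sd: 'fraction' must lie in [0.1, 0.4], got ", fraction,
         call. = FALSE)
  }
  fraction * mean
}

#' Frequency-weighted expected one-time burden
#'
#' Aggregates per-event costs or disutilities into a single expected
#' per-patient value, `sum(f_i * v_i)`, matching how strategy-level toxicity
#' costs and disutilities are built from trial adverse-event frequencies.
#'
#' @param frequencies Per-patient event probabilities in \[0, 1\].
#' @param values Per-event values (USD or utility decrement), nonnegative.
#' @return Expected per-patient value.
#' @export
weighted_event_average <- function(frequencies, values) {
  if (length(frequencies) != length(values)) {
    stop("weighted_event_average: 'frequencies' and 'values' lengths differ (",
         length(frequencies), " vs ", length(values), ")", call. = FALSE)
  }
  if (length(frequencies) == 0L) return(0)
  if (any(!is.finite(frequencies)) || any(frequencies < 0) ||
      any(frequencies > 1)) {
    stop("weighted_event_average: frequencies must lie in [0, 1]",
         call. = FALSE)
  }
  if (any(!is.finite(values)) || any(values < 0)) {
    stop("weighted_event_average: values must be nonnegative", call. = FALSE)
  }
  sum(frequencies * values)
}

#' Draw one value from a distribution specification
#'
#' `fixed` specs return the mean; `gamma` and `beta` specs are sampled via
#' their method-of-moments parameterization. Used by the PSA with a single
#' seeded RNG stream and a fixed draw order.
#'
#' @param spec A list with `kind` (one of "gamma", "beta", "fixed"),
#'   `mean`, and `sd`.
#' @return One numeric draw.
#' @keywords internal
draw_from_spec <- function(spec) {
  switch(spec$kind,
    fixed = spec$mean,
    gamma = {
      if (spec$mean == 0) return(0)
      g <- gamma_from_mean_sd(spec$mean, spec$sd)
      stats::rgamma(1L, shape = g$shape, scale = g$scale)
    },
    beta = {
      if (spec$mean == 0) return(0)
      b <- beta_from_mean_sd(spec$mean, spec$sd)
      stats::rbeta(1L, b$alpha, b$beta)
    },
    stop("draw_from_spec: unknown distribution kind '", spec$kind, "'",
         call. = FALSE)
  )
}
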