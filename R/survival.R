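# Survival curves on a monthly grid: the source of every transition
# probability in the model. Curves are monotone nonincreasing with S(0) = 1.

#' Construct a survival curve
#'
#' @param probabilities Survival probabilities on a contiguous monthly grid
#'   starting at month 0; must begin at 1 and be nonincreasing in \[0, 1\].
#' @return A `survival_curve` object (list with `times`, `surv`).
#' @export
survival_curve <- function(probabilities) {
  p <- as.numeric(probabilities)
  if (length(p) < 1L || any(!is.finite(p))) {
    stop("survival_curve: probabilities must be finite", call. = FALSE)
  }
  if (abs(p[1] - 1) > 1e-12) {
    stop("survival_curve: S(0) must equal 1, got ", p[1], call. = FALSE)
  }
  if (any(p < 0) || any(p > 1)) {
    bad <- which(p < 0 | p > 1)[1]
    stop("survival_curve: probability out of [0, 1] at month ", bad - 1,
         " (", p[bad], ")", call. = FALSE)
  }
  if (any(diff(p) > 1e-12)) {
    bad <- which(diff(p) > 1e-12)[1]
    stop("survival_curve: not nonincreasing between months ", bad - 1,
         " and ", bad, call. = FALSE)
  }
  structure(list(times = seq_along(p) - 1L, surv = pmin(p, cummin(p))),
            class = "survival_curve")
}

#' Survival probability at integer month(s)
#' @param curve A `survival_curve`.
#' @param t Month index (0-based), vectorized.
#' @return S(t).
#' @export
surv_at <- function(curve, t) {
  if (any(t < 0) || any(t > max(curve$times))) {
    stop("surv_at: month ", t[t < 0 | t > max(curve$times)][1],
         " outside curve domain [0, ", max(curve$times), "]", call. = FALSE)
  }
  curve$surv[t + 1L]
}

#' Read digitized survival points from a delimited text file
#'
#' Expects a headered two-column table (month, survival) including a month-0
#' row. Points on a coarser-than-monthly grid are interpolated onto the
#' monthly grid log-linearly (exponential interpolation), which preserves
#' positive hazards.
#'
#' @param file Path to the file; any whitespace/comma delimiter accepted by
#'   [utils::read.table()] with `header = TRUE`.
#' @return A validated `survival_curve`.
#' @export
read_survival_points <- function(file) {
  if (!file.exists(file)) {
    stop("read_survival_points: file not found: ", file, call. = FALSE)
  }
  d <- utils::read.table(file, header = TRUE, sep = "",
                         col.names = c("month", "survival"),
                         colClasses = "numeric")
  if (nrow(d) < 1L || d$month[1] != 0) {
    stop("read_survival_points: ", file, ": month 0 row required",
         call. = FALSE)
  }
  if (any(diff(d$month) <= 0)) {
    stop("read_survival_points: ", file, ": months must strictly increase",
         call. = FALSE)
  }
  if (any(d$survival < 0 | d$survival > 1)) {
    bad <- which(d$survival < 0 | d$survival > 1)[1]
    stop("read_survival_points: ", file, ": row ", bad,
         " survival out of [0, 1] (", d$survival[bad], ")", call. = FALSE)
  }
  if (any(diff(d$survival) > 1e-12)) {
    bad <- which(diff(d$survival) > 1e-12)[1]
    stop("read_survival_points: ", file, ": rows ", bad, "-", bad + 1,
         " not nonincreasing", call. = FALSE)
  }
  tmax <- d$month[nrow(d)]
  grid <- 0:tmax
  if (identical(as.numeric(grid), as.numeric(d$month))) {
    s <- d$survival
  } else {
    # log-linear interpolation; zeros are carried forward (absorbing)
    s <- numeric(length(grid))
    pos <- d$survival > 0
    s[grid %in% d$month] <- d$survival
    logs <- stats::approx(d$month[pos], log(d$survival[pos]), xout = grid,
                          method = "linear", rule = 2)$y
    s <- ifelse(grid <= max(d$month[pos]), exp(logs), 0)
    s[grid %in% d$month] <- d$survival  # keep supplied points exact
  }
  survival_curve(s)
}

#' Write a survival curve to the two-column text format
#' @param curve A `survival_curve`.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_survival_points <- function(curve, file) {
  utils::write.table(
    data.frame(month = curve$times, survival = curve$surv),
    file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Per-cycle event probability from a survival curve
#'
#' @param curve A `survival_curve`.
#' @param t Cycle index; `t` and `t + 1` must be in the curve domain.
#' @return `1 - S(t+1)/S(t)`.
#' @export
monthly_event_probability <- function(curve, t) {
  s0 <- surv_at(curve, t)
  s1 <- surv_at(curve, t + 1L)
  if (any(s0 <= 0)) {
    stop("monthly_event_probability: S(t) = 0 at month ",
         t[s0 <= 0][1], " (degenerate curve)", call. = FALSE)
  }
  1 - s1 / s0
}

#' Split the stable-state exit probability into progression and death
#'
#' Cause-specific hazard decomposition: the death probability comes from the
#' OS curve, `p_die = 1 - S_os(t+1)/S_os(t)`; the excess PFS-event hazard
#' over the OS hazard is attributed to progression,
#' `p_progress = 1 - exp(-max(0, h_pfs - h_os))`. Negative excess hazards
#' (crossing digitized curves) are floored at zero. By construction
#' `p_progress + p_die < 1` when both hazards are finite.
#'
#' @param s_pfs,s_os `survival_curve` objects covering `t` and `t + 1`.
#' @param t Cycle index (vectorized).
#' @return A list with numeric vectors `p_progress` and `p_die`.
#' @export
split_progression_death <- function(s_pfs, s_os, t) {
  os0 <- surv_at(s_os, t);  os1 <- surv_at(s_os, t + 1L)
  pf0 <- surv_at(s_pfs, t); pf1 <- surv_at(s_pfs, t + 1L)
  if (any(os0 <= 0) || any(pf0 <= 0)) {
    stop("split_progression_death: zero survival at month ",
         t[os0 <= 0 | pf0 <= 0][1], " (degenerate curve)", call. = FALSE)
  }
  h_os <- -log(os1 / os0)
  h_pfs <- -log(pf1 / pf0)
  excess <- h_pfs - h_os
  excess[is.nan(excess)] <- 0  # both hazards infinite: death dominates
  p_die <- 1 - os1 / os0
  # cap guards the corner case S_pfs(t+1) = 0 < S_os(t+1) (all remaining
  # stable patients progress within the cycle)
  list(p_progress = pmin(1 - exp(-pmax(0, excess)), 1 - p_die),
       p_die = p_die)
}

# ---------------------------------------------------------------------------
# Extrapolation beyond trial follow-up

#' Read a conditional-survival table
#'
#' Headered two-column text: year since the extrapolation boundary, annual
#' conditional survival probability in (0, 1].
#' @param file Path.
#' @return A data.frame with columns `year`, `cs`.
#' @export
read_conditional_survival <- function(file) {
  d <- utils::read.table(file, header = TRUE, sep = "",
                         col.names = c("year", "cs"), colClasses = "numeric")
  if (any(d$cs <= 0 | d$cs > 1)) {
    stop("read_conditional_survival: values must lie in (0, 1]",
         call. = FALSE)
  }
  if (any(diff(d$year) != 1)) {
    stop("read_conditional_survival: years must be contiguous",
         call. = FALSE)
  }
  d
}

#' Read a life table
#'
#' Headered two-column text: age in years, annual death probability q(x)
#' in (0, 1).
#' @param file Path.
#' @return A data.frame with columns `age`, `qx`.
#' @export
read_life_table <- function(file) {
  d <- utils::read.table(file, header = TRUE, sep = "",
                         col.names = c("age", "qx"), colClasses = "numeric")
  if (any(d$qx <= 0 | d$qx >= 1)) {
    stop("read_life_table: q(x) must lie in (0, 1)", call. = FALSE)
  }
  if (any(diff(d$age) != 1)) {
    stop("read_life_table: ages must be contiguous", call. = FALSE)
  }
  d
}

#' Extend a curve using annual conditional-survival probabilities
#'
#' Beyond the boundary month each month compounds the applicable year's
#' annual conditional survival: `S(t+1) = S(t) * cs^(1/12)`.
#'
#' @param curve A `survival_curve` defined through `boundary`.
#' @param cs_table data.frame (`year`, `cs`) as from
#'   [read_conditional_survival()]; year 1 governs months
#'   `boundary .. boundary + 11`, and so on.
#' @param boundary Month at which extrapolation starts (default 42).
#' @param horizon Last month the output must cover.
#' @return The extended `survival_curve`.
#' @export
extend_conditional <- function(curve, cs_table, boundary = 42, horizon) {
  if (max(curve$times) < boundary) {
    stop("extend_conditional: curve ends at month ", max(curve$times),
         ", before the boundary ", boundary, call. = FALSE)
  }
  if (horizon <= boundary) return(curve)
  s <- curve$surv[1:(boundary + 1L)]
  need_years <- ceiling((horizon - boundary) / 12)
  if (nrow(cs_table) < need_years) {
    stop("extend_conditional: conditional-survival table covers ",
         nrow(cs_table), " years, need ", need_years, call. = FALSE)
  }
  for (t in boundary:(horizon - 1L)) {
    yr <- (t - boundary) %/% 12 + 1L
    cs <- cs_table$cs[yr]
    s <- c(s, s[length(s)] * cs^(1 / 12))
  }
  survival_curve(s)
}

#' Extend a curve using general-population life-table mortality
#'
#' The cure assumption: beyond the boundary month survivors face only
#' age-specific background mortality,
#' `S(t+1) = S(t) * (1 - q(age at t))^(1/12)`, with age advancing
#' deterministically from `start_age`.
#'
#' @param curve A `survival_curve` defined through `boundary`.
#' @param life_table data.frame (`age`, `qx`) as from [read_life_table()].
#' @param start_age Cohort age in years at model entry (month 0).
#' @param boundary Month at which extrapolation starts (default 42).
#' @param horizon Last month the output must cover.
#' @return The extended `survival_curve`.
#' @export
extend_life_table <- function(curve, life_table, start_age, boundary = 42,
                              horizon) {
  if (max(curve$times) < boundary) {
    stop("extend_life_table: curve ends at month ", max(curve$times),
         ", before the boundary ", boundary, call. = FALSE)
  }
  if (horizon <= boundary) return(curve)
  s <- curve$surv[1:(boundary + 1L)]
  for (t in boundary:(horizon - 1L)) {
    age <- floor(start_age + t / 12)
    i <- match(age, life_table$age)
    if (is.na(i)) {
      stop("extend_life_table: age ", age, " not covered by the life table (",
           min(life_table$age), "-", max(life_table$age), ")", call. = FALSE)
    }
    s <- c(s, s[length(s)] * (1 - life_table$qx[i])^(1 / 12))
  }
  survival_curve(s)
}

#' Apply a proportional hazard ratio to a survival curve
#'
#' `S'(t) = S(t)^hr` on the monthly grid: scaling every monthly hazard by
#' `hr`. Used to regenerate the immunotherapy OS curve from the chemotherapy
#' anchor in hazard-ratio sensitivity analyses.
#'
#' @param reference A `survival_curve`.
#' @param hr Positive hazard ratio.
#' @return The transformed `survival_curve`.
#' @export
apply_hazard_ratio <- function(reference, hr) {
  if (!is.finite(hr) || hr <= 0) {
    stop("apply_hazard_ratio: hr must be positive, got ", hr, call. = FALSE)
  }
  survival_curve(reference$surv^hr)
}

#' Truncate or check a curve to cover exactly months 0..horizon
#' @keywords internal
curve_through <- function(curve, horizon) {
  if (max(curve$times) < horizon) {
    stop("curve ends at month ", max(curve$times),
         " but the horizon requires ", horizon, call. = FALSE)
  }
  survival_curve(curve$surv[1:(horizon + 1L)])
}
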