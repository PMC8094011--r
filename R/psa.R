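# Probabilistic sensitivity analysis: joint sampling of costs (gamma),
# utilities and probabilities (beta), and per-curve hazard multipliers, with
# a single seeded RNG stream and a fixed, documented draw order.

#' Draw one joint parameter replicate
#'
#' Draw order (fixed for reproducibility): (1) every parameter spec in its
#' declared order — gamma for costs, beta for utilities/probabilities,
#' `fixed` specs keep their mean; (2) one hazard multiplier per survival
#' curve, iterating strategies in their declared order, OS before PFS. The
#' multiplier is induced by a beta draw on the curve's mean monthly event
#' probability over trial follow-up (multiplier = draw/mean) and is applied
#' to all cycles' hazards, preserving curve monotonicity. A drawn
#' progression-decrement exceeding the drawn stable utility is clamped to
#' it, keeping the progressed-state utility nonnegative.
#'
#' Uses the current RNG state; seed management belongs to the caller
#' ([run_psa()]).
#'
#' @param inputs A `cea_inputs`.
#' @return A list with `params` (the resampled `parameter_set`) and
#'   `multipliers` (named per strategy, each `c(os = , pfs = )`).
#' @export
sample_parameters <- function(inputs) {
  ps <- inputs$params
  cfg <- ps$config
  for (nm in names(ps$params)) {
    sp <- ps$params[[nm]]
    v <- draw_from_spec(sp)
    ps$params[[nm]]$mean <- v
    ps$params[[nm]]$kind <- "fixed"  # drawn value is this replicate's truth
  }
  us <- ps$params[["utility_stable"]]$mean
  if (ps$params[["utility_progression_decrement"]]$mean > us) {
    ps$params[["utility_progression_decrement"]]$mean <- us
  }
  frac <- cfg$transition_sd_fraction
  if (is.null(frac)) frac <- 0.2
  mult <- lapply(names(ps$strategies), function(snm) {
    vapply(c("os", "pfs"), function(which) {
      if (frac == 0) return(1)
      curve <- inputs$curves[[snm]][[which]]
      tmax <- min(max(curve$times), cfg$trial_followup_cycles)
      pbar <- mean(monthly_event_probability(curve, 0:(tmax - 1L)))
      if (pbar <= 0) return(1)
      draw <- draw_from_spec(list(kind = "beta", mean = pbar,
                                  sd = frac * pbar))
      draw / pbar
    }, numeric(1))
  })
  names(mult) <- names(ps$strategies)
  list(params = ps, multipliers = mult)
}

# Apply per-curve hazard multipliers: scaling all monthly hazards by m is
# S'(t) = S(t)^m on the grid.
#' @keywords internal
apply_multipliers <- function(curves, multipliers) {
  for (snm in names(multipliers)) {
    for (which in c("os", "pfs")) {
      m <- multipliers[[snm]][[which]]
      if (m != 1) {
        curves[[snm]][[which]] <-
          survival_curve(curves[[snm]][[which]]$surv^m)
      }
    }
  }
  curves
}

#' Run the probabilistic sensitivity analysis
#'
#' Each replicate draws one joint parameter vector via
#' [sample_parameters()], reruns the full two-strategy cohort model, and
#' records discounted cost and QALYs per strategy. Replicate failures are
#' recorded and excluded with a warning; more than 1% failures aborts.
#'
#' @param inputs A `cea_inputs`.
#' @param n_reps Number of Monte Carlo repetitions (the reference analysis
#'   uses 100 000; desk-scale runs use fewer).
#' @param seed Integer seed for the single RNG stream.
#' @return A `psa_result`: list with matrices `cost` and `qalys`
#'   (`n_reps` rows, one column per strategy), `failed` (replicate
#'   indices), `n_reps`, `seed`, and a `summary` data.frame (mean cost and
#'   QALYs per strategy plus the ICER of means).
#' @export
run_psa <- function(inputs, n_reps, seed = inputs$params$config$seed) {
  stopifnot(n_reps >= 1)
  set.seed(as.integer(seed))
  strat_names <- names(inputs$params$strategies)
  # extend once; multipliers apply to the extended curves
  curves_ext <- lapply(names(inputs$curves), function(nm) {
    extend_strategy_curves(inputs$curves[[nm]], inputs)
  })
  names(curves_ext) <- names(inputs$curves)
  base_ext <- inputs
  base_ext$curves <- curves_ext

  cost <- qal <- matrix(NA_real_, n_reps, length(strat_names),
                        dimnames = list(NULL, strat_names))
  failed <- integer(0)
  for (r in seq_len(n_reps)) {
    draw <- sample_parameters(base_ext)
    res <- tryCatch({
      cur <- apply_multipliers(curves_ext, draw$multipliers)
      ps <- draw$params
      vapply(strat_names, function(nm) {
        strat <- ps$strategies[[nm]]
        sched <- build_schedule(cur[[nm]]$os, cur[[nm]]$pfs, strat,
                                ps$config, params = ps)
        out <- run_cohort(sched, ps, strat, ps$config)
        c(out$cost, out$qalys)
      }, numeric(2))
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failed <- c(failed, r)
      if (length(failed) > max(1, 0.01 * n_reps)) {
        stop("run_psa: more than 1% of replicates failed; last error: ",
             conditionMessage(res), call. = FALSE)
      }
    } else {
      cost[r, ] <- res[1, ]
      qal[r, ] <- res[2, ]
    }
  }
  if (length(failed)) {
    warning("run_psa: ", length(failed), " replicate(s) failed and were excluded")
  }
  ok <- setdiff(seq_len(n_reps), failed)
  mean_cost <- colMeans(cost[ok, , drop = FALSE])
  mean_qal <- colMeans(qal[ok, , drop = FALSE])
  int_name <- setdiff(strat_names, inputs$comparator)[1]
  icer_means <- icer(mean_cost[int_name] - mean_cost[inputs$comparator],
                     mean_qal[int_name] - mean_qal[inputs$comparator])
  structure(list(
    cost = cost, qalys = qal, failed = failed, n_reps = n_reps,
    seed = as.integer(seed), comparator = inputs$comparator,
    summary = data.frame(strategy = strat_names,
                         mean_cost = as.numeric(mean_cost),
                         mean_qalys = as.numeric(mean_qal)),
    icer_of_means = icer_means),
    class = "psa_result")
}

#' Cost-effectiveness acceptability curve
#'
#' At each willingness-to-pay value the probability a strategy is
#' cost-effective is the fraction of replicates in which it attains the
#' strictly highest net monetary benefit; exact NMB ties are credited to
#' the comparator (conservative against the intervention).
#'
#' @param psa A `psa_result` (or a list with `cost`/`qalys` matrices and a
#'   `comparator` name).
#' @param wtp_grid Numeric vector of willingness-to-pay values.
#' @return A data.frame: `wtp` plus one probability column per strategy;
#'   probabilities in each row sum to 1.
#' @export
ceac <- function(psa, wtp_grid) {
  if (length(wtp_grid) == 0L) {
    stop("ceac: empty willingness-to-pay grid", call. = FALSE)
  }
  ok <- which(stats::complete.cases(psa$cost))
  if (length(ok) == 0L) stop("ceac: no successful replicates", call. = FALSE)
  cost <- psa$cost[ok, , drop = FALSE]
  qal <- psa$qalys[ok, , drop = FALSE]
  strat <- colnames(cost)
  comp_i <- match(psa$comparator, strat)
  out <- lapply(wtp_grid, function(w) {
    benefit <- w * qal - cost
    best <- max.col(benefit, ties.method = "first")
    # strict-max rule with ties to the comparator
    maxb <- benefit[cbind(seq_len(nrow(benefit)), best)]
    tied <- rowSums(benefit == maxb) > 1
    best[tied] <- comp_i
    p <- tabulate(best, nbins = length(strat)) / length(best)
    c(wtp = w, stats::setNames(p, strat))
  })
  as.data.frame(do.call(rbind, out))
}

#' @export
print.psa_result <- function(x, ...) {
  cat(sprintf("PSA: %d replicates (%d failed), seed %d\n",
              x$n_reps, length(x$failed), x$seed))
  print(x$summary)
  cat("ICER of means: ",
      if (is.numeric(x$icer_of_means)) sprintf("$%.0f/QALY", x$icer_of_means)
      else x$icer_of_means, "\n", sep = "")
  invisible(x)
}
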