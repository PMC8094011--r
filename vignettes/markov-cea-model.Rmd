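---
title: "A Markov cohort model for first-line immunotherapy in advanced NSCLC: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A Markov cohort model for first-line immunotherapy in advanced NSCLC: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nsclcCEA)
```

## The decision problem

Dual checkpoint inhibition with nivolumab plus ipilimumab improves overall
survival over platinum-doublet chemotherapy as first-line treatment for
advanced non–small cell lung cancer, at a monthly drug cost roughly three
times the chemotherapy regimen's total. Whether that survival gain is worth
the spend is a resource-allocation question, answered here with a
state-transition (Markov) cohort model producing an incremental
cost-effectiveness ratio (ICER) in dollars per quality-adjusted life-year
(QALY), judged against a $100 000/QALY willingness-to-pay threshold.

## Model structure and assumptions

Four health states on a 1-month cycle over 120 cycles (10 years): stable
disease on first-line treatment, stable disease on second-line treatment,
progressed disease, and death. The cohort enters in stable/first-line.
Assumptions baked into the topology:

- Death is absorbing; progression is one-way (no return to stable).
- First-line treatment stops at disease progression or at the duration cap
  (24 months for the combination, 3 months for chemotherapy), whichever
  comes first. At the cap, patients still stable route to second-line
  treatment with the observed uptake proportions (37.7% / 53.7%); patients
  not routed remain stable without drug cost. Routing happens in the
  transition entering cycle `ceiling(cap)`, so drug cost covers exactly
  `cap` months.
- The second-line state has no duration cap of its own; its per-cycle drug
  cost applies while the patient stays stable. This is one of two readings
  of the published structure (per-cycle vs lump-sum second-line cost); the
  per-cycle reading was chosen because the state is defined as "stable
  disease *during receipt of* second-line treatment".

### Transition probabilities

All transitions derive from monthly-gridded OS and PFS curves. The split of
the stable-state exit into progression vs death is not identified by two
marginal curves alone; we use a cause-specific hazard decomposition:
death takes the OS monthly probability, and progression takes the PFS-event
hazard in excess of the OS hazard, floored at zero when digitized curves
cross. The floor mirrors the convention that PFS events include deaths.
Consequences worth knowing:

- `p_progress + p_die < 1` by construction, so schedules are always
  row-stochastic.
- Compounding survival through the schedule reproduces the input OS curve
  to machine precision (`trace_overall_survival()`); this is the package's
  standing validation that the engine does not distort its survival inputs,
  and it holds because the progressed state is given the marginal OS hazard
  (`post_progression_hazard_multiplier = 1` by default). No separate
  post-progression survival curve is published; a multiplier other than 1
  breaks the round-trip identity and is exposed only as an explicit
  sensitivity knob.

### Extrapolation beyond trial follow-up

Trial curves end at 42 months. Two regimes:

- **Conditional survival** (base case): each month beyond the boundary
  compounds an annual conditional-survival probability,
  `S(t+1) = S(t)·cs^(1/12)`, from a registry-style table of long-term
  advanced-NSCLC survivors.
- **Cure** (scenario): survivors at 42 months face only general-population
  life-table mortality, `S(t+1) = S(t)·(1−q(age))^(1/12)`, with age
  advancing deterministically from the configurable start age (64 years by
  default; the trial cohort's age is not printed in the source).

Both extenders agree exactly when `cs = 1 − q`, which the test suite
checks. PFS is extended by the same mechanism as OS: only survival is
discussed for the post-trial period in the source, and applying the same
conditional mechanism to both curves keeps the excess-hazard split
well-defined without inventing a second extrapolation model.

## Accrual conventions

- Costs and QALYs accrue on start-of-cycle occupancy; half-cycle
  correction is off by default (it would break the exact trace-vs-input OS
  comparison that anchors validation) but available as a flag.
- Utilities are annual values accrued at 1/12 per cycle: stable utility
  0.754/year in both stable states, minus a 0.180/year decrement when
  progressed. The strategy-level toxicity disutility is a one-time 1-month
  decrement (value/12 QALYs) charged to the whole cohort at cycle 0, and
  the weighted toxicity cost is likewise a one-time per-patient expected
  burden at entry — matching their construction as frequency-weighted
  averages over trial adverse events rather than recurring state costs.
- The one-time palliative/death cost is charged to each cycle's new
  entrants to the death state, discounted at that cycle's factor.
- Societal perspective adds patient-time, transport (arm-specific),
  caregiver and productivity-loss components to every alive cycle; the
  published per-cycle values carry no state restriction, so none is
  imposed.
- Discounting: `(1+r)^(−t/12)` with r = 3%/year for both costs and QALYs.

## Parameters and distributions

Every input carries a distribution specification for sensitivity analysis:
gamma for costs, beta for utilities and probabilities, parameterized by
method of moments from (mean, sd). Published 95% CIs are stored and drive
the one-way DSA ranges; the PSA uses the 20%-of-mean SD rule (the stated
convention for unknown SDs, and consistent with the printed CIs), with the
fraction configurable over the tested 10–40% band. Monetary values are
fixed 2020 USD; no inflation adjustment is applied (the source values are
already CPI-adjusted). Per-cycle drug costs include infusion ($143) and
follow-up/monitoring ($433).

Survival uncertainty in the PSA is one beta-derived hazard multiplier per
curve per replicate: a beta draw on the curve's mean monthly event
probability over follow-up, divided by that mean, applied to all cycles'
hazards (`S → S^m`). Independent per-cycle draws would break monotonicity
and inflate variance implausibly; a single multiplier preserves curve shape
and monotonicity by construction. Two numerical guards: a drawn progression
decrement exceeding the drawn stable utility is clamped to it, and exact
NMB ties in the acceptability curve are credited to chemotherapy —
conservative against the intervention.

## Sensitivity machinery

- **One-way DSA** re-runs both arms with one parameter at each range end,
  sorted by ICER spread. The OS hazard ratio (0.73; CI 0.64–0.84) is
  special-cased: the intervention OS curve is regenerated from the
  comparator anchor as `S^hr`, since the comparator arm is the natural
  control anchor when only the HR is varied.
- **Threshold searches** bisect on the intervention's monthly drug price
  (tolerance $1) or its maximum treatment duration (tolerance 0.1 month for
  reporting, matching the precision with which such thresholds are quoted;
  fractional months prorate the final cycle's drug cost). Both quantities
  move intervention drug spend monotonically while leaving QALYs untouched,
  so bisection is exact up to tolerance; the bisection core is checked
  against a $1-resolution brute-force scan on a toy model.
- **Scenarios** are single configuration changes on shared inputs:
  societal perspective, treatment continuation past progression (drug cost
  in the progressed state through month 24), maintenance pemetrexed
  (nonsquamous proportion × pemetrexed cost in stable states beyond the
  chemotherapy cap), cure extrapolation, and subgroup analyses via
  substitute curve sets.

## The synthetic-data generator

No deposited survival data exist for this model; real use starts from
digitized Kaplan–Meier points (digitization itself is out of scope). The
generator emulates the *shape* of such inputs: piecewise-exponential
comparator OS hitting a target median exactly (default 14 months, with a
1.4× hazard knot at month 24 for late convexity), PFS built by adding a
constant excess progression hazard calibrated to the PFS median (default
5.5 months) — which enforces PFS ≤ OS by construction — and the
intervention arm generated by proportional hazards (OS HR 0.73, PFS HR
0.82). Default medians are field-typical placeholder values, not estimates
of any trial.

What the generator does **not** emulate: Kaplan–Meier step noise and
censoring, non-proportional hazards (the delayed-separation pattern typical
of immunotherapy curves), and covariate heterogeneity. A green test
therefore establishes that the machinery is correct — transition algebra,
accrual, discounting, search and sampling logic — not that the package
reproduces the published headline ICERs, which depend on the true digitized
curves. Published values ($401 700/QALY base case, $5 058 threshold price,
1.4-month threshold duration, 99.9%/92.2% acceptability) serve as
qualitative calibration context; the acceptance suite checks the arithmetic
identities among them that are curve-independent.

## Numerical choices

- Curve validation tolerates 1e−12 non-monotonicity (floating-point dust)
  and requires S(0) = 1 exactly.
- Coarse digitized grids are interpolated log-linearly (exponentially),
  preserving positive hazards; supplied points are kept exact.
- Occupancy conservation is asserted at 1e−9 per cycle; the dead state must
  be nondecreasing at 1e−12.
- ICER dominance taxonomy: cheaper-and-at-least-as-effective is
  "dominant", costlier-and-less-effective "dominated", both-zero
  "indifferent"; the ratio is returned in the two same-sign quadrants.
  Rounding to the nearest $100 uses half-up.
- The PSA uses one seeded RNG stream with a fixed draw order (parameters in
  declared order, then curve multipliers by strategy, OS before PFS);
  identical seed and configuration give bit-identical output.
- Degenerate PSAs are expressible exactly: `fixed` specs draw their means,
  and `transition_sd_fraction = 0` disables curve uncertainty, making a
  1-replicate PSA equal the deterministic base case to the last bit.

## Limitations

- The progression/death split and post-progression mortality are modelling
  conventions, not published quantities; alternatives (e.g. a
  post-progression hazard multiplier ≠ 1) are supported but uncalibrated.
- Second-line treatment has no duration cap and toxicity-driven early
  discontinuation is not a separate transition (rates unpublished); its
  burden enters only through the one-time weighted toxicity terms.
- Only two strategies are compared; extended dominance logic is latent.
- The synthetic world is proportional-hazards by construction, so it cannot
  probe non-proportional survival patterns.
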