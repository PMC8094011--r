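# nsclcCEA

A Markov cohort cost-effectiveness model for first-line
**nivolumab–ipilimumab combination therapy versus platinum-doublet
chemotherapy** in advanced non–small cell lung cancer (NSCLC), built as a
tested, reusable R package. The package is aimed at health-economics
analysts who want a transparent, scriptable implementation of the full
decision-model pipeline — from digitized Kaplan–Meier survival points to
ICERs, tornado diagrams, threshold prices, scenario tables and
cost-effectiveness acceptability curves — with a synthetic-data generator
so every stage runs and is testable without access to trial data.

## The model

Patients move monthly between four health states: stable disease on
first-line treatment, stable disease on second-line treatment, progressed
disease, and death (absorbing). The cohort enters in the stable first-line
state and is simulated over a 10-year horizon (120 one-month cycles).

Transition probabilities come from overall-survival (OS) and
progression-free-survival (PFS) curves via a cause-specific hazard split.
With monthly hazards `h_os(t) = -log S_os(t+1)/S_os(t)` and `h_pfs(t)`
defined likewise,

```
p_die(t)      = 1 - S_os(t+1)/S_os(t)
p_progress(t) = 1 - exp(-max(0, h_pfs(t) - h_os(t)))
```

so progression carries only the PFS-event hazard in excess of death, and
compounding `1 - p_die` across cycles reproduces the input OS curve exactly
— the package's built-in analog of validating model survival against the
trial curve. Beyond 42 months of trial follow-up, curves are extended
either by registry-style annual conditional-survival probabilities (base
case) or by a cure assumption under general-population life-table
mortality.

Costs (2020 USD; drug, second-line, disease-state, one-time death,
weighted toxicity, and optional societal components) and utilities accrue
per cycle at a 3% annual discount rate. Cost-effectiveness is summarized
by the incremental cost-effectiveness ratio `ICER = ΔCost/ΔQALY` (rounded
to the nearest $100) against a $100 000/QALY willingness-to-pay threshold,
with net monetary benefit `NMB = WTP·QALY − Cost` underlying the
acceptability curve. The probabilistic sensitivity analysis samples costs
from gamma and utilities/probabilities from beta distributions
(method-of-moments from mean and SD; unknown SDs set to 20% of the mean),
plus one beta-derived hazard multiplier per survival curve.

## Worked example

```r
library(nsclcCEA)

dir <- tempfile()
synth_bundle(dir, synthetic_trial_spec(seed = 1))   # writes curves + tables + parameters
inputs <- load_cea_inputs(file.path(dir, "bundle.json"))

run_cea(inputs)
#> strategy 'nivo_ipi': discounted cost $342065, 1.384 QALYs, 27.6 life-months
#> strategy 'chemo': discounted cost $141890, 1.066 QALYs, 20.8 life-months
#> incremental: $200175 / 0.318 QALYs -> ICER $629434/QALY (rounded $629400)

threshold_search(inputs, 1e5, "monthly_price", bracket = c(100, 26425))
#> [1] 7746.927
```

On these *synthetic* trial-like curves (comparator median OS 14 months, OS
hazard ratio 0.73) the combination is far from cost-effective at
$100 000/QALY: its ICER is ≈$629 400/QALY, and its combined monthly price
would have to fall to ≈$7 747 to meet the threshold. The absolute numbers
are properties of the synthetic curves, not estimates for any real trial;
the qualitative structure (a several-hundred-percent price gap, scenario
ordering) mirrors what such models show on real data.

Other entry points: `one_way_dsa()` (tornado table), `run_scenarios()`
(societal perspective, treatment past progression, maintenance pemetrexed,
cure extrapolation, subgroup curve sets), `run_psa()` + `ceac()`
(probabilistic analysis), and the CLI wrapper
`inst/cli/nsclccea <synth|run|dsa|threshold|scenarios|psa>`.

## Layout

- `R/` — parameters & distributions, survival curves & extrapolation,
  Markov engine, CEA/DSA/threshold/scenarios, PSA/CEAC, synthetic data,
  CLI.
- `tests/testthat/` — unit and property suites per module plus
  `test-acceptance.R`; an independent patient-level microsimulation oracle
  lives in `helper-fixtures.R`.
- `vignettes/markov-cea-model.Rmd` — the methods vignette: model
  assumptions, parameter conventions, what the synthetic generator does
  and does not emulate, numerical choices, limitations.
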