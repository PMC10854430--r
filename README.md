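# nsclineage

Quantitative lineage analysis of adult pallial neural stem cells (NSCs)
tracked by long-term intravital imaging, for researchers studying
quiescence–activation dynamics and division fate in adult neurogenic
niches.

NSCs of the adult zebrafish pallium form a ventricular monolayer in which
each cell exposes an apical area (AA, µm²) and a *deltaA* (Notch-ligand)
reporter score. Imaging every 2–3 days over ~6 weeks yields per-cell
tracks with proliferation-marker flags and terminal events (division or
delamination). Two readouts organize lineage progression:

* **Activation from quiescence** is a rare exponential event with
  status-specific hazards, γ_neg = 0.0056 d⁻¹ (doubling time
  ln 2 / γ ≈ 124 d) for *deltaA*⁻ NSCs versus γ_pos = 0.0246 d⁻¹
  (≈ 28 d) for *deltaA*⁺ NSCs; once activated, cytokinesis follows after
  an exponential delay of rate λ = 0.326 d⁻¹ (median ln 2 / λ ≈ 2.1 d).
  λ is estimated from interval-censored durations by maximizing
  Σ log(e^{−λ·lower} − e^{−λ·upper}) with a profile-likelihood CI.
* **Division fate** is predicted by the mother's status: *deltaA*⁻
  mothers systematically produce one negative and one positive daughter
  (binary asymmetry), while *deltaA*⁺ mothers produce two positive
  daughters. Division propensity rises with AA within each status
  (logistic regression with fish fixed effects and type II Wald χ²
  tests); window probabilities compare across designs through the
  memoryless rescaling 1 − p_k = (1 − p_1)^k.

The package provides the validated track data model, event annotation
(divisions from quiescence, DC+k division modes, trajectories,
delaminations, per-daughter outcomes), descriptive statistics (area
conservation at division, slow quiescent growth, per-cell-per-day
division likelihoods with exact Poisson CIs), the interval-censored
timing estimator, the propensity/fate regressions, and a stochastic
simulator of the whole model so that every estimator is testable against
ground truth without external data.

## Worked example

```r
library(nsclineage)

params <- sim_params()                       # measured defaults
forest <- simulate_cohort(params, n_tracks = 828, seed = 1)
forest
#> <lineage_forest> 1780 tracks, 16961 points, 476 divisions, 188 delaminations

# deltaA-negative mothers divide 100% asymmetrically at DC+4
ev <- detect_divisions(forest)               # from-quiescence rule: >= 2 quiet intervals
negm <- ev[!ev$mother_status & ev$from_quiescence, ]
table(classify_division_mode(negm, forest, horizon = 4)$mode)
#>        neg_pos unclassifiable
#>             51             54

# activation-to-cytokinesis rate from 500 grid-censored durations
fit_exponential_ic(simulate_durations(500, rate = 0.326, seed = 5))
#> rate 0.3348 /day [95% CI 0.3057, 0.3659], doubling time 2.07 d, n = 500

# division likelihood under Notch blockade, from printed counts
division_likelihood(89, 261, 4)
#> rate 0.08525 /day [95% CI 0.06846, 0.1049], doubling time 8.13 d, n = 89
```

The 828 roots grow into 1780 tracks as daughters are born; every
classifiable daughter pair of a negative mother at four time points after
division is negative/positive, the asymmetric signature of self-renewal.
The fitted 0.335 d⁻¹ recovers the generating 0.326 d⁻¹ within its CI, and
89 divisions among 261 cells over 4 days give 0.0852 divisions per cell
per day. `run_pipeline()` chains all stages into one deterministic report
including a recovered-versus-configured rate table.

See `vignettes/nsc-lineage-model.Rmd` for the model, its assumptions, the
simulator's stated world, and all numerical conventions.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes, against the installed package: the division likelihood from
the printed blockade counts; the median normalized areal growth at day 40
recovered from 584 simulated nondividing *deltaA*⁻ tracks; the
activation-to-cytokinesis rate recovered by interval-censored fitting of
500 grid-censored durations; and the DC+4 asymmetric-division percentage
of *deltaA*⁻ mothers on simulator output — writing each as JSON keyed by
target id.
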