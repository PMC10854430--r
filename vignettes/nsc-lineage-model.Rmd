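---
title: "Quantifying adult NSC lineage progression from intravital tracks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying adult NSC lineage progression from intravital tracks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nsclineage)
```

## The biological system and the questions

Adult neural stem cells (NSCs) of the zebrafish pallium are radial glia
forming a ventricular monolayer, each contacting the ventricle through an
apical surface delimited by tight junctions. Long-term intravital imaging
(one stack every 2–3 days over ~6 weeks) resolves, for every cell, its
apical area (AA, µm²), the intensity of a *deltaA* transcriptional reporter
(binned into integer scores 0–3), a proliferation-marker flag (PCNA/MCM5
class G1 markers), and terminal events: cytokinesis — always in the plane
of the layer, producing two daughters — or delamination, the exit of a
small cell from the monolayer toward neuronal differentiation.

Two cell-intrinsic readouts organize NSC behavior along lineage
progression. *deltaA*-negative NSCs are large, rarely activate from
quiescence, and — crucially — divide asymmetrically: one daughter stays
*deltaA*-negative and regrows toward the mother's size, the other switches
the reporter on and engages, over further quiescence–division cycles,
toward delamination. *deltaA*-positive NSCs are smaller, activate several
times more often, and divide into two positive daughters of unequal score.
Within each status, a larger apical area predicts a higher division
propensity.

This package implements the quantitative machinery needed to extract those
statements from track tables — and a stochastic generator of the same
world, so that every estimator can be validated against known ground
truth.

## Data model

Tracks are long-format rows (`fish_id, treatment, track_id, parent_id,
tp_index, day, area_um2, delta_score, marker_on, event`), one per cell per
imaging time point. Missing values are empty fields, never 0 (a zero area
is invalid). Validation enforces: strictly increasing `tp_index` and
`day` per track, imaging-day gaps within a configured set (default
`{2, 3}`), events only at a track's final point, exactly two daughters per
division starting one time point after the mother's last observation, and
constant fish/treatment within a lineage tree. The division time point
(DC) is the first at which two daughters exist; the mother's last point is
the MC; DC+k is k imaging points later.

A division is *from quiescence* when the mother accumulated at least two
division-free imaging intervals (≈4–5 days) beforehand. The calibration
behind that rule is the activation-onset-to-cytokinesis delay: an
exponential fit of rate 0.326/day implies a median of 2.1 days and ≥86%
of onsets within 6 days of division, so two clean intervals make a
preceding quiescence phase highly likely.

## The simulator's stated world

`simulate_cohort()` runs a discrete-time event loop on the imaging grid;
hazards are converted per interval as `1 − exp(−rate · gap)` because
observations only exist at imaging days. Defaults are the measured values:

| parameter | default | meaning |
|---|---|---|
| `gamma_neg` | 0.0056 /day | activation hazard, *deltaA*⁻ (doubling time 124 d) |
| `gamma_pos` | 0.0246 /day | activation hazard, *deltaA*⁺ (doubling time 28 d) |
| `lambda_act` | 0.326 /day | activation-onset → cytokinesis rate |
| `growth_neg` | ln(1.3)/40 /day | quiescent areal growth, *deltaA*⁻ (30% in 40 d) |
| `growth_pos` | 0 | quiescent growth, *deltaA*⁺ |
| `delam_area_threshold` | 10 µm² | below this, positive cells may delaminate |
| `division_asym_noise` | 0.106 | SD of the daughter area fraction; calibrated so ~60% of pairs differ ≥20% |
| `fate_on_at_DC_prob` | 0.7 | positive daughter of a ⁻ mother already ON at DC (else at DC+1) |
| `requiescence_prob_pos` | 223/250 | positive daughter returns to quiescence |
| `pospos_binary_lag_mean` | 11.5 d | lag of ⁺/⁺ → ON/OFF conversion |
| `switch_off_rate`, `switch_on_rate` | 9/703, 5/703 | per-track-per-movie spontaneous switches in nondividers |
| `movie_days`, `imaging_gaps` | 43, {2, 3} | imaging design |
| `ly_rate` | 0.0852 /day | shared division hazard under Notch blockade |

Quiescent growth is exponential rather than linear: the observed growth
does not look linear, and the doubling-time arithmetic used throughout is
exponential. Daughter areas sum to the mother's area exactly before
measurement noise (5% multiplicative lognormal by default); the imbalance
SD of 0.106 is the solution of P(|2f−1|/max(f, 1−f) ≥ 0.2) = 0.6 for
f ~ N(0.5, σ). The higher-scoring daughter takes the smaller area with
probability 0.7, reflecting the predominance of higher *deltaA* in the
smaller daughter.

Several points of the stated world deserve explicit justification:

* **Area coupling.** The data constrain only monotonicity of division
  propensity in area, not a functional form. The hazard is therefore
  modulated by a logistic factor `2 · plogis(area_coupling · (A − A_ref))`
  whose slope defaults to **zero**: the neutral value keeps the configured
  hazards exact, so downstream rate-recovery checks are calibrated;
  power analyses switch the slope on explicitly.
* **Initial composition.** Roots are 80% *deltaA*⁻ (areas lognormal,
  mean 112 ± 15.4 µm²), 20% *deltaA*⁺ (54 ± 3.7 µm²), plus a fraction
  `frac_initial_np = 0.12` of small aNP-like positive cells
  (10 ± 3.6 µm²). The aNP pool and its per-day delamination hazard
  (`delam_rate = 0.15`) are invented parameters: they emulate the standing
  population of delamination-prone cells that produces ~12% of tracks
  ending in delamination; without them no track could shrink below the
  threshold within one movie.
* **Notch blockade.** Under LY the calibration constant is an *observed
  division rate* over a short window (0.0852 per cell per day), so in LY
  mode the elevated hazard drives cytokinesis directly and the marker
  onset is back-dated by an exponential `lambda_act` delay. Routing the
  hazard through activation first would halve the realized division rate
  over 4 days. Fate rules are untouched: blockade equalizes activation
  between statuses but not the asymmetric outcome of negative mothers.
* **Known tension in the source rates.** The per-track division
  frequencies (6.2% / 34.2% per movie) are not numerically consistent
  with γ = 0.0056 / 0.0246 per day under a simple exponential model. The
  generator exposes the γ parameterization and does not reconcile the
  two; consequently simulated cohorts divide more often than the in-vivo
  per-track frequencies, division chains are deeper, and the median
  delaminating area sits slightly below the in-vivo 8 µm² (chain
  daughters are born small). Tests account for this explicitly.

What the generator does **not** emulate: spatial arrangement and
neighborhoods, Notch signal propagation between neighbors, tracking
errors, score missingness, or photobleaching. A green test on simulator
output therefore establishes that the estimators recover the stated
world's parameters — not that the in-vivo data satisfy the model.

## Censoring conventions and the timing estimator

The marker onset is only bracketed by the grid: it lies between the last
marker-OFF day `t_off` and the first marker-ON day `t_on`. The division
day `d` is treated as exactly observed at the DC time point. Each
division with marker observations yields the interval
`[max(0, d − t_on), d − t_off]`; activated non-dividers are
right-censored at their last observation; mothers that divided before the
marker was ever imaged ON are excluded and counted.
`fit_exponential_ic()` maximizes
`Σ log(exp(−λ·lower) − exp(−λ·upper))` on (0, 10] per day to tolerance
1e−8 (degenerate intervals fall back to the density, so the closed-form
uncensored MLE `n/Σt` is a limiting case), and profiles the likelihood at
the χ²₁ cutoff 3.84 for the 95% CI — preferable to a Wald interval for a
boundary-constrained rate at moderate n. No shape parameter is offered:
the quantity of interest is a single transition rate.

Within `simulate_cohort()` the recorded onset day is the first imaging
day at or after the latent onset; extracted intervals provably contain
the latent duration measured to the DC day. Unbiased rate recovery is
checked on `simulate_durations()`, which censors raw exponential draws
onto the grid with exactly the conventions above.

## Statistical choices elsewhere

* **Growth curves** normalize each nondividing track to its first
  observed area; day bins snap to the union of observed relative days (no
  interpolation); the 95% CI is a seeded percentile bootstrap over tracks
  (1000 resamples by default — the CI method behind the published curves
  is unstated, and the percentile bootstrap of a median is the
  conventional choice); the growth rate is a log-linear fit of the median.
* **Division likelihoods** use the exact Poisson interval on the event
  count divided by exposure: divisions are rare events over cell-time,
  and the original CI method is unstated.
* **Mann–Whitney** comparisons use midranks, exact enumeration for
  tie-free groups up to n = 20 (deterministic small-sample p-values), and
  the tie-corrected normal approximation otherwise.
* **Logistic regression** is fitted by IRLS (`stats::glm`) with area in
  µm² untransformed, fish fixed effects as dummy intercept shifts, and
  convergence tolerance 1e−10; complete separation is detected from
  diverging linear predictors and flagged, never silently penalized.
  Type II Wald tests respect marginality by the classical route: a term
  is tested in the model from which every higher-order relative has been
  removed, using its coefficient block's Wald χ².
* **The fate multinomial** is a direct maximum-likelihood logit (BFGS
  with analytic gradient); with per-fish intercepts it is saturated, so
  fitted probabilities equal empirical per-fish proportions — an identity
  the tests assert to 1e−6.
* **Nondivider covariates** use the arithmetic mean area (the summary
  statistic is unstated in the source; the mean is the convention) and
  the most prevalent status, ties resolved by the last scored point.

## Worked example

```{r example, eval = FALSE}
params <- sim_params()
forest <- simulate_cohort(params, n_tracks = 828, seed = 1)
events <- detect_divisions(forest)
modes4 <- classify_division_mode(
  events[!events$mother_status & events$from_quiescence, ], forest, 4)
table(modes4$mode)
fit <- fit_exponential_ic(simulate_durations(500, seed = 5))
report <- run_pipeline(params, n_tracks = 400, seed = 1)
```

## Known limitations

The raw in-vivo track tables are not retrievable by accession, so the
package does not attempt to reproduce empirical medians or fitted
coefficients from real data; printed counts and rates serve as worked
examples, and simulation-based recovery establishes estimator
correctness. The on-disk CSV schema is this package's own invention.
Random-effects models are out of scope (the original analysis used fixed
effects), as are competing-risks duration models, spatial statistics, and
any image processing upstream of the track table.
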