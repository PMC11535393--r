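---
title: "Estimating in vivo Michaelis-Menten parameters from steady-state strain panels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating in vivo Michaelis-Menten parameters from steady-state strain panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

```{r setup}
library(invivokin)
```

## The measurement principle

Classical enzymology titrates the substrate in a cuvette. The in vivo
analogue titrates the substrate *inside* cells: a panel of otherwise
isogenic strains is engineered so that the enzyme producing the substrate of
the reaction of interest is expressed at different levels (different
promoters and gene copy numbers), while the enzyme under study is expressed
at one constant level. Each strain settles at a different intracellular
substrate concentration. During balanced exponential growth the cells are at
metabolic steady state, so for an end-product P that is neither degraded nor
re-consumed, synthesis is balanced solely by growth dilution:

$$ v = \mu \,[P] $$

with $\mu$ the specific growth rate (1/h). Measuring $[S]$, $[P]$ and $\mu$
per strain therefore yields one (substrate concentration, reaction rate)
point per strain and replicate, exactly the data shape of an in vitro
saturation experiment. Fitting the irreversible Michaelis–Menten law

$$ v = \frac{V_\max^{cell}\,[S]}{K_{1/2}^{cell} + [S]} $$

gives the in vivo analogues of $V_\max$ and $K_M$; dividing
$V_\max^{cell}$ by the absolute enzyme concentration gives
$k_{cat}^{cell}$. The carotenoid pathway in budding yeast — a GGPP synthase
feeding a phytoene synthase, itself feeding phytoene desaturases — is the
motivating system, and the package's defaults and presets are shaped on it,
but nothing in the code is specific to carotenoids.

## The design model

Before strains are built it pays to ask which expression level of the
studied enzyme will produce an informative saturation curve.
`pathway_model()` implements the minimal pathway for that question:

* constant substrate influx `v_in` (µM/h) — the substrate-producing enzyme;
* Michaelis–Menten conversion with parameters `vmax`, `k_half`;
* first-order growth dilution of the product, rate `mu`.

Without substrate dilution the steady state is closed-form,
$S^* = K_{1/2} v_{in} / (V_\max - v_{in})$, the conversion flux equals the
influx, and $P^* = v_{in}/\mu$. If `v_in >= vmax` the substrate has no
steady state; `steady_state()` reports this as an infeasible state (with the
flux pinned at the `vmax` asymptote) rather than an error, so that
`design_scan()` can tabulate entire design grids including their infeasible
region. An optional `dilute_intermediate = TRUE` mode also drains the
substrate pool by growth — real cells dilute every pool — in which case the
steady state solves a quadratic balance and every influx is feasible. The
default keeps the substrate undiluted, matching the three-reaction model
used for design simulations (influx, conversion, product dilution).

```{r design}
scan <- design_scan(pathway_model(0.1, 1, 1, 0.4),
                    vmax_levels = c(0.02, 0.4, 0.7),
                    v_in_grid = seq(0.01, 0.4, by = 0.01))
head(scan, 3)
```

The classic design lesson this scan reproduces: an enzyme level far above
the influx range never saturates (substrate stays low), and an enzyme level
below it makes the pathway infeasible (substrate accumulates without bound);
informative panels sit in between.

Time courses (`simulate_timecourse()`) are integrated with `deSolve::lsoda`
at relative tolerance 1e-8 and absolute tolerance 1e-10; a state is accepted
as stationary in the test oracles only when the residual time derivative,
scaled by the local relaxation rate, implies a relative deviation below
1e-8.

## From omics measurements to concentrations and rates

Metabolomics and proteomics report biomass-specific amounts; kinetics needs
intracellular molarities. `conversion_constants()` holds the three factors
involved, with yeast defaults:

| constant | default | units |
|---|---|---|
| `cells_per_gdcw` | 6.59e10 | cells per g dry cell weight |
| `cell_volume_fl` | 66 | fL per cell |
| `protein_fraction` | 0.63 | g protein per gDCW |

so 1 µmol/gDCW corresponds to `r round(amount_to_concentration(1), 1)` µM
and 1 fmol/µg protein to `r round(protein_to_concentration(1), 1)` nM. Both
maps are linear and exactly invertible. The cell volume is treated as a
constant, not growth-rate dependent: the panels this package targets are
grown at a single dilution-rate setpoint, and a single literature volume is
the appropriate level of detail.

`build_dataset()` assembles the (substrate, rate) pairs: units are
converted to µM, the rate is the product dilution flux
$\mu\,[P]$ per record, and replicates are kept as independent points —
averaging before fitting would hide the replicate scatter that the
uncertainty analysis needs. Records below the limit of quantification are
dropped by default (`loq_policy = "drop"`); an LOQ/2 substitution mode
exists for sensitivity analyses but is not the default, because a
low-expression series whose product cannot be quantified carries no usable
rate information.

## Fitting

`mm_fit()` minimises the unweighted sum of squared rate residuals.
Numerically it exploits the model's structure instead of a generic
optimiser: for fixed $K_{1/2}$ the optimal $V_\max$ is a linear
least-squares solution, so the problem is a 1-D minimisation of the profile
objective over $\log K_{1/2}$. That profile is evaluated on a 41-point
log-spaced grid spanning `[min(S)/1e4, max(S)*1e4]` and the bracketed
minimum is refined with `optimize()` (tolerance 1e-10 on the log scale).
This variable-projection scheme was chosen over multistart initialisation
because it cannot converge to a wrong local optimum inside the bracket, it
keeps both parameters positive by construction, and it is fast enough to
refit thousands of bootstrap datasets (well under a millisecond per fit),
which the Monte-Carlo stage needs. `residual_sd` follows the regression
convention $\sqrt{SSR/(n-2)}$ (two fitted parameters).

Unweighted least squares is a deliberate (and conventional) choice: the
uncertainty procedure below models the noise as homoscedastic on the rate
axis, and weighting would have to be invented since per-point measurement
variances are not part of the data contract.

## Monte-Carlo uncertainty and identifiability

`mm_monte_carlo()` implements a parametric bootstrap: 1000 datasets (the
default) are simulated by adding independent Gaussian noise with standard
deviation equal to the residual SD to the fitted rates; each is refitted
starting from the point estimate (narrow bracket around $\hat K_{1/2}$,
falling back to the full bracket if it binds); the refitted parameter
distributions are summarised by mean, SD, relative SD and percentile
2.5/97.5 interval. The percentile interval was chosen because it needs no
distributional assumption and is the least surprising default. Refit
failures are counted, reported and excluded. A noiseless fit has no
resampling scale; rather than silently doing nothing the function raises a
degenerate-noise error and asks for an explicit noise floor.

`mm_identifiability()` declares a parameter non-identifiable when any of
three signals fires: Monte-Carlo relative SD above 0.5, the Monte-Carlo
distribution piling onto a search bound (more than 5% of refits within 5%
of a bound on the log scale), or a near-singular normal matrix (condition
number above 1e8). The thresholds are package conventions; they are
deliberately permissive because the decision they feed is qualitative
("report an estimate" vs "report a limit"). For a non-identifiable
parameter the 2.5th Monte-Carlo percentile is reported as a finite lower
limit: even data that cannot pin $K_{1/2}$ from above exclude small values
of it.

Two calibration facts, both computed by the package's own test suite and
acceptance script, bound what this machinery can promise:

* Under its own noise model — homoscedastic Gaussian rate noise — the 95%
  percentile interval is well calibrated: across 200 simulated panels at
  the phytoene-synthase design point (rate noise SD 40 µM/h), coverage is
  ~94–96% per parameter.
* Under the synthetic generator's more realistic noise (multiplicative,
  on substrate *and* product), coverage drops to roughly 70–80%: the
  homoscedastic rate-only bootstrap understates noise on the
  high-rate strains and ignores substrate error entirely. The same
  mismatch pushes the median |relative error| of $\hat V_\max$ across such
  panels to ~11–13%. Users who believe their concentration errors are
  multiplicative should read the Monte-Carlo intervals as optimistic.

A further limitation, visible in simulation: identifiability triage is
conditional on the point estimate. Deep in the linear regime (~8% of noise
realisations in our simulations), the fit can collapse to a small
$\hat K_{1/2}$ whose local bootstrap looks tight, and a single panel is
then mis-triaged as identifiable. Preset-level verdicts in the tests and
acceptance script therefore take a majority vote over five replicate
panels; real studies should do the analogous thing across biological
repeats before trusting an "identifiable" verdict near the linear regime.

## The synthetic panel generator

`generate_strain_panel()` exists so every downstream stage is testable
without any external data. Its defaults are the study conditions the
package is designed around:

* 8 strains × 3 biological replicates;
* growth rate drawn per strain × replicate from Normal(0.40, 0.03) 1/h,
  truncated at zero — the observed between-strain spread of a healthy
  panel;
* enzyme concentration 42 nM;
* multiplicative lognormal measurement noise with CV 0.10 on substrate,
  product and enzyme concentrations, mean-corrected so the expectation
  equals the noiseless steady state. Multiplicative noise was chosen over
  additive because the concentrations span up to three orders of magnitude
  and must stay positive; 0.10 is a typical relative error for targeted
  LC–MS/HPLC quantification with internal standards;
* limits of quantification 0.05 µM (substrate) and 0.1 µM (product),
  matching the low ends of the calibration ranges such assays achieve;
  flags are set exactly when the noisy value falls below the limit;
* copy-number designs map linearly to influx (`v_in = copies ×
  per-copy strength`), the simplest mechanism consistent with
  promoter/copy-number titration.

The generating truth travels as a separate attribute (and a separate
`.truth.json` sidecar on disk), so fitting code cannot read it by accident.

`panel_preset()` bundles four regimes: `crtB_medium` (partial saturation,
truth 849 µM/h and 19 µM, substrate designed to span 0.12–20.78 µM, a
167-fold range), `crtI_fungal` (saturating, truth 168 µM/h and 380 µM over
4–1641 µM), `crtI_bacterial` (linear regime: truth shaped on the reported
lower limits 13 µM/h and 560 µM, with the substrate grid truncated at
$K_{1/2}/10$, i.e. 4–56 µM, so that only lower limits are recoverable —
with wider spans the verdict flips between noise realisations, which would
defeat the preset's purpose), and `ggpp_panel` (a producer-titration panel
spanning a 38-fold substrate range). Strain influxes are placed log-evenly
across each span, the standard choice for saturation designs.

What the generator does *not* emulate — and therefore what passing tests do
not show about real data: compartmentalisation and local substrate
depletion, substrate/product toxicity feeding back on growth, overflow and
competing pathways, between-batch replicate structure (a single CV is
used), and growth-rate-dependent cell volume. These are exactly the effects
the in vivo approach is meant to expose, so recovery on synthetic panels is
a necessary, not sufficient, validation.

## Reporting

`run_pipeline()` chains reading, conversion, fitting, uncertainty,
identifiability and (when enzyme concentrations are present) the turnover
number, and returns a self-describing report: constants, configuration and
seed are all recorded, floats are serialised at 6 significant digits with a
fixed key order, and identical inputs yield byte-identical JSON. The
default seed (42) is always written out. Problem sizes used by the shipped
checks — 8×3 panels, 100 panels for recovery medians, 200 panels for
coverage, 400–1000 bootstrap refits — were chosen as the smallest sizes at
which the summarised quantities are stable to well within their assertion
margins.

```{r pipeline, eval = FALSE}
f <- tempfile(fileext = ".csv")
write_panel(generate_strain_panel(panel_preset("crtB_medium"), seed = 7), f)
report <- run_pipeline(f)
report
```
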