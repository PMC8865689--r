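---
title: "Quantifying phage decay and damage under environmental stress"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying phage decay and damage under environmental stress}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phagestress)
library(dplyr)
```

## The measurement problem

Therapeutic bacteriophage preparations are suspensions of virus particles
whose infectivity degrades under environmental stress — elevated
temperature, high urea, osmotic extremes. Two distinct phenomena matter
clinically and are measured by two distinct assays:

* **Decay**: loss of plaque-forming ability. Quantified by exposing a
  phage stock to a stressor for a set duration, then titering by plaque
  assay and expressing the titer as percent survival relative to a
  reference treatment.
* **Damage**: surviving (still plaque-forming) particles that infect less
  effectively. Quantified by inoculating a fixed dose of surviving
  particles onto host bacteria and following the bacterial optical
  density: the *first local maximum* of the (smoothed) OD600 trajectory is
  a reverse proxy for phage fitness — the better the phage grow, the
  sooner and lower the bacterial population peaks before lysis collapses
  it.

`phagestress` implements both analysis chains as tidy, composable steps,
plus a generative simulator of the entire measurement process so each
step is testable against known ground truth.

## Titering and censoring

A plaque assay observes counts through serial tenfold dilutions: a plate
that received volume $v$ of a $10^{-d}$ dilution of a sample with titer
$N$ (PFU/mL) shows a count that is Poisson with mean $N v \cdot 10^{-d}$.
Each plate with a count in the *countable range* (default 3–300, the
standard plaque-count convention; configurable) contributes the estimate
$\text{count}/(v\,10^{-d})$, and the sample titer is the arithmetic mean
of those per-plate estimates. If no plate is countable but plaques were
seen, the most-dilute plate with a nonzero count is used and flagged; if
every plate is empty, the sample is **censored at its limit of
detection**,

$$\mathrm{LOD} = \frac{f_\text{pre}}{v \cdot 10^{-d_\text{min}}},$$

the titer implied by a single plaque on the least-dilute plate, scaled by
any protocol dilution $f_\text{pre}$ applied before plating (the solute
assays terminate the stress by an immediate 200-fold dilution, so their
LOD is 200-fold higher). The LOD is per sample, because dilution series
differ between samples.

Percent survival is $100 \cdot N / N_\text{ref}$, computed from the mean
titers (a per-plate mode is available via `survival_table(per_plate =
TRUE)`). The reference is configurable per stressor via
`survival_config()`; the defaults are the mildest heat treatment (55 °C
after 5 minutes) for the heat gradient, the unexposed source stock for a
single-temperature time course, and the medium control at 0 minutes for
the solute assays (LB is itself 0.17 M saline, so the saline control
level is 0.17). References are matched within phage stock, so biological
replicates are each normalized against their own baseline. Censored
observations keep their LOD-implied percent for plotting but carry a
`censored` flag and are **excluded from every model fit**; this exclusion
is asserted by tests at the pipeline level.

## The decay model

Within each stressor, survival is modeled on the log scale as straight-line
decay per stratum (temperature, concentration, or stock):

$$\log_{10}(\text{percent survival})_{ij}
  = \alpha_j + \beta_j\, t_{ij} + \varepsilon_{ij},$$

ordinary least squares with one intercept and one slope per stratum $j$
and no pooled duration main effect — the slope $\beta_j$ (log10 percent
per minute) *is* the stratum's decay rate, and the residual degrees of
freedom are $n - 2k$ for $k$ strata. Each slope is tested one-tailed
against zero in the direction of increased decay
($H_1: \beta_j < 0$), with a Bonferroni correction over the family of
estimable strata. Strata whose observations are entirely censored (or
retain fewer than two distinct durations) carry no slope and are reported
as `NA` rows rather than errors, preserving the familiar per-condition
table shape.

The accompanying ANCOVA is **sequential (Type I)** in a fixed term order:
stratifying factor first, then (optionally) the pooled duration main
effect, then the factor-by-duration interaction. This is stated
prominently because Type II sums of squares would change the F values;
term order is part of the analysis definition. Two parametrizations are
exposed because both appear in practice for this kind of data: the
gradient analysis uses the interaction-only model (interaction df $= k$),
while the time-course and solute analyses include the pooled duration
main effect (interaction df $= k-1$); `decay_analysis(include_main_effect
= )` and the `decay_main_effect` entry of `run_config()` switch between
them, and slope estimates are identical under either (a property the
suite checks).

The model is a Gaussian linear model on log10 percent; "GLM" language for
this analysis in the literature refers to exactly this fit (identity
link), and the reported t/F statistics follow from it.

## The fitness proxy

Growth curves are smoothed by a **moving median** (default window 5
points = 25 minutes at 5-minute reads; a moving average is available) with
symmetric window shrinkage at the edges, then scanned for the earliest
point that is at least as high as both neighbours and after which the
series drops by at least a **prominence** threshold. Ties on plateaus go
to the earliest index; if no interior maximum qualifies, the global
maximum is returned flagged `boundary_flag` (a still-rising culture). The
default prominence is data-driven: 3× the median absolute successive
difference of the series up to its global maximum — a noise floor that
scales with the plate reader rather than a fixed OD constant. Both the
smoothing settings and the prominence are recorded in the peak table.

Dosing is normalized before the assay: each well receives a target PFU
dose (default 200) at a constant multiplicity of infection (default
$10^{-5}$, hence $2\times 10^7$ bacterial cells per well);
`dose_wells()` plans the intermediate dilution needed to keep pipetted
volumes practical and flags wells whose stock cannot supply the target
dose. Flagged (under-dosed) wells are reported but **excluded from the
treatment ANOVA**.

Peak OD is compared by a sequential ANOVA with terms treatment, stock,
and treatment:stock, followed by Tukey HSD over treatment levels using
the model's residual mean square (Tukey–Kramer standard errors for
unbalanced groups). The pairwise results are summarized as a compact
letter display built by insert-and-absorb: start from one all-inclusive
group, split it for each significant pair, drop groups contained in
another. Letter displays are not unique; this construction guarantees
that two treatments share a letter exactly when their adjusted p is at or
above α (a property the suite asserts). The two phage-free control
groups (plain medium vs heat-shocked medium) are compared with a Welch
unequal-variance t-test with Welch–Satterthwaite degrees of freedom —
chosen over the pooled test because control variances need not be equal.

For $k = 2$ groups the studentized range reduces exactly to
$\sqrt{2}\,|T|$; `tukey_hsd()` uses that closed form there because the
general quadrature behind R's `ptukey` carries only ~6 significant
digits at small df, and the suite verifies the general path against
direct numerical double integration of the range distribution.

## What the simulator emulates — and what it does not

`simulate_decay_assay()` generates the decay side of the measurement
process: per-condition true titers
$N(t) = N_0\,m_s\,(f\,10^{k_1 t} + (1-f)\,10^{k_2 t})$ with a lognormal
per-stock offset $m_s$ (log10-scale sd `stock_sd`, default 0.1 — stocks
are observed to differ without a published model, so this is the
simulator's own choice), observed through Poisson plaque counts on a
serial dilution series. $f = 1$ gives mono-exponential decay; $f < 1$
gives biphasic decay, which the package deliberately does *not* fit —
the analysis model stays log-linear, and the suite demonstrates the
resulting lack of fit on strongly biphasic input instead. Default decay
rates follow the per-temperature estimates of the heat-stress literature
for this phage (≈0 at 55–60 °C, −0.0028 at 65 °C, −0.0182 log10/min at
70 °C), with an optional very-fast stratum whose measurements all fall
below detection, exercising the censoring path.

`simulate_growth_curves()` integrates a stage-structured predation model
per well:

$$\begin{aligned}
\dot B &= r B\,(1 - (B + \textstyle\sum_j I_j)/K) - a B P,\\
\dot I_1 &= a B P - (n/\lambda) I_1,\qquad
\dot I_j = (n/\lambda)(I_{j-1} - I_j),\\
\dot P &= \beta\,(n/\lambda) I_n - a B P,
\end{aligned}$$

with logistic host growth ($r = \ln 2/30$ per minute, a 30-minute
doubling; $K = 10^9$ cells/mL), mass-action adsorption
($a = 10^{-9}$ mL cell⁻¹ min⁻¹), an Erlang latent period ($n = 5$ stages,
mean $\lambda = 40$ min — smooth ODE dynamics without delay-equation
machinery), and burst size $\beta = 100$. OD600 is read every 5 minutes
for 12 hours as `od_blank + od_per_cell * (B + ΣI)` plus additive
Gaussian noise (sd 0.005 OD, plate-reader-like). Heat damage is modeled
as a `damage_factor` ≤ 1 multiplying the adsorption rate (or,
configurably, the burst size) of shocked phage — the
particle-conformational-damage reading: per-particle fitness falls while
the *inoculated PFU is unchanged*. The simulator makes no attempt to
discriminate that mechanism from receptor-interference or
population-heterogeneity explanations.

The system is numerically stiff once the phage population amplifies
(adsorption × phage density can exceed 10² min⁻¹), so integration uses
`deSolve`'s adaptive stiff solver (`lsoda`, maximum internal step a
quarter of the read interval) rather than a fixed-step scheme, which
diverges here at any practical step size.

Features of real data the simulator does **not** emulate: pipetting and
dilution-series volume errors (counting noise is purely Poisson), plaque
overlap and counting fatigue on dense plates, evolution of bacterial
resistance during the overnight assay (late regrowth), spatial effects in
wells, and condensation or drift artifacts in plate readers. Passing
tests on simulated data therefore validate the *statistical machinery and
its bookkeeping* (censoring, exclusion, normalization, model structure),
not the biological fidelity of any particular parameter value.

## Numerical and design choices

* Tolerances: OLS is solved by QR; rank deficiency is an error naming the
  aliased columns, never a silent drop. A fit is treated as "perfect"
  (slope tests refused) when the residual SS is below
  $10^{-10}(1 + \sum \hat y^2)$.
* Countable range [3, 300] plaques; titers average per-plate estimates
  rather than pooling counts (the simplest reading of triplicate
  titering; pooling is a config away via per-plate mode).
* Time is minutes, volume mL, concentration mol/L, temperature °C,
  everywhere; CSV (UTF-8, "." decimal) is the only raw format.
* The reference treatment for heat-gradient survival defaults to the
  55 °C/5-minute sample (the protocol's definition); a 0-minute variant
  is one config entry away, since figure captions and protocol text for
  such assays sometimes disagree on this point.
* Plaque counts above the 32-bit integer range (dense lawns on
  barely-diluted plates of a 10¹⁰ PFU/mL lysate) are kept as
  integer-valued doubles; simulated counts with mean above 10⁷ use a
  normal approximation to Poisson, indistinguishable at those counts.
* Simulations are seeded explicitly (`seed` in every sim config); the
  analysis pipeline itself draws no random numbers, so a rerun of
  `run_pipeline()` on the same inputs is byte-identical (asserted in the
  suite).

## Problem sizes used by the test suite

The packaged checks run the full measurement chain at the study's own
design sizes: the heat gradient at 4 temperatures × 4 durations ×
triplicate plating (16 samples, residual df 8), solute designs at 5
concentrations × 3 timepoints × 3 stocks with the 200-fold termination
dilution, and one growth plate of 60 wells × 145 timepoints. Parameter
recovery is evaluated over 100 seeded replicates of the gradient design;
the peak-finder is checked against an exhaustive scan on 1000 random
series; sequential-ANOVA and Tukey identities on 100 random datasets
each.

## Worked example

```{r example}
dir <- tempfile()
files <- make_fixture_bundle(dir, seed = 1)

counts <- dplyr::bind_rows(
  read_plaque_counts(files[["heat_plaque_counts"]]),
  read_plaque_counts(files[["solute_plaque_counts"]])
)
surv <- counts |> titer_table() |> survival_table()
heat <- decay_analysis(surv[surv$stressor == "heat", ])
heat$slopes
heat$ancova

plate <- read_plate_timeseries(files[["growth_measurements"]],
                               files[["growth_layout"]], "long")
fit <- plate |> extract_peaks() |> fitness_comparison()
fit
```

```{r plots, fig.width = 6, fig.height = 4}
autoplot(heat$fit)
autoplot(fit)
```

## Limitations

* The decay model is strictly log-linear; biphasic decay is generated by
  the simulator for robustness checks but never fitted (resolution for a
  second phase is generally poor in designs like this one).
* Stocks are treated as fixed strata, not random effects; no
  mixed-model machinery is provided.
* Only Bonferroni and Tukey adjustments are offered, matching the
  analyses this package reproduces.
* Reproduction of the original archived dataset requires downloading
  that archive; `reproduce_study()` maps its cleaned tables onto the
  pipeline via `reproduce_mapping()` and reports agreement with the
  printed statistics at printed precision.
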