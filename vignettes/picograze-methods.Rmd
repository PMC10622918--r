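---
title: "Methods: dilution-based growth and grazing analysis across a productivity gradient"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dilution-based growth and grazing analysis across a productivity gradient}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(picograze)
```

## The measurement model

The two-treatment dilution experiment estimates how fast a microbial
population grows and how fast protistan grazers remove it, from just two
bottles per depth. Diluting whole seawater to a fraction $D$ with
0.1-µm-filtered water from the same depth reduces predator–prey encounter
rates in proportion to $D$ while (ideally) leaving per-capita growth
unchanged. Writing $k = \ln(N_f/N_0)/t$ for the apparent net rate in the
undiluted bottle and $k_d$ for the diluted bottle, the model

$$\frac{1}{N}\frac{dN}{dt} = \mu - mD$$

gives the estimator implemented in `estimate_rates()`:

$$m = \frac{k_d - k}{1 - D}, \qquad \mu = k + m,$$

with net growth $r = \mu - m = k$ exactly. The estimator is the algebraic
inverse of the forward model, so the package's simulator and estimator
are mutual oracles: a noise-free simulated pair must round-trip to
machine precision, and the test suite enforces this over thousands of
random $(\mu, m, D, N_0)$ draws.

Assumptions worth keeping in mind:

* **Linearity of grazing in $D$.** The diluted bottle's net rate is
  $\mu - mD$. Saturating grazing responses violate this and bias $m$
  downward; the package deliberately implements the standard two-point
  estimator and leaves multi-point dilution series out of scope.
* **Growth unchanged by dilution.** No nutrients are added (additions
  can suppress grazers in oligotrophic water), and filtration artefacts
  (organic release) are not modelled.
* **What "mortality" means.** The method resolves grazing only; viral
  lysis is invisible to it. All mortality statements are grazing
  statements.
* **Negative estimates are data.** Sampling noise can push $m$ or $\mu$
  below zero; estimates are never clipped at the estimation stage.
  Log-scale regressions apply `floor_for_log()` (default floor
  0.01 d⁻¹) to nonpositive values, and only there.

The dilution factor is taken from the recorded `d_measured` when
present; otherwise from the initial counts as
`n0_diluted / n0_undiluted`, i.e. the dilution factor as measured from
initial flow-cytometry subsamples. A pair with $D \ge 1$ cannot resolve
grazing and is an error; a pair with nonpositive counts marks an absent
population and propagates as `defined = FALSE` rather than an error, so
structurally absent populations (PRO in cold water) flow through the
pipeline as "nd" records.

## Station aggregation

Depth-level estimates within the upper euphotic zone are treated as
independent assessments of one station-level rate, summarised as
arithmetic mean ± SEM ($s/\sqrt{n}$). The field design samples 6–8
depths and uses the upper half where rates are not light-limited; the
exact per-station rule is not published, so `aggregate_stations()`
exposes `depth_rule`: `"upper-half"` (default; the shallowest
$\lceil n/2 \rceil$ sampled depths) or `"all"` for inputs that already
contain only upper-euphotic incubations. A station contributing a single
depth reports SEM = 0 with a logged count — a deliberate convention that
keeps station tables rectangular while letting users filter such rows.

## Gradient regressions

Neither primary production nor a rate is a controlled variable, so
trends are fitted with Model II methods in `model2_fit()`: standardized
major axis (SMA, the default; slope $\mathrm{sign}(r)\,s_y/s_x$), major
axis (MA; leading eigenvector of the covariance matrix), and OLS for
reference. The published analysis names only the lmodel2 family without
singling out an estimator, so the method is an explicit argument
everywhere. The MA slope uses the cancellation-free branch of the
quadratic formula ($2s_{xy}/(s_{xx}-s_{yy}+\Delta)$ when
$s_{xx}>s_{yy}$), which matters for near-zero slopes.

Significance is a two-sided permutation test on $|r|$ (default 999
permutations, seedable): $p = (1 + \#\{|r^*| \ge |r|\})/(B+1)$. Whether
the published p-values were one- or two-tailed is not stated; two-tailed
is the conservative choice and is flagged here. The test suite checks
calibration: over 1,000 null datasets the 5% rejection rate must fall in
its binomial 95% interval (with $B=199$ the null $p$ is exactly uniform
on $\{1,\dots,B+1\}/(B+1)$, so the nominal level is exact).

Trends are fitted over overlapping production segments —
PP < 100 and PP > 10 mg C m⁻³ d⁻¹ by default, plus the extreme windows
and the full range — because picophytoplankton abundance peaks at
intermediate production and a single global line would average away the
rise-then-fall structure. Stations (upper-euphotic means), not depths,
are the regression unit. Rates and ratios are regressed log10–log10
following the field's plotting conventions; transforms are recorded in
every fit row.

## The synthetic cruise generator

`simulate_cruise()` emulates the statistical structure of a Lagrangian
survey across an upwelling productivity gradient, so that every
downstream stage is testable offline:

* **Environment.** Station log10 PP is uniform on `pp_log10_range`
  (default [0.26, 2.56], i.e. ~1.8–367 mg C m⁻³ d⁻¹) and shared by that
  station's depths up to a small log10 jitter (sd 0.03). Temperature
  declines along the gradient (upwelled water is cold) and crosses 14 °C
  near PP ≈ 80; nitrate rises with PP (hence falls with temperature);
  chlorophyll a follows a positive power law of PP with lognormal
  scatter. All values are clamped to the envelope observed across the
  field campaigns (temperature 11–19.5 °C, nitrate 0–14 µM, Chl a
  0.05–14 mg m⁻³, PP 1.8–367 mg C m⁻³ d⁻¹).
* **True rates.** Per population, abundance, µ and m are interpolated
  linearly in log10 PP through the published class means
  (`cce_picoplankton_rates()`), anchored at the class centers
  log10 PP = 0.5, 1.5, 2.5 and clamped beyond the end classes
  (abundance on the log10 scale, rates linear). The published table
  reports classes, not a functional form; piecewise interpolation is the
  weakest assumption that reproduces the class structure. PRO is made
  structurally absent (abundance 0, rates undefined) wherever simulated
  temperature < 14 °C — reproducing its observed cold-water cutoff
  without modelling physiology — and the generator couples that cutoff
  to high production, as observed.
* **Observations.** The realized dilution factor is drawn near
  `dilution_target` (default 0.33, sd 0.02, truncated to (0,1)); bottle
  dynamics are exponential at $\mu - m$ (undiluted) and $\mu - mD$
  (diluted) over `incubation_days` (default 1); all four counts then
  receive independent multiplicative lognormal noise with unit mean and
  CV `count_cv`. Within-bottle flow-cytometric replicate error is not
  published, so the 5% default is an instrument-level stand-in surfaced
  in the configuration. With `count_cv = 0` and `d_jitter_sd = 0` the
  generator is deterministic and exactly invertible.

Everything is driven by one integer seed; equal configurations give
bit-identical cruises, and the generators restore the caller's RNG
state.

What the generator does **not** emulate — and therefore what passing
tests do not show about field data: biological scatter of true rates
between stations at the same PP (the simulated rates sit exactly on the
interpolated trend, so simulated SEMs reflect counting noise and
within-class trend spread only, and are smaller than field SEMs);
bottle/container effects; nutrient dynamics inside bottles; saturating
grazing responses; advection between stations. Tests against the
generator validate the *statistical machinery*, not the field
conclusions.

## Shared-predation projections

`project_shared_predation()` computes the counterfactual at the center
of the gradient analysis: if grazers consumed a picophytoplankton
population in rich water in the same proportion to HBAC as in poor
water, its mortality would be
$m_\text{scaled} = R_\text{low} \cdot m_\text{HBAC,high}$, its net
decline rate $m_\text{scaled} - \mu$, its daily loss
$100(1 - e^{-r})$ %, and its time to nominal local extinction
$\ln(N_0/N_\text{thr})/r$ days. Conventions:

* Mortality ratios are averaged per experiment (mean of ratios), not
  formed from class-mean rates — the two differ by Jensen's inequality,
  and the published ratio means follow the former. Both routes exist:
  `shared_predation_inputs()` from station tables,
  `cce_projection_inputs()` from the published summaries.
* The extinction clock defaults to $N_0 = 10^4$ cells mL⁻¹ (the order
  of magnitude of high-production SYN/PEUK standing stocks) and a 1 cell
  mL⁻¹ threshold; both are arguments, since the exact class-mean
  abundances (13×10³, 22×10³) give slightly longer times.
* The percent decline uses the continuous-rate convention
  $100(1-e^{-r})$. Note one published figure (a 69% d⁻¹ PEUK decline)
  is not consistent with this convention applied to its own inputs
  ($1-e^{-1.01} = 0.636$); the package reports the computed value.

## Reporting conventions

`bin_stations()` assigns each station to exactly one production class by
its mean PP with edges at 10 and 100 mg C m⁻³ d⁻¹; the middle class is
closed ($[10, 100]$) so the three labels partition the axis — boundary
values are measure-zero in practice and the convention is documented
rather than consequential. Rate summaries average stations where the
population was present; abundance summaries include structural zeros, so
an always-absent population reports abundance 0 ± 0 with "nd" rates.

## Validation design and problem sizes

The test suite runs entirely on generated data at sizes chosen to make
each property sharp: 1,000 random experiments for the exact round trip;
a 200-station cruise at 5% counting CV for recovery under noise; 100
random datasets for the slope oracles (closed forms and an independent
eigen decomposition); 1,000 null datasets for permutation calibration; a
200-station cruise for the qualitative sign structure (HBAC mortality
rising, SYN mortality falling above 10 mg C m⁻³ d⁻¹, SYN:HBAC ratio
falling, all at permutation $p \le 0.05$).

One statistical subtlety in the recovery test deserves a note. Because
simulated true rates vary across each production class, the class mean
of truth is compared with the class mean of estimates (a paired
comparison in which the interpolation trend cancels), and the check
spans ~24 class × population × rate cells. A per-cell 2-SEM band is a
95% interval, so demanding *every* cell pass it would fail ~65% of
correct runs by multiplicity alone. The test therefore applies the
Bonferroni-corrected band that gives the whole family the same 95%
confidence a single cell would have, plus an absolute requirement that
well-populated cells recover their true means within 0.02 d⁻¹ — the
printed precision of the published rate table.

## Known limitations

* Two-point dilution cannot detect nonlinear grazing responses, and no
  correction is attempted.
* SEM propagation for ratios of means is not attempted; per-station
  ratio uncertainty comes from the depth spread.
* Model II confidence intervals are out of scope (permutation p-values
  only).
* The generator's rate trends are deterministic given PP; between-station
  biological variance is not represented, so simulated uncertainties
  understate field uncertainties.
* Field regression coefficients from the original cruises are not
  reproducible from synthetic data; only the qualitative sign structure
  is.
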