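# picograze

Growth and grazing mortality of marine picoplankton across ocean
productivity gradients.

`picograze` is an R implementation of the analysis chain behind
two-treatment dilution experiments on the ocean's smallest microbes —
heterotrophic bacteria (HBAC), *Prochlorococcus* (PRO), *Synechococcus*
(SYN), and photosynthetic picoeukaryotes (PEUK). It is aimed at microbial
ecologists who want to (i) estimate instantaneous growth and
microzooplankton grazing rates from paired diluted/undiluted bottle
incubations, (ii) analyse how those rates and their ratios change along a
primary-production (PP) gradient, and (iii) quantify what *shared
predation* — a common grazer pool coupling the mortality of co-occurring
prey — would imply for picophytoplankton persistence in rich waters. A
seeded synthetic-cruise generator reproduces the statistical structure of
a Lagrangian upwelling-gradient survey, so the whole pipeline is testable
without any field data.

## The estimator

Each experiment incubates two bottles from the same depth for ~24 h: one
with unfiltered seawater (100%) and one diluted to a fraction *D* (~33%)
of whole seawater with 0.1-µm-filtered water, which thins out the
protistan grazers in proportion. With apparent (net) exponential rates
*k* = ln(N_f/N_0)/t in the undiluted bottle and *k_d* in the diluted
bottle, grazing mortality and instantaneous growth follow from the
standard dilution-method assumption that grazing pressure scales linearly
with *D*:

```
m = (k_d − k) / (1 − D)        µ = k + m        net growth r = µ − m = k
```

(all rates in d⁻¹). Station-level rates are means ± SEM over the
upper-euphotic depths; trends along the gradient are fitted with Model II
regression (major axis, standardized major axis, or OLS) over overlapping
PP segments (PP < 100 and PP > 10 mg C m⁻³ d⁻¹), with two-sided
permutation p-values and a 0.01 d⁻¹ floor on nonpositive rates before
log-scale fits.

The shared-predation projection combines the mean mortality ratio of a
population to HBAC in poor waters (R = m_pop/m_HBAC at PP < 10) with
HBAC's measured mortality in rich waters: the scaled mortality R·m_HBAC
implies a net decline rate (against the population's own growth µ), a
daily percent decline 100(1 − e⁻ʳ), and a time to nominal local
extinction ln(N₀/1 cell mL⁻¹)/r.

## Worked example

```r
library(picograze)

cruise   <- simulate_cruise(sim_config(n_stations = 60, seed = 1))
rates    <- estimate_rates(cruise$bottles)
stations <- aggregate_stations(rates, cruise$environment)
bin_stations(stations)
#>    pp_bin    population n_stations mu_mean  mu_sem m_mean   m_sem net_mean
#>  1 PP<10     HBAC               16   0.262  0.0201  0.228  0.0319  0.0336
#>  2 PP<10     PRO                16   0.501  0.0195  0.405  0.0303  0.0957
#>  3 PP<10     SYN                16   0.475  0.0231  0.550  0.0375 -0.0752
#>  4 PP<10     PEUK               16   0.433  0.0169  0.438  0.0258 -0.00577
#>  5 10<PP<100 HBAC               30   0.449  0.0228  0.372  0.0250  0.0775
#>  ...
#>  9 PP>100    HBAC               14   0.682  0.0317  0.520  0.0320  0.161
#> 10 PP>100    PRO                14  NA     NA      NA     NA      NA
#> 11 PP>100    SYN                14   0.384  0.0236  0.212  0.0321  0.172
#> 12 PP>100    PEUK               14   0.442  0.0258  0.313  0.0340  0.129
```

Reading the table: HBAC growth and grazing rise steeply with production
(µ 0.26 → 0.68 d⁻¹, m 0.23 → 0.52 d⁻¹ from the poorest to the richest
class), SYN grazing falls (0.55 → 0.21 d⁻¹), and PRO is absent ("nd")
from the cold, high-production class — the three signatures the gradient
analysis is built to detect. Fits and their permutation significance come
from `segment_regressions(stations, "m_mean", population = "HBAC")`.

The shared-predation counterfactual, computed from the published CCE
summary tables bundled with the package:

```r
project_shared_predation(cce_projection_inputs())
#>   population ratio_low m_ref_high m_scaled net_rate daily_decline_pct
#> 1 SYN              3.9       0.61     2.38     2.00              86.5
#> 2 PEUK             2.4       0.61     1.46     1.01              63.7
```

If grazers consumed SYN in rich waters in the same proportion to HBAC as
they do in poor waters, SYN mortality would be 2.38 d⁻¹ — a net
2.0 d⁻¹ above its measured growth, an 86% daily population decline, and
local extinction (< 1 cell mL⁻¹ from 10⁴) within ~4.6 d (9.1 d for
PEUK). That these declines are not observed is the quantitative case that
shared predation does not transfer the bacterial mortality regime to
picophytoplankton.

A command-line front end (`exec/picograze`) exposes the same pipeline as
`simulate`, `estimate`, `regress`, `project`, `summarize`, and `run`
subcommands over the TSV tables documented in `?write_table`.

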