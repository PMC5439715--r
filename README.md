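# regrowr

Tools for analysing how a glioblastoma (GBM) cell population behaves after
high-dose ionizing radiation. A single acute dose of 8–16 Gy leaves only a
few percent (down to a few hundredths of a percent) of cells with clonogenic
capacity, yet cultures rebound to their pre-irradiation growth rate within
weeks, while the same populations implanted in vivo grow markedly slower
than unirradiated controls. `regrowr` implements the quantitative pipeline
for studying that discrepancy, for radiation biologists and computational
oncologists:

* **Clonogenic survival** — the linear-quadratic model
  `S(D) = exp(-αD - βD²)`, fitted either exactly through two published
  survival points or by constrained, Poisson-weighted least squares on full
  assay tables (`fit_lq()`, `lq_surviving_fraction()`).
* **Growth kinetics** — exponential rate fits above a detection threshold
  (the "above 200 mm³" convention for xenografts) and cumulative
  population doublings for serial cultures (`fit_exponential_growth()`,
  `cumulative_population_doublings()`).
* **A cellular-automaton regrowth model** — proliferative, quiescent and
  NPMA (non-proliferative but metabolically active, senescent-like) cells
  on a 2-D lattice, with per-day death `p_a`, division `p_d`, migration
  `mu`, maturation `m`, and NPMA conversion `p_s` on irradiation. Three
  scenarios discriminate the source of in vivo growth suppression: no
  inhibition, short-range (radius `R`) inhibition by NPMA cells, and a
  host-mediated global elevation of the death rate (`run_scenario()`,
  `dormancy_fraction()`, `extinction_probability()`).
* **Differential expression** — quantile normalization, probe collapse,
  batch mean-centering, per-gene one-way ANOVA across dose-by-day groups,
  Holm step-down correction and a fold-change filter (`de_pipeline()`,
  `anova_screen()`), plus `2^-ΔΔCt` qPCR quantification
  (`ddct_fold_change()`).
* **Dye-dilution division tracking** — EM deconvolution of log-intensity
  histograms into per-generation fractions with peak means fixed `ln 2`
  apart (`fit_division_profile()`, `fl2low_fraction()`).
* **Synthetic data generators** for every stage (`gen_clonogenic()`,
  `gen_growth_trajectories()`, `gen_expression_study()`, `gen_qpcr()`,
  `gen_dye_intensities()`), and a config-driven `run_pipeline()` that runs
  generate → fit → simulate → screen stages with a hashed JSON manifest.

Fitted objects are tibble-friendly: `tidy()`, `glance()` and `autoplot()`
methods are provided throughout.

## Worked example

Reconstruct the survival curve from two published clonogenic percentages,
then ask whether radiation kill alone can explain slow in vivo regrowth:

```r
library(regrowr)

lq <- fit_lq(data.frame(dose = c(8, 16), survival = c(0.0255, 0.00009)),
             method = "interpolate")
lq
#> Linear-quadratic survival fit (interpolate)
#>   alpha = 0.335038 1/Gy
#>   beta  = 0.0154496 1/Gy^2
#>   fitted on 2 dose point(s)
lq_surviving_fraction(lq, 12) * 100
#> [1] 0.194   # percent surviving 12 Gy
```

`alpha/beta ≈ 21.7 Gy` — heavily linear-dominated kill, typical of a
radioresistant line. Now simulate post-8 Gy regrowth with and without a
host-mediated death-rate elevation (5.5%/day after 8 Gy):

```r
S8 <- lq_surviving_fraction(lq, 8)
set.seed(1)
kill_only <- run_scenario(ca_params(npma_clearance = 0.05),
                          n0 = 2000, S8, scenario = "none")
set.seed(1)
host <- run_scenario(ca_params(global_pa = global_pa_preset(8),
                               npma_clearance = 0.05),
                     n0 = 2000, S8, scenario = "global")
dplyr::bind_rows(glance(kill_only), glance(host))
#> # A tibble: 2 × 8
#>   scenario surviving_fraction  days extinct  rate r.squared final_viable
#> 1 none                 0.0255    26 FALSE   0.172     1.000         9414
#> 2 global               0.0255    32 FALSE   0.137     1.000         8315
```

Radiation kill alone delays the tumor but then regrows at essentially the
baseline rate (0.172/day); only the global host-inhibition scenario
produces a clearly reduced rate (0.137/day). Finally, quantify divisions
from a dye-dilution experiment:

```r
x <- gen_dye_intensities(c(0.2, 0.3, 0.5), mu0 = 7, cv = 0.15,
                         n_cells = 20000, seed = 1)
fit_division_profile(x, reference_mu0 = 7, G = 4)
#> Division profile: 20000 cells, G = 4, mu0 = 7.0000 (fixed), sigma = 0.1490
#>   fractions: 0: 0.204, 1: 0.295, 2: 0.501, 3: 0.000, 4: 0.000
#>   FL2-low (>= 2 divisions): 0.501
```

The planted generation mix (20/30/50%) is recovered within half a point,
and the FL2-low readout (≥ 2 divisions) is 0.501 against a truth of 0.5.

See `vignette("regrowth-methods")` (source under `vignettes/`) for the
model details, calibration rationale and known limitations.

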