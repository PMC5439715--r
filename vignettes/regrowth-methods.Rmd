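---
title: "Modeling post-irradiation tumor population dynamics with regrowr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling post-irradiation tumor population dynamics with regrowr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(regrowr)
```

High-dose radiotherapy kills the overwhelming majority of a glioblastoma
cell population, yet recurrence is near-universal. `regrowr` implements the
quantitative toolkit needed to study what the surviving few percent of cells
do next: how severely they were depleted (clonogenic survival), how fast the
population rebounds (growth kinetics), what could be holding regrowth back
in a host (a cellular-automaton model with an arrested secretory
compartment), which transcriptional programs switch on (a multi-group
differential-expression screen and qPCR quantification), and how many times
the survivors have divided (dye-dilution deconvolution). Every stage has a
synthetic-data generator with known ground truth, so the full pipeline is
testable without any external download.

## Clonogenic survival and the linear-quadratic model

Reproductive survival after an acute dose $D$ follows the linear-quadratic
(LQ) model
$$S(D) = \exp(-\alpha D - \beta D^2),$$
with $\alpha$ (1/Gy) capturing single-track lethal lesions and $\beta$
(1/Gy²) pairwise-track interactions. `fit_lq()` offers two estimation modes
because two different situations arise in practice:

* **Interpolation.** Published survival curves are often summarised by a few
  printed percentages. Two distinct non-zero doses determine
  $(\alpha, \beta)$ exactly through a linear system in $-\ln S$; the fit
  reproduces its two inputs to machine precision and lets the whole curve be
  reconstructed from a pair of quoted numbers.
* **Constrained weighted least squares.** For full assay tables the fit
  minimises squared error of $-\ln S$ on $(D, D^2)$ with
  $\alpha, \beta \ge 0$. Survival is normalised to the plating efficiency
  estimated from the 0 Gy dishes, so $S(0)=1$ by construction. Weights are
  Poisson-motivated: the variance of $-\ln \hat S$ at a dose is roughly the
  reciprocal of its pooled colony count. Because using *observed* counts as
  weights correlates the weight with the response (doses that fluctuate high
  get both a low $-\ln S$ and a high weight), the initial fit is followed by
  two Fisher-scoring passes in which weights are replaced by the *expected*
  colony counts under the current parameters; this removes a several-percent
  upward bias in the fitted survival. A dose whose pooled colony count is
  zero carries zero weight and is dropped — with 500 cells per dish a
  16 Gy dose is expected to yield well under one colony, and a log transform
  of zero is not meaningful.

`gen_clonogenic()` is the matching generator: each plated cell forms a
colony with probability $\mathrm{pe} \cdot S(D)$, so per-dish counts are
binomial and the generator's mean converges to the LQ curve — the basis of
the parameter-recovery tests.

## Growth-rate kinetics

`fit_exponential_growth()` is an ordinary least-squares fit of
$\ln(\text{value})$ on time, restricted to points at or above a size
threshold (200 by default, the mm³ convention for xenograft detectability).
Restricting the fit window is essential: after irradiation both cultures and
xenografts show a lag of days to weeks before the surviving clone expands,
and including the lag biases the rate toward zero. Duplicate time points are
averaged in log space; the reported $R^2$ is the ordinary coefficient of
determination of the log-linear fit, and doubling time is $\ln 2 / r$
exactly. `cumulative_population_doublings()` tracks serial cultures as the
cumulative sum of $\log_2(\text{harvested}/\text{plated})$ per passage,
which exposes the suppression-then-recovery structure of irradiated cultures
without requiring a single continuous trajectory.

The in vitro generator produces piecewise-exponential trajectories (a
suppressed rate for a dose-dependent lag, then the control rate — the
"rebound" phenotype); the in vivo generator adds multiplicative log-normal
noise and a Bernoulli engraftment ("take") indicator per animal, because
failed engraftment is reported as a count of animals, not as a small tumor.

## The cellular-automaton regrowth model

The centrepiece is a stochastic lattice model of tumor regrowth after
irradiation. Cells occupy a 2-D square lattice with a Moore (8-site)
neighborhood and come in three states:

* **proliferative** — viable with free space nearby;
* **quiescent** — viable but fully enclosed; transiently arrested, and
  released the moment space frees up;
* **NPMA** — non-proliferative but metabolically active: stably arrested
  survivors of irradiation that never divide, persist for a long time, and
  correspond to the giant flattened senescent-like cells visible in
  post-irradiation cultures.

Each simulated day every cell, in freshly shuffled order, makes one
decision. An NPMA cell is cleared with probability `npma_clearance`,
otherwise persists. A viable cell draws once: with probability `p_a` it
dies; with probability `p_d` it divides, provided it is mature
(`maturity >= m`), has a free neighbor site, the total population is below
`capacity`, and its site is not suppressed by local inhibition; otherwise it
attempts on average `mu` random-neighbor migration steps. Death and
division are *mutually exclusive outcomes of a single draw*, so in the
low-density, maturity-saturated limit the expected per-day growth factor is
exactly $1 + p_d - p_a$ — a closed form (`mean_field_growth_factor()`) used
as an independent oracle for the step engine, alongside a Galton–Watson
extinction check: the offspring distribution (0 with $p_a$, 2 with $p_d$,
else 1) gives the extinction fixed point $q = p_a / p_d$ per founding cell.
Every non-dividing viable cell accrues one step of dormancy; division
resets mother and daughter to zero, which makes "fraction not divided for
$k$ steps" (`dormancy_fraction()`) a well-defined population readout.

Irradiation (`apply_irradiation()`) is an instantaneous filter: each cell
keeps clonogenic viability with probability $S(D)$ from the LQ curve;
inactivated cells convert to NPMA with probability `p_s` or are removed.

### Scenarios: where does growth inhibition come from?

Irradiated populations implanted in vivo grow far more slowly than the same
cells' in vitro rebound would predict. The model discriminates three
hypotheses, run by `run_scenario()` on matched seeds:

* **none** — radiation kill only. Regrowth is delayed (few founders) but the
  eventual rate is essentially the unirradiated rate: kill alone overshoots
  the observed in vivo growth.
* **local** — NPMA cells suppress *division* within a Chebyshev radius `R`
  (1–2 cell diameters), emulating short-range secreted inhibitors.
  Suppression affects only sites that mostly could not divide anyway (near
  arrested neighbors), so the fitted rate moves by only a few percent — the
  model's way of showing that short-range inhibition cannot explain the
  in vivo suppression. Local inhibition deliberately leaves migration and
  survival untouched: suppressing "growth" is read minimally as suppressing
  division.
* **global** — a host-mediated systemic effect: the death probability of
  *every* viable cell is raised to `global_pa` from irradiation onward
  (5.5% after 8 Gy, 6% after 12 Gy in the primary preset;
  `global_pa_preset()` also exposes a 4%/7% alternative preset that
  circulates for the same quantities). This is the only scenario that
  produces a clearly reduced growth rate, and it simultaneously raises the
  dormant fraction: at the end of a 12 Gy run roughly half the population
  has not divided for four or more steps.

### Calibration and numerical choices

The defaults are calibration, not claims:

* `p_d = 0.28`, `p_a = 0.01`, `mu = 5`, `m = 1` give an unirradiated
  doubling time of roughly 2.5–3 days, in line with U87-MG cultures; `m`
  delays a newborn by one maturation day, which is why the mean-field oracle
  is exercised at `m = 0` (its maturity-saturated regime).
* The lattice is 300×300 (90,000 sites) with 2,000 implanted cells; rates
  are fitted on total living cells in the 2,000→8,000 window
  (`detection_size` / `stop_size`), which keeps the measured phase clear of
  both the NPMA-dominated early dip and boundary effects. The dormancy
  readout is taken at a 20,000-cell endpoint — the analogue of a
  sacrifice-size tumor — because the dormant fraction is still rising at the
  detection threshold and plateaus only once colonies have built crowded
  interiors.
* **Engraftment geometry matters.** `run_scenario()` disperses the implant
  across the lattice ("scattered"), the way an injected suspension spreads
  through tissue. A packed bolus (the `"disc"` placement of `init_state()`,
  kept as that function's default for colony-like initial conditions) makes
  early regrowth front-limited; populations delayed by local inhibition then
  cross the measurement window with smaller, faster-growing colonies, and
  the fitted rate *rises* — a pure geometry artifact that would invert the
  scenario comparison.
* `p_s = 0.5` (half of inactivated cells become NPMA rather than dying
  immediately) and `npma_clearance = 0.05`/day in vivo (half-life ≈ two
  weeks, a plausible scale for immune clearance of arrested cells; 0 in
  vitro, where giant cells persist through the assay window).
* Random sequential update (cells shuffled each day) avoids the directional
  artifacts of raster-order updates and the daughter-conflict resolution
  synchronous updates would need. All randomness flows through R's RNG, so
  a fixed seed reproduces a run bit-for-bit.
* Migration frequency `mu` is implemented as the *expected number of
  migration attempts per day* (each attempt picks one of the 8 neighbor
  directions and succeeds only if the site is free); whether such a
  parameter is a frequency or a probability is genuinely ambiguous in the
  literature, and the attempts reading keeps `mu > 1` meaningful.

## The differential-expression screen

The expression stage mirrors the canonical bead-array pipeline, in the
canonical order:

1. **Quantile normalization** (via `limma::normalizeQuantiles`, ties
   averaged) on raw positive intensities — optionally *separately* for
   short-term (days 1/4/6) and long-term (day 35) samples, matching designs
   hybridised in separate runs; then `log2`.
2. **Probe collapse** to genes by maximal mean intensity.
3. **Batch adjustment** of the short-term samples by per-gene, per-batch
   mean-centering: each batch's mean is moved to the gene's grand mean,
   removing additive offsets exactly while preserving within-batch
   contrasts. This is a deliberate, documented simplification — a
   location-only adjustment with no empirical-Bayes shrinkage — so published
   gene counts obtained with ComBat-processed data are not expected to
   reproduce exactly.
4. **One-way ANOVA per gene** across the 12 dose-by-day groups, computed by
   vectorised matrix algebra (verified against `stats::aov` gene by gene in
   the tests), followed by **Holm step-down adjustment**
   (`stats::p.adjust`). The Holm procedure controls the family-wise error
   rate; the label "Bonferroni-Holm FDR" sometimes attached to it conflates
   FWER and FDR, so a Benjamini–Hochberg option is exposed for sensitivity
   analysis but Holm is the default and the tested path.
5. **Fold-change filter**: per irradiated (dose, day) group against the
   same-day 0 Gy control (falling back to the earliest-day control when a
   day lacks one), significant when the Holm-adjusted p is below 10% *and*
   the maximal absolute fold-change exceeds 1.5-fold. The 1.5 threshold is
   linear-scale (|log2 FC| ≥ log2 1.5); whether such cutoffs are linear or
   log-ratio is rarely stated, and the linear reading is flagged here as
   the assumption.

The generator plants known log2 effects on chosen genes in chosen groups,
plus additive batch shifts and Gaussian noise, and returns the truth table
alongside — enabling the two properties that matter: empirical FWER on
pure-null studies stays below the nominal 10%, and planted 2-fold effects
at realistic noise (SD 0.2 log2 units, 3 replicates) are recovered with
high power.

`ddct_fold_change()` implements relative qPCR quantification: per-well
$\Delta C_t$ (target minus 18S housekeeping), per-condition
$\Delta\Delta C_t$ against the pre-irradiated control, expression ratio
$2^{-\Delta\Delta C_t}$ — exactly invariant to any constant added to all
$C_t$ values.

## Dye-dilution division tracking

A lipophilic membrane dye halves with each division, so log fluorescence of
a dividing population is a mixture of equally spaced Gaussian peaks.
`fit_division_profile()` fits that constrained mixture by EM: component $k$
has mean $\mu_0 - k \ln 2$ (the spacing is *fixed*, not estimated), all
components share one $\sigma$, and the weights are the per-generation
fractions. When a day-0 stained, undivided reference sample is available its
$\mu_0$ should be passed and held fixed — estimation is then substantially
more stable when generation 0 has nearly vanished. A free $\mu_0$ is
initialised at the *brightest* local mode of the log-intensity density
(generation 0 is the brightest peak; the global mode belongs to whichever
generation is most abundant, and seeding there collapses the fit).
Convergence is declared when the log-likelihood gain drops below 1e-8
(500-iteration cap, non-convergence is an error); $\sigma$ is floored at
1e-6 to avoid degenerate spikes. `fl2low_fraction()` sums fractions at two
or more divisions — the model-based analogue of an "FL2-low" cytometry
gate, used as the readout of retained reproductive integrity. An optional
unconstrained background component for autofluorescence is deliberately
omitted: unstained-control parameters vary by instrument and would be pure
guesswork here.

## Synthetic data: what it does and does not emulate

The generators reproduce the *statistical structure* the analyses rely on:
binomial colony counts on an LQ mean, lag-then-recovery growth, the
39-sample/12-group expression layout with planted effects and batch shifts,
paired-well Ct tables, and log-normal generation peaks. They deliberately do
not emulate probe-level bead summarisation, scanner saturation, cytometry
compensation or gating, spatial tumor heterogeneity beyond the lattice
model, or real GEO series-matrix quirks. Passing tests therefore demonstrate
correctness of the statistical machinery under the stated models, not
robustness to every artifact of real instruments.

Problem sizes used throughout the tests and the acceptance analysis — 100
simulated assays for parameter recovery, 10 replicate automaton runs per
scenario on a 300² lattice, 500 null studies of 100 genes for the FWER
check, 20,000 cells for dye deconvolution — are the package's chosen
desk-scale study conditions: large enough that the Monte-Carlo error bands
quoted with each check are meaningful, small enough to run routinely.

## Known limitations

* The automaton is 2-D; orthotopic 3-D geometry, vasculature, oxygen and
  explicit immune agents are out of scope — the host effect is exactly the
  aggregate death-rate elevation, as hypothesised.
* The batch adjustment is location-only; strong batch-by-group confounding
  would require a proper empirical-Bayes method.
* The EM deconvolution assumes a common peak width in log space; strongly
  generation-dependent staining heterogeneity would violate it.
* Wet-lab quantities that depend on external data (animal take rates,
  published gene counts from the deposited series) are outside what the
  package can or does reproduce.
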