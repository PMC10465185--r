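---
title: "Quantifying NK-cell killing of proliferating CD4+ T cells"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying NK-cell killing of proliferating CD4+ T cells}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nkassay)
```

## The assay and what the package computes

In a dye-dilution NK cytotoxicity assay, sorted CD4+ conventional T cells
(Tconv) and regulatory T cells (Treg) are stained with a proliferation dye,
activated, and co-cultured with autologous CD56^bright^ or CD56^dim^ NK cells
at a fixed effector:target ratio. The proliferation dye halves its
fluorescence with each cell division, so on the log10 scale the dyed
population forms peaks at

\[ \mu_g = \mu_0 - g \cdot \log_{10} 2, \qquad g = 0, 1, 2, \dots \]

where \(g\) is the division generation and \(\mu_0\) the undivided peak. A
viability dye flags dead cells at acquisition. The analysis questions are:
how much killing do the NK subsets add over spontaneous death, and does that
killing depend on how many times the target cell has divided?

`nkassay` implements the full quantitative chain:

1. **Generation deconvolution** (`fitPeaks()`, `assignGenerations()`,
   `deconvolveGenerations()`): a constrained Gaussian mixture over the dye
   histogram with component means pinned to the halving grid, one shared
   standard deviation, and free weights, fitted by EM; each cell is assigned
   the generation with maximal posterior responsibility.
2. **Proliferation indices** (`percentDivided()`, `divisionIndex()`,
   `proliferationIndex()`): precursor-cohort statistics computed from the
   per-generation counts \(n_g\) via founder counts \(P_g = n_g / 2^g\).
3. **Specific killing** (`gateTargets()`, `buildKillingTable()`): dead-cell
   fractions per donor, effector, target and proliferation stratum, minus the
   matched-stratum spontaneous-death background of the same donor and target
   cultured without NK cells.
4. **Bayesian Beta regression** (`samplePosterior()`, `foldChange()`):
   posterior medians, equal-tailed 95% credible intervals, fold changes
   between groups and false sign rates, under a paired-donor design.
5. **Synthetic cohorts** (`simConfig()`, `simulatePanel()`): event-level
   data with the statistical structure the analysis assumes, so every stage
   is testable end to end without instrument exports.

## Gating assumptions

Two rules of the assay design are baked into the killing stage and deserve
emphasis. First, *all acquired cells* are analysed: no scatter-based
pre-gating and, critically, no viability-based exclusion, because removing
dead cells would bias the killing estimate downward. Second, T cells are
discriminated from NK cells by the proliferation dye (only the T-cell
fraction is stained), which is why `EventTable` enforces that dye intensity
is present exactly on T-cell rows, and why `gateTargets()` gates on subset
identity rather than viability.

## Deconvolution model and its numerical choices

The mixture likelihood for log10 intensities \(x_i\) is

\[ p(x_i) = \sum_{g=0}^{G} w_g \, \mathcal N(x_i \mid \mu_0 - g\log_{10}2,\ \sigma^2). \]

Fixing the peak spacing at exactly \(\log_{10} 2\) (perfect dye halving) and
sharing \(\sigma\) across peaks makes sparse high generations identifiable;
both are deliberate rigidities. \(G = 6\) by default, with more-divided
cells pooling into the top component — beyond six divisions the peaks are no
longer resolvable at realistic dye noise. EM stops when successive
log-likelihoods differ by less than `1e-8` (or at 500 iterations, which
flags the model rather than failing).

Initialization matters more than usual here because the likelihood is
invariant under whole-grid shifts when edge components are empty. `fitPeaks()`
anchors \(\mu_0\) at the brightest substantial density peak (refined by the
upper-quartile mode when both agree), screens the converged fit against
label shifts of ±1–2 generations, and finally re-anchors so that the
brightest *populated* component is generation 0. With no undivided cells in
the sample, \(\mu_0\) is fundamentally unidentifiable from dye data alone;
the brightest-populated-peak convention is then a documented convention, not
an inference.

Ties in the posterior responsibility (a cell exactly midway between two
peaks under equal weights) break toward the lower generation.

At the default generator noise (`dyeSigma = 0.08` log10 units against a peak
spacing of 0.301) the generations overlap enough that even the Bayes-optimal
assignment misclassifies about 6% of cells in interior generations
(\(2\Phi(-0.1505/0.08)\)), i.e. per-cell accuracy plateaus near 94–95%
however good the fit is. Mixture *weights*, in contrast, are recovered to
within ±0.02 because assignment errors between neighbouring generations
nearly cancel. Interval-valued statistics downstream (stratified killing)
are robust to this blur; per-cell labels are not, and should not be
over-interpreted at high dye noise.

## Proliferation indices

With \(P_g = n_g/2^g\) the founder (precursor) counts,

\[ \mathrm{DI} = \frac{\sum_g g P_g}{\sum_g P_g}, \qquad
   \mathrm{PI} = \frac{\sum_{g\ge1} g P_g}{\sum_{g\ge1} P_g}. \]

DI averages divisions over the whole original population; PI averages over
the founders that divided at least once, so \(\mathrm{DI} \le \mathrm{PI}\)
always, with equality only when every founder divided. PI is undefined for a
fully undivided population and the package raises a distinct
undefined-result condition there rather than returning 0, because 0 would be
a *wrong* number, not a missing one. The percent-divided statistic is
computed over acquired cells (not founders): the package follows the
convention in which "94% of cells have divided" describes the acquired
histogram. The founder-based alternative would be systematically lower; the
choice is stated here because the field uses both.

Paired donor comparisons of DI/PI use a two-tailed paired t-test
(`compareIndices()`).

## Stratified specific killing

A cell is *highly proliferative* at day 2.5 if it has undergone ≥ 2
divisions, and at day 3.5 if ≥ 3 — the later threshold accounts for the
extra day of proliferation. Specific killing is the arithmetic difference

\[ \text{specific killing} = \text{dead fraction (co-culture)} -
   \text{dead fraction (same donor, same target, no NK)} , \]

computed per stratum with the background taken from the *matching stratum*
of the matched control well. Negative values are preserved (they are
informative about noise) and only mapped into the open unit interval at the
inference boundary by `prepareResponse()`, which clamps into
\([\varepsilon, 1-\varepsilon]\) (default \(\varepsilon = 0.005\)) and
always reports the clamp count.

## The Beta regression

Specific-killing proportions \(y_i\) are modelled as

\[ y_i \sim \mathrm{Beta}(\mu_i \phi, (1-\mu_i)\phi), \qquad
   \mathrm{logit}(\mu_i) = \alpha + \beta_{g(i)} + \gamma_{p(i)}, \]

with the contrast of interest as the group factor \(g\) (proliferation
stratum, target subset, or assay day) and the donor/sample pair as a fixed
effect \(p\); reference levels of both are pinned at zero for
identifiability. Pair effects are fixed, not hierarchical: with 7–14 donors
a hierarchical variance would be weakly identified, and the fixed-effect
formulation matches treating the pair as a design variable.

Priors are weakly informative: \(\alpha, \beta, \gamma \sim \mathcal N(0,
2.5)\) on the logit scale and \(\log\phi \sim \mathcal N(3, 1.5)\). The
coefficient scale 2.5 is the common weakly-informative default for
logit-scale regression coefficients; the \(\log\phi\) prior centres the Beta
precision at \(e^3 \approx 20\) (proportion SD ≈ 0.09 at \(\mu = 0.2\))
while allowing the posterior to reach the very high precisions that arise
when well-to-well variation is small.

Posterior group means marginalize over the observed pair levels with equal
weight, per draw:
\(\mu_g = \tfrac1P \sum_p \mathrm{logit}^{-1}(\alpha + \beta_g + \gamma_p)\).
Fold changes are per-draw ratios of these group means, so the reported
median fold change is the median of ratios, not a ratio of medians.
Summaries are the posterior median and the equal-tailed 95% interval
(type-7 linear-interpolation quantiles); the false sign rate (FSR) is the
posterior mass whose sign opposes the sign of the median effect — 0 means a
certain sign, 0.5 total sign uncertainty.

### Sampler

Sampling uses 4 chains of 2500 warmup + 2500 kept draws (the assay's
reporting convention). The posterior has a mild funnel: conditional on
\(\phi\), the linear coefficients are close to Gaussian with spread
\(\propto 1/\sqrt\phi\). The default kernel exploits this structure with a
blocked Metropolis-within-Gibbs sweep: (i) a joint independence
Metropolis-Hastings update of all linear coefficients using a
multivariate-t proposal (df 10) centred at the posterior mode, whose scale
is the conditional inverse Hessian rescaled by
\(\sqrt{\phi_{\mathrm{mode}}/\phi}\); (ii) a stepping-out slice update of
\(\log\phi\). Typical acceptance is 0.6–0.9 and autocorrelation decays
within a handful of sweeps, giving split-R̂ at or below 1.01 at the default
chain lengths. A chain whose warmup acceptance drops below 0.1 is restarted
with a self-contained adaptive random-walk Metropolis kernel (also available
directly via `backend = "rwm"`); split-R̂ above 1.01 attaches a convergence
warning rather than failing. The sampler is validated against dense-grid
quadrature of the same log-posterior on small datasets and against
prior-quantile recovery when the likelihood is disabled.

## What the synthetic generator emulates — and what it does not

`simConfig()` defaults describe a cohort of 14 donors, 10 harvested at day
2.5 and 4 at day 3.5, with 20 000 acquired T cells per well (a desk-scale
stand-in for the ~50 000 plated in a real assay). Per subset and day, the
generation distribution is specified directly as a probability vector over
generations 0–6, calibrated so that 94%/71% of Tconv/Treg have divided at
day 2.5 (97%/87% at day 3.5), with the highly divided tail (G5 and
beyond) matched as well. Direct probability vectors (rather than a division-timer
model) keep the calibration transparent and the round-trip test exact.

Death is additive on the proportion scale — spontaneous background plus the
specific-killing mean for the cell's proliferation stratum in co-culture,
clamped to [0, 1] — because the assay's statistic is an arithmetic
subtraction of percentages; an additive generator makes the estimand equal
the configured kill mean. Spontaneous-death defaults are the day-specific
group medians (Tconv 7.0%/16.2%, Treg 8.6%/9.7% at days 2.5/3.5), applied
to both strata; specific-killing defaults are the stratified group medians
(CD56br on Tconv 25.6%/17.7% high/low, on Treg 22.0%/15.0%; CD56dim 22.5%
on Tconv and 20.7% on Treg, both strata).

Two logit-scale random offsets then shift every death probability: a
donor-level offset (SD 0.15) shared by all of a donor's wells — this is the
component the pair term of the regression absorbs — and a well-level offset
(SD 0.10) drawn independently per culture well, representing biological
replicate noise between separately cultured wells of the same donor. The
well-level component is a modelling choice of this package: without it,
paired contrasts at 20 000 cells/well would be binomially precise to a
degree no real assay achieves (posterior sign uncertainty would vanish),
and its SD was fixed once at "smaller than between-donor variation". Only
only medians and intervals of donor-level variability are reported for
the real assay, so
both SDs are calibration knobs, not measured values.

NK-cell events are generated undyed (they are never dye-stained in the
assay), at a fixed acquisition count per co-culture well with their own
nominal death rate; they are never counted as targets. The generator does
not simulate scatter channels, compensation, spillover, doublets, dye
transfer, death-in-culture corrections of the generation structure, or
effector:target ratio effects — so passing tests demonstrate the
*statistical* chain, not robustness to instrument artefacts. A real-data
ingestion path only needs a CSV with the `EventTable` columns
(`readEvents()` preserves extra columns).

Determinism: a fixed seed gives byte-identical event tables; per-donor RNG
substreams are derived from the seed so cohort composition changes do not
reshuffle existing donors.

## Problem sizes used in the packaged checks

The packaged acceptance checks run the full pipeline on the 14-donor cohort
at 20 000 cells per population (and a 7-donor cohort for the CD56dim
contrast) with the full 4 × (2500 + 2500) sampler; unit tests use smaller
cohorts (hundreds to a few thousand cells) chosen so each check still has
decisive power. Posterior-interval calibration is checked on 100
prior-predictive replicates of a reduced design (10 observations, 2 groups)
with shorter chains, where coverage of the 95% interval is required to land
in 90–98%. Prior-predictive responses are used exactly as drawn — clamping
them would break the match between generating and fitted model and visibly
ruins calibration for the low-precision replicates; the few replicates whose
Beta draws underflow double precision (exact 0 or 1) are redrawn, since the
likelihood is undefined there.

## Known limitations

* Per-cell generation labels blur at high dye noise (see above); stratified
  statistics inherit only a small attenuation, but single-cell claims
  should use a brighter separation (smaller `dyeSigma`, fewer generations).
* \(\mu_0\) cannot be identified without undivided cells; supply
  `mu0Init` from an unstimulated control when analysing real exports of
  fully divided populations.
* The day-3.5 "high" threshold is taken as ≥ 3 divisions; an alternative
  reading (> 3) exists in the field and shifts the stratum boundary by one
  generation at day 3.5.
* Negative specific killing is handled by clamping at the inference
  boundary; with many boundary values the Beta model is a poor description
  and a zero-inflated variant (out of scope here) would be preferable.
* Pair effects are fixed effects; with much larger cohorts a hierarchical
  donor term would borrow strength and may be preferable.

## A worked example

```{r example, eval = FALSE}
library(nkassay)

cfg <- simConfig(seed = 1)          # 14 donors, calibration defaults
panel <- simulatePanel(cfg)         # ~1.8M acquired cells
dec <- deconvolveGenerations(panel) # one PeakModel per donor x subset
kt <- buildKillingTable(panel, dec$generations)

fit <- samplePosterior(contrastStratum(kt, "CD56br", "Tconv"), seed = 11)
foldChange(fit)
#> fold change high : low: median 1.414, 95% CrI [1.372, 1.458], FSR 0
```

The same stages are scriptable through `runPipeline()` (YAML configuration,
CSV/JSON artifacts) or the installed `exec/nkassay` command-line tool.
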