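# nkassay

Quantification and Bayesian inference for in vitro NK-cell killing assays
against CD4+ T-cell targets.

## The problem

CD56^bright^ NK cells are rare in blood, expand under low-dose IL-2 therapy,
and appear to preferentially kill *proliferating* CD4+ T cells. Measuring
that preference from a dye-dilution co-culture assay requires a chain of
non-trivial quantitative steps: resolving the proliferation-dye histogram
into division generations, classifying each target cell as highly or lowly
proliferative with a day-specific division threshold, subtracting
spontaneous-death backgrounds from the *matched* stratum of the same donor's
no-NK control, and estimating group fold changes from small paired-donor
cohorts with honest uncertainty. `nkassay` packages this chain for analysts
working with cytometry event tables (and provides a synthetic cohort
generator so the whole pipeline is testable without instrument data).

## The models at the core

**Generation deconvolution.** Log10 dye intensities follow a constrained
Gaussian mixture whose component means are pinned to the dye-halving grid,

    x_i ~ sum_g  w_g  N(mu0 - g*log10(2), sigma^2),   g = 0..6,

with shared sigma and free weights, fitted by EM; cells take the generation
with maximal posterior responsibility. Precursor-cohort indices use founder
counts P_g = n_g / 2^g:

    DI = sum_g g*P_g / sum_g P_g          (whole population)
    PI = sum_{g>=1} g*P_g / sum_{g>=1} P_g  (dividers only), so DI <= PI.

**Specific killing.** Per donor, effector, target and proliferation stratum
(high: >= 2 divisions at day 2.5, >= 3 at day 3.5):

    specific_killing = dead_fraction(co-culture) - dead_fraction(no-NK control),

backgrounds matched by stratum, dead cells never gated out.

**Inference.** Beta regression with a logit-linked mean,

    y_i ~ Beta(mu_i*phi, (1-mu_i)*phi),  logit(mu_i) = alpha + beta_group + gamma_pair,

weakly informative priors (coefficients N(0, 2.5); log phi N(3, 1.5)),
sampled with 4 chains of 2500 warmup + 2500 kept draws by a self-contained
blocked Metropolis-within-Gibbs kernel (independence-MH coefficient block +
slice update of log phi). Reported: posterior median, equal-tailed 95%
credible interval, per-draw fold change between groups, and the false sign
rate (posterior mass on the opposite sign of the median effect).

## A worked example

```r
library(nkassay)

cfg <- simConfig(seed = 1)            # 14 donors: 10 at day 2.5, 4 at day 3.5
panel <- simulatePanel(cfg)           # event-level table, ~1.8M cells
dec <- deconvolveGenerations(panel)   # dye-peak mixture per donor x subset
kt  <- buildKillingTable(panel, dec$generations)

head(as.data.frame(kt), 3)
#>   donor_id effector target stratum day dead_fraction background_fraction specific_killing
#> 1      D01   CD56br  Tconv     all 2.5     0.3476000          0.06770000        0.2799000
#> 2      D01   CD56br  Tconv    high 2.5     0.3712858          0.06821255        0.3030732
#> 3      D01   CD56br  Tconv     low 2.5     0.2800462          0.06624424        0.2138020

fit <- samplePosterior(contrastStratum(kt, "CD56br", "Tconv"), seed = 11)
foldChange(fit)
#> fold change high : low: median 1.414, 95% CrI [1.372, 1.458], FSR 0
```

Row 2 reads: for donor D01 at day 2.5, 37.1% of highly proliferative Tconv
cells were dead after co-culture with CD56^bright^ NK cells; 6.8% of the
matching stratum died spontaneously in the no-NK control, leaving 30.3%
specific killing. The fold-change summary says highly proliferative Tconv
were killed ~1.41 times more than lowly proliferative ones in this synthetic
cohort (generated at stratified killing means of 25.6% and 17.7%), with an
FSR of 0: no posterior support for the opposite sign.

`runPipeline()` drives the same stages from a YAML config and writes
`records.csv`, per-contrast draw CSVs and a `summary.json` embedding the
resolved configuration; the installed `exec/nkassay` script exposes
`simulate`, `prolif`, `killing`, `fit` and `run` subcommands.

## Vignette

`vignettes/nk-killing-assay.Rmd` documents the models, priors, sampler
design, the synthetic generator's calibration and its limitations.
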