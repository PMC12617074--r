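---
title: "Methods: demographic resilience from coalescent Ne reconstructions"
author: "NeScape authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: demographic resilience from coalescent Ne reconstructions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(NeScape)
```

# The problem

Sequentially Markovian coalescent (SMC) tools such as MSMC2 reconstruct the
history of the effective population size Ne as a piecewise-constant function
of time, separately for every population and every bootstrap replicate, on
time discretizations that differ between runs. Comparative questions — do
host-specialist reef fishes lose more effective population size during
glacial sea-level cycles than generalists? — require (i) putting hundreds of
such reconstructions on a common footing, (ii) discarding estimates the
coalescent cannot support, (iii) summarizing each trajectory over climatic
epochs, and (iv) statistical models that respect the deeply nested and
crossed dependence structure of the data. NeScape implements that
post-inference pipeline, together with the split-time and
sequence-divergence statistics that accompany it, and a synthetic-data
module that generates every input with known parameters so the whole
pipeline is testable at desk scale.

# From scaled coalescence rates to Ne in years

SMC output is dimensionless: per time segment a scaled coalescence rate
$\lambda$ and scaled time boundaries. With a mutation rate $\mu$ per
generation per site and a generation time $g$ in years,

$$N_e = \frac{1}{2\mu\lambda}, \qquad
  t_\text{years} = \frac{t_\text{scaled}}{\mu}\, g .$$

Defaults are $\mu = 4\times10^{-8}$ and $g = 5$ years, the values in use
for clownfish; both are tunable through `scalingConstants()`. All times in
the package are years before present, present $= 0$, matching the
orientation of sea-level series. `scaleToReal()` and `realToScaled()` are
exact inverses (tested to $10^{-12}$ relative error), which the generator
exploits to emit files in scaled units that round-trip through the reader.

# Harmonization

Each trajectory is reduced to (midpoint, Ne) pairs — the midpoint of each
segment's time boundaries, with the terminal infinite segment dropped — and
interpolated onto a common grid of 100 logarithmically spaced points
between 1 year and the maximum reconstructed time rounded to the nearest
million years (`buildCommonGrid()`; round-half-up with a floor of one
million years so the grid always spans the last glacial cycles). Grid
points outside a trajectory's coverage stay `NA`; nothing is extrapolated
or imputed.

Two conventions were genuinely open and are both exposed:

* interpolation is **linear in raw time and raw Ne** by default, the most
  literal reading of "linear interpolation"; `logTime = TRUE` interpolates
  on a log10 time axis instead, for sensitivity analysis;
* epoch summaries operate on the **original segments**, not the
  interpolated grid, because segment durations are the natural weights
  (`gridHarmonicNe()` provides the grid-based variant as a cross-check;
  the two agree to a few percent on simulated cohorts).

The epoch summary is the weighted harmonic mean

$$H = \frac{\sum_i w_i}{\sum_i w_i / N_{e,i}},$$

with $w_i$ the overlap duration between segment $i$ and the epoch; masked
segments contribute no weight. The harmonic mean is the right functional
because drift compounds through $1/N_e$: one short bottleneck dominates
the epoch, as it dominates the loss of diversity. `weightedHarmonicNe()`
agrees with a 1-year-step Riemann discretization to well below 0.1%
relative error on random piecewise trajectories.

Default epochs are the two windows of pronounced sea-level fluctuation
(350–150 kya and 120–15 kya) and the post-glacial rise (15–0 kya). They
delimit qualitative phases of the global curve rather than sharp events,
so they are plain configuration (`defaultEpochs()`, or the `epochs` block
of the run config).

# Reliability filters

Two quantile rules, both using linear interpolation between order
statistics ($h = (n-1)q$, base R type 7, pinned so thresholds are
bit-reproducible):

1. **Replicate removal** (`flagOutlierReplicates()`, $q = 0.975$): per
   species and epoch, the threshold is the $q$-quantile of *all* in-epoch
   Ne values pooled over that species' trajectories; any replicate
   exceeding it at least once inside the epoch is removed entirely.
   Anomalously high bootstrap Ne typically reflects resampled hybrid or
   migrant individuals. Pooling across the species' populations is the
   default; `byPopulation = TRUE` switches the pool.
2. **Edge masking** (`trimExtremeValues()`, $q = 0.95$): per trajectory,
   values above the trajectory's own $q$-quantile are set to missing —
   these are usually the oldest/youngest segments, where little coalescent
   information exists. The default masks wherever the threshold is
   exceeded (the literal rule); `edgesOnly = TRUE` restricts masking to
   leading/trailing runs.

A caveat the tests document: with continuous noise, some values always
exceed a pooled 97.5% quantile; whether they concentrate in one replicate
depends only on the correlation structure of the noise, not on its scale.
On clean simulated ensembles the filter therefore removes a small but
nonzero number of unremarkable replicates (bounded by the exceedance
budget, $\lfloor 0.025\,n\rfloor + 1$ per pool); what it guarantees is
that a genuinely inflated replicate is always among those removed. Curated
dataset-specific exclusions go through `excludeReplicates()` — an explicit
list, never hard-coded.

# Split times from cross-coalescence rates

For a population pair, the relative cross-coalescence rate

$$r(t) = \frac{2\lambda_{01}(t)}{\lambda_{00}(t) + \lambda_{11}(t)}$$

is $\approx 1$ while the pair still coalesces as one ancestral population
and falls to 0 after complete isolation. `estimateSplit()` scans from the
present toward the past for the first adjacent pair of curve points
bracketing the threshold (default 0.5) and linearly interpolates the
crossing time. Conventions for the cases the rule leaves open: a curve
that never drops below the threshold is panmixia (split 0, flagged
`no_split`); one that never reaches it is `unresolved` (NA); when noise
produces several crossings the most recent is taken — reading the
completion of isolation — with an `"oldest"` switch and an optional
3-point median smoother (off by default, preserving the literal rule).
The estimate is invariant to uniform rescaling of the three rates, and on
logistic-shaped synthetic curves the error is below one grid interval and
shrinks as the time discretization refines.

# Windowed population-genetic statistics

All statistics consume diploid biallelic genotypes (`readGenotypeVCF()`,
GT field via vcfR) after the minor-allele-frequency filter
(`mafFilter()`, default 0.02, computed on non-missing chromosomes across
all individuals; kept iff $\min(p, 1-p) \ge 0.02$).

* **π** per site is $ab/\binom{n}{2}$ for allele counts $a, b$ among $n$
  observed chromosomes — the exact mean pairwise difference, verified
  against exhaustive pair enumeration.
* **FST** is the Weir–Cockerham (1984) estimator with variance components
  $a$ (among populations), $b$ (among individuals within populations) and
  $c$ (within individuals), for two populations with unequal sample sizes
  and observed heterozygosity. Genome-wide aggregation is the ratio of
  sums $\sum a / \sum (a+b+c)$, never the mean of per-site ratios (which
  are unstable and can be negative). On Balding–Nichols genotypes the
  estimator recovers the generator's F.
* **dxy** per site is $p_A(1-p_B) + p_B(1-p_A)$; windows (default 50 kb;
  π uses 10 kb) tile each chromosome from coordinate 0 in half-open
  0-based intervals. Window values average per-site values over the
  variant sites present (matching the averaging of per-site outputs); a
  sequence-length denominator is available by flag for comparability with
  per-bp conventions.
* **Geographic distance** is the haversine great-circle distance on a
  6371-km sphere between population centroids.

Missing genotypes are dropped per site per population; upstream
quality/depth filtering is assumed done by the variant caller.

# Comparative models

`buildModelTable()` lays out one row per (species, population, replicate,
grid point) with non-missing Ne and sea level; covariates are standardized
over exactly the rows entering the model, after all filtering.

**Mixed model** (`fitNeGLMM()`): fixed effects are the full three-way
interaction of standardized sea level × host category × standardized time;
random effects follow the nested species/population/replicate structure.
Two deliberate choices:

* *Backend.* The default fits a linear mixed model on $\log N_e$
  (lmerTest, Satterthwaite p-values) — the log-link correspondence of a
  Gamma model with multiplicative noise — because it is fast and robust at
  simulation scale; `backend = "glmm"` fits the literal Gamma GLMM with
  log link via glmmTMB. Every `FitResult` names the backend used, and
  degenerate fits are flagged, never silently replaced.
* *Random-effect structure.* The default adds a replicate-level random
  slope for sea level to the nested intercepts. Replicate-level noise
  induces replicate-to-replicate variation in the apparent sea-level
  response, and interpolation onto a dense grid makes residuals strongly
  autocorrelated within a replicate; intercept-only models then understate
  the uncertainty of the sea-level-by-host contrast and over-reject under
  the null. With the random slope the planted-interaction test attains
  full power while the null rejection rate sits at the nominal 5%.
  `formulaMode = "literal"` reproduces the plain nested-intercept
  structure for comparison. Population enters as a random intercept
  within species by default — listing it both as a fixed effect and
  inside the nesting is redundant — with `popFixed = TRUE` available.

**Functional ANOVA** (`functionalAnova()`): each trajectory is a
functional observation ($\log_{10} N_e$ on the grid). At every grid point
where each host group has at least two covering trajectories, a one-way F
statistic is computed across groups; the global statistic is the mean
pointwise F, and its significance comes from permuting host labels at the
*species* level, so all trajectories of a species move together —
bootstrap replicates are never treated as independent evidence. $p =
(1 + \#\{\text{permuted} \ge \text{observed}\})/(B+1)$, deterministic per
seed. With few species the permutation space is small: with three species
per group the observed partition is redrawn in roughly a tenth of random
permutations, so p bottoms out near 0.1 regardless of separation — the
honest floor of a species-level test at that size. Attaining the minimum
$1/(B+1)$ requires on the order of ten species per group.

**Epoch rank tests** (`epochRankTests()`): Kruskal–Wallis across host
groups within each epoch, Wilcoxon rank-sum between epochs within each
group, midranks for ties, raw p-values (no multiplicity correction is
applied, matching the descriptive use of these tables); rows with too few
values are flagged rather than dropped.

**Pairwise adjustment** (`adjustPairwise()`): FST or dxy is modelled as
distance + split time + host category with crossed random intercepts for
the two populations of each pair and a random intercept for species —
the crossed terms absorb the repeated use of populations across pairs.
The adjusted statistic removes only the fitted distance and split-time
fixed effects,
$\text{adj} = \text{obs} - \hat\beta_d\, d_z - \hat\beta_s\, s_z$,
retaining host and random effects, so species- and population-level
structure survives while spatial and temporal confounding is stripped. A
planted distance slope of 0.05 is reduced to below 0.01 in absolute value
on synthetic pair tables.

# What the synthetic data emulate — and what they do not

`simSeaLevel()` stands in for the late Quaternary eustatic curve: ~100 ky
and ~41 ky orbital sinusoids phased so lowstands fall at the known glacial
maxima (most recently ~20 kya, with a small seeded chronology jitter),
plus seeded smooth undulation of about 5 m — the scale of disagreement
among published reconstructions — anchored near 0 m at present and clamped
to $[-140, +10]$ m. The phasing is deterministic on purpose: the
post-glacial rise out of the LGM lowstand is the feature the epoch
comparisons rely on, and a stand-in without it would not be emulating the
dataset. One realization (seed 42) is designated the package's reference
chronology and used wherever the real analysis would use the single
published curve; cohort sampling varies by seed around it.

`simTrajectories()` draws, per population, log-spaced segment boundaries
on [100, maxAge] years and sets
$\log N_e = \log N_{e,\text{base}} + \gamma_g\, z(\text{sea at midpoint})
+ \varepsilon$, with $\varepsilon$ an AR(1) process across segments
(marginal sd `noiseSd`, default 0.2; lag correlation `arCoef`, default
0.6 — adjacent SMC segments share coalescent information) drawn
independently per replicate. Defaults encode the study design: host
categories {generalist, RM, EQ, SD}, 50 bootstraps per population sharing
the main run's discretization (the pipeline never relies on that
sharing), base Ne $10^5$, $\gamma = 0$ for generalists and $+0.5$ for
specialists — positive because the mechanism is habitat: lowstands drain
shelf habitat, so specialist Ne tracks sea level, and the harmonic-mean Ne
of the rise epoch (which spans the deglaciation out of the LGM minimum)
comes out lower than the fluctuation epochs', reproducing the observed
contrast. A configurable fraction of replicates can be "contaminated"
(uniformly inflated Ne) to exercise the outlier filter.

`simCrossCoal()` builds a pair series with constant within rates
$1/(2\mu N)$ and a cross rate rising from 0 to the within rate as a step
or logistic at a known split time (the logistic's RCCR is exactly 0.5 at
the split). `simGenotypes()` is the Balding–Nichols island model:
ancestral frequency $p \sim U(0.05, 0.95)$, population frequencies
$\sim \mathrm{Beta}(p(1-F)/F,\ (1-p)(1-F)/F)$, genotypes
$\sim \mathrm{Bin}(2, \cdot)$, positions uniform; it writes a minimal
VCF 4.2 and a sample metadata CSV.

What passing tests on these data do **not** show: the generators have no
linkage disequilibrium, no mutation/recombination along sequences, no
migration after the split, no selection, no time-lagged or cumulative
demographic response (log Ne reacts to the *contemporaneous* level), and
SMC estimation error enters only as the stylized AR(1) noise. Results on
real reconstructions inherit none of these simplifications' guarantees.

# Numerical choices and degenerate inputs

* Quantiles: type 7 everywhere, for bit-reproducible thresholds.
* Interpolation refuses to extrapolate; `standardize()` errors on fewer
  than two values or zero spread; `midpointTimes()` errors when every
  segment is infinite; `estimateSplit()` errors on a non-monotone time
  axis.
* Readers name the offending row in format errors; column order is taken
  from the header; a blank or "inf" final right boundary reads as
  infinite and writes back as "inf".
* All generators and permutation tests are pure functions of
  (configuration, seed); reruns of the pipeline with the same resolved
  config are byte-identical, and every output CSV is stamped with the
  config hash and seed.
* Singular (boundary) mixed-model fits are reported as converged with a
  note — a variance component estimated at zero is a valid estimate;
  optimizer failures and zero-residual-variance degeneracies set the
  convergence flag to FALSE.

# Problem sizes

The bundled demonstration cohort is two host categories × three species ×
two populations with 10 bootstraps each (grid of 100 points), 2000
Balding–Nichols SNPs per species across three populations of ten
diploids, and B = 199 permutations; a full pipeline run completes in a few
seconds and the whole verification suite in a few minutes on one CPU.
Statistical calibration checks use 20–100 seeded repetitions of cohorts
this size; FST recovery uses 2 × 25 diploids × 5000 SNPs over 20 seeds.
These sizes are the package's own reproducibility settings; all scale up
linearly through the configuration.

# Known limitations

* The FST/dxy/π module handles biallelic diploid sites only; multiallelic
  sites are dropped at read time.
* The pooled-quantile replicate filter is a rule, not a test: it has no
  false-positive control (see above), and its per-species pooling is an
  interpretation choice exposed as a switch.
* The functional ANOVA's species-level permutation is granular for small
  cohorts; its p-values cannot fall below the combinatorial floor.
* Gamma-GLMM and log-LMM backends agree on signs in all tested scenarios
  but are not numerically interchangeable; reported coefficients name
  their backend.
* Split-time estimation assumes the RCCR curve rises monotonically
  through the threshold in the neighbourhood of the split; heavily
  non-monotone curves are better served by the smoothing option plus
  visual inspection.
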