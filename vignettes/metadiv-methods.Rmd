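---
title: "Methods: coverage-standardized diversity for metabarcoding read tables"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: coverage-standardized diversity for metabarcoding read tables}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metadiv)
```

## The problem

Metabarcoding gives read counts per OTU (operational taxonomic unit), not
individual counts. Read counts are a usable abundance proxy *within* a
sample, but two things must be handled before diversity values can be
compared across samples:

1. **Sequencing errors inflate the singleton count.** Many error reads
   appear as OTUs observed exactly once, and singletons (`f1`) carry almost
   all of the weight in non-parametric coverage and richness estimation.
   Dropping all singletons, as many pipelines do, destroys real rare taxa
   and invalidates every estimator that needs `f1`.
2. **Sample coverage varies systematically between habitats, seasons and
   sequencing depths.** Coverage -- the proportion of the total community
   abundance belonging to the species detected in the sample -- can be
   estimated from the sample itself via Turing's argument, and diversity
   should be compared at equal coverage, not equal reads.

`metadiv` implements this workflow: a singleton-error filter, Turing
coverage estimation with rarefaction/extrapolation, taxonomic and
phylogenetic Hill numbers standardized to a coverage target, assembly of a
dated ultrametric phylogeny from barcodes plus a family backbone, and
coverage-standardized beta dissimilarity with distance-matrix regression.

## Singleton filter

For each sample we tally the frequency counts `f_r` (number of OTUs with
exactly `r` reads). Treating the doubleton, tripleton and quadrupleton
counts as reliable, the expected *true* singleton count follows from the
Good-Turing frequency ratios:

$$\hat f_1 = \frac{2 f_2^2}{3 f_3} \quad (f_3 > 0), \qquad
  \hat f_1 = \frac{2 f_2 (f_2 - 1)}{3 (f_3 + 1)} \quad (f_3 = 0), \qquad
  \hat f_1 = 0 \quad (f_2 = 0).$$

The surplus `max(0, f1_obs - round(f1_hat))` (rounding half away from zero
for symmetry, then clamping to `[0, f1_obs]` -- sparse samples can otherwise
produce negative removals) is removed by deleting that many singleton OTUs
uniformly at random under a caller-supplied seed. Counts of 2 or more are
never touched, raw reads (never relative reads) enter the filter, and every
decision is made within one sample. The estimator is a plain injectable
function of `(f2, f3, f4)` so an alternative closed form can be swapped in
without touching the pipeline; this isolates the one formula for which
published variants differ. Because the removal step is random,
`repeat_filter()` reruns it under several seeds and
`replicate_dispersion()` summarizes how much any downstream statistic moves
between replicates (with realistic error loads the movement is small; the
suite checks a relative SD below 5% on simulated data).

## Sample coverage

At the observed size the Turing/Good estimator with the usual small-sample
modification is

$$\hat C = 1 - \frac{f_1}{n}\,\frac{(n-1) f_1}{(n-1) f_1 + 2 f_2}.$$

Rarefied coverage uses the hypergeometric expectation
$\hat C(m) = 1 - \sum_i \frac{x_i}{n} \binom{n-x_i}{m} / \binom{n-1}{m}$,
with the binomial-coefficient ratios computed through `lgamma` so the curve
is overflow-free for any `n` and defined for *real-valued* `m` (the ratio is
0 when `m > n - x_i`). That continuous extension is what lets
`size_for_coverage()` invert the curve by root finding to a residual below
1e-8. Extrapolated coverage is
$\hat C(n + m^*) = 1 - \frac{f_1}{n}(1-A)^{m^*+1}$ with the Good-Turing
fraction `A`. Extrapolation is capped at `2n` by default (configurable):
diversity standardized far beyond the observed size rests mostly on the
asymptotic estimator rather than data, so the workflow's coverage targets
should sit near the mean observed coverage (0.996 is the package default,
0.98 the usual robustness alternative; both are arguments, not constants).

## Taxonomic Hill numbers

For relative abundances `p_i`, the order-`q` Hill number is
$^qD = (\sum_i p_i^q)^{1/(1-q)}$, with the `q = 1` limit
$\exp(-\sum p_i \log p_i)$: `q = 0` counts all species equally (richness,
rare species), `q = 1` weights by frequency (typical species), `q = 2`
emphasizes dominants. Standardization choices:

* `q = 0` rarefaction uses the exact hypergeometric expectation, `q = 2`
  the unbiased inverse-Simpson form
  $1/[\tfrac1m + \tfrac{m-1}{m}\sum_i \frac{x_i(x_i-1)}{n(n-1)}]$, which the
  suite checks against exhaustive enumeration of every read subsample at
  small `n`.
* `q = 1` rarefaction averages the observed exponential Shannon over `B`
  seeded subsamples without replacement (default `B = 200`). The exact
  combinatorial expectation exists but is lengthy; seeded Monte-Carlo is
  transparent, bit-reproducible, and its error is bounded in the tests.
* Asymptotes: Chao1 for `q = 0`, the Chao-Jost entropy estimator for
  `q = 1`, the unbiased inverse Simpson for `q = 2`. Extrapolation
  approaches the asymptote through the completion term
  $D(n+m^*) = D_{obs} + (D_{asym} - D_{obs})\,[1 - (1 - \frac{f_1}{n \hat f_0 + f_1})^{m^*}]$,
  exact for `q = 0` and reused for `q = 1`; since the recommended coverage
  targets sit at or below typical observed coverage, extrapolation-side bias
  is second-order in practice.
* Degenerate inputs: a sample of all singletons has no finite `q = 2`
  asymptote and is reported as `NA` with a warning; empty samples are
  errors for estimators but only warnings at table validation.

## Tree assembly

Within each family, aligned barcodes give JC69 distances
($d = -\tfrac34 \log(1 - 4p/3)$ over pairwise-complete unambiguous sites);
saturated pairs (`p >= 0.75`) are set to a finite ceiling (default 5
substitutions/site) with a warning rather than `NaN`, since neighbour
joining only needs finite dissimilarities. NJ trees (Saitou-Nei via ape)
get negative branches clamped to zero with the deficit moved to the
adjacent descendant edges, and are midpoint-rooted: NJ output is unrooted,
midpoint rooting is deterministic and parameter-free, and rooting within a
family hardly matters downstream because calibration discards the
substitution-scale lengths entirely.

Subtrees replace their family's tip on the dated backbone. Families absent
from the backbone are skipped and reported; a family known from the
literature to be sister to a backbone family can be inserted beforehand as
a cherry on the sister's terminal edge (a placeholder position -- ages are
fixed by calibration). Multiple-sequence alignment is an input, not a
stage: any aligner can sit upstream.

Age calibration is bladj-style: tips are age 0, calibrated internal nodes
keep their ages exactly, and every uncalibrated node is spaced evenly (by
node count) between its nearest calibrated ancestor and nearest calibrated
or tip descendant. The implementation processes nodes root-to-tip, so the
relevant ancestor age is always already assigned; if a farther calibrated
descendant would still end up older than the interpolated node, the node is
instead placed midway between its parent and that descendant's age, keeping
ages strictly monotone. Two guard rails are deliberate design choices: a
calibrated descendant at or above a calibrated ancestor's age is a hard
error naming the pair, and an uncalibrated root defaults to 1.05 x the
oldest calibration with a warning (setting it exactly equal would create a
zero-length root edge and violate strict monotonicity). Calibration is
idempotent. `force_ultrametric()` finally equalizes every root-to-tip path
by adjusting terminal edges, erroring if any adjustment exceeds `tol` --
after calibration the adjustments are numerically zero, the step is a
safety net for externally supplied chronograms.

## Phylogenetic Hill numbers

On the ultrametric tree each branch `b` carries length `L_b` and abundance
`a_b`, the summed relative abundance of its descendant tips. With reference
time `T` (the tree depth),

$$^q\bar D(T) = \Big[\sum_b \tfrac{L_b}{T}\, a_b^q\Big]^{1/(1-q)}, \qquad
  ^qPD = T \cdot {}^q\bar D(T),$$

with the usual `q = 1` limit; at `q = 0` with all tips present this is
Faith's total branch length. Three choices matter:

* **Coverage comes from the tips.** The standardization size is solved on
  the sample's read distribution; the tree only enters the diversity value.
* **T is global.** All samples share the mega-tree, and a sample's profile
  keeps the full root path (absent branches simply carry `a_b = 0`), so `T`
  is constant across samples and `qPD` values are comparable.
* **Standardization is seeded Monte-Carlo.** Rarefied `qPD` is the mean
  observed `qPD` over `B` read subsamples; the analytic branch-level
  expectations exist but the MC route is verifiable against brute force and
  identical in expectation. Extrapolation treats branches as pseudo-species
  with integer counts `n a_b` and weights `L_b`, applies the q-matched
  asymptotic machinery, and approaches it with the same completion term as
  the taxonomic side.

## Beta diversity and MRM

For a pair of samples standardized to a common coverage (expected rarefied
profiles from `B` seeded subsamples on the rarefaction side; the observed
profile when the target equals or exceeds the observed coverage, with the
pair flagged whenever the target is unreachable under the extrapolation
cap), gamma is the Hill number of the pooled mean abundances, alpha the
within-assemblage Hill number, and `beta = gamma/alpha` lies in `[1, 2]`.
Both overlap transforms are computed and reported -- the size-weighted
`C_qN` and richness-type `U_qN` -- because the conventional index names map
to different transforms per order: Jaccard is `1 - U` at `q = 0`, Horn is
`log(beta)/log 2` at `q = 1`, Morisita-Horn is `1 - C` at `q = 2`. Only
pairwise (`N = 2`) decomposition is implemented; the paper-style distance
matrices are pairwise by construction.

Environmental predictors use plain Euclidean distances on user-selected
columns (no implicit scaling; an explicit flag range-scales) and Gower
dissimilarity for categorical variables. `mrm()` regresses the unfolded
strict lower triangle of the response on the predictors by OLS and assesses
coefficients by simultaneously permuting rows and columns of the response
matrix only, the standard MRM scheme; p-values are the proportion of the
`n_perm + 1` arrangements (observed included) whose |coefficient| reaches
the observed one, so the smallest attainable p is `1/(n_perm + 1)`.
A rank-deficient design errors naming the collinear predictors.

## What the simulator emulates -- and what it does not

`simulate_dataset()` generates every pipeline input with known truth:
lognormal (skewed) community abundances, multinomial read sampling at
uneven depths, spurious count-1 pseudo-OTUs (the exact violation the
singleton filter targets), a dated coalescent family backbone with true
node ages as calibrations, JC-evolved gap-free barcode alignments on known
family subtrees, and a two-habitat block structure with partially distinct
species pools for the beta/MRM stage.

It deliberately does **not** model chimeras, index hopping, taxon-specific
amplification bias, biomass-read decoupling, alignment error or gaps, or
non-JC substitution processes. Passing tests therefore demonstrate that the
estimators recover what they claim under their own assumptions (and that
the JC distance model is matched to the generator, making NJ recovery an
honest oracle) -- not that real communities satisfy those assumptions. On
real data the filter corrects only count-1 errors, and read counts remain a
proxy whose validity rests on within-sample comparisons.

## Problem sizes and numerical conventions in the test-suite

The suite exercises deliberately small instances chosen so each check is an
exact or well-conditioned oracle: exhaustive subsample enumeration at
`n <= 12`, 1000-replicate resampling checks at `n = 2000`, 100-replicate
error-recovery runs at `n = 5000` with `k = 50` injected errors,
100 subtree-recovery simulations on 6-taxon trees with 650-site barcodes at
0.15 substitutions/site total depth (internal edges floored at 5% of the
longest edge so the generating topology is identifiable from finite
sequence), cross-depth comparisons at 2000 vs 8000 reads over 10 replicate
draws, and MRM null calibration over 300-1000 independent runs at
`n_perm = 199`. Symmetry is required to 1e-12, ultrametricity to 1e-9 on
tip-depth spread, root-finding residuals to 1e-8, and all Monte-Carlo
comparisons to three combined standard errors.

## Known limitations

* The exact closed form of the published singleton estimator differs
  between sources; the Good-Turing ratio form implemented here is the
  default and the estimator argument exists precisely so another form can
  be dropped in.
* `q = 1` interpolation and all standardized `qPD` values carry Monte-Carlo
  error of order `1/sqrt(B)`; raise `B` where tighter values are needed.
* Incidence (presence across sampling units) coverage, `q` outside
  `{0, 1, 2}`, bootstrap confidence intervals, multi-assemblage
  (`N > 2`) beta decompositions, and GAM-based inference on the exported
  diversity tables are out of scope; the tables are written for external
  modelling.
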