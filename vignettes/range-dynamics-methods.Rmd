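---
title: "Modelling range dynamics across climate periods: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling range dynamics across climate periods: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(RangeDynamics)
```

# Overview

`RangeDynamics` reconstructs the range dynamics of a species across
climate periods from presence-only occurrence records and per-period
bioclimatic raster stacks. The workflow is the standard one in
correlative niche modelling of glacial–interglacial dynamics:

1. spatial thinning of occurrence records to a minimum separation;
2. a Gaussian-kernel sampling-bias surface and bias-weighted background;
3. variable screening (pairwise Pearson pruning, jackknife contribution);
4. a maximum-entropy presence–background suitability model with
   replicated split-sample AUC evaluation;
5. clamped projection onto each period's climate, threshold-based
   binarisation (MTSS and 10th-percentile training presence);
6. contraction/expansion change classification with area/ratio
   accounting, overall-centroid and block-centroid migration vectors;
7. per-cell limiting-factor attribution.

All of it runs on projected planar grids treated as equal-area: the
package deliberately does **not** reproject. Analyses of this kind
project once (typically to an equidistant conic) and work in that plane;
the synthetic generator produces data directly in km coordinates. Grid
I/O supports ESRI ASCII grids and minimal single-band float32 GeoTIFF
(ModelPixelScale/ModelTiepoint/GDAL_NODATA tags), which this package
reads and writes itself. Grid alignment is checked to 1e-6 of a cell
width — stricter is brittle for files round-tripped through text
formats. Cell centres are the coordinate convention; row 1 is the
northernmost row.

# The maximum-entropy model

The core model is the Gibbs distribution over background cells

$$ q(x) = \frac{\exp\left(\sum_j \lambda_j f_j(x)\right)}{Z}, $$

with features $f_j$ built from the bioclimatic variables and coefficients
$\lambda_j$ chosen to maximise the penalised presence log-likelihood dual

$$ O(\lambda) = \frac{1}{m}\sum_{i \in \text{presence}} \eta(x_i)
   - \log Z_{\text{bg}} - \sum_j \beta_j |\lambda_j|, $$

where $\eta = \sum_j \lambda_j f_j$ and $m$ is the presence count. The
per-feature penalty is $\beta_j = \beta \, s_j / \sqrt{m}$ with $s_j$ the
feature's presence-sample standard deviation, floored at 0.05 of its
observed range; $\beta$ (the *regularisation multiplier*, default 1) is
the single user-facing knob.

**Features.** Linear, quadratic and hinge classes by default, mirroring
the conventional auto-feature choice for sample sizes in the tens (the
workflow targets datasets of roughly 15–80 thinned localities; larger or
smaller studies can restrict the classes). Over training bounds
$[lo, hi]$: linear is the min–max standardised value, quadratic its
square, hinge is $\max(0, (v-k)/(hi-k))$ at 16 evenly spaced interior
knots per variable. All features map clamped inputs to $[0,1]$. Constant
variables are dropped with a warning.

**Optimisation.** The objective is concave; it is maximised by monotone
proximal gradient descent (soft-thresholding for the L1 term) with
backtracking line search and Nesterov acceleration guarded so the
penalised objective never decreases. Convergence is declared at a KKT
subgradient residual below `tol` (default 1e-6). Coefficients live in a
wide box ($|\lambda_j| \le 200$): a feature that separates presences
from background perfectly would otherwise drive its coefficient to
infinity (its penalty can be smaller than the unpenalised gradient), and
the box keeps such degenerate fits finite and deterministic while being
unreachable for regular problems. Exceeding `maxIter` (default 5000) is
an error carrying the last objective value, not a silent result.

**Logistic output.** Predictions are reported on the familiar 0–1
logistic scale, $p = e^H q(x) / (1 + e^H q(x))$ where $H$ is the entropy
of the fitted distribution over the training background. The uniform
model therefore scores exactly 0.5 everywhere. Projection onto another
period's climate clamps variable values to the training bounds by
default — transfer beyond the training range is the central use here, and
clamping is the conservative convention.

**Evaluation.** Rank-based AUC (ties count one half), with `k` seeded
random splits (default 10 splits, 75% training / 25% test; the test split
takes `floor(m/4)` presences). The mapped model is refit on all
presences: replicate runs measure transferability, while the map should
use all the information available.

# Occurrence handling

**Thinning** returns the *largest* subset of localities with all
pairwise distances at least `minDistKm` (default 10 km). This is a
maximum-independent-set problem on the conflict graph; it is solved
exactly by branch and bound within each connected component of up to 25
localities, and by a seeded 1000-restart randomised greedy search for
larger components. Exactness at the scale of typical curated datasets
(tens of localities) matters because the thinned count is part of the
reported workflow; ties are broken by lexicographic id order so results
are reproducible.

**Sampling-bias surface.** Each cell receives
$\sum_i \exp(-d_i^2 / 2\sigma^2)$ over localities with $\sigma$ equal to
the search radius (default 60 km) and the kernel truncated at $3\sigma$,
then the surface is rescaled to a maximum of 1. The "search radius" of
kernel-density bias files is not a standardised convention (it could be
read as a truncation radius or an ArcGIS-style bandwidth); this package
fixes $\sigma$ = radius with $3\sigma$ truncation and documents it. With
no localities the surface falls back to uniform 1.

**Background.** 10 000 cells by default (configurable), drawn without
replacement with probability proportional to the bias surface, presence
cells eligible — the common presence-background convention. The bias
file weights *background selection* here; weighting the density estimate
instead is a different published variant and out of scope.

Note one real property of bias-file corrections that the synthetic
studies make visible: a tight kernel-density bias file concentrates the
background where the presences are, which deflates apparent AUC relative
to a background drawn from the true (usually unknowable) sampling
process. The pipeline reports what it measures.

# Variable screening

Pairwise Pearson correlations are computed over all unmasked
study-region cells (not just occurrence cells — the choice matters and
is documented; projection stability concerns the whole region).
`pruneCorrelated()` repeatedly removes one member of the most-correlated
pair above the threshold (default |r| > 0.85): the variable listed
earlier in a user-supplied physiological priority survives, otherwise
the one with lower mean absolute correlation to all others. The
jackknife refits the model with each variable alone and with all but it,
reporting regularised training gain and training AUC next to the
all-variable baseline. A contribution cutoff (variables whose alone-gain
share is below 1%) is computed and reported but never silently applied.

# Thresholds, change accounting and vectors

Two training thresholds are computed from the final model's scores:

- **MTSS** — the observed score maximising sensitivity over presences
  plus specificity over the background sample (ties break to the
  smallest threshold). The background stands in for the negative class,
  as in presence-background threshold tables.
- **10% TP** — the smallest presence score retained after excluding the
  `floor(0.10 m)` lowest-scoring training presences (an order statistic,
  so it is exact).

Binarisation marks a cell suitable iff its score is `>= t` (boundary
scores count as suitable), making suitability monotone in the threshold.

Change classification labels each cell contraction / no change /
expansion / absent. The accounting table expresses contraction and
no-change as percentages of the *early* period's area and expansion as a
percentage of the *late* period's area, rounded to one decimal, halves
away from zero — fixed-rounding so published-style tables are exactly
reproducible. The identities `early = contraction + no-change` and
`late = no-change + expansion` hold exactly on unrounded areas, and
`changeRatios()` accepts explicit period-area overrides for the case
where period areas are known at higher precision than the class
breakdown.

**Vectors.** The overall centroid is the unweighted mean of
suitable-cell centres; one vector connects the early to the late
centroid (distance in km, compass bearing clockwise from north). For the
detailed migration field, the grid is partitioned into 60 × 60 km tiles
anchored at the raster origin (deterministic and mask-independent;
partial edge tiles allowed), each tile with suitable cells contributes
the centroid of those cells, and each *late* centroid is matched to its
nearest *early* centroid — each new range patch is assigned the source it
most plausibly came from. The matching direction is a genuine ambiguity
in prose descriptions of this method; matching late-to-early was chosen
so every persisting or new patch gets a source, and early centroids
matched by nothing (extinct patches) are reported separately rather than
vectorised.

**A known aliasing limitation.** When a *contiguous* range translates
farther than one tile, nearest matching pairs each late tile-centroid
with an early centroid one tile away, and the median vector collapses
toward the cell size. Nearest-centroid matching is only identifiable
when source patches are farther apart than the displacement; the
package's shift-recovery diagnostics therefore measure recovery on
well-separated patches, and users should read dense-range vector fields
as local correspondence, not long-distance dispersal routes.

# Limiting factors

For each cell and model variable, the prediction is recomputed with that
variable replaced by its presence-sample mean (all else untouched,
clamping as in projection). The cell's limiting factor is the variable
whose substitution *raises* the logistic prediction most; cells where no
substitution helps stay unattributed. Substitution-by-presence-mean is
the convention of the established limiting-factor tooling; substituting
each variable's univariate optimum is a different convention and out of
scope. Shares within a change class are cell counts (the grid is
equal-area, so counts and areas are proportional), printed to one
decimal, descending, with the unattributed remainder reported — so
shares sum to 100% minus the unattributed share, exactly.

# The synthetic study system

`syntheticSpec()` defines a fully known ground truth so every stage is
testable offline:

- **Fields.** Each variable is a smooth planar gradient (direction
  varying by variable) mixed with spatially autocorrelated noise (white
  Gaussian noise smoothed at 60 km), standardised, then scaled to
  natural units (°C, mm, seasonality units). Designated pairs are mixed
  to a target Pearson correlation by empirical orthogonalisation, so the
  realised cell-level correlation hits the target (default: bio1–bio9 at
  r = 0.9, which exercises the pruning stage at the 0.85 cutoff).
- **Periods.** Three periods by default — a glacial "LGM", a "present"
  baseline, and a warmed "2080" — with purely additive per-variable
  offsets. The defaults contract the suitable range to roughly a quarter
  to a third of the baseline under the glacial offsets and expand it by
  roughly half under the future ones, the magnitude of change reported
  for glacial-relict tree species.
- **Truth and sampling.** True suitability is the logistic of a linear
  predictor on standardised variables. The default coefficients
  (|coef| ≈ 1.25–3.75, intercept −5) emulate a range-restricted,
  strongly climate-determined species: about a fifth of the region is
  suitable and the fitted models reach AUC ≈ 0.9, the regime in which
  these analyses are published. Presences are drawn without replacement
  with probability proportional to truth × bias, where the sampling bias
  is a Gaussian kernel centred off-centre in the region (collections
  cluster near accessible areas).
- **Sizes.** 120 × 120 cells of 10 km, six variables, 200 presences and
  5000 background cells for the recovery studies; smaller grids
  (44–60 cells a side) for fast unit fixtures. These sizes keep the full
  test suite in the tens of seconds while leaving the estimation problem
  genuinely hard (biased sampling, correlated predictors, autocorrelated
  noise).

What the generator does *not* emulate: topography and coastlines (no
mask by default), dispersal limitation, observation error in the
localities, and disequilibrium between climate and occupancy. Passing
recovery tests on this system shows the estimator and accounting
machinery are correct; it does not validate the ecological assumptions
(niche conservatism, equilibrium) any more than a real analysis can.

# Determinism

Every random stage takes an explicit seed; the pipeline derives one
stream per stage from the master seed by stage-name hashing, so changing
the replicate count cannot perturb the background draw. Two runs with
the same configuration and seed produce byte-identical CSV outputs and
identical manifest hashes; the manifest records per-file MD5 sums, the
evaluation summary, thresholds, change tables and any warnings, and on
failure it records the failed stage before the error propagates.

# Worked example

```{r example, eval = FALSE}
spec <- syntheticSpec(seed = 1)
fix <- tempfile()
writeFixture(spec, fix)

man <- runPipeline(list(
  stackDirs = list(LGM = file.path(fix, "LGM"),
                   present = file.path(fix, "present"),
                   `2080` = file.path(fix, "2080")),
  occurrencePath = file.path(fix, "occurrences.csv"),
  outDir = tempfile(), seed = 1,
  backgroundN = 5000, replicates = 10))

man$meanTestAUC        # replicated split-sample test AUC
man$thresholds         # MTSS and 10% TP
man$changeTables       # per-transition contraction/no-change/expansion
```

The acceptance script (`scripts/acceptance.R`) runs the same machinery
end-to-end and writes its measured quantities as JSON; see the README
for how to reproduce its numbers.
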