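# RangeDynamics

Reconstructing species range dynamics across climate periods from
presence-only occurrence records.

Correlative niche modelling of glacial–interglacial (and future) range
shifts is a standard workflow in biogeography and conservation
planning: occurrence localities are linked to bioclimatic raster layers
by a presence–background maximum-entropy model, the fitted suitability
surface is projected onto the climate of other periods, binarised with
training thresholds, and the resulting per-period ranges are compared —
how much area contracted or expanded, where the range centroid moved,
which climate variable limited suitability where. `RangeDynamics`
implements that entire workflow as a tested, deterministic R package
for people who want the analysis reproducible and runnable offline:
every stage is an exported function, a synthetic generator with known
ground truth exercises the pipeline end-to-end, and a config-driven
runner writes a hash-stamped manifest.

## The model

The suitability model is the Gibbs distribution over background cells

q(x) = exp( Σ_j λ_j f_j(x) ) / Z,

with linear, quadratic and hinge features f_j of the bioclimatic
variables, fitted by maximising the L1-penalised presence
log-likelihood dual

O(λ) = mean_presence(η) − log Z_bg − Σ_j β_j |λ_j|,   η = Σ_j λ_j f_j,

with per-feature penalty β_j = β·s_j/√m (presence-sample sd, floored).
Predictions use the logistic output p = e^H q / (1 + e^H q), where H is
the entropy of the fitted distribution, so the uninformative model
scores exactly 0.5. Around the model sit: distance-constrained
occurrence thinning (exact maximum independent set at typical dataset
sizes), a Gaussian-kernel sampling-bias surface with bias-weighted
background selection, Pearson/jackknife variable screening, MTSS and
10th-percentile-training-presence thresholds, contraction/expansion
accounting with fixed rounding rules, overall- and block-centroid
migration vectors, and per-cell limiting-factor attribution. The
methods vignette (`vignettes/range-dynamics-methods.Rmd`) documents
every convention and design choice.

## Worked example

```r
library(RangeDynamics)

spec <- syntheticSpec(seed = 1)        # 120 x 120 km-grid, 6 variables,
fix  <- tempfile()                     # 3 periods, 200 biased presences
writeFixture(spec, fix)

man <- runPipeline(list(
  stackDirs = list(LGM = file.path(fix, "LGM"),
                   present = file.path(fix, "present"),
                   `2080` = file.path(fix, "2080")),
  occurrencePath = file.path(fix, "occurrences.csv"),
  outDir = tempfile(), seed = 1,
  backgroundN = 5000, replicates = 10, doJackknife = FALSE))
```

The run prints one line per stage and returns a manifest. With seed 1:

```
man$meanTestAUC
#> [1] 0.6648678
man$thresholds$mtss
#> [1] 0.4588329
```

The replicated test AUC of 0.66 is the model evaluated against a
background drawn from the *estimated* bias file (a 60-km kernel density
of the thinned occurrences): concentrating the background where the
presences are is exactly what a bias-file correction does, and it
deflates apparent AUC. The same model fitted against a background drawn
from the generating sampling kernel reaches a mean test AUC of 0.90,
and its suitability ranking matches the generating truth at a Spearman
correlation of 0.97 over all 14 400 cells — numbers you can recompute
with the acceptance script below. The manifest also carries the
per-transition change tables (`man$changeTables`), the per-period areas
under both thresholds (`man$areas`), and MD5 hashes of every output
file; rerunning with the same seed reproduces the hashes byte for byte.

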