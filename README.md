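# hookmorph

Geometric-morphometric and phylogenetic-comparative analysis of hook-like
parasite attachment structures.

Cymothoid isopods are obligate fish ectoparasites that attach externally to
the skin, inside the branchial chamber, or in the mouth. Each of their
walking limbs (pereopods) ends in a recurved claw-like segment, the
*dactylus*, whose shape is hypothesised to reflect the functional demands of
the attachment site. This package implements the full analysis chain for
testing that hypothesis from 2D landmark data: does dactylus shape depend on
parasitic mode, on size (allometry), on their interaction — and does the
signal survive correction for shared ancestry?

It is written for morphometricians and parasite ecologists who have
landmark configurations in TPS format, a specimen table, and an ultrametric
phylogeny, and want the complete pipeline (alignment through permutation
tests) with every stage scriptable and testable. A built-in synthetic-data
generator produces TPS/metadata/Newick bundles with known effects, so every
stage of the pipeline can be validated without any real specimens.

## Methods at the core

* **Generalised Procrustes Analysis** with sliding semi-landmarks.
  Configurations are 42 points: 3 fixed landmarks and 39 semi-landmarks on
  two curves (13 medial, 26 lateral). Semi-landmarks slide along local
  tangents to minimise the Procrustes distance to the consensus. Centroid
  size CS = sqrt(sum_i ||x_i − x̄||²) is the size measure.
* **Quality control**: Tukey-fence outlier screening on each specimen's
  Procrustes distance to the consensus (flags are reported, never silently
  applied), and digitisation repeatability from replicated landmark sets via
  nested Procrustes ANOVA, R = s²_among / (s²_among + s²_within).
* **RRPP shape regression**: the sequential (type I) model
  `shape ~ size + mode + size:mode` on retained PC scores, every term
  evaluated by the residual randomisation permutation procedure —
  reduced-model residuals are permuted, the trace-based F recomputed, and
  effect sizes reported as standard deviates (z) of log F in the permutation
  distribution. Pairwise tests compare allometric slope angles and
  size-adjusted group mean shapes; an allometry-free comparison on
  shape-on-size residuals is gated on a common allometry.
* **Phylogenetic re-analysis**: phylogenetic PCA (GLS-centred evolutionary
  covariance), Pagel's λ estimated by REML on the full-model residuals
  (off-diagonals of the Brownian covariance C scaled by λ), and PGLS run by
  whitening response and design with C(λ)^(−1/2) before the identical RRPP
  machinery. Phylomorphospaces place internal nodes by maximum-likelihood
  Brownian ancestral states.

## Worked example

```r
library(hookmorph)
sim <- simulate_dataset(simulation_spec(seed = 1))   # 18 species, 126 specimens
res <- run_pipeline(sim$dataset, n_perm = 999, seed = 2)
print(res)
```

```
Shape-analysis pipeline (OLS, 126 specimens, 18 species)
       term df     SS     R2       F      Z     p
1      size  1 0.0309 0.5785 42.9564 2.9748 0.001
2      mode  2 0.0113 0.2115  7.8534 2.4175 0.005
3 size:mode  2 0.0026 0.0483  1.7942 0.8288 0.226
4 residuals 12 0.0086 0.1616      NA     NA    NA
5     total 17 0.0534 1.0000      NA     NA    NA
 -  repeatability: 97.3% (variance components) on 30 specimens
 -  0 specimen(s) flagged as consensus-distance outliers (0 species-consistent); all retained
 -  ordination: 12 components retained, PC1+PC2 = 98.0%
```

Reading the output: digitisation noise accounts for under 3% of shape
variation (repeatability 97.3%), so the landmarks are trustworthy. At
species level, both size (z = 2.97, p = 0.001) and parasitic mode (z = 2.42,
p = 0.005) have large significant effects on dactylus shape, while the
size-by-mode interaction does not (p = 0.23) — allometry is shared across
modes, so the size-adjusted pairwise mean comparisons in `res$means` are
interpretable, and indeed recover the generated contrast between the
externally-attaching group and the internal (gill/mouth) attachers.

The phylogenetic variant adds a tree:

```r
resp <- run_pipeline(sim$dataset, tree = sim$tree, phylogenetic = TRUE,
                     n_perm = 999, seed = 3)
resp$lambda          # REML estimate of Pagel's lambda on model residuals
resp$phylomorphospace
```

## Analysis workflow

The `analysis/` directory holds the numbered stage drivers, each a thin
narrative script over the package functions, writing tables under
`results/`:

1. `01_simulate.R` — generate the synthetic study bundle (TPS, metadata,
   Newick, truth log) and the calibration fixtures.
2. `02_align_qc.R` — GPA with sliding; outlier screen; repeatability.
3. `03_ordination.R` — two-stage species GPA, PCA, backtransformed shapes
   along PC1, morphospace scores.
4. `04_models_ols.R` — RRPP ANOVA, slope homogeneity, pairwise means,
   allometry-free comparison.
5. `05_models_pgls.R` — pPCA, REML λ, PGLS re-analysis, phylomorphospace.

Run them in order from the repository root: `Rscript analysis/01_simulate.R`
and so on.

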