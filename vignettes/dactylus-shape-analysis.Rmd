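---
title: "Shape of parasite attachment hooks: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Shape of parasite attachment hooks: models, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hookmorph)
```

This vignette is the package's own account of its methods: what is being
modelled, which knobs matter, what the synthetic-data generator does and
does not emulate, and where genuinely open design choices were settled.

## The scientific question

Cymothoid isopods attach to fish in one of three sampled microhabitats —
externally on the skin, in the branchial chamber ("gill"), or in the buccal
cavity ("mouth"). Every pereopod ends in a recurved dactylus that does the
gripping. The analysis asks whether dactylus *shape* is predicted by
parasitic mode, by size (allometry), by their interaction, and how much of
the apparent mode signal is instead attributable to shared ancestry.

Shape is captured as 42 two-dimensional points per dactylus: 3 fixed
landmarks (joint, distal tip, and a lateral point placed where a line at 5
degrees from the joint-tip chord crosses the lateral edge — a construction
that removes joint-shape information at the same relative point in every
specimen) and 39 semi-landmarks along two curves (13 medial, 26 lateral;
the lateral edge is roughly 1.5–2 times the medial length).

## Superimposition

`gpa()` implements Generalised Procrustes Analysis: every configuration is
centred, scaled to unit centroid size, and rotated (proper rotations only —
reflections are disallowed, so a mirrored digitisation shows up as a large
distance rather than being silently absorbed) onto the evolving consensus
until the root-mean-square change of the consensus is below `tol = 1e-8` or
`max_iter = 100` iterations have run. Non-convergence flags the fit rather
than erroring. The consensus orientation is pinned by aligning it to the
first configuration in input order; together with the principal-component
sign convention below this makes every downstream number deterministic.

Semi-landmarks slide along their local tangent — the chord between their
neighbours along the curve, with the fixed landmarks anchoring the curve
ends — by the closed-form projection of the residual to the consensus onto
the tangent. This is the Procrustes-distance criterion: each slide can only
reduce a point's distance to the consensus, a property the test suite
checks on randomised configurations. One deliberate restriction: sliding
passes are applied only for the first `slide_iter = 5` GPA iterations.
Iterating the distance criterion indefinitely is degenerate — the consensus
follows the semi-landmarks, which then migrate collectively along the
outline and pile up in low-variance regions. A handful of passes achieves
the intended repositioning, after which plain alignment iterations converge
normally. The bending-energy criterion, which does not have this failure
mode, is intentionally out of scope because the analysis design specifies
distance-based sliding.

Species-level shapes come from a second GPA over the per-species means of
the aligned specimens (`species_mean_gpa()`). No sliding is done at the
second stage by default: the semi-landmarks were already slid at specimen
level, and re-sliding means of slid points against a different consensus
would re-open positions that are no longer tied to outlines. Species size
is the mean of specimen log centroid sizes.

## Quality control

`flag_outliers()` computes each specimen's Procrustes distance to the
consensus and applies a Tukey fence (Q3 + 1.5 IQR; a plain upper-quartile
option exists). Flagged specimens whose conspecifics are all flagged too
are annotated *species-consistent* — joint displacement of a whole species
is genuine shape information, not digitisation error. Nothing is ever
removed automatically; retention is an analyst decision the pipeline logs.

`repeatability()` aligns replicated digitisations in one GPA and partitions
squared Procrustes variation into among-specimen and within-specimen
(digitisation) strata. Two estimators are reported because the informal
phrase "share of error attributable to replicates" is ambiguous between
them: the variance-components repeatability
R = s²_among / (s²_among + s²_within), which is the headline number, and
the mean-square share 100·(1 − SS_within/SS_total). They agree closely in
the high-repeatability regime where the data should live.

## Ordination

`shape_pca()` is an eigendecomposition of the covariance of the flattened
species coordinates. Variance proportions are over non-zero eigenvalues
(relative tolerance 1e-10 on singular values defines "zero"). Each loading
vector's largest-magnitude element is made positive — an arbitrary but
deterministic sign convention that stabilises plots and tests. Downstream
models retain `min(12, rank)` components; with 18 species the rank is 17,
and the retained 12 carry essentially all variance. The RRPP statistics are
trace-based and therefore invariant to orthogonal rotation of the response,
so using PC scores rather than raw Procrustes coordinates changes nothing —
a property the tests assert rather than assume.

`phylo_pca()` implements phylogenetic PCA: the species deviations from the
GLS mean a = (1'C⁻¹1)⁻¹1'C⁻¹X are weighted by the inverse Brownian
covariance to form the evolutionary covariance R = X_c'C⁻¹X_c/(n−1), whose
eigenvectors define the axes. Scores are unweighted projections of the
centred data (the "cov" convention of standard implementations). The
default covariance is pure Brownian motion (λ = 1); a λ-scaled covariance
can be supplied, but is not the default because the conventional pPCA is
the Brownian one.

`ancestral_states()` gives maximum-likelihood Brownian estimates for
internal nodes via the GLS/BLUP closed form — equivalent to weighted
squared-change parsimony — and `phylomorphospace()` projects tree edges
through those estimates in any score plane. Ancestral estimation is linear,
so estimating on scores or on shapes-then-projecting commute; this too is
asserted in tests. Zero and near-zero branch lengths are floored at 1e-8 of
tree height before matrix inversion.

## RRPP models

`fit_rrpp()` fits the sequential (type I) model
`shape ~ size + mode + size:mode`. For each term the reduced model contains
all preceding terms; its residuals are permuted whole-row (full shuffles,
not sign flips), re-added to the reduced fit, and the trace-based
F = (SS_term/df_term)/(SS_res/df_res) recomputed, with the residual SS
taken from the full model refitted to each permuted response. P-values are
(b + 1)/(n_perm + 1) counting the observed arrangement; effect sizes are
standard deviates of log F within the permutation distribution (the log
transform is the normalising convention for F-like statistics; distances
and angles in the pairwise tests are left untransformed). A permutation
distribution with zero spread yields z = 0 by definition.

Pairwise machinery:

* `test_slope_homogeneity()` — angles (degrees) between per-group
  multivariate allometric vectors extracted from the full-model
  coefficients, permuted under the additive (common-slope) null;
* `pairwise_group_means()` — Euclidean distances in score space (equals
  Procrustes distance between the corresponding shapes) between
  least-squares group means at the common mean size, permuted under the
  size-only null;
* `allometry_free_test()` — the mode test repeated on residuals of the
  shape-on-size regression. This is only meaningful under a common
  allometry, so a significant interaction (at 0.05) stops the function
  unless explicitly overridden, in which case it warns.

Pairwise p-values are reported raw (no multiplicity adjustment), matching
the reporting convention of this analysis family; a Holm option would be a
one-line wrapper for users who want it.

## Phylogenetic weighting

`estimate_lambda_reml()` estimates a single Pagel's λ for a multivariate
residual matrix by maximising the *sum of per-column univariate REML
log-likelihoods* under σ²_j·C(λ), with each column's variance profiled out.
The choice of one shared λ — rather than per-column estimates averaged, or
λ from the first component only — uses all response columns symmetrically
and returns one number per dataset, which is what a single correction
matrix requires; with only a handful of residual degrees of freedom per
column the pooled estimate is also much more stable. The residuals used are
those of the *full* OLS model (size, mode, interaction), so λ measures
phylogenetic signal in what the ecological model cannot explain. The search
is a 21-point grid on [0, 1] refined by local optimisation; the profile is
returned for inspection. Trees are rescaled to unit height first — λ is
scale-free, and conditioning improves. The estimator is validated in tests
against the `nlme::gls`/`corPagel` reference on single traits and by
recovery simulations (iid data push λ̂ to 0, pure-Brownian data to 1).

`pgls_rrpp()` then whitens: with C(λ) = EΛE', the transform P = EΛ^(−1/2)E'
(the symmetric inverse square root, not a Cholesky factor, so the result
does not depend on species ordering) is applied to the response and every
design matrix, after which residuals are exchangeable and the entire RRPP
machinery — sequential SS, permutations, pairwise comparisons — runs
unchanged on the transformed data. Exactly diagonal covariances take a
shortcut through element-wise scaling, so an identity covariance is a true
no-op and PGLS then reproduces OLS bit-for-bit at the same seed, which the
test suite checks. Group means for the pairwise tests are built from the
GLS coefficients with untransformed contrast rows, i.e. they are the
phylogenetically weighted least-squares means.

## The synthetic-data generator

`simulate_dataset()` emulates the data-collection design the analysis
expects, so that every stage is testable without specimens:

* a pure-birth tree rescaled to unit height;
* species latent parameters — curvature, aspect, proximal width of a
  claw-like template — evolving as base + mode effect + λ-damped Brownian
  deviations. Effects act in this three-parameter latent space rather than
  on landmarks directly, which gives the leading PC axes a known monotone
  relationship to interpretable anatomy (PC1 tracks curvature in tests);
* individuals adding an allometric latent displacement proportional to
  centred log centroid size, individual latent noise, and log-normal sizes;
* per-digitisation isotropic landmark noise, with a random subset of
  specimens digitised twice for repeatability estimation.

Default design (chosen once to mirror the motivating sampling design): 6
species in each of the three modes, 7 individuals per species (126
specimens; every species at least 3 individuals, every mode at least 26),
30 re-digitised specimens, digitisation noise of 0.4% of the template chord
(putting repeatability in the high-90s, where a careful operator sits),
externally-attaching species larger (mean centroid size ≈ 7.5 physical
units) and more strongly recurved than gill/mouth attachers, a modest
positive allometry of curvature on log size, and weak phylogenetic signal
(λ_true = 0.25) on top of Brownian rates of a few percent of the parameter
ranges. The mode displacement is set large relative to the between-species
noise so that the external/internal contrast separates cleanly in
morphospace, as the motivating system does.

What the generator does *not* emulate — and what passing tests therefore do
not show about real data: digitisation error is isotropic and independent
across landmarks (real tracing error is correlated along outlines and
larger near ambiguous curve ends); the latent space is three-dimensional,
so species shapes occupy a much lower-dimensional manifold than real
dactyli (PCA shares concentrate on fewer axes than in real datasets);
modes are assigned to species at random rather than clustered on the tree,
so mode and phylogeny are unconfounded by construction — the hard
real-world case where they covary is exactly what the PGLS step exists for
and cannot be certified by these simulations; and there is no model of
specimen preparation artefacts, missing landmarks, or operator drift.

Fixtures (`fixture_spec()`): reduced 3-individual bundles in three regimes —
`null` (no effects, no signal; used for type-I error checks),
`mode_effect` (default displacements, low individual noise; power checks),
`phylo_signal` (pure Brownian motion, no mode effect; λ recovery). Same
seed, same bytes out.

## Numerical choices, in one place

| choice | value | why |
|---|---|---|
| GPA convergence | RMS consensus change < 1e-8, ≤ 100 iterations | deterministic tests; far below data noise |
| sliding passes | 5 | distance-criterion crawl (see above) |
| orientation | consensus aligned to first configuration | deterministic; avoids axis-flip surprises |
| PCA rank cut | singular value > 1e-10 × largest | separates true zeros from noise |
| loading signs | largest element positive | deterministic plots/scores |
| branch-length floor | 1e-8 × tree height | invertible covariances |
| λ search | 21-point grid + local refine on [0, 1] | profile can be flat near boundaries |
| permutation p | (b + 1)/(n_perm + 1) | observed counts as one arrangement |
| z transform | log F; identity for distances/angles | normalising convention for F |
| outlier fence | Q3 + 1.5 IQR | standard Tukey; quartile option retained |

Test problem sizes were chosen to probe each property at the smallest scale
that exercises it: calibration uses 1000 null data sets of 18 species × 12
response dimensions at 199 permutations; λ recovery uses 100 simulations
per regime on 30-tip trees; power and error control of the end-to-end
pipeline use 100 seeded runs of the reduced fixtures at 499 permutations.

## Known limitations

Only 2D configurations and complete landmark sets are supported (missing
landmarks error out — the analysis design assumes complete outlines).
Sliding offers the Procrustes-distance criterion only. The RRPP engine
implements sequential (type I) sums of squares only, which is what a
nested size/mode/interaction design wants; there are no type II/III
options, no mixed models and no trajectory analysis. λ is the only
branch-length transform (no OU or early-burst), bounded to [0, 1] with no
extrapolation. Tree inference and ultrametricisation are out of scope: the
pipeline consumes an ultrametric Newick tree as input and warns, not
errors, when root-to-tip distances are unequal.
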