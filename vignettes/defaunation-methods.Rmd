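---
title: "Reconstructing assemblage defaunation: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing assemblage defaunation: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The problem

Regional defaunation — the decline and local extirpation of medium- to
large-bodied mammal populations — is usually invisible to snapshot surveys:
a site's contemporary species list says nothing about which species *should*
co-occur there under intact conditions. `defauna` reconstructs that missing
baseline and quantifies what was lost. It contrasts two spatially explicit
estimates per species:

* a **historical (potential) distribution**, from a presence–background
  maximum-entropy distribution model driven by climate and terrain, which
  approximates the fundamental niche free of modern land-use constraints;
* a **contemporary distribution**, interpolated from compiled local
  assemblage inventories by inverse distance weighting (IDW).

Stacking the per-species binary maps gives historical and contemporary
richness surfaces; their difference `D = S_hist - S_cont` is the defaunation
surface. Downstream metrics quantify assemblage *downsizing* (loss of
aggregate and mean body mass), per-species geographic range loss, the loss
of functional richness (FRic), and the drivers of defaunation via gradient
boosted trees with Shapley-value attribution.

Every stage is verifiable because the package ships a fully specified
virtual world: smooth correlated environmental fields, a pool of virtual
species with known Gaussian niches and body masses, human-pressure surfaces
and protected areas, and a logistic ground-truth extirpation process. All
acceptance checks are parameter-recovery exercises against that truth.

# The virtual world

`world_config()` fixes every study condition; `simulate_world()` is fully
deterministic given the configuration (including its seed).

* **Region**: a 100 × 100 grid of 1-km planar cells. All geometry in the
  package is planar; geographic inputs must be projected first.
* **Environment**: ten bioclim-style layers plus elevation, built as sums of
  low-frequency sinusoids (correlation length 25 cells) plus light noise,
  rescaled to plausible bioclim ranges. The first layer is generated as a
  near-copy of the second so the stack always contains an |r| ≥ 0.8 pair and
  the collinearity pre-screen has genuine work to do (it retains 10 of 11
  layers, mirroring a typical bioclim screen).
* **Species pool**: 51 virtual species. Each responds to 2–3 layers with
  Gaussian niches, `suit(cell) = prod_k exp(-(x_k - mu_k)^2 / (2 sigma_k^2))`;
  the true range is the upper half-maximum set `suit >= 0.5 * max`. Optima
  are drawn from the conditions of a random cell but shrunk 35% toward the
  regional median, which makes ranges overlap in a mid-domain richness
  hotspot — the richness gradient real faunas show. Niche breadths
  (`sigma` between 0.5 and 1.0 spatial SDs of a layer) keep ranges clear
  enough that presence–background models are learnable (range prevalence
  ~0.1–0.2). Body mass is log-uniform on 300 g – 300 kg; each species gets
  one feeding guild (of nine) and one locomotion mode (of five).
* **Sites**: 73 assemblage sites, stratified over blocks for spatial
  coverage, but within a block each site takes the faunally richest of six
  candidate cells. The bias is deliberate: compiled assemblage datasets
  over-represent well-surveyed, faunally rich localities, and the
  ≥ 5-species inclusion rule downstream presupposes such sites exist.
* **Pressures**: livestock (`ls`), cropland (`crop`) and pasture (`past`)
  proportions in [0, 1], mutually correlated through a shared latent field;
  a normalized human-footprint index (`hfp`) constructed with an exact
  in-sample correlation of 0.7 with `ls`; above-ground woody biomass
  (`agb`, 0–300 Mg/ha) positively tied to the precipitation-like layer; and
  rectangular protected areas (strict ~18% of area, sustainable-use ~12%)
  rasterized to per-cell protected area.
* **Extirpation truth**: for species *s* historically present at site *j*,
  `P(extirpated) = plogis(-4.8 + 0.5 log10(mass_g) + 2.5 hfp_j + 2.5 ls_j -
  2.5 [strict PA])`. These coefficients give a realized extirpation fraction
  around 0.3, a strong body-mass bias (large-bodied species roughly twice as
  likely to disappear), near-complete persistence inside strict reserves,
  and a wide spatial contrast in loss along the pressure gradient — the
  qualitative regime described for heavily defaunated dry-forest faunas.
  Sites whose surviving assemblage drops below five species are excluded,
  exactly like the inclusion rule for exhaustively sampled assemblages.

What the generator does **not** emulate: detection error and sampling effort
differences among sites (incidences are perfect draws from the truth),
dispersal limitation and biotic interactions (niches are the whole story),
commission in the contemporary data (off by default), and temporal dynamics.
Passing recovery tests therefore shows the estimators are consistent under
clean sampling, not that they are robust to survey artefacts.

# Historical distribution models

The historical stage is a presence–background maximum-entropy model fit in
the package (no external MaxEnt binary):

* **Pre-screen**: greedy scan in input order drops any layer with |Pearson
  r| ≥ 0.8 against an already-retained layer.
* **Features**: linear + quadratic + pairwise-product expansions of the
  retained layers, min–max scaled to [0, 1] over the background (all valid
  cells up to 10,000, else a seeded subsample). Hinge features are omitted:
  with Gaussian niches the log-density is exactly quadratic, so the feature
  class is sufficient, convex and closed-form checkable.
* **Fit**: maximize the L1-penalized Gibbs log-likelihood
  `L(lambda) = lambda·fbar - log Z - sum_j beta_j |lambda_j|` by cyclic
  coordinate descent (Newton steps, soft-thresholding, backtracking). The
  objective is non-decreasing by construction — an invariant the tests
  assert. An active-set strategy (full scans every tenth sweep) and warm
  starts across evaluation replicates keep the 51-species stack at roughly
  4–5 minutes on one core. Convergence stops when a full scan gains less
  than `obj_tol` relative objective (1e-5 for the pipeline; tighter for the
  closed-form unit tests).
* **Penalty**: `beta_j = beta_scale · sd_presence(f_j) / sqrt(n_presence)`.
  The default multiplier is 0.2: on simulated Gaussian niches the classical
  multiplier of 1 over-shrinks the quadratic terms and leaves test AUC a few
  points below the information ceiling of the data, while 0.2 tracks that
  ceiling without measurable overfitting (test AUC ≈ train AUC across
  replicates).
* **Evaluation**: ten replicates, each holding out 10% of presences; ROC
  AUC of held-out presences against the full background with ties counted
  one half. The reported surface is the mean of the replicate models'
  suitabilities (Gibbs probabilities rescaled to a maximum of 1).
* **Threshold**: of the four standard candidates (minimum training
  presence, 10th-percentile training presence, equal sensitivity–
  specificity, maximum sensitivity + specificity), the rule yielding the
  smallest predicted area wins — the conservative "smallest potential
  habitat" choice; ties go to the larger threshold.

On the default world this stack attains mean test AUC ≈ 0.93 and mean
Jaccard overlap ≈ 0.7 with the true ranges — close to the information
ceiling set by niche breadth (scoring cells by the *true* suitability gives
AUC ≈ 0.94).

# Contemporary surfaces and defaunation metrics

IDW uses power 2 and a global neighbourhood by default (both exposed in
`idw_config()`), returns a sample's exact value when a cell centre
coincides with it (tolerance 1e-9 cell sizes), and — with positive weights —
can never leave the range of the data. The per-species contemporary maps
threshold the interpolated incidence at 0.5 with the ≥ convention.

The defaunation raster keeps local gains (negative `D`) rather than
clamping; percent loss is only defined where historical richness is
positive, and area summaries report the severe (>50%), moderate (20–50%),
light (0–20%) and gain bands as fractions of valid cells — bands that
always partition to one. Because assemblage sites are (realistically)
biased toward rich faunas while the stacked model predicts the whole
region, IDW extrapolation inflates contemporary richness over poor areas;
the "gain" band absorbs that artefact, and per-hexcell responses remain
informative along the pressure gradient. Hexagonal summary cells are
flat-top regular hexagons (5 km edge, 64.95 km² each), anchored at the
region's bounding-box corner and ordered north-to-south then west-to-east
for reproducibility; a raster cell belongs to the hexagon containing its
centre.

Downsizing compares aggregate and mean body mass per site between the
reconstructed historical composition (binary map value in the cell holding
the site — no buffer) and the contemporary assemblage. Retained fractions
can exceed one where model omission makes the reconstructed baseline too
light; the protection comparison in the acceptance suite therefore runs on
the simulated world's realized (true) compositions, where the estimand is
unambiguous. The Tukey-Kramer table uses the studentized-range distribution
(`stats::ptukey`) with Kramer's unequal-n adjustment.

# Functional diversity

Traits are body mass (log10-transformed before distance computation, since
masses span three orders of magnitude; disable via `mass_transform`), nine
binary guild columns and five binary locomotion columns. Gower distances
weight all traits equally; constant continuous traits are excluded with a
warning. PCoA double-centres the squared distances; when a materially
negative eigenvalue appears (|lambda_min| > 1e-8 of the largest) the
Cailliez additive correction is applied — the choice compatible with the
standard dbFD workflow. Embedding quality `R2(m)` is the squared Pearson
correlation between original and embedded distances; the default axis
count is the smallest `m` with `R2 > 0.75` (capped at 4; on the default
trait scheme this lands at m = 4).

FRic is the exact convex-hull volume of a community in the first `m` axes,
standardized by the pool's hull so the full pool scores 1. Hull volumes are
computed exactly for d ≤ 4 by supporting-hyperplane enumeration with
recursive facet decomposition (coplanar facets are projected into the
hyperplane and measured in d−1 dimensions), cross-checked in the tests
against closed forms and an independent computational-geometry
implementation. Communities with richness ≤ m cannot span an
m-dimensional hull; they are measured in their first `richness - 1` axes
against the pool in that same subspace and flagged `reduced_dim`;
single-species communities are flagged degenerate with FRic 0. FD loss is
historical minus contemporary standardized FRic; negative values are
possible under commission and are preserved.

# Driver models

The hexcell defaunation response is regressed on the six driver covariates
with stochastic gradient boosting of depth-limited least-squares trees.
Split search is greedy variance reduction with deterministic tie-breaking
(lowest feature index, then lowest split value), so fits are exactly
reproducible. Tuning is a seeded random search (trees 50–1000, depth {1, 2,
3, 5}, shrinkage log-uniform on [0.01, 0.3], subsample [0.5, 1]) scored by
10-fold cross-validated RMSE on the 75% training split; the winner is refit
on the full training set and reported with train/test R² and RMSE.

Attribution uses interventional Shapley values: the value of a coalition is
the mean prediction with coalition features pinned to the observation and
the rest drawn from the background. With six drivers all 64 coalitions are
enumerated, so local accuracy (base + Σφ = prediction) holds to 1e-9 and
there is no Monte-Carlo error; beyond 12 features a seeded permutation
sampler takes over. Reported summaries are mean |φ| importance and a sign
trend (correlation of φ with the feature value); on the default world the
true drivers (`ls`, `hfp`) outrank the habitat covariate (`agb`) and
protected area is the only covariate with a negative trend.

# Numerical choices and degenerate inputs

* Raster I/O is plain-text ESRI ASCII grid with 17 significant digits, so
  write→read round trips are bit-exact; the CRS label travels in a `.prj`
  sidecar. Alignment of rasters is exact-match on origin, cell size,
  dimensions and CRS label.
* Terrain slope uses Horn's 8-neighbour method with replicated edges; the
  steep-slope mask uses a strict `>` so an exactly-45° plane is not flagged.
* The studentized-range, hull, maxent and tree codes all treat ties
  deterministically (documented in the respective help pages), so a fixed
  seed reproduces every artifact byte-for-byte.
* Degenerate cases return flagged values rather than NA surprises: empty
  zonal zones are missing, single-species communities have FRic 0, constant
  responses yield zero-tree ensembles, zero-variance responses report R² as
  missing.

# Problem sizes

The shipped analyses run at desk scale on one core: the default world
(100 × 100 cells, 51 species, 73 sites, 120 occurrence records per species,
10 evaluation replicates per species) takes about five minutes end-to-end,
with the distribution-model stack dominating. The acceptance workflow uses
a 10-candidate random search for the driver model; the package default is
25 candidates. Unit tests use a 40 × 40 world with 40 species and gentler
extirpation so every stage still has sites to work with.

# Known limitations

* The historical baseline inherits every bias of presence–background
  modelling: commission in climatically suitable but historically
  unoccupied areas, omission where occurrence sampling is thin.
* IDW extrapolates site values across unsampled space with no uncertainty;
  kriging-style variance surfaces are out of scope.
* Hull-based FRic is undefined above four ordination axes (exact volumes
  only); communities poorer than the axis count are measured in reduced
  subspaces, which makes their standardized FRic non-comparable across
  different reductions (the flag records this).
* The GBM driver analysis is correlational; confounding between the
  environment (through the historical baseline) and pressure covariates is
  attenuated but not eliminated by the attribution method.
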