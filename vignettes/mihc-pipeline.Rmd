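---
title: "Methods: from stained rounds to spatial immune phenotypes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from stained rounds to spatial immune phenotypes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

mihcflow implements the computational half of a sequential chromogenic
multiplex immunohistochemistry (mIHC) experiment: a tissue section is
stained with one AEC-visualised marker per cycle (plus a hematoxylin nuclear
counterstain), imaged in brightfield, stripped, and re-stained, yielding one
RGB image per marker for the same region of interest (ROI). The package
turns such a stack into a single-cell table, assigns phenotypes two ways
(hierarchical gating and unsupervised sparse subspace clustering), and
quantifies spatial organisation. Because public mIHC cohorts of this design
are rare, the package also ships a synthetic-tissue generator with complete
ground truth; every claim the test suite makes is checked against that
truth or against independent brute-force oracles.

## Synthetic tissue

`archetype()` fixes, per simulated phenotype, which of the ten panel markers
(CD45, CD3, CD8, FOXP3, CD20, CD68, CSF1R, CD163, CD1C, KI67) are positive
and two intensity levels on a unit scale: `mean_high` (default 0.45) for
positive markers and `mean_low` (0.02) for background, each multiplied by a
lognormal factor with sdlog `dispersion` (0.35) and clipped to [0, 1]. The
unit intensity scale is chosen so the conventional CD45 immune cut-off of
0.07 is directly meaningful; with the defaults, background intensities
essentially never cross 0.07 while positive ones essentially always do, so
the generator's phenotypes are recoverable in principle — tests measure how
well each algorithm actually recovers them. No public cohort documents the
true intensity distributions of this assay, so these levels are package
choices, fixed once; they are deliberately not calibrated to any dataset.

Layouts place cells in a rectangular ROI: uniform (`random`, optionally
with a minimum spacing via rejection sampling, used when a scene will be
rendered and nuclei must not overlap), per-label Gaussian clumps
(`clustered`, sd 25 µm), `two_block` (one label per ROI half — maximal
segregation for enrichment tests), and `epithelium_margin` (chosen labels
inside a left-anchored epithelial rectangle). `synth_cohort()` emulates a
staged esophageal progression cohort (NSQ → NDBE → Dys → EAC): mixing
weights shift so regulatory T cells and CD163+ myelomonocytic cells rise
with stage while the CD8 T-cell share falls, on a rising total immune
density. The default 6/9/12/13 ROI split mirrors a 40-ROI cohort.

`render_round_images()` renders rounds through a Beer–Lambert forward
model: nuclei are ellipses (area from the table, eccentricity lognormal)
painted with hematoxylin optical density; a round's marker adds AEC density
over its positive cells with an ~1.5 µm halo; optical densities map to RGB
as `background * exp(-(c_h v_h + c_a v_a))` with Ruifrok-style unit OD
vectors; Gaussian pixel noise (sd 0.008) is added per round. A weak smooth
background texture, identical across rounds, gives the feature matcher
tissue structure to lock onto. Pixels are 0.22 µm (20x brightfield
scanner). What the renderer does **not** model: stain bleed-through between
cycles, section deformation, cytoplasm-specific marker localisation,
out-of-focus blur, or 3-D structure — so passing tests demonstrate
correctness of the algorithms under the forward model, not robustness to
every real-world artifact.

## Registration

Serial rounds are acquired days apart after repeated heating/washing; the
field of view shifts, rotates and rescales but the section itself does not
deform, so the transform family is similarity (scale, angle, translation).
A full affine fit would absorb shear that the acquisition cannot produce
and is deliberately not the default.

Per round: Harris corners on the tissue intensity (1 − mean RGB; Sobel
gradients, structure tensor at σ = 2 px, κ = 0.05) with greedy non-maximum
suppression (7 px) and quadratic sub-pixel refinement; 11×11 mean/variance-
normalised patch descriptors; mutual nearest-neighbour matching under
Lowe's ratio test (0.9). The similarity fit is the closed-form
least-squares (Umeyama) solution inside a RANSAC loop (500 iterations,
2-point minimal samples, 2 px inlier band, fixed seed), refit twice on the
consensus set. Featureless inputs raise an explicit
"insufficient features" error rather than silently returning an identity.
The registered stack crops to the intersection of the inner axis-aligned
rectangles of every warped round. Interpolation is bilinear for
intensities, nearest-neighbour for label masks; coordinates are 0-based
pixels, x = column, y = row, with physical µm = px × 0.22.

On rendered fixtures with a planted (scale 1.02, 3°, (10, −5) px)
distortion the estimate lands within ~0.2 px at the crop corners; the
noiseless point fit is exact to machine precision.

## Stain separation and quantification

Brightfield RGB is converted to optical density
`OD = −log((rgb + ε)/background)` and projected onto the two-stain basis by
least squares; negative projections clip to zero and results rescale by a
fixed reference OD of 2 so intensities are comparable across ROIs. The OD
basis is configurable; OD separation is used (rather than a CMYK-channel
heuristic sometimes used in ImageJ macros) because it is the physically
grounded model and better conditioned; the basis default is the standard
AEC/hematoxylin pair.

Nuclei segment from the hematoxylin channel: Otsu threshold (override
available), watershed on the distance transform (tolerance 1) to split
touching nuclei, minimum area 8 µm². Labels renumber deterministically by
first raster pixel. Per cell, `quantify_cells()` reports the unweighted
pixel-centroid (µm), area (px × 0.22²) and the arithmetic mean of each
deconvolved marker over nucleus pixels — matching quantification on the
nuclear segmentation directly; an optional dilation radius (default 0)
grows the support for membrane markers. Background is not subtracted
before averaging; the gating thresholds operate on the same scale either
way.

## Hierarchical gating

The gating engine replaces interactive biaxial-plot gating with a
deterministic rule list: per-marker positivity is strict
`intensity > threshold`, rules are ordered most-specific-first, the first
full sign match labels the cell, and a catch-all final rule guarantees a
partition. The shipped configuration covers the canonical immune leaf
phenotypes (CD8 and proliferating CD8 T cells, regulatory and proliferating
regulatory T cells, other Th cells, B cells, CD1C+ dendritic cells, the
CD163+/− myelomonocytic split, monocyte/macrophage lineage, plus
catch-alls) and aggregate populations (pan-immune, total T, total
myelomonocytic, ...) each with a denominator for proportion reporting.
Thresholds ship at 0.07 for CD45 — the conventional immune cut-off on this
intensity scale — and 0.1 elsewhere; real cohorts gated by eye do not
publish per-marker thresholds, so these are config values the user is
expected to tune, not claims about any dataset.

The spatial gate keeps cells inside the epithelium or within a stromal
margin (default 200 µm) of its boundary. Distances come from a distance
transform of the region rasterised at 1 µm, so rectangle, polygon and mask
regions behave identically (and agree with exact geometry to the raster
resolution). Densities are counts per mm² of ROI area; proportions divide
by the configured denominator population and are flagged undefined (never
silently 0) when the denominator is empty.

## Sparse subspace clustering

Cells of one phenotype share a marker *direction* with varying overall
staining strength, i.e. they lie near a union of low-dimensional subspaces
in marker space. SSC exploits self-expressiveness: each cell's vector is
written as a sparse linear combination of other cells, and the nonzero
coefficients ideally select same-subspace cells. For scalability the
dictionary is a landmark subset (default min(2000, N); k-means
representatives, so every dense region contributes landmarks).

The coder solves, per cell, the noise-tolerant ℓ1 program
½‖x_i − D c_i‖² + λ_i‖c_i‖₁ with the self-coefficient pinned to zero for
landmark cells. The exact equality-constrained program is infeasible for
noisy intensities, hence the lasso relaxation. λ_i scales per cell as
α·‖Dᵀx_i‖∞ with α = 0.05: ‖Dᵀx_i‖∞ is the smallest λ that zeroes the
solution, so α positions every cell at the same relative point of its
regularisation path. The solver is FISTA, vectorised over all cells, followed by an exact
active-set coordinate-descent polish for any cell left short of the KKT
conditions; the stop is a per-cell relative KKT tolerance (default 1e−3,
the conventional lasso level — archetype-style data make the dictionary
highly coherent, where demanding much more buys no clustering accuracy) and
per-cell convergence flags are reported. By default the pipeline wrapper codes cells on
the unit sphere (`unit_norm = TRUE`): dividing each cell vector by its
Euclidean norm removes brightness as a direction of variation, which
otherwise can fragment one phenotype into dim/bright subclusters while
starving a genuinely distinct pair of the cluster budget — the standard
SSC preprocessing for magnitude-confounded data.

The affinity is `|C| + |C|ᵀ` when every cell is a landmark; with a reduced
dictionary two cells are similar through shared landmark support (cosine of
their |code| profiles), the usual landmark lift. Spectral clustering uses
the k smallest normalized-Laplacian eigenvectors, row-normalised, with
seeded k-means (10 restarts). Default k = 20 for a full cohort run;
`choose_k()` computes the dispersion (within-cluster sum of squares) of the
spectral embedding — eigenvectors damped by (1 − eigenvalue)² so
uninformative directions do not smear the curve — over a k range and takes
the maximum-curvature (discrete second difference) elbow. A smooth,
structureless decay also has a curvature maximum, so the elbow only counts
when the dispersion drop entering it exceeds three times the drop after it;
otherwise the smallest k is returned (a single isotropic cloud yields
k = 1). Group profiles are per-group mean marker intensities; interpreting
low-intensity groups (e.g. as "unclassified immune") is left to the user.

## Spatial statistics

The spatial graph links each cell to its k = 10 nearest neighbours
(Euclidean µm, ties broken by cell order). `mean_shortest_distance()` is
the classic reference-to-nearest-target distance with self-exclusion and an
explicit undefined flag for empty sets; `proximity_fractions()` reports the
fraction of reference cells within 30 and 50 µm. Neighbourhood enrichment
compares, per ordered (reference, target) pair, the observed mean count of
target neighbours against a null built by shuffling labels over the fixed
positions (default 1000 permutations, seeded). Both a z-score and the
empirical two-sided p with add-one correction,
p = (#{|perm − mean| ≥ |obs − mean|} + 1)/(n_perm + 1), are reported; the
add-one form is used because it is a genuine probability with guaranteed
type-I control, and the z-score is reported alongside so either convention
can be read off. Pairs are classed enriched/depleted at α = 0.05 without
multiple-testing correction by default (a Benjamini–Hochberg flag is the
caller's choice via `p.adjust` on the output); results are directional by
construction and never symmetrised. Stage aggregation averages z
element-wise across a stage's ROIs, skipping non-evaluable pairs and
reporting the contributing ROI count.

Under random labels on 2000 cells the test suite measures ~5% of pairs
significant at α = 0.05 and a Kolmogorov–Smirnov distance of ~0.02 from
uniformity over 200 seeded replicates.

## Group comparisons and reporting

Stage-wise comparisons treat each ROI as one sample point. Pairwise tests
are two-sided Mann–Whitney–Wilcoxon: exact enumeration for tie-free
combined n ≤ 12, otherwise the tie-corrected normal approximation. Fully
tied samples short-circuit to U = n₁n₂/2, p = 1 (they carry no ordering
information; the asymptotic formula would divide by zero). The Bonferroni
family is the set of tested pairs per population — the plotted-pairs
convention; all six stage pairs can be requested instead — and the
significance stars (ns > 0.05 ≥ * ≥ 0.01 ≥ ** ≥ 0.001 ≥ *** ≥ 0.0001 ≥
****) are computed from the adjusted p by default, with a raw-p option.
The Kruskal–Wallis omnibus test covers populations where no specific pair
is of interest. ROIs from one patient are treated as independent; no
patient-nested model is fitted.

`render_report()` writes the tidy CSVs (cohort summaries, pairwise and
omnibus comparisons, stage-aggregated enrichment, cluster profiles) and the
standard figures (stage box/jitter panels with stars, profile heatmap,
enrichment heatmap); output is deterministic for fixed inputs, which is
what the end-to-end determinism test asserts byte-for-byte.

## Problem sizes and limitations

The test and acceptance runs use desk-scale fixtures chosen as the smallest
sizes at which each property is informative: rendered ROIs of ~110 µm
(500×500 px, 50 cells, 11 rounds) for registration/segmentation, 600–900
cells for clustering, 2000 cells × 200 replicates × 1000 permutations for
the enrichment calibration, and a 4-ROI image-level pipeline for the
determinism check. Known limitations: similarity-only registration (no
deformation), nucleus-only quantification by default, no batch-effect or
patient-level modelling, no compensation for stain carry-over, and the
elbow rule — like all unsupervised model selection — is a heuristic whose
strength threshold (3) is a package choice validated on planted and null
fixtures.
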