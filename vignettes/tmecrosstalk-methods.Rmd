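---
title: "Methods: cross-cell-type expression coupling in tumor microenvironments"
author: "tmecrosstalk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cross-cell-type expression coupling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tmecrosstalk)
```

# The question the pipeline answers

In colorectal tumors, a transcription factor expressed in the malignant
epithelial compartment (the *anchor* gene, CEBPB in the motivating setting)
may reshape the immune compartment: T cells of the same tumor can show
elevated immune-checkpoint expression (CTLA4), altered differential
expression, and stronger clonal expansion. None of these signals live in a
single cell — the unit of replication is the *patient*. This package
implements the full chain of patient-level analyses that connects an anchor
gene in one cell type to target genes in other cell types:

1. library-size normalization and **Gaussian-mixture thresholding** of
   bimodal markers into high/low cells and patients;
2. **pseudobulk cross-cell-type correlation**: per-patient mean expression
   of every (gene, cell type) against the per-patient anchor mean, with a
   permutation null;
3. a **random-intercept linear mixed model** at single-cell resolution,
   `y_ij = β0 + β1·x_i + u_i + ε_ij`, with Satterthwaite degrees of freedom;
4. **Wilcoxon rank-sum differential expression** between anchor-defined
   groups with cohort-specific selection rules;
5. **TCR clonal-expansion** summaries and their correlation with the anchor;
6. **spatial co-expression** on Visium-style hexagonal lattices via 7-spot
   pseudo-spot aggregation;
7. **histology scoring**: IHC H-score, positive-cell counting score, and
   whole-slide immune-phenotype grids with an Inflamed Score.

Every stage is exercised against a synthetic cohort generator that plants
known effects, so recovery can be checked quantitatively.

# Normalization and thresholding

Counts are normalized per cell to counts-per-10,000 and transformed with
`log2(1 + x)`. Base 2 is a deliberate choice: group differences of mean
normalized expression are then literally log2 fold changes, so the DEG
stage's selection thresholds need no base conversion. Cells with zero total
count stay all-zero and are flagged.

A marker is dichotomized by fitting a two-component univariate Gaussian
mixture by maximum-likelihood EM (`fit_gmm2`) and cutting at the **first
intersection above zero** of the two weighted component densities
(`gmm_cutoff`). With unequal variances the intersection condition is a
quadratic with at most two real roots; the smaller positive root is used.
Equal-variance mixtures have the closed form
`cutoff = (μ1+μ2)/2 + σ²·log(w1/w2)/(μ2−μ1)`, which the tests verify.
Numerical choices:

* **Variance floor** `1e-6` on each component, preventing collapse onto the
  zero spike or a repeated value.
* **Initialization**: `n_init = 5` k-means-style starts with jittered
  centers, best final log-likelihood wins; results are deterministic given
  the seed and the EM trace is checked to be non-decreasing.
* **Ties at the cutoff go to "low"**: the classification rule is a strict
  `value > cutoff`, matching the convention that a patient whose mean sits
  exactly at the threshold is not called high.
* **Zeros**: by default the mixture is fitted on all values and only the
  cutoff search is restricted to x > 0. On sparse data whose zero fraction
  is large relative to the expressing component, the zero spike absorbs one
  component and pushes the first intersection to an uninformative point just
  above zero; `nonzero_only = TRUE` fits the expressing cells instead and is
  the default in the pipeline driver, where desk-scale gene panels make
  normalized values coarse. Both behaviours are exposed because neither is
  uniquely "correct" — the right choice depends on where the bimodality of
  interest lives.

# The cross-cell-type scan

`pseudobulk()` averages normalized expression per (patient, cell type,
gene); groups with fewer than `min_cells = 10` cells are dropped, since a
mean over a handful of cells is dominated by sampling noise. The threshold
is exposed; 10 is a common floor for per-patient cell-type summaries.

`cross_celltype_scan()` computes, for each (gene, cell type), the Pearson
correlation across patients between that pseudobulk profile and the anchor
profile, with pairwise deletion of patients missing either entry. The
p-value is a two-sided empirical permutation p: the target vector is
permuted across patients B times (default 100,000) and
`p = (1 + #{|r_b| ≥ |r_obs|}) / (B + 1)`. For n ≤ 8 an exhaustive mode
enumerates all n! permutations and returns the exact fraction. Internally
the scan shares one set of B permutations across all genes with the same
patient-availability pattern; under exchangeability this is equivalent in
distribution to independent per-pair permutations and reduces the scan to a
single matrix product per cell type.

A pair is *selected* when `|r| > 0.25` **and** `p < 0.05` (both strict).
One property of this joint rule deserves emphasis: the p-threshold
corresponds to a critical |r| of about `1.96/√(n−1)`, which exceeds 0.25
whenever fewer than about 62 patients are available. At typical cohort
sizes (~30 patients) the |r| clause is therefore redundant and the null
firing rate of the joint rule equals the test level, about 5% of null genes
— not less. The |r| clause only becomes the binding filter in large
cohorts, where it suppresses statistically significant but weak
correlations. The validation suite measures exactly this behaviour.

# The random-intercept mixed model

Patient-level correlation discards within-patient information; the mixed
model `y_ij = β0 + β1·x_i + u_i + ε_ij` (cell j in patient i, `x_i` the
z-scored patient-level anchor mean, `u_i ~ N(0, σu²)`,
`ε_ij ~ N(0, σε²)`) uses every cell while accounting for patient
clustering. `fit_random_intercept_lmm()` maximizes the full likelihood
(ML, not REML) by profiling: for a fixed variance ratio λ = σu²/σε², the
GLS fixed-effect solve collapses — because the covariate is constant within
patient — to a weighted regression of patient means with weights
`n_i/(1 + λ·n_i)`, making each likelihood evaluation O(#patients). The
profile is optimized over log λ and compared against the λ = 0 boundary;
boundary fits are reported (not an error) and reproduce OLS exactly.

The fixed-effect p-value uses a t reference with **Satterthwaite degrees of
freedom**: `df = 2·g² / (∇g' A⁻¹ ∇g)`, where `g(σu², σε²) = var(β̂1)`, the
gradient is computed by central finite differences, and A is the observed
information of the variance components (finite-difference Hessian of the
profiled negative log-likelihood). When the information matrix is singular
the conservative fallback `df = #patients − 2` is used and flagged. At the
λ = 0 boundary the residual-like `df = N − 2` applies. The implementation
is cross-checked against lmerTest on the same data in the tests.

# Differential expression rules

Per-gene two-sided Wilcoxon rank-sum tests compare two disjoint cell
groups; p-values are Bonferroni-corrected over the genes actually tested
(genes detected in fewer than 3 cells are excluded from testing, and from
the multiplier m — m is recorded on the result). The p-value is exact
(full null enumeration) when both groups have ≤ 25 cells and no ties;
otherwise the normal approximation with tie and continuity correction is
used. Two cohort rules are provided:

* **human**: `|log2FC| > 0.5` and adjusted p < 0.05 — two-sided in fold
  change, because both directions are reported in patient cohorts;
* **mouse**: `log2FC > 1.5`, adjusted p < 0.05, and detection in > 25% of
  cells in *each* group — one-sided, matching a "commonly up-regulated"
  design. All thresholds are strict inequalities.

`intersect_selected()` intersects selected gene sets across comparisons.

# TCR clonal expansion

Clonal size is the number of cells sharing a clonotype **within a patient**.
The operative size classes are absolute: 1 = Single, 2–5 = Low, 6–50 =
High, > 50 = Hyper. Percentile-based descriptions of the same classes
(top 5%, top 25%) are dataset-dependent, so they are available behind
`percentile_classes = TRUE` for comparison but are not the default. The
per-patient expanded proportion is the **cell-level** fraction: cells in
clones of size ≥ 2 over cells with any recovered clonotype (cells without a
TCR cannot be classified either way); the clone-level fraction is available
behind `clone_level = TRUE`.

# Spatial pseudo-spots

Spots live in Visium array coordinates, where row and column parity agree
(row + col even) and the six first-ring neighbors sit at offsets (0, ±2)
and (±1, ±1). One pseudo-spot is built per spot — the center plus its
existing neighbors, windows overlapping — by exact integer summation of
counts; pseudo-spots with fewer than 4 members are flagged as not retained.
Slides qualify for co-expression analysis when the fraction of spots with a
nonzero target-gene count strictly exceeds 5%. Correlation between the two
genes is computed on `log2(1 + x)` values by default (a raw-count option
exists; the transform is not dictated by the aggregation itself). Quadrant
co-expression classes cut each gene at its median **over the unit set being
classified** (spots, or retained pseudo-spots), with "high" strictly above
the median.

# Histology scores

* **H-score** per region: `3·%(3+) + 2·%(2+) + 1·%(1+)`, range 0–300; case
  score = unweighted mean over regions (a cell-count-weighted option
  exists).
* **Counting score**: cells with intensity ≥ 1+ per mm² of region area,
  averaged over regions.
* **Immune phenotype** per 0.25 mm² grid: inflamed when intratumoral TIL
  density ≥ 130/mm²; else excluded when stromal density ≥ 260/mm²; else
  desert. Boundary conventions follow these inequalities exactly. The
  slide-level **Inflamed Score** is the inflamed-grid proportion; all three
  class proportions are reported because the single-number summary discards
  the excluded/desert split.

# The synthetic cohort generator

`generate_cohort()` draws, per patient, an anchor activity `a_i` from a
two-component normal mixture; per-cell gene counts are negative binomial
with `log mean = log(baseline_g) + b_(g,t)·a_i` for coupled (gene, cell
type) pairs. Defaults define the emulated study conditions:

* **30 patients**, 80–150 cells each, 500 genes, five cell types
  (epithelial 40%, T 30%, B/myeloid/fibroblast 10% each) — a desk-scale
  stand-in for a 30-patient CRC cohort.
* **Anchor activity mixture** 0.5·N(0, 0.3²) + 0.5·N(2, 0.3²). The two
  components are well separated so that the marker is genuinely bimodal at
  the cell level — the regime in which mixture thresholding is meaningful
  and in which the motivating markers present themselves.
* **NB dispersion 0.5** (variance = μ + 0.5μ²), mimicking scRNA-seq
  overdispersion so pseudobulk means carry realistic noise; Poisson is the
  dispersion → 0 limit.
* **Gene baselines** lognormal(log 0.5, 1) mean counts; the anchor and
  coupled marker genes get a fixed baseline of 5 counts, since markers are
  well-detected genes and a lognormal draw would not guarantee that.
* **Clonotypes**: each T cell's receptor is recovered with probability
  0.85; the expanded-cell fraction is logistic in activity,
  `plogis(−1.5 + 2·a_i)` (≈ 0.18 for low-activity, ≈ 0.92 for
  high-activity patients), and expanded clone sizes are 2 + Geometric(0.35),
  giving the long right tail the size classes assume.
* All randomness flows from one root seed through named substreams
  (expression, tcr, spatial, ihc, til), so modules regenerate independently
  and identical (config, seed) give byte-identical output.

Coupling slopes are expressed on the correlation scale via
`calibrate_coupling_slope()`, which Monte-Carlo estimates the true
patient-level correlation implied by a slope on a large cohort (400
patients by default) and interpolates to a target r. The validation suite
uses a slope calibrated to a true patient-level r of 0.6 at the default
cohort size.

`generate_slide()` plants spatial co-expression as two Poisson count
channels driven by shared smooth latent Gaussian fields with correlation ρ;
smoothing (two neighbor-averaging passes) gives the fields spatial range,
which is what makes 7-spot aggregation genuinely increase the measured
correlation — with spatially independent latents, aggregation would leave
the correlation unchanged. `generate_ihc()` and `generate_til_grid()` draw
staining intensities and density pairs from configurable class profiles
such that downstream scoring reproduces the profile in expectation.

What the generator does **not** emulate: doublets, ambient RNA, batch
effects, cell-type misassignment, realistic gene–gene correlation beyond
the planted couplings, or genome-scale gene panels. Passing tests therefore
demonstrate correctness of the procedures and their calibration under the
stated generative model, not robustness to every artifact of real data.

# Validation problem sizes

The shipped validation suite runs: mixture-cutoff recovery on 5,000 draws;
exhaustive-vs-exact permutation checks at n = 7 (5,040 permutations, 50
pairs); null calibration on 200 cohorts of 30 patients × 500 genes with
B = 4,999 permutations; planted-effect power on 100 cohorts at true
r = 0.6; 200 mixed-model simulations (30 patients × 50 cells, β1 = 0.3,
σu² = 0.5, σε² = 1); exhaustive lattice checks up to 20 × 20; and clone
class partitions up to size 10,000. These sizes were chosen so the whole
suite completes in a few minutes on one core while keeping Monte-Carlo
error well inside the asserted tolerances.

# Known limitations

* The joint selection rule's null firing rate at ~30 patients equals the
  5% test level, as explained above; the |r| > 0.25 clause adds no
  specificity at that cohort size.
* The permutation adjustment is per-pair; no family-wise (max-statistic)
  adjustment across genes is applied, and no FDR layer is added on top of
  the |r|/p rule.
* The mixed model supports a single patient-level covariate and a random
  intercept only — no random slopes, no REML.
* Percentile-based clone classes and the clone-level expansion fraction are
  provided as options but not defaults; with few clonotyped cells per
  patient both are unstable.
* H-score percentages are exact rational arithmetic in floating point; with
  region cell counts below ~10 the 0–300 scale is coarse.
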