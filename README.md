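# tmecrosstalk

Patient-level analysis of cross-cell-type expression coupling in tumor
microenvironments, from single-cell RNA-seq, TCR, spatial, and histology
data.

## The problem

A gene expressed by malignant epithelial cells can remodel the immune
compartment of the same tumor. Detecting that remodeling is a
*patient-level* question: the anchor gene (e.g. the transcription factor
CEBPB in colorectal cancer epithelium) and its candidate targets (e.g. the
immune checkpoint CTLA4 in T cells) live in different cells, so no
single-cell correlation can link them. This package implements the analysis
chain for that question, for computational biologists working with
multi-patient single-cell cohorts:

- **Mixture thresholding** — a 2-component Gaussian mixture is fitted to a
  marker's expression distribution and the first intersection of the two
  weighted densities above zero, `w1·N(x; μ1, σ1²) = w2·N(x; μ2, σ2²)`,
  dichotomizes cells and patients into high/low groups.
- **Cross-cell-type scan** — for every (gene *g*, cell type *t*), Pearson's
  *r* across patients between pseudobulk means `ȳ_i(g,t)` and the anchor
  `x̄_i`, with a permutation p-value
  `p = (1 + #{|r_b| ≥ |r_obs|})/(B + 1)`, B = 100,000 by default;
  selection requires `|r| > 0.25` and `p < 0.05`.
- **Random-intercept mixed model** — `y_ij = β0 + β1·x_i + u_i + ε_ij`
  with `u_i ~ N(0, σu²)`, fitted by maximum likelihood with Satterthwaite
  degrees of freedom for the `β1` t-test.
- **Wilcoxon DEG** with Bonferroni correction and cohort rules
  (human: `|log2FC| > 0.5`, adj. p < 0.05; mouse: `log2FC > 1.5`,
  adj. p < 0.05, detection > 25% per group).
- **TCR expansion** — clone sizes within patient, classes Single (1), Low
  (2–5), High (6–50), Hyper (> 50), and the expanded-cell proportion per
  patient correlated with the anchor.
- **Spatial pseudo-spots** — Visium hexagonal first-ring aggregation
  (center + 6 neighbors, drop aggregates with < 4 members), median-quadrant
  co-expression classes, and a 5% expressing-spot slide filter.
- **Histology** — IHC H-score `3·%(3+) + 2·%(2+) + 1·%(1+)` (0–300),
  CTLA-4 counting score (positive cells/mm²), and immune-phenotype grids
  (inflamed ≥ 130/mm² intratumoral; excluded ≥ 260/mm² stromal; desert
  otherwise) with a whole-slide Inflamed Score.

A synthetic-cohort generator with planted, recorded ground truth (bimodal
anchor activity, tunable gene–cell-type couplings, negative-binomial
counts, logistic expansion fractions, latent spatial fields) backs the
entire test suite. See `vignettes/tmecrosstalk-methods.Rmd` for the full
methods account.

## Worked example

```r
library(tmecrosstalk)
cfg <- default_pipeline_config(n_patients = 20, n_genes = 300)
run_pipeline(cfg, "demo_out", seed = 1)
```

```
[tmecrosstalk] simulated cohort: 20 patients, 2321 cells, 300 genes
[tmecrosstalk] thresholds: cutoff 9.294; 7 high / 13 low patients
[tmecrosstalk] crosscor: 1500 pairs tested, 71 selected
[tmecrosstalk] deg (T cells, human rule): 300 tested, 3 selected
[tmecrosstalk] tcr: expansion-anchor r = 0.963 (p = 0.0005, n = 20)
[tmecrosstalk] spatial: r_spot = 0.311, r_pseudospot = 0.443
```

Reading the output: the GMM cutoff (9.294 on the log2 CP10K scale of this
small gene panel) splits the 20 patients into 7 anchor-high and 13
anchor-low. The scan tests 1,500 (gene, cell type) pairs; the planted
coupled target is the top non-self hit (`CTLA4` in T cells, r = 0.98,
p = 1e-4 at B = 10,000). With only 20 patients the `p < 0.05` clause of
the selection rule corresponds to `|r| ≳ 0.45 > 0.25`, so the rule fires
at its ~5% test level on null genes — most of the other 69 "selected"
pairs are exactly that, which is why the package reports the permutation p
alongside r rather than a yes/no call alone. The expansion–anchor
correlation (0.963) recovers the planted logistic coupling, and the
pseudo-spot correlation (0.443) exceeds the spot-level one (0.311), the
expected effect of 7-spot aggregation under a shared latent field. Every
output lands as a TSV in `demo_out/`, with a `manifest.json` recording the
seed, config hash, and per-file checksums; rerunning with the same seed
reproduces identical checksums.

A thin command-line wrapper over the same function is provided at
`inst/cli/tmecrosstalk.R`:

```sh
Rscript inst/cli/tmecrosstalk.R run --config demo.yaml --out results/ --seed 1
```

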