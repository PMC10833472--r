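# livage

Tested, reusable building blocks for single-nucleus RNA-seq analyses of
liver aging: how transcriptional noise, cell identity, zonation-resolved
differential expression and cell–cell communication change between young
and aged animals. The package targets computational biologists who want
the downstream statistics of such a study as auditable, seedable R
functions — driven by a synthetic snRNA-seq generator with known ground
truth, so every stage can be verified without access to raw sequencing
data.

## What it computes

Given a sparse gene×cell UMI matrix (Matrix Market triplet), cell metadata
(sample, age group ∈ {young, aged}, cell type), and optional gene sets /
ligand–receptor pairs:

- **QC and normalization** — cells with < 200 detected genes or a
  mitochondrial UMI fraction > 5% are removed; expression is log1p-CP10K:
  `value(g,c) = log(1 + count(g,c) · 10⁴ / total(c))`.
- **Transcriptional noise** — cells are down-sampled to an equal UMI total
  (multivariate hypergeometric draw), cell numbers are balanced between
  groups per cell type, and each cell's noise is its Euclidean distance to
  the mean normalized vector of its (cell type, age group). Per cell type
  the package reports `log2(median aged noise / median young noise)` with a
  two-sided Wilcoxon rank-sum p and BH adjustment, plus the genes whose
  expression tracks noise (Pearson |r| > 0.6, FDR < 0.05).
- **Cell-identity scoring** — binned-control module scores (each set gene
  compared against control genes drawn from its mean-expression bin); the
  top-50 young-group marker sets per cell type (avg_log2FC ≥ 0.5, adjusted
  p ≤ 0.05) and young/aged identity drift.
- **Aging DEGs** — per cell type, two-sided Wilcoxon rank-sum (exact by
  enumeration at ≤ 8 cells/group, tie-corrected normal approximation
  otherwise) on normalized values, with
  `avg_log2FC = log2(mean(expm1(aged)) + 1) − log2(mean(expm1(young)) + 1)`;
  a gene is an aging DEG when `|avg_log2FC| ≥ 0.25` and BH-adjusted
  `p ≤ 0.05`. Sharing across ≥ 3 cell types, the 14 zonation overlap
  modules (2 directions × 7 non-empty subsets of {PP, MZ, PC}), and signed
  overlap with an external signature.
- **Zonation** — hepatocytes placed on the periportal→pericentral axis by
  the difference of PC- and PP-marker module scores, cut at its terciles.
- **Cell–cell communication** — ligand–receptor score = mean of ligand
  expression over sender cells and receptor expression over receiver cells,
  computed only when both are detected in > 10% of their cluster; p from a
  cell-type-label permutation null (add-one estimator); young/aged
  differential networks with signed edge weights.
- **Term networks** — hypergeometric over-representation of user-supplied
  terms plus a Cohen's-kappa term-similarity graph (edges at kappa > 0.3).
- **Synthetic data** — negative-binomial counts with log-normal library
  sizes, per-type marker genes, injected DEGs with known sign and size,
  age-dependent dispersion inflation (aged variance up, means preserved), a
  continuous zonation gradient, group-specific ligand–receptor effects and
  Beta-distributed mitochondrial fractions. Same seed ⇒ bit-identical data.

## Worked example

```r
library(livage)

cfg <- sim_config(
  n_genes = 800,
  cell_types = list(
    sim_cell_type("Hep", 200, 200, zonated = TRUE,
                  aged_dispersion_multiplier = 2),
    sim_cell_type("EC", 100, 100),
    sim_cell_type("Kupffer", 100, 100)),
  deg_spec = data.frame(gene = sprintf("G%04d", 101:120), cell_type = "Hep",
                        log2fc = rep(c(1, -1), 10)),
  seed = 7)
sim <- simulate_counts(cfg)

qc <- qc_filter(sim$counts, sim$meta)
qc$report
#> QC: 800 cells in, 723 pass (0 fail min_genes=200, 77 fail mito>0.05)

nm  <- normalize_log1p_cp10k(qc$counts)
sel <- balance_groups(qc$meta, seed = 7)
cmb <- CountMatrix(qc$counts$counts[, sel], gene_ids = qc$counts$gene_ids,
                   cell_ids = sel)
ds  <- downsample_umi(cmb, default_target_umi(cmb), seed = 7)
noise_ratio(transcriptional_noise(ds, qc$meta))
#>   cell_type log2_ratio        p    p_adj n_young n_aged
#> 1        EC   -0.00181 9.67e-01 9.67e-01      90     89
#> 2       Hep    0.03299 4.75e-24 1.43e-23     179    179
#> 3   Kupffer   -0.00550 4.23e-01 6.35e-01      89     90

deg <- wilcoxon_deg(nm, qc$meta, "Hep")
sum(deg$significant)
#> [1] 19
```

Only the hepatocytes — simulated with doubled aged dispersion — show a
positive, significant aged/young noise ratio; the two null cell types sit
at 0. Of the 19 genes the DEG caller flags, 18 are injected |log2fc| = 1
effects (18/20 recovered, one extra call). Zonation assignment splits
the 362 post-QC hepatocytes into 121/120/121 PP/MZ/PC cells.

A full run (QC → scoring → noise → DEG → modules → crosstalk → termnet)
with one seed and a provenance manifest:

```r
run_pipeline(pipeline_config(counts_dir = "data", out_dir = "run1",
                             seed = 1, lr_pairs = "data/lr_pairs.tsv",
                             zonation_gmt = "data/zonation.gmt"))
make_report("run1")
```

or from the shell: `inst/cli/livage run --config pipeline.json`
(subcommands: simulate, qc, score, noise, deg, crosstalk, termnet, run,
report).

## Documentation

`vignettes/livage-methods.Rmd` describes the statistical model behind each
stage, all tunable parameters with defaults and units, what the synthetic
generator does and does not emulate, and the numerical/design choices.
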