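---
title: "Methods: models, parameters and design choices in livage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices in livage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette is the package's own account of its statistics: the model
behind each stage, the parameters that matter and why their defaults are
what they are, what the synthetic generator does and does not emulate, and
the places where the design was genuinely open and a choice had to be
made. It states no empirical result that the test suite or the acceptance
script does not itself compute.

## Data model and normalization

Counts are UMI counts, genes × cells, stored sparse. Quality control
removes cells with fewer than 200 detected genes or a mitochondrial UMI
fraction strictly above 5% — both rules evaluated independently, so the QC
report can count one cell in both failure tallies; the threshold value
itself (exactly 5%) passes, since the exclusion rule is "more than".
Mitochondrial genes are recognized by an id prefix (default `"MT-"`),
configurable because mitochondrial annotations differ between assemblies.

All downstream stages operate on log1p-CP10K values,
$v_{gc} = \log(1 + 10^4\, x_{gc} / \sum_g x_{gc})$. The study this package
re-implements used variance-stabilizing normalization with anchor-based
sample integration at this step; we standardize on log1p-CP10K instead.
The downstream procedures are all defined on expression values, not on the
integration machinery, and the synthetic data has no batch structure, so
nothing downstream depends on that machinery — but it is a real divergence:
on real multi-sample data the user is responsible for batch structure.

## Synthetic data: the stated world

`simulate_counts()` draws
$x_{gc} \sim \mathrm{NB}\!\left(\mu = s_c\,\mu_g\,e_{g,t(c),a(c)}\,z_{g,c},\ \theta_{t,a}\right)$
with

- $\mu_g$ log-normal(meanlog −1, sdlog 1): a right-skewed gene-mean
  distribution with median ≈ 0.37 counts/cell;
- $s_c$ log-normal(meanlog 1.5, sdlog 0.35): median cell depth ≈ 2,500
  UMIs over the default 1,000 genes, with realistic ~35% CV. The depth was
  chosen so that essentially all cells clear the 1,000-UMI floor used by
  the equal-depth down-sampling default;
- $e$ the injected effects: cell-type marker genes (default log2FC 2, both
  age groups) and aging DEGs (`deg_spec`, aged cells only);
- $z$ the hepatocyte zonation factor (below);
- $\theta = 10$ for young cells (moderate overdispersion; variance
  $\mu + \mu^2/10$), divided by the cell type's
  `aged_dispersion_multiplier` for aged cells.

Aging-related "transcriptional noise" is modeled purely as dispersion
inflation — $\theta \to \theta/m$, $m \ge 1$ — which preserves group means.
This isolates exactly the quantity the noise statistic is meant to measure
and deliberately avoids asserting any mechanism for the variance increase.

Zonation: each hepatocyte carries a latent position $t \sim U(0,1)$ along
the portal–central axis. A gradient gene with signed log2 amplitude $a$ is
multiplied by $2^{a(2t-1)}$: periportal markers ($a<0$, default 10 genes at
amplitude 2) decay monotonically in $t$, pericentral markers rise, and
$t = 0.5$ sits at the geometric mean of the endpoints. Truth labels for
recovery tests cut $t$ at 1/3 and 2/3.

Mitochondrial fractions are Beta(2, 78) per cell (mean 2.5%, right tail
crossing the 5% QC limit for roughly a tenth of cells), injected by scaling
a block of `MT-` genes so the expected mitochondrial share equals the drawn
fraction. Ligand–receptor effects upregulate the ligand in sender cells and
the receptor in receiver cells of the configured age group(s).

Not emulated: ambient RNA, doublets, batch/sample structure, splicing,
gene–gene correlation beyond the injected effects, and zero inflation
beyond what the NB produces. A green recovery test therefore establishes
that the statistics behave correctly under their own model assumptions —
not that they are robust to artifacts the generator does not produce.

## Transcriptional noise

Depth differences and group-size differences both inflate naive distance
measures, so the pipeline first (i) balances cell numbers per (cell type,
group) by sampling `min(n_young, n_aged)` cells from each group, and (ii)
down-samples every retained cell to the same UMI total — a without-
replacement multivariate hypergeometric draw from the cell's observed
UMIs, implemented by sampling UMI indices and mapping them back to genes
through the cumulative counts. The default target is the minimum post-QC
cell total, floored at 1,000 (cells below the floor are dropped): the floor
keeps one extremely shallow cell from dragging every other cell down to
uninformative depth.

Noise is the Euclidean distance of each cell's normalized vector to its
(cell type, group) centroid, computed over genes detected in ≥ 10% of the
cell type's retained cells — unfiltered zeros would otherwise dominate the
distance. Per cell type we report `log2(median aged / median young)` with a
two-sided rank-sum test and BH adjustment across cell types; the source
study showed adjusted p-values without naming a test, so the rank-sum is
this package's choice. Gene–noise correlations are computed per cell with
both groups pooled (per-bin correlation inflates r; the rank bins are kept
for display only), with p from the t transform of Pearson's r.

## Module scores, identity drift, zonation assignment

`module_score()` re-implements the binned-control scheme: genes are placed
into `n_bins = 24` equal-frequency bins by mean expression; each set gene
is compared against `n_ctrl = 100` controls drawn uniformly with
replacement from its bin; the score is the mean over set genes of
(set-gene value − mean control value). Equal-frequency (not equal-width)
bins and with-replacement draws are deliberate choices the upstream tool
leaves implicit; `n_ctrl = Inf` uses the whole bin and makes the score
deterministic, which the tests exploit. Identity sets are the top 50
young-group one-vs-rest markers (avg_log2FC ≥ 0.5, adjusted p ≤ 0.05),
ranked by fold change with lexicographic tie-break for determinism.

The source study derived PP/MZ/PC hepatocyte subtypes by re-clustering;
clustering is out of scope here, and the study itself observed a
*continuous* transcriptional gradient between the poles. Assignment is
therefore score-based: $d = \text{score}_{PC} - \text{score}_{PP}$, cut at
its empirical terciles, boundaries assigned to MZ. On continuous $d$ this
partitions hepatocytes into near-equal thirds by construction — which is a
modeling assumption, not a biological finding.

## Differential expression

The per-gene test is a two-sided Wilcoxon rank-sum: exact by full
enumeration of rank assignments when both groups have ≤ 8 cells and no
ties, tie-corrected normal approximation with continuity correction
otherwise. (The upstream tool's documentation says "signed-rank"; what it
computes, and what makes sense for two independent cell groups, is the
rank-sum test.) Fold changes use the pseudocount-on-averaged-expm1
convention
$\mathrm{lfc} = \log_2(\overline{\mathrm{expm1}(v_a)} + 1) -
\log_2(\overline{\mathrm{expm1}(v_y)} + 1)$,
and a gene is tested only if detected in ≥ 10% of either group and
$|\mathrm{lfc}| \ge 0.25$.

One correction to the specification this package was built against: p-value
adjustment. Restricting BH to the lfc-prefiltered genes does not control
FDR — at a few hundred cells per group, a null gene that reaches
$|\mathrm{lfc}| \ge 0.25$ by chance almost surely has a small p too,
because the same sampling fluctuation drives both statistics; measured
empirically this pushed the false-discovery proportion of injected-effect
recovery to ~0.3. The tool the source study used computes p only for
prefiltered genes but adjusts over *all* features for exactly this reason.
`livage` follows that substance: BH with denominator equal to the number of
detection-passing genes, untested genes entering as p = 1. The significant
set is `p_adj ≤ 0.05` and `|lfc| ≥ 0.25`.

Sharing analysis counts, per gene and direction, the cell types where the
gene is a significant DEG (a gene may appear as "up" in some types and
"down" in others — that is two records). The zonation overlap classifier
assigns each gene significant in ≥ 1 subtype to one of 2 × (2³ − 1) = 14
classes (direction × non-empty subset of {PP, MZ, PC}); genes with
discordant directions across subtypes are excluded from the modules and
reported separately, since the source study does not say how it handled
them.

## Cell–cell communication

The interaction score is the arithmetic mean of the ligand's mean
expression over sender cells and the receptor's mean over receiver cells
(the cited tool's convention), computed per ordered (sender, receiver)
pair within one age group. The expression filter is strict: both genes
must be detected in *more than* 10% of their cluster. The null shuffles
cell-type labels among the group's cells — groups are separate datasets,
so age labels never mix — and the p-value is the add-one estimator
$(1 + \#\{\text{perm} \ge \text{obs}\})/(1 + n_{perm})$, bounded below by
$1/(n_{perm}+1)$ and exactly uniform under exchangeability. No multiplicity
correction is applied by default, matching the stated "p ≤ 0.05" rule of
the source analysis. Group-specific interactions are set differences of the
significant records over identical (pair, sender, receiver) universes;
edges aggregate them per (sender, receiver) with signed weight
`n_aged_specific − n_young_specific`. Multi-subunit receptor complexes are
not supported.

## Term similarity and enrichment

Cohen's kappa between two term gene sets over a universe is computed from
the 2×2 membership table; the default universe is the union of member
genes over the network's terms (the enrichment service the source study
used leaves its universe implicit; ours is explicit and configurable).
Edges require kappa strictly above 0.3. The enrichment helper is an
upper-tail hypergeometric test with BH across terms; it replaces the
external enrichment service so that term sets can be produced from
synthetic annotations offline.

## Pipeline, seeding, determinism

`run_pipeline()` executes qc → normalize → scoring/zonation → noise → deg
→ modules → crosstalk → termnet, skipping optional stages whose inputs are
not configured, and writes a manifest with parameters and input/output
checksums. One global seed is used everywhere; each stage derives an
independent substream seed by hashing (seed, stage name), so adding or
removing a stage never perturbs another stage's draws, and rerunning a
config reproduces bit-identical TSVs. The pipeline config is JSON rather
than YAML — the target environment ships no YAML parser for R, and nothing
in the schema needs one.

## Numerical details and edge cases

- Down-sampling: cells at exactly the target are kept unchanged; cells
  below it are dropped.
- Noise: a single-cell group gets distance 0 and a `degenerate` flag; a
  zero young median makes the ratio NA with a recorded reason rather than
  ±Inf.
- Rank bins and marker rankings break ties by cell/gene id for
  determinism.
- `bh_adjust` errors on NA input and clips at 1; kappa returns 1 when the
  chance agreement is exactly 1 (identical full-universe sets).
- All p-value containers are validated to [0, 1].

## Known limitations

Recovery guarantees are model-internal (see the generator section). The
noise statistic conflates any residual depth or composition difference
with biological variance if the balancing/down-sampling stage is skipped.
The DEG test treats cells as independent replicates (no pseudobulk or
sample-level modeling), so on real multi-animal data its p-values are
anticonservative with respect to animal-level variation. The zonation
terciles force a 1/3–1/3–1/3 split regardless of true compartment sizes.
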