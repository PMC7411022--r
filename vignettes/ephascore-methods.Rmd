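---
title: "Methods: scoring EphA receptor clustering in single cells"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: scoring EphA receptor clustering in single cells}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ephascore)
```

## The assay and the measurement model

Cells spread on a fluid supported lipid bilayer functionalized with
fluorescent ephrinA1 gather the receptor-bound ligand into clusters.
Under wide-field fluorescence the cluster pattern of one cell is a set
of bright puncta over a dim background; its morphology — many scattered
small puncta versus a few large aggregates — is the phenotype of
interest. The analysis chain is: image + cell label mask → per-cell
intensity multiset → entropy score → chip normalization → population
statistics.

### The intensity-entropy score

For one cell with pixel intensities $I_1,\dots,I_N$ and mean
$\bar I$, writing $\rho_i = I_i/\bar I$,

$$ S \;=\; \frac{1}{N}\sum_{i=1}^{N} \rho_i \ln \rho_i,
   \qquad 0 \ln 0 := 0 . $$

Properties that drive every design decision downstream:

* $S = 0$ iff the signal is uniform, and $S \le \ln N$, with equality
  when all signal sits in one pixel (Jensen/concentration bounds);
* **intensive**: the $1/N$ discretization of $\int\!\rho\ln\rho$ makes
  $S$ independent of cell area, so differently sized cells are
  comparable. An unnormalized sum would grow with area;
* **gain invariance**: $S(cI) = S(I)$ for $c>0$, so illumination and
  detector gain cancel — but *additive* offsets do not, which is why
  background is subtracted first;
* **permutation invariance**: $S$ sees only the intensity histogram,
  deliberately ignoring the spatial arrangement of the clusters (which
  mostly reflects cell type rather than state).

Natural logarithm throughout. Whether the original analysis normalized
its discretized integral per pixel is not documented; the intensive
per-pixel-mean reading is adopted here because the score is described
as intensive, and it is the only reading under which the area
independence holds.

### Background handling

The score's sensitivity to additive offsets forces an explicit
background policy: the default estimator is the median intensity over
label-0 pixels of each field, subtracted per cell and floored at zero
(zero pixels are legal thanks to $0\ln 0 = 0$). The raw-intensity
variant stays available behind `score_cells(background_subtract =
FALSE)` for data that is already background-corrected. Cells under
`min_area = 200` px are dropped and logged; border-touching cells are
flagged but kept. All of these are configurable because the upstream
protocol (manual outlining) leaves them open.

## Chip normalization and quality gating

Day-to-day fluctuations of the detection chain shift all scores on a
chip proportionally. Each 9-well chip therefore carries triplicate
wells of a reference line (MDA MB231, chosen for its broad score
distribution). The gate: a Kruskal–Wallis test across the three
reference samples must give $p > \alpha$ (default 0.05) or the whole
chip is excluded; Dunn's pairwise $z$-tests (Bonferroni over the three
pairs) are computed as diagnostics only, since the published criterion
is the single omnibus $p$. Accepted chips are normalized by the
arithmetic mean of the *pooled* triplicate scores (pooling the cells,
not averaging per-well means — the reference distributions are
"combined into a single distribution"):

$$ \hat S = S / \bar S_{\mathrm{ref}} . $$

Pooled-reference mean 1 on every chip is an exact identity, and any
chip-wide multiplicative effect cancels to machine precision. The
package requires $\ge 10$ cells per reference well and targets
$> 150$ pooled reference cells for stable normalization.

## Population statistics

* **Distribution comparisons** use the two-sample Kolmogorov–Smirnov
  test (shape-sensitive, not just location); pairwise KS matrices
  report the fraction of population pairs distinguishable after a
  Bonferroni correction (configurable). That fraction is this package's
  operationalization of "how characteristic is a score distribution of
  its population" — a pairwise reading, documented as an
  interpretation.
* **Multi-group comparisons** (reference triplicates, colonies) use
  Kruskal–Wallis plus Dunn's post hoc $z$-tests with tie correction.
  Dunn's test is implemented in the package (rank means, pooled-rank
  variance with tie term, Bonferroni over pairs) because no
  implementation is available among the package's dependencies; it is
  unit-tested against independently computed statistics.
* **Colony inheritance**: `colony_divergence_fraction()` is the
  fraction of unordered colony pairs with adjusted $p < \alpha$. The
  published counting ("x% of colonies differed") does not fully specify
  pairs-versus-colonies or the post-correction level; the pair-fraction
  reading at adjusted $p<0.05$ is implemented and labeled as such.
* **Bootstrap subset test**: the null resamples subsets of the colony's
  size *without replacement* from the unsorted baseline (matching the
  "random subset" hypothesis); the statistic is the absolute difference
  of subset mean from baseline mean, with add-one p-value
  $(k+1)/(n_{\mathrm{iter}}+1)$ and $n_{\mathrm{iter}} = 10{,}000$ by
  default. A KS-distance statistic is available behind a flag. The test
  is calibrated: under the true null its p-values are uniform (checked
  by simulation).
* **Phenotype correlation**: `pearson_with_split()` reports the overall
  Pearson $r$ and the within-group $r$'s after splitting populations at
  $\hat S = 0.4$ — the threshold that separates slow from fast
  migrating lines — with groups contributing only at $\ge 3$ members.

## Transcriptomic enrichment score

From a genes × cells matrix of $E = \log_2(\mathrm{TPM}+1)$: restrict
to the declared EphA2-cascade panel (71 genes in the original study;
the package ships a clearly labeled *synthetic* placeholder list and a
loader for user-supplied panels); drop genes with mean $E < 1$ across
all cells (kept at exactly 1); score each cell as the unweighted mean
of the surviving genes; discard cells with score strictly below 3
("EphA2 score" is read as the pathway score, not the single gene's
expression — both readings exist, this one is the default and the
toggle is the threshold applied to `cell_scores()` output); normalize
per patient by the mean score of that patient's primary-tumor line, so
every primary-line mean is 1 and patient genetic background divides
out. Patients are inferred from line-name suffixes (`p`, `m`, `pcr`)
and can be overridden. The filter order is fixed and recorded in the
result object.

## Synthetic data: what it emulates, and what it does not

The generators exist so the full pipeline is testable without the
deposited imagery, and their defaults are the study conditions.

**Cell images** (`generate_cell_image`): one circular cell (radius 60
px in a 256×256, 16-bit field), total foreground signal $2\times10^5$
counts split equally over 40 puncta, background 100 counts, Poisson
noise. Each punctum joins one of ≤ 3 aggregate centers with probability
equal to the `aggregation` parameter (centers drawn in the inner 50% of
the cell radius, mirroring the inward transport of clusters), otherwise
it lands uniformly in the cell. Punctum kernels are normalized
Gaussians, so the integrated signal is independent of aggregation —
aggregation redistributes photons rather than adding them. Aggregation
raises the expected score only if stacking concentrates signal, i.e.
$3\sigma_{\mathrm{agg}}^2 < n_{\mathrm{puncta}}\sigma_{\mathrm{punctum}}^2$;
the defaults ($\sigma_{\mathrm{agg}} = 4$, $\sigma_{\mathrm{punctum}} =
2$, $n = 40$) satisfy this with a 2.5× margin and the constructor warns
when a configuration violates it. The imagery has no real-world optics:
no PSF anisotropy, no bilayer inhomogeneity, no bleed-through, no
cell-shape irregularity. Passing tests therefore validate the
*analysis* chain, not robustness to those artifacts.

**Chips** (`generate_chip`): the chip effect is one multiplicative gain
per chip applied to every score — not to raw intensities, to which the
score is invariant; proportional score shifts are exactly what a
reference-mean normalization implies and removes. Two paths produce
per-cell scores: the image path (render → extract → score) and a fast
lognormal score sampler; `fit_score_profile()` fits the sampler to the
image path, and the two agree in distribution (KS-checked in the test
suite). Study conditions used in simulations: reference scores
lognormal with log-mean $\ln 1$ and log-sd 0.4 (a broad distribution,
as the reference line's), test population log-mean $\ln 0.6$, log-sd
0.35, chip gains lognormal with $\sigma = 0.15$, 9 wells × 100 cells
(200 in the batch-variability simulation). No per-well effects within a
chip are modeled, matching the normalization's assumption.

**Colonies** (`generate_colony_series`): day-10 scores are
founder-centered Gaussians (sd 0.05, truncated at 0); day-20 scores
come from the mixture $(1-w)\,$colony-law$ + w\,$baseline. $w = 0$
freezes clonal memory, $w = 1$ reverts fully to the population; the
divergence fraction and the convergence of colony means follow
monotonically. Real colonies also shift their overall mean upward
(selection against the most epithelial clones); the generator does not
model that selection.

**Expression** (`generate_expression_matrix`): pathway genes get
line-specific Gaussian log-expression means, other genes a common mean,
truncation at 0, and uniform dropout. No gene–gene correlation, no
library-size variation, no mean–variance trend: enough structure for
the enrichment score's filters and normalization to be exercised, not a
model of scRNA-seq noise.

## Numerical and algorithmic choices

* Score computation: plain vectorized arithmetic; machine-precision
  invariance is asserted at $10^{-12}$ relative tolerance.
* KS p-values: exact for $nm \le 10^4$, asymptotic otherwise; the KS
  statistic is tested against a brute-force ECDF sweep.
* Spot detection: threshold at background + 0.5 × (cell max −
  background), 8-connectivity (4-connected labeling with diagonal-label
  merging), minimum component 4 px. A contrast-free cell yields zero
  puncta by convention, since nothing stands out from the cell's own
  signal.
* Descriptor ranking: Random Forest (impurity importances normalized to
  sum 1, OOB accuracy reported) on standardized descriptors; constant
  descriptors are excluded with a message. The 2D embedding is an exact
  t-SNE implemented in the package (perplexity matched by bisection,
  early exaggeration, momentum descent) — adequate for the few hundred
  cells of a run and deterministic under its seed.
* Determinism: every stochastic routine takes a seed, saves and
  restores the caller's RNG state, and is bit-reproducible.
* Degenerate inputs fail loudly and specifically: all-zero cells,
  gapped label masks, missing reference wells or profiles, all-tied
  group tests, zero-variance correlations, patients without primary
  cells.

## Problem sizes

Simulation-backed checks run at sizes chosen to make their expected
effects decisive while keeping the full suite around a minute: 50 cells
per aggregation level for the monotonicity check, 250/500 cells for the
two-path agreement, 6 chips × 800 cells for batch normalization, 1000
replicates for type-I-error calibration, 500 × 1000 draws for bootstrap
calibration, and 9 colonies × 30 cells per day for the inheritance
pipeline (the study's own colony scale).

## Known limitations

* The descriptor bank is a documented, configurable 18-feature set, not
  a reproduction of the original 75-descriptor panel (whose definitions
  are in unavailable supplementary material); the ranking machinery is
  the methodological replication.
* Automatic segmentation is a convenience for synthetic fixtures; the
  reference analysis outlined cells manually, and no attempt is made to
  match human outlines on real imagery.
* Real-data headline numbers (line-level correlations, colony
  fractions) require the deposited per-cell tables and expression data
  (GSE117872); the package computes them from any such tables supplied
  in its input formats but does not download data.
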