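# ephascore

Single-cell phenotyping by EphA receptor clustering.

When a cell is placed on a fluid supported lipid bilayer presenting
fluorescently tagged ephrinA1, its EphA receptors bind the ligand and
rearrange it into clusters. The morphology of those clusters — scattered
small puncta versus a few large aggregates — reflects the cell's
signaling and migratory state, and is heritable over cell divisions.
`ephascore` turns fluorescence images of these clusters into a
quantitative, chip-comparable single-cell phenotype, and links it to
population structure, clonal inheritance, migration potential, and
single-cell transcriptomics.

## The score

For each cell, with pixel intensities *I* under the cell mask and
cell-mean intensity *Ī*, the clustering score is the intensity entropy

&nbsp;&nbsp;&nbsp;&nbsp;*S* = ⟨ρ ln ρ⟩, &nbsp; ρ = *I* / *Ī*,

the average of ρ ln ρ over the cell's *N* pixels (with 0·ln 0 = 0).
Uniform signal gives *S* = 0; full concentration in one pixel gives the
maximum ln *N*. *S* is intensive (area-independent), invariant to
detector gain, and depends only on the intensity histogram, not the
spatial arrangement. Scattered small puncta score low; large aggregates
score high.

Chip-to-chip detector fluctuations are removed with a reference cell
line (MDA MB231) measured in triplicate wells on every chip: chips whose
triplicates differ (Kruskal–Wallis with Dunn's post hoc, p ≤ 0.05) are
excluded, and on accepted chips every score is divided by the mean of
the pooled reference triplicates,

&nbsp;&nbsp;&nbsp;&nbsp;*Ŝ* = *S* / *S̄*<sub>reference</sub>,

so the pooled reference mean is exactly 1 on every chip.

Around the score, the package provides:

- **imaging** — lossless 16-bit TIFF field/label-mask I/O, per-cell ROI
  extraction, median background estimation, and automatic segmentation
  (Otsu + watershed) for unattended synthetic runs;
- **scoring** — `sepha()`, batch scoring, a documented morphological
  descriptor bank with spot detection, and Random-Forest descriptor
  ranking with a t-SNE embedding;
- **chipnorm** — `chip_qc()`, `normalize_chip()`, `batch_normalize()`;
- **popstats** — two-sample Kolmogorov–Smirnov comparisons and pairwise
  KS matrices, Kruskal–Wallis/Dunn, colony-divergence fractions, a
  bootstrap subset-confidence test, convergence summaries, and
  threshold-split Pearson correlations with migration/EMT phenotypes;
- **transcriptomics** — the single-cell EphA2-pathway enrichment score:
  E = log2(TPM+1), pathway gene selection, mean-expression ≥ 1 gene
  filter, per-cell linear averaging, score < 3 outlier removal, and
  per-patient primary-line normalization;
- **synthetic data** — generators for cell images with tunable punctum
  aggregation at conserved total signal, multi-well chips with
  multiplicative gain effects, clonal colony score series, and
  expression matrices coupled to the clustering phenotype.

## Worked example

```r
library(ephascore)

## 1. render two synthetic cells and score them
scattered  <- generate_cell_image(cell_synth_params(aggregation = 0.1), seed = 1)
aggregated <- generate_cell_image(cell_synth_params(aggregation = 0.9), seed = 1)
s1 <- score_cells(extract_cells(scattered$field,  scattered$mask))
s2 <- score_cells(extract_cells(aggregated$field, aggregated$mask))
cat(sprintf("S (scattered puncta):  %.3f\nS (large aggregates):  %.3f\n",
            s1$s_epha, s2$s_epha))
#> S (scattered puncta):  1.215
#> S (large aggregates):  2.042

## 2. simulate a 9-well chip with reference triplicates, gate and normalize
profiles <- list(MDA_MB231 = score_profile(log(1), 0.4),
                 HN137m    = score_profile(log(0.75), 0.35))
chip <- generate_chip(
  chip_synth_params(wells_per_population = list(MDA_MB231 = 1:3, HN137m = 4:9),
                    cells_per_well = 100, chip_gain = 1.3),
  profiles, seed = 2)
chip <- normalize_chip(chip_qc(chip))
print(chip)
#> chip_record chip1 - 900 cells, 9 wells
#>   reference: MDA_MB231 in w1, w2, w3
#>   QC: pass (KW p = 0.49)
#>   reference mean = 1.4513 (normalized)

## 3. compare the two populations' normalized score distributions
ref  <- subset(chip$cells, population_id == "MDA_MB231")$s_epha_hat
test <- subset(chip$cells, population_id == "HN137m")$s_epha_hat
ks <- ks_compare(ref, test)
cat(sprintf("KS D = %.3f, p = %.2g\n", ks$D, ks$p))
#> KS D = 0.285, p = 1.6e-14
```

The same-seed cell pair differs only in how its 40 puncta are placed:
at aggregation 0.9 most of the signal stacks into at most three central
aggregates, concentrating the intensity histogram and roughly doubling
the entropy score. The chip's simulated ×1.3 gain inflates the raw
reference mean to 1.45, which normalization divides away; the two
populations then differ decisively in distribution shape (KS test).

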