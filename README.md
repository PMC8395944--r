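# immunorewire

Tools for quantifying **immune remodeling** in tumors profiled by
two-condition (control vs treated) single-cell RNA-seq of sorted CD45+
cells, with a companion tumor growth-curve test. The package targets the
standard design in mouse immuno-oncology: graft a syngeneic tumor, treat
one arm, sort the infiltrating immune cells, and ask what changed — in
composition, in effector phenotype, and in cell-to-cell signaling.

## What it computes

| Stage | Method |
|---|---|
| Synthetic data | Negative-binomial scRNA-seq counts with planted cell types, library-size variation and treatment effects; exponential tumor growth curves with a planted endpoint reduction |
| QC | Keep cells with `min_features < detected genes < max_features` (default 200/4000, strict) and mitochondrial % strictly below 3 |
| Normalization | `log1p(10^4 × count / cell total)` |
| Clustering | PCA → kNN graph → asynchronous label-propagation communities (seeded, deterministic) |
| Annotation | Marker-sign panel (14 immune populations: M1/M2 macrophage spectrum, monocytes, CD4/CD8 T, NK, T_M, DC); cluster score = mean of `sign(t,g) · z(c,g)` over the panel, z-scored across clusters |
| Population shifts | Per-cell marker-set means compared between arms by a two-sample Kolmogorov–Smirnov test on the ECDFs: `D = sup |F̂_ctl − F̂_trt|`, asymptotic p with small-sample correction |
| Differential expression | Wilcoxon rank-sum (tie-corrected normal approximation) with detection gates `max(pct₁, pct₂) ≥ 0.25` and `|logFC| ≥ 0.25`, `logFC = ln(mean(expm1 x_trt)+1) − ln(mean(expm1 x_ctl)+1)`; BH adjustment per cell type |
| Ligand–receptor scoring | `score = mean(ligand \| sender) × mean(receptor \| receiver)` per condition; `delta = treated − control`; ligands prefiltered at DE p < 0.05; label-propagation communities on the LR gene graph |
| Growth curves | `V = W²L/2`; group comparison by permuting mouse labels, statistic = mean over days of \|difference of group mean volumes\|, `p = (1 + #{perm ≥ obs})/(1 + n_perm)` |

Everything is exercised on synthetic data with planted ground truth — no
external downloads.

## Worked example

```r
library(immunorewire)

cfg <- run_config(out_dir = "demo_run", seed = 1, n_perm = 1000)
man <- run_pipeline(cfg)
man
#> RunManifest (seed 1 )
#>   simulate   ok (4 file(s))
#>   qc         ok (1 file(s))
#>   cluster    ok (1 file(s))
#>   annotate   ok (2 file(s))
#>   popfreq    ok (1 file(s))
#>   de         ok (1 file(s))
#>   lrscore    ok (1 file(s))
#>   lrnet      ok (1 file(s))
#>   growth     ok (2 file(s))

read.delim("demo_run/popfreq.tsv")
#>   cell_type                   markers n_control n_treated         D            p direction
#> 1     CD8_T Gzmb,Gzmk,Prf1,Ifng,Lamp1       263       430 0.4587231 7.423961e-31         1
#> 2        NK Gzmb,Gzmk,Prf1,Ifng,Lamp1       174       270 0.3911877 7.536734e-15         1

read.delim("demo_run/growth_test.tsv")
#>   statistic n_perm           p endpoint_reduction
#> 1  360.3336   1000 0.000999001          0.6463621
```

Reading: the cytotoxic-marker distribution of CD8 T and NK cells shifts up
under treatment (`direction = 1`, KS p ≪ 0.05) — the planted effector
program; the treated arm's endpoint tumor volume is reduced by ~65%
(planted: 66%) with permutation p = 1/1001. The DE table (`de.tsv`)
recovers the planted fold changes, and `lr_scores.tsv` ranks the planted
Ccl5/Ccl22/Cxcl13 signaling shifts by `delta`.

A command-line front end covers the same stages:

```sh
exec/immunorewire simulate --n-cells 500 --seed 1 --out-dir sim
exec/immunorewire run --in-dir sim --seed 1 --out-dir results
```

## Documentation

See `vignettes/immune-remodeling-methods.Rmd` for the model and every
numerical design choice (boundary semantics, stand-in tests, seeding
scheme, known limitations of the annotation scoring, and what the
synthetic world does and does not emulate).
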