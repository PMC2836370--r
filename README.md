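# methcna

Integrative analysis of DNA methylation and copy-number alteration (CNA) in
tumors.

Tumor genomes are reshaped by two largely distinct somatic processes:
epigenetic dysregulation, visible as altered CpG methylation (the array beta
value, β = max(M, 0)/(|U| + |M| + 100) from methylated/unmethylated
fluorescence), and structural instability, visible as integer copy-number
states (CNS) along the chromosomes. `methcna` implements the statistical
machinery for asking whether these processes are coordinated **globally** —
does genome-wide CNA burden, mean |CNS − 2| over all loci, differ between
methylation-defined tumor classes? — while remaining uncorrelated
**locally**, CpG by CpG.

The toolkit covers:

- **RPMM methylation classing** — recursively partitioned mixture of beta
  distributions over CpG profiles, fit by weighted EM with BIC-gated binary
  splits; leaves are methylation classes, and the root split defines the
  left/right class grouping used for stratified analyses.
- **Copy-number calling** — a 5-state Gaussian HMM on log2 ratios
  (emission mean log2(max(s, 0.5)/2) for s = 0..4) decoded by Viterbi, and
  the per-tumor burden statistic mean |CNS − 2|.
- **Global association test** — Kruskal–Wallis H of burden across
  methylation classes with a 10,000-iteration label-permutation p-value
  (add-one estimator), plus Fisher/Monte-Carlo-Fisher/Wilcoxon covariate
  tests against the high/low CNA grouping.
- **Local correlation screen** — nearest-coordinate CpG↔SNP matching,
  promoter (upstream-of-TSS) averaging to gene level, Pearson correlation
  with 5,000-permutation two-sided p-values and Storey q-values, significance
  at q < 0.05.
- **Alteration tests** — Welch two-sample t (tumor vs normal methylation)
  and one-sample t against CN = 2, as volcano tables stratified by the RPMM
  left/right grouping.
- **Clustering layer** — Ward clustering of tumors on Hamming distances
  between state profiles, dichotomized into high/low CNA groups, and the
  LINE-1 global-methylation difference between those groups with a Welch CI.
- **Synthetic cohorts** — `simulate_cohort()` generates methylation + CNA
  cohorts with latent classes, recurrent segmental alterations whose rate is
  coupled to class membership, optional planted gene-level
  methylation–copy-number coupling, and full ground truth for calibration,
  power, and recovery studies.

## Worked example

```r
library(methcna)

co     <- simulate_cohort(simulation_config(seed = 7))   # 19 tumors, 11 normals
burden <- cn_burden(co$cn)                               # mean |CNS - 2| per tumor
gt     <- permutation_test_global(burden, co$truth$class_label,
                                  n_perm = 10000, seed = 7)
print(gt)
#> Permutation Kruskal-Wallis test: H = 14.0237, p = 0.0004 (10000 permutations)
#>  class n median_burden mean_burden
#>      1 4        0.4855     0.50010
#>      2 4        0.0538     0.04975
#>      3 4        0.5179     0.52130
#>      4 4        0.0121     0.02525
#>      5 3        0.0268     0.03500
```

Classes 1 and 3 carry genome-wide burden around 0.5 while the remaining
classes sit near the 0.05 background, and the permutation test rejects the
hypothesis that burden is exchangeable across methylation classes
(p = 0.0004, well under the 0.002 level): copy-number and methylation
alteration are globally coordinated in this cohort.

```r
grp <- dichotomize_cna(ward_cluster(hamming_matrix(co$cn)), burden)
l1  <- line1_summary(co$line1)
line1_group_difference(setNames(l1$line1, l1$sample), grp)
#> LINE-1 difference (high - low): -6.4%   95% CI (-19.2, 6.4)
```

High-CNA tumors show lower LINE-1 (surrogate global) methylation; with 11
measured samples the interval is wide, as expected at this cohort size.

The one-call pipeline `run_pipeline(analysis_config(seed = 1), out_dir,
cohort = co)` chains every stage and writes all result tables (TSV) and a
JSON run manifest; identical seeds reproduce the outputs byte-identically.

## Vignette

`vignettes/methcna-methods.Rmd` documents the models, the tunable
parameters and their defaults, what the synthetic-data generator does and
does not emulate, and the numerical choices behind the EM, HMM, and
permutation machinery.
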