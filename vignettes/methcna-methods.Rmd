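---
title: "Methods: integrative methylation / copy-number analysis in methcna"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: integrative methylation / copy-number analysis in methcna}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`methcna` asks two complementary questions about a tumor cohort profiled for
both CpG methylation (beta values in [0, 1]) and SNP-array copy number
(integer states 0–4): whether genome-wide copy-number alteration (CNA) is
**globally** coordinated with the tumor's methylation profile class, and
whether methylation and copy number are **locally** correlated locus by
locus. This vignette documents the models behind each stage, the parameters
that matter, and the numerical and design choices, in the package's own
terms.

## Methylation classes: the RPMM model

Tumor methylation profiles are clustered by a recursively partitioned
mixture model. At each tree node, samples (with soft membership weights
inherited from ancestors) are modeled as a 2-component mixture in which each
CpG follows an independent beta distribution per component:

$$ f_k(x_i) = \prod_j \mathrm{Beta}(x_{ij};\, a_{kj},\, b_{kj}), \qquad
   x_i \in [0,1]^J . $$

The beta family is the natural emission model for methylation fractions:
bounded support, flexible skew, and a variance that shrinks near 0 and 1 the
way array betas do. Its cost is the independence assumption across CpGs —
co-methylated CpG blocks are treated as independent evidence, which
overstates certainty; this is shared with the mixture-of-betas clustering
tradition and is acceptable for class discovery, less so for per-class
inference.

Fitting is weighted EM:

* **E-step**: responsibilities from the profile-level mixture (one latent
  class per *sample*, shared across its CpGs).
* **M-step**: per CpG and component, the weighted beta likelihood is
  maximized by 2-D Newton iteration on (a, b) with analytic digamma/trigamma
  derivatives and step halving, warm-started from the previous parameters
  (weighted method of moments at the first iteration). Step halving accepts
  only non-decreasing objectives, so the observed-data log-likelihood is
  monotone across EM iterations — a property the test suite asserts on every
  fixture.
* Shape parameters are clamped to [1e-4, 1e4] and betas to
  [1e-6, 1 − 1e-6]; the beta log-likelihood diverges at {0, 1}, and the caps
  stop tiny nodes from collapsing onto point masses.

A split is accepted iff the 2-component BIC is lower than the 1-component
BIC at that node, counting 2 parameters per CpG per component plus one
mixing weight, with the node's total sample weight as the effective n; both
children must retain at least `min_node_weight` (default 2) effective
samples, and recursion stops at `max_depth` (default 3). Component order is
canonicalized (lower-mean-methylation child = "left"), leaves are numbered
left to right, and samples are assigned to the leaf with the largest
cumulative responsibility (ties to the left). The root split's two sides are
the "left/right class" grouping used by the stratified alteration tests.

EM restarts (default 5) use deterministic random-projection splits of the
profiles derived from the seed and the node's tree path — not from sample
order — so the classing is invariant to permuting input rows, which the
suite also asserts.

**Known behavior at small n:** with 19 tumors and 1,500 CpGs the BIC
penalty, ~2·J·log(n), is large relative to the class signal, and de-novo
classing is unstable: nodes may refuse to split or over-split near the
minimum node size. This mirrors the method's real-data practice of fitting
classes on larger cohorts and carrying them to subsets. Recovery is reliable
in the regime the recovery tests use (40 samples, class pairs differing by
gap 0.6 at 20% of CpGs: adjusted Rand index ≥ 0.9).

## Copy-number states and burden

States are inferred from log2 tumor/normal ratios by a 5-state Gaussian HMM:
emission mean log2(max(s, 0.5)/2) for s ∈ {0..4} — the 0.5 floor avoids
log2(0) for homozygous deletions — shared emission sd (default 0.2, the
scale of a well-normalized array track), self-transition probability
`stay_prob` (default 0.98, matching segment lengths of tens of loci), and
the remaining mass split uniformly over the other four states since no
transition-decay structure is assumed. Chromosomes are decoded independently
by Viterbi; score ties break toward the state closer to diploid, then the
lower state. The decoder is checked against exhaustive path enumeration on
short chains and recovers ≥ 95% of states at emission sd 0.2 on segmental
tracks. This module is a generic, documented stand-in for vendor CNA
pipelines: no Gaussian pre-smoothing and no paired-normalization steps are
applied (inputs are assumed normalized; optional per-tumor median centering
is off by default).

The per-tumor **burden** is mean |CNS − 2| over loci (0 for a fully diploid
genome, at most 2 for states 0–4), with missing loci excluded pairwise.

## Global association test

Burden is compared across methylation classes with the Kruskal–Wallis H
statistic (midranks, ties correction) under a label-permutation null:
class labels are permuted over tumors (equivalent to permuting burdens under
exchangeability, with simpler bookkeeping), and

$$ p = \frac{1 + \#\{H_b \ge H_{obs}\}}{n_{perm} + 1}, \qquad
   n_{perm} = 10{,}000 \text{ by default}, $$

the add-one estimator, which never returns 0 and has resolution floor
1/(n_perm + 1). Only the partition matters — relabeling class identities
leaves p unchanged. No asymptotic chi-square p is reported; at 19 tumors the
permutation distribution is the honest reference. Covariate checks against
the high/low CNA grouping use Fisher's exact test (stage dichotomized I/II
vs III/IV; HPV16), Fisher with Monte-Carlo simulation for site (> 2 levels;
100,000 draws by default, seeded), and the Wilcoxon rank-sum test for age.

## Local integration screen

Each CpG is matched to the nearest SNP on the same chromosome by coordinate
(ties to the lower coordinate; no distance cutoff by default, matching is
typically within 1 kb on dense arrays). Gene-level summaries average beta
over a gene's upstream-of-TSS ("promoter") CpGs and state over the gene's
SNPs; genes lacking either are excluded with a reason flag.

Per unit, the Pearson product-moment correlation is computed over tumors —
Pearson rather than a rank correlation because HMM states are discrete with
heavy ties — with a two-sided permutation p-value on |r| (5,000 permutations
by default) obtained by permuting the methylation vector while copy number
stays fixed. One permutation schedule, drawn from the seed, is shared by all
units: results are reproducible and comparable across units, at the price of
weak dependence between unit-level p-values (irrelevant for the marginal
q-value machinery). Units with zero variance or fewer than 3 complete pairs
are excluded with flags.

False-discovery control uses Storey q-values: π₀ estimated on the λ grid
0.05–0.95 (step 0.05) with a cubic smoothing spline (3 df) extrapolated to
λ → 1 and clamped to (0, 1]; q is the usual running minimum of
π₀·m·p/rank, monotone in p. With fewer than 10 p-values the estimator is
unstable, and the implementation falls back to π₀ = 1 — exactly
Benjamini–Hochberg, which the tests verify against `p.adjust`. Significance
is declared at q < 0.05.

The screen's designed behavior under the package's central scientific claim
— global coordination without local coupling — is testable by simulation:
with class-coupled burden but no planted gene coupling, ≤ 5% of gene units
reach q < 0.05, while planted genes with target |r| = 0.95 are recovered
with power ≥ 0.8 (both exercised in the acceptance suite).

## Alteration tests and stratification

Methylation alteration per unit is a two-sided Welch (unequal-variance,
Satterthwaite df) t-test of tumors against normals; copy-number alteration
is a one-sample t of gene-mean CN against the diploid expectation 2. Mean
alterations are reported in beta units and copies respectively, and volcano
tables carry −log10 p consistent with the test p to 1e-12. Zero-variance
units at the null value get t = 0, p = 1; zero-variance units off the null
are excluded as degenerate rather than assigned p = 0 (no infinities,
flagged for audit). The multiple-testing family is one per (alteration type
× stratum) — the narrowest defensible reading of a per-analysis q < 0.05
rule. Both tests are rerun within the RPMM left/right strata; strata with
fewer than 2 tumors are skipped with a flag.

## Clustering layer

Tumor CN profiles are clustered on Hamming distances (mismatch counts;
pairwise-complete with rescaling to the full locus number when states are
missing) by Ward's minimum-variance method. The Ward recurrence is applied
to squared input distances (the "ward.D2" convention) since the metric is
non-Euclidean and the variant is otherwise ambiguous; `squared = TRUE`
selects the raw-distance ("ward.D") variant. Cutting at k = 2 and labeling
the heavier-mean-burden cluster "high" yields the high/low CNA grouping; an
exact tie labels the larger cluster "low" with a warning. The LINE-1
comparison reports mean(high) − mean(low) in percentage points with a Welch
95% CI (point estimate only, flagged, when a group has < 2 values).

## The synthetic cohort generator

`simulate_cohort()` emulates the data structure the analysis assumes, with
defaults at the study design's scale: 19 tumors + 11 normals, 1,500 CpGs in
the promoter regions of 800 genes, 5,000 SNP loci over 22 autosomes (a
reduced-scale stand-in for a 500k array), K = 5 latent classes, and LINE-1
pyrosequencing triplicates for 11 tumors.

* **Methylation**: class-informative CpGs (fraction `informative_frac`,
  default 0.5) follow a block design — class k is hypermethylated (mean 0.8)
  at its own block and hypomethylated (mean 0.2) at the other classes'
  blocks, so every class pair differs at 2/K of the informative CpGs;
  uninformative CpGs share one tumor law and normals draw from a distinct
  normal-epithelium law. All betas use a (mean, precision)
  parameterization, precision 40 (≈ sd 0.06 at beta 0.2), the scale of
  bead-averaged array noise. The 0.5/40 defaults put a 19-sample cohort in
  the regime where class structure is detectable; panels targeted at
  cancer-relevant genes are class-informative at a large share of loci.
* **Copy number**: a shared per-chromosome segment grid (geometric lengths,
  mean 50 loci) carries a recurrence weight (hotspot propensity,
  Beta(0.5, 1.5)) and a preferred direction (gain or loss) per segment —
  emulating the recurrent arm-scale and focal events of tumor genomes, which
  is what makes Hamming/Ward clustering group high-CNA tumors. Without
  recurrence, two heavily altered genomes are as distant from each other as
  from diploid ones and no CNA clustering signal exists. Each tumor alters
  segments at a rate scaled (solved exactly against hotspot saturation) so
  its expected altered-locus fraction matches its burden target: classes 1
  and 3 target burden 0.5, the rest 0.05, interpolated by the coupling
  κ ∈ [0, 1] (κ = 0 is the exchangeable null by construction). Altered
  states draw from {0, 1, 3, 4} with probabilities {.15, .35, .35, .15}
  renormalized within the segment's direction, so E|CNS − 2| = 1.3 per
  altered locus and the maximum achievable burden is 1.3 (higher targets are
  rejected). Normals are exactly diploid (tumor ratios are referenced
  against matched normal DNA). Log ratios add N(0, sd = 0.2) to
  log2(max(s, 0.5)/2).
* **Local coupling**: `plant_local_coupling()` drives both a gene's promoter
  betas and its SNP states from one tumor-level latent Gaussian with target
  correlation ρ, giving expected gene-level Pearson r of the requested sign
  and approximate magnitude (rounding to integer states attenuates |r|
  slightly; planted 0.95 realizes ~0.85–0.95).
* **LINE-1**: per-sample means of 52% (high-burden tier) vs 65.2% (low),
  between-sample sd 8, within-replicate sd 2 — a planted high-minus-low
  difference of −13.2 percentage points at realistic pyrosequencing noise.
* **Not emulated**: tumor purity/stromal dilution, bead-level replicates,
  CNV polymorphism in normals, methylation measurement bias inside deleted
  regions, chromosome-specific alteration preferences, and real genomic
  coordinates. Passing tests therefore demonstrate correctness and
  calibration of the statistics under the assumed generative structure, not
  robustness to these real-data complications.

The segment-length distribution (geometric, mean 50) is a modeling choice:
it yields a mix of focal and near-arm-scale events with a one-parameter
knob.

## Reproducibility and problem sizes

Every stochastic stage derives a named child seed from the master seed (and,
inside RPMM, from the node's tree path), so stage-level reruns and full
pipeline runs are byte-identical for a fixed configuration; the pipeline
writes a JSON manifest of seed, parameters, and dimensions beside its TSV
outputs. Missing values are propagated by pairwise-complete deletion, never
imputed. Coordinates are 0-based half-open internally (BED convention on
disk).

The test and acceptance suites choose problem sizes that keep each
simulation informative at modest cost: the headline cohort at the full
default scale (19 tumors, 5,000 SNPs, 10,000 permutations); null calibration
over 1,000 reduced cohorts (500 SNP loci, 999 permutations); screen power
and specificity over full-scale cohorts with 10 planted genes and 5,000
permutations; RPMM recovery on 40-sample, 100-CpG 4-class fixtures; HMM
accuracy over 30,000 simulated states; LINE-1 CI coverage over 2,000 Welch
replicates.

## Limitations

* De-novo RPMM classing at n ≈ 19 is unstable (see above); the package
  accepts externally supplied class labels everywhere class labels are
  consumed.
* The permutation tests assume exchangeability of tumors under the null —
  batch structure or cohort substructure would violate it.
* The q-value machinery treats units as a marginal family; the shared
  permutation schedule and genomic correlation induce dependence that BH-type
  procedures tolerate but do not model.
* The HMM stand-in does not reproduce any vendor pipeline's smoothing or
  transition decay; called states on real arrays will differ from vendor
  calls, though burden is robust to modest state disagreement.
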