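---
title: "Selecting and evaluating ancestry-informative marker panels"
author: "aimsel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Selecting and evaluating ancestry-informative marker panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aimsel)
```

## The problem

A recently admixed population — the canonical example is the
African-American population, formed over the last few centuries from
West-African and European sources — carries long chromosomal blocks of
single ancestry that recombination has not yet broken up. Admixture
mapping and ancestry-aware association testing exploit this structure,
but they need a panel of *ancestry informative markers* (AIMs): SNPs
whose allele frequencies differ sharply between the ancestral
populations. Since genotyping budgets are finite, the practical question
is which ranking statistic picks the most informative small panel, and
how panels chosen by different statistics compare.

`aimsel` implements the five measures in common use, panel construction
with a physical-spacing constraint, three concordance analyses (Spearman
correlation, decile-based Cohen's kappa, top-*n* overlap patterns), a
maximum-likelihood estimator of individual admixture proportions, panel
evaluation (discriminant accuracy, bias, RMSE, random-subset and
sensitivity experiments), and a forward-time simulator that provides
ground-truth individual ancestries.

## The five measures

All five operate on reference-allele frequencies `p1`, `p2` of a
biallelic SNP in the two ancestral populations (`aim_in()` also accepts
K ≥ 2 populations and N ≥ 2 alleles).

* **δ** `= |p1 − p2|`. Scale [0, 1]; 1 means fixed difference.
* **F_ST** `= (p1 − p2)² / [(p1 + p2)(2 − p1 − p2)]`, the two-population
  biallelic form; equivalently `(p1 − p2)²/(4 p̄(1 − p̄))`. Undefined when
  both populations are fixed for the same allele (0/0); such markers
  carry no ancestry information and are scored 0 with a `monomorphic`
  flag.
* **FIC** `= Σ_j δ_j²/p_Aj`, where `p_Aj = p_2j + m1 δ_j` is the expected
  admixed frequency under an assumed contribution `m1` of population 1.
  FIC rewards markers close to fixation in the majority-contribution
  population, and therefore *requires* `m1 ∈ (0, 1)` strictly. For
  in-range `m1` the admixed frequency is a strict convex combination, so
  it can vanish only when `δ_j = 0` (which contributes 0); the
  documented `+Inf` return for a zero `p_Aj` with nonzero `δ_j` is a
  guard for degenerate inputs and ranks above every finite score.
* **SIC** `= m1 Σ p_1j log p_1j + m2 Σ p_2j log p_2j − Σ p_Aj log p_Aj`:
  the entropy of the admixed allele distribution minus the `m`-weighted
  average of the ancestral entropies. By concavity of entropy this is
  non-negative (a Jensen–Shannon-type divergence).
* **I_n** `= Σ_j [−p̄_j log p̄_j + Σ_i p_ij log p_ij / K]`, the expected
  log-likelihood ratio of assigning an allele to its own population
  versus an "average" population; bounded by `log K`.

Numerical conventions: `0·log 0 = 0` throughout; the natural logarithm
is the default for SIC and I_n with a `log_base` option (`exp(1)` or 2) —
the base rescales values, never ranks, so every downstream panel is
base-invariant. The default assumed contribution is `m1 = 0.8`
(a majority contribution of 80%, the conventional operating point for
FIC/SIC in two-way African/European-style scenarios); it is always
user-overridable and `sensitivity_overlap()` quantifies how much the
FIC/SIC rankings move when it is misspecified.

Ranks are assigned in descending score order with a deterministic
tie-break — (chromosome, position, marker id) — so every ranking,
decile grouping and panel is reproducible. No convention for ties is
universal; this one was chosen because it is total, cheap and follows
genome order.

## Panels

`distance_filter()` implements the standard LD-avoidance heuristic:
selected AIMs must be at least 100 kb apart (configurable). Selection is
*greedy by score*: markers are admitted in rank order and rejected if a
better marker on the same chromosome is strictly closer than the
threshold. A left-to-right genomic scan would keep whichever marker
happens to come first on the chromosome; the greedy rule keeps the most
informative marker of each crowded region, which is the intent of
filtering "for the most informative ones". Exactly 100,000 bp apart is
allowed ("at least 100 kb"). `select_markers()` applies top-n (erroring,
not truncating, when n exceeds the panel), top-fraction (with
`ceiling`, so any positive fraction returns at least one marker) and
cutoff rules; the conventional literature cutoffs (δ ≥ 0.3, F_ST ≥ 0.4,
FIC ≥ 2.0, SIC ≥ 0.3, I_n ≥ 0.3) are available via `aim_cutoffs()`.
`combined_rank()` builds the AVE (mean of the five ranks) and MIN
(best single rank) composite rankings; raw scores are never averaged
because the five measures live on incomparable scales.

## Concordance

`spearman_rho()` is the Pearson correlation of tie-averaged ranks.
`decile_groups()` orders markers by informativeness and cuts them into
ten groups of equal size (±1), group 1 the most informative; with the
global tie-break the labels are deterministic even for heavily tied
scores. `kappa_deciles()` computes Cohen's κ = (Pr(a) − Pr(e))/(1 −
Pr(e)) from the decile cross-tabulation and returns the full
contingency table. κ below zero (worse than chance) is reported and
flagged rather than clamped: clamping would hide genuine disagreement.
`overlap_patterns()` encodes top-n membership as a 5-digit binary
pattern in the fixed order (δ, F_ST, FIC, SIC, I_n) — `"11001"` means
selected by δ, F_ST and I_n only — and counts patterns over the union
plus all ten pairwise intersections. Deciles are normally computed on
the distance-filtered set that downstream analyses consume, but any
score vector can be supplied.

## Admixture estimation

For individual genotypes `g_l ∈ {0, 1, 2}` (copies of the reference
allele) and a candidate proportion `q` from population 1, the model is
Hardy–Weinberg within individuals and independence across markers
(reasonable for spaced panels): `g_l ~ Binomial(2, q p_1l + (1−q)
p_2l)`. `estimate_ancestry()` maximizes this likelihood per individual
over `q ∈ [0, 1]`; it is the K = 2 special case of the EM-based global
ancestry estimators (PSMIX/FRAPPE-style) with the same maximizer found
by Brent's bounded search instead of EM, since the log-likelihood is
concave in `q`.

Numerical choices:

* allele frequencies are clamped to `[1e-6, 1 − 1e-6]` (configurable
  `eps`) so fixed alleles cannot produce `−Inf`;
* boundary candidates `q = 0, 1` are compared explicitly, and ties on
  the clamp plateau resolve to the boundary;
* estimates are snapped to a dyadic grid of spacing `2^-40` (≈ 9e-13,
  three orders below the search tolerance) so that `1 − q̂` is exactly
  representable: together with an internal canonical orientation of the
  two populations (the one with the larger total reference-allele
  frequency is treated as population 1 and the result flipped back),
  swapping the population labels returns exactly `1 − q̂`, bit for bit;
* missing genotypes are dropped per marker; an individual with no
  usable genotype is flagged and excluded from the sample mean;
* a panel with `p1 = p2` everywhere has a flat likelihood: the
  estimator warns and returns `NA` (non-identifiable) instead of an
  arbitrary interior point.

## Evaluation

`lda_accuracy_curve()` fits a two-class linear discriminant on the top-n
AIMs with pooled covariance, priors proportional to class sizes, and
classification by the largest posterior, reporting leave-one-out
cross-validated accuracy (the model is refit on every fold; "cross-
validation" is otherwise underspecified, and LOOCV is the deterministic
choice — a k-fold variant would only add a partitioning seed). A ridge
term `λ = 1e-6 · trace(Σ)/p` keeps the pooled covariance invertible when
panels approach the sample size; when the panel is perfectly fixed
(zero pooled variance) an absolute floor is used and the rule
degenerates gracefully to nearest-class-mean. `markers_needed()` reads
the first threshold crossing (90%/95%) off the curve, literally — a
non-monotone curve crossing early reports the early crossing.

`rmse_bias()` computes `rmse = sqrt(mean((q_i − q̂_i)²))` over
individuals and `bias = |mean(q̂) − mean(q)|` at the population level.
`random_subset_experiment()` draws, for each measure and each of the
top 1/2/5/10% panels, repeated random subsets (default 100 subsets of
20 markers), re-estimates the sample mean ancestry from each subset and
summarizes the signed errors; widening the source panel admits less
informative markers, so the mean magnitude and spread of the errors
grow from 1% to 10%. The whole experiment is reproducible from one
seed. `sensitivity_overlap()` scores the table under two assumed
contributions and counts the 11/10/01 membership patterns of the two
top-fraction sets; δ, F_ST and I_n ignore the contribution and serve as
controls (always 100% overlap).

## The synthetic-data generator

The simulator replaces haplotype-resampling machinery with a
self-contained parametric equivalent, so all analyses run without any
external data.

* **Ancestral frequencies.** Each marker gets an ancestral frequency
  `p ~ Uniform(0.05, 0.95)` — emulating a common-variant (MAF > 5%)
  filter — and two population frequencies drawn independently from the
  Balding–Nichols distribution `Beta(p(1−F)/F, (1−p)(1−F)/F)`. `F` is a
  one-parameter divergence knob. Under the pairwise statistic above,
  `E[F_ST] ≈ F/2`: the default `F = 0.15` yields a realized mean
  pairwise F_ST of about 0.07, the CEU/YRI (European/West-African)
  scale of differentiation, while the `chbjpt_config()` preset
  (`F = 0.015`) emulates a roughly ten-fold less differentiated pair
  such as CHB/JPT.
* **Demography.** An admixed deme of 200 founders, each founder drawn
  wholly from population 1 with probability `m0` (default 0.7, a 70:30
  founding contribution; 0.72 for the weak-divergence preset), followed
  by `G = 10` generations of random mating: monoecious, non-overlapping
  generations, constant deme size, two distinct parents per offspring,
  no selection, mutation or continued gene flow — the simplest scheme
  consistent with a one-pulse admixture model. 100 individuals are
  sampled from the final generation.
* **Recombination.** Crossovers per chromosome are Poisson with mean
  `recomb_rate × length` (Haldane model, default 1e-8 Morgans/bp, the
  human genome-wide average over 22 chromosomes of 125 Mb), positions
  uniform, chromosomes assorting independently.
* **Truth.** Every allele copy carries an ancestry label through
  meiosis; an individual's true ancestry `q_i` is the fraction of its
  `2L` allele copies labelled population 1. This marker-weighted
  definition (rather than physical-length-weighted) is exactly the
  quantity the genotype-based estimator targets, so estimator error is
  measured against the right truth.

Because the deme is finite, the realized mean ancestry drifts around
`m0` (standard deviation of a few percent after 10 generations in a
deme of 200); evaluation therefore always compares estimates to the
*realized* truth of the run, not to the nominal `m0`. What the
generator does **not** emulate: background LD within the ancestral
populations (markers are drawn independently given the frequencies),
mutation, non-random mating, continuous migration and genotyping error.
Passing tests on this synthetic data therefore demonstrate correctness
of the statistics and the estimation machinery under the model's
assumptions — not robustness to LD or data artefacts in real panels.

## Problem sizes and reference conditions

The package's own end-to-end checks run the reference scenario at
20,000 markers, deme size 200, 100 sampled individuals and 10
generations, with three fixed replicate seeds; the random-subset
experiment uses 100 subsets of 20 markers per (measure, fraction) cell.
These sizes keep a full replicate under a minute on one CPU while
leaving the qualitative behaviour (panel concordance structure,
error-growth trends, FIC/SIC sensitivity direction) clearly resolved.

## Known limitations

* δ, F_ST (this biallelic form), FIC and SIC are two-population
  statistics; only I_n is implemented for K > 2, and multiallelic
  variants are out of scope.
* The estimator infers a single global proportion per individual; it
  does not model local ancestry along chromosomes (no hidden-Markov
  ancestry blocks).
* Real-data panel sizes after distance filtering depend on the
  tie/ordering convention; the package promises the spacing invariant
  and deterministic output, not reproduction of any particular
  published panel size.
* The HapMap-dialect reader parses the allele-frequency file layout
  (one population per file) only; VCF/PLINK ingestion is deliberately
  out of scope — frequency tables are the unit of exchange.
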