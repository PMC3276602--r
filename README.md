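# aimsel — ancestry-informative marker selection and admixture estimation

Admixture mapping and ancestry inference in recently admixed populations
(e.g. African-Americans, with European and West-African ancestral sources)
rely on small panels of **ancestry informative markers (AIMs)**: SNPs whose
allele frequencies differ strongly between the ancestral populations.
Several competing statistics are in routine use for ranking candidate
SNPs, and they do not select the same markers. `aimsel` implements the
five standard measures, the machinery to turn scores into spaced AIM
panels, statistics to quantify how much the measures agree, a
maximum-likelihood estimator of individual admixture proportions, and a
forward-time admixture simulator with tracked truth so that panels can be
evaluated against known individual ancestries.

It is aimed at statistical geneticists designing AIM panels or comparing
selection criteria before committing to genotyping.

## The five measures

For a biallelic SNP with reference-allele frequencies `p1`, `p2` in the
two ancestral populations, an assumed contribution `m1` of population 1
to the admixed gene pool, per-allele differences `δ_j = p_1j − p_2j` and
expected admixed frequencies `p_Aj = m1 p_1j + (1 − m1) p_2j`:

| measure | definition | needs `m1`? |
|---|---|---|
| δ (delta) | absolute difference `abs(p1 − p2)` | no |
| F_ST | `(p1 − p2)² / [(p1 + p2)(2 − p1 − p2)]` | no |
| FIC (Fisher information content) | `Σ_j δ_j² / p_Aj` | yes |
| SIC (Shannon information content) | mixture entropy minus `m`-weighted ancestral entropies | yes |
| I_n (informativeness for assignment) | `Σ_j [−p̄_j log p̄_j + Σ_i p_ij log p_ij / K]` | no |

δ, F_ST, FIC and SIC are two-population statistics; I_n generalizes to
K ≥ 2 populations and is bounded by `log K`. Entropy-based measures use
the natural logarithm by default (a `log_base` switch rescales values but
never reorders markers). Admixture proportions are estimated per
individual by maximizing the Hardy-Weinberg likelihood
`Π_l Binom(g_l | 2, q p_1l + (1 − q) p_2l)` over `q ∈ [0, 1]`.

## Worked example

Simulate a CEU/YRI-scale scenario (differentiation `F = 0.15`, admixed
deme founded 70:30 and randomly mated for 10 generations), score the
markers, build a spaced panel and re-estimate ancestry:

```r
library(aimsel)

cfg   <- sim_config(L = 5000, chrom_lengths = rep(125e6, 10), seed = 7)
freqs <- generate_ancestral_freqs(cfg)
sim   <- simulate_admixed(freqs, cfg)
sim
#> Simulated admixed population: 100 individuals x 5000 markers
#>   m0 = 0.7, G = 10 generations; realized mean q_true = 0.6489

scores <- score_markers(freqs, m1 = 0.8)
round(colMeans(scores[, c("delta", "fst", "fic", "sic", "i_n")]), 3)
#> delta   fst   fic   sic   i_n
#> 0.182 0.070 0.328 0.025 0.038

panel <- select_markers(distance_filter(scores, "i_n"), top_n = 20)
head(panel, 3)
#>   marker_id chrom       pos     score rank
#> 1 snp004938  chr9 110932568 0.4358350    1
#> 2 snp004736  chr9  62547352 0.3752284    2
#> 3 snp001111  chr2  32708799 0.3709261    3

est <- estimate_ancestry(sim$genotypes, freqs, panel)
est
#> Admixture estimates for 100 individuals: mean q_hat = 0.6194 (sd 0.1070)

unlist(rmse_bias(est, sim$truth))
#>       rmse       bias          n
#> 0.10606098 0.02952631 100.00000000

spearman_rho(scores$fst, scores$i_n)
#> [1] 0.999075
```

The realized mean ancestry (0.649) drifts away from the founding 0.70
because the deme is finite; the 20-marker panel recovers it to within
0.03 with a per-individual RMSE of about 0.11. F_ST and I_n rank markers
almost identically (Spearman 0.999), as expected from their functional
forms. `concordance_report()` adds decile-based Cohen's kappa and top-n
overlap patterns; `lda_accuracy_curve()`/`markers_needed()` measure how
many top AIMs a linear discriminant needs to separate the ancestral
samples; `random_subset_experiment()` and `sensitivity_overlap()` probe
panel robustness.

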