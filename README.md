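# eqtloverlap

Tools for asking whether quantitative trait loci (QTL) for production and
fertility traits are *expression* QTL (eQTL) — variants that act by moving
the mRNA abundance of a nearby gene — in multi-breed livestock populations
with long-range linkage disequilibrium. The package is aimed at quantitative
geneticists who have (or want to simulate) genome-wide dosage genotypes,
trait deviations of unequal accuracy, and an RNA-seq expression cohort.

It implements three complementary strategies end to end:

1. **Local GEBV × expression correlation.** Variant effects `a_j` are
   estimated jointly with Bayes R (a four-class normal-mixture prior with
   classes at 0, 10⁻⁴, 10⁻³ and 10⁻² of a variance scale, fitted by Gibbs
   sampling). Local genomic estimated breeding values over 250 kb sliding
   windows (step 50 kb), `locGEBV_{w,i} = Σ_{j∈w} x_{ij} a_j`, are ranked by
   their variance across individuals; the greedy non-overlapping set defines
   `Σσ²_locGEBV`. Window GEBVs are Pearson-correlated with the log expression
   of genes within 1 Mb, and the count of significant correlations is
   compared with a null that permutes effects within each window — which
   preserves the window's effect multiset and so isolates what LD alone can
   produce.
2. **top300 vs random300 enrichment.** The 300 highest-variance
   non-overlapping windows are compared with randomly drawn non-overlapping
   window sets through the filter chain nE → nG → nEG → nC → nEC → nEGC
   (eQTL present; variant correlated with the window GEBV; both for one
   variant and gene; GEBV correlated with expression; and all of it with
   consistent effect directions).
3. **Colocalisation.** For loci around QTL leads (mixed-model GWAS,
   sex-stratified scans combined by the sample-size weighted z-score model,
   leads at p ≤ 10⁻⁶ with ≥ 1 Mb spacing) and eQTL leads (cis scan,
   p ≤ 10⁻⁵, one per gene), per-variant posterior inclusion probabilities
   are computed in each study by enumerating causal configurations under
   `z ~ N(0, Σ + ncp²·Σ diag(c) Σ)`, and multiplied into the colocalisation
   posterior probability CLPP; CLPP ≥ 0.01 counts as shared.

Because the motivating data are not public, a first-class synthetic-data
module generates genotypes with tunable LD decay and Balding–Nichols
cross-breed divergence, trait deviations with sex-dependent accuracy,
negative-binomial expression counts with cis effects and covariates, and a
ground-truth causal registry (trait-only, expression-only, shared) so every
stage is testable by recovery. See the methods vignette
(`vignettes/qtl-eqtl-overlap.Rmd`) for the models, parameter meanings and
design choices.

## Worked example

```r
library(eqtloverlap)

g <- simulate_genotypes(c(A = 600, B = 200), m_variants = 1500,
                        chrom_lengths = c(3e7, 3e7), seed = 11)
truth <- implant_truth(g, n_trait_qtl = 12, n_eqtl = 12, n_shared = 4,
                       expr_effect_sd = 1.2, seed = 11)
pheno <- simulate_phenotypes(g, truth, h2 = 0.4, seed = 11)
truth <- attr(pheno, "truth")   # effects rescaled to the target h2

fit <- bayes_r_fit(g, pheno$deviation,
                   bayesr_config(iterations = 2000, burn_in = 500,
                                 thin = 4, seed = 11))
fit
#> EffectEstimates: 1500 variants; pi = (0.910, 0.069, 0.007, 0.014);
#>   sigma2_g = 0.4261, sigma2_e = 0.335

expr <- simulate_expression(g, truth, n_genes = 80, seed = 11)
g_cows <- subset_genotypes(g, individuals = attr(expr, "cohort"))
windows <- make_windows(g_cows$variants)
lg <- local_gebv(g_cows, fit, windows)
rank_nonoverlapping(lg)
#> NonOverlapRanking: U = 195 non-overlapping windows, sum sigma2 = 0.4045

expr_f <- filter_genes(expr, 25)
eq_calls <- select_eqtl(eqtl_scan(g_cows, expr_f, compute_grm(g_cows)), 1e-5)
nrow(eq_calls)
#> [1] 6
corr <- correlate_gebv_expression(lg, expr_f)
sum(corr$selected)
#> [1] 11
perm <- permutation_comparison(g_cows, fit, windows, expr_f,
                               reps = 20, seed = 11)
c(observed = perm$observed, permuted_mean = mean(perm$permuted))
#> observed permuted_mean
#>       11           4.8
```

Reading the numbers: the mixture estimate puts 91% of variants in the zero
class and recovers the simulated heritability (σ²_g ≈ 0.43 against a target
of 0.4); 195 non-overlapping windows carry the genetic variance; 6 genes get
a cis-eQTL call at p ≤ 10⁻⁵ in the 131-cow cohort; and 11 window–gene
correlations pass p ≤ 10⁻⁵, versus 4.8 on average when effects are permuted
within windows — the excess over the permutation null is the signal that is
not explained by LD within the window.

The full pipeline (simulation → filtering → GWAS/meta → Bayes R → windows →
eQTL → overlap → colocalisation, with all tables written as TSV/BED) runs
from one YAML-configurable call:

```r
res <- run_all(default_config(seed = 1), out_dir = "run1")
```

or from the shell via `inst/scripts/run_pipeline.R`.

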