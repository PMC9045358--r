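# mgscohort

Metagenomic species quantification and cohort association analysis.

`mgscohort` re-implements, as a tested and reusable R pipeline, the analysis
chain used in shotgun-metagenomics studies of the gut microbiome in clinical
cohorts — here modeled on an overweight/obese early-pregnancy cohort with
diet-quality scores (IDQ, 0–15 points) and serum markers of glucose
metabolism (insulin, glucose, HOMA2-IR, QUICKI) and low-grade inflammation
(hsCRP, GlycA). The stages:

1. **Read-pair filtering** — sliding-window quality trimming (window 4,
   Phred 20, minimum 100 bases), high-quality non-host (HQNH) pair
   retention, and the gene-catalog mapping acceptance rule
   (both mates MAPQ ≥ 20, alignment ≥ 100 bp, identity ≥ 95 %, a single
   candidate gene, ≤ 10 unaligned bases at either read end), duplicate
   removal, per-gene tallies and per-sample read accounting.
2. **MGS quantification** — a metagenomic species (MGS) is counted through
   its 100 designated *core genes*; an MGS is detected only if read pairs
   hit at least 3 distinct core genes, otherwise its count is zeroed.
   Relative abundance divides the core-count sum by the total core-gene
   length (kb) and closes each sample to 1. Rarefaction is an exact
   multivariate-hypergeometric subsample to a fixed depth (reference
   default 7,281,907 read pairs).
3. **Alpha diversity** — species richness and the Shannon index
   `H = −Σ pᵢ ln pᵢ` on rarefied profiles, plus quartile (Q1–Q4) groups.
4. **Beta diversity** — centered log-ratio (CLR) transform, Aitchison
   distance, and a single-covariate permutation PERMANOVA using the
   McArdle–Anderson trace form: with Gower-centered `G = −½ J D² J` and
   hat matrix `H` of the intercept+covariate design,
   `F = tr(HGH) / (tr((I−H)G(I−H)) / (n−2))`, permuting the covariate
   (exhaustive enumeration when `n! ≤ 10 080`); Bonferroni across the
   covariate family per stratum.
5. **Association battery** — Spearman correlations and Mann-Whitney U
   contrasts (diversity quartiles, BMI groups, dichotomized diet quality
   at 10/15 points), QUICKI = `1/(log₁₀ insulin + log₁₀ glucose[mg/dl])`,
   and a deliberately plain negative-binomial differential-abundance test
   (median-of-ratios size factors, per-taxon ML dispersion, Wald test,
   Bonferroni) for taxa against a continuous covariate.
6. **Functional analysis** — gene→KO→KEGG-module aggregation, the strict
   "> 40 % prevalence" module filter, and module-level Spearman/Wilcoxon
   associations with BH correction.

Because participant-level data of such studies are not publishable, the
package ships a first-class **synthetic cohort generator**: log-normal serum
markers moment-matched to published median/IQR scales, a Gaussian copula
that injects stratum-specific rank correlations (including with the latent
drivers of richness and Shannon diversity), abundance profiles whose
true-profile Shannon hits its target exactly, multinomial read allocation,
and alignment-record noise with known expected pass rates. Every analysis
stage is validated against this known ground truth.

## Worked example

```r
library(mgscohort)

co     <- generate_cohort(234, 152, seed = 1)    # cohort + ground truth
prof   <- generate_profiles(co, seed = 2)        # true MGS profiles
counts <- generate_mgs_counts(prof, seed = 3)    # multinomial read counts
rare   <- rarefy_counts(counts, 7281907, seed = 4)
div    <- alpha_diversity(rare)
tables <- replicate_result_tables(co$cohort, div, counts,
                                  n_perm = 999, seed = 5)

subset(tables$permanova, covariate == "glyca")
subset(tables$idq_diversity, index == "shannon")
```

```
    stratum covariate         f   r_squared p_raw n_perm p_adj        tier
        all     glyca  9.871138 0.025061846 0.001    999 0.004 significant
 overweight     glyca 12.864122 0.052535755 0.001    999 0.004 significant
      obese     glyca  1.156965 0.007654067 0.279    999 1.000          ns

    stratum   index         rho        p_raw        p_adj        tier
        all shannon  0.13843305 6.448000e-03 1.289600e-02 significant
 overweight shannon -0.02528679 7.003829e-01 8.176312e-01          ns
      obese shannon  0.37653350 1.743824e-06 3.487647e-06 significant
```

The default effect registry injects the stratum-specific structure the
pipeline is meant to resolve, and the output shows it resolved: GlycA
associates with community composition in the overweight stratum only
(PERMANOVA, Bonferroni over the four-covariate family per stratum), and
diet quality correlates with Shannon diversity in the obese stratum only.
Median Shannon (2.68) and richness (235) sit on the scale of a deeply
sequenced pregnancy cohort.

An end-to-end configuration-driven run (all tables, read accounting,
functional analysis, provenance manifest) is

```r
res <- run_pipeline(run_config(seed = 1), outdir = "runs/demo")
```

or, from a shell, the thin wrapper `inst/scripts/run_pipeline.R`.

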