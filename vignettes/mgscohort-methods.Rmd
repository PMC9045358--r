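---
title: "Models and methods behind mgscohort"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind mgscohort}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mgscohort)
```

`mgscohort` implements the quantification and statistical chain of a
shotgun-metagenomics cohort study — from read-pair filtering to
stratum-specific association testing — together with a synthetic cohort
generator that provides ground truth for every stage. This vignette explains
the models, the tunable parameters, the numerical choices, and what the
synthetic validation does and does not demonstrate about real data.

## Filtering and quantification rules

**Trimming.** `trim_read()` removes leading and trailing bases below
Phred 20, then truncates at the first 4-base window whose mean Phred falls
below 20, scanning 5′→3′ over full windows. Reads shorter than 100 bases
after trimming are discarded. Two details are deliberate: the window step
uses full windows only, and trailing sub-threshold bases exposed by the
window cut are stripped again. The second pass makes the operation
idempotent — `trim(trim(r)) == trim(r)` — which a one-pass reading of the
rule does not guarantee; without it a window cut can leave a low-quality
base at the new 3′ end. Adapter clipping is out of scope (synthetic reads
carry no adapters).

**Pair retention and mapping.** A pair is high-quality non-host (HQNH) iff
both mates survive trimming and the pair is not host-flagged. A mapping is
accepted iff `min(MAPQ₁, MAPQ₂) ≥ 20`, aligned length ≥ 100 bp, identity
≥ 95 %, the pair hits a single candidate gene, and no more than 10 bases at
either read end fail to align. All thresholds are inclusive at their stated
boundary; only the overhang rule is strict (`> 10` rejects). The MAPQ
aggregation over mates (minimum) and the per-pair reading of the 100-bp rule
(the shorter mate's aligned length) are design choices where the upstream
convention is ambiguous; both are arguments of `accept_mapping()`.
Duplicate removal keeps the first record per coordinate key — the survivor
choice is arbitrary and order-stable.

**MGS counting.** An MGS is quantified through its designated core genes
(default 100): the count is the sum over core genes, zeroed unless read
pairs hit at least `min_core_hits = 3` *distinct* core genes. Distinct genes
— not read pairs — is the operative reading of the detection rule. Non-core
genes never contribute. Relative abundance divides the core-count sum by the
MGS's total core-gene length in kb and closes each sample to 1; a per-gene
variant (sum of count/length over core genes) is available via
`mgs_profile(method = "per_gene")` because "normalizing for gene length" is
ambiguous between the two. Core-gene sets are declared by the generator
rather than estimated from co-abundance across a reference panel; the
panel-based estimation is a proprietary upstream step outside this package's
scope.

**Rarefaction.** `rarefy_counts()` draws an exact multivariate
hypergeometric subsample (sequential `rhyper`, O(#features) memory), so each
retained sample sums to the depth exactly and each feature's expectation is
depth × its original proportion. Samples below the depth are dropped with a
warning rather than resampled upward — upsampling would fabricate reads.
The reference depth 7,281,907 read pairs is recorded as the documented
default for alpha diversity; beta diversity always runs on unrarefied
counts.

## Diversity and compositional analysis

Richness is the number of detected (nonzero) MGSs; Shannon diversity is
`H = −Σ pᵢ ln pᵢ` in nats (natural log, the common ecology default;
`base` is an argument). Quartile groups use type-7 sample quantiles; tied
boundary values take the lowest applicable label, and a fully degenerate
vector is assigned Q1 with a warning. Quartile membership near boundaries
depends on the quantile convention, which is why it is pinned and
documented.

The CLR transform adds a pseudocount (default 1, intended for raw counts)
before logs; zero handling before log-ratio analysis is a genuinely open
choice and the pseudocount is exposed. The Aitchison distance is the
Euclidean distance between CLR rows.

PERMANOVA uses the McArdle–Anderson trace form on the Gower-centered
inner-product matrix, with the covariate — continuous or binary — entering
through an intercept-plus-slope hat matrix. Because `G` is doubly centered,
the model sum of squares reduces to `pᵀGp` for the normalized centered
covariate, which makes the permutation loop a single matrix product.
Significance permutes the covariate; the observed statistic is included in
numerator and denominator (`p = (1 + #{F* ≥ F}) / (1 + n_perm)`), the
standard guard against zero p-values, and all `n!` permutations are
enumerated exactly when `n! ≤ 10 080`. On Euclidean distances of univariate
data with a binary covariate the statistic reduces to the classical one-way
ANOVA F, which the tests verify to 1e-9, and F and R² agree with
`vegan::adonis2`. The PERMANOVA covariate family (default IDQ, insulin,
HOMA2-IR, GlycA) is Bonferroni-corrected within each stratum, family size 4.

## The association battery

Spearman and Mann-Whitney tests use midranks, exact enumeration for small
untied samples (n ≤ 9 pairs; m+n ≤ 12), and t- or normal approximations with
tie correction otherwise. Families are corrected per stratum; Bonferroni
where the upstream convention names it (PERMANOVA family, taxa-vs-marker
tests), Benjamini-Hochberg elsewhere — the SPSS-style analyses this mirrors
do not name their correction, so BH is the documented default and every
result row carries its family and method. Significance tiers are
adjusted P < 0.05 (significant) and < 0.1 (borderline).

QUICKI is computed as `1/(log₁₀ I + log₁₀ G)` with insulin in mU/l and
glucose converted to mg/dl (× 18.016); the formula as usually quoted is
unit-silent, and this is the convention under which the index lands in its
familiar 0.30–0.40 band. HOMA2-IR is modeled, not computed: the real index
comes from an external calculator, so the generator emits a synthetic
monotone stand-in, `insulin × glucose / 36.2 × exp(N(0, 0.1))`, whose
constant matches the published median at the configured insulin/glucose
medians.

The NB differential-abundance test is an intentionally plain version of the
negative-binomial framework used by count-based differential-abundance
tools: median-of-ratios size factors over all-positive taxa, per-taxon ML
dispersion (Poisson fallback at the dispersion→0 boundary), a Wald test on
the covariate slope with a t(n−2) reference — the small-sample guard — and
Bonferroni over tested taxa. There is no dispersion shrinkage across taxa,
no fold-change moderation, and no independent filtering; a 25 % prevalence
filter (configurable) excludes near-absent taxa before testing, and
non-convergent fits are reported but excluded from the family. Log-fold
changes are natural-log internally and also reported in log₂.

## What the generator emulates

`generate_cohort()` draws, per stratum, a latent multivariate normal over
(shannon, richness, IDQ, insulin, glucose, hsCRP, GlycA, age) whose
correlation matrix encodes the requested effects (Spearman targets converted
to latent Pearson via `2 sin(πρ/6)`; infeasible matrices are rejected as
configuration errors). Markers are log-normal, moment-matched to per-stratum
median/IQR on the scale of an overweight/obese early-pregnancy cohort
(insulin median 8 vs 13 mU/l, glucose 4.7 vs 4.8 mmol/l, hsCRP 4.5 vs
6.7 mg/l, GlycA 1.2 mmol/l in both strata); IDQ and age are normal, IDQ
clamped to [0, 15] and reported to 0.1 points. All markers are positive and
right-skewed in such cohorts, which motivates the log-normal choice; no
claim is made about the true distributional forms.

`generate_profiles()` maps each subject's richness latent to the number of
present species (median 237, SD 62, nested presence structure) and the
Shannon latent to a per-sample Shannon target (median 2.7, SD 0.297 nats).
Each profile is a dominant block of 50 species carrying 98 % of the mass —
truncated-log-normal weights whose spread is solved by root-finding so the
true-profile Shannon equals the target exactly — plus a rare tail spreading
2 % of the mass across all present species over one decade. The tail floor
keeps every present species above ~1e-5 relative abundance, hence reliably
detected at the reference depth, so observed richness equals the latent
driver and the injected rank correlations survive the counting pipeline
essentially unattenuated. A single log-normal block cannot do this: at
richness ≈ 237 and Shannon ≈ 2.7 its rare tail falls to ~1e-10 relative
abundance and detection noise destroys the richness signal. A strong
composition shift can lower the entropy ceiling of a profile; targets are
clamped just below the per-sample achievable maximum, which affects only
extreme samples.

The default effect registry injects: IDQ↔Shannon ρ = 0.35 in the obese
stratum only; richness↔insulin and richness↔GlycA ρ = −0.32 in the
overweight stratum only (HOMA2-IR and QUICKI inherit their associations
through insulin, as derived quantities should); a Shannon–richness coupling
of 0.5 in both strata; and a GlycA-driven shift of 30 dominant-block taxa
(±0.6 log-units per SD of the GlycA latent) in the overweight stratum only.
Magnitudes sit at the upper end of the correlation scale reported for
comparable cohorts (|ρ| ≈ 0.2–0.3): large enough that one simulated cohort
at n = (234, 152) resolves the pattern with high power, small enough to stay
in the realistic range. The composition default produces PERMANOVA
F ≈ 8–13 (R² ≈ 0.03–0.05) in the affected stratum — stronger than the
borderline F ≈ 2 regime real cohorts often show, a deliberate choice so the
pattern-recovery validation measures the pipeline, not luck; the borderline
regime is reachable by lowering `beta` in the registry.

Alignment-record generation allocates pairs multinomially with probability ∝
MGS abundance × gene length and exposes independent noise fractions
(low-quality, host, unmapped, orphan-gene, duplicate, and each
mapping-filter failure mode), so every filter stage has a known expected
pass rate; duplicates copy the key of a uniformly chosen non-duplicate, so
the post-dedup count is exactly Binomial(n, 1 − f).

**What passing tests do and do not show.** The generator reproduces the
marginal scales, the stratum-specific correlation structure, and the
count-sampling noise of a real cohort, but not: taxon-taxon interaction
structure, zero-inflation beyond sampling zeros, compositional effects of
varying sequencing effort across batches, adapter contamination, or real
rank-abundance tails below the detection limit. Passing the battery
demonstrates that the pipeline recovers known structure under its own model
assumptions — it does not validate the biological findings of any particular
study.

## Numerical choices and problem sizes

Sliding-window trimming uses cumulative sums; the Shannon solve uses
`uniroot` on [0, 30] with downward interval extension and tolerance 1e-10;
PERMANOVA permutations are vectorized as one `G %*% P` product; rarefaction
is sequential-hypergeometric; NB p-values are floored at 1e-300 to protect
the correction step from underflow. The validation suite runs at sizes
chosen to make Monte-Carlo bands decisive: marker marginals at n = 5000 per
stratum (3 SEs of a sample median inside the 5 % band), rarefaction
calibration over 2000 replicates, PERMANOVA null calibration over 200
datasets (n = 50, 20 MGSs, 199 permutations), NB null calibration over 100
fresh 50-taxon datasets at n = 150, and pattern recovery over 50 full
cohorts at n = (234, 152) with 199 permutations. Under a perfectly uniform
null, the probability that zero of 50 Bonferroni-tested taxa is significant
is 0.999⁵⁰ ≈ 0.951 per replicate; the implementation's measured rate
(≈ 0.967 over 300 independent replicates) sits at this ideal limit, which is
worth knowing when reading the calibration test: its bar (≥ 95 of 100)
leaves little Monte-Carlo slack by construction.

## Known limitations

The PERMANOVA is single-covariate by design (no multi-term models or
restricted permutation strata). The NB test's t-reference Wald inference is
simple rather than shrunken; with few samples or very low counts a
quasi-likelihood or shrinkage estimator would be more powerful and better
calibrated. The generator's nested presence structure makes richness a
strong compositional gradient, which is realistic in direction but stronger
than many real cohorts; covariates correlated with richness therefore
associate with beta diversity more readily than in typical data. HOMA2-IR
is a stand-in, not the calculator model. Taxonomic name assignment,
orthology inference and alignment itself are out of scope — mapping tables
and alignment records are inputs.
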