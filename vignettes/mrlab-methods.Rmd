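---
title: "Methods: two-sample MR, mediation and cross-trait analysis in mrlab"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-sample MR, mediation and cross-trait analysis in mrlab}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrlab)
```

`mrlab` implements the statistical machinery of cross-trait genetic
epidemiology from GWAS summary statistics: harmonization, instrument
selection, a two-sample Mendelian randomization (MR) battery, two-step MR
mediation, cross-phenotype meta-analysis, genetic correlation,
colocalization and the TWAS association statistic, together with a
synthetic-data generator that makes every stage testable end-to-end.
This vignette is the package's account of the underlying models, the
parameters that matter, the numerical choices, and what the synthetic
experiments do and do not demonstrate.

## Harmonization

Two-sample MR combines per-variant effects on an exposure (cohort 1) and
an outcome (cohort 2). Before any estimate, the outcome effects must be
expressed per copy of the exposure's effect allele. `harmonize()`:

* excludes variants missing from the outcome (`missing`);
* excludes palindromic variants (allele pair A/T or C/G)
  **unconditionally** — their strand cannot be resolved from alleles
  alone, and we do not attempt an allele-frequency rescue window; the
  cost is a few instruments, the benefit is that no silently mis-aligned
  variant can enter the estimators;
* excludes variants whose allele sets disagree between studies
  (`allele_mismatch`); strand-flipping a non-palindromic mismatch
  (A/G recorded as T/C) would be possible in principle but is ambiguous
  without strand annotations, so we exclude rather than guess;
* flips outcome records coded on the opposite allele, negating the beta
  and reflecting the allele frequency simultaneously (β → −β,
  f → 1 − f).

An aligned-frequency sanity check warns (never excludes) when
|f_exp − f_out| > 0.2; the threshold is configurable. The exclusion log
partitions the input exactly: retained + excluded = instruments in.

## Instruments

`clump()` is a deterministic greedy clumping: the smallest-p unassigned
variant with p < p1 indexes a clump; unassigned variants with p < p2,
r² ≥ the LD threshold with the index, and within the kb window on the
same chromosome join it; ties in p break by (chromosome, position).
`select_instruments()` applies the strict convention p < 5×10⁻⁸ with
r² < 0.001. No distance cap is usually quoted for this pruning, so the
default window is 10,000 kb — effectively whole-chromosome, letting LD
alone govern — and it is configurable.

Instrument strength uses the summary-data approximation of the variance
explained,

r² = Σⱼ β²·2f(1−f) / (β²·2f(1−f) + se²·2n·f(1−f)),

which is invariant to allele recoding, and the instrument F statistic
F = ((n−k−1)/k)·(r²/(1−r²)); F > 10 is the usual weak-instrument
comfort bound. `exclude_confounder_snps()` removes instruments annotated
at genome-wide significance to blocklisted confounder traits from a
user-supplied table (a frozen snapshot of a catalogue query — no live
web access).

## The MR estimator battery

All estimators consume per-variant ratio estimates θⱼ = β_out/β_exp with
first-order delta SEs se(θⱼ) = se_out/|β_exp| (second-order SEs are
available behind a flag; first-order is the dominant convention and the
difference is negligible for the strong instruments the selection step
admits).

**IVW (primary).** Weighted mean with wⱼ = 1/se(θⱼ)²; Cochran's
Q = Σwⱼ(θⱼ − β̂)²; the multiplicative random-effects SE multiplies the
fixed-effect SE by max(1, √(Q/(J−1))). The floor at 1 means the SE never
drops below the fixed-effect SE under sub-Poisson dispersion.

**Weighted median.** Interpolated weighted quantile at 0.5 using
standardized cumulative weights (cum(w) − w/2)/Σw; consistent when valid
instruments carry at least half the weight. The SE is a seeded
parametric bootstrap (default 1000 replicates) resampling
θⱼ ~ N(θⱼ, se(θⱼ)).

**MR-Egger.** Weighted regression of β_out on β_exp with a free
intercept after orienting each variant so β_exp ≥ 0 (the fit is then
invariant to allele recoding). The intercept estimates directional
pleiotropy; SEs carry the same multiplicative inflation floored at 1,
with normal p-values by default (t available). Egger's intercept is only
identifiable when instrument strengths vary; with a narrow strength
distribution the intercept and slope are nearly collinear and both are
imprecise — visible in the calibration tests, which use a spread of
instrument strengths.

**RAPS.** Profile likelihood over θ with standardized residuals
tⱼ = (β_out − θβ_exp)/√(se_out² + θ²se_exp² + τ²), accounting for
measurement error in the exposure effects (hence robust to many weak
instruments). Options: Huber loss (δ = 1.345) against idiosyncratic
pleiotropy, and an overdispersion variance τ² ≥ 0 against systematic
pleiotropy. The Huber consistency factor 2Φ(δ)−1 keeps the τ² estimating
equation unbiased. Optimization is bounded scalar search over three
successively widened brackets; the SE is a numeric sandwich (score outer
product over observed curvature). Defaults are plain loss without
overdispersion.

**PRESSO-style outlier test.** Observed residual sum of squares
Σⱼ (β_out,j − θ̂₍₋ⱼ₎β_exp,j)² with leave-one-out IVW fits; the null
distribution is simulated by redrawing both effect vectors from normals
centred on fitted means with observed SEs. The global p is the
Monte-Carlo exceedance probability; per-variant outlier p-values are
Bonferroni-gated; the corrected estimate is IVW on the retained set and
the raw (all-instrument) estimate is kept alongside.

**Steiger directionality.** r² summed over instruments per trait via
zⱼ²/(zⱼ² + n − 2); the assumed direction holds when the instruments
explain more of the exposure than of the outcome, with a two-sample
z-test on Fisher-transformed √r² values. Steiger is reported as a
diagnostic, not applied as an instrument filter.

**Power.** For a binary outcome the IVW z-test has non-centrality
|log OR|·√(n·r²·K(1−K)). We evaluate the exact two-sided power
Φ(ncp − z₁₋α/₂) + Φ(−ncp − z₁₋α/₂): at OR = 1 this equals α, as a
two-sided test must, and away from the null the second term vanishes,
recovering the familiar one-term expression.

Exposures with a single instrument fall back to a Wald ratio labeled
`wald_ratio`; the battery applies each method only when its minimum
instrument count is met. Bonferroni-corrected significance defaults to
0.05/6 in the battery table (six trait-pair analyses) and 0.05/11 in the
mediation screen (eleven candidate mediators); unadjusted p < 0.05 is
treated as suggestive only.

## Two-step MR mediation

With a the exposure→mediator effect, b the mediator→outcome effect and c
the total exposure→outcome effect (all IVW), the product-of-coefficients
decomposition is indirect = a·b, direct c′ = c − a·b (the identity
indirect + direct = c holds to machine precision), proportion mediated =
indirect/c, adjusted OR = exp(c′). A mediation is significant only when
*both* step p-values pass the Bonferroni threshold, and only significant
mediators contribute to the combined indirect effect.

Two reporting conventions for the proportion coexist in the tables this
module reproduces: dividing the unrounded indirect effect by c, or
dividing the 3-decimal-rounded indirect by c. They can differ in the
final printed digit, so both are exposed (`proportion`,
`proportion_table`); unrounded values are always retained internally.
The reproduced study table carries one further quirk: its per-mediator
"direct effect" column is consistent with a total of ≈0.622 rather than
the 0.629 its own footnote prescribes subtracting from; we implement the
footnote rule and make no attempt to reverse-engineer the discrepancy.

## Cross-trait stages

**SHet.** For traits with z-scores z, sample sizes n and trait
correlation R, the statistic maximizes, over all non-empty trait subsets
T, S(T) = (w_T′R_T⁻¹z_T)²/(w_T′R_T⁻¹w_T) with w = √n and subset z-scores
sign-aligned to the first trait (equivalently |z| after squaring) —
a sample-size-weighted fixed-effect meta-analysis that retains power
when only a subset of traits carries the effect. Enumeration is exact
for the small trait counts used here (feasible to ~10 traits). R
defaults to the identity, appropriate for non-overlapping cohorts; an
estimate from null-SNP z-products can be supplied instead. The p-value
is Monte-Carlo against z* ~ MVN(0, R) (default 10⁴ draws, shared across
a scan); beyond Monte-Carlo resolution the tail switches to a
moment-matched gamma fit of the simulated max distribution. The gamma
tail is an approximation — adequate for thresholding genome-wide claims
(the calibration tests check the body of the distribution by Monte
Carlo, the scan tests check that planted loci clear, and null scans do
not), but extreme p-values should be read as orders of magnitude, not
exact probabilities.

**Scan.** `cross_trait_scan()` computes SHet per shared variant, keeps
variants with meta p below the genome-wide threshold (2.5×10⁻⁸ = 5×10⁻⁸
halved for two meta-analyses) *and* both trait-specific p < 10⁻⁵, and
clumps survivors (r² 0.4 within 500 kb) into index loci.

**Genetic correlation.** LD-score regression: E[z²] = 1 + n·h²·ℓ/M per
trait and E[z_a z_b] = √(n_a n_b)·ρ_g·ℓ/M across traits, both with free
intercepts (absorbing confounding and any residual overlap); rg =
gencov/√(h²_a·h²_b). Weights follow the usual two-pass scheme (1/ℓ, then
heteroskedasticity weights from the first pass); SEs come from a
delete-one block jackknife over 200 contiguous variant blocks with
regression weights held fixed. Non-positive heritability estimates make
rg undefined and are reported as such with diagnostics rather than
clipped. This is the LDSC-style estimator; the full-likelihood
refinement of genetic-correlation estimation is out of scope, so
headline correlations estimated that way are matched here only at the
level of the regression model.

**Colocalization.** Per-variant Wakefield log-ABFs
½[log(V/(V+W)) + W·z²/(V+W)] with V = se² and prior effect SD 0.15
(quantitative) or 0.2 (case-control), combined over the five
configuration hypotheses with priors p1 = p2 = 10⁻⁴, p12 = 10⁻⁵ via
log-sum-exp. PP4 > 0.9 is the conventional colocalization call.

**TWAS.** Given precomputed expression weights w, trait z-scores and the
LD matrix Σ of the weight support, z_twas = w′z/√(w′Σw) with a
Bonferroni flag over the number of gene-tissue pairs tested. Training
expression weights is out of scope: weights are an input (synthetic in
the tests).

## The synthetic-data generator

The generator emulates the study conditions the analyses target, and its
defaults are fixed at those conditions: heritabilities 0.13 and 0.05,
genetic correlation 0.26, outcome case fraction 26676/159208 ≈ 0.168,
and mediation coefficients a = 0.315, b = 0.581, c′ = 0.446 (indirect
0.183, total 0.629). Cohort sizes and variant counts are desk-scale —
20,000 individuals per cohort and 2,000 variants by default — because
the estimators' behaviour, not data volume, is what the package must
demonstrate.

**LD panel.** Block-diagonal correlation with r = ρ^distance inside
blocks (ρ configurable per block; a spread of ρ across blocks produces
the spread of LD scores that LD-score regression needs for
identification — with near-constant LD scores the free-intercept
regression is ill-posed, exactly as on real data it would be without
low- and high-LD regions). Blocks sit 1 Mb apart round-robin across 22
chromosomes, 5 kb between variants within a block, so distance windows
behave sensibly in clumping tests.

**Genotypes.** Haplotypes are binary Markov chains along each block with
per-block MAF: binary chains have linear conditional expectations, so
correlations multiply along the chain and the realized genotype
correlation is *exactly* ρ^distance, matching the panel matrix. (A
latent-Gaussian copula was rejected because thresholding attenuates the
binary correlation below the latent one, which would bias every LD-aware
expectation against the panel.) MAF is constant within a block — the
price of exactness; across blocks MAF varies uniformly in the configured
range.

**Phenotypes and summary statistics.** Causal effects for a trait pair
are bivariate normal with per-variant variance h²/M_c and covariance
r_g√(h²_x h²_y)/M_c on the standardized-genotype scale. Phenotypes are
genetic score plus independent normal noise; summary statistics are
per-variant marginal OLS on allele counts. A z-score-only mode draws
z ~ MVN(√n·Σβ, Σ) block-wise for calibration experiments at larger M —
it exercises everything downstream of the regressions at a fraction of
the cost. Two (or three) cohorts are disjoint by construction and the
truth record stores realized effects, heritabilities and cohort index
ranges.

**Mediation design.** X = Gγ + ε; M = aX + Gδ + ε; liability
L = c′X + bM + ε with total variance normalized to 1 and thresholded at
the case fraction K. The binary outcome's 0/1 marginal regressions are
rescaled by 1/φ(Φ⁻¹(1−K)), the first-order liability conversion, so
reported outcome effects are approximately liability-scale coefficients
(the attenuation left after this rescale is second-order at the per-SNP
effect sizes simulated here; the generator documents the scale rather
than emulating a specific logistic pipeline). The mediator's direct
genetic component δ lives on LD blocks disjoint from γ so that each
trait's instruments tag a single causal path — without this, tags mixing
the two paths contaminate the mediator→outcome step with ratio
(c′ + ab)/a, which is a genuine limitation of two-step MR on overlapping
architectures, not an estimator bug. With per-variant exposure signals
kept well below the mediator-selection threshold scaled by a (the test
design uses dense-enough exposure architecture for this), winner's-curse
leakage of exposure loci into the mediator instrument set is negligible.

**What passing tests show — and don't.** Calibration and recovery on
these simulations demonstrate the estimators' arithmetic, their
frequentist behaviour under the stated models, and the pipeline's
bookkeeping. They do not demonstrate robustness to the pathologies of
real consortium data: population stratification, sample overlap,
imputation error, MAF-dependent architecture, or assortative mating.
The generator deliberately omits these.

## Numerical choices

* Ratio SEs: first-order delta method (dominant convention); the
  second-order form is a flag.
* Random-effects inflation is always floored at 1 (never shrinks the
  fixed-effect SE). A consequence: under *sub*-dispersed data the IVW
  and Egger tests are mildly conservative; calibration is checked under
  the balanced-pleiotropy dispersion the multiplicative model assumes.
* Weighted-median bootstrap: 1000 seeded replicates by default; below
  100 a warning is raised.
* RAPS: `optimize()` with tolerance 10⁻¹⁰ over three widening brackets
  centred on the median ratio; τ² bounded below at 0 and searched up to
  a multiple of the residual variance; non-convergence (boundary or
  non-positive curvature) errors carrying the best iterate.
* PRESSO: minimum 500 simulation replicates; per-variant outlier tests
  Bonferroni-gated at 0.05; empty retained sets are an error.
* SHet: Monte-Carlo p-values use the add-one estimator
  (1 + #exceedances)/(n_mc + 1); the gamma tail activates only at zero
  exceedances. Seeds are explicit everywhere.
* Degenerate inputs fail loudly: zero instruments (with a near-miss
  count), all-equal exposure effects in Egger, singular trait
  correlation in SHet, f ∈ {0,1} variants in variance explained
  (skipped with a warning), mismatched variant sets in coloc.
* One master seed drives every stage; derived streams use fixed offsets
  and stay below 2³¹.

## Study-scale problem sizes used in the tests

Tests run at sizes chosen to make each check informative: marginal-z
calibration at M = 2000, n = 20,000 (individual level); rg recovery at
M = 2500 with the study's actual cohort sizes in z-score mode; the
mediation recovery loop at three 20,000-individual cohorts over M = 800
and 20 seeds; SHet calibration over 2000 replicates against a 10⁴-draw
null. The power cross-check simulates 10⁴ logistic cohorts of n = 20,000
at an OR where power (~0.95) is informative, then asserts the analytic
value at the full study design (power ≥ 0.99, numerically 1).

## Known limitations

* The SHet gamma tail is an approximation beyond Monte-Carlo resolution;
  genome-wide threshold decisions are robust to it, exact extreme
  p-values are not claimed.
* LD-score regression at desk scale (thousands of variants) carries
  jackknife SEs an order of magnitude larger than consortium-scale
  analyses; the tests therefore check coverage, not precision.
* The liability rescale of binary-outcome effects is first-order; very
  large per-SNP effects would need an exact link.
* Two-step mediation inherits the usual exclusion caveat: mediator
  instruments must not act through the exposure. The generator enforces
  the separation; real analyses must argue it.
* The CLI (`inst/scripts/mrlab.R`) is a thin wrapper over
  `run_pipeline()` / `simulate_*`; the R functions are the primary
  interface.
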