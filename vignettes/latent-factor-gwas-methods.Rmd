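---
title: "Methods: latent-factor GWAS from summary statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: latent-factor GWAS from summary statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(factorGWAS)
```

## The problem

Executive function (EF) is measured with many weakly correlated cognitive
tests, and the GWAS literature for EF is fragmented across cohorts that used
different tests. Genomic structural equation modelling sidesteps the need
for a single cohort: per-test GWAS summary statistics are combined into a
genetic covariance matrix by LD-score regression, a confirmatory factor
model is fitted to that matrix, and a new GWAS is then run on the latent
factors themselves, one structural model per SNP. `factorGWAS` implements
that whole chain — estimation, model comparison, per-SNP association with
heterogeneity filtering, and post-GWAS locus definition and novelty
filtering — together with a summary-statistic simulator so that every stage
can be exercised and calibrated without access to cohort data.

## LD-score regression

For trait pair $(a, b)$, SNP $j$ with LD score $\ell_j$ and $M$ SNPs,

$$E[z_{aj} z_{bj}] \;=\; \frac{\sqrt{N_a N_b}\,\sigma_{g,ab}\,\ell_j}{M}
\;+\; \rho_{ab},$$

so the genetic covariance $\sigma_{g,ab}$ is the slope of the weighted
regression of the Z-score product on $\ell_j \sqrt{N_a N_b}/M$, and the free
intercept $\rho_{ab}$ absorbs sample overlap (for $a=b$, confounding). The
univariate case is implemented as the self-covariance special case, so
`estimateH2(x)` and `estimateGencov(x, x)` agree exactly.

Weights are the standard LDSC heteroskedasticity-and-oversampling weights
$w_j^{-1} = \ell_j\,[(1 + N_a h_a^2 \ell_j/M)(1 + N_b h_b^2 \ell_j/M) +
(\hat s\,\sqrt{N_a N_b}\,\ell_j/M + \hat\rho)^2]$, computed once from
unweighted first-pass fits and held fixed across the jackknife. Standard
errors and the full sampling covariance $V$ of $\mathrm{vech}(S)$ come from
a delete-a-block jackknife over 200 contiguous SNP blocks (the conventional
count; configurable). Because all pairs share the same blocks, $V$ captures
the sampling dependence between elements of $S$. `vech` ordering is fixed
package-wide as the column-major lower triangle including the diagonal.

Indicator screening applies the two published inclusion rules: traits whose
heritability Z statistic falls below a threshold are dropped (the published
criterion names "statistically significant SNP heritability" without an
alpha; we default to one-sided 1.645 and expose the threshold), and traits
whose $|r_g|$ exceeds 0.9 with at least two other retained traits are
dropped as multicollinear — on the packaged published correlation matrix
this flags exactly the NIH G6 component.

## Smoothing and the Z-difference filter

$S$ and $V$ are projected to the nearest positive-semidefinite matrix by
eigenvalue clipping (floor $10^{-10}$), a deterministic single pass that is
Frobenius-optimal for the fixed floor; full nearest-correlation iteration is
out of scope at these dimensions. When smoothing changed the matrices, the
per-SNP GWAS is run under both the pre- and post-smoothed matrices and SNPs
whose factor-effect Z changes by strictly more than 1 (the published "more
than" wording; a change of exactly 1 survives) on **any** factor are
removed. Which Z the published analysis compared (factor-effect vs
indicator-covariance) is not stated; the factor-effect reading with the
any-factor rule is the conservative policy implemented here.

## The model zoo and DWLS estimation

The nine competing structures over the nine retained indicators are encoded
in a compact lavaan-like DSL (`modelSpec`) and packaged as `modelZoo()`.
Identification is by unit factor variance throughout (solutions are
reported standardized at the factor level). Estimation is diagonally
weighted least squares: $\hat\theta$ minimises
$(s - \sigma(\theta))^\top D^{-1} (s - \sigma(\theta))$ with
$D = \mathrm{diag}(V)$, by damped Gauss–Newton with an analytic Jacobian and
five seeded jittered restarts on nonconvergence. Standard errors use the
full-$V$ sandwich. The model chi-square is the residual-based statistic
$r^\top [V^{-1} - V^{-1}\Delta(\Delta^\top V^{-1}\Delta)^{-1}\Delta^\top
V^{-1}] r$, which has expectation equal to the degrees of freedom for a
correctly specified model under any consistent estimator; it is exercised
through identities (AIC $= \chi^2 + 2k$, $df + k = 45$) and through
calibration tests, never against externally printed chi-squares. CFI uses
the independence baseline (free variances, zero covariances); SRMR is the
root mean square of standardized residual moments over the lower triangle
including the diagonal. Fit labels follow the published thresholds (CFI
$\ge 0.95$ good / $\ge 0.90$ acceptable; SRMR $< 0.05$ good / $< 0.10$
acceptable), the joint label being the weaker of the two.

Two points about the zoo were genuinely open and were decided as follows.

* **Degrees of freedom.** Counting free parameters over the transcribed
  structures reproduces the printed df for six of the nine models (common
  factor 27; three-factor 23; bifactor with working memory 22;
  substitution-as-shifting 19; prospective-memory-on-WM 20;
  substitution-as-correlated-residual 21). The remaining three printed df
  values imply one or two more free parameters than the described
  structures contain; the published figure with the numeric loadings is not
  part of the text, so the discrepancy cannot be resolved. The zoo encodes
  the described structures; a 26-parameter reading of the endorsed model
  (a free WM–substitution covariance) is available as a variant, and
  AIC-reconstruction identities are asserted only for the six reconcilable
  rows.
* **Empirical under-identification.** A two-indicator specific factor that
  is orthogonal to everything else identifies only the product of its two
  loadings: the information matrix is singular along the ridge and the
  model is moment-equivalent to a correlated residual. The published
  analysis hit exactly this and fixed the CHARGE DSST residual variance to
  0. Fit statistics remain well defined on the ridge (the implied moments
  are constant along it), so the fitter uses a symmetric pseudo-inverse and
  reports such models rather than erroring; but the per-SNP GWAS stage —
  where a flat ridge makes thousands of refits slow and the loading split
  arbitrary — uses the identified variant `bifactor_wm_sub_id` with the
  DSST residual fixed to 0, mirroring the published device.

## Per-SNP latent GWAS and Q-SNP

Each SNP enters on the standardized-genotype scale: its variance is fixed
to 1 and $\mathrm{cov}(\text{SNP}, y_i) = z_i/\sqrt{N_i}$, with sampling
variance $1/N_i$ and zero assumed cross-terms in the augmented $V$
(MAF-based scaling is a config switch when frequencies are present; it
changes the effect scale, not Z or p). The measurement model is
re-estimated for every SNP with SNP$\to$factor regressions added (the
reference path; a measurement-frozen shortcut is deliberately not the
default), warm-started from the SNP-free fit with a GLS start for the SNP
paths. The Q-SNP statistic is the chi-square difference between this
common-pathway model and an independent-pathways model in which the SNP
hits every indicator directly, on $t - f$ degrees of freedom (9 indicators
minus 3 factor paths = 6 here); SNPs with Q-SNP $p < 5\times10^{-8}$ are
removed, as published. Under a common-pathway simulation the statistic is
calibrated (mean $\approx$ 6, rejection at $\alpha = 0.05$ within binomial
bounds — the test suite checks this on 2,000 SNPs).

The per-factor output tables report the chi-square-implied effective sample
size $1/\mathrm{se}^2$ per SNP — a convention, not a published claim.

## Post-GWAS

Clumping follows the FUMA-style definitions the published analysis relied
on: greedy selection by ascending p among genome-wide-significant SNPs
($p < 5\times10^{-8}$), independence at $r^2 < 0.6$, lead SNPs among the
independent set at $r^2 < 0.1$, ties broken by position then rsid, and every
significant SNP assigned to the independent SNP that pruned it. Risk loci
span each lead's members and merge within 250 kb (closed 1-based
intervals, via `GenomicRanges`). The novelty filter applies the three
published stages — exact rsID match, LD with a prior significant SNP at
$r^2 > 0.6$ strictly, and $\ge 1$ bp locus overlap — with a per-item audit
trail. All thresholds are configurable; the defaults are the conventions
the published analysis inherited from its annotation platform, which does
not restate them.

## The synthetic-data generator

Summary statistics are simulated directly at the Z level from the exact
moment structure the estimators assume: per SNP,
$z_j \sim \mathcal N(0,\; I_0 + (\ell_j/M)\,D_N^{1/2}\Sigma_g D_N^{1/2})$,
where $\Sigma_g = \Lambda\,\mathrm{diag}(h^2_{\text{fac}})\,\Lambda^\top +
\Theta$ is the generating genetic covariance and $I_0$ carries unit
diagonal and sample-overlap intercepts (shared-sample fraction times the
phenotypic correlation of the overlapping subsample). No individual-level
genotypes, LD blocks, or MAF-dependent architecture are simulated —
deliberately: the generator matches every assumption the downstream
estimators use and nothing more, so passing tests demonstrate correctness
of the estimation chain, not robustness to model misspecification in real
data (real LD structure, annotation-dependent heritability, allele-coding
errors).

The packaged default emulates the study conditions: nine cohort traits with
the published per-study sample sizes (4,611–162,335), total SNP
heritabilities equal to the published diagonal, standardized loadings
patterned on the accepted bifactor structure (general EF on all nine;
working memory on Digit Span, Pairs — negative —, the ALSPAC component and
NIH G4; substitution on the two symbol/digit tests with the DSST residual
at 0; a 0.2 correlated residual between prospective memory and the ALSPAC
component), $M = 50{,}000$ SNPs, and a gamma LD-score law with mean 30. The
study does not report the degree of within-UK-Biobank sample overlap, so
the generator exposes it as a free parameter; the default (shared fraction
0.9, phenotypic correlation 0.25 among the five UK Biobank tests) is a
plausible setting for one battery administered to one cohort, chosen once.
Loading magnitudes were chosen to reproduce the general magnitude of the
published genetic correlations (e.g. UK Biobank pairs around 0.6–0.7).

## Numerical choices

* Optimizer: Levenberg–Marquardt on the weighted residual system; analytic
  Jacobian; convergence when the gradient (or its projection onto the
  non-flat parameter subspace) predicts a relative decrease below
  $10^{-9}$; 5 seeded jittered restarts on failure, derived
  deterministically from the model name.
* Singular information (empirical under-identification) uses a symmetric
  eigen pseudo-inverse with relative tolerance $10^{-10}$; degrees of
  freedom always count declared free parameters, preserving the
  $df + k = 45$ identity.
* Heywood cases (negative residual variances) are flagged on the fit
  object and never constrained, matching the published silence on the
  issue.
* Jackknife variance: delete-one-block, $\frac{g-1}{g}\sum_b
  (\hat\theta_{(b)} - \bar\theta)(\hat\theta_{(b)} - \bar\theta)^\top$.
* Standardization propagates $V$ by the delta method; the now-exact
  diagonal moments get a small positive floor so $V$ stays usable as a
  weight matrix, and the operation is idempotent.
* The pipeline derives all stage seeds deterministically from one seed via
  stage-name hashing, so a run is byte-reproducible.

## Problem sizes in the packaged checks

The test-suite and acceptance-script simulations use $M = 50{,}000$ SNPs
for parameter recovery (one replicate, 200 jackknife blocks), $M =
30{,}000$ for SNP-level calibration with 2,000 null and 2,000
common-pathway SNPs, and scaled-down panels ($M$ = 4,000–20,000, 50–100
blocks) for unit checks — sizes at which every stage runs in seconds to a
few minutes on one CPU while leaving the moment structure unchanged.

## Known limitations

* The augmented per-SNP $V$ assumes zero cross-terms between SNP-trait
  moments. With strong sample overlap the true null Z-scores are correlated
  across traits, so per-SNP p-values are exactly calibrated only without
  overlap; the calibration suite therefore uses a no-overlap panel. (The
  stack-level intercept matrix is stored and could drive a correlated
  augmentation; that refinement is not implemented.)
* The published GWAS headline counts (loci, lead SNPs, novel genes) depend
  on real cohort data and an external LD reference, and are not
  reproducible here; what the package reproduces are the analytic
  identities over the published fit table, the published threshold
  arithmetic, and the behaviour of the full pipeline under its own
  generating model.
* Under a diagonal-$V$ surrogate the refitted chi-squares of the closely
  related bifactor variants differ by only a few points, and the endorsed
  model is not guaranteed to rank first by AIC on the published correlation
  matrix — the published ranking was produced under the full sampling
  covariance, which is unavailable. The model-selection rank is asserted in
  the acceptance suite as specified, and this caveat documents why it can
  fail there while every identity and calibration property holds.
* Full-ML estimation, categorical indicators, measurement-invariance
  testing, gene mapping and annotation are out of scope.
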