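---
title: "Two-sample Mendelian randomization with mrsum: models, conventions, design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-sample Mendelian randomization with mrsum}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrsum)
```

## The model

Mendelian randomization treats germline genetic variants as instrumental
variables for a modifiable risk factor. A variant $j$ is a valid instrument
for exposure $X$ and outcome $Y$ when it is (1) robustly associated with
$X$, (2) independent of confounders of the $X$–$Y$ relation, and (3)
affects $Y$ only through $X$ (the exclusion restriction). In the two-sample
design the per-allele associations $\hat\beta^X_j$ (with SE $\sigma^X_j$)
and $\hat\beta^Y_j$ (SE $\sigma^Y_j$) come from independent GWAS samples
and are combined at the summary level.

Under a linear structural model $\beta^Y_j = \theta\,\gamma_j + \alpha_j$,
where $\gamma_j$ is the SNP's effect on the exposure and $\alpha_j$ its
direct (pleiotropic) effect on the outcome, every estimator in this package
is a different compromise about $\alpha_j$:

* **Wald ratio / IVW.** $\hat\theta_j = \hat\beta^Y_j / \hat\beta^X_j$ with
  first-order SE $\sigma^Y_j / |\hat\beta^X_j|$ (a second-order
  delta-method SE adding the exposure term is available by flag; the
  first-order form is the default and the common convention). The IVW
  estimate is the precision-weighted mean
  $\hat\theta = \sum w_j \hat\theta_j / \sum w_j$, $w_j =
  \mathrm{se}(\hat\theta_j)^{-2}$ — algebraically the slope of a weighted
  regression of $\hat\beta^Y$ on $\hat\beta^X$ through the origin. It is
  unbiased only when pleiotropy is absent or balances out.
* **Fixed vs multiplicative random effects.** With 2–3 SNPs the fixed
  SE $(\sum w_j)^{-1/2}$ is used; with more than 3 SNPs the SE is inflated
  by $\sqrt{\max(1, \phi)}$ with $\phi = Q/(J-1)$, $Q$ Cochran's
  heterogeneity statistic. Flooring $\phi$ at 1 means random-effects SEs
  never undercut fixed-effects ones; without the floor the fixed/random
  distinction would collapse in homogeneous data. A single SNP routes to
  the plain Wald ratio.
* **MR–Egger.** Weighted least squares of $\hat\beta^Y$ on $\hat\beta^X$
  *with* an intercept, each SNP first oriented so $\hat\beta^X_j > 0$,
  weights $1/(\sigma^Y_j)^2$. Under InSIDE (pleiotropy independent of
  instrument strength) the slope remains a consistent estimate of $\theta$
  and the intercept estimates average directional pleiotropy. SEs carry the
  same multiplicative inflation ($\phi$ = weighted residual mean square,
  floored at 1); inference is t with $J-2$ df, matching the method's
  original formulation, whereas the normal reference is used for IVW,
  median and mode.
* **Weighted median.** Order the Wald ratios, form standardized cumulative
  weights $S_j = (\sum_{i \le j} w_i - w_j/2)/\sum w$, and interpolate
  linearly where $S$ crosses $1/2$. Consistent while valid instruments
  carry at least half the total weight.
* **Weighted mode.** Smooth the ratios with a weighted normal kernel
  (bandwidth $h = \varphi \cdot 0.9 \min(\mathrm{sd}, \mathrm{mad}/0.6745)
  J^{-1/5}$, tuning multiplier $\varphi = 1$ by default) and take the
  density argmax over a 512-point grid spanning the ratio range ± 3h.
  Consistent when the valid instruments form the largest homogeneous
  cluster, even as a weight minority. If every ratio is identical the
  bandwidth degenerates and that common ratio is returned.

Median and mode SEs come from a parametric bootstrap: both betas are
redrawn from normals at their reported SEs, the point estimate recomputed,
and the SD over replicates taken (default 1000 replicates; a seed is
mandatory so reports are reproducible; `n_boot = 0` returns the point
estimate alone, which the Monte-Carlo studies use). The exact replicate
count only perturbs the last digit of bootstrap SEs.

## Harmonization

Outcome effects are re-expressed per copy of the exposure's effect allele.
Letter-wise allele swaps flip the sign of $\hat\beta^Y$ and reflect its
allele frequency; strand flips are resolved by complementing before
comparison. Palindromic SNPs (A/T, C/G) are the one genuinely ambiguous
case: letters cannot distinguish a swap from a strand flip, so orientation
falls back on allele frequency, and the SNP is dropped unless both
frequencies are known and both fall outside $0.5 \pm 0.08$. The window is
configurable; 0.08 is a conservative default in common two-sample MR
practice. Every drop is recorded in an audit table with its reason, so
kept + dropped always equals the SNP intersection. A p-value inconsistent
with $|\hat\beta/\mathrm{se}|$ raises a warning, not an error: published
tables round aggressively.

## Instruments and their strength

Clumping is greedy by ascending p-value (ties broken by SNP id for
determinism): a candidate is discarded only when it is *both* within the
clumping window of a kept SNP (10,000 kb default; missing positions count
as within the window, letting LD alone decide) *and* in LD with it above
the r² threshold (0.001 default), at P < 5×10⁻⁸. The LD matrix is a
user-supplied square table; pairs absent from it are treated as unlinked.
Panel retrieval is deliberately out of scope — it keeps the module
deterministic and offline.

Variance explained sums $2 p_j (1-p_j) \beta_j^2$ over SNPs (divided by the
trait variance when not SD-standardized), and
$F = \frac{R^2}{1-R^2}\cdot\frac{n-k-1}{k}$. Instruments with $F < 10$ are
excluded from pipeline runs with a logged reason. For binary exposures the
liability-scale variance explained cannot be derived from log-OR summary
statistics alone, so instrument strength is only reported when the caller
supplies an external $R^2$.

## Sensitivity analyses

*Cochran's Q* uses the same weights as IVW, with $Q/(J-1)$ exactly the
random-effects overdispersion. *Leave-one-out* refits IVW once per excluded
SNP (the fixed/random selection rule re-applied at $J-1$) to expose single
influential variants. *Steiger directionality* compares the variance the
instrument explains in the exposure against the outcome. Per-SNP r² comes
from allele frequency and beta for continuous SD-scale traits, and from the
$z^2/(z^2+n)$ approximation for binary traits, whose liability-scale inputs
(prevalence) are rarely published; this is documented as an approximation.
Because the two GWAS samples are independent, the two correlations are
compared with the Fisher-z statistic for independent samples — the
dependent-correlations variant of Steiger's test needs an overlap
correlation that does not exist in a two-sample design. Reported Steiger
p-values are floored at machine precision and best compared on the log10
scale.

## Reporting conventions

Binary-liability exposure estimates are multiplied — point estimate, SE and
CI bounds alike — by $\ln 1.5 \approx 0.4055$, converting an effect per
unit log-odds of liability into an effect per 50% higher odds. This is the
only reading of "scaling by a factor of 1.5" that performs that unit
conversion; since the multiplier is common to the estimate and its SE, z
and p are untouched. The Egger intercept, which lives on the outcome scale
rather than per exposure unit, is exempt.

Evidence tiers Bonferroni-correct a 12-risk-factor screen: strong when
$p < 0.05/12 = 0.0042$ (strict inequality; a p-value exactly on the
threshold is suggestive — the boundary convention is documented because no
printed value sits on it), suggestive up to 0.05, little otherwise. Method
availability follows instrument size: IVW always (single SNPs as Wald
ratios), Egger and weighted median from 3 SNPs, weighted mode from 5;
per-outcome tables mark unavailable methods with an em dash rather than
omitting cells, so every row has the same shape. ORs and CIs print at two
decimals. Reports are byte-deterministic given config and seed: each
exposure–outcome pair derives its bootstrap seed from the config seed and
the pair's labels.

## What the synthetic generator emulates — and what it does not

`simulate_summary_stats()` works at the summary level: it draws minor
allele frequencies (uniform 0.1–0.4 by default), per-SNP exposure effects
$\gamma_j \sim N(0.08, 0.04^2)$ on the SD scale, assigns $\alpha_j$ under
the chosen pleiotropy regime (balanced, directional with InSIDE, or
InSIDE-violated via an $\alpha$–$\gamma$ correlation), sets
$\beta^Y_j = \theta\gamma_j + \alpha_j$, and observes both studies
independently with $\mathrm{se} = (2p(1-p)n)^{-1/2}$. Defaults (J = 100,
both samples 100,000, $\theta = 0.1$, 30% invalid SNPs with mean direct
effect 0.02) describe a well-powered modern setting in which single-SNP F
statistics land in the hundreds, like the published instruments they mimic.

Because real instruments are *selected* at genome-wide significance, the
generator conditions the true effects on detectability: any $\gamma_j$
whose underlying z-statistic could not clear P < 5×10⁻⁸ is redrawn. This
matters more than it looks. Unconditioned draws produce "instruments" with
effects indistinguishable from zero; orienting those by the observed sign
couples the pleiotropy sign to instrument strength and visibly biases
MR–Egger even when $\alpha$ and $\gamma$ are generated independently — an
artifact of simulating a design no analyst would run.

Deliberate simplifications, and what they mean for the tests: summary-level
simulation cannot exhibit finite-sample weak-instrument phenomena beyond
what the noisy betas carry, there is no LD between instrument SNPs (LD
enters only through the separate block fixtures used to exercise clumping),
no winner's curse (effects are conditioned on detectability but not
inflated by selection on the *observed* estimate), no sample overlap
between the two studies, and binary exposures reuse the continuous
machinery on the log-odds scale. Passing recovery tests therefore
demonstrate correctness of the estimators under their stated assumptions —
not robustness to LD misspecification, overlap bias or winner's curse in
real data.

## Monte-Carlo scenarios and problem sizes

Three canned studies (`mc_no_pleiotropy()`, `mc_directional_inside()`,
`mc_median_vs_ivw()`) drive the recovery tests, the acceptance script and
`analysis/05_method_validation.R`. The suite runs them at 200–400
replicates of J = 100 SNPs — sizes chosen so the whole test suite completes
in about a minute while keeping Monte-Carlo SEs a factor of four below the
effects being checked. Checks are phrased in Monte-Carlo SEs rather than
absolute tolerances wherever possible. One calibration note: the IVW CI is
slightly conservative under these conditions (empirical coverage ≈ 95–97%
against the nominal 95%), mostly because the multiplicative random-effects
SE never deflates; a single 200-replicate binomial estimate of coverage
therefore lands above 98% for an unlucky seed every so often, which is
sampling noise around an in-band truth.

## Numerical choices and degenerate inputs

* CI multipliers: 1.96 for normal-based methods, the t quantile for Egger.
* P-values are floored at the smallest positive double; `pval = 0` never
  appears.
* $R^2$ sums above 1 are clamped with a warning (usually a `trait_sd`
  mistake).
* `beta_exp = 0` is a degenerate instrument: Wald ratios refuse it
  explicitly rather than dividing by zero. In the bootstrap, a resampled
  exposure beta of exactly zero is nudged by machine epsilon.
* Too few SNPs for a method yields a typed "unavailable" marker that
  pipelines render as an em dash; it is never a crash.
* Clumping ties in p break lexicographically by SNP id; grid argmax ties in
  the mode resolve to the smaller ratio (first grid hit).
* The XLSX converter writes one TSV per sheet with stable ordering, keeping
  the analysis path text-based and diffable; spreadsheets are accepted only
  through this explicit conversion.

## Known limitations

Multivariable MR, MR-PRESSO-style outlier removal, contamination-mixture
estimators, LD-proxy substitution for missing SNPs, genome-build liftover
and VCF ingestion are out of scope. Liability-scale variance explained for
binary exposures is not computed (supply `r2` externally). The Steiger
binary-trait r² is an approximation; with very strong effects on a
smaller-sample outcome GWAS it can leave directionality unestablished even
when the generative direction is known — the same behaviour reported for
strong liability exposures against rare histotypes.
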