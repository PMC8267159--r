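---
title: "Methods: two-sample MR screening with mratlas"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-sample MR screening with mratlas}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mratlas)
```

# The model

For instrument $j = 1..J$, let $\hat\gamma_j \pm \sigma_{xj}$ be the
variant–exposure association (per SD of a continuous exposure) and
$\hat\Gamma_j \pm \sigma_{yj}$ the variant–outcome association (log-odds
for a binary outcome), taken from two independent GWAS. Under the
instrumental-variable assumptions — relevance, exclusion restriction, and
independence from confounders — each instrument identifies the same causal
effect $\beta$ through its Wald ratio $\hat\Gamma_j/\hat\gamma_j$, and the
estimators differ in how they combine the $J$ ratios when some instruments
are invalid:

* **IVW**: the slope of the zero-intercept weighted regression of
  $\hat\Gamma$ on $\hat\gamma$ with weights $\sigma_{yj}^{-2}$. Efficient
  when every instrument is valid; biased by the weighted mean of any
  pleiotropic effects.
* **MR-Egger**: the same regression with a free intercept, after orienting
  all instruments to $\hat\gamma_j \ge 0$. Under InSIDE (pleiotropy
  independent of instrument strength) the slope is consistent for $\beta$
  and the intercept estimates the mean pleiotropic effect — the basis of
  the directional-pleiotropy test.
* **Weighted median**: the weighted median of the per-SNP ratios with
  weights $\hat\gamma_j^2\sigma_{yj}^{-2}$, computed by interpolating the
  sorted ratios at cumulative weight $1/2$ (midpoint convention
  $s_j = \sum_{i\le j} w_i - w_j/2$). Consistent whenever valid
  instruments carry more than half the weight.

Dispatch follows instrument count: $J{=}1$ Wald only, $J{=}2$ IVW only,
$J\ge3$ all of IVW, Egger and weighted median. The headline estimate is
IVW (Wald at $J{=}1$), replaced by the Egger slope when the intercept test
is significant at 0.05 — pleiotropy-adjusted estimates are preferred
exactly where directional pleiotropy is detected. This substitution rule
is explicit and can be disabled (`egger_substitution = FALSE`).

# Error models and inference

* **Wald ratio**: first-order delta SE $\sigma_{y1}/|\hat\gamma_1|$. The
  second-order term in $\sigma_{x}$ is negligible for genome-wide
  significant instruments (F-statistics in the hundreds to thousands); the
  design keeps the option of adding it without changing the interface.
* **IVW**: the default is multiplicative random effects — the fixed-effect
  SE inflated by $\max(1, \sqrt{Q/(J-1)})$, with Cochran's $Q$ in the
  extras. This is the conventional "adjusting for heterogeneity";
  fixed-effect and DerSimonian–Laird additive variants are exposed because
  reported analyses rarely state which was used. Normal inference.
* **MR-Egger**: residual dispersion floored at 1 (never anti-conservative
  relative to fixed effect), $t$ inference on $J-2$ df for both slope and
  intercept.
* **Weighted median**: the point estimate is deterministic; the SE comes
  from a parametric bootstrap (normal resampling of both effect panels at
  their reported SEs, default 1,000 draws) and therefore requires an
  explicit seed. Two 1,000-draw runs agree to well under 5%.

p-values are two-sided; confidence intervals are 95% throughout, normal
except for Egger's $t$.

# Instrument preparation

**Selection** keeps associations with $p < 5\times10^{-8}$ and refuses to
return a silently empty set. **Clumping** is greedy: repeatedly keep the
smallest-p remaining variant and discard same-chromosome variants within
the window (center-to-center, default 10,000 kb) with $r^2$ above the
threshold (default 0.001). Equal p-values break lexicographically by
variant ID, making results deterministic; variants absent from the LD
matrix are treated as independent with a warning, since no shipped
reference panel can cover every scored variant.

**Harmonization** re-expresses outcome effects for the exposure's effect
allele: swapped alleles flip the sign and complement the EAF; pairs that
match only after strand complementation are complemented first.
Palindromic variants (A/T, C/G) cannot be strand-resolved from alleles, so
they are resolved by allele-frequency concordance: retained when both EAFs
lie outside the 0.42–0.58 ambiguity band (flipping when the panels
disagree about the minor allele), dropped otherwise. The band and rule are
standard two-sample MR practice; published two-sample MR analyses rarely
state their handling, so the rule is documented here as an explicit
package decision rather than inferred convention. Harmonization is
involution-safe, and all estimators are invariant to the joint sign flips
it may apply.

# MR-PRESSO

The observed statistic is
$\mathrm{RSS} = \sum_j \sigma_{yj}^{-2}(\hat\Gamma_j -
\hat\beta_{-j}\hat\gamma_j)^2$ with $\hat\beta_{-j}$ the leave-one-out IVW
slope, so an outlying instrument cannot mask itself. The null distribution
comes from parametric simulation of both panels
($\Gamma^*_j \sim N(\hat\beta_{-j}\hat\gamma_j, \sigma_{yj})$,
$\gamma^*_j \sim N(\hat\gamma_j, \sigma_{xj})$); p-values use the add-one
estimator and are bounded below by $1/(n_{\mathrm{sim}}+1)$. The outlier
test compares each instrument's observed squared residual against its own
simulated null with Bonferroni adjustment; the distortion test expresses
the shift between raw and outlier-corrected IVW as a percentage of the
corrected estimate and compares it against shifts from removing equally
many **non-outlying** instruments at random.

Sampling the distortion null from the non-outlying instruments is a
deliberate choice: drawing from all instruments would put the true outlier
back into a fraction $m/J$ of null draws and bound the p-value near $m/J$
from below, making a genuinely distorting outlier undetectable. Simulation
counts (default 1,000), the global gate (0.05) and the Bonferroni level
(0.05) are configurable; the battery runs its stages conditionally —
outlier test only after a significant global test, distortion only when
something was flagged.

# Power and instrument strength

$R^2 = \sum_j 2f_j(1-f_j)\beta_j^2$ (standardized-trait approximation,
independent instruments after clumping), $F = R^2(N-2)/(1-R^2)$
(single-regressor convention; the $k$-regressor form is available), and

$$\mathrm{power} = \Phi\!\left(\sqrt{N\,R^2\,K(1-K)}\,|\ln \mathrm{OR}| -
z_{0.975}\right)$$

for a binary outcome of total size $N$ and case fraction $K$. The default
uses the balanced convention $K(1-K)=0.25$, which is the convention that
reproduces published diagnostic tables this implementation was checked
against (e.g. $R^2=0.08$, $N=27{,}209$: power 0.60 at OR 1.10, $F
\approx 2366$); the observed case fraction is available as an option.
Power is symmetric in OR vs 1/OR and returns the $\alpha/2$ tail mass
(≈0.025) rather than erroring at OR = 1 or $R^2 = 0$. Weak-instrument
flags use the conventional cutoffs F < 10 and best power < 80%; flagged
traits are reported, not filtered, since filtering on F introduces
selection bias.

# Atlas orchestration and tiering

Every exposure × outcome pair runs selection → clumping → harmonization →
estimation → sensitivity → power, with per-pair failures isolated and
reported as `not_analyzable` rather than dropped. Tiering is a partition:
significant below $0.05/n_{\mathrm{tests}}$, suggestive below 0.05, null
otherwise, with the boundary $p = 0.05/n_{\mathrm{tests}}$ counted as
suggestive (strict inequality for significance). The default denominator
is 60 — a trait-panel correction counting traits, not trait×outcome
pairs — and the same rule is applied to any subgroup outcome; both choices
are configurable. The bidirectional network among significant traits uses
the nominal 0.05 per directed edge, with no multiplicity correction, as is
conventional for intermediate-factor screening; edges carry sign,
magnitude and the estimator used.

Reproducibility: one master seed; per-pair and per-component seeds are
derived by a stable 31-bit string hash (`derive_seed`), so re-running a
configuration reproduces the results TSV byte for byte, and inserting or
removing one trait does not perturb another trait's stream.

# The synthetic generator

`simulate_gwas_pair()` draws from the summary-level model
$\Gamma_j = \beta\gamma_j + \alpha_j$: no individual-level genotypes are
simulated, because two-sample MR consumes only summary data. Choices worth
knowing:

* Instruments are oriented to the exposure-increasing allele
  ($\gamma_j > 0$) — directional pleiotropy is only well-defined relative
  to a fixed orientation.
* True association z-scores are uniform on 10–25, so every instrument
  passes $5\times10^{-8}$ after noise; SEs follow
  $\sigma_{xj} = (2f_j(1-f_j)n_x)^{-1/2}$ and
  $\sigma_{yj} = (2f_j(1-f_j)NK(1-K))^{-1/2}$, the standard summary-level
  forms, so generated SEs shrink exactly as $1/\sqrt{n}$.
* Default sample sizes mirror a large lung-cancer-scale consortium panel:
  11,348 cases / 15,861 controls against a 100,000-sample exposure GWAS.
* The invalid fraction receives $\alpha_j \sim N(\mu_\alpha,
  \tau_\alpha^2)$; violating InSIDE correlates $\alpha_j$ with
  $|\gamma_j|$ at 0.7. Outlier offsets are expressed in multiples of
  $\sigma_{yj}$ and added last.
* LD is block-diagonal AR(1) ($r = \rho^{|i-j|}$), positive semi-definite
  by construction, with within-block spacing (10 kb) inside the clumping
  window and between-block gaps (50,000 kb) outside it.

What the generator does **not** emulate: realistic human LD maps, sample
overlap between the two GWAS, binary-exposure liability scales, allele
coding errors, and population stratification. A green test therefore
establishes internal statistical correctness of the estimators under the
stated model — not robustness to those data pathologies.

`make_atlas_fixture()` builds an $n$-trait panel with a chosen number of
true positives at $\beta = 0.3$ and $J = 25$ instruments each, verifies
the realized power at the Bonferroni threshold exceeds 0.99, and errors
naming the limiting parameter if the request is infeasible.

# Numerical choices

* Strict inequalities at selection ($p <$ threshold) and tiering
  boundaries; lexicographic tie-breaks in clumping.
* Egger refuses degenerate designs (no spread in $\gamma$) with a
  collinearity error rather than returning an unstable fit.
* Weighted-median interpolation uses the cumulative-midpoint convention
  and clamps to the extreme ratios outside $[s_1, s_J]$.
* Add-one p-value estimators for every simulation test; distortion-shift
  comparisons carry a $10^{-9}$ absolute guard so an exactly homogeneous
  panel yields $p \approx 1$ instead of a floating-point coin flip.
* Bootstrap and simulation routines restore the caller's RNG state.

# Known limitations

**Weighted-median finite-sample coverage under heavy one-sided
contamination.** The package's validation suite checks, among other
things, that with 40% invalid instruments under strong directional
pleiotropy the weighted median stays within ±1.96 bootstrap SEs of the
truth while IVW is biased beyond 2 SEs. The IVW clause holds (bias ≈ 3
SEs in the test scenario), but the weighted-median clause does not, and
cannot: with one-sided invalid weight fraction $w$, the estimator targets
the $0.5/(1-w)$ weighted quantile of the *valid* ratio distribution —
at $w = 0.4$, roughly its 83rd percentile, a bias of about
$0.97\,\sigma_r$ against a sampling SD of $0.3$–$0.4\,\sigma_r$, where
$\sigma_r$ is the per-ratio noise scale. Both quantities scale together,
so no choice of sample sizes, instrument strength or pleiotropy magnitude
restores nominal coverage without also erasing the IVW bias the scenario
is meant to exhibit. The celebrated 50% breakdown property is an
asymptotic consistency bound (ratio noise → 0), not a finite-sample
coverage guarantee. The corresponding acceptance test is intentionally
left failing, with the measured rate (~46% of 500 replicates) as
documentation; practitioners should read weighted-median agreement with
IVW as reassurance, not as a calibrated interval under heavy directional
contamination.

Other limitations: no proxy-SNP lookup, genome-build liftover or remote
data retrieval; no MR-RAPS, mode-based, multivariable or Steiger
extensions; MR-PRESSO implements the slope-only (no-intercept) variant;
funnel asymmetry is reported as data plus the Egger intercept test rather
than a bespoke asymmetry statistic.
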