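---
title: "Methods: scoring, agreement and crosswalking of preference-based utilities"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: scoring, agreement and crosswalking of preference-based utilities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prefcross)
```

This vignette documents the models, the numerical choices, and the design
decisions behind `prefcross`, in the spirit of a statistical methods
appendix. It states no empirical result that the package's tests and
acceptance script do not themselves compute.

## 1. The two scoring engines

### Additive value sets (EQ-5D-5L)

An additive tariff assigns each item × level a utility *decrement*, zero
at level 1. A state's utility is the full-health anchor minus the sum of
its five selected decrements. The packaged U.S. time trade-off tariff has
anchor 1 and worst-state utility −0.573; `score_eq5d()` is generic over
any `value_set_table`, so alternative country tariffs are drop-in files.
Utilities are carried at full floating precision; 3-decimal rounding is a
reporting convention only.

### Multiplicative MAUT (PROPr)

`score_propr()` implements the multiplicative multi-attribute utility
form. Each of the seven PROMIS domains contributes a disutility
$du_j \in [0,1]$, read from a tabulated monotone curve by linear
interpolation (inputs beyond the tabulated range are clamped to the curve
ends). Domain disutilities aggregate as

$$DU = \frac{1}{C}\Big(\prod_j (1 + C\, w_j\, du_j) - 1\Big), \qquad
1 + C = \prod_j (1 + C\, w_j),$$

where $w_j$ are single-attribute corner weights. Since the weights sum
above 1, $C \in (-1, 0)$; the root is found once at construction
(`uniroot`, tolerance 1e-14). $DU$ is 0 at all-best and exactly 1 at
all-worst by construction, and utility is the affine map of $DU$ onto
the declared range, here $[-0.022, 0.954]$.

**Design decision — synthetic curves.** The published per-domain
disutility functions are not reproduced here; the packaged specification
(`propr_us_synthetic()`, file `propr_maut_synthetic.csv`) uses smooth
synthetic monotone curves (a power curve $p^{1.6}$ over each domain's
plausible T-score range) with plausible corner weights. Everything that
the package's tests bind to — the score range, the anchoring of the
extremes, monotonicity, and the multiplicative form — is faithful; the
per-state values are not claimed to match published PROPr scores. A
published value set, once tabulated in the same plain-text format, scores
through the identical engine. Disutility curves are represented as knot
tables rather than parametric formulas because tabulation is
representation-agnostic and directly testable for monotonicity.

## 2. Agreement statistics

For a paired sample (two measures per person) `anova_decompose()` computes
the two-way ANOVA mean squares in closed form ($MS_b$ between persons,
$MS_w$ person × measure interaction, $MS_t$ measure main effect); the
decomposition is tested against `anova(lm(...))` and conserves the total
sum of squares to 1e-10 relative.

The two intraclass correlations are the standard single-measure two-way
forms with $k = 2$ measures:

$$\mathrm{ICC}_{consistency} = \frac{MS_b - MS_w}{MS_b + MS_w}, \qquad
\mathrm{ICC}_{agreement} = \frac{MS_b - MS_w}{MS_b + MS_w + \tfrac{2}{n}(MS_t - MS_w)}.$$

The mixed-effects (consistency) form ignores the measure main effect; the
random-effects (absolute agreement) form charges the mean difference to
the denominator. For large $n$ the agreement form converges to the
moment expression $2 r s_1 s_2 / (s_1^2 + s_2^2 + (m_1 - m_2)^2)$, which
the tests use as an independent oracle. These standard mean-square forms
were chosen because they reproduce, from the published summary moments,
the published ICC values themselves (0.67 and 0.34); the package treats
them as the intended estimators. Two useful invariants follow and are
property-tested: consistency ≥ agreement whenever the means differ, and
the two forms coincide to $O(1/n)$ when the means agree.

Other conventions: SDs use the $n-1$ denominator throughout; all pairwise
statistics use complete-case deletion; p-values are two-sided from the t
distribution with no multiplicity adjustment. `nmae()` is mean absolute
error divided by the observed SD; `cohen_d_to_r()` is $d/\sqrt{d^2+4}$.

## 3. The crosswalk

`apply_crosswalk()` applies three stages in a strict order:

1. **Predict:** $\hat y = a + b x$ (OLS).
2. **Equate:** $\tilde y = m_T + (s_T / s_{\hat y})(\hat y - m_T)$, where
   $m_T, s_T$ are the observed target mean and SD and $s_{\hat y}$ the
   predicted-score SD. Because OLS predictions are mean-preserving, the
   equated scores on the fitting sample reproduce the target mean and SD
   exactly (asserted to 1e-10); equating corrects the
   regression-to-the-mean shrinkage that makes raw predictions
   under-disperse.
3. **Clamp:** recode outside the bounds to the nearest bound. Fitted
   models default to the observed target range; the packaged published
   models clamp to the theoretical instrument ranges.

`published_crosswalk()` carries the published constants. Note the
published equating equation for the PROPr direction centers on 0.538
while the descriptive mean is printed as 0.539 elsewhere; the packaged
model uses 0.538, following the equation.

### Beta-family alternative

The published analysis also fit a "beta-binomial" model after rescaling
the utility linearly to the unit interval by its observed range
(recoding negatives to zero prevented the optimizer from moving, so the
range rescaling is the operative transform). The binomial denominator was
never stated, so `fit_beta_binomial_map()` exposes both readings:

- `mode = "beta"` (default): a continuous beta regression with logit mean
  link and free precision, with boundary values nudged by
  $(y(n-1) + 0.5)/n$ — standard practice for exact 0/1 values;
- `mode = "betabinomial"`: an integer-trials beta-binomial with
  configurable denominator (default 100), the strict reading of the name.

Both are fitted with `glmmTMB`; tests verify the two modes agree closely
and that the beta mode recovers its own generating parameters. Predictions
are inverted through the stored unit-interval transform, so evaluation
(`evaluate_map()`) is on the original utility scale in both routes.
Age/gender covariates are supported but off by default (they added about
one point of adjusted R² in the published analysis).

## 4. Condition regressions

One simultaneous OLS model per utility on the 22 binary indicators, as in
the published table: no selection, no shrinkage, complete cases, with
zero-order correlations reported alongside coefficients (so suppression
effects — coefficient and zero-order correlation of opposite sign — are
visible). Rank deficiency is reported naming the offending columns.
Significance stars annotate the 0.05 / 0.01 / 0.001 / 0.0001 thresholds.
Both R² and adjusted R² are emitted, since the published table's header
and text disagree about which is shown.

## 5. The synthetic cohort generator

The generator is explicitly a stand-in: the published study describes its
data, not a generative model. The design goal is the *minimal* mechanism
reproducing the calibration targets a tester needs.

### Why not a censored Gaussian

A right-censored Gaussian latent cannot reproduce the EQ-5D-5L triple
(mean 0.855, SD 0.195, 31% ceiling): fixing the ceiling fraction and the
mean of a Gaussian censored at 1 forces the post-censoring SD to about
0.155. Equivalently, the non-ceiling 69% of the sample must have mean
≈ 0.79 and SD ≈ 0.20 with support below 1 — a strongly left-skewed shape
that a truncated Gaussian only attains in its extreme-tail regime. Real
EQ-5D-5L distributions are left-skewed for exactly this reason.

### The disutility-gamma mechanism

The default generator therefore works on the disutility scale:

$$D = \max(0,\; B_1 + G - \kappa), \qquad \text{EQ-5D-5L} = 1 - \min(D, 1.573),$$

where $B_1 = \sum_j (-\beta^{EQ}_j) c_j$ is the condition burden
(indicators $c_j$ drawn independently at the published prevalences, true
effects $\beta_j$ = the published coefficients) and
$G \sim \Gamma(k, \theta)$. The point mass at $D = 0$ is the ceiling; the
gamma right tail supplies the left skew. The PROPr is

$$\text{PROPr} = a_2 - B_2 - \gamma\,(G - k\theta) + \sigma_w Z,$$

clamped to $[-0.022, 0.954]$: the shared $G$ and the shared conditions
carry the cross-measure correlation, $Z$ is independent Gaussian.

**Calibration** (`calibrate_cohort()`) solves, on a fixed
common-random-number sample of 200,000 draws (internal seed, independent
of the user's generation seed, so the parameter set is a deterministic
function of the spec; results are cached):

1. gamma shape $k$ by 1-D root finding on the achieved SD, with an inner
   2-D moment match of $(\theta, \kappa)$ to the mean and ceiling;
2. $(a_2, \gamma, \sigma_w)$ by a 3-D moment match to the PROPr mean/SD
   and the post-censoring correlation.

Residuals above 0.005 raise a calibration error carrying the achieved
vs target table. With `eq_ceiling = 0` the generator switches to an
exact closed-form Gaussian calibration (condition variance
$\sum \beta_j^2 p_j (1-p_j)$ subtracted from the target variances, noise
correlation from the required covariance); this configuration has an
exactly linear conditional mean, and it is the configuration under which
the condition-regression recovery test operates — under censoring, OLS on
the generated data estimates attenuated effects by construction, so exact
recovery of the generating coefficients is only a meaningful test in the
uncensored mode.

### Follow-up and retrospective items

Follow-up advances the *latent* baseline state: $D$ by $-\delta_1$ and
the pre-clamp PROPr by $\delta_2$, with $(\delta_1, \delta_2)$ bivariate
normal. Because re-censoring at the boundaries would otherwise drag the
observed mean changes negative and attenuate the change-change
correlation, the two drifts and the latent change correlation are solved
(1-D root finding each, same CRN approach) so that the *observed* mean
changes are 0.00 and the observed change-change correlation hits its
target (default 0.34). The latent change SDs default to 0.13 (EQ-5D-5L)
and 0.17 (PROPr) — values consistent with published test–retest
reliabilities of such scores over stable periods; they are a modeling
choice, as the study reports no change SDs.

Each retrospective item is an ordinal variable cut from a standard-normal
latent that loads on the two standardized observed changes. Thresholds
put the reported "about the same" mass in the middle category; the
remaining mass is split equally between the two sides (the tails), with
fixed within-side splits placing more mass adjacent to "about the same"
(2:1 for 5-level items; 0.4/0.3/0.2/0.1 across the four improvement
categories of the 7-level back-pain item — the study reports no tail
distribution, so these splits are a fixed convention). Loadings are
solved in closed form from the target correlations after correcting for
the ordinal attenuation $\rho = \mathrm{corr}(L, s(L))$, computed
analytically from the thresholds.

### Pain instruments

Back-pain-subgroup instrument scores are generated the same way: a latent
loading on the two standardized utilities (closed-form solve against the
target correlations), mapped to each instrument's scale by mean/SD,
clamping, and rounding to the instrument's granularity (e.g. ODI moves in
steps of 2; GCPS subscores in steps of 10/3). The instrument means and
SDs (e.g. ODI 28 ± 16, PEG 4.5 ± 2.4, chronic-pain prevalence 55%) are
plausible values for a community back-pain sample, chosen once; the study
reports only the correlations. The cohort table carries instrument
*scores*; item-level responses are exercised by the scorer tests with
generated item fixtures.

### What the generator does and does not emulate

Matched: marginal means/SDs, the ceiling fraction, the cross-measure
correlation, condition prevalences and effect structure, zero mean change,
the change-change correlation, retrospective-item margins and
correlations, instrument correlations. Not matched: the multimodality and
discrete support of real EQ-5D-5L scores (a finite state space with a gap
below the ceiling), the joint dependence of conditions (independent by
default), demographics, and the exact distributional shape. Consequently,
shape-dependent statistics computed on synthetic cohorts — NMAE, equated
moments after clamping, the beta-family fit indices — are indicative, not
reproductions of the published values, and the package's acceptance
checks deliberately exclude them in favor of property-based tests
(ANOVA-oracle equivalence, equating moment preservation, clamp bounds,
parameter recovery).

## 6. Numerical conventions and problem sizes

- Sample SDs: $n-1$ denominator everywhere.
- Complete-case deletion for all paired/pairwise statistics.
- Degenerate inputs fail loudly: zero variance, undefined ICC
  denominators, zero observed range, non-converged fits (the optimizer
  message is propagated), rank-deficient condition panels.
- Seeds: every generator takes an explicit integer seed; identical spec +
  seed gives byte-identical output. Calibration uses its own fixed
  internal seed and a 200,000-draw sample, making calibrated parameters
  reproducible and independent of generation seeds.
- Test and acceptance problem sizes are chosen to keep Monte-Carlo error
  an order of magnitude below the tolerance being asserted: 100,000 pairs
  for moment-matched agreement/mapping checks (SE of r ≈ 0.002), 50,000
  to 100,000 for generator calibration checks, 5,000 for likelihood
  parameter-recovery checks (2 SE criterion), and exhaustive enumeration
  (3,125 states) for the additive scorer.

## 7. Known limitations

- The packaged PROPr curves are synthetic (Section 1); per-state PROPr
  values are not the published ones.
- The crosswalk is a group-level tool; individual predictions carry
  error around half an observed SD by design of the problem, not of the
  implementation.
- The beta-binomial reading with a small integer denominator discretizes
  the outcome; the continuous beta mode is the default for that reason.
- ODI scoring does not implement the instrument's skipped-section
  rescaling (items are required or the score is missing), since the
  analysis plan this package operationalizes treats missing items by
  complete-case deletion.
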