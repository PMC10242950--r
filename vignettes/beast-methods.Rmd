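---
title: "Models and methods: social information use in the BEAST"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: social information use in the BEAST}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(beastr)
```

This vignette is the package's account of its science: the scoring and
exclusion rules, the statistical models, the generative model behind the
synthetic cohorts and how it is calibrated, the numerical choices, and what
the tests do and do not establish about real data.

## The task and the adjustment weight

Each of five task rounds shows an image with a fixed animal count
(43, 58, 34, 44, 39 — chosen for similar difficulty and presented in fixed
order), collects a first integer estimate $E_1$, shows a peer estimate $X$,
and collects a second estimate $E_2$. Social information use per round is
the weight of advice

$$s = \frac{E_2 - E_1}{X - E_1}, \qquad E_2 = (1-s)E_1 + sX.$$

Rounds are classified **stay** ($E_2 = E_1$, $s=0$), **copy**
($E_2 = X \ne E_1$, $s=1$) or **compromise** ($E_2$ strictly between $E_1$
and $X$); stay and copy jointly are *all-or-nothing* strategies. Because
estimates are integer keyboard entries, classification is done entirely in
integer arithmetic (sign and magnitude comparisons of $E_2-E_1$ vs
$X-E_1$), so the boundary cases $s=0$ and $s=1$ involve no floating-point
tie-breaking; the floating `s` column is derived afterwards for modelling.
The test suite proves the integer classifier equivalent to a brute-force
interval-membership oracle on every triple in $[1,60]^3$.

Rounds with $s<0$ (adjustment away from the advice) or $s>1$ (overshooting
it) are invalid; $X=E_1$ leaves $s$ undefined and is treated like an
invalid round (the calibrated task never produces it, but arbitrary input
files can). Participants with **three or more** invalid rounds out of five
are excluded and logged; retained participants contribute only their valid
rounds to the models, while first-estimate accuracy uses all five rounds
(validity concerns $E_2$ only). Where rates of invalid responding are
reported, the package always prints raw counts next to an explicit
denominator, because rates with implicit denominators are ambiguous after
participant-level exclusions.

## The social-information calibration

The exact calibration rule of the original task is not specified in the
main text beyond its intent: a *relatively constant scope for adjustment*
across rounds, controlling away distance-weighting effects. The package
adopts a symmetric multiplicative band: $X = \mathrm{round}(E_1(1+\delta))$
with $|\delta| \sim U(0.15, 0.25)$ and the sign following a balanced
per-round schedule (`+,−,+,−,+` by default; whether the original schedule
was fixed or randomized per participant is not stated, so it is exposed as
configuration). Relative offsets are scale-invariant, which is what keeps
the scope for adjustment comparable across estimate magnitudes. A minimum
integer distance $|X-E_1| \ge 2$ guarantees an interior integer exists, so
a compromise is always representable; for tiny $E_1$ where the band cannot
achieve that distance the generator falls back to $X = E_1 \pm 2$, flipping
the sign upward if the downward fallback would leave $X<1$. Consequently
$X \ne E_1$ on every generated round.

## Statistical models

**Degree of adjustment.** A linear mixed model of round-level $s$ on group
(TD reference) with a participant random intercept, fit by REML via
`lme4::lmer`. The intercept is the TD round-level mean of $s$. Wald
intervals and normal p-values are reported on the identity scale. Fitting
the *round-level* $s$ (rather than participant means) is the only reading
consistent with a subject random factor and an observation count equal to
the retained valid rounds.

**Strategy choice.** A random-intercept logistic model of the
all-or-nothing indicator (stay/copy = 1, compromise = 0) on group, fit by
ML with adaptive Gauss–Hermite quadrature (`nAGQ = 10`) via `lme4::glmer`.
Reported odds ratios are conditional (subject-specific). Exploratory
codings re-fit the same model for stay-vs-rest and copy-vs-rest. The group
factor is tested by a likelihood-ratio χ² of nested ML fits (the χ²
statistics of the original analysis are not labelled LR vs Wald; LR is
implemented because it is invariant to the reference level). Age and IQ
covariates, when requested, are mean-centered so the intercept remains the
TD reference mean.

**Derived quantities.** The latent-scale residual variance of the logistic
model is $\pi^2/3 \approx 3.29$; the intraclass correlation is
$\tau_{00}/(\tau_{00}+\sigma^2)$, and Nakagawa's
$R^2_m = V_f/(V_f+\tau_{00}+\sigma^2)$,
$R^2_c = (V_f+\tau_{00})/(V_f+\tau_{00}+\sigma^2)$ with $V_f$ the variance
of the fixed-effect linear predictor over the estimation sample (the
model's own design matrix, not population weights). These closed forms are
verified in tests, including the internal-consistency check that inverting
a marginal $R^2$ of 0.068 with components (3.96, 3.29) yields a
conditional $R^2$ of 0.577.

**Contrasts.** Pairwise group contrasts use the single-step
multivariate-normal (Tukey) adjustment via `multcomp::glht`. The adjusted
p-values involve a quasi-random multivariate-normal integral; the package
evaluates them under a fixed local RNG seed so pipeline output is
byte-reproducible. With two groups the table reduces to the unadjusted
Wald test.

**Degenerate outcomes.** A constant strategy outcome (e.g. an all-stay
cohort under the stay-vs-rest coding) or complete separation makes the
GLMM likelihood unbounded. The package then falls back to a
Firth-penalized plain logistic regression (Jeffreys-prior score
correction, implemented as hat-value-corrected IRLS), flags the fit, and
reports `tau00 = NA` — finite estimates with an honest label rather than a
divergent fit.

**Accuracy.** A one-way ANOVA of per-participant `mean(E1/true_count)`
with $\eta^2 = SS_{between}/SS_{total}$.

## The generative model

A simulated participant in group $g$ carries one heterogeneity draw
$u_i \sim N(0, \tau_{00})$. Per round:

1. $E_1 = \max(1, \mathrm{round}(T \cdot e^{\varepsilon}))$,
   $\varepsilon \sim N(\log m_g, c^2)$ — multiplicative underestimation of
   the true count $T$ with lognormal noise;
2. $X$ from the calibrated task rule;
3. all-or-nothing vs compromise with probability
   $\mathrm{logit}^{-1}(c_g + u_i)$; all-or-nothing rounds split stay vs
   copy with fixed odds $p_{stay}:p_{copy}$; compromise rounds draw
   $w \sim \mathrm{Beta}(a,b)$ and set
   $E_2 = \mathrm{round}(E_1 + w(X-E_1))$ clamped to the open integer
   interval, so an intended compromise is never re-labelled stay or copy
   by rounding.

Heterogeneity enters *only* the all-or-nothing propensity — the simplest
structure consistent with a strategy model that has a single random
factor. The conditional intercept $c_g$ is solved from the group's target
*marginal* all-or-nothing share by integrating the logistic over the
random-effect distribution with 40-node Gauss–Hermite quadrature
(`marginal_aon_probability` / `aon_intercept`): with $\tau_{00} = 3.96$
the conditional and marginal scales differ substantially, and a naive
logit of the marginal share would miscalibrate the simulator by several
percentage points.

### Calibration by moment matching

Three observable round-level statistics identify the mixture: the
compromise share $p_c$, the mean adjustment
$\bar s = p_{copy} + p_c E(w)$, and the below-half share
$P(s<0.5) = p_{stay} + p_c F_w(0.5)$. With four free parameters
($p_{stay}, p_{copy}, a, b$) the system is underdetermined by one degree
of freedom; it is resolved by preferring a Beta concentration $a+b$ near
20 (the solver scans a log-spaced grid when no feasible root exists
there). The concentration mainly affects the spread of $s$ among
compromise rounds, which no target constrains; 20 gives the
moderately-peaked weight distributions typical of advice-taking data.
Infeasible targets raise a calibration error naming the violated
constraint.

**Integer discretization.** Simulated $s$ values of compromise rounds live
on the grid $j/d$ with $d = |X-E_1|$. For even $d$ the grid contains
exactly $0.5$, so the *strictly*-below-half share of the discretized
weight is systematically smaller than the continuous $F_w(0.5)$ (by
$\approx f_w(0.5)/(2d)$ per even-$d$ round — several percentage points at
these distances), and clamping to the open interval shifts the extreme
grid cells inward. Calibrating against continuous Beta moments therefore
reproduces the latent weights but *not* the observed statistics. The
solver instead uses the exact discretized moments: for each distance $d$
it enumerates $P(\mathrm{round}(wd) = j)$ from the Beta CDF, applies the
clamp, and mixes over the distance distribution implied by the task band
and the estimation-error model — which is independent of the strategy
parameters and is tabulated once per calibration from a fixed-seed draw of
$2\times10^5$ $(E_1, X)$ pairs. Realized statistics of large simulated
cohorts then match the targets to Monte-Carlo error, which is what the
calibration acceptance checks require.

### Default targets

The packaged defaults (`paper_profiles()`,
`inst/extdata/paper_defaults.yaml`) encode the published group statistics:
compromise shares 64.11% (TD) and 35.86% (CP/LCU); mean adjustments
0.36/0.32/0.36 and below-half shares 80.00%/74.19%/68.75% for
TD/CP-LCU/CP-HCU; $\tau_{00} = 3.96$; mean first-estimate accuracy
69%/68%/74% of the true count; group sizes 45/31/32; and age/IQ moments
from the published demographics table (used only to exercise covariate
re-runs). The CP/HCU compromise share is **not** published (it appears
only in a figure); the default of 0.50 interpolates between the other
groups, consistent with the finding that CP/HCU differed significantly
from neither, and is flagged as synthetic wherever it appears.

The estimation-error model is parameterized so the realized *mean* of
$E_1/T$ matches the published average accuracy: the lognormal median is
the target mean divided by $e^{c^2/2}$. The noise scale $c = 0.25$ is a
fixed default in the range typical of brief numerosity estimation; no
published dispersion constrains it. The same convention applies to the
YAML field `accuracy_mean`.

The generator can inject invalid rounds ($s<0$ or $s>1$) at a configurable
rate to exercise the exclusion filter, but the default is 0: whether real
invalid rounds arise from typos or strategy cannot be known, and no
mechanism is claimed.

## Numerical choices

* Quadrature: 40 Gauss–Hermite nodes for the logistic-normal integral
  (agrees with a $10^6$-draw Monte-Carlo oracle to ~3 decimals); intercept
  inversion by `uniroot` to $10^{-12}$.
* Moment solver: root-bracketing over the Beta mean on a 97-point grid per
  concentration, `uniroot` tolerance $10^{-12}$; residuals of the moment
  system below $10^{-6}$.
* GLMM: `nAGQ = 10` adaptive quadrature; REML for the linear model; Wald
  intervals on the link scale, exponentiated for odds ratios.
* Ties and degeneracy: integer-exact classification (no ties possible);
  singular linear-model fits are flagged, not failed; constant outcomes
  and separation route to the Firth fallback.
* Determinism: every stochastic routine takes or derives an explicit seed
  (wall-clock seeding is refused), and internal fixed-seed draws
  (calibration tabulation, Tukey p-values) preserve the caller's RNG
  state. Two pipeline runs from the same config are byte-identical.

## Problem sizes used in validation

Scoring equivalence is exhaustive on $[1,60]^3$ (~2.1×10⁵ triples with
$E_1 \ne X$). Calibration checks simulate 10⁵ rounds per group; accuracy
checks 10⁵ rounds; odds-ratio recovery refits 100 replicate cohorts at the
study's 108-participant design; the test suite uses smaller versions of
the same checks (dozens of replicates, 10³–10⁵ rounds) chosen to keep the
full suite in the low minutes while leaving Monte-Carlo error well inside
the asserted tolerances.

## What the synthetic cohorts do and do not show

The generator reproduces the *marginal structure* the analysis assumes:
strategy mixtures with realistic between-participant heterogeneity,
calibrated first-estimate accuracy, and the published group sizes. Passing
tests therefore demonstrate that the scoring, exclusion and modelling
machinery recovers known generating parameters under the study's design —
not that the original behavioural findings replicate. Real data differ in
ways the generator deliberately omits: no learning or order effects across
rounds (the task gives no feedback, but humans may drift anyway), no
distance weighting (the calibration controls it away by design), no
response-time structure, homogeneous stay-vs-copy odds and compromise
weights within group, and invalid responses only by explicit injection.
Group labels are inputs throughout; the screening instruments that define
them are out of scope.

## Known limitations

* The CP/HCU strategy targets are partly synthetic (see above); results
  involving that group's defaults are illustrative.
* Conditional (subject-specific) odds ratios at $\tau_{00} \approx 4$ are
  much larger than the corresponding marginal effects; users comparing
  against population-averaged analyses should use
  `marginal_aon_probability` to translate.
* The moment system pins only three statistics per group; the Beta
  concentration default is a modelling choice, and quantities sensitive to
  the spread of $s$ among compromise rounds (beyond the below-half share)
  are not calibrated.
* With five rounds per participant, $\tau_{00}$ estimates from single
  cohorts at n = 108 are noisy; the recovery checks therefore compare
  medians across replicates, not single fits.
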