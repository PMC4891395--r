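---
title: "Bayes factors for the Pearson correlation: model, priors, and numerics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bayes factors for the Pearson correlation: model, priors, and numerics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(corbf)
```

## The model and its assumptions

The data are assumed to be n independent pairs from a bivariate normal
distribution with five parameters: two means, two variances, and the
correlation $\rho$, which is the parameter of interest. The means and
variances are nuisance parameters: they are never estimated, but removed
analytically, after which the likelihood depends on the data only through
the sample size $n$ and the sample Pearson correlation $r$. `corbf`
implements the exact reduced likelihood (the sampling density of $r$),

$$p(r \mid \rho, n) \;=\; \frac{(n-2)\,\Gamma(n-1)}{\sqrt{2\pi}\,
\Gamma(n-\tfrac12)}\,(1-\rho^2)^{\frac{n-1}{2}}\,(1-r^2)^{\frac{n-4}{2}}\,
(1-\rho r)^{\frac{3-2n}{2}}\;
{}_2F_1\!\Bigl(\tfrac12,\tfrac12;\,n-\tfrac12;\,\tfrac{1+\rho r}{2}\Bigr),$$

rather than the classical large-n approximation
$(1-\rho^2)^{(n-1)/2}(1-\rho r)^{(3-2n)/2}$; the approximation remains
available via `r_density(..., method = "jeffreys")` strictly for
cross-checking (the two agree to well under 1% for $n$ in the hundreds).
The bivariate-normality assumption matters: a zero correlation is
misleading when the true relation is U-shaped, so raw data should always
be inspected before a correlational analysis is trusted.

All tests compare the point null $\mathcal H_0:\rho=0$ with an
alternative defined by a prior $\pi(\rho)$ on $(-1,1)$:

$$\mathrm{BF}_{01} \;=\; \frac{p(r \mid \rho=0, n)}
{\int p(r \mid \rho, n)\,\pi(\rho)\,d\rho}.$$

The Bayes factor is the factor by which the data shift any reader's prior
model odds, whatever those odds are (`update_odds()`); it is a *relative*
measure, so changing $\pi$ changes the question being asked — that is the
organizing idea of the whole suite.

## The prior families

* **Uniform, $\rho\sim U(-1,1)$** (`uniform_prior()`): the default
  two-sided test. Every correlation is equally plausible a priori.
* **One-sided, $\rho\sim U(0,1)$** (`one_sided_prior()`): for directional
  substantive hypotheses. Two structural facts are enforced by tests: a
  sign restriction can favor the alternative at most two-fold
  ($\mathrm{BF}_{0+}\ge\mathrm{BF}_{01}/2$), and an effect observed in
  the *wrong* direction amplifies the evidence for the null.
* **Stretched beta** (`stretched_beta_prior(gamma)`): $\;(\rho+1)/2 \sim
  \mathrm{beta}(\alpha,\alpha)$, parameterized by the width
  $\gamma = 1/\alpha \in (0,1]$ (the user-facing axis; $\alpha$ is
  internal). $\gamma=1$ is the uniform prior; as $\gamma\to 0$ the
  alternative collapses onto the null and the Bayes factor tends to 1.
  `bf_sensitivity()` sweeps a $\gamma$ grid to show how much (or little)
  conclusions depend on prior width. For a pooled summary of the packaged
  replication series:

```{r sensitivity}
bf_sensitivity(study_summary(1153, -0.03),
               gamma = c(0.05, 0.25, 0.5, 0.75, 1))
```

  Support for the null at every width — robustness of exactly the kind a
  sensitivity analysis is meant to reveal. Asymmetric beta$(a,b)$ priors
  are deliberately out of scope.
* **Interval null** (`interval_prior(c)`, `bf_interval_null()`): replaces
  the "known to be false" point null with $\rho\sim U(-c,c)$. With
  $c=0.01$ the result is virtually identical to the point-null analysis
  (the packaged tests bound the difference at 0.05 on the log scale),
  which is why the point mass is a mathematical convenience rather than a
  substantive commitment.
* **Posterior of an original study** (`replication_prior()`,
  `bf_replication()`): the replication test. The proponent's hypothesis
  $\mathcal H_r$ is the posterior of $\rho$ after the original study; the
  Bayes factor asks "is the effect similar to what was found before, or
  absent?" rather than "is there any effect at all?".

## Design decisions

**Replication prior base.** The original-study posterior could be formed
under a uniform or a one-sided base prior. The package defaults to the
uniform base, and the choice was adjudicated numerically against the
published analysis this package reproduces: for the strongest original
study the uniform base recovers the published replication Bayes factor to
within 2%, while a one-sided base is off by more than 20%. The base
remains configurable (`bf_replication(..., base = )`).

**Analytic posterior-based prior.** The posterior-of-original-study prior
is represented exactly as the normalized product
likelihood $\times$ base, with its normalizing constant computed once by
adaptive quadrature and cached, rather than as an interpolated grid. This
removes an interpolation-error term from the replication Bayes factor and
keeps every density evaluation deterministic.

**Sequential analysis at summary level.** `bf_sequential()` defines the
joint Bayes factor on the product of the two reduced likelihoods (studies
independent given a shared $\rho$). This differs infinitesimally from
pooling raw data — pooled r is not a deterministic function of the two
study-level r values — but it is the only coherent definition when only
summaries are available, and the multiplication rule
$\mathrm{BF}(E_1,E_2)=\mathrm{BF}(E_1)\,\mathrm{BF}(E_2\mid E_1)$ is
verified to $10^{-6}$ relative. The direction of the naive-product error
depends on the data: under null-generated studies the naive product
*overstates* the evidence for the null (the published demonstration:
multiplying four individual BFs gives $\approx 1100$ where the pooled
analysis gives $\approx 16$); under a shared true effect the coherent
joint analysis is the more extreme one, because updating sharpens the
prediction of the second study.

**Central credible intervals.** Equal-tailed intervals were chosen over
highest-density intervals for determinism and simplicity; HDIs are a
possible extension. For the skewed posteriors that small-n, large-|r|
studies produce, the two differ visibly.

## Numerical scheme

* **Hypergeometric term.** No installed numerical library exposes the
  Gauss ${}_2F_1$, so the package evaluates it by its defining series,
  which for these arguments ($a=b=\tfrac12$, $c=n-\tfrac12\ge 3.5$,
  $z\in[0,1)$) has positive terms, ratio bounded by $z$, and a sum that
  stays $O(1)$ — geometric convergence with no cancellation. The density
  itself is assembled in log space.
* **Marginal likelihoods** use adaptive quadrature (`stats::integrate`,
  relative tolerance $10^{-11}$ per panel) with the integration range
  split at the observed $r$, at 0, and at the original study's $r$ for
  posterior-based priors, so the sharp likelihood peak of a large-n study
  can never fall between quadrature nodes. Every `bf_result` carries the
  achieved relative error (`numeric_error`; $<10^{-6}$ required,
  typically $\sim 10^{-13}$). A result that cannot reach tolerance raises
  a classed error rather than returning silently degraded output.
* **Posterior grids** (default 4001 nodes) are equally spaced in
  $\operatorname{artanh}\rho$ — denser near $\pm 1$, where densities with
  $\gamma<1$ endpoint behavior change fastest — with $\rho=0$ guaranteed
  to be a node, so the Savage–Dickey height at the null involves no
  interpolation. Normalization is by the trapezoid rule on the grid
  (hence exact for the grid object by construction); doubling the grid
  changes the density at zero by $<10^{-4}$ relative.
* **Degenerate inputs.** $|r|=1$, zero-variance coordinates, and $n<4$
  are rejected (classed conditions), not clamped: every downstream
  integral diverges or degenerates there. $n<10$ triggers a warning that
  the Bayes factor will be prior-dominated. Support endpoints are treated
  as limits from inside, which is what lets the one-sided $U(0,1)$ prior
  have a well-defined Savage–Dickey height at $\rho=0$.
* **Determinism.** Everything outside the simulator is deterministic
  quadrature; there are no internal random tie-breaks.

## The simulator and what passing tests show

`simulate_bivariate()` draws bivariate-normal pairs via the Cholesky
construction, with defaults mean 0 and scale 1 — unitless, because
location and scale are nuisance parameters, a fact asserted by a test
that rescaling the data leaves $r$ and every Bayes factor unchanged.
Each replicate has its own seed derived by a fixed jump, so replicate k
is reproducible independently of how many replicates are requested.

Calibration experiments in the test suite use sizes chosen to probe the
relevant asymptotics at desk scale: consistency under the null with
$n\in\{50,200,800\}$ and 200 replicates (median $\mathrm{BF}_{01}$
strictly increasing in $n$), and 95% credible-interval coverage at
$n=100$, $\rho=0.3$ over 500 replicates (observed coverage required in
[0.93, 0.97]). The generator emulates exactly the model the tests assume
— bivariate normality, independent pairs, a single shared $\rho$. It does
not emulate heavy tails, nonlinearity, ordinal measurement, or dependent
observations, so passing calibration says nothing about robustness to
model violation in real data; for real analyses the scatterplot check
remains the user's responsibility.

## Input rounding: the accuracy limit of summary-based reanalysis

The packaged fixtures carry $r$ to two printed decimals, and this — not
quadrature — is the accuracy bottleneck of reproducing a published
analysis from summaries. The package's own computations quantify it. For
the study with $n=494$ and printed $r=0.10$:

```{r rounding}
bf0plus(study_summary(494, 0.10))$bf01   # printed r
bf0plus(study_summary(494, 0.098))$bf01  # r perturbed by 0.002
```

A perturbation of $r$ by 0.002 — a fifth of the final printed digit —
moves $\mathrm{BF}_{0+}$ from 0.77 to 0.85, a 10% change; the published
value for this study is 0.85. Rows with $|r|\approx 0.01$ are the extreme
case, since rounding there perturbs $r$ by up to half its magnitude. For
replication Bayes factors beyond $10^4$ the log-tail sensitivity is large
enough that `bf_replication()` warns that input rounding dominates
precision. Consequently, agreement with published values should be judged
on a sliding scale (the packaged regression tests use 5% below 100, 15%
up to $10^4$, 35% beyond), and any discrepancy within those bands traces
to the printed inputs, not the method.

## Known limitations

* Pearson correlation only: no rank-based (Spearman, Kendall) or partial
  correlations, no comparisons between correlations.
* Symmetric priors only; the stretched-beta width is restricted to the
  $\gamma\in(0,1]$ axis users actually sweep.
* Summary-level sequential analysis (see above); raw-data pooling, when
  raw data exist, is preferable and trivially done upstream.
* Extreme Bayes factors ($>10^4$) are reported but their trailing digits
  carry no information once inputs are rounded.
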