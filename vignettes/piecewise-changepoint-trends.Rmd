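---
title: "Piecewise change-point trend models for injury surveillance rates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Piecewise change-point trend models for injury surveillance rates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lawbend)
```

## The problem

All fifty US states and the District of Columbia passed youth
traumatic-brain-injury (TBI) laws between 2009 and 2014. These laws differ
in language: some name the category of healthcare provider allowed to clear
an injured athlete to return to play (RTP), some require concussion
education of both coaches and parents/guardians rather than either. A
natural policy question is whether high-school concussion *rates* — events
per athlete-exposure (AE), one athlete participating in one practice or
competition — changed their trend around law passage, and whether that
change differs across law-language groups.

Because passage dates are staggered across states, calendar time is the
wrong axis. `lawbend` aligns every state on a **standardized month (STDM)**
axis: the calendar-month difference between an event and the state's
law-passage month (0 = passage month, negative = before). Weekly exposure
records are summed over four-week increments (weeks 1–4, 5–8, …, 49–52,
giving 13 blocks per academic year), events are mapped to the same blocks
through their injury dates, and each block lands on the STDM of the
calendar month containing its centre.

## The model

For state $j$ and standardized month $m$, the event count $y_{jm}$ with
exposure denominator $A_{jm}$ is modelled as NB2 (variance
$\mu + \alpha\mu^2$) with

$$\log E[y_{jm}] = \log A_{jm} + \beta_0 + b_j + \beta_1 m +
  \gamma_1 (m-\tau_1)_+ + \gamma_2 (m-\tau_2)_+ , \qquad
  b_j \sim N(0, \sigma_b^2).$$

The hinge terms $(m-\tau)_+$ are zero at and below their knot, so the
fitted log-rate is continuous and only its slope breaks at the two change
points $\tau_1 < \tau_2$. $\beta_1$ is the log-linear trend before
$\tau_1$; $\gamma_1$ and $\gamma_2$ are the *additional* slopes after each
change point. Slopes are reported as percent per STDM via
$100(e^\gamma - 1)$.

The state random intercept $b_j$ absorbs persistent between-state rate
differences (participation mix, reporting culture). It is integrated out of
the likelihood by adaptive Gauss–Hermite quadrature: per state the
integrand is re-centred at its mode (found by Newton steps — the log
integrand is strictly concave in $b$) and scaled by the curvature there,
with 15 nodes by default and one node giving the Laplace approximation. At
$\sigma_b = 0$ the marginal likelihood reduces exactly to a sum of
independent NB2 terms, which the test suite exploits as an oracle.

All parameters — $\beta_0, \beta_1, \gamma_1, \gamma_2$, the NB2
dispersion $\alpha$ and $\sigma_b$ — are estimated jointly by maximum
likelihood. The optimizer is `nlminb` fed with the exact analytic score of
the quadrature approximation (the dependence of the quadrature centre and
scale on the parameters is differentiated via the implicit-function
theorem) and a Newton model built from score differences; starting values
come from a fixed-effects Poisson fit. The covariance of the fixed effects
is the corresponding block of the inverse observed information at the
optimum. Dispersion and variance parameters are bounded away from overflow
on the log scale; a fit whose optimizer stops with a zero score at a
boundary (typically $\hat\sigma_b \to 0$) is accepted as converged.

## Finding the change points

$\tau_1$ and $\tau_2$ are not assumed known. Following the profile-likelihood
approach for unknown knots, `profile_search()` enumerates every ordered
pair of candidates on a six-month grid anchored at STDM 0 and clipped to
the observed range (35 points and $\binom{35}{2} = 595$ pairs for a
−96..+108 window), refits the full model at each pair — dispersion and
variance re-estimated every time — and keeps the pair with the largest
log-likelihood. Exact ties (within $10^{-6}$) go to the smallest
$\tau_1$, then $\tau_2$. Pairs with no data strictly on both sides of each
knot are recorded as ineligible rather than fitted, since their hinge
coefficients are unidentified. Consecutive fits are warm-started from the
last converged parameter vector; the final inference model is refit from
cold at the winning pair.

A consequence worth stating plainly: intervals from the final fit do not
account for the data-driven choice of $\tau_1, \tau_2$. All outputs label
them *unadjusted for change-point selection*; they are narrower than they
should be, which is also why the cluster bootstrap below exists.

## A worked example

```{r example}
cfg <- sim_config(n_states = 20, stdm_range = c(-36, 36),
                  tau1 = -12, tau2 = 18, seed = 7)
sim <- simulate_surveillance(cfg)
cells <- sim$cells[sim$cells$classification == "incident", ]
scan <- profile_search(cells, enumerate_knot_grid(-36, 36))
scan
summary(scan$fit)
```

```{r plot, fig.width = 6, fig.height = 4}
plot(scan$fit)
```

## The synthetic-data generator

The real national surveillance data (High School RIO) is available only by
request, so every stage is validated against `simulate_surveillance()` and
`simulate_raw_records()`, which generate data from exactly the model above
plus the surrounding record structure. What the generator emulates, with
defaults chosen to look like the study system:

* 49 reporting jurisdictions (two-letter codes), passage years 2009–2014
  with the observed staggering (2, 8, 27, 7, 6, 1 of 51), passage months
  uniform within the year;
* an STDM window of −96..+108 months;
* a baseline rate of 3 events per 10,000 AE — a typical high-school
  concussion rate — with lognormal per-cell AE around 8,000
  (`ae_log_sd = 0.5`);
* NB2 dispersion 0.25 and state random-intercept SD 0.25, both mid-range
  for overdispersed surveillance counts;
* a 9.1% recurrent share, split from total events by binomial thinning
  (which preserves the NB2 dispersion within each classification — the
  incident baseline is shifted by $\log 0.909$, slopes unchanged);
* law-language labels drawn with the marginal frequencies of the published
  51-state classification (27/51 specify the provider; 7/27 physicians
  only; 40/51 educate both parties), that table itself shipping as a
  plain-text fixture with synthetic July-1 passage dates (only passage
  years are public);
* per-field missingness for exclusion-filter testing, with each corrupted
  record flagged so filter counts can be checked against generator truth.

What it does **not** emulate: sport- and sex-specific structure,
within-year seasonality, school-level clustering below the state, media
coverage covariates, or secular reporting drift. Passing recovery tests
therefore demonstrate the estimation machinery is correct under the stated
model, not that the model captures everything in real surveillance data.

The effect sizes have no public reference values, so the recovery harness
fixes a *strong-signal* configuration: 40 states, window −36..+36 (at
least 24 months per trend segment, so each slope is identified), true
knots at (−12, 18), $\beta_1 = 0$, $\gamma_1 = +0.03$,
$\gamma_2 = -0.05$ on the log scale (about +3%/−5% per month). Under these
conditions 200-replicate experiments show essentially unbiased slopes,
the searched change points within one grid step of truth in well over half
of replicates, and near-nominal Wald coverage; the test suite asserts
exactly these properties. A narrower window starves the pre-law segment
and degrades $\tau_1$ identification — a design fact, not an estimator
defect, and the reason the window brackets both knots generously.

## Group comparisons and reports

`compare_slopes()` contrasts a slope change between two independently
fitted models (incident vs recurrent, or two law-language groups) with the
large-sample statistic
$(\hat\gamma_a - \hat\gamma_b)/\sqrt{se_a^2 + se_b^2}$ referred to the
standard normal — coefficient estimates have no natural finite degrees of
freedom. The reported difference is
$100(e^{\hat\gamma_a}-1) - 100(e^{\hat\gamma_b}-1)$ relative to the
declared reference group, with a delta-method interval; this difference is
antisymmetric under swapping the groups, which a ratio-style transform
would not be. Incident-vs-recurrent comparisons treat the two fits as
independent although they share AE denominators; the events are disjoint
and the shared-denominator correlation is ignored as an approximation.

`report_tables()` assembles the 14-model plan (overall + three
dichotomies, each for incident and recurrent events) into two tables: one
row per stratum and change point with percent changes, intervals and
significance at $\alpha = 0.05$; and the between-group differences per
dichotomy with the conventional reference levels (specified,
physicians-only, either). No multiplicity correction is applied across the
14 models.

## Cluster bootstrap

`cluster_bootstrap()` resamples *states* with replacement (duplicated
states are relabelled so each draw is its own cluster) and refits at fixed
change points, or in parametric mode simulates new intercepts and counts
from the fitted model. Beyond standard errors and percentile intervals it
reports the moment skewness of each coefficient's bootstrap distribution
and flags coefficients whose $|$skewness$|$ exceeds a threshold (default
1): with a highly influential state, cluster-bootstrap distributions
become asymmetric and the resulting standard errors untrustworthy — the
flag says so instead of letting them pass silently.

## Numerical choices and edge cases

* Optimizer tolerance $10^{-12}$ relative; refits from five jittered
  starts agree in log-likelihood to $10^{-6}$ on test fixtures, and
  increasing quadrature nodes 15 → 30 moves the log-likelihood by less
  than $10^{-4}$.
* Likelihood evaluation is exactly permutation-invariant: per-state
  contributions are sorted before summation, so reordering cells or
  relabelling states changes nothing, bit for bit.
* Cells with zero AE and zero events are dropped (log-offset undefined)
  with a logged count; zero AE with positive events is an error.
* Exclusion filtering removes a record once however many rules it
  violates, while per-reason counts record every applicable reason — so
  reason counts may legitimately sum to more than the excluded total.
* The academic-year week-1 anchor (first Monday of August) and the
  block→STDM rule (calendar month of the block centre) are conventions,
  configurable at the aggregation layer; surveillance systems do not
  publish a canonical mapping.
* Problem sizes in the shipped experiments (200 replicates for recovery,
  500 null pairs for the size check, 25 replicates in the acceptance
  script) were chosen to keep Monte-Carlo error comfortably below the
  asserted margins.

## Known limitations

Inference after knot selection is optimistic by construction; only the
bootstrap diagnostics hint at how optimistic. The two change points are
fixed in number and restricted to a six-month grid. No random slopes,
serial correlation, or zero-inflation are modelled. The group-comparison
test ignores the shared-denominator correlation between incident and
recurrent fits. And the generator's defaults are a stylized portrait of
one surveillance system — conclusions about real data require the real
data.
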