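---
title: "Modelling unsafe work behavior with sampled observations and a discrete Bayesian network"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling unsafe work behavior with sampled observations and a discrete Bayesian network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sbsbn)
```

## The problem and the model

Behavior-based safety programs must decide which workplace factor to
target first. `sbsbn` supports that decision with three linked pieces
of machinery: a work-sampling design for collecting behavioral
observations, a discrete Bayesian network (BN) relating nine workplace
variables to the binary high-risk unsafe behavior (HRUB) outcome, and a
belief-updating sensitivity analysis that ranks the variables by their
influence on that outcome.

The nine variables and their discrete states are fixed by
`default_scheme()`: age (<30, 30–40, >40 years), experience (<1, 1–5,
>5 years), marital status (yes/no), previous accident (none / minor /
major, "major" meaning at least one lost working day), education
(primary / high school / academic), weekday (first two / middle three /
last two days), time of day (8–11, 11–14, 14–18), safety training (s1 =
1–2 courses, s2 = 3–4, s3 = 5+), and HRUB (no/yes). The joint
distribution factorizes over an expert-elicited DAG
(`default_study_network()`): every factor except age is a direct parent
of HRUB; age acts only through experience and marital status; a
previous accident feeds into training because site policy sends
employees with an accident to more safety courses.

## Sampling design

Work sampling estimates a behavior proportion from instantaneous
observations. With a pilot estimate $p = N_1/N_0$, the campaign size at
standard-normal multiplier $K$ and *relative* accuracy $S$ is

$$ n = \frac{K^2 (1-p)}{S^2\, p}. $$

`required_sample_size()` defaults to this relative-precision form
(with $K = 2$, $S = 0.05$, the conventional values in this literature);
the absolute-precision alternative $K^2 p(1-p)/S^2$ is available via
`method = "absolute"`. Only the relative form is consistent with a
campaign of roughly two thousand observations at $p = 0.45$; the
absolute form would require only a few hundred. The function reports
the unrounded value, its ceiling, and a nearest-ten presentation
figure.

Observation schedules (`build_schedule()`) must cover the whole working
week. Independent uniform draws cannot *guarantee* coverage at
realistic sizes (at $n$ equal to twice the number of weekday-hour
cells, missing some cell is near-certain), so the schedule is built by
repeatedly shuffling the complete weekday-by-hour grid and attaching a
uniform random minute — a stratified randomization that is marginally
uniform, standard in work-sampling practice, and covers every cell once
$n$ reaches the grid size.

## Exact inference

Posteriors are computed by variable elimination over the CPT factors
with a min-degree elimination ordering; with nine nodes this is always
exact and instantaneous. Probabilities are kept in linear space (the
scale of a nine-node network makes underflow a non-issue; dataset
log-likelihoods are accumulated in log space). Evidence whose marginal
probability is zero raises an error rather than returning NaN — a loud
signal of data/model mismatch. Querying an evidenced variable returns a
point mass, matching the belief-updating convention of BN tools. A
brute-force full-enumeration oracle, written independently in the test
helpers, verifies the engine on one hundred random networks per test
run.

## EM parameter estimation

`bn_fit()` estimates every CPT from records that may have missing
cells. Records are aggregated into unique rows; for each partially
observed row the E-step enumerates the completions of its missing
variables, weights them by their exact joint probability under the
current parameters (this is exact inference, just organized around the
row), and accumulates expected counts for every node family. The
M-step normalizes each expected-count row. The log-likelihood is
evaluated after each M-step; the trace is non-decreasing (a property
asserted on every test run) and iteration stops when its relative
change drops below `tol` (default `1e-6`) or at `max_iter` (default
500). With complete data the first M-step already lands on the
maximum-likelihood frequencies and the fit converges in two
iterations. Initialization is uniform by default (`init = "random"`
with a seed gives seeded Dirichlet rows), and identical data plus
identical configuration yields bit-identical results.

### Smoothing and sparse CPTs: a deliberate choice

The outcome node has seven parents, hence $3^5 \times 2 \times 3 =
1{,}458$ parent configurations — compared with about 1,960 records in a
realistic campaign. Two standard conventions behave badly at this
sparsity, and the package departs from them deliberately:

* **Laplace smoothing (+1 per cell)** shrinks every row toward uniform
  with weight $2/(n_{\text{row}}+2)$; at ~1.3 records per row that is a
  60 % pull toward 0.5, which would inflate a fitted outcome marginal
  of 0.25 to roughly 0.40. The default is therefore `pseudocount = 0`;
  any non-negative value remains available and small values (or
  BDeu-style tiny fractions) are harmless.
* **Uniform fill for never-observed configurations** biases the fitted
  outcome marginal upward by (unobserved parent mass) × (0.5 − true
  rate), several percentage points here. The default `empty_row =
  "pooled"` instead fills such rows with the node's conditional
  distribution aggregated over all configurations — a back-off estimate
  that carries no likelihood information either, but preserves the
  fitted marginals. `empty_row = "uniform"` is available for
  comparison.

With these defaults, EM fitted to a complete synthetic campaign of
1,960 records recovers the generating HRUB marginal to well within two
percentage points (binomial sampling noise at that size has a standard
deviation of about one point).

## Sensitivity analysis

For predictor $X$ with state $s$ and target rate $b = P(\mathrm{HRUB} =
\mathrm{yes})$, the variation statistic is the relative percent change

$$ V_s = 100\,\frac{P(\mathrm{HRUB}=\mathrm{yes}\mid X=s) - b}{b}, $$

computed with evidence on the single variable only (no mediators are
clamped, so age's influence flows through experience and marital
status). Variables are ranked by the mean of $|V_s|$; ties are broken
by mutual information

$$ I(X;T) = \sum_{x,t} P(x,t)\,\log_2 \frac{P(x,t)}{P(x)P(t)}, $$

then alphabetically — a deterministic convention. MI is reported in
bits by default (`base` is configurable; the reference analyses do not
state their base). `sensitivity_report()` also returns the per-state
conditional outcome probabilities, the table a practitioner would read
off as "the HRUB rate among the most-trained employees".

The mean-absolute-variation ranking and the pure-MI ranking usually
agree near the top but need not coincide everywhere; the report carries
both columns so their agreement can be inspected rather than assumed.

## The synthetic ground truth

Field observation records of this kind are not published, so the
package ships `ground_truth_network()`, a fully parameterized network
on the study structure used for simulation and for validating the
estimation machinery. It is calibrated so that these exact equalities
hold (to 1e-9, asserted in the tests):
P(HRUB=yes) = 0.248, P(married) = 0.736, P(major accident) = 0.0411,
P(high school) = 0.595, and P(HRUB=yes | Training=s3) = 0.123.

The outcome CPT follows an additive logistic model: each parent state
contributes a fixed log-odds effect, chosen once so that training is by
far the strongest driver and the signs follow the field's qualitative
findings (inexperience, being unmarried, a previous major accident,
primary education, end-of-week days and afternoon hours all raise the
rate); the intercept and the training-s3 effect are then solved by
nested root finding so the two outcome calibration targets hold
exactly. The solve is deterministic, takes milliseconds, and is cached
per session — shipping a solved fixture file would only add a copy that
could drift from the code. Distributions not pinned by any reported
figure (age 30/45/25 %, experience and training responses, weekday
28/50/22 %, daytime 35/33/32 %) are fixed plausible values consistent
with the qualitative description of the site (most workers aged 30–40
with >5 years' experience, about half of observations midweek); they
are synthetic and labelled as such.

`sample_observations()` draws records by ancestral sampling in
topological order and masks cells independently (MCAR) at a requested
rate; field missingness mechanisms (e.g. observers systematically
failing to record education) are *not* emulated. Consequently the
passing tests demonstrate correctness of the machinery and
recoverability under the stated conditions — not robustness to
informative missingness, observer effects, or within-employee
correlation (repeated observations of one employee are treated as
independent records, as in the sampling design itself).

## Numerical conventions and edge cases

* Discretization bins are half-open and lower-inclusive ([30, 40) for
  age 30–40), the final finite edge inclusive (an 18:00 stamp is still
  the afternoon window); "above 5 years" experience is treated as
  [5, ∞). Out-of-domain raw values are errors naming the variable.
* State labels match case-insensitively after trimming; missing cells
  are represented as absent values (CSV: empty or `NA`), never as a
  sentinel state.
* CPT rows must sum to 1 within 1e-9 (`validate_network()`); serialized
  row order is lexicographic in declared parent order with the first
  parent most significant, documented in `parent_configs()` so JSON
  and XMLBIF files are bit-stable.
* All randomness flows through a seed argument and restores the
  caller's RNG state; pipeline reruns with one configuration are
  byte-identical (for that reason the run log carries parameters and
  input checksums but no wall-clock timestamps).

## Problem sizes used in the test suite

The suite exercises inference against the enumeration oracle on 100
random networks of up to 6 nodes, EM recovery on a 3-node network at
n = 5,000 with 20 % MCAR (every CPT entry within 0.05 of truth), full
nine-variable recovery at n = 10,000 complete (every marginal within
0.02), sampling calibration at n = 50,000 (3-sigma binomial bands),
and end-to-end campaigns of n = 1,960 — the scale the design formula
itself prescribes. These sizes give comfortable statistical margins
for the assertions while keeping a full test run around half a minute.

## Known limitations

* No structure learning: the DAG is fixed by domain expertise, by
  design; with ~2,000 records structure learning would be fragile.
* Conditioning is observational, not causal do-calculus; "variation"
  quantifies belief updating, not intervention effects, and mediated
  correlations (accident → training) can mask direct effects in the
  report.
* No approximate inference, continuous nodes, or decision/utility
  nodes; the implementation targets small expert-built networks.
* Published variation and MI magnitudes from the original site depend
  on that site's unpublished fitted CPTs; the synthetic ground truth
  emulates their direction and ranking behavior, not their exact
  values.
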