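---
title: "Modelling the risks of prehospital D-positive transfusion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the risks of prehospital D-positive transfusion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dposrisk)
```

## The problem

Bleeding trauma patients transfused before hospital arrival receive blood
of unknown compatibility. Issuing D-positive red cells or low-titre group
O whole blood (LTOWB) instead of scarce D-negative units eases supply, but
exposes D-negative recipients to three harms: a haemolytic transfusion
reaction (HTR) at the index transfusion if the patient already carries
anti-D; an HTR at a future transfusion after new D-alloimmunization; and,
for females of childbearing potential (CBP), haemolytic disease of the
foetus and newborn (HDFN) in a future pregnancy. `dposrisk` implements a
quantitative risk model for such a policy change: each harm requires an
ordered chain of contingent events, so its per-transfusion probability is
the product of the conditional probabilities of those events.

## The event-chain model

For harm $h$ with chain $X_1, \dots, X_k$ and conditional probabilities
$p_1, \dots, p_k$ (each "event occurs given all upstream events"),

$$P(h) \;=\; \prod_{j=1}^{k} p_j,$$

and the probability of *any* harm is taken as the capped sum
$\min(1, \sum_h P(h))$. We use the additive rather than the exact union
form $1 - \prod_h (1 - P(h))$ because at the small probabilities this
model operates in ($10^{-5}$ to $10^{-3}$ per transfusion) the two agree
to within $10^{-5}$ absolute, and the additive form is the one whose
reciprocal-sum reproduces published "any harm" summary rows from the
per-harm rows at 2-significant-figure display precision. The exact union
remains available via `combined_risk(..., method = "union")`.

The default model has 14 events. Three chains share a prefix — the
recipient must be D-negative (X1) and survive the index event (X2) — and
the two delayed harms additionally share the alloimmunization event (X6):

* index HTR: X1, X2, pre-existing anti-D, HTR occurs, major morbidity;
* future HTR: X1, X2, X6, future transfusion, D-positive exposure, HTR,
  major morbidity;
* HDFN: X1, X2, X6, female of CBP, future pregnancy, D-positive foetus,
  death or lifelong disability.

Two recipient populations are modelled from one chain definition. The
all-recipient population uses every event as configured; the D-negative
female CBP subgroup *overrides* the D-negative (X1) and female-CBP (X11)
events with point masses at 1, since membership in the subgroup makes
those certain. Overrides were chosen over duplicated configurations so
both populations provably share one model.

## Inputs as probability distributions

Uncertainty about each conditional probability $N_i$ is expressed as a
bounded distribution: `point`, `uniform`, `triangular`, `beta` or
`log_uniform` (uniform in $\log p$ — appropriate when only the order of
magnitude of a rare event is known). All chain inputs are probabilities,
so supports are restricted to $[0, 1]$ and validated at load time with
errors naming the offending input and parameter.

The shipped configuration (`default_config()`) carries **placeholder**
uniform bands around plausible values; every `source_note` marks them as
such. The published input distributions for this model live in
supplementary material that this package deliberately does not transcribe;
to reproduce a published risk table, copy each of the 14 input
distributions into the YAML config over the placeholders and re-run —
the 1000-iteration model completes in well under a second. Quantities
that do not depend on those inputs (the combination arithmetic, the
population scaling, the years-to-event table) are reproduced exactly by
the package as shipped.

## Monte Carlo propagation

`run_simulation()` draws one value per input per iteration (default 1000
iterations, configurable), evaluates every chain, and summarises each harm
by the mean of its probability samples and an equal-tailed credibility
interval — empirical quantiles at $(1-\gamma)/2$ and $1-(1-\gamma)/2$
with linear interpolation between order statistics (`quantile()` type 7).
Results are also expressed in reciprocal form, "one event per $N$
transfusions": the point estimate is the reciprocal **of the mean
probability**, not the mean of reciprocals (the mean is computed on the
probability scale, then transformed), and the reciprocal interval is the
reciprocated quantile pair, sorted ascending.

Three reproducibility choices matter:

* **Per-input substreams.** Each input draws from its own RNG substream
  seeded deterministically from (root seed, input id). Adding, removing or
  re-typing one input never perturbs any other input's draws — verified by
  a regression test that changes one input's family and checks another's
  draws bit-for-bit.
* **Shared draws.** Events referencing the same input share its draws
  within an iteration; population overrides draw from their own stream.
* **Exact degeneracy.** With all inputs point masses every sample equals
  the analytic chain product bit-exactly (both sides multiply
  sequentially in double precision), which makes the analytic engine a
  true oracle for the stochastic one.

Default iterations are 1000 — convergence tests in the suite use $10^5$
for tighter tolerances (the Monte Carlo mean must fall within 4 standard
errors of the product of input means, which is the exact mean under input
independence; inputs are sampled independently because no correlation
structure is specified for them).

## Population and time scaling

Annual prehospital transfusion episodes are
`incidence_per_million × population / 10^6 × subgroup_fraction`; with the
configured 83 per million per year and a population of 67 million this
gives 5561 per year for all recipients. The subgroup's annual count is
controlled by `subgroup_fraction`, set to 0.01798 so the D-negative
female CBP subgroup sees ≈100 episodes per year, the scale used in
national projections; its derivation from demographic data is outside the
model, hence configuration rather than computation. Years to the first
expected event are `reciprocal risk / annual count`, applied to the mean
and to both interval endpoints (a monotone transform). Display tables
round to 2 significant figures; raw values are always retained.

A mixed issuing policy (`apply_policy_mix()`) scales every harm
probability linearly by the fraction of episodes using D-positive units —
a 50:50 mix halves each risk. Unit counts within an episode are not
modelled; there is no unit-level structure in the model.

## Life-years break-even

For the subgroup, the benefit of earlier/whole-blood transfusion is
weighed against HDFN: each HDFN death or lifelong disability is equated
to 83 undiscounted life-years lost (life expectancy at birth). For each
of 10,000 bootstrap replicates, an HDFN probability is resampled from the
Monte Carlo output and a survivor life-years value is drawn from a
configurable distribution (years gained per life saved; the shipped
uniform(30, 50) is a placeholder, *not* a published survival model). A
survival benefit of $s$ percent gains $s/100 \times$ survivor life-years
per transfused patient and loses HDFN probability $\times$ 83 years; the
break-even benefit is the smallest grid value at which gains meet or
exceed losses in 95% of replicates. Ties count as break-even
(`gained >= lost`), so a zero HDFN risk breaks even at 0% — with
continuous inputs the tie set has measure zero and the choice is
inconsequential otherwise. Degenerate (point-mass) inputs reproduce the
closed-form break-even $s^\* = 100\,p\,\cdot 83 / L$ exactly, which the
tests exploit.

## Sensitivity analysis

The first-order Sobol index
$S_i = \mathrm{Var}(E[Y \mid N_i]) / \mathrm{Var}(Y)$ is the expected
proportional reduction in output variance if input $N_i$ were known
exactly. `sobol_first_order()` implements the pick-freeze (Saltelli)
estimator — two $n \times k$ matrices plus one re-evaluation per input,
$n(k+2)$ model calls, default $n = 2^{13}$ for configured models and
$2^{14}$ for toy models — chosen over the double-loop conditional-variance
estimator for efficiency; the double loop is retained in the test helpers
as an independent oracle and the two agree within replication noise on
two-input models. Estimator noise can make indices slightly negative;
raw values are reported alongside a zero-clipped column for display.
If the output variance is zero all indices are defined as 0, with a
warning. `scatter_pairs()` exports (input draw, output draw) pairs using
exactly the simulation's substreams, so scatterplots describe the run
actually performed.

## Synthetic scenarios

`generate_scenario()` emits random chain configurations with closed-form
ground truth: every input's mean and variance, and each harm's analytic
mean (product of means) and variance (product of second moments minus
squared product of means) are recorded. Scales are anchored to the
$10^{-5}$–$10^{-3}$ per-transfusion regime so tests exercise the
small-probability floating-point range the real model lives in.
`study_shaped_scenario()` reproduces the full structural shape — 14
events, 3 harms with shared prefixes, 2 populations with subgroup
overrides — with all-recipient reciprocal risks near $3\times10^4$,
$9\times10^5$ and $3\times10^4$.

What the generator does *not* emulate: the actual published input values
(out of scope by design), correlation between inputs, multiple events in
one chain sharing an input, or within-episode transfusion structure.
Passing recovery tests therefore demonstrate correctness of the
*machinery* — sampling, propagation, summarisation — not the clinical
accuracy of any particular input set.

## Numerical and testing choices

* Chain products are sequential double-precision multiplications in both
  the analytic and stochastic engines, so the point-mass oracle holds
  bit-exactly.
* Configurations serialize to YAML with doubles emitted at 17 significant
  digits, making `load_config(write_config(cfg))` an exact round trip.
* Test problem sizes: $10^5$ iterations for convergence checks, 20
  synthetic scenarios for parameter recovery (pass criterion ≥ 19 of 20
  within 4 SE), $n = 4096$ pick-freeze matrices with 8–10 replications
  for sensitivity, 1000–10,000 bootstrap replicates. The full suite runs
  in seconds on one core.

## Limitations

The model excludes hyperhaemolysis and ABO incompatibility, correlation
between harms beyond shared chain prefixes, discounting of life-years,
demographic projection of trauma incidence, and any variance-reduction or
Bayesian updating of inputs. The shipped input bands are placeholders:
absolute risk numbers produced from the default configuration illustrate
the pipeline and must not be quoted as clinical estimates. Published
headline values that depend on the supplementary input distributions
(per-harm means and intervals, the 1.0% break-even benefit) are
reproducible only after transcribing those inputs; the internal
consistency of the published summary tables, by contrast, is reproduced
exactly by the shipped arithmetic.
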