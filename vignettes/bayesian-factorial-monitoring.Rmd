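---
title: "Bayesian interim monitoring of a 2x2 factorial trial"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bayesian interim monitoring of a 2x2 factorial trial}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bayesfactorial)
```

## The problem

A monitoring committee looking at interim data from a factorial trial needs
an answer on a clinical scale: how likely is it, given everything known so
far, that an arm confers a meaningful benefit — or a meaningful harm? This
package provides that machinery for 2×2 factorial designs with a binary
outcome, built around the interim reanalysis of the Optimizing Cooling
Trial, a neonatal hypothermia trial (standard whole-body cooling at
33.5 °C for 72 h versus deeper cooling to 32.0 °C, longer cooling for
120 h, or both) monitored on predischarge mortality.

## Model and assumptions

With depth and duration coded 1 for the experimental levels, the outcome
model is Bernoulli with a log link,

$$\log(p_i) = \beta_0 + \beta_1\,\mathrm{depth}_i +
  \beta_2\,\mathrm{duration}_i +
  \beta_3\,\mathrm{depth}_i \times \mathrm{duration}_i,$$

so $\beta_0$ is the log baseline risk and the coefficients are log relative
risks: $e^{\beta_1}$, $e^{\beta_2}$, $e^{\beta_1+\beta_2+\beta_3}$ for the
three experimental arms versus standard care, and
$e^{\beta_1+\beta_3/2}$, $e^{\beta_2+\beta_3/2}$ for the two marginal
(factor-level) comparisons. The log link requires every cell probability
to stay below 1; the posterior is restricted to that region. Risk
differences are derived per draw from the cell probabilities as
$p_\text{control} - p_\text{treatment}$ (positive favors treatment).
The model assumes independent outcomes, equal-probability cells within
arm (no covariates — the reanalysis deliberately omits center and disease
severity), and a constant risk over the enrollment period.

**Marginal risk difference.** There is no unique "marginal RD" in a
factorial design. We use the equal-weight average of the two cell risks at
each factor level, consistent with the $\beta_3/2$ equal-weight convention
for the marginal log RR. With balanced randomization this is nearly
identical to the observed-allocation weighting; both are computed from the
same cell probabilities and users can derive alternatives from the stored
draws.

## Priors

All four coefficients get independent normal priors. The shipped sets:

| set | $\mu_0$ | $\tau_0$ | $\mu_1=\mu_2$ | $\tau_1=\tau_2$ | $\mu_3$ | $\tau_3$ |
|---|---|---|---|---|---|---|
| neutral | $\log 0.19 = -1.66$ | 0.565 | 0 | 0.565 | 0 | 0.14 |
| enthusiastic | $-1.66$ | 0.565 | $\log 0.85 = -0.1625$ | 0.565 | 0 | 0.14 |
| flat_intercept | 0 | 10 | 0 | 0.565 | 0 | 0.14 |

The intercept center is the 19% control-group predischarge mortality of the
preceding multicenter cooling trial with the same eligibility criteria; its
SD triples the historical log-scale uncertainty (0.19) to allow for drift
between study populations. The effect SD 0.565 corresponds to a 95% prior
CrI of roughly 0.33–3.0 around RR 1 — wide enough to admit large harm or
benefit while down-weighting the implausibly extreme effects rarely seen in
neonatal trials. Two construction routes are exposed for custom elicitation
(`effect_prior_from_cri()` gives $\ln 3 / 1.96 = 0.5605$;
`intercept_prior()` gives $0.19\times3 = 0.57$); the presets pin the
canonical 0.565 so the shipped analysis is reproduced exactly.

The interaction SD comes from `interaction_sd(prob, threshold_rr)`
$= \log(\text{threshold})/\Phi^{-1}(\text{prob})$: $\tau_3 = 0.14$ says
that, with both main effects null, a direction-reversing ("qualitative")
interaction as large as RR 0.76 has prior probability only 0.025. The
sensitivity value 0.408 (probability 0.25) leaves the stopping conclusions
unchanged. Note $\tau_3$ *grows* with the allotted probability.

The `flat_intercept` set is the sensitivity analysis that ignores the
historical control rate. This requires a genuinely vague intercept (SD 10
at mean 0): an *informative* zero-mean prior would instead drag the
baseline risk upward (toward $e^0$) and shrink every RR toward or past 1 —
the opposite of ignoring the historical evidence. With the vague intercept
the baseline follows the unusually low observed control rate (7/95), the
arm RRs move away from 1, and all three experimental arms cross the RR
futility threshold.

A skeptical set (centered at harm) is not shipped because its parameters
were never specified for this trial; `prior_spec("custom", ...)` covers it.

## Sampling and numerical choices

The posterior has no closed form. `fit_trial()` runs univariate slice
sampling with stepping out (Neal 2003), one coordinate sweep per iteration,
implemented in C++. Slice sampling was chosen over random-walk Metropolis
because it is tuning-free and its per-coordinate adaptivity copes with the
very different conditional scales of $\beta_0$ (data-dominated) and
$\beta_3$ (prior-dominated). Details that matter:

* **Support constraint.** Any state implying a cell probability $\ge 1$
  has $-\infty$ log posterior; the slice procedure never accepts it. All
  stored draws satisfy the constraint (asserted exhaustively in tests).
* **Step width** 1.0 on the log scale, shrunk to $6\tau_k$ for
  near-degenerate priors so stepping out stays proportionate; maximum 50
  step-out moves.
* **Initialization.** Each chain starts at the prior mean, with the
  intercept pulled down if needed to satisfy the constraint, plus a
  jitter of 0.1 SD (halved until admissible). The posterior is unimodal in
  practice, and split-$\hat R$ guards against undetected multimodality.
* **Defaults.** 3 chains × 40,000 kept iterations after 4,000 burn-in —
  the configuration of the shipped reanalysis (about a second of CPU for
  this 4-parameter model). `mcmc_config_sim()` (3 × 4,000 after 1,000) is
  for operating-characteristics runs, where thousands of fits are needed
  and per-fit Monte Carlo error averages out across replicates.
* **Diagnostics.** Split-chain Gelman–Rubin $\hat R$ per coefficient plus
  an autocorrelation-based effective sample size. Exceeding `rhat_limit`
  (default 1.01) warns rather than errors: an interim analysis should
  surface, not hide, a shaky fit. On the shipped data $\hat R < 1.001$.
* **Seeding.** One user seed drives all chains through R's RNG, so fits,
  reports and simulations are exactly reproducible; acceptance-style
  checks assert within-tolerance (never bitwise) agreement.
* **Ties and NNT.** Threshold probabilities use strict inequalities; draws
  exactly at a cutoff are reported separately (a measure-zero concern for
  continuous draws). NNT summaries drop draws with $|RD| < 10^{-12}$ and
  report how many were dropped.

Correctness is established against independent oracles rather than a
second MCMC package: collapsed 1-D and 2-D versions of the model (point-mass
priors on the remaining coefficients) are compared with dense grid
quadrature, and a no-data fit is compared with rejection sampling from the
support-truncated prior. The truncation matters: the constraint removes
about 2% of prior mass for sums like $\beta_0+\beta_1$, shifting prior
means by more than Monte Carlo error, so the *truncated* prior is the
correct reference.

## Stopping rules

Rules pair a clinically meaningful effect with a probability threshold
(presets in `rule_presets()`):

* futility: $\Pr(\mathrm{RR} < 0.90) < 0.10$, or
  $\Pr(\mathrm{RD} > 0.01) < 0.10$;
* safety: $\Pr(\mathrm{RD} < -0.05) > 0.50$;
* efficacy: $\Pr(\mathrm{RR} < 0.85) > 0.99$.

The asymmetry is deliberate: less evidence is demanded to stop for harm
than to claim benefit. `monitoring_report()` evaluates every rule against
every comparison and flags whether *all three* experimental arms are
futile — the condition for stopping the whole trial rather than one arm.
Whether the per-arm or the marginal comparisons should govern that verdict
is a design decision the report leaves to the committee: both are shown.
The efficacy rule is included for completeness even though the shipped
interim data never approach it.

## The trial simulator

`simulate_trial()` generates per-subject enrollment under scenario-true
cell probabilities: permuted-block randomization (block size 4, one subject
per arm per block) and Bernoulli outcomes. `run_interim_sequence()` replays
the interim schedule (default: first look at 50 subjects, then every 25, to
a planned 726) refitting the posterior at each look;
`operating_characteristics()` estimates per-rule trigger frequencies,
expected stopping sample size, and binomial MCSEs across replicates. Under
an all-null scenario the efficacy-trigger frequency estimates type I error;
under an effect scenario, power. No pass/fail thresholds are baked in — the
simulator reports estimates for the designer to judge.

What the generator emulates and what it does not: it reproduces the
factorial structure, block-balanced allocation, sequential looks and
Bernoulli outcomes, but not stratified randomization (the real trial
stratified by center and severity), enrollment-time drift, dropout or
missing outcomes. Simulated stopping is all-arms-futile or efficacy; a
safety trigger is recorded but stops only the arm, matching a plan that
would continue the remaining groups. Passing simulator-based tests
therefore says the *method* behaves as designed under clean conditions,
not that a real trial's messier data would behave identically.

Test and example problem sizes (hundreds of replicates, reduced MCMC,
n ≤ 20,000 subjects) were chosen so the whole suite runs in well under a
minute on one core; parameter-recovery checks use 100 replicates at 5,000
subjects per arm, where the 95% CrIs cover the generating coefficients at
their nominal rate.

## Known limitations

* Aggregated counts are sufficient for this model; per-subject covariates
  (center, severity) are out of scope, so the fitted RRs are unadjusted —
  by design, they differ from covariate-adjusted frequentist estimates.
* Normal priors only; heavier-tailed robust priors would need the custom
  hook and a corresponding sampler check.
* The marginal RD definition is a convention (see above); alternatives are
  derivable from the draws but not built in.
* The simulator's MCMC-in-the-loop makes very large operating-characteristic
  studies (tens of thousands of replicates) CPU-bound; the reduced
  configuration trades per-fit precision for throughput.
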