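---
title: "Cognitive effort discounting: models, simulation and design analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cognitive effort discounting: models, simulation and design analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's own account of the science it implements: the
cognitive-effort-discounting (COG-ED) task and its staircase arithmetic, the
subjective-value scale, the mixed models and Bayesian correlation machinery
behind the three-stage test of domain-general cognitive motivation, the
sequential Bayes-factor design analysis, and the synthetic cohorts everything
is exercised on. It also records the numerical and design choices that were
genuinely open, and what the passing tests do and do not establish about real
data.

## The task and the staircase

In the COG-ED decision phase a participant repeatedly chooses between
repeating an easy baseline task (1-back, or listening at 0 dB SNR) and a
harder level of the same task (2/3/4-back; −4/−8/−12 dB SNR) for money. Each
of the 9 cells (3 load levels × base offers of \$2, \$3, \$4) opens with both
options at the base amount. Whichever option is chosen first becomes the
*titrated* side: after the choice on trial $k$ the titrated offer moves by
$\mathrm{base}/2^k$ — down if the titrated option was just chosen, up
otherwise — while the fixed side stays at the base amount. With 5 choices per
cell (4 adjustments) the titrated offer after the final adjustment is the
*indifference point*, and the total trial count is $3 \times 3 \times 5 = 45$
per domain.

Two readings of "5 calibration trials" circulate: 5 choices including the
equal-offer trial (4 adjustments, consistent with the printed 45-trial
total), or 5 adjustments after it (which would give 54 trials). The package
defaults to the first and exposes `n_trials_per_cell` for the other. Under
the default, a deterministic agent with threshold $v \in (0,1)$ ends within
$\mathrm{base}/2^4$ of its true indifference value — the staircase is a
binary search — and the tests verify this against exhaustive enumeration of
all choice paths on a 0.01 grid of thresholds. Ties at exact indifference go
to the easy option, so effort seeking is never overstated. All offers are
dyadic rationals (multiples of $\mathrm{base}/2^4$), which binary doubles
represent exactly; the CSV layer serialises them with four decimals so a
written log replays bit-identically.

## The subjective-value scale

Indifference points are mapped to subjective value (SV) exactly as
discounting studies report them: participants who first chose the easy
option get $SV = \mathrm{ip}/\mathrm{base} \in [0,1]$; participants who
first chose the hard option get $SV = 1 + (\mathrm{base} -
\mathrm{ip})/\mathrm{base} \in [1,2]$. Both branches give 1 at
$\mathrm{ip} = \mathrm{base}$, and values above 1 mark *effort seekers* who
prefer the harder task at equal pay. A participant × domain score is the
mean over the 9 cells, and a complete grid is required — missing cells are
an error, never imputed.

One subtlety is worth recording. A simulated agent whose utility for the
hard option is $v \cdot \mathrm{offer}$ titrates, when it prefers the hard
task ($v > 1$), to $\mathrm{ip} = \mathrm{base}/v$; the standard transform
then recovers $2 - 1/v$, not $v$. For ground-truth recovery to be exact on
both branches the simulator's agents use the indifference-consistent mirror
rule above 1: the gap is $v \cdot \mathrm{offer}_{hi} - \mathrm{offer}_{lo}$
for $v \le 1$ and $\mathrm{offer}_{hi} - (2 - v)\,\mathrm{offer}_{lo}$ for
$v > 1$, so the agent's indifference point sits exactly where the scoring
transform inverts to $v$. `choice_policy()` retains the plain logistic form
for the exported primitive; the mirror rule lives in the cohort simulator
and the deterministic `threshold_chooser()`.

## Synthetic cohorts

`generate_cohort()` draws, per participant, a standard-normal
domain-general motivation latent $g$ and two domain latents
$u_d = \sqrt{|\rho|}\, g + \sqrt{1 - |\rho|}\, e_d$ whose correlation is the
configured `rho_domains`. True SV in domain $d$ at load $\ell$ is

$$ SV_d(\ell) = \mathrm{clip}_{[0,1]}\!\big(\alpha_d - \beta_d(\ell - 1) +
\sigma_s u_d + w\,\Delta\mathrm{perf}_{d,\ell}\big), $$

with defaults $\alpha = (0.78, 0.80)$, $\beta = (0.09, 0.19)$ per level
(the published working-memory and speech load effects), subject SD
$\sigma_s = 0.20$, and a weight $w = 0.3$ on the participant's load-specific
performance deviation, so task performance genuinely shapes value (the
pathway the residualisation stage is meant to remove). Participants in the
top `p_effort_seeker` quantile of $u_d$ (default 5/104) continue above the
ceiling with slope `seeker_scale`·$\sigma_s$: a *continuous* tail map rather
than a shifted mixture component. Two designs were tried and rejected: an
independent Bernoulli seeker indicator shared across domains injects ~0.27
of spurious cross-domain correlation even at $\rho = 0$, and a
discontinuous intercept shift attenuates $\rho = 0.5$ to ≈ 0.44; the
continuous monotone map keeps the realized correlation of true mean SV
within ±0.05 of the target at every $\rho$ tested (0, 0.3, 0.5; n = 4000).

Around the value model the generator emulates the study's measured
quantities: logistic load/capacity models for N-back hit and
correct-rejection rates, linear RT growth, a logistic SNR curve for speech
intelligibility (≈ 0.94/0.80/0.52/0.23 at 0/−4/−8/−12 dB), workload ratings
on the 1–21 scale with load slopes near the published 3.7/2.5/1.0, span and
questionnaire totals loading on weakly SV-correlated capacity and
reward-sensitivity factors, and headphone/completion exclusion flags at the
study's rates (10/132 and 18/132). Choices come from a softmax agent with
temperature 0.10 in currency units and cell-level value noise of SD 0.10 —
values at which score-level recovery keeps 95% credible intervals covering
the generating $\rho$ in ≥ 90% of cohorts, chosen once while building the
generator. Randomness is organised as per-participant substreams derived by
counter from the root seed, so participant $i$ is bit-identical in cohorts
of any size.

What the generator does *not* emulate: item-level questionnaire responses,
real speech materials or audio, session order effects, and — deliberately —
the missingness mechanism (incomplete participants carry complete simulated
tables plus a flag, because the exclusion logic operates on metadata).
Passing recovery tests therefore show the *pipeline arithmetic* is sound
under the assumed generative structure, not that real discounting data obey
that structure.

## Mixed models and residualisation

The discounting and rating analyses the package mirrors were originally run
as flat-prior Bayesian multilevel models and described by their authors as
equivalent to maximum likelihood. The package takes that equivalence at
face value: `fit_effort_model()` is a REML random-intercept model (lme4)
with numeric 0/1/2 load coding, Gaussian 95% intervals, and a
Nakagawa-style conditional $R^2$ in $[0,1]$. With one observation per
participant it degenerates to OLS (verified against `lm` to 1e−6), and a
simulated zero trait variance lands on the OLS solution with a boundary
variance estimate.

For the second analysis stage, `residualize_domain()` regresses cell-level
SV on load plus the domain-appropriate performance covariates (hit rate,
correct-rejection rate, mean RT for working memory; intelligibility for
speech) and averages each participant's residuals *from the fixed-effect
prediction only*. The random intercept is deliberately not subtracted:
participant-level intercepts are exactly the trait variance the
cross-domain correlation is supposed to measure, and subtracting them would
leave residual means of numerical zero — the published pattern (the
correlation surviving, even rising slightly, after covariate control) is
only arithmetically possible under the fixed-effects-only reading. The
alternative is exposed as `subtract_random_intercept = TRUE` for anyone who
wants to see it collapse.

## Bayesian correlation machinery

`bayes_correlation()` computes the posterior of $\rho$ by integrating the
exact reduced likelihood of the sample correlation — the hypergeometric
sampling density of $r$, evaluated through a Gauss series for
$_2F_1(\tfrac12, \tfrac12; n - \tfrac12; z)$ — against the prior on an
equispaced grid (4001 points; results stable to ~1e−4), and the Bayes
factor against $\rho = 0$ as the Savage–Dickey ratio, which on the
likelihood's normalisation reduces to the prior-weighted marginal
likelihood. The default prior is the stretched beta with width 1/3
("medium", the convention for estimation-grade correlation tests); a
truncated, renormalised Cauchy(0, √2/2) is provided because
effort-discounting papers describe their prior that way, even though a
Cauchy is the *t*-test default and not a proper correlation prior without
truncation. The tests pin the implementation to an independent quadrature
oracle (Euler-integral $_2F_1$, adaptive integration) within 1%, and to
externally computed reference values of the exact correlation Bayes factor.

`bayes_partial_correlation()` residualises both variables on the covariates
by least squares and runs the same machinery with effective sample size
$n - k$, matching classical partial-correlation sampling theory.
`paired_t_bf()` is the one-sample JZS test on within-participant
differences: Cauchy(0, √2/2) on the standardised effect, marginal
likelihood by adaptive quadrature over the non-central *t* density, also
pinned to external reference values.

## Sequential design analysis

`simulate_sequential()` reruns the study's power analysis: bivariate-normal
streams at a generating $\rho$, the correlation Bayes factor recomputed at
each look over the accumulating sample (data grow, never regenerate), and
stopping at BF10 ≥ 10, BF10 ≤ 0.1, or the 300-participant cap. The
`"registered"` preset is the schedule the study preregistered — first look
at 100 participants, then every 10 — and the `"fine"` preset looks after
every participant from n = 20.

The design module's default prior is the *uniform* stretched beta
(width 1), and that choice is forced by arithmetic rather than taste: under
the medium prior the correlation Bayes factor at $r = 0$, $n = 300$ bottoms
out at 0.135, and under the truncated Cauchy at 0.106 — the null boundary
of 0.1 is unreachable within the study's maximum sample under either, so a
design analysis run with them could never deliver the null-evidence
stopping times the design promises. Width 1 is the only conventional width
for which both boundaries are live (floor ≈ 0.072 at n = 300).

Reproducing the study's printed planning medians (112 to reach the upper
boundary under $\rho = 0.3$; 140 to reach the lower under $\rho = 0$) turns
out not to be possible from the described ingredients: across every
documented prior and schedule combination we simulated, the upper-boundary
median ranges from 66 (medium prior, fine looks) through 75 (uniform, fine)
to 100 (any prior, registered schedule — the first look caps the median
because more than half of replicates already exceed BF 10 at n = 100), and
the lower-boundary median sits near 180–190 two-sided. The package reports
what its engine actually produces under the registered preset — medians of
100 and 190 at 1000 replicates — and the acceptance checks record the
discrepancy rather than papering over it. The simulation scale (1000
replicates rather than 10,000) is the package's desk-scale default; the
medians shift by at most a look-step between scales.

## Numerical choices and degenerate inputs

Posterior summaries (median, central 95% interval) come from the normalised
grid posterior without interpolation; grid resolution bounds the error at
half a grid step (~5e−4). The $_2F_1$ series is summed to a relative 1e−14
with the large third parameter guaranteeing fast geometric convergence.
Staircase arithmetic is exact in doubles. Zero-variance outcomes,
rank-deficient designs, inconsistent logs, missing cells, out-of-range
ratings and invalid probabilities all raise errors naming the offending
component, row or trial; validation of whole table sets
(`validate_tables()`) collects violations non-fatally instead.

## Known limitations

The ML mixed models stand in for the original flat-prior Bayesian fits, so
interval endpoints can differ in the second decimal from an MCMC run. The
headline correlations and coefficients of the original study depend on its
participant data, which the package does not ship; the analysis scripts
demonstrate the full pipeline on synthetic cohorts with known truth
instead, and the recovery tests quantify exactly how well the pipeline
finds planted effects of the published magnitude. The effort-seeker flag
fires on ~2% of simulated participants against the study's ~5% — seekers
generated by the continuous tail map sit just above 1, whereas real
reverse-discounters were described as near-ceiling choosers; the flag's
*logic* is what the tests exercise. The design module reproduces the
study's procedure, not its printed medians, for the reasons given above.
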