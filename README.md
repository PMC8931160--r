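# coged

Cognitive effort discounting (COG-ED) in two cognitive domains: simulation,
scoring, mixed models, Bayesian correlation inference, and sequential
Bayes-factor design analysis.

## The problem

Is the willingness to spend cognitive effort a stable, domain-general trait?
COG-ED studies answer this behaviourally: participants repeatedly choose
between an easy baseline task (1-back working memory, or listening to speech
at 0 dB SNR) for a small reward and a harder level (2/3/4-back; −4/−8/−12 dB)
for more money. An adaptive staircase titrates one offer by successively
halved steps — $\mathrm{base}/2, \mathrm{base}/4, \dots$ — until the
*indifference point*, the amount at which the two offers are equally
attractive, is bracketed. Indifference points become subjective values (SV)
on a 0–2 scale:

- initial choice = easy: $SV = \mathrm{ip}/\mathrm{base} \in [0, 1]$
  (effort discounting);
- initial choice = hard: $SV = 1 + (\mathrm{base}-\mathrm{ip})/\mathrm{base}
  \in [1, 2]$ (effort seeking).

The scientific test is then correlational, in three stages of increasing
control: (1) the zero-order correlation of mean SV across the two domains;
(2) the same correlation after residualising SV on task load and
domain-appropriate performance (N-back hit/correct-rejection rates and RT;
speech intelligibility) in random-intercept mixed models; (3) a partial
correlation additionally controlling working-memory-capacity and
reward-sensitivity composites (sums of z-scores). Evidence is quantified
with exact correlation Bayes factors (grid integration of the reduced
likelihood of $r$; Savage–Dickey density ratio), and the study's sample size
came from a sequential Bayes-factor design analysis with boundaries
BF10 ≥ 10 / ≤ 0.1 and a 300-participant cap.

The package implements all of it — the task engine, scoring, a synthetic
cohort generator with known ground truth, the models, the Bayesian
machinery, and the design analysis — as an R package plus a numbered
analysis workflow.

## Worked example

The analysis workflow lives in `analysis/` and writes everything under
`results/` (regenerable; not shipped):

```sh
Rscript analysis/01_simulate_cohort.R    # cohort of 132, seed 20260113
Rscript analysis/02_score_discounting.R  # staircase replay -> SV, exclusions
Rscript analysis/03_effort_analysis.R    # three-stage correlational test
Rscript analysis/04_design_analysis.R    # sequential BFDA
```

Step 3 prints, for that seed (true cross-domain correlation 0.3, 103 of 132
retained after headphone/completion exclusions):

```
primary sample (n = 103):
  stage 1, zero-order:       r = 0.23 [0.05, 0.40], BF10 = 4.63 (n = 103)
  stage 2, residualised:     r = 0.22 [0.03, 0.39], BF10 = 3.27 (n = 103)
  stage 3, partial:          r = 0.20 [0.02, 0.38], BF10 = 2.21 (n = 103)
pooled model: load B = -0.176 [-0.189, -0.162]
ratings mental_demand  load B = 3.51 [3.24, 3.78]
domain contrast load_1: t(102) = 0.56, BF10 = 0.13
domain contrast load_3: t(102) = -5.89, BF10 = 237423.68
```

Read: mean subjective value declines with load (B ≈ −0.18 per level pooled);
the cross-domain association survives performance residualisation and
composite control (the domain-general-motivation signature); the domains
separate only at high load; workload ratings climb ~3.5 points per load
level on the 1–21 scale. With a single ~100-participant draw the Bayes
factors sit in the "moderate" range — the recovery tests
(`tests/testthat/test-acceptance.R`) quantify behaviour across 100 such
cohorts.

Programmatic use:

```r
library(coged)
cohort <- generate_cohort(cohort_config(n_participants = 132, seed = 1))
report <- run_pipeline(cohort)
report$primary$h1_zero_order
```

## Layout

- `R/` — package code: cohort generator, titration engine, scoring,
  mixed models, Bayesian correlation/partial-correlation/paired tests,
  sequential design, pipeline and table schemas.
- `analysis/` — the numbered workflow drivers shown above.
- `scripts/acceptance.R` — design-analysis reproduction script.
- `tests/testthat/` — unit, property and study-level tests, including
  independent quadrature and enumeration oracles in `helper-oracles.R`.
- `vignettes/coged-methods.Rmd` — the models, their assumptions, parameter
  defaults, numerical choices, and known limitations.
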