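---
title: "Life-course socioeconomic mobility and stroke risk: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Life-course socioeconomic mobility and stroke risk: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lcmob)
```

## The problem

Disadvantageous socioeconomic conditions, in childhood as well as in
adulthood, are associated with increased risk of ischemic stroke. A natural
follow-up question is whether *movement* between socioeconomic positions —
upward mobility relative to one's father, or decline between adolescence and
late adulthood — carries risk information beyond the positions themselves.
`lcmob` implements the full analysis pipeline for this question in a
frequency-matched case-control design: additive life-stage risk scores,
control-tertile risk strata, two families of mobility classifiers, and exact
conditional logistic regression with three nested adjustment models. A
synthetic-data generator with known ground truth makes every stage testable
and lets the estimation machinery be calibrated end-to-end.

## Life-stage scores

Each life stage gets an unweighted additive point score over questionnaire
items; higher values mean more disadvantage.

* **Childhood (0–12):** paternal occupation (0/1/2), maternal occupation
  (0/1), family structure (0/1/2), more than three siblings (1), rooms per
  person (0/1/2), no toilet in the house (1), no parental car (1), family
  income in the lower half (1), episodes of paternal unemployment (1).
* **Adolescence (0–8):** highest school degree (0/2/4) plus professional
  education (0/1/2/4).
* **Adulthood (0–8):** last profession before stroke or retirement
  (0/1/2/4), unemployment longer than six months (2), not being married or
  partnered (2).

The point values are fixed by the questionnaire design; the package does not
derive or reweight them (see Non-goals below). One deliberate asymmetry is
preserved exactly as designed: a housewife contributes 0 points in the
*mother's* childhood item but 4 points in the *subject's* adolescence and
adulthood profession items. Scores are validated by exhaustive enumeration:
additivity against an independent per-item lookup, attainable ranges
\{0,12\}/\{0,8\}/\{0,8\}, and monotonicity (worsening any single item never
lowers a score).

### Missing items

The source analyses imputed missing questionnaire values with a procedure
that is not spelled out in the text. The package substitutes a declared,
deterministic strategy: single-pass mode imputation within sex × case/control
cells, ties broken towards the lower-risk level, with `complete_case` as a
selectable alternative. Matching variables (age, sex, status) must never be
missing — that is a hard error, not an imputable condition. The imputation
log (cells imputed per field) is attached to the returned table and written
to the run log.

## Risk strata and mobility

Scores are categorized into **low / middle / high risk strata** at the
tertiles of the *controls'* score distribution. Discrete scores with heavy
ties make textbook quantiles ambiguous, so the package uses the
empirical-CDF threshold rule: `q1` is the smallest observed value with
CDF ≥ 1/3, `q2` the smallest with CDF ≥ 2/3, and strata are
`x ≤ q1` / `q1 < x ≤ q2` / `x > q2`. This rule is deterministic, involves no
interpolation, and degrades gracefully (all controls sharing one value puts
everyone in `low`). Cutpoints depend on controls only — perturbing case
scores cannot move them.

Two mobility families, each an ordered trichotomy
advancement / no change / descent:

* **Occupational (intergenerational):** professions collapsed to
  academic > white collar > blue collar/other (housewives included in the
  last), comparing father vs the subject's professional training, father vs
  last profession, and training vs last profession.
* **Score-stratum:** transitions between life-stage risk strata
  (childhood→adolescence, childhood→adulthood, adolescence→adulthood).
  Because higher score = higher risk, reaching a *higher* tertile is
  *descent*. Any higher tertile counts the same: low→high and low→middle are
  both one category (the trichotomy carries no magnitude).

Both classifiers are antisymmetric (swapping arguments exchanges
advancement and descent), verified over all nine ordered pairs.

## Conditional logistic regression

The design frequency-matches controls to cases within 2-year age bands
crossed with sex, and the analysis conditions on exactly those strata: bands
`[18,20), [20,22), …` with the last band closed at 80 (the design fixes only
the 2-year width; anchoring at 18 with half-open intervals is the package's
convention). Strata without both a case and a control are uninformative and
are flagged and excluded.

For stratum $s$ with members $x_1,\dots,x_{n_s}$ and $m_s$ cases, the exact
conditional log-likelihood is

$$\ell(\beta) = \sum_s \left[ \sum_{i \in \text{cases}_s} x_i^\top\beta
  - \log \sum_{|S| = m_s} \exp\Big(\sum_{i\in S} x_i^\top\beta\Big) \right],$$

the inner sum running over all case-label subsets of size $m_s$. The
denominator and its first two derivatives are computed by the standard
recursion over elementary sums in the weights $e^{x_i^\top\beta}$
(implemented in C++), never by subset enumeration; linear predictors are
centered at their stratum maximum for overflow safety. The exact likelihood
(not the Breslow approximation) was chosen because it is directly testable:
on strata of size ≤ 8 the recursion, its analytic gradient, and the fitted
coefficients are checked against a brute-force enumeration oracle to 1e-10
/ 1e-5, and whole fits are cross-validated against an independent
implementation (`survival::clogit(method = "exact")`). The Breslow
approximation is not offered.

Fitting is Newton–Raphson with analytic gradient and Hessian and
step-halving; convergence when the largest score component falls below 1e-8
or the step below 1e-10, at most 50 iterations. Covariates with no variation
inside any informative stratum carry no conditional information and are
dropped with a warning (their coefficients report as `NA`); a monotone
likelihood (separation, operationalised as a coefficient exceeding 12 in
absolute value, a failed or indefinite Hessian solve, or non-convergence) is
flagged and confidence intervals are suppressed — never silently returned as
converged. Odds ratios are $e^\beta$ with Wald intervals
$e^{\beta \pm z\,\mathrm{se}}$; rounding to two decimals happens only in the
presentation layer.

## The three models

For each of the six mobility exposures (entered as advancement and descent
indicators, reference *no change*):

* **Model 1** conditions on the age-band × sex strata only;
* **Model 2** adds the 14 binary medical/lifestyle risk factors
  (hypertension, diabetes, hypercholesterolemia, atrial fibrillation,
  coronary heart disease, peripheral arterial disease, cardiac failure, low
  number of teeth, smoking, high alcohol consumption, low dentist visits,
  low physical activity, low fruit and low vegetable consumption), no
  interactions;
* **Model 3** adds the three life-stage scores. The scores enter as
  categorical tertile strata by default (two indicators per stage, reference
  `low`), matching the stratum-based framing of the score analyses;
  continuous entry is available via `lc_config(model3_scores =
  "continuous")`. The stratum coding was chosen as default because the
  published analysis treats the scores categorically everywhere else.

Covariate sets are nested, so the model-2 optimum log-likelihood can never
fall below model 1's (model 1's optimum padded with zeros is feasible for
model 2); the pipeline tests assert exactly this, not a per-parameter
comparison. Model 3 for the score-based exposures adjusts for the same
strata the exposure is built from; the exposure indicator is an interaction
of the two stage-stratum factors and remains identifiable, but the
adjustment is heavy and its intervals are accordingly wide — the null
calibration below covers this case. No multiple-testing adjustment is
applied anywhere, and the output metadata say so.

Table percentages are rounded half-up in two stages (to two decimals, then
to one). Single-stage half-up rounding disagrees with two control
percentages in the published tables (211/807 prints as 26.2, 462/807 as
57.3, while 26.146 and 57.249 round straight to 26.1 and 57.2); the staged
rule reproduces every printed cell and is therefore adopted as the
presentation convention.

## The synthetic world

The generator emulates the statistical structure the analysis assumes — it
is a stated world, not a fitted one, and its defaults are fixed once:

* **Latent trajectory.** One standard-normal latent "SES risk" value per
  life stage, higher = more disadvantaged;
  $Z_\text{adol} = \rho_1 Z_\text{child} + \sqrt{1-\rho_1^2}\,\varepsilon$,
  $Z_\text{adult} = \rho_2 Z_\text{adol} + \sqrt{1-\rho_2^2}\,\varepsilon$,
  with defaults $\rho_1 = 0.6$, $\rho_2 = 0.7$: life-course SES tracks
  strongly but far from perfectly, with adolescence→adulthood tracking the
  stronger of the two.
* **Items.** Each questionnaire item has its own latent loading 0.75 on its
  stage value (a Gaussian copula; thresholding the stage latent directly
  would make all items of a stage perfectly concordant, which real
  questionnaire data never are). Ordered items are cut at configured
  cumulative marginals; the sibling count is a Poisson(2.2) quantile
  transform. Default marginals are plausible for the birth cohorts of a
  study interviewing 18–80-year-olds around 2010 (e.g. 10% academic fathers,
  15% homes without an indoor toilet); they are stated, not estimated.
* **Risk factors.** Bernoulli with logit = qlogis(baseline prevalence) +
  0.3 × adult SES, baseline prevalences typical of an elderly European
  case-control sample (e.g. hypertension 0.55, diabetes 0.20).
* **Outcome.** $P(\text{case}) = \text{logit}^{-1}(\alpha + \eta)$ where
  $\eta$ accumulates configured true log odds ratios for mobility categories
  and risk factors; $\alpha$ is solved by root finding so the expected case
  count hits `case_rate` (default 0.08) times the population size (default
  20,000 — large enough to fill every matching cell at the published study
  size). Mobility in the true model is classified against the whole
  pre-outcome population's tertiles; the analysis then re-derives cutpoints
  from the sampled controls, exactly as the estimator would face them.
* **Ages and matching.** Case ages are drawn from a truncated normal
  (66.5, 10.8), control ages from (66.9, 10.5), echoing the reported
  per-status means; 41% of subjects are female. The study sampler draws 466
  cases (default) and allocates 807 controls across the cases' age × sex
  cells by largest-remainder rounding. Because age is independent of every
  other attribute in the generating model, sparse tail cells (a case at an
  extreme age) are topped up with randomly drawn same-sex controls re-aged
  uniformly into the band — distributionally identical to conditional
  sampling, and the only way a finite population can match reliably in the
  tails. A genuinely exhausted sex pool is an error naming the cell.
* **Missingness** is missing-completely-at-random at a configurable rate
  (default 0), sufficient to exercise the imputation path and nothing more.

What the generator does *not* emulate: participation bias, age–SES
correlation (cohort effects on e.g. education), migration background,
recruitment logistics, or any real joint distribution of the questionnaire
items. A green simulation test therefore establishes that the *estimation
machinery* is correct and calibrated for data of this structure — not that
the substantive findings of any particular study are reproduced.

## What the tests establish

* Score arithmetic is exact (exhaustive enumeration, independent lookup
  oracle).
* The percentage builder reproduces every count-derived percentage in the
  published mobility tables from the printed counts and totals.
* The likelihood recursion, derivatives and fits agree with brute-force
  subset enumeration (strata ≤ 8) and with `survival::clogit`; a 1:1-matched
  fit equals the classical discordant-pair estimator
  $\log(n_{10}/n_{01})$.
* End-to-end parameter recovery: 200 replicate studies of 466/807 with a
  true adolescence→adulthood descent log-OR of log 2 give a mean estimate
  within ±0.1 of the truth with CI coverage in [0.90, 0.99].
* Null calibration: with all true effects zero, the 36 mobility CIs per
  replicate (6 exposures × 3 models × 2 categories) cover OR 1.0 at ≈95%
  pooled over 200 replicates.
* Determinism: identical seeds and configs give byte-identical tables,
  fits and logs.

## Known limitations

* Wald intervals only; no profile-likelihood or Firth-type correction —
  separation is flagged, not repaired.
* The imputation strategy is a declared substitute, not a reconstruction of
  the original procedure.
* The published conditional odds ratios themselves are not reproducible
  without the individual-level age/sex data, which were never deposited;
  the package's claims are therefore about correctness and calibration of
  the method, checked against oracles and simulations.
* The generator's marginals and correlations are stated defaults, not
  estimates; they are deliberately not tuned to any test outcome.
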