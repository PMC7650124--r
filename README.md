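# lcmob — life-course socioeconomic mobility and stroke risk

`lcmob` is an R toolkit for analysing social mobility as a risk factor for
ischemic stroke in frequency-matched case-control studies. It is aimed at
epidemiologists and biostatisticians who have subject-level questionnaire
data (or want to simulate it) and need the complete chain from raw items to
adjusted odds ratios:

1. **Life-stage socioeconomic risk scores** — additive point scores for
   childhood (0–12), adolescence (0–8) and adulthood (0–8), higher = more
   disadvantaged, with deterministic mode imputation for missing items;
2. **Risk strata and mobility** — low/middle/high strata cut at the
   *controls'* score tertiles (empirical-CDF threshold rule for tied
   integer scores), plus two mobility classifiers: intergenerational
   occupational mobility on an ordered academic > white-collar >
   blue-collar/other scale, and score-stratum mobility between life stages
   (reaching a higher-risk tertile = descent);
3. **Exact conditional logistic regression** — the matched design
   (2-year age bands × sex) is analysed with the exact conditional
   likelihood

   $$\ell(\beta)=\sum_s\Big[\sum_{i\in\text{cases}_s} x_i^\top\beta-\log\!\!\sum_{|S|=m_s}\exp\big(\textstyle\sum_{i\in S}x_i^\top\beta\big)\Big],$$

   computed by the elementary-sum recursion in C++ (no subset enumeration),
   maximised by Newton–Raphson with analytic derivatives, with Wald 95%
   intervals $e^{\hat\beta\pm 1.96\,\mathrm{se}}$, stratum-constant
   covariates dropped, and separation flagged rather than reported;
4. **The analysis pipeline** — for each of six mobility exposures, three
   nested models (Model 1: matching strata only; Model 2: + 14
   medical/lifestyle risk factors; Model 3: + the three life-stage scores),
   assembled into publication-style mobility tables, plus sex-stratified
   Model 3 fits;
5. **A synthetic-data generator** — Gaussian-copula latent SES trajectories
   with configurable stage-to-stage correlations, item marginals, true
   mobility/risk-factor log odds ratios and a solved intercept, so the whole
   pipeline can be exercised and calibrated with known ground truth.

## Worked example

Simulate a matched study of 466 cases / 807 controls in which social descent
between adolescence and adulthood doubles the odds of stroke (true log-OR =
log 2), then run the full analysis:

```r
library(lcmob)

cfg <- sim_config(seed = 42,
                  log_or_mobility = list(
                    mobility_adol_adult = c(advancement = 0, descent = log(2))))
study <- simulate_study(cfg)
res <- run_analysis(study, lc_config(seed = 42))

res$table2[res$table2$exposure == "mobility_adol_adult",
           c("category", "case_n", "case_pct", "control_n", "control_pct",
             "model1_or", "model1_lo", "model1_hi")]
#>     category case_n case_pct control_n control_pct model1_or model1_lo model1_hi
#>  advancement    106     22.8       212        26.3      1.00     0.754      1.34
#>    no_change    198     42.5       398        49.3      1.00        NA        NA
#>      descent    162     34.8       197        24.4      1.65     1.263      2.16

res$fits$mobility_adol_adult$model1
#> Exact conditional logistic fit: 39 informative strata, 1273 subjects
#> loglik -757.9422, converged in 3 iteration(s)
#>          term    or     lo    hi
#> 1 advancement 1.005 0.7537 1.340
#> 2     descent 1.650 1.2627 2.157
```

Reading the output: descent shows the built-in effect (OR 1.65 in this
single replicate, 95% CI 1.26–2.16 — the truth, OR 2, is recovered without
bias *on average*; a single draw scatters around it), advancement sits at
the null as configured, and `no_change` is the reference category (OR 1.00).
Counts partition the 466 cases and 807 controls, and percentages are
recomputed from counts with the same rounding convention as the published
tables. Model 2/Model 3 columns and the other five exposures are in
`res$table1`/`res$table2`; `write_analysis(res, "outdir")` serialises
tables, fits and cutpoints.

The same run from the shell:

```sh
inst/cli/lcm simulate --seed 42 --out study.csv
inst/cli/lcm analyze --input study.csv --seed 42 --out outdir/
```

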