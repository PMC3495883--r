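# webrds

Simulation, cleaning, estimation and convergence diagnostics for **web-based
respondent-driven sampling (webRDS)** surveys of hidden populations.

Populations without a sampling frame — the motivating case is internet-using
men who have sex with men in a highly stigmatizing setting — can be reached by
chain referral: a few purposively chosen *seeds* answer the survey and each
participant may invite up to four peers electronically, producing recruitment
chains that, after enough waves, no longer depend on who the seeds were.
Running the whole design online makes recruitment fast but invites duplicate
and fraudulent submissions, so the analysis has three inseparable parts, all
implemented here:

1. **Cleaning** — screen submissions for stated age below 18, previously
   registered phone/e-mail/chat tokens, repeated IP addresses, sub-3-minute
   completions, "no education" answers and >1,000 six-month partners, and
   build progressively stricter inclusion groups (L0–L3) for sensitivity
   analysis.
2. **Estimation** — the RDS-II (Volz–Heckathorn) estimator, which corrects
   the degree bias of chain-referral inclusion by weighting each respondent
   by the reciprocal of their personal network size $d_i$:

   $$\hat p_A = \frac{\sum_{i\in A} d_i^{-1}}{\sum_i d_i^{-1}}, \qquad
     \hat d = \frac{n}{\sum_i d_i^{-1}},$$

   with the harmonic-mean estimate $\hat d$ also used to impute missing
   network sizes.
3. **Diagnostics** — recruiter-to-recruit transition matrices per variable,
   their stationary compositions, the number of waves a first-order Markov
   chain needs to come within a 2% relative difference of stationarity,
   running-composition curves, full-sample vs last-200 comparisons, chain
   depth statistics and the cross-province recruitment fraction.

Because no real data ship with the package, a first-class synthetic module
generates attributed social networks (configuration model with trait and
province homophily), simulates coupon-limited voluntary recruitment with
realistic local-saturation die-out, and fabricates submission tables with
invalid records injected at known rates — so every downstream stage is tested
against exact bookkeeping.

## Worked example

```r
library(webrds)

cfg    <- default_pipeline_config(rng_seed = 42)
pop    <- generate_population(cfg$population, 42)
forest <- simulate_recruitment(pop, cfg$simulation)
forest
#> Recruitment forest: 454 participants, 20 seeds, max wave 19

subs  <- fabricate_submissions(forest, pop, cfg$simulation)
flags <- flag_invalid(subs)
sum(flags$any_invalid)                       # 51 invalid of 454 (11.2%)
cleaned <- apply_inclusion(subs, flags, "L1")

fit <- rdsII(~ partner_preference + province + stated_age, cleaned)
fit
#> RDS-II estimates (n = 383, estimated mean network size 4.24)
#>
#> partner_preference:
#>                    both men_only
#> sample proportion 0.183    0.817
#> RDS-II estimate   0.164    0.836
#> ...
#> stated_age (numeric): RDS-II mean 21.961, sample mean 21.987 (n = 383)
```

The gap between the sample proportion and the RDS-II estimate is the
degree-bias correction: categories over-represented among high-degree
(well-connected) respondents are weighted down. The estimated mean network
size (4.24) is the harmonic mean of the reported 7-day network sizes and is
what gets imputed for the respondents who declined that question.

Diagnostics use the same objects:

```r
waves_to_equilibrium(rbind(c(0.8, 0.2), c(0.3, 0.7)))
#> [1] 7    # worked two-state example: pi = (0.6, 0.4), |lambda| = 0.5

repaired <- reattach_orphans(forest, setdiff(forest$id, cleaned$id))
cross_group_recruitment_fraction(repaired, cleaned, "province")
#> [1] 0.298   # ~30% of recruitment events cross provinces
```

`run_rds_pipeline(cfg, outdir = "out")` chains the stages
simulate → clean → estimate → diagnose → report, writing CSV/JSON artifacts,
figures, a plain-text report and an MD5 manifest; identical config and seed
reproduce identical data artifacts. A thin CLI wrapper lives at
`inst/scripts/webrds.R`.

## Package layout

- `R/population.R` — synthetic attributed networks, random-walk oracle
- `R/recruitment.R`, `R/submissions.R` — webRDS simulator and submission
  fabricator (with injection bookkeeping)
- `R/cleaning.R` — validity flags, inclusion levels L0–L3, chain repair,
  sensitivity report
- `R/estimators.R` — `rdsII()` fit object plus the low-level estimators
- `R/diagnostics.R` — transition matrices, stationarity, waves to
  equilibrium, composition curves, wave statistics
- `R/pipeline.R` — stage orchestration, manifest, report
- `vignettes/webrds-methods.Rmd` — the model, its assumptions and the design
  choices in detail
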