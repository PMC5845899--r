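# streamsdt

Hierarchical Bayesian signal detection analysis for auditory streaming
experiments with polyphonic music.

## The problem

In two-voice polyphonic music, a listener can *segregate* the scene —
follow the bassoon or the cello as its own stream — or *integrate* it,
hearing both voices as one percept. A behavioural paradigm for studying
both modes embeds a rhythmic triplet pattern inside the music: under an
attend-bassoon, attend-cello or attend-aggregate instruction, the listener
reports after each excerpt whether the pattern occurred in the attended
stream(s). A companion experiment manipulates the bottom-up cue of
instrument timbre distance over three levels (maximum = original
instruments, minimum = the listener's own perceptual centre between the
two, intermediate = centre minus 20 percentage points), individually
calibrated from morph-rating data.

`streamsdt` implements the complete analysis pipeline for this paradigm,
plus a synthetic-subject generator so every stage is testable without
human data. It is aimed at auditory psychophysicists building or analysing
streaming tasks of this family.

## What it computes

* **Trial classification and edge-corrected d′** — hits/misses/false
  alarms/correct rejections per attention instruction, and
  `d'_ec = Φ⁻¹((H+0.5)/(H+M+1)) − Φ⁻¹((FA+0.5)/(FA+CR+1))`,
  finite at ceiling, with a parallel symmetric criterion summary.
* **A hierarchical probit-binomial model** — per subject × condition cell
  *m*: `H_m ~ Bin(n_tri, Φ(0.5·d'_m − bias_m))`,
  `FA_m ~ Bin(n_ntri, Φ(−0.5·d'_m − bias_m))`, with
  `d'_m ~ N(β₀ + β_att + β_timb + β_att×timb + β_subj, σ²_att)`, priors
  `β₀ ~ N(0, 1000)`, coefficient scales `σ_β ~ Γ(1.64, 0.32)` (mode 2,
  sd 4), `σ_att ~ Unif(0, 4)`, and a mirrored criterion sub-model.
  Estimation is by a compiled adaptive Metropolis-within-Gibbs sampler
  (10,000 draws + 2,000 burn-in per chain, 4 chains by default), with
  split-R̂/ESS diagnostics; effects are reported as sum-to-zero recentered
  cell-mean deviations with highest-density intervals (`hdi()` = shortest
  interval holding the stated mass).
* **Constrained session schedules** — generators and an independent
  validator for the 96-trial attention session, the 90/135-trial
  (laboratory/scanner) attention × timbre sessions and the 176-trial
  morph-rating session, satisfying all ordering, balance and coverage
  constraints of the protocols.
* **Timbre psychometrics** — the rating sigmoid
  `S(r) = 1 + (b−a)/(1+10^((x50−r)·m))` with a = 1, b = 5 fixed, fitted by
  Levenberg–Marquardt least squares; per-listener timbre distances derived
  from the fitted centre.
* **Reliability and descriptives** — odd/even split-half reliability of
  edge-corrected d′, Spearman rank correlation (exact permutation p for
  n ≤ 9), per-subject morph effects, median/IQR group summaries.

## Worked example

Simulate a 19-listener cohort on the laboratory attention × timbre design,
aggregate it into measurement cells, and fit the hierarchical model:

```r
library(streamsdt)

truth  <- truth_params("exp2", n_subjects = 19, seed = 42)
cohort <- simulate_cohort(truth, group = "LAB", seed = 42)
cells  <- aggregate_counts(cohort$trials)
nrow(cells)
#> [1] 171

head(cells[, c("subject_id", "attention", "timbre_level",
               "n_hit", "n_tri", "n_fa", "n_ntri", "dprime_ec")], 3)
#>   subject_id attention timbre_level n_hit n_tri n_fa n_ntri dprime_ec
#> 1        S01   bassoon      maximum     4     4    0      6  2.746785
#> 2        S01   bassoon intermediate     6     6    0      4  2.746785
#> 3        S01   bassoon      minimum     6     6    0      4  2.746785

fit <- fit_model(cells, model_config("exp2", seed = 1))
fit
#> <sdt_fit> exp2 model: 171 cells, 19 subjects
#>   chains: 4  retained draws/chain: 10000
#>   max split-R-hat (structural): 1.027  min ESS: 271

eff <- cell_effects(fit)
hdi(eff$grand)
#> 95% HDI [5.089, 8.114]
round(colMeans(eff$timbre), 3)
#>      maximum intermediate      minimum
#>        1.008        0.248       -1.256

ct <- contrast(fit, "timbre", c("maximum", "minimum"))
ct$hdi; ct$excludes_zero
#> 95% HDI [0.8621, 3.798]
#> [1] TRUE

rel <- split_half_reliability(cohort$trials, seed = 42)
round(c(r = rel$r, p = rel$p), 3)
#>     r     p
#> 0.806 0.004
```

Reading the output: the cohort is simulated near ceiling (grand mean
sensitivity 4.7), so most 10-trial cells are perfect and the latent grand
mean is bounded from below but not sharply from above — hence the high,
right-skewed grand-mean HDI. The injected minimum-timbre deficit (−0.7,
amplified at ceiling; see the methods vignette) shows up in the recentered
timbre effects, and the maximum−minimum contrast excludes zero. Split-half
reliability across the 19 simulated listeners is 0.81.

The end-to-end driver `run_pipeline()` performs
design → simulate → aggregate → fit → report and writes schedule/trial/cell
CSVs, posterior exports, a JSON report and a reproducibility manifest.

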