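# forpanel

Blood-protein biomarkers of **functional overreaching (FOR)** — the
short-term performance dip athletes deliberately provoke with a block of
heavy training — are hard to establish: the candidate signals are small,
the designs are repeated-measures crossovers with a handful of athletes,
and dried-blood-spot (DBS) proteomics adds batch structure and
non-trivial technical variability. `forpanel` is an R package for
analysts working with this kind of data. It implements, as a tested and
reusable pipeline, the full path from a long-format DIA quantitation
table to acute and chronic/FOR protein clusters, together with a
design-faithful synthetic-data generator (so every stage is verifiable
against planted ground truth) and a mixed-model power simulation for the
crossover design.

## The design and the model

The study design is a two-arm randomized crossover: each athlete
completes a 3-day exercise arm and a 3-day rest arm (counterbalanced
order), sampled pre and post on each day plus two recovery mornings — 8
occasions × 2 arms = 16 DBS samples per athlete. Each athlete's samples
form one MS batch with 4 pooled-QC injections (before, after, and twice
during the batch).

Per protein, after top-3 peptide rollup, empirical-Bayes batch
correction and row-max normalization, the normalized intensity
*y\_{ijk}* of athlete *i* at occasion *j* in arm *k* is modeled
marginally (GEE-style) with the time-by-condition cell as a single
16-level categorical predictor:

    E[y_ijk] = mu_{jk},   clusters = athletes,
    working correlation: exchangeable,
    Var(beta_hat): bias-reduced (Mancl–DeRouen) cluster-robust sandwich.

Five difference-of-differences contrasts of the cell means are reported
(t reference with *n*−1 df, multiplicity-adjusted):

* `acute_dK` = (DKpost − DKpre | exercise) − (DKpost − DKpre | rest), K = 1,2,3
* `recovery_rK` = (RK − D1pre | exercise) − (RK − D1pre | rest), K = 1,2

Each protein is tested at a **CV-gated significance level**: α = 0.01 if
its technical CV (from the pooled-QC injections) exceeds 15%, else
α = 0.05. Proteins are then classified by temporal pattern:
**acute_sustained** (all three acute contrasts up), **acute_day1**
(day-1 contrast up), **chronic_FOR** (elevated on a recovery morning
with no acute response — the FOR candidate cluster), or **none**.

## Worked example

```r
library(forpanel)
cfg <- pipeline_config(seed = 1L)     # 10 athletes, 20 acute + 20 chronic
res <- run_pipeline(cfg, "demo_out")  # + 160 null proteins, 2.0-fold effect
res$summary$counts
#> $acute_day1      [1] 4
#> $acute_sustained [1] 18
#> $chronic_FOR     [1] 20
#> $none            [1] 158
res$summary$recovery
#> $sensitivity_acute   0.9
#> $sensitivity_chronic 0.95
#> $fpr_by_label        acute_day1 0.0125, acute_sustained 0, chronic_FOR 0.00625
median(res$matrix$technical_cv)
#> [1] 0.103
```

Of the 20 planted acute proteins, 18 are recovered as `acute_sustained`
(sensitivity 0.90); 19 of 20 planted chronic proteins come back as
`chronic_FOR` (0.95, with one extra null protein picking up the label —
FPR 0.006); the median technical CV lands on the generator's 10%
calibration target, so these proteins are gated at α = 0.05. Per-protein
evidence looks like:

```r
subset(res$contrasts, protein_id == "P0001")[, 2:6]
#>      contrast estimate     se    p_raw p_adjusted
#> 1    acute_d1   0.4073 0.0615 9.72e-05   0.000486
#> 2    acute_d2   0.3684 0.0680 4.21e-04   0.002105
#> 3    acute_d3   0.3501 0.0441 2.37e-05   0.000118
#> 4 recovery_r1   0.0229 0.0192 2.64e-01   1.000000
#> 5 recovery_r2   0.0523 0.0267 8.22e-02   0.410989
```

— a planted acute protein: all three acute contrasts positive and
significant after adjustment, recovery contrasts null, so the classifier
labels it `acute_sustained`.

A real (non-simulated) table enters the same way:

```r
cfg <- pipeline_config(simulate = FALSE, input = "my_quant.tsv")
run_pipeline(cfg, "out")
```

and the power simulation for planning a larger cohort:

```r
pc <- power_config(effect_size = c(0.5, 1, 2), reps = 500L, seed = 1L)
curve <- simulate_power(pc, technical_sd = 0.0998)
report_power(curve, plot = TRUE)
```

A thin command-line wrapper over these functions is installed at
`inst/cli/forpanel.R` (subcommands `run`, `simulate`, `power`).

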