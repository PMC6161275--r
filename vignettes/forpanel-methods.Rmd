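---
title: "Methods: detecting functional-overreaching protein biomarkers in a crossover DBS-proteomics design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: detecting functional-overreaching protein biomarkers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(forpanel)
```

# The problem

Functional overreaching (FOR) is the transient performance decrement an
athlete incurs from a deliberate block of overload training; it resolves
with recovery, and anticipating its maladaptive cousins (non-functional
overreaching, overtraining syndrome) motivates a blood-protein panel
that distinguishes *acute* exercise responses from *chronic* recovery
signatures. The measurement setting is dried-blood-spot (DBS) DIA
proteomics in a two-arm randomized crossover: each athlete serves as
their own control, completing a 3-day exercise arm and a 3-day rest arm
in counterbalanced order, with samples pre and post on each of the three
days and on two recovery mornings — 16 study samples per athlete. Each
athlete's samples are one MS batch, monitored by 4 injections of a
pooled QC sample (before, after, twice during).

`forpanel` implements the full analysis path for this design, plus a
synthetic-data generator that emulates it, so that every downstream
stage can be validated against planted ground truth — the original raw
data not being publicly deposited.

# The synthetic-data generator

`make_design()` reproduces the sampling/injection schedule exactly
(16 study samples per athlete, randomized injection order within batch,
QC at slots 1, 7, 14, 20 of the 20-injection batch). `make_archetypes()`
plants protein response classes:

* **acute** — multiplicative fold-change at D1post, D2post, D3post,
  exercise arm only;
* **chronic** — fold-change at the recovery mornings (both R1 and R2 by
  default; configurable to either alone, covering the "day 1 and/or
  day 2" pattern);
* **null** — no response (effect forced to 1).

Effects are present in a per-(protein, athlete) Bernoulli subset of
athletes ("responders", prevalence 0.8 by default, the planning
assumption of the power analysis).

`generate_dataset()` draws intensities **lognormal** — all model
components act additively on the natural-log scale: a per-protein
baseline (log-mean 14, log-sd 1, i.e. intensities around 1.2 million
counts with a proteome-wide spread of one log unit, typical of DIA
label-free scales), a per-athlete random effect (log-sd 0.3), a
per-batch location shift (log-sd 0.2) and scale multiplier (log-sd
0.05), and technical noise whose log-sd is calibrated from the target
technical CV by the lognormal identity `cv = sqrt(exp(sd^2) - 1)`
(target 10% by default). The lognormal choice reflects that MS
intensities are positive and right-skewed; the power simulation
(below) separately uses plain normal data, which is the convention that
analysis states. The QC sample is the same pooled material in every
batch: per protein its injections share the grand-mean level plus the
batch's location effect, and differ only by technical noise.

What the generator does **not** emulate: peptide-identification
artifacts, intensity-dependent missingness (a completely-at-random
`missing_rate` exists, default 0), heavy-tailed contamination, and
carryover between crossover periods (the design uses a 3-week washout).
Passing tests on this generator therefore demonstrate correctness of
the statistical machinery under the stated sampling model, not
robustness to every pathology of real DIA data.

# Preprocessing

The order is fixed: rollup → batch correction → CV computation →
row-max normalization (correction happens *before* normalization).

**Top-3 rollup.** Per protein, peptides are ranked once by their mean
intensity across study samples (ties broken lexicographically by
peptide id), and the top `min(3, #peptides)` contribute. The protein
quantity is the mean of their log-intensities — the log of the
geometric mean, the common top-N convention, monotone-equivalent to a
geometric-mean rollup. Ranking on the across-sample mean keeps the
peptide set fixed across samples.

**Batch correction.** A transparent parametric empirical-Bayes
location-scale adjustment on the log scale, in the ComBat style: each
protein is standardized against the batch-design fit (weighted grand
mean of batch means; pooled within-batch residual variance), per-batch
location/scale parameters are estimated and shrunk toward their
across-protein moments (normal prior on locations, inverse-gamma on
scales, hyperparameters by method of moments), and all records in a
batch — QC included — are adjusted. A single batch is a no-op. The test
suite cross-checks the adjustment against `sva::ComBat` on a seeded
dataset.

**Technical CV.** Computed per protein from the pooled-QC injections on
the (batch-corrected) raw-intensity scale, *within* batch — per-batch
`sd/mean` over the 4 injections, pooled across batches as the root mean
square. The intra-batch form is deliberate: athlete and batch are
confounded in this design (one batch per athlete), so any between-batch
spread remaining in QC records after correction reflects that confound
rather than injection precision, and pooling QC across batches would
systematically inflate the CV (in our generator, from the 10% target to
roughly 22%). An alternative `zscore` mode — z-score the protein across
all samples, then `sd(z_QC)/|mean(z_QC)|` — is exposed for sensitivity
analysis; it is not the default because the QC mean z-score can sit
arbitrarily close to zero, making the ratio unstable. Proteins with
fewer than 2 QC observations get an undefined CV and are conservatively
gated at the strict α.

**Row-max normalization.** Each protein row is divided by its own
maximum on the raw intensity scale (after back-transforming from log),
so rows have maximum exactly 1 and values in (0, 1]. The operation is
idempotent and invariant to rescaling any row by a positive constant;
per-protein t statistics are unaffected by the row scale, so this
changes interpretability (fraction of the protein's own peak), not
inference.

# Per-protein inference

Each protein's normalized intensity is modeled marginally with the
16-level time-by-condition cell as a single categorical predictor,
athletes as clusters. The fitter is a gaussian GEE (identity link) with
an exchangeable working correlation by default (independence available
for sensitivity); in this balanced design the point estimates are the
cell means under either choice, so the working correlation is a
robustness, not an identification, device. Standard errors are the
**Mancl–DeRouen bias-reduced cluster-robust sandwich** — the plain
sandwich is biased downward with 10 clusters — and all tests use a t
reference with `n_athletes − 1` degrees of freedom. Degenerate inputs
(constant response) are kept well-defined by flooring the residual
variance; zero-variance contrasts report t = 0 at a zero estimate.
Non-converged proteins and non-estimable contrasts (missing cells)
carry status codes and classify as `none`; they are never silently
dropped.

The five reported contrasts are differences of differences of cell
means. The acute contrasts compare the pre-to-post change on each
exercise day with the matching change in the rest arm. The recovery
contrasts are baselined at each arm's D1pre by default — recovery
mornings have no natural "pre", and the within-arm baseline removes any
arm-level offset; an unbaselined `(RK | exercise) − (RK | rest)` mode
is available.

**Multiplicity.** Two adjustments are implemented. `tukey` refers each
contrast's |t| to the studentized-range distribution for the 16-level
family (`ptukey` with 16 means), the classical correction for all
pairwise level comparisons. `bonferroni5` multiplies the raw p by 5,
the number of reported contrasts. The pipeline default is
`bonferroni5`: the five contrasts are *not* members of the 120
pairwise-level family — each is a 4-point linear combination — so the
studentized-range family badly over-corrects them (at 9 denominator df
its effective two-sided threshold is |t| ≈ 3.95 versus 3.25 for
Bonferroni-over-5), and sizing the correction to the five tests
actually performed is the coherent family. Both modes are computed by
the same code path and recorded in the run manifest.

**Calibration.** The acceptance tests verify that under null generation
the day-1 acute contrast's raw p-values are calibrated (empirical
type-I error at α = 0.05 within 0.05 ± 0.02 over 500 null proteins; the
Mancl–DeRouen correction makes the test mildly conservative, by design)
and that significance calls agree ≥ 90% with an exact paired sign-flip
permutation test (statistic: mean per-athlete difference-of-differences;
all 2^10 within-athlete arm swaps enumerated — the exact version of the
≥ 2000-resample approximation).

# The significance gate and classification

`select_alpha()` implements the technical-variability gate: α = 0.01
when the protein's technical CV **exceeds** 15% (strict inequality — a
CV of exactly 0.15 keeps the default), else α = 0.05; undefined CV
defaults to 0.01.

`classify_protein()` encodes the cluster rules on the adjusted
p-values at the gated α. Two readings of the chronic rule coexist in
the source material — "did not increase or decrease acutely" versus
"not more than one of the exercise days" — and both are implemented:
`strict` (default; no acute significance in either direction) defines
the chronic cluster's membership, `lenient` tolerates one significantly
positive acute day. Precedence is `acute_sustained` → `chronic_FOR` →
`acute_day1` → `none`; in lenient mode a protein with exactly one acute
day plus a recovery rise is `chronic_FOR` rather than `acute_day1`,
because the lenient chronic definition explicitly tolerates that single
acute elevation. "Elevated" always means a significantly *positive*
contrast. Label monotonicity in α holds for the purely
significance-required acute labels; the chronic label's exclusion
clause is intentionally anti-monotone (shrinking α can unblock it), and
the tests pin both behaviors. The cluster report reserves free-text
annotation columns (`literature_support`, `biological_plausibility`)
for the manual narrowing criteria of the original workflow; the
pipeline never fills them.

# Power simulation

`simulate_power()` reproduces the planning analysis: plain-normal data
on the full 16-cell grid (random athlete intercept + technical noise),
cohort sizes 10–50 in steps of 10, the effect — a shift in
technical-sd units, present in 80% of athletes — planted at the tested
contrast's occasions, a linear mixed model (`lme4::lmer`, random
intercept per athlete, 16-level fixed categorical) fitted per
replicate, and the day-1 acute contrast tested at the
Bonferroni-adjusted level 0.05/5 for a five-protein panel. Contrast
p-values use a t reference with the balanced-design within-athlete
residual df `15(n − 1)`. No effect size is asserted as "the" historical
one — none is printed in the source analysis — so the effect grid is a
required user choice and the tests verify properties instead: size
under the null within Monte-Carlo error of 0.01, and power
non-decreasing in cohort size and effect.

# Numerical and design choices

* All randomness flows from explicit integer seeds; identical
  configuration and seed reproduce every pipeline artifact byte for
  byte (numeric columns are written with fixed 12-digit formatting, and
  the manifest carries no timestamps).
* Exchangeable correlation is clamped to `[-1/(max cluster size − 1),
  0.99]`; GEE iteration stops at a 1e-10 coefficient change.
* Aliased model columns (empty cells) are dropped via QR, the affected
  contrasts flagged `not_estimable`.
* Adjusted p-values are clipped to `max(p_adj, p_raw)` and to 1.
* Test-suite problem sizes: 500 null proteins for calibration, the
  20/20/160 default scenario for recovery, 500 Monte-Carlo replicates
  per power cell — sizes at which the Monte-Carlo error is comfortably
  inside the asserted bounds.

# Known limitations

* The generator's noise levels (athlete, batch, technical) are stated
  assumptions, not reconstructions of the unpublished raw data; the
  intensity distribution and missingness of the real 593-protein
  dataset are unknown.
* The marginal model assumes gaussian normalized intensities; heavy
  tails would transfer weight to the permutation oracle, which is
  provided in the test helpers but not as a pipeline stage.
* The chronic cluster's published narrowing to a final panel involved
  graphical inspection and literature judgement; those steps are
  represented only as empty annotation columns.
* With 10 clusters, sandwich-based t tests are approximate even with
  bias reduction; the calibration tests quantify (and bound) the
  resulting mild conservatism.
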