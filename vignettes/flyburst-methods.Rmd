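---
title: "Quantifying Drosophila seizure phenotypes: methods and design notes"
author: "flyburst"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying Drosophila seizure phenotypes: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flyburst)
```

# Scope

`flyburst` implements the quantitative layer of a fly seizure study: it
starts from already-extracted spike times of larval motor-neuron
(aCC/RP2) loose-patch recordings and from per-animal behavioral
measurements, and produces burst statistics, normal/elongated trace
classification, and estimation statistics for group comparisons. Spike
detection from raw voltage traces, acquisition hardware, and any
neurobiological interpretation are out of scope.

# The burst model

A **burst** is a maximal run of at least `minSpikes` (default 3)
consecutive spikes in which every successive inter-spike interval (ISI)
is at most `maxISI` (default 100 ms); a burst ends when no spike follows
within `maxISI` of its last spike. This is the classical ISI-threshold
("max-interval") segmentation with a single threshold and is a chain
rule: only consecutive gaps matter, not all pairwise distances. Burst
duration is the time from first to last spike, with no padding by the
threshold.

Three choices in this rule were genuinely open and are fixed as follows:

* **Boundary inclusivity.** An ISI of exactly `maxISI` *continues* the
  burst ("within 100 ms" read as less-than-or-equal). Both the fast
  detector and the exhaustive oracle implement the same rule, so the
  choice cannot silently diverge between them.
* **Floating-point guard.** The comparison is `isi <= maxISI + 1e-9` s.
  Spike times are typically stored as decimal seconds at millisecond
  resolution; successive differences of such values are often one ulp
  above the nominal value (`3*0.1 - 2*0.1 > 0.1` in doubles), which
  would flip exact-boundary ISIs to "gap" unpredictably. One nanosecond
  is orders of magnitude below any acquisition resolution, so the guard
  cannot change the classification of any physically distinct interval.
* **Sub-minimum runs.** Runs of one or two spikes are not bursts; their
  spikes count toward the overall firing rate only.

`detectBursts()` is a vectorised run-length pass over the ISI sequence;
`detectBurstsOracle()` is an independent per-index forward scan with the
identical contract. They are required to agree exactly (including
boundaries) on randomized trains; this dual-route check is part of the
test suite and the acceptance script.

# Per-trace and per-genotype statistics

For each trace, `summarizeTrace()` reports: number of bursts, mean and
sample SD (n − 1) of burst duration, burst frequency, firing rate, mean
spike count per burst, and mean AP frequency per burst. Conventions that
needed fixing:

* **Denominators.** Burst frequency and firing rate divide by the full
  declared recording duration (default 180 s), not the last-spike time.
* **AP frequency per burst** is the *mean of per-burst ratios*
  (`n_spikes / duration` averaged over bursts), not the ratio of means.
  With right-skewed burst durations the two differ noticeably; the mean
  of ratios is the standard per-burst statistic and is the only reading
  consistent with a reported mean AP count and mean duration that imply
  a *lower* frequency than the reported one. Zero-duration bursts
  (possible only for degenerate inputs, not for detected bursts of
  distinct spike times) are excluded from this mean and logged.
* **Burst-duration SD** is computed within trace (across that trace's
  bursts) and then averaged per genotype, matching how the statistic is
  reported alongside per-trace averages. An across-trace reading exists
  but is not used; the within-trace one is the recorded choice.
* Traces with no bursts keep their firing rate; all burst statistics
  are `NA`-flagged. `summarizeGenotype()` aggregates by unweighted mean
  over traces, excludes flagged traces from burst-statistic means only,
  and reports how many were excluded.

Internal units are seconds and Hz throughout; `genotypeSummaryTable()`
converts durations to ms (exact ×1000) for the conventional report.

# Classification against a wild-type band

`buildReferenceBand()` computes the **per-trace mean burst durations**
of the reference genotype (default `"CS"`, configurable — the reference
is a config key, not a constant) and forms the band mean ± k·SD with
k = 1.5 by default and the sample SD. Using per-trace means rather than
the pooled burst population is the recorded choice: the classification
object is the trace, and its summary statistic is its mean burst
duration.

`classifyTraces()` labels each trace `elongated` (above the band),
`short` (below), `normal` (inside, bounds inclusive — the band defines
the normal range, and a relative 1e-12 guard keeps at-bound values
normal despite round-off in `mean + k*sd`), or `unclassifiable` (no
bursts). Only the upper exceedance is the phenotype of interest;
`fractionElongated()` reports elongated/classifiable per genotype with
unclassifiable counts alongside, never silently folded in.

Under a near-normal distribution of per-trace means, a trace of the
reference population itself falls above its own k = 1.5 band with
probability ≈ Φ(−1.5) ≈ 6.7%; the acceptance suite verifies the
observed rate against the binomial 95% interval at n = 200.

# Estimation statistics

The package reports effect sizes with bootstrap confidence intervals
and **no p-values** anywhere.

**Bootstrap mean difference.** Each group is resampled with replacement
at its own size, 5000 times by default. The default interval is BCa:
bias correction \(z_0 = \Phi^{-1}(\#\{\theta^* < \hat\theta\}/B)\) and
acceleration from the grouped jackknife,
\(a = \sum u_i^3 / (6 (\sum u_i^2)^{3/2})\). When either is undefined
(degenerate bootstrap distribution or zero jackknife spread) the
interval downgrades to the percentile method with a logged message, and
the returned object records which method was actually used. The BCa CI
flavor is itself an open choice (the percentile method is available by
argument); simulation in the test suite shows both achieve 92–98%
coverage for the n = 20 normal-shift design. Quantiles use R's default
type-7 interpolation. The implementation is authored here and is
cross-checked in the tests against `boot::boot.ci` on a shared problem;
the external package is never the computation path.

**Cohen's d** uses the pooled-SD form
\(d = (\bar b - \bar a)/s_p\),
\(s_p^2 = ((n_a{-}1)s_a^2 + (n_b{-}1)s_b^2)/(n_a{+}n_b{-}2)\). The
pooled (rather than average-SD) denominator is a recorded assumption.
Two zero-variance groups make d undefined (error; `NA` inside the
bootstrap wrapper).

**Percent change** is `100·(mean(treated) − mean(control))/mean(control)`,
the "seizure duration increased by X%" convention; **cumulative seizing
fraction** counts, at each checkpoint, the animals with onset at or
before it over the full cohort, censored animals never entering the
numerator.

**Cross-assay regression** (`fitEffectSizeRegression()`) fits OLS
through per-genotype effect-size points — larval electroshock Cohen's d
on x against the adult assay appropriate to each genotype class on y
(vortex for bang-sensitive, heat for heat-sensitive lines; the mapping
is part of the run config, never hardcoded). R² is the squared Pearson
correlation, snapped to exactly 1 when within 1e-12 of it so collinear
designs report 1; an optional CI bootstraps over points (genotypes), the
recorded choice for the R² uncertainty. The bootstrap-over-genotypes
flavor is honest about its tiny n: with five genotypes the R² interval
is very wide.

**Seeds.** One root seed per run; every comparison derives a child seed
deterministically from the root seed and its group/assay labels
(`deriveSeed()`, a 31-bit polynomial string hash), so adding, removing
or reordering comparisons never perturbs existing results, and any
stage rerun standalone with its derived seed reproduces the in-pipeline
result bit for bit.

# The synthetic-data generator

No raw recordings or behavioral measurements are published for this
kind of study, so the generator is a first-class module: every pipeline
stage is tested against data with known ground truth.

**Spike trains** come from an alternating renewal process: draw an
inter-burst gap, then a burst duration, fill the burst with spikes at
the within-burst ISI distribution (whole fills redrawn until ≥ 3 spikes
fit), repeat to 180 s; isolated noise spikes are superposed at a small
Poisson rate. Distribution families are configurable (exponential /
gamma / lognormal, parametrised by natural-scale mean and SD); the true
families in real recordings are unknown, so they are options with
recorded defaults, not claims.

The wild-type-like defaults were chosen once from the published
wild-type summary row — bursts of mean 175 ms with SD ≈ 91 ms
(lognormal), ≈ 0.47 bursts/s, ≈ 14 spikes/burst via a 13.5 ms mean
within-burst ISI, 0.01 Hz noise — and the elongated preset scales burst
duration ×3. These presets are conveniences that land the simulated
wild type near the published values; they are not a reproduction of any
measured table.

**Ground-truth exactness** is engineered, not hoped for: within-burst
ISIs are rejection-capped strictly below the detection threshold
(default cap 95 ms), inter-burst gaps below `maxISI + 5 ms` are
redrawn, and noise spikes landing within `maxISI + 5 ms` of *any*
accepted spike are rejected (slightly stricter than rejecting only near
burst edges, so noise spikes can never chain with anything). The cost
is a slightly non-Poisson noise process and truncated tails on the gap
and ISI distributions; the benefit is that `detectBursts()` equals the
generator's ground truth exactly, which the tests assert as
`identical()`.

What the generator does **not** emulate: between-trace heterogeneity of
the burst-duration mean beyond sampling noise, within-burst rate
structure (acceleration/adaptation), bursty noise, non-stationarity
over the 180 s, and recording artifacts. Passing parameter-recovery and
classification tests on these data therefore shows the analysis is
correct for the assumed data-generating process, not that real
recordings satisfy that process.

**Behavioral data** are lognormal or gamma per genotype–assay group
(long right tails, as seizure durations are), parametrised by
natural-scale mean/SD; heat-assay onset times are censored at the
120 s exposure window.

**Fixture suite.** `makeFixtureSuite()` writes a deterministic 24-trace
spike set (12 wild-type-like `WTL`, 12 elongated `ELG`), a behavioral
panel (three bang-sensitive mock mutants of graded severity vs a shared
control; two heat-sensitive mock lines vs matched controls; 20 animals
per group), a ready-to-run pipeline config, and a JSON manifest of
every true parameter for use as a test oracle. All files are
plain-text and regenerate byte-identically from the root seed.

# Pipeline and reproducibility

`runPipeline()` executes ingestion → burst detection → trace/genotype
summaries → band classification → effect sizes → regression → heat
curve, writes seven TSV result tables plus a timestamped run log, and
aborts with a stage-named error on any failure. Result tables are
byte-identical across reruns of the same config (the log differs by its
timestamps, which is why determinism is asserted over the tables). The
test suite additionally pins the fixture-suite results to committed
golden tables.

Problem sizes used by the tests and acceptance script — 1000 random
trains for the oracle equivalence, 50 traces for parameter recovery,
200 reference + 100 elongated traces for classification, 500×2000 for
CI coverage, 10⁴ per group for the Cohen's d limit — were chosen as the
smallest sizes at which the binomial/normal tolerances quoted alongside
each check are meaningful.

# Known limitations

* The ISI-threshold rule is the only detector offered (no Poisson
  surprise or two-threshold variants), matching the analysis it
  implements.
* Classification assumes the reference per-trace means are roughly
  normal; with few reference traces the band is noisy and the 6.7%
  nominal exceedance is only an asymptotic statement.
* BCa with very small groups (n < ~8) can be unstable; the downgrade
  path exists for the degenerate cases, not as a small-sample fix.
* The generator's independence assumptions (renewal process, i.i.d.
  ISIs) are idealisations; see above for what that implies about
  real-data claims.
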