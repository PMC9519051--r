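---
title: "Quantifying tonic immobility: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying tonic immobility: models, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(zfarrest)
library(dplyr)
```

`zfarrest` quantifies a defensive behavioural state in larval zebrafish:
after an intense, inescapable vibratory stimulus, larvae suppress
locomotion and reflexes and later recover abruptly, each fish at its own
latency. This vignette explains the models behind the package, the
conventions that fix otherwise ambiguous definitions, and the reasoning
behind the design choices. It states no empirical result beyond what the
test suite and `scripts/acceptance.R` themselves compute.

## The assay and its protocol

A trial consists of a tracked baseline, a 15-s train of 95 vibratory
pulses, a 0.5-s un-tracked gap (residual water movement makes imaging
useless immediately after the shaker stops), and a 210-s recovery window.
Locomotion is summarised as total path distance per 5-s epoch. The default
`stim_protocol()` encodes exactly these values; the baseline summary is a
trailing 60-s window, configurable because trial baselines can be longer
than the window used for normalisation.

Three per-fish statistics carry the analysis:

* **Arrest statistic.** Δv = v(first post-stimulus epoch) − mean
  v(baseline); also reported normalised, v₁/v̄. Arrest is a negative Δv.
  Fish averaging < 0.5 mm/s at baseline are excluded (they cannot show a
  speed reduction); when an experimental manipulation alters baseline
  locomotion, comparisons can be restricted to fish inside a 2–3 mm/s
  baseline band.
* **Half-recovery time (T₀.₅).** The end time, on the epoch grid and
  relative to stimulus offset, of the first post-stimulus epoch whose speed
  reaches half the baseline mean; censored at 210 s. Because epochs start
  0.5 s after stimulus offset but are reported on the 5-s grid, the
  attainable values are 5, 10, 15, … seconds.
* **Path straightness.** Headings are the four-quadrant arctangent of
  consecutive (smoothed) displacement vectors, in degrees; straightness is
  the mean circular SD of headings over moving windows. A straight path has
  circular SD 0.

### Numerical conventions

* A step between consecutive samples belongs to the epoch containing its
  *ending* sample; the first sample of a tracked phase has no predecessor,
  so a phase's first 5-s epoch at 20 Hz sums 99 steps, not 100.
* Positions are smoothed with a centred moving average (default 5 samples
  at 20 Hz) before distances are taken. Tracking jitter otherwise inflates
  path length, most severely in stationary fish — the arrest statistic is
  conservative for exactly this reason.
* Division-by-zero guard: a fish with zero baseline mean gets Δv only;
  normalised speed is undefined and flagged, consistent with the exclusion
  rule.
* Coordinates follow the image convention (x right, y down, origin at the
  arena's top-left), millimetres throughout.

### The T₀.₅ estimator reads upward

A fish recovering abruptly at latency L crosses the half-baseline threshold
in the first epoch that is mostly (≈ 50% for a fully immobile fish)
recovered, and the estimate is then rounded up to the epoch end. The
estimator therefore sits 0 to ~7.5 s *above* the true latency, ~4–5 s on
average. This is a property of the binned estimator itself — printed
half-recovery values produced by the same convention carry the same grid —
and the package documents rather than hides it: the estimator-fidelity test
asserts the one-epoch agreement in expectation, and the acceptance check of
the 20-s reference condition is expected to read near the top of its
one-epoch tolerance.

## The locomotion simulator

`simulate_cohort()` is a first-class, tested component, not a fixture.
Spontaneous swimming is modelled as discrete bouts initiated within 400-ms
epochs: per epoch, at most one bout starts (turn with probability 0.3,
forward swim with probability 0.3 at baseline), displaces the fish by a
gamma-distributed distance (mean 1.7 mm) over ~200 ms with a raised-cosine
speed profile, and rotates the heading (turns: ±60° ± 12°; forward swims:
0° ± 8°). These defaults give an expected baseline speed of ~2.6 mm/s,
inside the 2–3 mm/s band the assay itself uses for comparisons. The arena
is a 10-mm square well with reflective walls; tracked positions carry
isotropic Gaussian jitter (default SD 0.01 mm, a realistic sub-pixel
centroid error for macro-lens tracking).

**Arrest and recovery.** Each fish draws an arrest depth d (its expected
fractional speed reduction) and, during arrest, both its initiation rates
and its per-bout displacement are scaled by √(1−d) — the assay observes
reductions in both initiation frequency and per-movement displacement, and
the product recovers the intended speed scaling. Recovery is abrupt: the
fish uses arrest parameters until its latency (log-normal, median 20 s,
sdlog 0.4, drawn per fish), then baseline parameters. A configurable
fraction never recovers within the window.

**The reference condition.** The calibrated study condition halves the
group's first-epoch speed through heterogeneous individuals, not a uniform
slowdown: one third fully immobile (d = 1), one third halved (d = 0.5), one
third unresponsive (d = 0), giving E[d] = 0.5. This mixture was fixed from
the qualitative description of individual variability (prolonged
immobility / reduced speed / no response) before any acceptance measurement
and is exposed as `reference_arrest_config()`. Cohorts for half-recovery
estimation use a uniformly immobile population (d = 1), because fish at or
above half-baseline speed throughout trivially read T₀.₅ = 5 s and carry no
information about recovery latency.

**What the simulator does not emulate:** wall-following and thigmotaxis,
inter-bout pauses with structure (bout chaining, hunting bouts), tail
kinematics and body shape, habituation across repeated stimulus trains, and
any direct effect of the stimulus during the (untracked) pulse train.
Passing tests therefore demonstrate estimator correctness under a
bout-structured random walk with abrupt state switches — not robustness to
every behaviour of real larvae.

## Bout kinematics at 1000 Hz

Segmentation uses hysteresis on instantaneous speed (enter > 4 mm/s, leave
< 1 mm/s). At 1000 Hz, raw sample-to-sample speed has a noise floor of
√2·σ·f ≈ 14 mm/s for σ = 0.01 mm — far above any threshold — so speed is
estimated over a 10-ms stride on smoothed positions, which brings the floor
under 1 mm/s while leaving real bout peaks (tens of mm/s) untouched. Net
heading change is measured between the displacement vectors of the first
and last thirds of the bout, because the tiny edge steps of a soft-onset
bout are noise-dominated. Turns are |Δheading| ≥ 30°, ties counting as
turns; the threshold is this package's convention (the angular criterion
used by tracker-internal classifiers is not public) and is configurable.
Initiation frequency counts only the first bout of each 400-ms epoch, so
per-type percentages sum to at most 100%.

## Calcium responder pipeline

The simulator renders static Gaussian nuclei (σ = radius/√2) on a jittered
grid with guaranteed minimum separation, a signal channel with per-cell
gain, responders whose signal is multiplied by 1 + a·r(t), linear global
drift applied by bilinear translation, and i.i.d. Gaussian pixel noise. The
response r(t) is a linear ramp over the 5-s stimulus convolved with the
indicator impulse kernel `gcamp_kernel()` — difference of exponentials with
rise 0.55 s and decay 3.5 s, whose peak sits 1.1 s after an impulse,
matching slow nuclear GCaMP6s — so fluorescence builds during stimulation
and peaks at stimulus cessation. The default protocol is 10 s baseline, 5 s
of 1-Hz pulses, 45 s recovery at 2 Hz acquisition.

Analysis stages and their choices:

* **Detection.** Scale-normalised Laplacian-of-Gaussian filtering at three
  scales around the expected radius, strict 8-neighbour maxima with
  parabolic sub-pixel refinement, greedy non-maximum suppression. The
  automatic threshold is k (default 6) times the response-map noise SD,
  obtained by propagating a robust (MAD of first differences) pixel-noise
  estimate through the LoG kernel 2-norm — a blank noise image yields no
  detections regardless of its scale.
* **Registration.** Per-frame translation against the mean of the first 10
  reference-channel frames, by FFT cross-correlation with parabolic
  sub-pixel peak refinement. Detection runs on the same early-movie
  reference, so detected coordinates live in reference space and per-frame
  shifts place them in each frame. The original assay registered manually;
  automation is required for reproducibility. Full affine estimation is out
  of scope — a single global translation per frame covers rigid stage/tissue
  drift.
* **Extraction.** Disc photometry of both channels at the registered
  centres; ΔR/R = (signal/reference) normalised to its baseline-window
  mean, so every trace averages exactly 1 over the baseline. No neuropil
  correction (none is described for this preparation). QC proxies flag
  z-drift (reference intensity dropping below half its baseline) and
  struggle (frame displacement > 5 px); flagged ROIs are excluded from
  classification by default.
* **Classification.** A cell is a responder when its stimulus-window
  statistic of ΔR/R exceeds baseline mean + 3 × baseline SD. The statistic
  defaults to the **mean** over the stimulus window rather than the max:
  a max over m frames exceeds any k-SD threshold with probability
  ≈ 1−(1−α)^m per cell *independently of the noise scale* (≈ 1.3% for
  m = 10 at 3 SD), which would plant false responders in every few hundred
  silent cells at any SNR; the mean statistic has no such floor. The max
  remains available by argument. A zero-SD baseline (only synthetic traces
  produce one) falls back to "any increase" and is flagged.

## Activity maps and enrichment

Masked pERK/tERK summaries compute the voxelwise ratio first and then the
mean over the mask (ratio-then-mean, matching "ratios were calculated and
averaged"), excluding and counting zero-denominator voxels, and refusing
masks where more than 1% of the denominator is non-positive. The statistic
is invariant to common rescaling of both volumes. Volumes are assumed
pre-registered; registration itself is external tooling.

Enrichment follows the small-pool RNA protocol: genes with fewer than 5000
summed raw reads across target-group samples are removed (interpreted as
summed counts; a per-sample-mean variant is configurable), counts are
normalised by median-of-ratios size factors, each gene is tested with a
two-sided Wilcoxon rank-sum test (exact for the small group sizes involved;
midranks under ties, with all-tied genes assigned p = 1 and flagged), and
p-values are Benjamini–Hochberg adjusted. Genes are flagged enriched at
log₂FC > 8 and q < 0.05, with fold change computed on normalised group
means under a pseudocount of 1 (the analysis description is silent here;
the choice is recorded in the output attributes). Note a structural
property of rank-sum enrichment at n = 6 vs 6: the smallest attainable
two-sided p is 2/924, so Benjamini–Hochberg can only admit discoveries when
enough genes share small p-values — isolated single enriched genes are
undetectable by construction, which is why simulations plant realistic
numbers of differing genes.

The count simulator draws per-gene base means log-normally (median 2000
counts, so a realistic fraction of genes clears the 5000-read filter),
applies per-sample depth factors, and samples negative-binomial counts with
a common dispersion; planted genes shift the target-group mean by stated
log₂ fold changes.

## Estimation statistics

Cohen's d is the mean difference divided by the (n−1)-weighted pooled SD,
signed treated-minus-control. Estimation intervals are percentile
bootstraps (default 5000 resamples, seeded); BCa is deliberately omitted —
percentile intervals are transparent and sufficient at these group sizes.
Dunnett many-to-one comparisons take their p-values from a seeded
Monte-Carlo max-|t| null (default 10⁵ draws) rather than multivariate-t
quadrature: the implementation is dependency-free and verifiable against
its k = 2 reduction to a two-sample t test, which the suite checks to
within 0.01.

## Problem sizes used by the suite

The test and acceptance runs use the study's own scales where they are
what is being checked — 27-fish cohorts, 8 fish × 25 escape trials × 200
replicates, 420 nuclei with 41 responders (20 seeds) — and smaller
configurations (e.g. 60-nucleus movies, 100–400-gene matrices, reduced
null-simulation sweeps) for module-level properties, chosen so the whole
suite completes in a few minutes while keeping Monte-Carlo error well below
the asserted tolerances.

## Known limitations

* The half-recovery estimator's upward grid bias (above) is inherent to the
  5-s binning; comparisons across conditions are unaffected because all
  conditions share the grid.
* Bout classification uses net heading change only; compound bouts (turn
  then glide) classify by their net rotation.
* Registration assumes one global translation per frame; rotation, scaling
  and non-rigid tissue motion are not corrected.
* The trial-QC proxies for z-drift and struggle are heuristics on the
  reference channel and estimated displacement, not a reimplementation of
  manual trial curation.
* Wilcoxon-based enrichment has the discreteness limitation noted above;
  count-model differential expression is deliberately out of scope.
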