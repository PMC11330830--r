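---
title: "Circadian and sleep analysis of DAM recordings: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Circadian and sleep analysis of DAM recordings: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(circasleep)
```

This vignette is the package's account of its methods: the statistics it
computes, the generative model behind the synthetic data, the numerical
conventions adopted where the field's informal descriptions leave room,
and the limits of what the test suite demonstrates.

## The experimental design being analysed

The canonical protocol is a Drosophila Activity Monitor (DAM) recording of
individually housed flies: infrared beam crossings counted once per minute
for 3 days of 12:12 light–dark entrainment (LD) followed by 7 days of
constant darkness (DD). Zeitgeber time 0 (ZT0) is lights-on; day 1 starts
at ZT0 of the first LD day. From one such recording the pipeline derives:

* **Total activity** — beam crosses summed over LD day 2 (day 1 is
  habituation).
* **Rhythmicity and free-running period** — chi-square periodogram on
  30-minute bins over the DD window.
* **Morning/evening anticipation** — the escalation of activity over the
  hours preceding each light transition on LD day 2.
* **Sleep** — the 5-minute immobility rule applied to the 1-minute counts
  of LD day 2, restricted to rhythmic flies.
* **Group statistics** — mean ± SEM with Student's t or ANOVA + Tukey HSD
  for continuous metrics; percentage ± binomial SD with Fisher's exact
  test for binary phenotypes.

## The chi-square periodogram

For a trial period of $p$ bins, the series is folded into
$K = \lfloor N/p \rfloor$ complete cycles (the remainder is discarded).
With column means $M_h$ ($h = 1 \dots p$) and grand mean $\bar M$ over the
$Kp$ used points, the Sokolove–Bushell statistic is

$$
Q_P \;=\; \frac{K\,\sum_h (M_h - \bar M)^2}{s^2}, \qquad
s^2 = \frac{1}{Kp}\sum_i (x_i - \bar M)^2 ,
$$

approximately $\chi^2_{p-1}$ under the null of no rhythm. The
significance line is the $1-\alpha$ quantile ($\alpha = 0.05$), and
**power** is defined as the peak $Q$ minus the significance line at the
peak; a fly is *rhythmic* when power $\ge 20$. Periodogram software in
this field ("power of ≥ 20" conventions) does not publish its internals,
so this definition is stated explicitly: absolute power values — and
therefore the rhythmic fraction — depend on it.

Numerical conventions:

* trial periods are integer bin multiples inside 16–32 h; at 30-min bins
  the step is 0.5 h;
* ties at the peak are broken toward the period closest to 24 h;
* the analysis window is DD days 2 to the end — the first DD day is
  excluded as an entrainment transition;
* a constant series has an undefined statistic and is reported
  non-rhythmic with power 0;
* the series must cover at least twice the longest trial period.

The test suite checks $Q$ against an independently coded fold-and-average
oracle at $10^{-9}$ relative tolerance, verifies that pure Poisson noise
exceeds the 0.05 line at per-period rate ≈ α and essentially never reaches
power 20, and that strongly rhythmic synthetic flies recover their period
within one grid step.

## Anticipation indices

The morning index of a fly on a given day is

$$
\mathrm{MI} = \frac{\sum \text{activity in the 3 h before lights-on}}
                   {\sum \text{activity in the 6 h before lights-on}} - 0.5,
$$

ranging over $[-0.5, +0.5]$; the evening index is the mirrored
construction around lights-off. Both are evaluated on LD day 2 by default.
A fly *has* morning (evening) anticipation when its index is strictly
positive. The strict-positive cut-off is the simplest defensible rule
where no published threshold exists; it is deliberately exposed — the
indices themselves are returned, so any other threshold is one comparison
away. An index is undefined when the 6-h denominator is zero; such flies
are excluded from the anticipation percentages (and logged). The indices
are scale-invariant, exact on hand-computable inputs (uniform activity
gives 0, fully concentrated activity gives ±0.5), and these identities are
asserted in the tests.

## Sleep scoring

Fly sleep is operationally ≥ 5 consecutive minutes without beam crossings.
On single-beam monitors "does not change position" can only be read as a
zero count, so **any** count > 0 makes a wake minute regardless of
magnitude, and runs of 1–4 zero minutes are quiet wake. Sleep is always
scored on the raw 1-minute series (the 30-minute binning applies to the
circadian analysis only); passing rebinned data is an error.

Boundary conventions, chosen once and applied everywhere:

* scoring happens on the uncut series first, then the analysis day is
  clipped out, so zero runs straddling the day edges are resolved before
  truncation;
* an episode straddling the light→dark boundary is counted **once**, in
  the phase where it starts, while its minutes are split between the
  phase totals — no episode is double-counted;
* the per-phase mean episode length is the mean in-day duration of the
  episodes attributed to that phase, so
  `n_episodes × mean_length` summed over phases reconciles exactly with
  total sleep.

The scorer is verified against a naive scan oracle on all $2^{10}$
binary patterns of length 10 and on random full days, and — using the
generator's latent sleep state with wake counts forced positive — recovers
the latent state exactly except in bouts shorter than 5 minutes.

Sleep summaries follow the field's convention of analysing **rhythmic
flies only**; the rhythmic flags from the periodogram stage are passed in
and exclusions are logged.

## Group statistics

* Continuous metrics: per-genotype mean ± SEM; two-tailed **Student's**
  t-test (equal variances — the classical convention here; Welch is
  available behind a flag) for two groups, one-way ANOVA with Tukey HSD
  for three or more.
* Binary phenotypes (rhythmic, morning/evening anticipation): percentage
  of flies with the binomial standard deviation
  $\sigma = \sqrt{n p q}$ as the error bar, compared by the two-sided
  Fisher's exact test (probability-mass rule: the p-value sums all tables
  with the observed margins no more probable than the observed one). A
  zero margin carries no information and returns p = 1.
* Stars: \*, \*\*, \*\*\*, \*\*\*\* at p < 0.05, 0.01, 0.001, 0.0001.
* Pairwise comparisons default to versus-control (the first group), with
  all-pairs as an option. No correction is applied across metrics; Tukey
  adjusts within a metric only.

Degenerate inputs are resolved explicitly: identical zero-variance
samples give p = 1; zero variance with different means gives p = 0 with a
warning. The tests verify Fisher against full hypergeometric enumeration
on all small tables, Student's t against a permutation oracle and the
$t^2 = F$ identity, and Tukey's adjusted p against the unadjusted LSD p
from the same ANOVA (which it must dominate; note that an unpooled
two-sample t-test uses a different standard error and is *not* uniformly
dominated).

## The synthetic-data generator

No raw recordings accompany the phenotypes the presets emulate, so the
generator is the package's ground truth. One fly is simulated at 1-minute
resolution as:

1. **Sleep/wake**: a two-state alternating-renewal process with
   geometrically distributed bout lengths whose means are the
   phase-appropriate `sleep_bout_mean_min` / `wake_bout_mean_min`.
   Geometric bouts are realised as per-minute exit hazards equal to the
   reciprocal bout means, so a bout spanning a phase transition simply
   continues under the new phase's hazard. This memoryless realisation is
   what makes the model analysable: the per-minute sleep probability
   follows an exact two-state recursion whose periodic fixed point gives
   closed-form per-phase sleep expectations (including the relaxation
   transients after each transition), and those closed forms are what the
   Monte-Carlo tests converge to.
2. **Activity**: during wake minutes, counts are Poisson with rate
   $\lambda(t) = \text{base} \times [1 + \text{morning ramp}(t) +
   \text{evening ramp}(t)]$, where each ramp rises linearly from 0 to its
   strength over the 3 h preceding (subjective) lights-on / lights-off —
   matching the 3-h window of the morning index. Sleep minutes always
   emit 0, so the latent state is exact ground truth for the scorer.
3. **Free-run**: once DD begins, subjective time advances at $24/\tau$
   circadian hours per clock hour, so the entire waveform (bout structure
   and ramps) free-runs with period $\tau$.
4. **Arrhythmicity**: with probability `arrhythmic_fraction` a fly's rate
   modulation is flattened to its time-average *and* its bout means are
   phase-averaged. Flattening the rate alone would leave the phase-locked
   sleep structure intact and the fly would still appear rhythmic, which
   is why the sleep gate is flattened too. The base rate is recalibrated
   so an arrhythmic fly keeps the same expected daily activity —
   rhythmicity and total activity are separate phenotype dials.
5. **Calibration**: the base rate is set so the expected total activity
   on a steady-state LD day equals `mean_daily_activity`, using the exact
   occupancy recursion rather than the stationary approximation.
6. **Reproducibility**: each fly consumes its own L'Ecuyer-CMRG stream
   derived from the group seed with `parallel::nextRNGStream()`. Deriving
   integer sub-seeds from a Mersenne-Twister stream — the naive scheme —
   produces measurably correlated flies and overdispersed group means;
   CMRG streams are guaranteed disjoint. Output is a pure function of
   (preset, schedule, seed).

### Preset calibration

The built-in presets pin the reported phenotype values where the source
reports them, and fix the unreported magnitudes once as package
calibration choices:

| preset | activity/day | τ (h) | ramps | arrhythmic | sleep means L/D (min) | wake means L/D (min) |
|---|---|---|---|---|---|---|
| `wild_type` | 500 | 23.6 | 2 / 2 | 0.05 | 20 / 40 | 80 / 20 |
| `pink1_b9` | 250 | 26.2 | 0 / 0 | 0.35 | 60 / 150 | 60 / 10 |
| `tim_usp14_kd` | 500 | 24.5 | 2 / 2 | 0.05 | 20 / 40 | 80 / 20 |
| `pdf_usp14_kd` | 500 | 24.2 | 2 / 2 | 0.05 | 20 / 40 | 80 / 20 |
| `pink1_usp14_rescue` | 500 | 26.2 | 2 / 2 | 0.05 | 20 / 40 | 80 / 20 |

Activity per day (wild type), the four periods, and the rescue's retained
long period are reported values; everything else is calibration with the
following rationale. Wild-type bout means give ≈ 144 min of day sleep and
≈ 480 min of night sleep — a day-active fly with consolidated night
sleep. Ramp strength 2 makes *most* (not all) flies score positive
anticipation on a single analysis day, as described for controls. The
Pink1 mutant is given qualitative directions only: halved activity, no
anticipation ramps, a higher arrhythmic fraction, and longer/fewer bouts
in both phases (more total sleep, less fragmented); its day/night
wake contrast (wake 60 vs 10 min means) is what lets the periodogram read
τ from the rhythmic subset, as it must for the reported 26.2 h period to
be measurable at all. The rescue preset is wild-type in everything except
the retained 26.2 h period. Sleep bout magnitudes are deliberately
round numbers: the source plots, but does not tabulate, its sleep
quantities, so only directions are calibrated, not values.

The optional `siesta_factor` multiplies the light-phase sleep bout mean
with a triangular peak at mid-light, reproducing the wild-type midday
siesta when set > 1; the default (1) leaves it off because none of the
calibrated comparisons depend on it.

### What the generator does not emulate

Light masking, startle responses at transitions, temperature effects,
aging, social housing, heavy-tailed bout distributions, and positional
micro-movements are all absent. Bout lengths are geometric (memoryless) —
real fly sleep bouts are heavier-tailed — and anticipation is a linear
rate ramp rather than a shaped wake-probability change. Consequently,
passing tests demonstrate that the *pipeline* recovers the parameters of
this model class, not that it would be unbiased on real recordings; in
particular the 5-minute scorer's known inflation by quiet wake (zero-count
wake minutes) is visible here exactly as with real monitors, and the
tests quantify rather than hide it.

## Other conventions and degenerate inputs

* Monitor files: tab-delimited TriKinetics dialect — reading index, date
  (`dd Mon yy`), time (`hh:mm:ss`), a status code, a light-sensor column,
  then 32 channel counts; further columns are ignored. Malformed rows
  name their line number; timestamp gaps are errors, never silently
  interpolated; recordings must start at ZT0.
* Bins are half-open `[t, t + bin)` and 0-based internally; rebinned bins
  take the phase of their first constituent minute; trailing partial bins
  are dropped with a warning, never padded (padding would bias the
  periodogram column means).
* Dead-fly exclusion: a fly with zero counts over the final 24 h is
  excluded from all group statistics (logged); the window is
  configurable and the rule can be disabled — the source protocol does
  not state its censoring rule, so this standard DAM practice is a
  documented default rather than a claim.
* The pipeline computes activity, anticipation and sleep on the rhythmic
  subset and rhythmicity on all flies, matching the figure conventions of
  the study design it follows.

## Problem sizes in the test suite

The suite simulates groups of 25–60 flies for distributional checks,
200 flies for expectation-convergence checks, 1000 noise series for the
null calibration of the periodogram and 1000 replicates for the type-I
calibration of the t and Fisher tests, and seed-averages the
direction-of-effect comparisons over 10 seeds at n = 50 per genotype.
These sizes give Monte-Carlo standard errors comfortably inside the
3-SE bands asserted, while keeping the full suite under a few minutes.

## Known limitations

* The periodogram's "power ≥ 20" cut-off is definition-dependent;
  comparisons with other software should compare definitions first.
* Fisher's exact test is conservative; its realised type-I error is below
  its nominal level by construction.
* The equal-variance Student's t follows the classical convention of this
  literature; with strongly unequal group variances prefer
  `welch = TRUE`.
* Only single-beam count data are supported — no positional or multi-beam
  inference.
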