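---
title: "Quantifying the microstructure of natural reward pacing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying the microstructure of natural reward pacing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rewardpace)
```

## The problem

Male rat sexual behavior and operant sucrose self-administration are both
naturally rewarding behaviors whose *temporal patterning* carries more
information than raw counts. A male copulating with a receptive female
produces runs of mounts and intromissions ("mount bouts") separated by
pauses ("time-outs"), and each ejaculation is followed by a long
post-ejaculatory interval (PEI) before the next series begins. Likewise,
lever pressing for sucrose comes in bouts separated by long pauses, and
the pace of reward collection - not just the total - differentiates
motivational states. `rewardpace` turns the raw data streams of such
experiments (annotated behavior event logs, arena tracking traces,
operant timestamp logs, and brain-section images) into the standard pacing
and motivation measures, and ships synthetic generators with exact ground
truth so every stage is verifiable without animal data.

## Mount-bout segmentation

The ethogram classifies every behavior into three functional classes:

* **copulatory**: mount, intromission, ejaculation;
* **bout-breaking**: behaviors not oriented towards the female
  (non-genital "other" grooming, head not towards female);
* **bout-neutral**: genital grooming, anogenital sniffing, chasing,
  head towards female.

A mount bout is a sequence of one or more copulatory behaviors
uninterrupted by any bout-breaking behavior. Operationally, for every
pair of consecutive copulatory events the segmenter asks whether any
bout-breaking event's interval intersects the *open* gap between the end
of the earlier and the start of the later event. If so, the earlier bout
ends at the end of its last copulatory member, the next bout starts at
the next copulatory event, and the gap is recorded as a time-out. This
interval-intersection rule is the natural generalization of the scoring
rule to interval-valued annotations: a breaking event wholly
contained within (or exactly abutting) a copulatory event cannot split a
bout, because copulatory annotations are mutually exclusive in time and
the open-gap test then fails. Bout-neutral events never split.

Ejaculations are copulatory for bout membership (they terminate the final
bout of their series) but are excluded from mount/intromission counts and
from the intromission ratio, which are reported separately per bout.

Two intervals are never time-outs by construction: the stretch before the
first copulatory behavior of a series, and the PEI. The PEI is taken
strictly as the time from an ejaculation to the next mount or
intromission, regardless of which behaviors fill it - the definition
involves only its two endpoints. A bout can never span an ejaculation
into the next series, because the series partition cuts immediately after
each ejaculation.

### Censoring and degenerate inputs

* No ejaculation in the 30-min test: latency to ejaculation is scored as
  1800 s (the test duration).
* No copulatory behavior at all: latency to first copulatory behavior is
  scored as 1800 s.
* Undefined ratios (no mounts *and* no intromissions) are reported as
  `NA`, never 0; likewise the mean time-out duration of a series with a
  single bout.
* Percent-time budgets divide by the time from test start to the first
  ejaculation (the full 1800 s when none occurred); "non-copulation
  oriented" time is the summed duration of the bout-breaking class.
* Tests invalidated for external reasons (e.g. a non-receptive stimulus
  female) are excluded by flagging them in the design table, never
  inferred from the data.

## Sexual incentive motivation (SIM)

The SIM arena is a 100 x 50 cm rectangle with a 30 x 21 cm virtual zone
in front of each of the two stimulus cages. The subject is "in" a zone
whenever its tracked point of gravity is. Zones are half-open rectangles
(`[x0, x1) x [y0, y1)`) so a point on a shared edge belongs to at most
one zone; each inter-sample interval accrues to the zone of its earlier
sample (left-constant interpolation, matching how trackers export
sample-based statistics), and no sub-sample interpolation of crossings is
attempted. An entry is an out-to-in transition of the membership
sequence, with no minimum-visit filter. The preference score is
`t_female / (t_female + t_male)`, `NA` when the subject visited neither
zone; 0.5 is chance.

## Operant sessions

Under FR1 every active lever press delivers a reward; the software log
carries timestamps of active presses, inactive presses, rewards and the
first receptacle nosepoke after each reward. The summary measures are

* mean reward interval = (time of last reward − time of first reward) /
  (number of rewards − 1), absent with fewer than two rewards;
* the cumulative reward curve in 1-s bins;
* the time to each successive 10% of total rewards.

Under PR the j-th reward requires `r_j = round(5 exp(0.2 j)) − 5`
presses (the exponential progression of Richardson & Roberts: 1, 2, 4,
6, 9, 12, 15, 20, 25, ...). The breakpoint is the requirement of the
last obtained reward. A PR session ends when no further reward is
obtained within 30 min of the previous one; the recorded duration is
then the time of the last reward + 1800 s, or the recorded session end
if the log stops earlier. The mean lever-press interval is (total test
duration) / (number of active presses).

### Press bouts and the interval threshold

Press bouts are runs of presses separated by gaps below an
inter-bout-interval threshold; a gap exactly at the threshold starts a
new bout (a deterministic tie-break). The default threshold is the fixed
10 s adopted for full-data analyses after per-animal scree plots of
ordered interval durations clustered around 10 s. The automatic mode
(`method = "knee"`) reproduces that scree-plot procedure: intervals are
sorted in descending order, both axes are normalized to `[0, 1]` (so the
result does not depend on units), and the elbow is the point of maximum
perpendicular distance to the chord joining the first and last points.

One numerical refinement matters here. The elbow point itself is almost
always the largest within-bout interval or the smallest between-bout
interval - an *observed* interval. Returning that value verbatim would
make the `>=` tie-break split (or merge) the very gap the elbow sits on,
so the returned threshold is instead the midpoint of the steepest drop
adjacent to the elbow, with steepness judged on the log scale because
interval durations live on a multiplicative scale (a 40 s to 20 s drop
within the long-interval population is less of a cliff than 6 s to 1 s).
The threshold then falls strictly between the two interval populations
whenever they are separable. Degenerate input (all intervals equal) has
no knee; the fixed fallback is returned with a warning. When thresholds
are derived per animal they should be pooled under vehicle conditions
only, as treatment may alter pacing.

## c-Fos particle counting

Section images are reduced to 8-bit grayscale, binarized at one global
threshold shared across an experiment (the threshold is a config input -
it is chosen once on a range of high- and low-density images and is not
printed anywhere, so it cannot be a package constant), and counted
inside fixed ROI boxes, one per region per hemisphere, identical in
shape and size across animals. Particles are 8-connected components
(the reference tool's default) filtered to area 5-2000 px and
circularity 0.5-1.0, where circularity is `4 pi area / perimeter^2`
capped at 1. The perimeter is the chain-code length of the Moore-traced
boundary (1 per axial step, sqrt(2) per diagonal step). This estimator
is not bit-identical to the reference tool's, and no parity is claimed;
on rendered disks of radius >= 3 px it yields circularity >= 0.85, and
on a 1-px-wide line < 0.2, so the printed filter window behaves
identically on the shapes that matter. Particles touching the ROI edge
are kept by default (no edge exclusion is stated for the original
analysis); `exclude_edge = TRUE` drops them. Hemisphere counts are
averaged per region; a region with one usable hemisphere is carried
through flagged, not imputed.

## Post-hoc statistics

The omnibus model of such designs (a linear mixed model with
virus x treatment(x condition) fixed effects and a subject random
intercept) is standard software; this package implements the contrast
layer that annotates the figures and leaves the omnibus fit pluggable.
`posthoc_family()` emits paired within-group contrasts (CNO vs vehicle
per virus group) and independent between-group contrasts on the CNO
cells (Gi vs Sham, Gq vs Sham only), Bonferroni-corrected. The family
size is the number of contrasts actually emitted (5 for the full
design) because no explicit family size is printed for the original
analyses; it is overridable. Between-group tests pool variances by
default, with a Welch option, as the original software's default is not
stated. Preference scores are tested against chance with one-sample
t-tests, zone times with paired t-tests, and c-Fos densities with
one-tailed independent t-tests that fall back to a one-tailed
Mann-Whitney U test when an F-test rejects variance equality at 0.05.

## Synthetic generators

Every input stream has a generator that emits data *and* exact ground
truth in the shapes the analysis stages produce, so recovery can be
asserted event-for-event.

* **Copulation** (`simulate_copulation()`): an explicit semi-Markov
  chain over bout / time-out / PEI macro-states - the simplest structure
  whose ground truth is exact for the segmenter. Defaults (all
  overridable, all in seconds): latency to first copulatory behavior
  ~ lognormal(log 60, 0.5); 1 + Poisson(1.5) copulatory events per bout;
  within-bout gaps ~ lognormal(log 8, 0.5); intromission probability
  0.5; ejaculation after 8 intromissions; time-outs
  ~ lognormal(log 40, 0.5); PEI ~ lognormal(log 300, 0.3). These place
  the medians at figure-scale magnitudes for sexually experienced male
  rats (a handful of series per 30-min test, time-outs of tens of
  seconds, PEIs of minutes) without claiming fidelity to any animal.
  Every generated time-out contains a bout-breaking filler event
  strictly inside the gap - otherwise it would not be a time-out by
  definition - and within-bout gaps may contain bout-neutral fillers,
  which must never split. `timeout_mult` and `pei_mult` inject
  per-design-cell effects for validating the statistics layer.
* **Operant** (`simulate_operant()`): press bouts of 1 + Poisson(4)
  presses; within-bout intervals are a nosepoke latency
  (~ lognormal(log 1, 0.3)) plus lognormal(log 1.5, 0.4); between-bout
  pauses ~ lognormal(log 60, 0.4), so the two interval populations are
  stochastically well separated, which is what makes a bout criterion
  meaningful at all. FR1 honors the trial structure (reward at the
  press, nosepoke before the next press); PR replays the requirement
  schedule and the 30-min stop rule.
* **Arena** (`simulate_trace()`): epochs of dwelling at the female zone,
  the male zone, or roaming, drawn with set probabilities (defaults
  0.45/0.20/0.35, a female-directed preference), exponential dwell times
  (mean 15 s), and a small reflected random walk (step SD 0.5 cm per sample, giving mean speeds of a few cm/s) within the current
  region, sampled at 10 Hz for 600 s. The generator's per-sample state
  sequence is its occupancy ledger.
* **Images** (`simulate_section_image()`): non-touching bright disks
  (radius 5-15 px) on a noisy dark background, with the rendered pixel
  area of each disk as ground truth.

What these generators deliberately do *not* emulate: annotation noise
and observer disagreement, tracker jitter and smoothing, satiety drift
within a session, staining artifacts, or touching cells. Passing
recovery tests therefore demonstrates that the analysis stages implement
their definitions exactly, not that they are robust to every failure
mode of real recordings.

## Verification scales

The test suite asserts, among others: segmenter-vs-brute-force
equivalence on 10,000 randomized small logs; exact bout/time-out
recovery on 1,000 simulated copulation tests (tolerance 1e-9 s);
automatic-threshold recovery of press-bout partitions on >= 95% of 200
simulated sessions; planted-disk counts recovered exactly across
separating thresholds; a one-sample t type-I error within 0.05 +/- 0.01
over 10,000 null replicates; and detection of a 1-SD within-subject
slowing of time-outs (injected through the generator, measured through
the full pipeline, n = 12 subjects) in >= 80% of 500 replicate
experiments. For the power check the effect multiplier is calibrated at
run time so that the realized standardized effect equals 1: the
multiplier implied by the null SD of paired differences is attenuated by
the 1800-s test bound and inflated variance under treatment, so the
calibration measures the realized effect at two candidate multipliers
and interpolates. These problem sizes keep the whole suite comfortably
within a desktop run while leaving the Monte-Carlo tolerances
meaningful.

## Known limitations

* The bout rule is only as good as the annotation: logs scored as point
  events lose the interval-intersection subtleties (a point breaking
  event exactly at a copulatory event's end does not split).
* ImageJ parity for perimeters is approximate by design; filter
  behavior at the circularity boundary 0.5 may differ for pathological
  shapes.
* The PR stop-rule duration convention (last reward + 1800 s) is one of
  several defensible readings of a session-end rule stated in
  behavioral, not logging, terms.
* The omnibus mixed model is out of scope; the contrast layer assumes
  it has been run (or that the user accepts uncorrected families of 5).
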