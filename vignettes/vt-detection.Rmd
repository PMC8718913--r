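---
title: "Automated ventilatory threshold detection: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automated ventilatory threshold detection: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vtdetect)
```

## The problem

An incremental (ramp) cycle test yields breath-averaged gas-exchange
channels — oxygen uptake (VO2), carbon-dioxide output (VCO2), minute
ventilation (VE) — on a 10-s grid. Two physiological inflections partition
the test into intensity domains. At the first ventilatory threshold (VT1),
bicarbonate buffering of accumulating lactate adds non-metabolic CO2, so
VCO2 and VE begin rising out of proportion to VO2. At the respiratory
compensation point (VT2), falling blood pH drives ventilation out of
proportion even to VCO2. Visual identification of these points needs two to
three trained readers and strict consensus rules; this package automates it
and provides the statistics used to validate the automation against visual
reads.

## Detection model

Each threshold is located by two methods whose results are averaged:

* **VT1**: the excess-CO2 signal `ExCO2 = VCO2^2/VO2 - VCO2` and the
  V-slope signal (the VCO2 sequence, whose slope against VO2 crosses 1 at
  VT1);
* **VT2**: the excess-ventilation signal `ExVE = VE^2/VCO2 - VE` and the
  V-slope signal for VT2 (the VE sequence against VCO2).

Because work rate, and with it VO2, increases monotonically during a ramp,
the time ordering of samples and the x-ordering of the V-slope scattergram
agree; the changepoint detector therefore consumes the y-sequence in time
order rather than a resampled scattergram. No smoothing is applied before
deriving signals — the 10-s cart averaging is treated as sufficient — but
`smooth_series()` offers an optional centred rolling mean for noisier data.

On each signal, restricted to a percentile window of the post-warm-up
samples (30th–80th for VT1, 50th–100th for VT2, each half of the signal),
a single changepoint is placed at the argmin over split points `k` of

```
cost(y[1..k-1]) + cost(y[k..n]),   cost(z) = |z| * log(max(var_mle(z), 1e-12))
```

with `var_mle` the maximum-likelihood variance about the segment's own
mean. This is the Gaussian "change in standard deviation" statistic; using
the per-segment mean makes both mean shifts and spread changes register,
which matters because the dispersion of the gas-exchange signals grows
after the thresholds. The two method times are averaged and snapped to the
sample grid, and **all** channel values are read at that one instant:
averaging channel values taken at two different instants would produce a
physiologically inconsistent tuple (a VO2 from one moment, a VE from
another).

### Quality control

An estimate is flagged *indeterminate* when either sub-detection's split
fails to undercut the no-split cost by more than the tolerance (1e-9), or
when the combined time falls at or before 240 s — the onset of the first
credible stage, mirroring the rule used for visual reads that a threshold
during or immediately after warm-up is not believable. The pipeline still
reports the argmin in that case (a candidate is always produced), leaving
rejection to the caller.

Three-evaluator annotations are combined by a cascade
(`combine_annotations()`): any indeterminate call rejects the test; three
values within one exercise stage (50 W) or within 15% of their mean are
averaged; failing that, a pair within 15% of each other is averaged and the
outlier dropped; no agreeing pair rejects the test; and a consensus below
75 W (or at/below 240 s) is rejected. The 50-W stage tolerance is kept as
stated even though the nominal protocol increments by 25 W, because the
rule is conventionally quoted that way. Agreement is judged on work rates;
the rule wording is in watts, and work rate is what exercise prescriptions
use.

## Tunable parameters

| parameter | default | units | rationale |
|---|---|---|---|
| `min_seg` | 3 | samples | variance needs 2 points; a third adds stability at 10-s sampling |
| changepoint `tolerance` | 1e-9 | cost units | split must strictly beat no-split |
| trim windows | 0.30–0.80 / 0.50–1.00 | sample fraction | where VT1/VT2 plausibly lie in a ramp |
| `min_time` | 240 | s | first credible stage onset |
| peak `window` | 3 | samples (30 s) | conventional peak-VO2 averaging window |
| TOST `bound` | 25 | W | one stage's worth of disagreement treated as equivalent |
| `stage_tolerance` / `relative_tolerance` | 50 W / 0.15 | — | evaluator-agreement rules |

Stage boundaries are half-open: the work-rate formula
`warmup_watts + increment*(1 + floor((t - warmup - eps)/stage_duration))`
assigns a boundary instant to the earlier stage, so at exactly 240 s the
nominal protocol still reads 75 W and "a threshold after 4 min" means
"strictly after 240 s". Timestamps mark the *end* of each 10-s averaging
interval (first sample at 10 s); when the mean of two method times falls
between grid samples, it rounds half *up* to the later sample — a
deterministic choice that is conservative for threshold-based
prescriptions.

## The synthetic generator

`simulate_test()` emulates a progressive test: the protocol's work rate
drives a first-order VO2 response (`vo2_rest + vo2_gain * W`, time constant
`tau` = 30 s); VCO2 is piecewise-linear in that metabolic drive with a
continuous slope break 0.85 → 1.20 at `vt1_frac * peak_vo2`; VE is
piecewise-linear in noise-free VCO2 with a continuous gain break 27 → 40 at
the VCO2 value reached when the drive crosses `vt2_frac * peak_vo2`;
independent Gaussian noise (SDs 0.05 / 0.05 / 2.0 L/min) is added per
channel. Defaults plant VT1 at 58% and VT2 at 79% of a 3.3 L/min peak VO2 —
the typical whole-cohort positions for incremental cycle tests — with age
41 y, mass 76.8 kg, and HR linear in work rate capped at the age-predicted
maximum `207 - 0.67*age`.

Measured VO2 is truncated at `peak_vo2` while the metabolic drive keeps
rising through the final stage (the test ends one stage after the drive
reaches peak). Driving VCO2 and VE from the *untruncated* drive makes the
end of the test physiologically right: a VO2 plateau with RER still
climbing through 1.0, which is exactly the maximal-effort signature the
4-of-5 criteria look for. Had VCO2 been tied to truncated VO2, RER could
never reach 1.0 at these defaults (its endpoint would be
`1.20 - 0.35 * 0.58 ≈ 0.997`).

Per-test seeds in `recovery_experiment()` derive deterministically from the
base seed and the test index, so batches are reproducible and individual
tests re-creatable in isolation.

What the generator does **not** model: breath-by-breath variability and
its irregular timing, cardiovascular drift, protocol non-compliance,
sensor drift or calibration error, and the smoothly accelerating
(supra-linear) post-threshold rise of real gas-exchange data — its knots
are deliberately piecewise-linear so the planted truth is unambiguous.
Passing recovery tests on this generator therefore shows the pipeline is
internally consistent and deterministic, not that it reproduces human
reads on real tests.

## Known limitations

The variance-cost changepoint has a **window-centre attraction on ramp
signals**. For a noise-free straight line the two-segment cost
`n1*log(var1) + n2*log(var2)` is minimised exactly at the middle of the
window (each segment's variance scales with its squared length); a mild
slope change such as 0.85 → 1.20 moves the argmin only part of the way
from the window centre toward the knot. Two consequences on the synthetic
ramps, quantified by `recovery_experiment()` and the acceptance script:

* detected thresholds sit systematically *late* relative to the planted
  knots (VT1 more so than VT2, because the planted VT1 falls near the left
  edge of its 30th–80th percentile window while the cost attracts toward
  the centre);
* detected relative intensities are correspondingly biased high.

The bias is a property of the statistic-plus-signal combination, not of
the implementation: the detector matches an independently coded
brute-force minimiser of the same cost exactly, localises planted mean or
spread *steps* to within two samples, and always orders VT1 before VT2 on
the synthetic cohort. On real data the post-threshold rise is
supra-linear, which sharpens the variance contrast at the knee and is the
regime the method was designed for; on near-linear data the estimates
should be read as upper bounds. Users wanting knot localisation on
piecewise-linear data should fit segmented regressions instead — that is a
different statistic with different failure modes, and deliberately out of
scope here.

Other limitations: treadmill protocols and real-time (during-test)
detection are unsupported; end-tidal pressures are carried and displayed
but not used for detection; no lactate-based confirmation of the
thresholds is attempted.

## Numerical conventions

Zero-variance segments are floored at 1e-12 before the log; changepoint
ties break to the smallest index; the TOST with zero-variance differences
reports the smallest positive double as its p value when the mean is
strictly inside the bounds and 1 otherwise; the ICC interval uses the
F-distribution method and degenerates to a point at perfect agreement;
differences throughout are automated − visual (configurable by argument
order); the limits-of-agreement multiplier is the classic 1.96, not a
t quantile; SDs of differences use the n−1 denominator. Problem sizes in
the shipped checks — 100-test recovery batches, 200-sequence oracle
comparisons, 50-dataset statistical cross-checks — were chosen to make the
Monte-Carlo rates stable at the asserted tolerances.
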