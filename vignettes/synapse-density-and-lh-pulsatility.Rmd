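---
title: "Quantifying synaptic density on GnRH dendrites and LH pulsatility"
author: "synpulse"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying synaptic density on GnRH dendrites and LH pulsatility}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(synpulse)
```

GnRH neurons drive pituitary LH secretion in two modes: episodic pulses
(roughly every 15 minutes in ovariectomized mice) and a prolonged
preovulatory surge. Their unusual bipolar morphology - a soma-proximal
dendritic zone plus a long blended dendrite/axon ("dendron") projecting to
the median eminence - raises the question of where the synaptic input that
drives each mode arrives. This package implements the two computational
procedures needed to study that question on a desk: (i) calling synapses in
expansion-microscopy image volumes by calibrated intensity-profile overlap
and converting the calls into synaptic densities per unit dendrite length,
and (ii) identifying LH pulses in tail-tip bleed series by the
nadir-to-peak increment rule, classifying surges, and comparing groups.
Because the original microscopy volumes and bleed series are not deposited,
both halves come with synthetic generators that emulate the stated
acquisition conditions and carry exact ground truth, so every step can be
validated by parameter recovery.

## The synapse-calling model

### Units and the expansion factor

Expansion microscopy swells tissue isotropically so that a confocal
microscope resolves ~70 nm structures. Every length therefore exists in two
frames: pre-expansion (biological) and post-expansion (imaged). We take the
linear factor `E = 4.2` as canonical, derived from the printed proximal
segment pair (60 um pre / 252 um post); the same factor maps the distal
segment (15 / 63 um) exactly. The printed side-on threshold pair
(0.23 / 0.95 um) implies `E ~ 4.13` and is treated as a rounded report, not
a different calibration; `convert_expansion()` recovers 0.23 and 0.42 um
from 0.95 and 1.75 um at 2-decimal rounding under `E = 4.2`. All thresholds
are applied in pre-expansion units and post-expansion values derived by
multiplication, so `overlap_post / overlap_pre = E` holds exactly.

### What counts as a synapse

With only a cytoplasmic fill (channel 1) and a pan-presynaptic marker
(channel 2), apposition is necessary but not sufficient for a synapse. The
decision statistic is the overlap of the two channels' relative-fluorescence
line profiles across the contact:

1. each candidate bouton is viewed in 3D and scanned either **side-on**
   (in-plane, across the contact) or **face-on** (along the optical z axis);
2. both channels are normalized to their own maximum within the scan
   window;
3. each channel contributes the contiguous interval around its global peak
   where intensity is at least 0.5 - the full-width-at-half-maximum (FWHM)
   support, with boundaries linearly interpolated;
4. the overlap is the length of the intersection of the two supports
   (zero when disjoint).

The FWHM-support convention is our operationalization: the source material
shows "overlap" on relative-intensity plots without a formula, and half-max
support is the standard width convention that reproduces the published
no-overlap examples as zero. When a channel is multimodal only the interval
around its global peak is used (with a warning), keeping the statistic
local to the apposition.

Thresholds are **calibrated**, not assumed: profiles from appositions
independently confirmed as synapses by paired pre/post-synaptic markers
(VGAT/gephyrin in the original design; generator ground truth here) define
the floor of confirmed-synapse overlaps, separately for side-on (25
profiles) and face-on (12 profiles) geometries. `calibrate_thresholds()`
takes the minimum overlap per geometry; `classify_apposition()` then calls
a synapse only when an overlap **strictly exceeds** the floor. Strictness
matters at the boundary: an apposition overlapping by exactly the threshold
is not a synapse, and a bouton of exactly the 0.4 um minimum diameter is
not a candidate.

The orientation rule is geometric: with `a` the axis from the dendrite
surface point to the punctum centroid, an angle to z of at most 45 degrees
selects face-on (the boundary included), otherwise side-on. One deliberate
refinement: when the centroid lies exactly on the surface point - which is
the generator's definition of a synapse - the surface vector is degenerate,
so the radial axis-to-centroid direction (its limit) is used instead;
side-on is the default only when both are degenerate.

### From calls to densities

Densities are reported per 10 um of dendrite over fixed segment lengths
(60 um proximal, 15 um distal, pre-expansion). Two denominator conventions
exist: `all_segments` divides total contacts by all dendrite length
counted, `contacted_only` by the length of segments with at least one
contact. Only the contacted-only arithmetic reproduces the published distal
density (10 x 330 / (112 x 15) = 1.96 -> 2.0), while the proximal zone
prints 0.8 either way; `contacted_only` is therefore the default and every
report states its `denominator_mode`. The distal:proximal fold ratio is
computed on the 1-decimal displayed densities (2.0 / 0.8 = 2.5), matching
how a reader derives it from the printed table; the unrounded ratio with
mixed denominators would differ, which is why the report carries both the
exact and displayed densities. Because the averaging unit behind the
published standard errors (per-animal, per-dendrite, or pooled) is not
stated, dispersion is not a reproduction target here.

## The synthetic volume generator

`generate_exm_volume()` builds what the quantification expects to see:

* a dendrite as a filled tube of radius 0.3 um pre-expansion (a ~0.6 um
  calibre process) around a straight - optionally gently curved -
  centerline;
* presynaptic puncta as isotropic Gaussian blobs. A punctum of "diameter"
  `d` is rendered with sigma `d*E / (2 * FWHM)`, i.e. the stated diameter
  is twice the blob's FWHM; diameters are lognormal with mean 0.8 um and sd
  0.15 um pre-expansion, comfortably above the 0.4 um candidate filter;
* **synapses** with centroids exactly on the membrane and **decoys** pushed
  radially outward by `decoy_gap` (default 1.0 um pre-expansion), the
  generator's model of apposing-but-unconnected boutons;
* Poisson counts at the study densities (defaults 2.0 synapses/10 um
  distal, 0.8 proximal; decoys 2.0/10 um);
* imaging at 0.1 um lateral pixels and the 600 nm focus interval, blurred
  by an anisotropic Gaussian PSF with sigma 0.07 um laterally (the ~70 nm
  effective resolution treated as the lateral scale) and 0.3 um axially,
  then additive Gaussian noise (sd 0.01 relative to unit punctum peak)
  clipped at zero.

Placements and noise draw from separate seeded sub-streams, so changing
only the noise level leaves the ground truth bit-identical - the property
that makes recovery testing clean. Detection
uses a threshold of 6.25% of the channel maximum because, for blobs
rendered with diameter = 2 FWHM, the 6.25% iso-surface has exactly the
nominal diameter; the threshold is floored at median + 6 robust sigma
(estimated as the 84.1th percentile minus the median, which tolerates
zero-clipped noise), so an empty channel yields no detections.

What the generator does **not** emulate, and what passing recovery tests
therefore cannot certify on real data: gelation distortion or anisotropic
expansion (expansion is one scalar), crossing or tangled processes (one
dendrite per volume), spatial clustering of innervation (counts are
Poisson; the published 53% contacted / 2.0 per 10 um distal pair hints at
clustered inputs, but no clustering model is given, so none is invented),
immunolabelling noise structure, and chromatic offsets. The recovery
acceptance (sensitivity and specificity >= 0.9 against truth over 20
volumes, thresholds calibrated on 25 side-on / 12 face-on synthetic
confirmed synapses) validates the *pipeline logic*, not those tissue
effects.

```{r recovery, eval = FALSE}
gen <- generate_exm_volume(exm_params(zone = "distal", seed = 1))
cal <- calibrate_thresholds(side_profiles, face_profiles, 4.2)
calls <- quantify_volume(gen$volume, gen$centerline, cal,
                         dendrite_radius = 0.3)
```

## The LH secretion model

`generate_pulsatile()` uses the minimal standard description of episodic
secretion: instantaneous boluses cleared mono-exponentially,

    LH(t) = baseline + sum_i A_i * 2^(-(t - t_i) / halflife),  t >= t_i

with inter-event intervals Gamma(shape 8, mean 15 min) - near-regular, as
the pulse generator is - bolus amplitudes lognormal with mean 3 ng/ml (CV
0.2), baseline 0.5 ng/ml, clearance half-life 10 min, sampling every 3 min
for 120 min, multiplicative lognormal assay noise (CV 0.05 by default) and
a 0.02 ng/ml assay floor. The half-life and the amplitude CV are simulator
conventions, not physiological claims; the amplitude is defined as the
bolus height above the pre-event level precisely so that it is commensurable
with the analyser's peak-minus-nadir amplitude. The suppressed-pulse state
is emulated phenomenologically by lowering the bolus amplitude and event
rate. `generate_surge()` produces the four-sample surge design (16:00
baseline, 19:00-21:00) as a smooth rise-and-decay bump
`(1 - exp(-u/rise_tau)) * exp(-u/fall_tau)` from a 17:30 onset, peaking
around 6 ng/ml; suppressed mode returns baseline at all samples.

## The pulse-identification rule

A pulse is an increment from nadir to peak strictly over 25%,
`100 * (peak - nadir) / nadir`. Neither "nadir" nor "peak" is formally
defined in the source; we fix them with the sequential sweep that matches
standard endocrine pulse-counting practice:

* the running nadir is the minimum observed since the last confirmed peak,
  initialized at the first sample;
* candidate peaks are local maxima (>= both neighbours; the final sample
  qualifies against its inner neighbour; the first sample may only serve as
  a nadir, because a pulse needs an observed rise; equal-valued consecutive
  maxima resolve to the earliest);
* a qualifying increment confirms a pulse and restarts the nadir search
  after the peak;
* a nadir below the detectability floor (0.02 ng/ml) cannot anchor a pulse,
  which also guards the division.

This makes the published criterion a well-defined algorithm, and an
exhaustive property test verifies that the sweep equals a brute-force
search over all (nadir, subsequent-local-maximum) chains for every series
up to length 12 over value grids. The criterion is relative, so calls are
scale-invariant; an additive shift can only shrink increments, so the call
count is non-increasing in baseline elevation - both tested.

Summaries report the pulse count, frequency per hour over the sampled
duration, mean peak-minus-nadir amplitude (missing, not zero, when no
pulses are called), mean LH and inter-peak intervals. One quantitative
limitation is intrinsic to 3-minute sampling of a hormone with a 10-minute
half-life: the sampled peak captures on average
`E[2^(-U/h)], U ~ Uniform(0, 3)` = 90% of a bolus, and the elevated
inter-pulse nadir (the decaying tail of earlier pulses) loses a further few
tenths of a ng/ml between the nadir sample and the peak sample. Recovered
mean amplitudes therefore sit, by construction, noticeably below the
generating bolus amplitude even at low noise - the acceptance script
measures exactly this bias - whereas inter-pulse-interval recovery is
unbiased. Surge classification (first sample as baseline, surge iff the
later maximum exceeds 2x baseline and an absolute 1 ng/ml floor) is an
explicit convention of this package; the raw fold rise is always reported
so users can re-threshold.

## Statistics

Two-group comparisons of pulse amplitude and frequency use the
Mann-Whitney U test via `stats::wilcox.test`: exact (full enumeration) when
both groups have at most 8 untied values, the tie-corrected normal
approximation otherwise, without continuity correction so that identical
groups give p = 1. An exhaustive permutation oracle confirms the exact
branch in the test suite. Families of p-values are adjusted by the
Holm-Sidak step-down (`1 - (1 - p_(j))^(m - j + 1)` with the running
maximum), which base R's `p.adjust` does not provide. Repeated-measures
ANOVA over surge time courses is deliberately out of the tested core - it
is an off-the-shelf procedure available from any standard implementation.

## Problem sizes and numerical conventions

The test suite and the analysis scripts run everything at sizes a laptop
handles comfortably: recovery uses 20 distal 15-um volumes (plus the
calibration volumes) at the full 0.1 um / 0.6 um voxel grid; coarser
0.2 um grids are used for pure determinism and I/O checks; pulse-recovery
acceptance uses 20 two-hour series; the exhaustive sweep-oracle
equivalence enumerates ~12,000 short series. Tie-breaks are fixed
throughout: earliest peak on equal maxima, earliest minimum as nadir,
lower arc length on equidistant projections, the 45-degree orientation
boundary to face-on, and strict inequalities at every published threshold.
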