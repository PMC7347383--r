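# synpulse

Desk-scale tools for two questions about GnRH neurons, the final output
cells of the fertility network: **where on the neuron do synaptic inputs
land**, and **how is the resulting LH secretion patterned in time**?

GnRH neurons are bipolar: a soma with short proximal dendrites, and a long
blended dendrite/axon (the "dendron") running to the median eminence. The
density of presynaptic contacts differs between these domains, and the two
modes of LH output - episodic pulses roughly every 15 minutes in
ovariectomized mice, versus the prolonged preovulatory surge - are
controlled from different domains. `synpulse` implements the computational
machinery for both measurements, aimed at neuroendocrinologists and image
analysts who want the procedures as tested, reusable code:

* **Expansion-microscopy synapse quantification.** Tissue expanded ~4.2x
  and imaged confocally (600 nm z-steps) shows a cytoplasmic fill and a
  pan-presynaptic marker. An apposing bouton (diameter > 0.4 um,
  pre-expansion) is called a synapse when the full-width-at-half-maximum
  supports of the two channels' relative-fluorescence line profiles
  overlap by more than a calibrated threshold θ - side-on (in-plane scan)
  and face-on (z scan) geometries carry separate thresholds, calibrated as
  the minimum overlap over profiles from marker-confirmed synapses
  (0.23 um and 0.42 um pre-expansion in the original calibration).
  Synaptic density is reported per 10 um of dendrite over 60 um proximal /
  15 um distal segments.
* **Synthetic volume generator.** Tube dendrite + Gaussian puncta placed
  on the membrane (synapses) or offset from it (decoys), PSF blur, noise,
  and exact ground truth - so detection, apposition pairing, orientation
  choice, overlap measurement, calibration and density reporting are all
  validated by parameter recovery.
* **LH pulse analysis.** The validated tail-tip criterion: a pulse is an
  increment from nadir to peak strictly over 25%,
  `100·(peak − nadir)/nadir`, implemented as a sequential sweep with a
  running nadir; plus per-animal summaries (frequency, peak-minus-nadir
  amplitude, mean LH), a fold-rise surge classifier, and an episodic
  secretion simulator (boluses + exponential clearance) with ground-truth
  event times.
* **Statistics.** Mann-Whitney U (exact for small untied groups) and
  Holm-Sidak adjustment, assembled with the density and pulse tables into
  a single report.

## Worked example

Feed the published apposition-table counts through the density arithmetic:

```r
library(synpulse)
prox <- density_from_counts(38, 36, 183, 60, zone = "proximal",
                            denominator_mode = "all_segments",
                            expansion_factor = 4.2)
dist <- density_from_counts(211, 112, 330, 15, zone = "distal",
                            denominator_mode = "contacted_only",
                            expansion_factor = 4.2)
print(prox); print(dist)
build_report(list(prox, dist))$density_ratio_distal_over_proximal
```

```
proximal dendrites (60 um segments, n = 38):
  % with contact: 95%   contacts: 183   density: 0.8 /10 um (all_segments)
distal dendrites (15 um segments, n = 211):
  % with contact: 53%   contacts: 330   density: 2.0 /10 um (contacted_only)
[1] 2.5
```

The distal dendron carries 2.0 synapses per 10 um against 0.8 proximally -
the 2.5-fold difference that makes the dendron the most densely innervated
compartment. Now simulate a two-hour pulse bleed and recover the events:

```r
sim <- generate_pulsatile(pulsatile_params(seed = 7))
calls <- detect_pulses(sim$series)
summarize_pulses(calls, sim$series)
round(sim$truth$event_times, 1)
```

```
6 pulses (3.00 /h), mean amplitude 2.24 ng/ml, mean LH 2.14 ng/ml
[1]  28.3  36.8  55.4  81.0  94.5 112.7
```

All six secretion events are called (each peak lands on the first sample
after its event). The recovered amplitude sits below the 3 ng/ml generating
bolus because 3-minute sampling of a hormone with a 10-minute half-life
catches each peak slightly late and each nadir slightly high - see the
methods vignette for the arithmetic of that bias.

## Analysis workflow

The `analysis/` scripts run the whole study pipeline end to end, writing
tables under `results/` (large image binaries under `scratch/`):

1. `01_simulate_exm.R` - simulate proximal and distal segments with truth;
2. `02_quantify_synapses.R` - calibrate thresholds (25 side-on / 12
   face-on confirmed synapses), quantify every segment, reproduce the
   published table arithmetic;
3. `03_simulate_lh.R` - simulate pulse bleeds (normal and suppressed
   groups) and four-sample surge series;
4. `04_pulse_analysis.R` - pulse calls, summaries, Mann-Whitney +
   Holm-Sidak comparisons, surge incidence;
5. `05_report.R` - assemble `results/report.json` / `report.md`.

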