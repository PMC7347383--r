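#!/usr/bin/env Rscript
# Step 3: simulate tail-tip LH bleed series. Pulse experiments: OVX-like
# animals sampled every 3 min for 2 h, a "saline" group at the normal pulse
# physiology (~3 ng/ml boluses every ~15 min) and an "inhibited" group with
# the suppressed phenotype (sparser, ~0.5 ng/ml boluses on a lowered
# baseline). Surge experiments: OVX+E+P-like animals sampled at 16:00,
# 19:00, 20:00 and 21:00, a control group surging from ~17:30 and a
# suppressed group held flat.

library(synpulse)
dir.create("results/lh", recursive = TRUE, showWarnings = FALSE)

n_per_group <- 6

pulse_series <- data.frame(); pulse_truth <- list()
for (i in seq_len(n_per_group)) {
  id <- sprintf("saline_%02d", i)
  g <- generate_pulsatile(pulsatile_params(seed = 100 + i), animal_id = id)
  pulse_series <- rbind(pulse_series, g$series)
  pulse_truth[[id]] <- g$truth
}
for (i in seq_len(n_per_group)) {
  id <- sprintf("inhibited_%02d", i)
  g <- generate_pulsatile(pulsatile_params(mean_ipi = 40, bolus_amp_mean = 0.5,
                                           baseline = 0.3, seed = 200 + i),
                          animal_id = id)
  pulse_series <- rbind(pulse_series, g$series)
  pulse_truth[[id]] <- g$truth
}
write_lh_series(pulse_series, "results/lh/pulse_series.csv")
jsonlite::write_json(pulse_truth, "results/lh/pulse_truth.json",
                     auto_unbox = TRUE, digits = NA)

surge_series <- data.frame()
for (i in seq_len(n_per_group)) {
  surge_series <- rbind(
    surge_series,
    generate_surge(surge_params(seed = 300 + i),
                   animal_id = sprintf("control_%02d", i)),
    generate_surge(surge_params(suppressed = TRUE, seed = 400 + i),
                   animal_id = sprintf("suppressed_%02d", i)))
}
write_lh_series(surge_series, "results/lh/surge_series.csv")

message(sprintf("wrote %d pulse animals and %d surge animals",
                2 * n_per_group, 2 * n_per_group))
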