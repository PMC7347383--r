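#!/usr/bin/env Rscript
# Step 1: simulate expansion-microscopy volumes of GnRH-neuron dendrite
# segments. Two zones are generated at their study geometries: proximal
# dendrite (60 um pre-expansion, sparser innervation) and distal dendron
# (15 um, denser innervation). Each volume carries a known ground truth of
# synaptic (on-membrane) and decoy (offset) presynaptic puncta.
#
# Image volumes are large binaries and go to scratch/exm/; the ground truth
# and centerlines (small text) are duplicated under results/exm/.

library(synpulse)

proximal_seeds <- 1:3
distal_seeds <- 11:16

dir.create("scratch/exm", recursive = TRUE, showWarnings = FALSE)
dir.create("results/exm", recursive = TRUE, showWarnings = FALSE)

manifest <- data.frame()
for (zone in c("proximal", "distal")) {
  seeds <- if (zone == "proximal") proximal_seeds else distal_seeds
  for (s in seeds) {
    gen <- generate_exm_volume(exm_params(zone = zone, seed = s))
    stem <- sprintf("%s_seed%02d", zone, s)
    write_exm_volume(gen$volume, file.path("scratch/exm", paste0(stem, ".tiff")))
    write_swc(gen$centerline, file.path("results/exm", paste0(stem, ".swc")))
    write_exm_truth(gen$truth, file.path("results/exm", paste0(stem, "_truth.json")))
    manifest <- rbind(manifest, data.frame(
      zone = zone, seed = s,
      segment_length_um = if (zone == "proximal") 60 else 15,
      n_true_synapses = length(gen$truth$synapse_positions),
      n_decoys = length(gen$truth$decoy_positions)))
    message(sprintf("%s: %d synapses, %d decoys", stem,
                    length(gen$truth$synapse_positions),
                    length(gen$truth$decoy_positions)))
  }
}
write.csv(manifest, "results/exm/manifest.csv", row.names = FALSE)
message(sprintf("simulated %d segments (%d proximal, %d distal)",
                nrow(manifest), length(proximal_seeds), length(distal_seeds)))
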