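#!/usr/bin/env Rscript
# Step 2: calibrate the overlap thresholds on marker-confirmed synthetic
# synapses (25 side-on, 12 face-on profiles, mirroring the tri-label
# calibration design), then quantify synaptic density on the simulated
# segments from step 1 and compare against each volume's ground truth.
# Also reproduces the published apposition-table arithmetic from its
# printed counts.

library(synpulse)

manifest <- read.csv("results/exm/manifest.csv")

# --- threshold calibration -------------------------------------------------
side <- list(); face <- list()
s <- 101L
while (length(side) < 25 || length(face) < 12) {
  gen <- generate_exm_volume(exm_params(zone = "distal", seed = s))
  pr <- make_calibration_profiles(gen$volume, gen$centerline, gen$truth,
                                  dendrite_radius = 0.3)
  side <- c(side, pr$side); face <- c(face, pr$face)
  s <- s + 1L
}
cal <- calibrate_thresholds(side[1:25], face[1:12], 4.2)
print(cal)
jsonlite::write_json(unclass(cal), "results/calibration.json",
                     auto_unbox = TRUE, digits = NA)

# --- per-segment quantification --------------------------------------------
all_calls <- data.frame()
counts <- list(proximal = integer(), distal = integer())
for (i in seq_len(nrow(manifest))) {
  stem <- sprintf("%s_seed%02d", manifest$zone[i], manifest$seed[i])
  tp <- file.path("scratch/exm", paste0(stem, ".tiff"))
  if (file.exists(tp)) {
    vol <- read_exm_volume(tp)
    cl <- read_swc(file.path("results/exm", paste0(stem, ".swc")))
  } else {  # regenerate deterministically if the binary scratch was cleaned
    gen <- generate_exm_volume(exm_params(zone = manifest$zone[i],
                                          seed = manifest$seed[i]))
    vol <- gen$volume; cl <- gen$centerline
  }
  apps <- suppressWarnings(quantify_volume(vol, cl, cal, dendrite_radius = 0.3))
  n_syn <- sum(apps$is_synapse)
  counts[[manifest$zone[i]]] <- c(counts[[manifest$zone[i]]], n_syn)
  if (nrow(apps)) {
    sel <- apps[, c("arc_length_pre", "orientation", "overlap_pre",
                    "is_synapse")]
    names(sel)[1] <- "arc_length_um_pre"
    all_calls <- rbind(all_calls,
                       cbind(segment = stem, zone = manifest$zone[i], sel))
  }
  message(sprintf("%s: %d appositions, %d synapses (truth: %d)", stem,
                  nrow(apps), n_syn, manifest$n_true_synapses[i]))
}
write.csv(all_calls, "results/synapse_calls.csv", row.names = FALSE)

reports <- list(
  proximal = compute_density(counts$proximal, 60, zone = "proximal",
                             expansion_factor = 4.2),
  distal = compute_density(counts$distal, 15, zone = "distal",
                           expansion_factor = 4.2)
)
print(reports$proximal); print(reports$distal)
jsonlite::write_json(lapply(reports, unclass), "results/density_reports.json",
                     auto_unbox = TRUE, digits = NA)

# --- published-table arithmetic --------------------------------------------
prox_pub <- density_from_counts(38, round(0.95 * 38), 183, 60,
                                zone = "proximal",
                                denominator_mode = "all_segments",
                                expansion_factor = 4.2)
dist_pub <- density_from_counts(211, round(0.53 * 211), 330, 15,
                                zone = "distal",
                                denominator_mode = "contacted_only",
                                expansion_factor = 4.2)
pub <- build_report(list(prox_pub, dist_pub))
message(sprintf("published-counts check: %.1f vs %.1f per 10 um, ratio %.1f",
                prox_pub$density_display, dist_pub$density_display,
                pub$density_ratio_distal_over_proximal))
jsonlite::write_json(list(proximal = unclass(prox_pub),
                          distal = unclass(dist_pub),
                          ratio = pub$density_ratio_distal_over_proximal),
                     "results/table_check.json", auto_unbox = TRUE, digits = NA)
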