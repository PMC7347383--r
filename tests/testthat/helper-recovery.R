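# Shared fixtures for synapse-recovery checks against generator truth.

# Calibration pooled over generator seeds (side-on and face-on
# confirmed-synapse profiles), mirroring the tri-label calibration step with
# its 25 side-on and 12 face-on confirmed synapses.
recovery_calibration <- function(side_n = 25, face_n = 12, seed_start = 101,
                                 params_fn = exm_params) {
  side <- list(); face <- list()
  s <- seed_start
  while (length(side) < side_n || length(face) < face_n) {
    g <- generate_exm_volume(params_fn(seed = s))
    pr <- make_calibration_profiles(g$volume, g$centerline, g$truth,
                                    dendrite_radius = 0.3)
    side <- c(side, pr$side); face <- c(face, pr$face)
    s <- s + 1L
    if (s - seed_start > 60L) break  # safety valve
  }
  calibrate_thresholds(side[seq_len(min(side_n, length(side)))],
                       face[seq_len(min(face_n, length(face)))], 4.2)
}

# Sensitivity/specificity of classified synapse calls against truth.
# A truth punctum counts as called when a classified-synapse apposition
# centroid lies within match_tol um post-expansion (about one punctum
# diameter, to tolerate merged detections of adjacent puncta; still well
# inside the 4.2 um decoy offset, so decoys cannot cross-match).
recovery_confusion <- function(cal, seeds, params_fn = exm_params,
                               match_tol = 3.4) {
  tp <- fn <- tn <- fp <- 0L
  for (s in seeds) {
    g <- generate_exm_volume(params_fn(seed = s))
    apps <- suppressWarnings(
      quantify_volume(g$volume, g$centerline, cal, dendrite_radius = 0.3))
    rec <- g$truth$punctum_records
    for (i in seq_len(nrow(rec))) {
      called <- FALSE
      if (nrow(apps) > 0) {
        d <- sqrt((apps$x - rec$x[i])^2 + (apps$y - rec$y[i])^2 +
                    (apps$z - rec$z[i])^2)
        called <- any(d < match_tol & apps$is_synapse)
      }
      if (rec$label[i] == "synapse") {
        if (called) tp <- tp + 1L else fn <- fn + 1L
      } else {
        if (called) fp <- fp + 1L else tn <- tn + 1L
      }
    }
  }
  list(tp = tp, fn = fn, tn = tn, fp = fp,
       sensitivity = tp / max(1L, tp + fn),
       specificity = tn / max(1L, tn + fp))
}

# Small, fast generator settings for deterministic unit tests (coarser
# voxels keep the arrays tiny; physics otherwise as the defaults).
tiny_exm_params <- function(synapse_rate = 2, decoy_rate = 2, ...) {
  exm_params(segment_length = 6, voxel_xy = 0.2, voxel_z = 0.6,
             synapse_rate = synapse_rate, decoy_rate = decoy_rate, ...)
}
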