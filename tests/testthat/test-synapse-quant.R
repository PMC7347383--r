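# One deterministic volume with explicitly placed, well-separated puncta is
# shared across the detection / apposition / profile tests.
manual_truth <- exm_truth_manual(
  synapse_positions = c(2, 5, 8, 11, 14),
  synapse_azimuths = c(0, pi / 2, pi, 3 * pi / 2, pi / 4),
  synapse_diameters = 0.8,
  decoy_positions = c(3.5, 9.5),
  decoy_azimuths = c(pi / 3, 4 * pi / 3),
  decoy_diameters = 0.8
)
manual_gen <- generate_exm_volume(exm_params(zone = "distal", noise_sd = 0.005,
                                             seed = 2),
                                  truth = manual_truth)

test_that("puncta are recovered at their true centroids and diameters", {
  pn <- detect_puncta(manual_gen$volume)
  expect_equal(nrow(pn), 7)  # 5 synapses + 2 decoys
  rec <- manual_gen$truth$punctum_records
  for (i in seq_len(nrow(rec))) {
    d <- sqrt((pn$x - rec$x[i])^2 + (pn$y - rec$y[i])^2 + (pn$z - rec$z[i])^2)
    expect_lt(min(d), 0.6)  # within one (z) voxel of truth
  }
  # nominal diameter 0.8 um pre-expansion, slight PSF inflation allowed
  expect_true(all(abs(pn$diameter - 0.8) < 0.12))
})

test_that("a channel with no puncta yields an empty detection list", {
  g <- generate_exm_volume(tiny_exm_params(seed = 1, synapse_rate = 0,
                                           decoy_rate = 0))
  expect_equal(nrow(detect_puncta(g$volume)), 0)
})

test_that("the bouton diameter filter is strictly greater-than", {
  pn <- data.frame(x = 1:3, y = 1, z = 1,
                   diameter = c(0.4, 0.400001, 1.2),
                   peak_intensity = 1, voxel_count = 100L)
  kept <- filter_puncta(pn, 0.4)
  expect_equal(kept$diameter, c(0.400001, 1.2))
})

test_that("appositions keep membrane-touching puncta and reject offset ones", {
  pn <- detect_puncta(manual_gen$volume)
  apps <- find_appositions(pn, manual_gen$centerline, 0.3, 4.2)
  # the 5 surface synapses are retained, the 1.0 um (4.2 um post) decoys are not
  expect_equal(nrow(apps), 5)
  rec <- manual_gen$truth$punctum_records
  syn <- rec[rec$label == "synapse", ]
  for (i in seq_len(nrow(syn))) {
    d <- sqrt((apps$x - syn$x[i])^2 + (apps$y - syn$y[i])^2 +
                (apps$z - syn$z[i])^2)
    expect_lt(min(d), 0.6)
  }
  expect_equal(apps$membrane_gap, rep(0, 5))
  # recovered arc-length positions match truth (um pre-expansion)
  expect_equal(sort(apps$arc_length_pre), c(2, 5, 8, 11, 14), tolerance = 0.05)
  # a punctum far from the tube is excluded
  far <- data.frame(x = 30, y = 1, z = 1, diameter = 0.8,
                    peak_intensity = 1, voxel_count = 100L)
  expect_equal(nrow(find_appositions(far, manual_gen$centerline, 0.3, 4.2)), 0)
  expect_error(find_appositions(pn, manual_gen$centerline[1, , drop = FALSE],
                                0.3, 4.2), "at least 2 nodes")
})

test_that("viewing geometry follows the 45-degree rule with the boundary face-on", {
  mk <- function(v) {
    data.frame(x = 10 + v[1], y = 10 + v[2], z = 10 + v[3],
               spx = 10, spy = 10, spz = 10, axx = 9, axy = 10, axz = 10)
  }
  expect_equal(choose_orientation(mk(c(0, 0, 1)))$orientation, "face_on")
  expect_equal(choose_orientation(mk(c(0, 1, 0)))$orientation, "side_on")
  expect_equal(choose_orientation(mk(c(0, 1, 1)))$orientation, "face_on")  # 45 deg
  expect_equal(choose_orientation(mk(c(0, 1, 0.99)))$orientation, "side_on")
  # centroid on the surface point: radial fallback, not a hard default
  on_surface <- data.frame(x = 10, y = 10, z = 10, spx = 10, spy = 10,
                           spz = 10, axx = 10, axy = 10, axz = 9)
  expect_equal(choose_orientation(on_surface)$orientation, "face_on")
  degenerate <- data.frame(x = 10, y = 10, z = 10, spx = 10, spy = 10,
                           spz = 10, axx = 10, axy = 10, axz = 10)
  expect_warning(out <- choose_orientation(degenerate), "degenerate")
  expect_equal(out$orientation, "side_on")
})

test_that("profiles are normalized per channel with the orientation's step", {
  # identical channels -> identical normalized profiles
  blob <- array(0, c(40, 40, 12))
  xg <- (seq_len(40) - 0.5) * 0.1
  zg <- (seq_len(12) - 0.5) * 0.6
  for (k in seq_len(12)) {
    blob[, , k] <- 5 * exp(-(outer((xg - 2)^2, (xg - 2)^2, "+") +
                               (zg[k] - 3.6)^2) / (2 * 0.5^2))
  }
  vol <- structure(list(data = array(c(blob, blob), c(40, 40, 12, 2)),
                        voxel_xy = 0.1, voxel_z = 0.6,
                        expansion_factor = 4.2,
                        channel_names = c("cyto", "presyn")),
                   class = "exm_volume")
  app <- data.frame(x = 2.2, y = 2, z = 3.6, spx = 1.8, spy = 2, spz = 3.6,
                    axx = 1, axy = 2, axz = 3.6, orientation = "side_on")
  prof <- extract_profile(app, vol, half_window = 1.5)
  expect_equal(prof$cyto, prof$presyn)
  expect_equal(max(prof$cyto), 1)
  expect_equal(attr(prof, "step"), 0.1)
  # face-on scans step at the 0.6 um focus interval
  app$orientation <- "face_on"
  proz <- extract_profile(app, vol, half_window = 1.5)
  expect_equal(attr(proz, "step"), 0.6)
  expect_equal(unique(round(diff(proz$position), 9)), 0.6)
  # truncation when the window exits the volume
  app_edge <- app
  app_edge$orientation <- "side_on"
  app_edge$x <- 0.4; app_edge$spx <- 0.2; app_edge$axx <- 0.1
  expect_warning(pt <- extract_profile(app_edge, vol, half_window = 3),
                 "truncated")
  expect_lt(nrow(pt), length(seq(-3, 3, by = 0.1)))
  # a window containing no signal at all is an error
  vol0 <- vol
  vol0$data[31:40, , , ] <- 0
  app_far <- app
  app_far$x <- 3.7; app_far$spx <- 3.4; app_far$axx <- 3.3
  app_far$orientation <- "side_on"
  expect_error(extract_profile(app_far, vol0, half_window = 0.2), "no signal")
})

test_that("half-maximum overlap matches the closed-form Gaussian result", {
  # disjoint supports -> zero overlap (an apposition, not a synapse)
  p0 <- gauss_profile(-1, 1, sd = 0.2)
  expect_equal(compute_overlap(p0, 4.2)$overlap_post, 0)
  # identical channels -> overlap equals the FWHM support length
  p1 <- gauss_profile(0, 0, sd = 0.2)
  expect_equal(compute_overlap(p1, 4.2)$overlap_post,
               2 * 0.2 * sqrt(2 * log(2)), tolerance = 0.005)
  # two unit Gaussians, sd 0.2 um, peaks 0.3 um apart
  p2 <- gauss_profile(-0.15, 0.15, sd = 0.2)
  expect_equal(compute_overlap(p2, 4.2)$overlap_post,
               oracle_fwhm_overlap(-0.15, 0.15, 0.2), tolerance = 0.005)
  expect_equal(compute_overlap(p2, 4.2)$overlap_post, 0.171, tolerance = 0.005)
  # pre/post unit coherence is exact
  ov <- compute_overlap(p2, 4.2)
  expect_equal(ov$overlap_post / ov$overlap_pre, 4.2)
  # a multimodal channel warns and uses the global-peak interval
  pos <- seq(-3, 3, by = 0.01)
  pm <- intensity_profile(pos,
                          cyto = exp(-pos^2 / (2 * 0.2^2)) +
                            0.8 * exp(-(pos - 2)^2 / (2 * 0.2^2)),
                          presyn = exp(-pos^2 / (2 * 0.2^2)))
  expect_warning(ovm <- compute_overlap(pm, 4.2), "multimodal")
  expect_equal(ovm$overlap_post, 2 * 0.2 * sqrt(2 * log(2)), tolerance = 0.01)
})

test_that("calibration takes the floor of confirmed-synapse overlaps", {
  seps <- c(0.40, 0.30, 0.20, 0.10)  # increasing overlap
  profs <- lapply(seps, function(s) gauss_profile(0, s, sd = 0.2))
  cal <- calibrate_thresholds(profs, profs[2], 4.2)
  expect_equal(cal$theta_side, min(cal$overlaps_side))
  expect_equal(cal$theta_side, oracle_fwhm_overlap(0, 0.40, 0.2) / 4.2,
               tolerance = 0.01)
  expect_equal(cal$n_side, 4)
  expect_equal(cal$n_face, 1)
  # singleton calibration: theta is that overlap
  cal1 <- calibrate_thresholds(profs[3], profs[3], 4.2)
  expect_equal(cal1$theta_side, compute_overlap(profs[[3]], 4.2)$overlap_pre)
  # a confirmed synapse with zero overlap invalidates the calibration
  expect_error(calibrate_thresholds(c(profs, list(gauss_profile(-1.5, 1.5, 0.2))),
                                    profs[1], 4.2), "zero overlap")
})

test_that("classification is strict and self-consistent on the calibration set", {
  seps <- c(0.40, 0.30, 0.20, 0.10)
  profs <- lapply(seps, function(s) gauss_profile(0, s, sd = 0.2))
  cal <- calibrate_thresholds(profs, profs, 4.2)
  res <- lapply(profs, classify_apposition, calibration = cal,
                orientation = "side_on")
  ovs <- vapply(res, `[[`, 1, "overlap_pre")
  is_min <- ovs <= min(ovs) + 1e-12
  # the minimal element sits exactly at theta: strict > excludes it
  expect_false(any(vapply(res[is_min], `[[`, TRUE, "is_synapse")))
  expect_true(all(vapply(res[!is_min], `[[`, TRUE, "is_synapse")))
  expect_false(res[[1]]$overlap_pre > res[[1]]$threshold_used)
})

test_that("synapse calls are monotone in the true profile overlap", {
  cal <- calibrate_thresholds(list(gauss_profile(0, 0.35, sd = 0.2)),
                              list(gauss_profile(0, 0.35, sd = 0.2)), 4.2)
  seps <- seq(0.8, 0, by = -0.05)  # presynaptic peak approaching the cyto peak
  ovs <- numeric(length(seps)); calls <- logical(length(seps))
  for (i in seq_along(seps)) {
    r <- classify_apposition(gauss_profile(0, seps[i], sd = 0.2), cal,
                             orientation = "side_on")
    ovs[i] <- r$overlap_pre; calls[i] <- r$is_synapse
  }
  expect_true(all(diff(ovs) >= -1e-9))
  # once a call is made it never reverts as overlap keeps growing
  expect_true(all(diff(as.integer(calls)) >= 0))
})
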