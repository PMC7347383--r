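test_that("equal seeds give bit-identical volumes and truth", {
  g1 <- generate_exm_volume(tiny_exm_params(seed = 3))
  g2 <- generate_exm_volume(tiny_exm_params(seed = 3))
  expect_identical(g1$volume$data, g2$volume$data)
  expect_identical(g1$truth$punctum_records, g2$truth$punctum_records)
  g3 <- generate_exm_volume(tiny_exm_params(seed = 4))
  expect_false(identical(g1$volume$data, g3$volume$data))
})

test_that("ground truth is unchanged when only the noise level changes", {
  g1 <- generate_exm_volume(tiny_exm_params(seed = 5, noise_sd = 0.01))
  g2 <- generate_exm_volume(tiny_exm_params(seed = 5, noise_sd = 0.05))
  expect_identical(g1$truth$punctum_records, g2$truth$punctum_records)
})

test_that("zero rates give an empty truth and a noise-only presynaptic channel", {
  g <- generate_exm_volume(tiny_exm_params(seed = 1, synapse_rate = 0,
                                           decoy_rate = 0, noise_sd = 0.01))
  expect_length(g$truth$synapse_positions, 0)
  expect_length(g$truth$decoy_positions, 0)
  presyn <- g$volume$data[, , , 2]
  expect_lt(max(presyn), 6 * 0.01)  # nothing but clipped Gaussian noise
  expect_true(all(g$volume$data >= 0))
})

test_that("the distal segment images at 63 um post-expansion", {
  g <- generate_exm_volume(exm_params(zone = "distal", synapse_rate = 0,
                                      decoy_rate = 0, noise_sd = 0))
  expect_equal(centerline_length(g$centerline), 15 * 4.2, tolerance = 1e-9)
})

test_that("synapse and decoy counts are Poisson with mean rate x length / 10", {
  n_seeds <- 400
  p <- exm_params(zone = "distal", synapse_rate = 2.0, decoy_rate = 1.0)
  counts <- t(vapply(seq_len(n_seeds), function(s) {
    tr <- generate_exm_truth(exm_params(zone = "distal", synapse_rate = 2.0,
                                        decoy_rate = 1.0, seed = s))
    c(length(tr$synapse_positions), length(tr$decoy_positions))
  }, numeric(2)))
  mu_syn <- 2.0 * 15 / 10  # 3 expected synapses per 15 um segment
  se <- sqrt(mu_syn / n_seeds)
  expect_lt(abs(mean(counts[, 1]) - mu_syn), 3 * se)
  expect_lt(abs(var(counts[, 1]) - mu_syn), 1.0)  # Poisson: var = mean
  mu_dec <- 1.0 * 15 / 10
  expect_lt(abs(mean(counts[, 2]) - mu_dec), 3 * sqrt(mu_dec / n_seeds))
})

test_that("truth geometry: synapses sit on the tube surface, decoys at the stated offset", {
  for (s in 1:5) {
    g <- generate_exm_volume(tiny_exm_params(seed = s))
    rec <- g$truth$punctum_records
    if (!nrow(rec)) next
    R_post <- 0.3 * 4.2
    for (i in seq_len(nrow(rec))) {
      q <- as.numeric(rec[i, c("x", "y", "z")])
      np <- synpulse:::.nearest_on_polyline(g$centerline, q)
      expected <- if (rec$label[i] == "synapse") R_post else R_post + 1.0 * 4.2
      expect_lt(abs(np$dist - expected), 0.6)  # within one (z) voxel
    }
  }
})

test_that("degenerate generator inputs are rejected or flagged", {
  expect_error(generate_exm_volume(exm_params(segment_length = 0.01,
                                              voxel_xy = 0.5)),
               "shorter than one voxel")
  expect_warning(generate_exm_volume(tiny_exm_params(seed = 1,
                                                     decoy_gap = 0.02)),
                 "unresolvable")
  expect_error(exm_params(expansion_factor = 1))
  expect_error(exm_params(decoy_gap = 0))
})

test_that("TIFF + sidecar, SWC and truth JSON round-trip", {
  g <- generate_exm_volume(tiny_exm_params(seed = 8))  # 1 synapse, 2 decoys
  dir <- withr::local_tempdir()
  tp <- file.path(dir, "vol.tiff")
  write_exm_volume(g$volume, tp)
  v2 <- read_exm_volume(tp)
  expect_equal(v2$data, g$volume$data, tolerance = 1e-6)
  expect_equal(v2$voxel_z, g$volume$voxel_z)
  expect_equal(v2$expansion_factor, 4.2)
  expect_identical(v2$channel_names, c("cyto", "presyn"))

  sp <- file.path(dir, "centerline.swc")
  write_swc(g$centerline, sp)
  cl2 <- read_swc(sp)
  expect_equal(unname(cl2), unname(g$centerline), tolerance = 1e-6)

  jp <- file.path(dir, "truth.json")
  write_exm_truth(g$truth, jp)
  t2 <- read_exm_truth(jp)
  expect_equal(t2$synapse_positions, g$truth$synapse_positions)
  expect_equal(t2$punctum_records$label, g$truth$punctum_records$label)
  expect_equal(t2$punctum_records$x, g$truth$punctum_records$x)
})
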