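# Synthetic expansion-microscopy volumes: a tube-shaped dendrite (cytoplasmic
# fill, channel 1) surrounded by Gaussian presynaptic puncta (channel 2) at
# known synaptic (on-membrane) and non-synaptic (offset) placements, blurred
# with an anisotropic PSF and sampled on the confocal voxel grid.

#' Parameters for the synthetic expansion-microscopy generator
#'
#' Defaults emulate the imaging conditions of the quantification this package
#' targets: ~4.2x expanded tissue imaged at 0.1 um lateral pixels with a
#' 0.6 um z-step (600 nm focus interval), an effective lateral resolution of
#' order 70 nm (psf_sigma_xy = 0.07 um post-expansion), dendrite segments of
#' 60 um (proximal dendrite) or 15 um (distal dendron) pre-expansion, and
#' presynaptic boutons of ~0.8 um pre-expansion diameter.
#'
#' All lengths are micrometres; `dendrite_radius`, `segment_length`,
#' `decoy_gap` and the punctum diameters are pre-expansion, the voxel and PSF
#' sizes post-expansion. Rates are events per 10 um of pre-expansion dendrite.
#'
#' @param zone `"distal"` (15 um segment, 2.0 synapses/10 um) or `"proximal"`
#'   (60 um segment, 0.8 synapses/10 um); sets defaults only.
#' @param expansion_factor Isotropic linear expansion factor (> 1).
#' @param voxel_xy,voxel_z Voxel size, um post-expansion.
#' @param psf_sigma_xy,psf_sigma_z Gaussian PSF sigma, um post-expansion.
#' @param dendrite_radius Tube radius, um pre-expansion.
#' @param segment_length Centerline length, um pre-expansion.
#' @param synapse_rate Synapses per 10 um pre-expansion (Poisson).
#' @param decoy_rate Non-synaptic puncta per 10 um pre-expansion (Poisson).
#' @param decoy_gap Radial offset of decoy puncta from the membrane,
#'   um pre-expansion (> 0).
#' @param punctum_diameter_mean,punctum_diameter_sd Lognormal punctum diameter,
#'   um pre-expansion.
#' @param noise_sd Additive Gaussian noise sd, relative to unit punctum peak.
#' @param curvature_amp Amplitude (um post-expansion) of a gentle sinusoidal
#'   in-plane bend of the centerline; 0 gives a straight dendrite.
#' @param seed Integer seed; placements and noise use separate sub-streams so
#'   the ground truth is unchanged when only `noise_sd` changes.
#' @return A list of class `exm_params`.
#' @export
exm_params <- function(zone = c("distal", "proximal"),
                       expansion_factor = 4.2,
                       voxel_xy = 0.1,
                       voxel_z = 0.6,
                       psf_sigma_xy = 0.07,
                       psf_sigma_z = 0.3,
                       dendrite_radius = 0.3,
                       segment_length = NULL,
                       synapse_rate = NULL,
                       decoy_rate = 2.0,
                       decoy_gap = 1.0,
                       punctum_diameter_mean = 0.8,
                       punctum_diameter_sd = 0.15,
                       noise_sd = 0.01,
                       curvature_amp = 0,
                       seed = 1L) {
  zone <- match.arg(zone)
  if (is.null(segment_length)) segment_length <- if (zone == "distal") 15 else 60
  if (is.null(synapse_rate)) synapse_rate <- if (zone == "distal") 2.0 else 0.8
  stopifnot(expansion_factor > 1, voxel_xy > 0, voxel_z > 0,
            psf_sigma_xy >= 0, psf_sigma_z >= 0,
            dendrite_radius > 0, segment_length > 0,
            synapse_rate >= 0, decoy_rate >= 0, decoy_gap > 0,
            punctum_diameter_mean > 0, punctum_diameter_sd >= 0,
            noise_sd >= 0, curvature_amp >= 0)
  structure(list(zone = zone, expansion_factor = expansion_factor,
                 voxel_xy = voxel_xy, voxel_z = voxel_z,
                 psf_sigma_xy = psf_sigma_xy, psf_sigma_z = psf_sigma_z,
                 dendrite_radius = dendrite_radius,
                 segment_length = segment_length,
                 synapse_rate = synapse_rate, decoy_rate = decoy_rate,
                 decoy_gap = decoy_gap,
                 punctum_diameter_mean = punctum_diameter_mean,
                 punctum_diameter_sd = punctum_diameter_sd,
                 noise_sd = noise_sd, curvature_amp = curvature_amp,
                 seed = as.integer(seed)),
            class = "exm_params")
}

# Margin (um post-expansion) of empty space beyond the centerline ends.
.exm_margin_x <- 1.5

#' Draw ground-truth punctum placements for a synthetic volume
#'
#' The placement stage of [generate_exm_volume()], exposed separately so that
#' count statistics can be checked over many seeds without rasterising images.
#' Synapse and decoy counts are Poisson with mean `rate * segment_length / 10`;
#' arc-length positions are uniform over the segment interior, azimuths
#' uniform on the circle, diameters lognormal.
#'
#' @param params An [exm_params()] object.
#' @return A list of class `exm_truth` with `synapse_positions` and
#'   `decoy_positions` (arc length, um pre-expansion) and a `punctum_records`
#'   data frame (centroid x/y/z um post-expansion filled in by the
#'   rasteriser, diameter um pre-expansion, label, azimuth).
#' @export
generate_exm_truth <- function(params) {
  stopifnot(inherits(params, "exm_params"))
  p <- params
  with_seed(p$seed, {
    L <- p$segment_length
    buf <- min(0.5, L / 10)
    draw <- function(rate) {
      n <- stats::rpois(1L, rate * L / 10)
      pos <- sort(stats::runif(n, buf, L - buf))
      az <- stats::runif(n, 0, 2 * pi)
      lp <- lognorm_pars(p$punctum_diameter_mean,
                         max(p$punctum_diameter_sd, 1e-12))
      diam <- stats::rlnorm(n, lp$meanlog, lp$sdlog)
      list(pos = pos, az = az, diam = diam)
    }
    syn <- draw(p$synapse_rate)
    dec <- draw(p$decoy_rate)
    new_exm_truth(syn, dec)
  })
}

new_exm_truth <- function(syn, dec) {
  rec <- data.frame(
    arc_length_pre = c(syn$pos, dec$pos),
    azimuth = c(syn$az, dec$az),
    diameter = c(syn$diam, dec$diam),
    label = rep(c("synapse", "decoy"), c(length(syn$pos), length(dec$pos))),
    x = rep(NA_real_, length(syn$pos) + length(dec$pos)),
    y = rep(NA_real_, length(syn$pos) + length(dec$pos)),
    z = rep(NA_real_, length(syn$pos) + length(dec$pos)),
    stringsAsFactors = FALSE
  )
  structure(list(synapse_positions = syn$pos,
                 decoy_positions = dec$pos,
                 punctum_records = rec),
            class = "exm_truth")
}

#' Build an explicit (non-random) ground truth
#'
#' Validation plumbing: place synapses and decoys at stated arc lengths so a
#' detection run can be compared against exactly known positions.
#'
#' @param synapse_positions,decoy_positions Arc lengths, um pre-expansion.
#' @param synapse_azimuths,decoy_azimuths Radians around the tube; default
#'   spreads them evenly.
#' @param synapse_diameters,decoy_diameters Punctum diameters, um
#'   pre-expansion (recycled).
#' @return An `exm_truth` object, as from [generate_exm_truth()].
#' @export
exm_truth_manual <- function(synapse_positions = numeric(),
                             decoy_positions = numeric(),
                             synapse_azimuths = NULL,
                             decoy_azimuths = NULL,
                             synapse_diameters = 0.8,
                             decoy_diameters = 0.8) {
  even_az <- function(n) if (n == 0) numeric() else seq(0, 2 * pi, length.out = n + 1L)[seq_len(n)]
  ns <- length(synapse_positions); nd <- length(decoy_positions)
  syn <- list(pos = synapse_positions,
              az = if (is.null(synapse_azimuths)) even_az(ns) else rep_len(synapse_azimuths, ns),
              diam = rep_len(synapse_diameters, ns))
  dec <- list(pos = decoy_positions,
              az = if (is.null(decoy_azimuths)) even_az(nd) else rep_len(decoy_azimuths, nd),
              diam = rep_len(decoy_diameters, nd))
  new_exm_truth(syn, dec)
}

# Centerline polyline (um post-expansion), node spacing ~0.25 um.
exm_centerline <- function(p, yc, zc) {
  L_post <- p$segment_length * p$expansion_factor
  x <- seq(.exm_margin_x, .exm_margin_x + L_post, by = 0.25)
  if (x[length(x)] < .exm_margin_x + L_post) x <- c(x, .exm_margin_x + L_post)
  y <- yc + p$curvature_amp * sin(2 * pi * (x - x[1]) / L_post)
  cbind(x = x, y = y, z = rep(zc, length(x)))
}

#' Generate a two-channel synthetic expansion-microscopy volume
#'
#' Channel 1 ("cyto") is a filled tube of radius `dendrite_radius * E` around
#' the centerline; channel 2 ("presyn") contains isotropic Gaussian puncta
#' whose centroids sit exactly on the tube surface (synapses) or are pushed
#' radially outward by `decoy_gap * E` (decoys). A punctum of diameter `d`
#' (pre-expansion) is rendered as a Gaussian of sigma `d * E / (2 * FWHM)`
#' with FWHM = 2.3548 sigma, i.e. the stated diameter is twice the blob's
#' full width at half maximum. Both channels are convolved with the
#' anisotropic PSF, then Gaussian noise of sd `noise_sd` is added and the
#' result clipped at zero. Identical seeds give bit-identical output.
#'
#' @param params An [exm_params()] object.
#' @param truth Optional `exm_truth` (e.g. [exm_truth_manual()]); when `NULL`
#'   placements are drawn by [generate_exm_truth()] under `params$seed`.
#' @return A list with elements `volume` (class `exm_volume`: `data` is an
#'   x-y-z-channel array, plus voxel sizes, expansion factor and channel
#'   names), `centerline` (n x 3 matrix, um post-expansion) and `truth`
#'   (`exm_truth` with punctum centroids filled in, um post-expansion).
#' @export
generate_exm_volume <- function(params, truth = NULL) {
  stopifnot(inherits(params, "exm_params"))
  p <- params
  E <- p$expansion_factor
  L_post <- p$segment_length * E
  if (L_post < p$voxel_xy) {
    stop("segment shorter than one voxel post-expansion")
  }
  if (p$decoy_gap * E < 2 * p$psf_sigma_xy) {
    warning("decoy_gap is below the PSF scale; decoys will be unresolvable")
  }
  if (is.null(truth)) truth <- generate_exm_truth(p)
  stopifnot(inherits(truth, "exm_truth"))

  R_post <- p$dendrite_radius * E
  d_post_typ <- p$punctum_diameter_mean * E
  has_decoys <- length(truth$decoy_positions) > 0
  radial_extent <- R_post + (if (has_decoys) p$decoy_gap * E else 0) +
    0.75 * d_post_typ + 3 * p$psf_sigma_xy + 0.3

  nx <- as.integer(ceiling((L_post + 2 * .exm_margin_x) / p$voxel_xy))
  ny <- as.integer(2L * ceiling(radial_extent / p$voxel_xy) + 1L)
  nz <- as.integer(2L * ceiling(radial_extent / p$voxel_z) + 1L)
  yc <- ny * p$voxel_xy / 2
  zc <- nz * p$voxel_z / 2

  cl <- exm_centerline(p, yc, zc)
  xg <- (seq_len(nx) - 0.5) * p$voxel_xy
  yg <- (seq_len(ny) - 0.5) * p$voxel_xy
  zg <- (seq_len(nz) - 0.5) * p$voxel_z

  # channel 1: tube. Cross-section evaluated in the yz-plane at each x
  # (valid for the gentle curvatures this generator produces).
  ycl_at <- stats::approxfun(cl[, 1], cl[, 2], rule = 2)
  dy2 <- outer(xg, yg, function(x, y) (y - ycl_at(x))^2)  # nx x ny
  cyto <- array(0, c(nx, ny, nz))
  R2 <- R_post^2
  for (k in seq_len(nz)) {
    dz2 <- (zg[k] - zc)^2
    if (dz2 <= R2) cyto[, , k] <- (dy2 <= (R2 - dz2)) * 1.0
  }

  # channel 2: puncta at truth placements.
  rec <- truth$punctum_records
  presyn <- array(0, c(nx, ny, nz))
  if (nrow(rec) > 0) {
    arc_post <- rec$arc_length_pre * E
    cum <- c(0, cumsum(sqrt(rowSums(diff(cl)^2))))
    px <- stats::approx(cum, cl[, 1], xout = arc_post, rule = 2)$y
    py0 <- stats::approx(cum, cl[, 2], xout = arc_post, rule = 2)$y
    offset <- ifelse(rec$label == "synapse", R_post, R_post + p$decoy_gap * E)
    pyv <- py0 + offset * cos(rec$azimuth)
    pzv <- zc + offset * sin(rec$azimuth)
    rec$x <- px; rec$y <- pyv; rec$z <- pzv
    for (i in seq_len(nrow(rec))) {
      sig <- rec$diameter[i] * E / (2 * 2 * sqrt(2 * log(2)))
      ext <- 3 * sig
      ix <- which(abs(xg - px[i]) <= ext)
      iy <- which(abs(yg - pyv[i]) <= ext)
      iz <- which(abs(zg - pzv[i]) <= ext + p$voxel_z)
      if (!length(ix) || !length(iy) || !length(iz)) next
      gx <- exp(-(xg[ix] - px[i])^2 / (2 * sig^2))
      gy <- exp(-(yg[iy] - pyv[i])^2 / (2 * sig^2))
      gz <- exp(-(zg[iz] - pzv[i])^2 / (2 * sig^2))
      blob <- outer(gx, gy) %o% gz
      presyn[ix, iy, iz] <- presyn[ix, iy, iz] + blob
    }
  }
  truth$punctum_records <- rec

  cyto <- blur_gauss3(cyto, p$psf_sigma_xy / p$voxel_xy, p$psf_sigma_z / p$voxel_z)
  presyn <- blur_gauss3(presyn, p$psf_sigma_xy / p$voxel_xy, p$psf_sigma_z / p$voxel_z)

  if (p$noise_sd > 0) {
    with_seed(p$seed + 1000003L, {
      cyto <- cyto + stats::rnorm(length(cyto), sd = p$noise_sd)
      presyn <- presyn + stats::rnorm(length(presyn), sd = p$noise_sd)
    })
  }
  cyto[cyto < 0] <- 0
  presyn[presyn < 0] <- 0

  data <- array(0, c(nx, ny, nz, 2L))
  data[, , , 1L] <- cyto
  data[, , , 2L] <- presyn
  volume <- structure(list(data = data,
                           voxel_xy = p$voxel_xy, voxel_z = p$voxel_z,
                           expansion_factor = E,
                           channel_names = c("cyto", "presyn")),
                      class = "exm_volume")
  list(volume = volume, centerline = cl, truth = truth)
}

#' @export
print.exm_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("exm_volume: %d x %d x %d voxels, %d channels (%s)\n",
              d[1], d[2], d[3], d[4], paste(x$channel_names, collapse = ", ")))
  cat(sprintf("  voxel %.3g x %.3g x %.3g um post-expansion, E = %.3g\n",
              x$voxel_xy, x$voxel_xy, x$voxel_z, x$expansion_factor))
  invisible(x)
}

#' Total centerline arc length (um post-expansion)
#' @param centerline n x 3 matrix of node coordinates, um post-expansion.
#' @return Arc length in um post-expansion.
#' @export
centerline_length <- function(centerline) {
  sum(sqrt(rowSums(diff(centerline)^2)))
}
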