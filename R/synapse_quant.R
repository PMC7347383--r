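# Synapse calling on expansion-microscopy volumes: detect presynaptic
# puncta, pair them with the dendrite as candidate appositions, pick the
# side-on or face-on scan geometry, extract two-channel relative-intensity
# line profiles, measure half-maximum overlap, and classify against
# calibrated thresholds.

#' Detect presynaptic puncta in one channel of a volume
#'
#' Pipeline: (optional extra Gaussian smoothing), intensity threshold,
#' 26-connected component labelling, equivalent-sphere diameter from voxel
#' count. The diameter is converted to pre-expansion micrometres and a
#' strict `> min_diameter` bouton-size filter applied (a 0.4 um bouton is
#' excluded, matching the convention that only boutons strictly larger than
#' 0.4 um are candidates). Centroids are intensity-weighted and reported in
#' um post-expansion.
#'
#' The threshold is `rel_threshold` times the channel maximum, floored at a
#' robust noise ceiling (median + 8 MAD); on a channel containing only noise
#' no component survives. `rel_threshold` defaults to 0.0625 = exp(-2 ln 16 /
#' 2): for a Gaussian blob rendered with diameter = 2 FWHM, the iso-surface
#' at 6.25% of the peak has exactly the nominal diameter, so the
#' equivalent-sphere estimate recovers the generator's diameter.
#'
#' @param volume An `exm_volume`.
#' @param channel Channel index or name (default `"presyn"`).
#' @param min_diameter Strict lower bound on punctum diameter,
#'   um pre-expansion.
#' @param rel_threshold Detection threshold relative to the channel maximum.
#' @param min_voxels Minimum component size in voxels.
#' @return Data frame of class `puncta`: `x`, `y`, `z` (um post-expansion),
#'   `diameter` (um pre-expansion), `peak_intensity`, `voxel_count`.
#' @export
detect_puncta <- function(volume, channel = "presyn", min_diameter = 0.4,
                          rel_threshold = 0.0625, min_voxels = 4L) {
  stopifnot(inherits(volume, "exm_volume"))
  if (is.character(channel)) channel <- match(channel, volume$channel_names)
  arr <- volume$data[, , , channel]
  empty <- data.frame(x = numeric(), y = numeric(), z = numeric(),
                      diameter = numeric(), peak_intensity = numeric(),
                      voxel_count = integer())
  class(empty) <- c("puncta", "data.frame")
  mx <- max(arr)
  if (mx >= 0.999) warning("channel close to or at saturation")
  # robust noise scale tolerant of zero-clipping: the 84.1th percentile sits
  # one sigma above the median for (half-)Gaussian background
  med <- stats::median(arr)
  sigma_hat <- stats::quantile(arr, 0.8413, names = FALSE) - med
  noise_ceiling <- med + 6 * sigma_hat
  thr <- max(rel_threshold * mx, noise_ceiling)
  if (mx <= noise_ceiling || thr <= 0) return(empty)
  comps <- label_components(arr > thr)
  comps <- comps[vapply(comps, length, 1L) >= min_voxels]
  if (!length(comps)) return(empty)
  dims <- dim(arr)
  voxel_vol <- volume$voxel_xy^2 * volume$voxel_z
  rows <- lapply(comps, function(idx) {
    co <- arrayInd(idx, dims)
    w <- arr[idx]
    cx <- sum((co[, 1] - 0.5) * volume$voxel_xy * w) / sum(w)
    cy <- sum((co[, 2] - 0.5) * volume$voxel_xy * w) / sum(w)
    cz <- sum((co[, 3] - 0.5) * volume$voxel_z * w) / sum(w)
    d_post <- (6 * length(idx) * voxel_vol / pi)^(1 / 3)
    data.frame(x = cx, y = cy, z = cz,
               diameter = d_post / volume$expansion_factor,
               peak_intensity = max(w), voxel_count = length(idx))
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$x), , drop = FALSE]
  rownames(out) <- NULL
  out <- filter_puncta(out, min_diameter)
  class(out) <- c("puncta", "data.frame")
  out
}

#' Apply the strict minimum-diameter bouton filter
#'
#' Keeps puncta with `diameter > min_diameter` (strict: a punctum measuring
#' exactly the boundary value is excluded).
#'
#' @param puncta Data frame with a `diameter` column (um pre-expansion).
#' @param min_diameter Strict lower bound, um pre-expansion.
#' @return The filtered data frame.
#' @export
filter_puncta <- function(puncta, min_diameter = 0.4) {
  puncta[puncta$diameter > min_diameter, , drop = FALSE]
}

# Nearest point on a polyline to point q; returns the projection point,
# arc length at the projection, and the distance.
.nearest_on_polyline <- function(cl, q) {
  a <- cl[-nrow(cl), , drop = FALSE]
  b <- cl[-1, , drop = FALSE]
  ab <- b - a
  len2 <- rowSums(ab^2)
  aq <- sweep(-a, 2, q, `+`)
  t <- pmin(pmax(rowSums(aq * ab) / pmax(len2, 1e-300), 0), 1)
  proj <- a + ab * t
  d2 <- rowSums(sweep(proj, 2, q, `-`)^2)
  i <- which.min(d2)
  seg_len <- sqrt(len2)
  cum <- c(0, cumsum(seg_len))
  list(point = proj[i, ], arc = cum[i] + t[i] * seg_len[i],
       dist = sqrt(d2[i]))
}

#' Pair detected puncta with a dendrite as candidate appositions
#'
#' A punctum is a candidate apposition when the surface-to-surface distance
#' between its (spherical) boundary and the dendrite tube is at most
#' `gap_tol`. Records the nearest centerline arc length (um pre-expansion),
#' the membrane gap (um post-expansion, floored at 0), and the nearest axis
#' and surface points used later for scan geometry.
#'
#' @param puncta Data frame from [detect_puncta()].
#' @param centerline n x 3 matrix, um post-expansion (>= 2 nodes).
#' @param dendrite_radius Tube radius, um pre-expansion.
#' @param expansion_factor Linear expansion factor.
#' @param gap_tol Maximum surface-to-surface gap, um post-expansion.
#' @return Data frame of class `appositions`: punctum columns plus
#'   `arc_length_pre`, `dist_axis`, `membrane_gap`, axis point (`axx`,
#'   `axy`, `axz`) and surface point (`spx`, `spy`, `spz`).
#' @export
find_appositions <- function(puncta, centerline, dendrite_radius,
                             expansion_factor, gap_tol = 0.2) {
  if (is.null(dim(centerline)) || nrow(centerline) < 2L) {
    stop("centerline must have at least 2 nodes")
  }
  R_post <- dendrite_radius * expansion_factor
  rows <- lapply(seq_len(nrow(puncta)), function(i) {
    q <- as.numeric(puncta[i, c("x", "y", "z")])
    np <- .nearest_on_polyline(centerline, q)
    d_post <- puncta$diameter[i] * expansion_factor
    s2s <- np$dist - R_post - d_post / 2
    if (s2s > gap_tol) return(NULL)
    v <- q - np$point
    nv <- sqrt(sum(v^2))
    sp <- if (nv > 1e-9) np$point + v / nv * R_post else np$point
    cbind(puncta[i, , drop = FALSE],
          data.frame(arc_length_pre = np$arc / expansion_factor,
                     dist_axis = np$dist,
                     membrane_gap = max(0, s2s),
                     axx = np$point[1], axy = np$point[2], axz = np$point[3],
                     spx = sp[1], spy = sp[2], spz = sp[3]))
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (!length(rows)) {
    out <- cbind(puncta[0, , drop = FALSE],
                 data.frame(arc_length_pre = numeric(), dist_axis = numeric(),
                            membrane_gap = numeric(), axx = numeric(),
                            axy = numeric(), axz = numeric(), spx = numeric(),
                            spy = numeric(), spz = numeric()))
  } else {
    out <- do.call(rbind, rows)
  }
  rownames(out) <- NULL
  class(out) <- c("appositions", "data.frame")
  out
}

#' Choose the side-on or face-on viewing geometry for each apposition
#'
#' Let `a` be the apposition axis from the dendrite surface point to the
#' punctum centroid. If the angle between `a` and the optical (z) axis is at
#' most 45 degrees the apposition is viewed face-on (line scan along z),
#' otherwise side-on (in-plane scan along `a`); the 45-degree boundary is
#' assigned to face-on. When the centroid lies on the surface point the
#' surface vector is degenerate; the radial axis-to-centroid direction is
#' used instead, and only if that too is degenerate does the call default to
#' side-on with a warning.
#'
#' @param appositions Data frame from [find_appositions()].
#' @return The same data frame with an `orientation` column
#'   (`"side_on"`/`"face_on"`).
#' @export
choose_orientation <- function(appositions) {
  n <- nrow(appositions)
  orientation <- character(n)
  for (i in seq_len(n)) {
    q <- as.numeric(appositions[i, c("x", "y", "z")])
    v <- q - as.numeric(appositions[i, c("spx", "spy", "spz")])
    if (sqrt(sum(v^2)) < 1e-9) {
      v <- q - as.numeric(appositions[i, c("axx", "axy", "axz")])
    }
    nv <- sqrt(sum(v^2))
    if (nv < 1e-9) {
      warning("degenerate apposition axis; defaulting to side_on")
      orientation[i] <- "side_on"
      next
    }
    cosang <- abs(v[3]) / nv
    orientation[i] <- if (cosang >= cos(pi / 4) - 1e-12) "face_on" else "side_on"
  }
  appositions$orientation <- orientation
  appositions
}

#' Extract a two-channel relative-fluorescence line profile
#'
#' Samples both channels along the scan axis through the apposition midpoint
#' (halfway between the dendrite surface point and the punctum centroid) over
#' +/- `half_window`. Side-on scans run in-plane along the apposition axis
#' with step `voxel_xy`; face-on scans run along z with step `voxel_z`.
#' Values are trilinearly interpolated and each channel is divided by its own
#' maximum within the window ("relative fluorescence"). Positions are um
#' post-expansion relative to the midpoint.
#'
#' @param apposition A single row of an oriented `appositions` data frame.
#' @param volume The `exm_volume` the apposition came from.
#' @param half_window Scan half-length, um post-expansion.
#' @return Data frame of class `intensity_profile` with `position`, `cyto`,
#'   `presyn`; attributes `axis` (`"in_plane"`/`"z"`), `step`, `orientation`.
#' @export
extract_profile <- function(apposition, volume, half_window = 3.0) {
  stopifnot(nrow(apposition) == 1L, !is.null(apposition$orientation))
  q <- as.numeric(apposition[, c("x", "y", "z")])
  sp <- as.numeric(apposition[, c("spx", "spy", "spz")])
  mid <- (q + sp) / 2
  if (apposition$orientation == "face_on") {
    u <- c(0, 0, 1)
    step <- volume$voxel_z
    axis <- "z"
  } else {
    v <- q - sp
    if (sqrt(sum(v[1:2]^2)) < 1e-9) v <- q - as.numeric(apposition[, c("axx", "axy", "axz")])
    u <- c(v[1], v[2], 0)
    u <- u / sqrt(sum(u^2))
    step <- volume$voxel_xy
    axis <- "in_plane"
  }
  s <- seq(-half_window, half_window, by = step)
  pts <- cbind(mid[1] + s * u[1], mid[2] + s * u[2], mid[3] + s * u[3])
  dims <- dim(volume$data)
  lim <- c(dims[1] * volume$voxel_xy, dims[2] * volume$voxel_xy,
           dims[3] * volume$voxel_z)
  inside <- pts[, 1] >= 0 & pts[, 1] <= lim[1] &
    pts[, 2] >= 0 & pts[, 2] <= lim[2] &
    pts[, 3] >= 0 & pts[, 3] <= lim[3]
  if (!all(inside)) {
    warning("scan window exits the volume; profile truncated")
    pts <- pts[inside, , drop = FALSE]
    s <- s[inside]
  }
  if (length(s) < 3L) stop("profile has fewer than 3 samples")
  cyto <- interp3(volume$data[, , , 1L], pts, volume$voxel_xy, volume$voxel_z)
  presyn <- interp3(volume$data[, , , 2L], pts, volume$voxel_xy, volume$voxel_z)
  if (max(cyto) <= 0 || max(presyn) <= 0) {
    stop("no signal in scan window")
  }
  out <- data.frame(position = s, cyto = cyto / max(cyto),
                    presyn = presyn / max(presyn))
  attr(out, "axis") <- axis
  attr(out, "step") <- step
  attr(out, "orientation") <- apposition$orientation
  class(out) <- c("intensity_profile", "data.frame")
  out
}

#' Construct an intensity profile from raw position/intensity vectors
#'
#' Convenience constructor for calibration sets supplied as plain columns
#' (e.g. read from CSV): normalizes each channel to its own maximum.
#'
#' @param position Monotone increasing positions, um post-expansion.
#' @param cyto,presyn Channel intensities (any non-negative scale).
#' @param axis `"in_plane"` or `"z"`.
#' @return An `intensity_profile`.
#' @export
intensity_profile <- function(position, cyto, presyn,
                              axis = c("in_plane", "z")) {
  axis <- match.arg(axis)
  stopifnot(length(position) >= 3L, length(cyto) == length(position),
            length(presyn) == length(position), !is.unsorted(position),
            max(cyto) > 0, max(presyn) > 0)
  out <- data.frame(position = position, cyto = cyto / max(cyto),
                    presyn = presyn / max(presyn))
  attr(out, "axis") <- axis
  attr(out, "step") <- stats::median(diff(position))
  class(out) <- c("intensity_profile", "data.frame")
  out
}

# Contiguous half-maximum support around the global peak of one channel.
# Boundaries are linearly interpolated to the exact 0.5 crossing; warns when
# further super-half-max samples exist outside the chosen interval.
half_max_interval <- function(position, y) {
  pk <- which.max(y)  # earliest global peak on ties
  l <- pk
  while (l > 1L && y[l - 1L] >= 0.5) l <- l - 1L
  r <- pk
  n <- length(y)
  while (r < n && y[r + 1L] >= 0.5) r <- r + 1L
  left <- if (l == 1L) position[1L] else {
    position[l - 1L] + (0.5 - y[l - 1L]) / (y[l] - y[l - 1L]) *
      (position[l] - position[l - 1L])
  }
  right <- if (r == n) position[n] else {
    position[r] + (y[r] - 0.5) / (y[r] - y[r + 1L]) *
      (position[r + 1L] - position[r])
  }
  if (any(y[-(l:r)] >= 0.5)) {
    warning("multimodal channel: using the interval around the global peak")
  }
  c(left, right)
}

#' Measure the half-maximum overlap between the two channels of a profile
#'
#' For each normalized channel, take the contiguous interval around its
#' global peak where intensity >= 0.5 (full-width-at-half-maximum support,
#' boundaries by linear interpolation). The overlap is the length of the
#' intersection of the two intervals, 0 when they are disjoint; apposing
#' profiles with no overlap do not represent a synapse.
#'
#' @param profile An `intensity_profile`.
#' @param expansion_factor Linear expansion factor used to state the overlap
#'   in pre-expansion units.
#' @return List with `overlap_post` and `overlap_pre` (um); their ratio is
#'   exactly `expansion_factor`.
#' @export
compute_overlap <- function(profile, expansion_factor) {
  stopifnot(inherits(profile, "intensity_profile"), expansion_factor > 1)
  ic <- half_max_interval(profile$position, profile$cyto)
  ip <- half_max_interval(profile$position, profile$presyn)
  ov <- max(0, min(ic[2], ip[2]) - max(ic[1], ip[1]))
  list(overlap_post = ov, overlap_pre = ov / expansion_factor)
}

#' Calibrate synapse thresholds from marker-confirmed synapse profiles
#'
#' Given profiles from appositions independently confirmed as synapses by
#' paired pre/post-synaptic markers, the classifier threshold for each
#' viewing geometry is the minimum half-maximum overlap observed in that
#' calibration set: every confirmed synapse overlaps by more than any
#' unconfirmed apposition may and still be called. A confirmed synapse with
#' zero overlap invalidates the premise and is an error.
#'
#' @param side_profiles,face_profiles Lists of `intensity_profile`s from
#'   side-on and face-on confirmed synapses (each >= 1 profile).
#' @param expansion_factor Linear expansion factor.
#' @return List of class `synapse_calibration`: `theta_side`, `theta_face`
#'   (um pre-expansion), `n_side`, `n_face`, `overlaps_side`,
#'   `overlaps_face`.
#' @export
calibrate_thresholds <- function(side_profiles, face_profiles,
                                 expansion_factor) {
  stopifnot(length(side_profiles) >= 1L, length(face_profiles) >= 1L)
  ov <- function(ps) vapply(ps, function(p) {
    compute_overlap(p, expansion_factor)$overlap_pre
  }, numeric(1))
  os <- ov(side_profiles)
  of <- ov(face_profiles)
  if (any(os <= 0) || any(of <= 0)) {
    stop("a confirmed synapse has zero overlap; calibration invalid")
  }
  structure(list(theta_side = min(os), theta_face = min(of),
                 n_side = length(os), n_face = length(of),
                 overlaps_side = os, overlaps_face = of,
                 expansion_factor = expansion_factor),
            class = "synapse_calibration")
}

#' @export
print.synapse_calibration <- function(x, ...) {
  cat(sprintf("synapse calibration: theta_side = %.3f um (n = %d), theta_face = %.3f um (n = %d), pre-expansion\n",
              x$theta_side, x$n_side, x$theta_face, x$n_face))
  invisible(x)
}

#' Classify one apposition profile against the calibrated thresholds
#'
#' An apposition is a synapse when its overlap (pre-expansion) strictly
#' exceeds the threshold for its viewing geometry; an overlap exactly at the
#' threshold is not a synapse.
#'
#' @param profile An `intensity_profile` (orientation from its attribute or
#'   `orientation`).
#' @param calibration A `synapse_calibration`.
#' @param orientation `"side_on"` or `"face_on"`; defaults to the profile's
#'   `orientation` attribute.
#' @return List of class `overlap_result`: `overlap_post`, `overlap_pre`,
#'   `is_synapse`, `threshold_used` (um pre-expansion), `orientation`.
#' @export
classify_apposition <- function(profile, calibration, orientation = NULL) {
  stopifnot(inherits(calibration, "synapse_calibration"))
  if (is.null(orientation)) orientation <- attr(profile, "orientation")
  stopifnot(orientation %in% c("side_on", "face_on"))
  ov <- compute_overlap(profile, calibration$expansion_factor)
  theta <- if (orientation == "side_on") calibration$theta_side else calibration$theta_face
  structure(list(overlap_post = ov$overlap_post,
                 overlap_pre = ov$overlap_pre,
                 is_synapse = ov$overlap_pre > theta,
                 threshold_used = theta, orientation = orientation),
            class = "overlap_result")
}

#' Run detection, apposition pairing and classification over a volume
#'
#' Convenience pipeline: [detect_puncta()] on the presynaptic channel,
#' [find_appositions()] against the centerline, [choose_orientation()],
#' profile extraction and threshold classification for every candidate.
#'
#' @param volume An `exm_volume`.
#' @param centerline n x 3 matrix, um post-expansion.
#' @param calibration A `synapse_calibration`.
#' @param dendrite_radius Tube radius, um pre-expansion.
#' @param min_diameter,gap_tol,half_window Passed to the component steps.
#' @return An `appositions` data frame with `orientation`, `overlap_pre`,
#'   `overlap_post`, `threshold_used` and `is_synapse` columns (0 rows when
#'   nothing is detected).
#' @export
quantify_volume <- function(volume, centerline, calibration, dendrite_radius,
                            min_diameter = 0.4, gap_tol = 0.2,
                            half_window = 3.0) {
  puncta <- detect_puncta(volume, min_diameter = min_diameter)
  apps <- find_appositions(puncta, centerline, dendrite_radius,
                           volume$expansion_factor, gap_tol = gap_tol)
  if (nrow(apps) > 0) apps <- choose_orientation(apps)
  else apps$orientation <- character(0)
  apps$overlap_pre <- numeric(nrow(apps))
  apps$overlap_post <- numeric(nrow(apps))
  apps$threshold_used <- numeric(nrow(apps))
  apps$is_synapse <- logical(nrow(apps))
  for (i in seq_len(nrow(apps))) {
    prof <- extract_profile(apps[i, , drop = FALSE], volume, half_window)
    res <- classify_apposition(prof, calibration,
                               orientation = apps$orientation[i])
    apps$overlap_pre[i] <- res$overlap_pre
    apps$overlap_post[i] <- res$overlap_post
    apps$threshold_used[i] <- res$threshold_used
    apps$is_synapse[i] <- res$is_synapse
  }
  apps
}

#' Extract calibration profiles at known synapse locations
#'
#' Emulates the calibration step in which appositions confirmed as synapses
#' by paired pre/post-synaptic markers provide the reference overlap set:
#' profiles are taken at the generator's ground-truth synapse placements
#' (not at detected puncta) and split by viewing geometry.
#'
#' @param volume,centerline,truth Output of [generate_exm_volume()].
#' @param dendrite_radius Tube radius, um pre-expansion.
#' @param half_window Scan half-length, um post-expansion.
#' @return List with `side` and `face` lists of `intensity_profile`s.
#' @export
make_calibration_profiles <- function(volume, centerline, truth,
                                      dendrite_radius, half_window = 3.0) {
  rec <- truth$punctum_records
  rec <- rec[rec$label == "synapse", , drop = FALSE]
  side <- list(); face <- list()
  E <- volume$expansion_factor
  for (i in seq_len(nrow(rec))) {
    q <- as.numeric(rec[i, c("x", "y", "z")])
    np <- .nearest_on_polyline(centerline, q)
    v <- q - np$point
    nv <- sqrt(sum(v^2))
    if (nv < 1e-9) next
    sp <- np$point + v / nv * dendrite_radius * E
    app <- data.frame(x = q[1], y = q[2], z = q[3],
                      spx = sp[1], spy = sp[2], spz = sp[3],
                      axx = np$point[1], axy = np$point[2], axz = np$point[3])
    app <- choose_orientation(cbind(app, data.frame(dist_axis = np$dist)))
    prof <- tryCatch(extract_profile(app, volume, half_window),
                     error = function(e) NULL)
    if (is.null(prof)) next
    if (app$orientation == "face_on") face[[length(face) + 1L]] <- prof
    else side[[length(side) + 1L]] <- prof
  }
  list(side = side, face = face)
}
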