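# Internal numerical helpers shared by the image and hormone simulators.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# meanlog/sdlog of a lognormal with given arithmetic mean and sd (or cv).
lognorm_pars <- function(mean, sd) {
  stopifnot(mean > 0, sd >= 0)
  if (sd == 0) return(list(meanlog = log(mean), sdlog = 0))
  sdlog <- sqrt(log(1 + (sd / mean)^2))
  list(meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
}

gauss_kernel <- function(sigma_vox) {
  if (sigma_vox <= 0) return(1)
  r <- max(1L, ceiling(3 * sigma_vox))
  k <- stats::dnorm(seq(-r, r), sd = sigma_vox)
  k / sum(k)
}

# Separable 1D Gaussian convolution of a 3D array along one dimension,
# zero-padded at the edges (shift-and-add; kernels here are short).
blur1d <- function(a, k, along) {
  if (length(k) == 1L) return(a)
  r <- (length(k) - 1L) / 2L
  n <- dim(a)[along]
  out <- array(0, dim(a))
  for (j in seq_along(k)) {
    o <- j - r - 1L
    src <- seq_len(n) - o
    keep <- src >= 1L & src <= n
    dst <- which(keep)
    srk <- src[keep]
    if (along == 1L) {
      out[dst, , ] <- out[dst, , ] + k[j] * a[srk, , ]
    } else if (along == 2L) {
      out[, dst, ] <- out[, dst, ] + k[j] * a[, srk, ]
    } else {
      out[, , dst] <- out[, , dst] + k[j] * a[, , srk]
    }
  }
  out
}

blur_gauss3 <- function(a, sigma_xy_vox, sigma_z_vox) {
  kxy <- gauss_kernel(sigma_xy_vox)
  kz <- gauss_kernel(sigma_z_vox)
  a <- blur1d(a, kxy, 1L)
  a <- blur1d(a, kxy, 2L)
  blur1d(a, kz, 3L)
}

# Trilinear interpolation of a 3D array at physical points (micrometres).
# Voxel i is centred at (i - 0.5) * step along its axis.
interp3 <- function(a, pts, voxel_xy, voxel_z) {
  dims <- dim(a)
  f <- cbind(pts[, 1] / voxel_xy + 0.5,
             pts[, 2] / voxel_xy + 0.5,
             pts[, 3] / voxel_z + 0.5)
  i0 <- pmin(pmax(floor(f), 1), pmax(dims[col(f)] - 1L, 1L))
  w <- f - i0
  w <- pmin(pmax(w, 0), 1)
  i1 <- pmin(i0 + 1L, matrix(dims, nrow(f), 3, byrow = TRUE))
  at <- function(ix, iy, iz) a[cbind(ix, iy, iz)]
  v000 <- at(i0[, 1], i0[, 2], i0[, 3]); v100 <- at(i1[, 1], i0[, 2], i0[, 3])
  v010 <- at(i0[, 1], i1[, 2], i0[, 3]); v110 <- at(i1[, 1], i1[, 2], i0[, 3])
  v001 <- at(i0[, 1], i0[, 2], i1[, 3]); v101 <- at(i1[, 1], i0[, 2], i1[, 3])
  v011 <- at(i0[, 1], i1[, 2], i1[, 3]); v111 <- at(i1[, 1], i1[, 2], i1[, 3])
  wx <- w[, 1]; wy <- w[, 2]; wz <- w[, 3]
  (v000 * (1 - wx) + v100 * wx) * (1 - wy) * (1 - wz) +
    (v010 * (1 - wx) + v110 * wx) * wy * (1 - wz) +
    (v001 * (1 - wx) + v101 * wx) * (1 - wy) * wz +
    (v011 * (1 - wx) + v111 * wx) * wy * wz
}

# 26-connected component labelling of a logical 3D mask.
# Returns a list of integer vectors of linear voxel indices, one per component.
label_components <- function(mask) {
  dims <- dim(mask)
  nx <- dims[1]; ny <- dims[2]; nz <- dims[3]
  fg <- which(mask)
  if (length(fg) == 0L) return(list())
  visited <- logical(length(mask))
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0L, , drop = FALSE]
  comps <- list()
  while (length(fg) > 0L) {
    seed <- fg[1L]
    visited[seed] <- TRUE
    comp <- seed
    frontier <- seed
    while (length(frontier) > 0L) {
      co <- arrayInd(frontier, dims)
      cand_i <- rep(co[, 1], each = nrow(offs)) + offs[, 1]
      cand_j <- rep(co[, 2], each = nrow(offs)) + offs[, 2]
      cand_k <- rep(co[, 3], each = nrow(offs)) + offs[, 3]
      ok <- cand_i >= 1L & cand_i <= nx & cand_j >= 1L & cand_j <= ny &
        cand_k >= 1L & cand_k <= nz
      lin <- unique((cand_k[ok] - 1L) * nx * ny + (cand_j[ok] - 1L) * nx +
                      cand_i[ok])
      lin <- lin[mask[lin] & !visited[lin]]
      visited[lin] <- TRUE
      comp <- c(comp, lin)
      frontier <- lin
    }
    comps[[length(comps) + 1L]] <- comp
    fg <- fg[!visited[fg]]
  }
  comps
}
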