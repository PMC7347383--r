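# Independent oracles used to check the package implementations.

# Brute-force pulse caller: enumerate every maximal chain of
# (nadir window, subsequent local maximum) pairs with non-overlapping
# resets, then return the lexicographically smallest chain of peak indices.
# Independent of the package's sequential sweep.
oracle_pulse_peaks <- function(y, thr = 25, minv = 0.02) {
  n <- length(y)
  if (n < 3) stop("need >= 3 samples")
  locmax <- Filter(function(i) {
    y[i] >= y[i - 1] && (i == n || y[i] >= y[i + 1])
  }, 2:n)
  feasible_from <- function(start) {
    Filter(function(p) {
      if (p - 1 < start) return(FALSE)
      nad <- min(y[start:(p - 1)])
      nad >= minv && nad > 0 && 100 * (y[p] - nad) / nad > thr
    }, locmax[locmax > start])
  }
  chains <- list()
  recurse <- function(start, chosen) {
    nxt <- feasible_from(start)
    if (!length(nxt)) {
      chains[[length(chains) + 1L]] <<- chosen
      return(invisible())
    }
    for (p in nxt) recurse(p + 1L, c(chosen, p))
  }
  recurse(1L, integer())
  # lexicographically smallest maximal chain
  best <- chains[[1L]]
  for (ch in chains[-1L]) {
    k <- min(length(ch), length(best))
    if (k > 0) {
      d <- which(ch[seq_len(k)] != best[seq_len(k)])
      if (length(d) && ch[d[1]] < best[d[1]]) best <- ch
      else if (!length(d) && length(ch) > length(best)) best <- ch
    } else if (length(ch) > length(best)) best <- ch
  }
  best
}

# Two-sided permutation p-value for the Mann-Whitney U statistic by full
# enumeration of group assignments.
oracle_mw_p <- function(a, b) {
  pool <- c(a, b)
  n <- length(pool)
  na <- length(a)
  u_stat <- function(x, y) sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  u_obs <- u_stat(a, b)
  idx <- utils::combn(n, na)
  us <- apply(idx, 2, function(i) u_stat(pool[i], pool[-i]))
  p <- 2 * min(mean(us <= u_obs), mean(us >= u_obs))
  min(1, p)
}

# Closed-form intersection length of the FWHM supports of two unit-height
# Gaussians with common sd (um).
oracle_fwhm_overlap <- function(mu1, mu2, sd) {
  w <- sd * sqrt(2 * log(2))
  max(0, 2 * w - abs(mu1 - mu2))
}

# Two-Gaussian test profile on a fine grid (positions um post-expansion).
gauss_profile <- function(mu_cyto, mu_presyn, sd, step = 0.01,
                          half_window = 3, axis = "in_plane") {
  pos <- seq(-half_window, half_window, by = step)
  intensity_profile(pos,
                    cyto = exp(-(pos - mu_cyto)^2 / (2 * sd^2)),
                    presyn = exp(-(pos - mu_presyn)^2 / (2 * sd^2)),
                    axis = axis)
}
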