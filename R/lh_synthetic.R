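# Synthetic tail-tip LH series. Pulsatile mode emulates the ovariectomized
# (OVX) state: near-regular episodic boluses of ~3 ng/ml roughly every
# 15 min, sampled every 3 min for 2 h. Surge mode emulates the OVX +
# estradiol + progesterone state: a baseline afternoon sample followed by a
# prolonged rise commencing between 17:00 and 18:00, sampled at 16:00,
# 19:00, 20:00 and 21:00.

#' Parameters for the pulsatile LH simulator
#'
#' Secretion is instantaneous boluses cleared mono-exponentially:
#' `LH(t) = baseline + sum_i A_i * 2^(-(t - t_i)/halflife)` for `t >= t_i`.
#' Inter-event intervals are Gamma(shape, scale = mean_ipi/shape) - shape 8
#' gives the near-regular rhythm of the OVX pulse generator - and bolus
#' amplitudes are lognormal. The clearance half-life is a free kinetic
#' parameter of the simulator, not a physiological claim.
#'
#' @param mean_ipi Mean inter-pulse interval, min.
#' @param ipi_shape Gamma shape of the interval distribution.
#' @param bolus_amp_mean Mean bolus amplitude, ng/ml (height added to the
#'   pre-event level, matching the analyser's peak-minus-nadir amplitude).
#' @param bolus_amp_cv Coefficient of variation of bolus amplitudes.
#' @param clearance_halflife Mono-exponential clearance half-life, min.
#' @param baseline Non-pulsatile baseline, ng/ml.
#' @param sample_interval Sampling interval, min (must be <= mean_ipi/2 for
#'   pulses to be detectable).
#' @param duration Sampling duration, min.
#' @param noise_cv Multiplicative lognormal assay noise CV.
#' @param lod Assay detectability floor, ng/ml (values are clipped up to it).
#' @param seed Integer seed; event placement and noise use separate
#'   sub-streams so the truth is unchanged when only `noise_cv` changes.
#' @return A list of class `pulsatile_params`.
#' @export
pulsatile_params <- function(mean_ipi = 15, ipi_shape = 8,
                             bolus_amp_mean = 3.0, bolus_amp_cv = 0.2,
                             clearance_halflife = 10, baseline = 0.5,
                             sample_interval = 3, duration = 120,
                             noise_cv = 0.05, lod = 0.02, seed = 1L) {
  stopifnot(mean_ipi > 0, ipi_shape > 0, bolus_amp_mean > 0,
            bolus_amp_cv >= 0, clearance_halflife > 0, baseline > 0,
            sample_interval > 0, duration > 0, noise_cv >= 0, lod > 0)
  if (sample_interval > mean_ipi / 2) {
    stop("sample_interval must be <= mean_ipi/2 for pulses to be detectable")
  }
  structure(list(mean_ipi = mean_ipi, ipi_shape = ipi_shape,
                 bolus_amp_mean = bolus_amp_mean, bolus_amp_cv = bolus_amp_cv,
                 clearance_halflife = clearance_halflife, baseline = baseline,
                 sample_interval = sample_interval, duration = duration,
                 noise_cv = noise_cv, lod = lod, seed = as.integer(seed)),
            class = "pulsatile_params")
}

#' Simulate a pulsatile LH series with known secretion events
#'
#' @param params A [pulsatile_params()] object.
#' @param animal_id Identifier copied into the series.
#' @return List with `series` (data frame `time_min`, `lh_ng_per_ml`,
#'   `animal_id`, class `lh_series`, attribute `mode = "pulse"`) and `truth`
#'   (list `event_times` min, `event_amplitudes` ng/ml).
#' @export
generate_pulsatile <- function(params, animal_id = "animal1") {
  stopifnot(inherits(params, "pulsatile_params"))
  p <- params
  ev <- with_seed(p$seed, {
    times <- numeric()
    t <- 0
    repeat {
      t <- t + stats::rgamma(1L, shape = p$ipi_shape,
                             scale = p$mean_ipi / p$ipi_shape)
      if (t >= p$duration) break
      times <- c(times, t)
    }
    lp <- lognorm_pars(p$bolus_amp_mean,
                       max(p$bolus_amp_mean * p$bolus_amp_cv, 1e-12))
    amps <- stats::rlnorm(length(times), lp$meanlog, lp$sdlog)
    list(times = times, amps = amps)
  })
  t_samp <- seq(0, p$duration, by = p$sample_interval)
  lh <- rep(p$baseline, length(t_samp))
  for (i in seq_along(ev$times)) {
    dt <- t_samp - ev$times[i]
    on <- dt >= 0
    lh[on] <- lh[on] + ev$amps[i] * 2^(-dt[on] / p$clearance_halflife)
  }
  if (p$noise_cv > 0) {
    lp <- lognorm_pars(1, p$noise_cv)
    lh <- lh * with_seed(p$seed + 2000003L,
                         stats::rlnorm(length(lh), lp$meanlog, lp$sdlog))
  }
  lh <- pmax(lh, p$lod)
  series <- data.frame(time_min = t_samp, lh_ng_per_ml = lh,
                       animal_id = animal_id, stringsAsFactors = FALSE)
  attr(series, "mode") <- "pulse"
  class(series) <- c("lh_series", "data.frame")
  list(series = series,
       truth = list(event_times = ev$times, event_amplitudes = ev$amps))
}

#' Parameters for the LH surge simulator
#'
#' The surge is a smooth rise-and-decay bump starting at `onset_time`
#' (default 17.5 h, i.e. between 17:00 and 18:00):
#' `LH(t) = baseline + peak_amp * g(t - onset) / max(g)` with
#' `g(u) = (1 - exp(-u/rise_tau)) * exp(-u/fall_tau)`. In suppressed mode
#' (e.g. chemogenetic inhibition) the bump is absent and all samples sit at
#' baseline.
#'
#' @param baseline Baseline LH, ng/ml.
#' @param onset_time Surge onset, clock hours (must be after the first
#'   sample so that sample is a valid baseline).
#' @param peak_amp Peak surge height above baseline, ng/ml (> baseline
#'   unless suppressed).
#' @param rise_tau,fall_tau Rise and decay time constants, hours.
#' @param sample_times Clock hours sampled (default 16, 19, 20, 21).
#' @param noise_cv Multiplicative lognormal noise CV.
#' @param lod Assay floor, ng/ml.
#' @param suppressed Logical; `TRUE` gives a flat baseline-level profile.
#' @param seed Integer seed.
#' @return A list of class `surge_params`.
#' @export
surge_params <- function(baseline = 0.3, onset_time = 17.5, peak_amp = 6,
                         rise_tau = 0.75, fall_tau = 4,
                         sample_times = c(16, 19, 20, 21),
                         noise_cv = 0.05, lod = 0.02,
                         suppressed = FALSE, seed = 1L) {
  stopifnot(baseline > 0, rise_tau > 0, fall_tau > 0,
            length(sample_times) >= 2L, !is.unsorted(sample_times),
            noise_cv >= 0, lod > 0)
  if (onset_time <= sample_times[1]) {
    stop("onset_time must be after the first (baseline) sample")
  }
  if (!suppressed && peak_amp <= baseline) {
    stop("peak_amp must exceed baseline for a surge")
  }
  structure(list(baseline = baseline, onset_time = onset_time,
                 peak_amp = peak_amp, rise_tau = rise_tau,
                 fall_tau = fall_tau, sample_times = sample_times,
                 noise_cv = noise_cv, lod = lod, suppressed = suppressed,
                 seed = as.integer(seed)),
            class = "surge_params")
}

#' Simulate a four-sample LH surge series
#'
#' @param params A [surge_params()] object.
#' @param animal_id Identifier copied into the series.
#' @return Data frame (`clock_hour`, `lh_ng_per_ml`, `animal_id`), class
#'   `lh_series`, attribute `mode = "surge"`.
#' @export
generate_surge <- function(params, animal_id = "animal1") {
  stopifnot(inherits(params, "surge_params"))
  p <- params
  g <- function(u) ifelse(u <= 0, 0,
                          (1 - exp(-u / p$rise_tau)) * exp(-u / p$fall_tau))
  u_peak <- p$rise_tau * log(1 + p$fall_tau / p$rise_tau)
  bump <- if (p$suppressed) 0 else {
    p$peak_amp * g(p$sample_times - p$onset_time) / g(u_peak)
  }
  lh <- p$baseline + bump
  if (p$noise_cv > 0) {
    lp <- lognorm_pars(1, p$noise_cv)
    lh <- lh * with_seed(p$seed + 2000003L,
                         stats::rlnorm(length(lh), lp$meanlog, lp$sdlog))
  }
  lh <- pmax(lh, p$lod)
  series <- data.frame(clock_hour = p$sample_times, lh_ng_per_ml = lh,
                       animal_id = animal_id, stringsAsFactors = FALSE)
  attr(series, "mode") <- "surge"
  class(series) <- c("lh_series", "data.frame")
  series
}

#' Write / read LH series as CSV
#'
#' The CSV dialect has one row per sample with a time column (`time_min` for
#' pulse series, `clock_hour` for surge series), `lh_ng_per_ml` and
#' `animal_id`; multiple animals may be stacked in one file.
#'
#' @param series An `lh_series` data frame (or several rbind-ed together).
#' @param path CSV path.
#' @return `path` invisibly (write); an `lh_series` (read).
#' @export
write_lh_series <- function(series, path) {
  utils::write.csv(as.data.frame(series), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_lh_series
#' @export
read_lh_series <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  attr(df, "mode") <- if ("time_min" %in% names(df)) "pulse" else "surge"
  class(df) <- c("lh_series", "data.frame")
  df
}
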