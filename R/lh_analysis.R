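# LH pulse identification by the nadir-to-peak rule, pulse summaries, and a
# fold-rise surge classifier.

#' Criteria for LH pulse identification
#'
#' A pulse is an increment in LH from nadir to peak of strictly more than
#' `min_increment_pct` percent, computed as `100 * (peak - nadir) / nadir`.
#' The default 25% reflects the validated tail-tip criterion for mouse LH.
#' `min_value` is a detectability floor: a nadir below it cannot anchor a
#' pulse (and guards the division by the nadir).
#'
#' @param min_increment_pct Percent increment threshold (strict `>`).
#' @param min_value Minimum valid nadir, ng/ml.
#' @return A list of class `pulse_criteria`.
#' @export
pulse_criteria <- function(min_increment_pct = 25, min_value = 0.02) {
  stopifnot(min_increment_pct > 0, min_value >= 0)
  structure(list(min_increment_pct = min_increment_pct,
                 min_value = min_value),
            class = "pulse_criteria")
}

# Local maxima of y: value >= both neighbours; the last sample counts when
# >= its inner neighbour; the first sample never serves as a peak (a pulse
# needs an observed rise).
.local_maxima <- function(y) {
  n <- length(y)
  i <- 2:n
  up <- y[i] >= y[i - 1L]
  down <- c(y[2:(n - 1L)] >= y[3:n], TRUE)
  i[up & down]
}

#' Identify LH pulses by the nadir-to-peak increment rule
#'
#' Left-to-right sweep: the running nadir is the minimum observed since the
#' last confirmed peak (initialised at the first sample). At each local
#' maximum, a pulse is called when the increment from the running nadir
#' strictly exceeds the criterion and the nadir is at or above the
#' detectability floor; on a call, the nadir search restarts after the peak.
#' Equal-valued consecutive maxima resolve to the earliest.
#'
#' @param series An `lh_series` in pulse mode (uniformly sampled), or any
#'   data frame with `time_min` and `lh_ng_per_ml` columns.
#' @param criteria A [pulse_criteria()] object.
#' @return Data frame of class `pulse_calls`: `nadir_time`, `nadir_value`,
#'   `peak_time`, `peak_value`, `increment_pct`, `amplitude` (peak minus
#'   nadir, ng/ml); attribute `duration_min` is the sampled span.
#' @export
detect_pulses <- function(series, criteria = pulse_criteria()) {
  stopifnot(inherits(criteria, "pulse_criteria"))
  t <- series$time_min
  y <- series$lh_ng_per_ml
  n <- length(y)
  if (n < 3L) stop("need at least 3 samples")
  if (any(y < 0)) stop("LH values must be non-negative")
  maxima <- .local_maxima(y)
  calls <- vector("list", 0L)
  start <- 1L
  for (p in maxima) {
    if (start > p - 1L) next
    win <- start:(p - 1L)
    nad_i <- win[which.min(y[win])]
    nad <- y[nad_i]
    if (nad == 0 && criteria$min_value <= 0) {
      stop("zero nadir with no detectability floor")
    }
    if (nad < criteria$min_value || nad <= 0) next
    inc <- 100 * (y[p] - nad) / nad
    if (inc > criteria$min_increment_pct) {
      calls[[length(calls) + 1L]] <- data.frame(
        nadir_time = t[nad_i], nadir_value = nad,
        peak_time = t[p], peak_value = y[p],
        increment_pct = inc, amplitude = y[p] - nad)
      start <- p + 1L
    }
  }
  out <- if (length(calls)) do.call(rbind, calls) else {
    data.frame(nadir_time = numeric(), nadir_value = numeric(),
               peak_time = numeric(), peak_value = numeric(),
               increment_pct = numeric(), amplitude = numeric())
  }
  attr(out, "duration_min") <- max(t) - min(t)
  class(out) <- c("pulse_calls", "data.frame")
  out
}

#' Summarize pulse calls for one series
#'
#' @param calls A `pulse_calls` data frame from [detect_pulses()].
#' @param series The series the calls came from.
#' @return List of class `pulse_summary`: `n_pulses`, `frequency_per_hour`
#'   (pulses over the sampled duration), `mean_amplitude` (ng/ml, `NA` when
#'   no pulses were called), `mean_lh` (ng/ml), `interpulse_intervals` (min,
#'   between successive peaks) and `mean_ipi` (min, `NA` when fewer than two
#'   pulses).
#' @export
summarize_pulses <- function(calls, series) {
  stopifnot(inherits(calls, "pulse_calls"))
  dur <- attr(calls, "duration_min")
  if (is.null(dur)) dur <- max(series$time_min) - min(series$time_min)
  n <- nrow(calls)
  ipi <- if (n >= 2L) diff(calls$peak_time) else numeric()
  structure(list(n_pulses = n,
                 frequency_per_hour = n / (dur / 60),
                 mean_amplitude = if (n > 0) mean(calls$amplitude) else NA_real_,
                 mean_lh = mean(series$lh_ng_per_ml),
                 interpulse_intervals = ipi,
                 mean_ipi = if (length(ipi)) mean(ipi) else NA_real_),
            class = "pulse_summary")
}

#' @export
print.pulse_summary <- function(x, ...) {
  cat(sprintf("%d pulses (%.2f /h), mean amplitude %s ng/ml, mean LH %.2f ng/ml\n",
              x$n_pulses, x$frequency_per_hour,
              if (is.na(x$mean_amplitude)) "NA" else sprintf("%.2f", x$mean_amplitude),
              x$mean_lh))
  invisible(x)
}

#' Classify a four-sample series as surge or no surge
#'
#' The first sample is the pre-surge baseline; the series is called a surge
#' when the maximum of the later samples exceeds `fold_threshold` times the
#' baseline AND an absolute floor. The criterion is an explicit convention
#' of this analysis (the underlying biology reports surge presence/absence
#' without a numeric rule), so the raw fold rise is always returned for
#' re-thresholding.
#'
#' @param series An `lh_series` in surge mode (>= 2 samples).
#' @param fold_threshold Fold-rise threshold `k` (strict `>`).
#' @param floor Absolute threshold `m` on the post-baseline maximum, ng/ml
#'   (strict `>`).
#' @return List of class `surge_call`: `baseline_value`, `max_post_value`,
#'   `fold_rise`, `is_surge`, `fold_threshold`, `floor`.
#' @export
classify_surge <- function(series, fold_threshold = 2.0, floor = 1.0) {
  y <- series$lh_ng_per_ml
  if (length(y) < 2L) stop("need at least 2 samples")
  baseline <- y[1L]
  if (baseline <= 0) stop("baseline must be positive")
  max_post <- max(y[-1L])
  fold <- max_post / baseline
  structure(list(baseline_value = baseline, max_post_value = max_post,
                 fold_rise = fold,
                 is_surge = fold > fold_threshold && max_post > floor,
                 fold_threshold = fold_threshold, floor = floor),
            class = "surge_call")
}
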