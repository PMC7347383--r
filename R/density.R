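# Per-segment synaptic density reporting: counts of contacted segments,
# percent contacted, and synapses per 10 um of dendrite, in the shape of the
# quantitative apposition table this analysis reproduces.

#' Synaptic density report from aggregate counts
#'
#' Density per 10 um is `10 * n_contacts_total / (denominator *
#' segment_length)` where the denominator is the number of contacted
#' segments (`"contacted_only"`, the default) or all segments counted
#' (`"all_segments"`). Percent contacted is `100 * n_contacted /
#' n_segments`. Display values are rounded to 1 decimal.
#'
#' @param n_segments Number of dendrite segments counted (> 0).
#' @param n_contacted Number of segments with at least one synaptic contact.
#' @param n_contacts_total Total synaptic contacts across segments.
#' @param segment_length Segment length, um pre-expansion (60 proximal /
#'   15 distal by convention).
#' @param zone `"proximal"` or `"distal"` (label only).
#' @param denominator_mode `"contacted_only"` or `"all_segments"`.
#' @param expansion_factor Optional expansion factor carried for provenance
#'   checks when reports are combined.
#' @return A list of class `density_report`.
#' @export
density_from_counts <- function(n_segments, n_contacted, n_contacts_total,
                                segment_length,
                                zone = c("distal", "proximal"),
                                denominator_mode = c("contacted_only",
                                                     "all_segments"),
                                expansion_factor = NA_real_) {
  zone <- match.arg(zone)
  denominator_mode <- match.arg(denominator_mode)
  if (n_segments <= 0) stop("need at least one segment")
  stopifnot(n_contacted >= 0, n_contacted <= n_segments,
            n_contacts_total >= 0, segment_length > 0)
  denom <- if (denominator_mode == "contacted_only") n_contacted else n_segments
  if (denom == 0) {
    if (n_contacts_total > 0) stop("contacts present but no contacted segments")
    warning("no contacted segments; density reported as 0")
    density <- 0
  } else {
    density <- 10 * n_contacts_total / (denom * segment_length)
  }
  structure(list(zone = zone, segment_length = segment_length,
                 n_segments = n_segments, n_contacted = n_contacted,
                 n_contacts_total = n_contacts_total,
                 percent_contacted = 100 * n_contacted / n_segments,
                 density_per_10um = density,
                 density_display = round(density, 1),
                 denominator_mode = denominator_mode,
                 expansion_factor = expansion_factor),
            class = "density_report")
}

#' Synaptic density report from per-segment contact counts
#'
#' @param counts_per_segment Integer vector: number of classified synaptic
#'   contacts on each segment (one element per segment analysed).
#' @inheritParams density_from_counts
#' @return A `density_report`; the sum of `counts_per_segment` equals the
#'   report's `n_contacts_total`.
#' @export
compute_density <- function(counts_per_segment,
                            segment_length,
                            zone = c("distal", "proximal"),
                            denominator_mode = c("contacted_only",
                                                 "all_segments"),
                            expansion_factor = NA_real_) {
  if (length(counts_per_segment) == 0) stop("need at least one segment")
  stopifnot(all(counts_per_segment >= 0))
  density_from_counts(n_segments = length(counts_per_segment),
                      n_contacted = sum(counts_per_segment > 0),
                      n_contacts_total = sum(counts_per_segment),
                      segment_length = segment_length, zone = zone,
                      denominator_mode = denominator_mode,
                      expansion_factor = expansion_factor)
}

#' @export
print.density_report <- function(x, ...) {
  cat(sprintf("%s dendrites (%g um segments, n = %d):\n", x$zone,
              x$segment_length, x$n_segments))
  cat(sprintf("  %% with contact: %.0f%%   contacts: %d   density: %.1f /10 um (%s)\n",
              x$percent_contacted, x$n_contacts_total, x$density_per_10um,
              x$denominator_mode))
  invisible(x)
}
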