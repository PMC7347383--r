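# Group comparisons (Mann-Whitney U, Holm-Sidak adjustment) and assembly of
# the combined synaptic-density / pulse / surge report.

#' Mann-Whitney U comparison of two groups
#'
#' Two-sided test on `group_a` vs `group_b`. With both groups of size at
#' most 8 and no ties the p-value is exact (full enumeration of rank
#' assignments); otherwise the tie-corrected normal approximation is used
#' (no continuity correction, so identical groups give p = 1). U is
#' reported for `group_a`; `U_a + U_b = n_a * n_b`.
#'
#' @param group_a,group_b Numeric vectors (each non-empty; at least 3 per
#'   group for a meaningful comparison).
#' @param mode `"auto"` (default), `"exact"` or `"normal_approx"`.
#' @return List of class `group_comparison`: `statistic_U`, `p_two_sided`,
#'   `method`, `n_a`, `n_b`.
#' @export
mann_whitney_u <- function(group_a, group_b,
                           mode = c("auto", "exact", "normal_approx")) {
  mode <- match.arg(mode)
  if (length(group_a) == 0 || length(group_b) == 0) stop("empty group")
  ties <- anyDuplicated(c(group_a, group_b)) > 0
  exact_ok <- length(group_a) <= 8 && length(group_b) <= 8 && !ties
  if (mode == "exact" && !exact_ok) {
    stop("exact mode requires both groups <= 8 with no ties")
  }
  use_exact <- switch(mode, auto = exact_ok, exact = TRUE,
                      normal_approx = FALSE)
  res <- suppressWarnings(
    stats::wilcox.test(group_a, group_b, alternative = "two.sided",
                       exact = use_exact, correct = FALSE)
  )
  structure(list(statistic_U = unname(res$statistic),
                 p_two_sided = res$p.value,
                 method = if (use_exact) "exact" else "normal_approx",
                 n_a = length(group_a), n_b = length(group_b)),
            class = "group_comparison")
}

#' Holm-Sidak step-down adjustment of p-values
#'
#' Sort the `m` raw p-values ascending; the i-th adjusted value is
#' `max_{j <= i} (1 - (1 - p_(j))^(m - j + 1))`, capped at 1, with the
#' original ordering restored. Adjusted values are elementwise at least the
#' raw values and invariant to input order.
#'
#' @param raw_p Numeric vector of p-values in (0, 1].
#' @return List of class `adjusted_pvalues`: `raw`, `adjusted`, `procedure`.
#' @export
holm_sidak <- function(raw_p) {
  stopifnot(length(raw_p) >= 1L, all(raw_p > 0), all(raw_p <= 1))
  m <- length(raw_p)
  o <- order(raw_p)
  ps <- raw_p[o]
  adj <- pmin(cummax(1 - (1 - ps)^(m - seq_len(m) + 1)), 1)
  out <- numeric(m)
  out[o] <- adj
  structure(list(raw = raw_p, adjusted = out, procedure = "holm_sidak"),
            class = "adjusted_pvalues")
}

#' Assemble the combined density / pulse / surge report
#'
#' Produces a table of per-zone synaptic densities (counts, percent
#' contacted, density per 10 um with its denominator convention), the
#' distal:proximal density ratio computed on the 1-decimal displayed
#' densities (the convention of the printed table it mirrors), per-group
#' pulse summaries, surge incidence, and group comparisons with Holm-Sidak
#' adjusted p-values.
#'
#' @param density_reports List of `density_report`s (may be empty). An error
#'   is raised when they carry differing non-missing expansion factors.
#' @param pulse_summaries Named list of lists of `pulse_summary`s, one
#'   element per experimental group.
#' @param surge_calls Named list of lists of `surge_call`s, one element per
#'   group.
#' @param comparisons Named list of `group_comparison`s.
#' @return List of class `synapse_lh_report` with `density_table`,
#'   `density_ratio_distal_over_proximal`, `pulse_table`, `surge_table`,
#'   `comparison_table`.
#' @export
build_report <- function(density_reports = list(), pulse_summaries = list(),
                         surge_calls = list(), comparisons = list()) {
  efs <- vapply(density_reports, function(d) d$expansion_factor, numeric(1))
  efs <- efs[!is.na(efs)]
  if (length(unique(efs)) > 1L) {
    stop("density reports carry differing expansion factors")
  }
  density_table <- if (length(density_reports)) {
    do.call(rbind, lapply(density_reports, function(d) {
      data.frame(zone = d$zone, segment_length_um = d$segment_length,
                 n_segments = d$n_segments, n_contacted = d$n_contacted,
                 percent_contacted = d$percent_contacted,
                 n_contacts_total = d$n_contacts_total,
                 density_per_10um = d$density_per_10um,
                 density_display = d$density_display,
                 denominator_mode = d$denominator_mode,
                 stringsAsFactors = FALSE)
    }))
  } else {
    data.frame(zone = character(), segment_length_um = numeric(),
               n_segments = integer(), n_contacted = integer(),
               percent_contacted = numeric(), n_contacts_total = integer(),
               density_per_10um = numeric(), density_display = numeric(),
               denominator_mode = character(), stringsAsFactors = FALSE)
  }
  ratio <- NA_real_
  if (all(c("proximal", "distal") %in% density_table$zone)) {
    dprox <- density_table$density_display[density_table$zone == "proximal"][1]
    ddist <- density_table$density_display[density_table$zone == "distal"][1]
    if (dprox > 0) ratio <- ddist / dprox
  }
  pulse_table <- if (length(pulse_summaries)) {
    do.call(rbind, lapply(names(pulse_summaries), function(g) {
      ss <- pulse_summaries[[g]]
      data.frame(group = g, n_animals = length(ss),
                 mean_n_pulses = mean(vapply(ss, `[[`, 1, "n_pulses")),
                 mean_frequency_per_hour =
                   mean(vapply(ss, `[[`, 1, "frequency_per_hour")),
                 mean_amplitude =
                   mean(vapply(ss, `[[`, 1, "mean_amplitude"), na.rm = TRUE),
                 mean_lh = mean(vapply(ss, `[[`, 1, "mean_lh")),
                 stringsAsFactors = FALSE)
    }))
  } else {
    data.frame(group = character(), n_animals = integer(),
               mean_n_pulses = numeric(), mean_frequency_per_hour = numeric(),
               mean_amplitude = numeric(), mean_lh = numeric(),
               stringsAsFactors = FALSE)
  }
  surge_table <- if (length(surge_calls)) {
    do.call(rbind, lapply(names(surge_calls), function(g) {
      cs <- surge_calls[[g]]
      data.frame(group = g, n_animals = length(cs),
                 n_surge = sum(vapply(cs, `[[`, TRUE, "is_surge")),
                 mean_fold_rise = mean(vapply(cs, `[[`, 1, "fold_rise")),
                 stringsAsFactors = FALSE)
    }))
  } else {
    data.frame(group = character(), n_animals = integer(),
               n_surge = integer(), mean_fold_rise = numeric(),
               stringsAsFactors = FALSE)
  }
  comparison_table <- if (length(comparisons)) {
    raw <- vapply(comparisons, `[[`, 1, "p_two_sided")
    adj <- holm_sidak(raw)$adjusted
    data.frame(comparison = names(comparisons),
               U = vapply(comparisons, `[[`, 1, "statistic_U"),
               p_raw = raw, p_holm_sidak = adj,
               method = vapply(comparisons, `[[`, "", "method"),
               stringsAsFactors = FALSE)
  } else {
    data.frame(comparison = character(), U = numeric(), p_raw = numeric(),
               p_holm_sidak = numeric(), method = character(),
               stringsAsFactors = FALSE)
  }
  rownames(density_table) <- rownames(pulse_table) <- NULL
  rownames(surge_table) <- rownames(comparison_table) <- NULL
  structure(list(density_table = density_table,
                 density_ratio_distal_over_proximal = ratio,
                 pulse_table = pulse_table,
                 surge_table = surge_table,
                 comparison_table = comparison_table),
            class = "synapse_lh_report")
}

#' Write / read a report as JSON
#' @param report A `synapse_lh_report`.
#' @param path JSON path.
#' @return `path` invisibly (write); a `synapse_lh_report` (read).
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "synapse_lh_report"))
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       na = "null", dataframe = "rows")
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(x$density_ratio_distal_over_proximal)) {
    x$density_ratio_distal_over_proximal <- NA_real_
  }
  x[c("density_table", "pulse_table", "surge_table", "comparison_table")] <-
    lapply(x[c("density_table", "pulse_table", "surge_table",
               "comparison_table")], as.data.frame)
  structure(x, class = "synapse_lh_report")
}

#' Render a report as Markdown
#' @param report A `synapse_lh_report`.
#' @param path Output path for the Markdown file.
#' @return `path`, invisibly.
#' @export
render_report_md <- function(report, path) {
  stopifnot(inherits(report, "synapse_lh_report"))
  fmt_table <- function(df) {
    if (!nrow(df)) return("(no data)\n")
    num <- vapply(df, is.numeric, TRUE)
    df[num] <- lapply(df[num], function(x) signif(x, 4))
    header <- paste0("| ", paste(names(df), collapse = " | "), " |")
    sep <- paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|")
    rows <- apply(df, 1, function(r) paste0("| ", paste(r, collapse = " | "), " |"))
    paste(c(header, sep, rows, ""), collapse = "\n")
  }
  lines <- c(
    "# Synaptic density and LH secretion report", "",
    "## Synaptic density (per 10 um, pre-expansion)", "",
    fmt_table(report$density_table),
    if (!is.na(report$density_ratio_distal_over_proximal)) {
      sprintf("Distal:proximal density ratio (displayed densities): %.1f\n",
              report$density_ratio_distal_over_proximal)
    },
    "## LH pulses (per group)", "", fmt_table(report$pulse_table),
    "## LH surge incidence", "", fmt_table(report$surge_table),
    "## Group comparisons (Mann-Whitney, Holm-Sidak adjusted)", "",
    fmt_table(report$comparison_table))
  writeLines(lines, path)
  invisible(path)
}
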