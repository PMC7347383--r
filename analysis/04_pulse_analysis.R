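#!/usr/bin/env Rscript
# Step 4: apply the nadir-to-peak >25% pulse rule and the fold-rise surge
# classifier to the simulated bleed series, summarize per animal, and
# compare groups (Mann-Whitney on amplitude and frequency, Holm-Sidak
# across the comparison family).

library(synpulse)

pulse <- read_lh_series("results/lh/pulse_series.csv")
summaries <- list()
rows <- data.frame()
for (id in unique(pulse$animal_id)) {
  ser <- pulse[pulse$animal_id == id, ]
  calls <- detect_pulses(ser)
  sm <- summarize_pulses(calls, ser)
  group <- sub("_[0-9]+$", "", id)
  summaries[[group]] <- c(summaries[[group]], list(sm))
  rows <- rbind(rows, data.frame(animal_id = id, group = group,
                                 n_pulses = sm$n_pulses,
                                 frequency_per_hour = sm$frequency_per_hour,
                                 mean_amplitude = sm$mean_amplitude,
                                 mean_lh = sm$mean_lh))
}
write.csv(rows, "results/pulse_summaries.csv", row.names = FALSE)
message("per-group means:")
print(aggregate(rows[, c("frequency_per_hour", "mean_amplitude", "mean_lh")],
                by = list(group = rows$group), FUN = mean))

amp <- split(rows$mean_amplitude, rows$group)
freq <- split(rows$frequency_per_hour, rows$group)
comparisons <- list(
  amplitude_saline_vs_inhibited = mann_whitney_u(amp$saline, amp$inhibited),
  frequency_saline_vs_inhibited = mann_whitney_u(freq$saline, freq$inhibited))
adj <- holm_sidak(vapply(comparisons, `[[`, 1, "p_two_sided"))
message(sprintf("amplitude: U = %g, p = %.4g (Holm-Sidak %.4g)",
                comparisons[[1]]$statistic_U, adj$raw[1], adj$adjusted[1]))
message(sprintf("frequency: U = %g, p = %.4g (Holm-Sidak %.4g)",
                comparisons[[2]]$statistic_U, adj$raw[2], adj$adjusted[2]))

surge <- read_lh_series("results/lh/surge_series.csv")
surge_calls <- list()
for (id in unique(surge$animal_id)) {
  ser <- surge[surge$animal_id == id, ]
  group <- sub("_[0-9]+$", "", id)
  surge_calls[[group]] <- c(surge_calls[[group]],
                            list(classify_surge(ser)))
}
for (g in names(surge_calls)) {
  n_surge <- sum(vapply(surge_calls[[g]], `[[`, TRUE, "is_surge"))
  message(sprintf("surge incidence in %s: %d / %d", g, n_surge,
                  length(surge_calls[[g]])))
}

saveRDS(list(summaries = summaries, comparisons = comparisons,
             surge_calls = surge_calls), "scratch/lh_analysis.rds")
jsonlite::write_json(
  list(comparisons = lapply(comparisons, unclass),
       holm_sidak_adjusted = adj$adjusted),
  "results/comparisons.json", auto_unbox = TRUE, digits = NA)
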