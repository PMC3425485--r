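#!/usr/bin/env Rscript
# Stage 2 — event-log analysis.
#
# Reads the study tables from results/data/ and derives, per tray and
# species: foraging bouts (one-minute gap rule), minimum residency
# times, quitting points with cumulative peck counts, and the
# minimum-individual densities from visit concurrency.

suppressPackageStartupMessages(library(gudpeck))

study <- read_study(list(trials = "results/data/trials.csv",
                         pecks = "results/data/pecks.csv",
                         intervals = "results/data/intervals.csv"))
events <- analyze_events(study)

dir.create("results/events", showWarnings = FALSE, recursive = TRUE)
write_results(events$bouts, "results/events/bouts.csv")
write_results(events$quit_points, "results/events/quit_points.csv")
write_results(events$foraging_times, "results/events/foraging_times.csv")
write_results(events$density, "results/events/density.csv")

cat(sprintf("Segmented %d bouts across %d tray-species series.\n",
            nrow(events$bouts), nrow(events$foraging_times)))
cat(sprintf("Quitting points for %d species-tray visits; %d final foragers.\n",
            nrow(events$quit_points),
            sum(events$quit_points$is_final_forager)))
dens <- unique(events$density[c("tray_id", "tray_total_min_individuals")])
cat(sprintf("Tray densities (minimum individuals): median %d, range %d-%d.\n",
            as.integer(stats::median(dens$tray_total_min_individuals)),
            min(dens$tray_total_min_individuals),
            max(dens$tray_total_min_individuals)))
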