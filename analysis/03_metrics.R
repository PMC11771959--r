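#!/usr/bin/env Rscript
# Per-day central-place foraging metrics from the filtered tracks:
# colony distances, daily route under the 10-hr coverage rule, colony
# visits detected from reception gaps, foraging/net foraging durations,
# flight speed, roost timing relative to sunset/sunrise, and
# inter-individual distance in 5-min bins.
suppressPackageStartupMessages(library(aeroforage))

out <- "results/run"
fixes <- read_fixes(file.path(out, "filtered.csv"))
met <- compute_daily_metrics(fixes, site_config())

write.csv(met$daily, file.path(out, "metrics.csv"), row.names = FALSE)
if (!is.null(met$visits))
  write.csv(transform(met$visits, entry = format(entry, "%Y-%m-%dT%H:%M:%OS6Z"),
                      exit = format(exit, "%Y-%m-%dT%H:%M:%OS6Z")),
            file.path(out, "visits.csv"), row.names = FALSE)

d <- met$daily
cat(sprintf("%d days; active tags/day: %.1f +/- %.1f\n",
            nrow(d), mean(d$n_tags), sd(d$n_tags)))
cat(sprintf("Mean colony distance: %.0f m; max: %.0f m; route (when defined): %.1f km\n",
            mean(d$mean_dist), mean(d$max_dist),
            mean(d$route, na.rm = TRUE) / 1000))
cat(sprintf("Visits: %.2f per tag per hour; arrival %.1f min vs sunset; roost %.2f +/- %.2f h\n",
            mean(d$visit_freq), mean(d$arrival_offset, na.rm = TRUE),
            mean(d$roost_dur, na.rm = TRUE), sd(d$roost_dur, na.rm = TRUE)))
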