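#!/usr/bin/env Rscript
# Insect movement traffic rate from the radar echo table: per-echo 1-km
# beam-width normalization, hourly totals, and the 05:00-20:00 daily mean.
suppressPackageStartupMessages(library(aeroforage))

out <- "results/run"
echoes <- read_echoes(file.path(out, "echoes.csv"))
ms <- motr_series(echoes, beam_config(), site_config())

write.csv(ms$hourly, file.path(out, "motr_hourly.csv"), row.names = FALSE)
write.csv(ms$daily, file.path(out, "motr.csv"), row.names = FALSE)

m <- ms$daily$motr
cat(sprintf("Daily MoTR over %d days: %.1f +/- %.1f insects/km/hr (range %.1f-%.1f)\n",
            length(m), mean(m), sd(m), min(m), max(m)))
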