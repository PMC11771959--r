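#!/usr/bin/env Rscript
# Clean the raw fix table: daylight restriction, then the four fix-level
# filters (30 m/s speed, pooled 1.5xIQR StdLoc fence, NBS >= 4, 500 m
# jump) and the minimum-four-active-tags day rule, with per-stage
# attrition accounting.
suppressPackageStartupMessages(library(aeroforage))
library(jsonlite)

out <- "results/run"
fixes <- read_fixes(file.path(out, "fixes.csv"))
res <- run_filter_chain(fixes, filter_config(), site_config())

write_fixes(res$fixes, file.path(out, "filtered.csv"))
write_json(res$attrition, file.path(out, "attrition.json"),
           auto_unbox = TRUE, digits = NA)

at <- res$attrition
cat(sprintf("Raw daylight fixes: %d  (removed before daylight: %d)\n",
            at$raw_n, at$pre_daylight_removed))
print(transform(at$stages, pct_of_raw = round(100 * frac_of_raw, 1)))
cat(sprintf("StdLoc fence: %.1f m\n", at$stdloc_fence))
cat(sprintf("Fix-level filters removed %.1f%%; day rule removed %.1f%%; total %.1f%%\n",
            100 * at$total_removed_frac, 100 * at$day_rule_frac,
            100 * at$grand_total_frac))
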