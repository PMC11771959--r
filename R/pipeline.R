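#' Run the full simulate -> filter -> metrics -> MoTR -> fit chain
#'
#' Orchestrates one reproducible end-to-end run on simulated data: draws
#' the per-day true MoTR, simulates fix and echo tables, writes them to
#' `out_dir`, reads them back (so every artifact round-trips through its
#' reader/writer), runs the filter chain with attrition accounting,
#' extracts the behavioural metrics, estimates MoTR from the echoes, joins
#' the two day tables and fits the model suite. All stages derive their
#' seeds from `cfg$seed`; a manifest with the seed and full configuration
#' is written next to the artifacts.
#'
#' @param cfg A [truth_config()].
#' @param out_dir Output directory (created if needed).
#' @param site A [site_config()].
#' @param filter_cfg A [filter_config()].
#' @param beam A [beam_config()].
#' @param colony_radius_m Visit-attribution radius passed to
#'   [compute_daily_metrics()].
#' @param fit_models If `FALSE`, stop after the metrics/MoTR join (useful
#'   for runs too short to support the model suite).
#' @return Invisibly, a list: `truth`, `attrition`, `metrics`, `motr`,
#'   `joined`, and (when fitted) `report` from [run_paper_models()].
#' @export
run_all <- function(cfg, out_dir, site = site_config(),
                    filter_cfg = filter_config(), beam = beam_config(),
                    colony_radius_m = 100, fit_models = TRUE) {
  stopifnot(inherits(cfg, "truth_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(out_dir, f)

  motr_true <- generate_motr_days(cfg)
  world <- generate_tracks(cfg, motr_true, site)
  dates <- cfg$start_date + seq_len(cfg$n_days) - 1
  echoes <- do.call(rbind, lapply(seq_len(cfg$n_days), function(d)
    generate_echoes(dates[d], motr_true[d], beam, site,
                    seed = cfg$seed + 100L + d)))
  write_fixes(world$fixes, p("fixes.csv"))
  write_echoes(echoes, p("echoes.csv"))
  write_truth(world$truth, p("truth.json"))

  fixes <- read_fixes(p("fixes.csv"))
  filt <- run_filter_chain(fixes, filter_cfg, site)
  write_fixes(filt$fixes, p("filtered.csv"))
  jsonlite::write_json(filt$attrition, p("attrition.json"),
                       auto_unbox = TRUE, digits = NA)

  met <- compute_daily_metrics(filt$fixes, site,
                               colony_radius_m = colony_radius_m)
  utils::write.csv(met$daily, p("metrics.csv"), row.names = FALSE)
  if (!is.null(met$visits))
    utils::write.csv(
      transform(met$visits, entry = .format_ts(entry),
                exit = .format_ts(exit)),
      p("visits.csv"), row.names = FALSE)

  ms <- motr_series(read_echoes(p("echoes.csv")), beam, site)
  utils::write.csv(ms$daily, p("motr.csv"), row.names = FALSE)

  joined <- merge(met$daily, ms$daily, by = "date")
  res <- list(truth = world$truth, attrition = filt$attrition,
              metrics = met$daily, motr = ms$daily, joined = joined)
  if (fit_models) {
    report <- run_paper_models(joined)
    res$report <- report
    jsonlite::write_json(
      list(table1 = report$table1, table2 = report$table2$models,
           table2_average = report$table2$average,
           seasonal = report$seasonal),
      p("report.json"), auto_unbox = TRUE, digits = NA)
  }
  jsonlite::write_json(
    list(seed = cfg$seed,
         config = within(as.list(unclass(cfg)),
                         start_date <- as.character(start_date)),
         site = unclass(site), filter = unclass(filter_cfg),
         beam = unclass(beam)),
    p("manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(res)
}
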