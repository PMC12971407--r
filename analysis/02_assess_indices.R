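# Stage 2 -- ecosystem health (VORS) and human activity intensity.
#
# Computes per-unit EV / EO / ER / ESI and their geometric mean EHI, the
# SLUCC + population + nighttime-light composite HAI, and five-level
# gradings of both. Normalizations pool both years, so levels are
# comparable over time.

source("analysis/00_config.R")

cfg <- analysis_config(drivers_enabled = FALSE)
rep <- suppressWarnings(suppressMessages(run_pipeline(cfg)))

out <- results_dir("indices")
write.csv(rep$vors, file.path(out, "vors_units.csv"), row.names = FALSE)
write.csv(rep$hai, file.path(out, "hai_units.csv"), row.names = FALSE)
jsonlite::write_json(
  list(ehi = rep$level_shares$ehi, hai = rep$level_shares$hai,
       service_weights = as.list(rep$service_weights)),
  file.path(out, "level_shares.json"), auto_unbox = TRUE, pretty = TRUE)

for (y in rep$years) {
  e <- rep$vors$ehi[rep$vors$year == y]
  h <- rep$hai$hai[rep$hai$year == y]
  say("%s: mean EHI %.3f (poor-or-worse %.1f%%), mean HAI %.3f (good-or-better %.1f%%)",
      y, mean(e), sum(rep$level_shares$ehi[[y]][c("very poor", "poor")]),
      mean(h), sum(rep$level_shares$hai[[y]][c("good", "excellent")]))
}
say("entropy service weights: %s",
    paste(sprintf("%s %.3f", names(rep$service_weights),
                  rep$service_weights), collapse = ", "))
say("unit-level correlation between HAI and EHI: %.3f",
    cor(rep$hai$hai, rep$vors$ehi))
say("unit tables written to %s/", out)
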