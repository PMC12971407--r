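# Stage 1 -- generate the synthetic study landscape.
#
# Produces the multi-year raster stack the rest of the analysis consumes:
# land cover on a six-class legend concentrated along an elevation
# gradient, NPP responding to temperature, soil moisture and a piecewise
# PET effect (slope change at 850 mm), five ecosystem-service layers, and
# human-activity layers (population, nighttime lights, GDP) negatively
# coupled to ecological condition and drifting upward between years.

source("analysis/00_config.R")

cfg <- analysis_config()
sc <- cfg$scenario
sc$seed <- ecocoupling:::sub_seed(cfg$seed, 1L)
ds <- make_scenario(sc)

out <- results_dir("simulated")
write_grid(ds$landcover, file.path(out, "landcover.asc"))
write_grid(ds$elevation, file.path(out, "elevation.asc"))
for (y in names(ds$years)) {
  write_grid(ds$years[[y]]$npp, file.path(out, paste0("npp_", y, ".asc")))
  write_grid(ds$years[[y]]$ntl, file.path(out, paste0("ntl_", y, ".asc")))
}
jsonlite::write_json(ds$truth, file.path(out, "truth.json"),
                     auto_unbox = TRUE, pretty = TRUE)

shares <- table(factor(ds$landcover$codes, levels = unname(lc_legend()),
                       labels = names(lc_legend()))) /
  length(ds$landcover$codes)
say("landscape %d x %d cells, %d years, seed %d",
    nrow(ds$landcover$codes), ncol(ds$landcover$codes),
    length(ds$years), analysis_seed)
say("realized cover shares: %s",
    paste(sprintf("%s %.1f%%", names(shares), 100 * as.numeric(shares)),
          collapse = ", "))
say("mean NPP year1 %.1f -> year%d %.1f",
    mean(ds$years[[1]]$npp$values), length(ds$years),
    mean(ds$years[[length(ds$years)]]$npp$values))
say("mean NTL year1 %.2f -> year%d %.2f (planted drift %.0f%%/yr)",
    mean(ds$years[[1]]$ntl$values), length(ds$years),
    mean(ds$years[[length(ds$years)]]$ntl$values), 100 * ds$truth$drift)
say("planted PET breakpoint: %s mm",
    ds$truth$breakpoints[[1]]$breakpoint)
say("rasters and truth record written to %s/", out)
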