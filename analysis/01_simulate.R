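#!/usr/bin/env Rscript
# Stage 1: simulate the synthetic study landscape.
#
# Builds the default volcano scene — a 200x200-cell (10x10 km, 50 m) cone
# with correlated roughness, lapse-rate monthly climate, the nine-factor
# set, and an expansion-only presence series observed in 2002/2010/2017/
# 2021 — and writes the rasters plus the truth ledger under results/scene/.

library(treelineq)

out <- "results/scene"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

truth <- synthetic_truth(seed = 42L)
scene <- simulate_scene(truth)

write_ascii_grid(scene$dem, file.path(out, "dem.asc"))
for (nm in names(scene$factors))
  write_ascii_grid(scene$factors[[nm]], file.path(out, paste0("factor_", nm, ".asc")))
for (y in scene$series$years)
  write_ascii_grid(scene$series$maps[[as.character(y)]],
                   file.path(out, paste0("cover_", y, ".asc")))

jsonlite::write_json(
  list(seed = truth$seed, grid = c(truth$nrow, truth$ncol),
       cell_size = truth$cell_size, years = truth$years,
       summit = attr(scene$dem, "summit"),
       beta0 = truth$beta0, beta = as.list(truth$beta),
       beta_int = truth$beta_int,
       colonization_scale = truth$colonization_scale,
       neighborhood_radius = truth$neighborhood_radius,
       init_quantile = truth$init_quantile, lapse_rate = truth$lapse_rate),
  file.path(out, "truth.json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)

pres <- sapply(scene$series$maps, function(m) sum(m$values == 1, na.rm = TRUE))
cat("Simulated scene written to", out, "\n")
cat("Presence cells by year:",
    paste(scene$series$years, pres, sep = ": ", collapse = ", "), "\n")
cat("Elevation range:", round(range(scene$dem$values)), "m\n")
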