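#!/usr/bin/env Rscript
# Stage 4: expansion metrics from the multi-year cover maps.
#
# Reads the cover series and sector/slope-class rasters, builds the
# 2002-2021 change map, per-sector areas, annual expansion rates (the
# full-period rate under the inclusive span convention) and maximum
# presence elevations, the slope-class distribution of presence, and the
# 500 m density-increase response used by the detectors. Products go to
# results/change/.

library(treelineq)

out <- "results/change"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

dem <- read_ascii_grid("results/scene/dem.asc")
yrs <- sub("^cover_(\\d+)\\.asc$", "\\1", list.files("results/scene", "^cover_"))
series <- cover_series(as.integer(yrs),
                       lapply(list.files("results/scene", "^cover_",
                                         full.names = TRUE), read_ascii_grid))
sectors <- read_ascii_grid("results/terrain/sectors.asc")
attr(sectors, "legend") <- c("northern", "eastern", "southern", "western")
slope_class <- read_ascii_grid("results/terrain/slope_class.asc")
attr(slope_class, "legend") <- c("plain", "gentle ramp", "ramp", "steep",
                                 "very steep", "scarp", "vertical")

ch <- change_map(series, min(series$years), max(series$years))
areas <- attr(ch, "areas_hm2")
cat(sprintf("2002-2021 change: %.1f hm2 unchanged, %.1f hm2 expanded, %.1f hm2 reduced\n",
            areas[["unchanged"]], areas[["expanded"]], areas[["reduced"]]))
tot_rate <- annual_rate(areas[["unchanged"]],
                        areas[["unchanged"]] + areas[["expanded"]],
                        year_span(min(series$years), max(series$years),
                                  "inclusive"))
cat(sprintf("Whole-area annual expansion rate (inclusive span): %.2f %% a-1\n",
            tot_rate))

summ <- sector_summary(series, sectors, dem, span_convention = "inclusive")
sdist <- slope_distribution(series, slope_class)
dens <- density_increase(ch, 10L)

write_ascii_grid(ch, file.path(out, "change_map.asc"))
write_ascii_grid(dens, file.path(out, "density_increase.asc"))
write.csv(summ$areas, file.path(out, "sector_areas.csv"), row.names = FALSE)
write.csv(summ$rates, file.path(out, "sector_rates.csv"), row.names = FALSE)
write.csv(sdist, file.path(out, "slope_distribution.csv"), row.names = FALSE)
write.csv(as_response_table(dens), file.path(out, "density_response.csv"),
          row.names = FALSE)

cat("Per-sector full-period rates (% a-1):\n")
full <- summ$rates[summ$rates$from == min(series$years) &
                     summ$rates$to == max(series$years), ]
print(full, row.names = FALSE)
cat("Maximum presence elevation by sector, final year (m):\n")
fin <- summ$areas[summ$areas$year == max(series$years), ]
print(fin[, c("sector", "max_elevation_m")], row.names = FALSE)
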