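#!/usr/bin/env Rscript
# Stage 2: derive the topographic factors from the simulated DEM.
#
# Reads results/scene/dem.asc and derives slope, aspect, 3x3 relief, D8
# specific catchment, TWI, the seven slope classes and the summit-azimuth
# aspect sectors (eastern sector masked, mirroring a study-area
# exclusion). Products go to results/terrain/.

library(treelineq)

out <- "results/terrain"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

dem <- read_ascii_grid("results/scene/dem.asc")
terr <- terrain_stack(dem)
summit <- c(ncol(dem$values) * dem$cell_size / 2,
            nrow(dem$values) * dem$cell_size / 2)
sectors <- assign_aspect_sector(dem, summit, mask = "eastern")

write_ascii_grid(terr$slope_deg, file.path(out, "slope_deg.asc"))
write_ascii_grid(terr$aspect_deg, file.path(out, "aspect_deg.asc"))
write_ascii_grid(terr$relief, file.path(out, "relief.asc"))
write_ascii_grid(terr$twi, file.path(out, "twi.asc"))
write_ascii_grid(terr$slope_class, file.path(out, "slope_class.asc"))
write_ascii_grid(sectors, file.path(out, "sectors.asc"))
writeLines(c("slope_class legend: 1 plain [0,2) | 2 gentle ramp [2,5) | 3 ramp [5,15)",
             "  4 steep [15,25) | 5 very steep [25,35) | 6 scarp [35,55) | 7 vertical >= 55",
             "sectors legend: 1 northern | 2 eastern (masked) | 3 southern | 4 western"),
           file.path(out, "legends.txt"))

cat("Slope class distribution (cells):\n")
print(table(terr$slope_class$values))
cat("Sector sizes (cells):\n")
print(table(sectors$values))
cat("TWI range:", round(range(terr$twi$values, na.rm = TRUE), 2), "\n")
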