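#!/usr/bin/env Rscript
# Stage 3: climate downscaling check and factor pruning.
#
# Regenerates the scene's monthly climate, aggregates the August mean
# temperature to a 500 m grid (emulating a coarse climate product),
# downscales it back to 50 m with the terrain regression, and scores the
# prediction against the fine-grid truth at 200 random station cells.
# Then prunes the nine-factor set at |r| > 0.90. Products go to
# results/climate/.

library(treelineq)

out <- "results/climate"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

truth <- synthetic_truth(seed = 42L)
dem <- read_ascii_grid("results/scene/dem.asc")
clim <- generate_climate(dem, truth)

fine_aug <- clim$tmean[[8]]
coarse_aug <- aggregate_raster(fine_aug, 10)        # 50 m -> 500 m
coarse_dem <- aggregate_raster(dem, 10)
fine_topo <- terrain_stack(dem)
coarse_topo <- terrain_stack(coarse_dem)

pred <- downscale_mlr(coarse_aug, coarse_topo, fine_topo)
set.seed(42)
st <- data.frame(x = runif(200, 0, 1e4), y = runif(200, 0, 1e4))
skill <- validate_downscaling(extract_at_points(pred, st$x, st$y),
                              extract_at_points(fine_aug, st$x, st$y))
write.csv(data.frame(metric = c("rmse", "r2"),
                     value = c(skill$rmse, skill$r2)),
          file.path(out, "downscaling_validation.csv"), row.names = FALSE)
cat(sprintf("August downscaling skill at 200 stations: RMSE %.3f, R2 %.3f\n",
            skill$rmse, skill$r2))
cat(sprintf("Fitted lapse coefficient: %.6f degC/m (truth %.4f)\n",
            coef(attr(pred, "model"))[["elev"]], truth$lapse_rate))

factors <- lapply(list.files("results/scene", "^factor_", full.names = TRUE),
                  read_ascii_grid)
names(factors) <- sub("^factor_(.*)\\.asc$", "\\1",
                      list.files("results/scene", "^factor_"))
pruned <- prune_correlated(factors, threshold = 0.90)
cat("Factors kept after |r| > 0.90 pruning:",
    paste(names(pruned$kept), collapse = ", "), "\n")
if (nrow(pruned$dropped)) {
  cat("Dropped:\n"); print(pruned$dropped)
  write.csv(pruned$dropped, file.path(out, "pruned_factors.csv"),
            row.names = FALSE)
}
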