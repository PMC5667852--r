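#!/usr/bin/env Rscript
# Stage 1: simulate the synthetic study landscape.
#
# The study region is a 200 x 200 km grid holding three reserve pairs in
# water-separated compartments: a planted open corridor (west), a corridor
# cut by a thin converted band that serves as the severed reference (center),
# and a corridor cut by a thick band (east). Interview-style validation
# points are planted on/off the open corridor. Everything downstream reads
# the files this script writes.

library(corridornet)

seed <- 1
out <- "results/landscape"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

spec <- demo_landscape_spec(seed = seed)
bundle <- generate_landscape(spec)

write_ascii_grid(bundle$conversion, file.path(out, "conversion.asc"))
write_ascii_grid(bundle$water_mask, file.path(out, "water.asc"))
write_pas_geojson(bundle$pas, file.path(out, "pas.geojson"))
write_validation_points(bundle$points, file.path(out, "points.csv"))
write.csv(bundle$truth, file.path(out, "truth.csv"), row.names = FALSE)

frac <- mean(bundle$conversion$values)
cat(sprintf("landscape: %d x %d cells at %.0f km, seed %d\n",
            spec$grid_rows, spec$grid_cols, spec$cell_size_km, seed))
cat(sprintf("converted cells overall: %.1f%% (background target %.0f%%)\n",
            100 * frac, 100 * spec$conversion_fraction))
cat(sprintf("reserves: %d | planted links: %d | validation points: %d+%d\n",
            nrow(bundle$pas), nrow(bundle$truth),
            sum(bundle$points$label == "movement"),
            sum(bundle$points$label == "none")))
cat("ground truth:\n")
print(bundle$truth, row.names = FALSE)
cat("wrote", out, "\n")
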