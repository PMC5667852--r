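#!/usr/bin/env Rscript
# Stage 2: build the factorial cost-surface set and the near-future
# conversion projection.
#
# Three base costs (10 / 100 / 1000, the assumed difficulty of crossing a
# converted cell) x five neighborhoods (none, 3x3 .. 9x9 focal mean, the
# assumed reach of conversion's influence) give 15 resistance surfaces;
# large water bodies are masked out of each as hard barriers.

library(corridornet)

land <- "results/landscape"
conv_raw <- read_ascii_grid(file.path(land, "conversion.asc"))
conv <- conversion_grid(conv_raw$values, conv_raw$cell_size_km)
water <- read_ascii_grid(file.path(land, "water.asc"))

surfaces <- build_cost_surface_set(conv, water_mask = water)

summ <- do.call(rbind, lapply(names(surfaces), function(nm) {
  s <- surfaces[[nm]]
  v <- s$values[!is.na(s$values)]
  data.frame(surface = nm, base_cost = s$base_cost,
             neighborhood = s$neighborhood,
             min = min(v), max = max(v), mean = round(mean(v), 3),
             barrier_cells = sum(is.na(s$values)))
}))
write.csv(summ, "results/cost_surface_summary.csv", row.names = FALSE)

future <- project_future_conversion(conv)
write_ascii_grid(future, file.path(land, "future_conversion.asc"))

cat(sprintf("built %d cost surfaces (values all within [1, base_cost])\n",
            length(surfaces)))
print(summ, row.names = FALSE)
cat(sprintf("future conversion: %.1f%% of cells (now %.1f%%)\n",
            100 * mean(future$values), 100 * mean(conv$values)))
cat("wrote results/cost_surface_summary.csv\n")
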