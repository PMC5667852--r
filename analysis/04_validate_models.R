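#!/usr/bin/env Rscript
# Stage 4: score all 60 corridor models against the validation points and
# select the best model.
#
# Each model = one cost surface sliced at one width (lowest 5/10/15/20% of
# corridor cells). A model captures a validation point when a sliced cell
# center falls within the 5 km buffer; Cohen's kappa measures
# chance-corrected agreement. The best model has the highest kappa up to a
# 0.05 tolerance, then the smallest corridor footprint.

library(corridornet)

land <- "results/landscape"
conv_raw <- read_ascii_grid(file.path(land, "conversion.asc"))
conv <- conversion_grid(conv_raw$values, conv_raw$cell_size_km)
water <- read_ascii_grid(file.path(land, "water.asc"))
pas <- read_pas_geojson(file.path(land, "pas.geojson"))
points <- read_validation_points(file.path(land, "points.csv"))
truth <- read.csv(file.path(land, "truth.csv"), stringsAsFactors = FALSE)

pairs <- lapply(seq_len(nrow(truth)), function(i)
  c(truth$pa_a[i], truth$pa_b[i]))

surfaces <- build_cost_surface_set(conv, water_mask = water)
results_by_surface <- lapply(surfaces, function(s)
  lapply(pairs, function(p) pair_metrics(p[1], p[2], pas, s)))

scores <- score_models(results_by_surface, model_param_grid(), points, conv,
                       buffer_radius_km = 5)
write.csv(scores, "results/model_scores.csv", row.names = FALSE)

best <- select_best_model(scores, kappa_tolerance = 0.05)
write.csv(best, "results/best_model.csv", row.names = FALSE)

cat(sprintf("scored %d models against %d validation locations\n",
            nrow(scores), nrow(points)))
cat(sprintf("kappa range: %.3f .. %.3f | models at max kappa: %d\n",
            min(scores$kappa), max(scores$kappa),
            sum(scores$kappa == max(scores$kappa))))
cat("selected model (kappa within tolerance, fewest cells):\n")
print(best, row.names = FALSE)
cat("wrote results/model_scores.csv, results/best_model.csv\n")
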