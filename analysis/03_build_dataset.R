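#!/usr/bin/env Rscript
# Stage 3: per-pixel sequence dataset.
#
# Keeps rice pixels on plausible terrain, gap-fills cloud-invalidated cells
# by linear interpolation in time, splits 80/20 stratified by class, and
# standardizes channels on training statistics. Stores the standardized
# datasets for the training stage.

suppressMessages(library(ricegru))

SEED <- 2022
scene <- read_scene("results/scene")
indices <- apply_cloud_mask(compute_indices(scene$stack), scene$stack$qa)
mask <- slope_mask(compute_slope(scene$dem), 8) & scene$labels$labels > 0L

series <- build_series(indices, scene$labels, mask)
split <- split_dataset(series, train_fraction = 0.8, seed = SEED)
std <- standardize_series(split$train, split$test)

tab <- function(s) table(factor(s$label, levels = 1:2,
                                labels = c("rice_unstressed", "rice_stressed")))
dataset_df <- data.frame(
  class = c("rice_unstressed", "rice_stressed"),
  train = as.integer(tab(std$train)),
  test = as.integer(tab(std$test)),
  mean_gap_fill_fraction = round(c(
    mean(series$gap_fraction[series$label == 1]),
    mean(series$gap_fraction[series$label == 2])), 4)
)
write.csv(dataset_df, "results/tables/dataset_summary.csv", row.names = FALSE)
saveRDS(list(std = std, series = series), "results/dataset.rds")

print(series)
print(dataset_df, row.names = FALSE)
cat("pixels dropped (no valid observations):", series$n_dropped, "\n")
cat("dataset stored in results/dataset.rds\n")
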