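#!/usr/bin/env Rscript
# Stage 2: spectral indices and masking.
#
# Computes the eight stress-sensitive indices per pixel per date, invalidates
# cloud-flagged observations, derives slope from the DEM and applies the
# 8-degree terrain mask. Writes the per-date class means of NDRE1 (the
# stress-signal summary) and a mask accounting table.

suppressMessages(library(ricegru))

scene <- read_scene("results/scene")
indices <- apply_cloud_mask(compute_indices(scene$stack), scene$stack$qa)
slope <- compute_slope(scene$dem)
mask <- slope_mask(slope, 8)

lab <- scene$labels$labels
ndre1 <- indices$values[, "NDRE1", , ]
valid <- indices$valid[, "NDRE1", , ]
class_mean <- function(t, cl) {
  sel <- matrix(lab == cl, dim(ndre1)[2], dim(ndre1)[3]) & valid[t, , ]
  if (!any(sel)) NA_real_ else mean(ndre1[t, , ][sel])
}
curve_df <- data.frame(
  doy = indices$dates,
  nonrice = vapply(seq_along(indices$dates), class_mean, numeric(1), cl = 0),
  rice_unstressed = vapply(seq_along(indices$dates), class_mean, numeric(1),
                           cl = 1),
  rice_stressed = vapply(seq_along(indices$dates), class_mean, numeric(1),
                         cl = 2)
)
curve_df$stress_gap <- curve_df$rice_unstressed - curve_df$rice_stressed
write.csv(round(curve_df, 5), "results/tables/ndre1_by_class_date.csv",
          row.names = FALSE)

mask_df <- data.frame(
  pixels_total = length(mask),
  pixels_steeper_than_8deg = sum(!mask),
  fraction_masked = round(mean(!mask), 4),
  invalid_index_cells = sum(!indices$valid),
  invalid_cell_fraction = round(mean(!indices$valid), 4)
)
write.csv(mask_df, "results/tables/mask_summary.csv", row.names = FALSE)

print(mask_df, row.names = FALSE)
cat(sprintf("NDRE1 stress gap: min %.4f, max %.4f at DOY %d\n",
            min(curve_df$stress_gap, na.rm = TRUE),
            max(curve_df$stress_gap, na.rm = TRUE),
            curve_df$doy[which.max(curve_df$stress_gap)]))
cat("noisy class-mean gap positive at every date:",
    all(curve_df$stress_gap > 0, na.rm = TRUE),
    "(guaranteed only in the noise-free limit; early-season vigor is ~0)\n")
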