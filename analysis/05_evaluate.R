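#!/usr/bin/env Rscript
# Stage 5: accuracy assessment.
#
# Evaluates the trained model on the held-out test pixels (confusion matrix,
# user's/producer's accuracy, precision/recall/F1 per class, overall accuracy
# and Cohen's Kappa), classifies the whole rice mask into a map, and
# recomputes the derived metrics of the published 2020/2021 validation count
# tables through the same evaluation code.

suppressMessages(library(ricegru))

dataset <- readRDS("results/dataset.rds")
model <- readRDS("results/model.rds")
std <- dataset$std

y_pred <- predict_series(model, std$test)
code_of <- function(v) match(v, model$classes) - 1L
cm <- confusion(code_of(std$test$label), code_of(y_pred), 2,
                class_names = c("rice_unstressed", "rice_stressed"))
report <- metric_report(cm)
write_metric_report(report, "results/tables/metrics_test.csv")
write.csv(as.data.frame(unclass(cm)), "results/tables/confusion_test.csv")

map <- predict_map(model, dataset$series)
tiff::writeTIFF(map / 255, "results/classified_map.tif",
                bits.per.sample = 32L)

cat("== Held-out test pixels, synthetic scene ==\n")
print(report)

# Published validation tables re-derived with the same metric code
published <- list(
  `2020` = matrix(c(291, 31, 44, 629), 2, 2, byrow = TRUE),
  `2021` = matrix(c(182, 43, 32, 597), 2, 2, byrow = TRUE)
)
rows <- lapply(names(published), function(yr) {
  pcm <- as_confusion(published[[yr]], c("nonstressed", "stressed"))
  up <- users_producers(pcm)
  data.frame(year = yr,
             overall_accuracy_pct = round(100 * overall_accuracy(pcm), 2),
             kappa_pct = round(100 * kappa_coef(pcm), 2),
             users_nonstressed_pct = round(100 * up$users[1], 2),
             users_stressed_pct = round(100 * up$users[2], 2),
             producers_nonstressed_pct = round(100 * up$producers[1], 2),
             producers_stressed_pct = round(100 * up$producers[2], 2))
})
pub_df <- do.call(rbind, rows)
write.csv(pub_df, "results/tables/published_validation_metrics.csv",
          row.names = FALSE)
cat("\n== Published validation tables, metrics recomputed ==\n")
print(pub_df, row.names = FALSE)
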