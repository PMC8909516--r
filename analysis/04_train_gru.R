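#!/usr/bin/env Rscript
# Stage 4: GRU training.
#
# Trains the stressed-vs-unstressed classifier on the standardized sequences
# with the study's hyperparameters (input size 8, batch size 8, learning rate
# 1e-4) at a desk-scale hidden size of 32, for at most 50 epochs with
# patience-based early stopping. Writes the full epoch history.

suppressMessages(library(ricegru))

SEED <- 2022
dataset <- readRDS("results/dataset.rds")

cfg <- gru_config(input_size = 8, hidden_size = 32, batch_size = 8,
                  learning_rate = 1e-4, n_classes = 2, max_epochs = 50,
                  patience = 10, seed = SEED)
model <- train_gru(dataset$std$train, dataset$std$test, cfg)

hist_out <- model$history
hist_out$seconds <- NULL
write.csv(round(hist_out, 6), "results/tables/training_history.csv",
          row.names = FALSE)
saveRDS(model, "results/model.rds")

pdf("results/training_curves.pdf", width = 9, height = 4.5)
plot_history(model)
invisible(dev.off())

print(model)
h <- model$history
cat(sprintf("epoch 1:  train loss %.4f, test accuracy %.4f\n",
            h$train_loss[1], h$test_accuracy[1]))
cat(sprintf("epoch %d: train loss %.4f, test accuracy %.4f\n",
            nrow(h), h$train_loss[nrow(h)], h$test_accuracy[nrow(h)]))
cat(sprintf("first epoch reaching 95%% test accuracy: %s\n",
            if (any(h$test_accuracy >= 0.95))
              min(h$epoch[h$test_accuracy >= 0.95]) else "never"))
cat("model stored in results/model.rds\n")
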