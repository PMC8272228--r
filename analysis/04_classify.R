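#!/usr/bin/env Rscript

# Step 4: four-class activation classification.
#
# Simulates a 120-session benchmark cohort (30 per class, randomized
# baseline/rates/hotspot position), builds the (S1-E3)/(S1-S3) difference
# maps, splits 90/10, and trains the small CNN with the default recipe
# (Adam, lr 1e-4, batch 16, 50 epochs) at 64 x 64 input resolution.

suppressMessages(library(brachytherm))

dir.create("results", showWarnings = FALSE)
seed <- 7

cat("Simulating 120 benchmark sessions...\n")
bench <- simulate_cohort(cohort_labels(30), seed = seed)
ds <- build_dataset(bench$sets, bench$labels)
sp <- split_dataset(ds, 0.1, seed = seed + 1)
cat(sprintf("Dataset: %d maps -> %d train / %d test\n",
            length(ds), length(sp$train), length(sp$test)))

model <- train_classifier(sp$train, train_config(seed = seed + 2),
                          out_size = 64)
write.csv(model$curve, "results/04_training_curve.csv", row.names = FALSE)

ev <- evaluate_model(model, sp$test)
write.csv(ev$per_item, "results/04_test_predictions.csv", row.names = FALSE)
jsonlite::write_json(
  list(n_train = length(sp$train), n_test = length(sp$test),
       train_accuracy = max(model$curve$accuracy),
       test_accuracy = ev$accuracy,
       confusion = as.data.frame.matrix(ev$confusion)),
  "results/04_metrics.json", auto_unbox = TRUE, digits = NA)

cat(sprintf("\nFinal training accuracy: %.1f%% (reached %.1f%% at epoch %d)\n",
            100 * tail(model$curve$accuracy, 1),
            100 * max(model$curve$accuracy),
            which.max(model$curve$accuracy >= 1)))
cat(sprintf("Test accuracy: %.1f%% on %d held-out maps (chance 25%%)\n",
            100 * ev$accuracy, length(sp$test)))
print(ev$confusion)
cat("\nCurve in results/04_training_curve.csv; metrics in results/04_metrics.json\n")
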