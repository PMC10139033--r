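#!/usr/bin/env Rscript
# Stage 2 — QSAR modelling and validation.
#
# Splits the stage-1 dataset 92/11, runs correlation-based feature
# selection on the training set only, cross-validates reference regressors
# (mean baseline, ordinary least squares, 1-nearest-neighbour), ranks them
# by cross-validated Q2 then MAE, and subjects the winner to the full
# external-validation battery and both acceptance decision rules.

suppressMessages(library(funnelscreen))
seed <- 20260101L

ds <- read_fingerprint_csv("results/qsar_dataset.csv", "synthetic")
sp <- split_dataset(ds, 0.10, seed = seed + 3L)
cat(sprintf("split: %d train / %d test\n", length(sp$train),
            length(sp$test)))

train <- subset_dataset(ds, sp$train)
sel <- cfs_select(train)
cat(sprintf("CFS selected %d bits, merit %.4f\n",
            length(sel$selected_bits), sel$merit))
jsonlite::write_json(list(selected_bits = sel$selected_bits,
                          merit = sel$merit),
                     "results/feature_selection.json", auto_unbox = TRUE)

train_s <- subset_dataset(ds, sp$train, sel$selected_bits)
test_s <- subset_dataset(ds, sp$test, sel$selected_bits)
folds <- make_folds(length(sp$train), 10, seed = seed + 4L)

models <- list(mean = model_spec("mean"), ols = model_spec("ols"),
               knn1 = model_spec("knn", hyperparameters = list(k = 1)))
reports <- lapply(models, function(m) {
  r <- regression_metrics(cross_validate(train_s, folds, m))
  validation_report(r2 = r$r2, mae = r$mae, q2_cv = r$r2)
})
rank <- select_best_model(reports)
print(rank)
write.csv(rank, "results/model_ranking.csv", row.names = FALSE)

best <- rank$name[1]
cat("best model:", best, "\n")
cv_rep <- regression_metrics(cross_validate(train_s, folds, models[[best]]))
ext <- fit_predict_external(train_s, test_s, models[[best]])
ext_rep <- regression_metrics(ext)
print(ext_rep)

gtr <- gtr_decision(ext_rep, q2_cv = cv_rep$r2)
cg <- cg_decision(ext_rep)
cat("\nGolbraikh-Tropsha decision:\n"); print(gtr)
cat("\nChirico-Gramatica decision:\n"); print(cg)

auc <- classification_auc(
  prediction_set(ds$activity[sp$train], cross_validate(train_s, folds,
                                                       models[[best]])$predicted,
                 kind = "cv"), 6.0)
cat(sprintf("\nclassification AUC at pIC50 >= 6: %.4f\n", auc))

out <- c(as.list(ext_rep)[c("r2", "mae", "ccc", "qf1", "qf2", "qf3",
                            "rm2_bar", "k_slope", "k_prime")],
         list(q2_cv = cv_rep$r2, gtr_pass = gtr$overall,
              cg_pass = cg$overall, auc = auc, best_model = best))
jsonlite::write_json(out, "results/qsar_validation.json", auto_unbox = TRUE)
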