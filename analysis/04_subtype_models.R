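#!/usr/bin/env Rscript
# Step 4 — LASSO Radscore models: washout region vs whole tumor.
#
# Emulates the three binary classification tasks (Luminal vs rest,
# HER2-enriched vs rest, HER2-positive vs HER2-negative) on synthetic
# feature cohorts at the study's scale: 124 patients split 7:3 (87/37,
# stratified), task prevalences matching the reported cohort composition,
# and a regime where only the washout-region features carry class signal
# (standardized effect 1.5 on 5 of 100 features). For each task and ROI a
# 10-fold cross-validated LASSO-logistic Radscore is fitted on the training
# split only, then evaluated on the held-out test split with ROC, Youden
# operating metrics and decision curves.
#
# Outputs:
#   results/model_performance.csv  per task x ROI: train/test AUC + metrics
#   results/dca_<task>.csv         test-set decision curves, both ROIs

library(kinhet)

tasks <- data.frame(task = c("luminal", "her2_enriched", "her2_positive"),
                    prevalence = c(86 / 124, 29 / 124, 67 / 124))

perf <- list()
for (t in seq_len(nrow(tasks))) {
  task <- tasks$task[t]
  pr <- simulate_paired_roi_cohort(
    cohort_spec(n_patients = 124L, prevalence = tasks$prevalence[t],
                feature_effect = 1.5, n_features = 100L, n_informative = 5L,
                seed = 300L + t))
  dca_both <- list()
  for (roi in c("washout", "whole_tumor")) {
    x <- if (roi == "washout") pr$washout else pr$tumor
    res <- run_radscore_task(x, pr$labels, train_fraction = 0.7,
                             seed = 300L + t, rank_test = FALSE)
    perf[[paste(task, roi)]] <- data.frame(
      task = task, roi = roi,
      n_train = length(res$split$train), n_test = length(res$split$test),
      n_selected = length(res$model$selected),
      lambda = res$model$lambda,
      auc_train = res$roc_train$auc,
      auc_test = res$roc_test$auc,
      ci_low = res$roc_test$ci[1], ci_high = res$roc_test$ci[2],
      sensitivity = res$roc_test$sensitivity,
      specificity = res$roc_test$specificity,
      ppv = res$roc_test$ppv, npv = res$roc_test$npv,
      accuracy = res$roc_test$accuracy)
    d <- res$dca_test; d$roi <- roi
    dca_both[[roi]] <- d
  }
  write.csv(do.call(rbind, dca_both), sprintf("results/dca_%s.csv", task),
            row.names = FALSE)
}
performance <- do.call(rbind, perf)
write.csv(performance, "results/model_performance.csv", row.names = FALSE)

cat("model performance (test split):\n")
print(performance[, c("task", "roi", "n_train", "n_test", "n_selected",
                      "auc_train", "auc_test")], row.names = FALSE,
      digits = 3)
wa <- performance$auc_test[performance$roi == "washout"]
tu <- performance$auc_test[performance$roi == "whole_tumor"]
cat(sprintf("\nwashout-region model beats the whole-tumor model in %d/%d tasks (signal lives only in the washout ROI)\n",
            sum(wa > tu), length(wa)))
cat("tables -> results/model_performance.csv, results/dca_<task>.csv\n")
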