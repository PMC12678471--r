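#!/usr/bin/env Rscript
# Step 3 — fit the three diagnostic models on the training cohort.
#
# us_only:   lasso-selected logistic model on the ultrasound features alone;
# mmp7_only: two-variable logistic model on log10(1 + MMP-7) + age stratum;
# combined:  lasso-selected logistic model on both modalities.
# All features are min-max scaled to [0, 1] on training data; the decision
# threshold is the Youden maximum of the training scores. Models are frozen
# to JSON for the evaluation step.

library(badx)

SEED <- 1
feats <- read.csv("results/features_training.csv", check.names = FALSE)
cohort <- read.csv("results/data/training/cohort.csv")
cohort <- cohort[match(feats$patient_id, cohort$patient_id), ]
stopifnot(identical(cohort$patient_id, feats$patient_id))

dir.create("results/models", showWarnings = FALSE, recursive = TRUE)

us <- train_diagnostic_model(feats, cohort$label, "us_only", seed = SEED)
mm <- build_mmp7_model(cohort$mmp7_ng_ml, cohort$age_days, cohort$label)
cb <- build_combined(feats, cohort$mmp7_ng_ml, cohort$age_days,
                     cohort$label, seed = SEED)

models <- list(us_only = us, mmp7_only = mm, combined = cb)
for (kind in names(models)) {
  m <- models[[kind]]
  write_model(m, file.path("results/models", paste0(kind, ".json")))
  cat(sprintf("%-9s lambda=%s  threshold=%.3f  selected: %s\n", kind,
              format(m$meta$lambda, digits = 3), m$decision_threshold,
              if (length(m$selected_features))
                paste(m$selected_features, collapse = ", ")
              else "(intercept only)"))
}

# training-set performance at the frozen thresholds
cat("\ntraining-set performance:\n")
train_scores <- list(
  us_only = predict(us, feats),
  mmp7_only = predict(mm, add_mmp7_features(NULL, cohort$mmp7_ng_ml,
                                            cohort$age_days)),
  combined = predict(cb, add_mmp7_features(feats, cohort$mmp7_ng_ml,
                                           cohort$age_days))
)
for (kind in names(train_scores)) {
  ev <- evaluate_scores(train_scores[[kind]], cohort$label,
                        models[[kind]]$decision_threshold)
  cat(sprintf("%-9s AUC %.3f (%.3f-%.3f)\n", kind,
              ev$auc$auc, ev$auc$ci[1], ev$auc$ci[2]))
  print(ev$report)
}
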