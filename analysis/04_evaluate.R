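#!/usr/bin/env Rscript
# Step 4 — diagnostic-accuracy evaluation.
#
# Scores the frozen models on both cohorts and reports, per cohort and
# model: AUC with DeLong 95% CI, sensitivity/specificity/accuracy with
# Clopper-Pearson exact CIs at the training-frozen threshold, paired DeLong
# comparisons of the combined model against each single modality, the
# internal/external-center subgroup split of the validation cohort, and
# calibration curves. Writes a Table-2-shaped CSV plus a full JSON report
# and ROC/calibration plots.

library(badx)

models <- list(
  us_only = read_model("results/models/us_only.json"),
  mmp7_only = read_model("results/models/mmp7_only.json"),
  combined = read_model("results/models/combined.json")
)

score_cohort <- function(cohort_name) {
  feats <- read.csv(sprintf("results/features_%s.csv", cohort_name),
                    check.names = FALSE)
  co <- read.csv(sprintf("results/data/%s/cohort.csv", cohort_name))
  co <- co[match(feats$patient_id, co$patient_id), ]
  list(
    cohort = co,
    scores = list(
      us_only = predict(models$us_only, feats),
      mmp7_only = predict(models$mmp7_only,
                          add_mmp7_features(NULL, co$mmp7_ng_ml, co$age_days)),
      combined = predict(models$combined,
                         add_mmp7_features(feats, co$mmp7_ng_ml, co$age_days))
    )
  )
}

rows <- list(); full <- list()
for (cohort_name in c("training", "validation")) {
  sc <- score_cohort(cohort_name)
  for (kind in names(models)) {
    ev <- evaluate_scores(sc$scores[[kind]], sc$cohort$label,
                          models[[kind]]$decision_threshold)
    p <- ev$report$pct
    rows[[paste(cohort_name, kind)]] <- data.frame(
      cohort = cohort_name, model = kind, n = ev$n,
      auc = sprintf("%.3f (%.3f-%.3f)", ev$auc$auc, ev$auc$ci[1], ev$auc$ci[2]),
      sensitivity = sprintf("%.1f (%.1f-%.1f)", p$estimates["sensitivity"],
                            p$ci$sensitivity[1], p$ci$sensitivity[2]),
      specificity = sprintf("%.1f (%.1f-%.1f)", p$estimates["specificity"],
                            p$ci$specificity[1], p$ci$specificity[2]),
      accuracy = sprintf("%.1f (%.1f-%.1f)", p$estimates["accuracy"],
                         p$ci$accuracy[1], p$ci$accuracy[2])
    )
    full[[cohort_name]][[kind]] <- ev[c("n", "auc", "report")]
  }
  # paired DeLong: combined vs each single modality
  for (other in c("us_only", "mmp7_only")) {
    dl <- delong_compare(sc$scores$combined, sc$scores[[other]],
                         sc$cohort$label)
    cat(sprintf("%s: combined (AUC %.3f) vs %s (AUC %.3f): p = %.4g\n",
                cohort_name, dl$auc_a, other, dl$auc_b, dl$p_value))
    full[[cohort_name]][[paste0("delong_combined_vs_", other)]] <- dl
  }
}

# internal (model-origin center C1) vs external centers, validation cohort
sc <- score_cohort("validation")
grp <- ifelse(sc$cohort$center_id == "C1", "internal", "external")
sub <- subgroup_report(sc$scores$combined, sc$cohort$label, grp,
                       models$combined$decision_threshold)
for (g in names(sub)) {
  p <- sub[[g]]$report$pct
  rows[[paste("validation", g)]] <- data.frame(
    cohort = paste0("validation/", g), model = "combined", n = sub[[g]]$n,
    auc = if (is.null(sub[[g]]$auc)) NA_character_
          else sprintf("%.3f (%.3f-%.3f)", sub[[g]]$auc$auc,
                       sub[[g]]$auc$ci[1], sub[[g]]$auc$ci[2]),
    sensitivity = sprintf("%.1f (%.1f-%.1f)", p$estimates["sensitivity"],
                          p$ci$sensitivity[1], p$ci$sensitivity[2]),
    specificity = sprintf("%.1f (%.1f-%.1f)", p$estimates["specificity"],
                          p$ci$specificity[1], p$ci$specificity[2]),
    accuracy = sprintf("%.1f (%.1f-%.1f)", p$estimates["accuracy"],
                       p$ci$accuracy[1], p$ci$accuracy[2])
  )
}
full$validation_subgroups <- sub

table2 <- do.call(rbind, rows)
write.csv(table2, "results/performance_table.csv", row.names = FALSE)
jsonlite::write_json(full, "results/evaluation_report.json",
                     auto_unbox = TRUE, digits = NA, force = TRUE)
cat("\n"); print(table2, row.names = FALSE)

# plots: ROC overlays and combined-model calibration, both cohorts
pdf("results/roc_and_calibration.pdf", width = 9, height = 4.5)
par(mfrow = c(1, 2))
for (cohort_name in c("training", "validation")) {
  sc <- score_cohort(cohort_name)
  plot(0:1, 0:1, type = "l", lty = 3, col = "gray",
       xlab = "1 - specificity", ylab = "sensitivity",
       main = paste("ROC,", cohort_name))
  cols <- c(us_only = "steelblue", mmp7_only = "darkorange",
            combined = "firebrick")
  for (kind in names(models)) {
    r <- roc_and_auc(sc$scores[[kind]], sc$cohort$label)
    o <- order(1 - r$points$specificity, r$points$sensitivity)
    lines(1 - r$points$specificity[o], r$points$sensitivity[o],
          col = cols[kind], lwd = 2)
  }
  legend("bottomright", names(models), col = cols, lwd = 2, bty = "n")
  cal <- calibration_curve(pmin(1, pmax(0, sc$scores$combined)),
                           sc$cohort$label)
  plot(cal$mean_predicted, cal$observed_fraction, xlim = 0:1, ylim = 0:1,
       pch = 19, xlab = "predicted probability", ylab = "observed fraction",
       main = paste("calibration (combined),", cohort_name))
  abline(0, 1, lty = 3, col = "gray")
  lines(cal$mean_predicted, cal$observed_fraction)
}
dev.off()
cat("wrote results/performance_table.csv, results/evaluation_report.json, results/roc_and_calibration.pdf\n")
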