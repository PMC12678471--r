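# Diagnostic-accuracy statistics: ROC/AUC with DeLong confidence intervals
# and paired comparisons (via pROC), sensitivity/specificity/accuracy with
# Clopper-Pearson exact binomial CIs, calibration curves, subgroup reports,
# and descriptive cohort comparisons.

make_roc <- function(scores, labels) {
  y <- label_to_binary(labels)
  if (length(unique(y)) < 2)
    stop_badx("both classes must be present for ROC analysis",
              "badx_input_error")
  if (any(!is.finite(scores)))
    stop_badx("scores must be finite", "badx_input_error")
  pROC::roc(response = y, predictor = scores, levels = c(0, 1),
            direction = "<", quiet = TRUE)
}

#' ROC curve, AUC and DeLong 95% confidence interval
#'
#' The AUC is the tie-corrected rank statistic (concordant pairs plus half
#' of tied pairs over all case-control pairs); the CI uses DeLong's
#' structural-components variance with a normal approximation, truncated to
#' \[0, 1\].
#'
#' @param scores numeric scores or probabilities (higher = more BA-like).
#' @param labels labels (`"BA"`/`"non-BA"`, logical, or 0/1).
#' @param conf_level confidence level (default 0.95).
#' @return list with `auc`, `ci` (length 2), and `points` (tibble of
#'   threshold, sensitivity, specificity).
#' @export
roc_and_auc <- function(scores, labels, conf_level = 0.95) {
  r <- make_roc(scores, labels)
  ci <- suppressWarnings(
    as.numeric(pROC::ci.auc(r, conf.level = conf_level, method = "delong"))
  )
  list(
    auc = as.numeric(pROC::auc(r)),
    ci = c(max(0, ci[1]), min(1, ci[3])),
    points = tibble::tibble(threshold = r$thresholds,
                            sensitivity = r$sensitivities,
                            specificity = r$specificities)
  )
}

#' Paired DeLong comparison of two AUCs
#'
#' Two-sided p-value from the paired DeLong z-statistic on scores computed
#' for the same patients. Identical score vectors have zero variance of the
#' difference; the comparison is then defined as difference 0, p = 1.
#'
#' @param scores_a,scores_b paired score vectors (same patients, same
#'   order).
#' @param labels shared labels.
#' @return list with `auc_a`, `auc_b`, `difference`, `p_value`.
#' @export
delong_compare <- function(scores_a, scores_b, labels) {
  if (length(scores_a) != length(scores_b))
    stop_badx("paired score vectors must have equal length",
              "badx_input_error")
  ra <- make_roc(scores_a, labels)
  rb <- make_roc(scores_b, labels)
  aa <- as.numeric(pROC::auc(ra)); ab <- as.numeric(pROC::auc(rb))
  if (isTRUE(all.equal(scores_a, scores_b, tolerance = 0)))
    return(list(auc_a = aa, auc_b = ab, difference = 0, p_value = 1))
  tst <- suppressWarnings(
    pROC::roc.test(ra, rb, method = "delong", paired = TRUE)
  )
  p <- as.numeric(tst$p.value)
  if (!is.finite(p)) p <- 1  # zero-variance degenerate pair
  list(auc_a = aa, auc_b = ab, difference = aa - ab, p_value = p)
}

# Clopper-Pearson exact binomial interval, closed form via beta quantiles.
clopper_pearson <- function(x, n, conf_level = 0.95) {
  a <- (1 - conf_level) / 2
  lower <- ifelse(x == 0, 0, qbeta(a, x, n - x + 1))
  upper <- ifelse(x == n, 1, qbeta(1 - a, x + 1, n - x))
  c(lower, upper)
}

#' Confusion-matrix metrics with exact binomial confidence intervals
#'
#' Sensitivity = TP/(TP+FN), specificity = TN/(TN+FP), accuracy =
#' (TP+TN)/n, each with a Clopper-Pearson exact 95% CI. Percentages are
#' formatted to one decimal, rounding half away from zero.
#'
#' @param calls predicted classes (`"BA"`/`"non-BA"`, logical, or 0/1;
#'   positive = BA).
#' @param labels reference labels.
#' @param conf_level confidence level (default 0.95).
#' @param threshold optional threshold recorded in the report.
#' @return an `accuracy_report`: `counts` (tp, fn, tn, fp), `estimates`
#'   (proportions), `ci` (list of length-2 intervals), `pct` (one-decimal
#'   percentages for estimates and CI bounds), `threshold`.
#' @export
confusion_metrics <- function(calls, labels, conf_level = 0.95,
                              threshold = NA_real_) {
  if (length(calls) == 0)
    stop_badx("empty input", "badx_input_error")
  if (length(calls) != length(labels))
    stop_badx("calls and labels must have equal length", "badx_input_error")
  yhat <- label_to_binary(calls); y <- label_to_binary(labels)
  tp <- sum(yhat == 1 & y == 1); fn <- sum(yhat == 0 & y == 1)
  tn <- sum(yhat == 0 & y == 0); fp <- sum(yhat == 1 & y == 0)
  n <- length(y)
  est <- c(sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
           specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
           accuracy = (tp + tn) / n)
  ci <- list(
    sensitivity = if (tp + fn > 0) clopper_pearson(tp, tp + fn, conf_level)
                  else c(NA_real_, NA_real_),
    specificity = if (tn + fp > 0) clopper_pearson(tn, tn + fp, conf_level)
                  else c(NA_real_, NA_real_),
    accuracy = clopper_pearson(tp + tn, n, conf_level)
  )
  structure(list(
    counts = c(tp = tp, fn = fn, tn = tn, fp = fp),
    estimates = est,
    ci = ci,
    pct = list(estimates = as_pct(est),
               ci = lapply(ci, as_pct)),
    threshold = threshold,
    conf_level = conf_level
  ), class = "accuracy_report")
}

#' @export
print.accuracy_report <- function(x, ...) {
  p <- x$pct
  for (m in names(x$estimates)) {
    cat(sprintf("%-12s %5.1f%% (95%% CI %.1f%%-%.1f%%)\n", m,
                p$estimates[[m]], p$ci[[m]][1], p$ci[[m]][2]))
  }
  cat(sprintf("counts: TP=%d FN=%d TN=%d FP=%d\n",
              x$counts["tp"], x$counts["fn"], x$counts["tn"], x$counts["fp"]))
  invisible(x)
}

#' Calibration curve by equal-frequency bins
#'
#' Bins patients into (by default) deciles of predicted probability and
#' contrasts the per-bin mean prediction with the observed event fraction.
#' Tied predictions that straddle a quantile boundary collapse bins, so
#' fewer than `n_bins` bins may be returned; bin counts always sum to n.
#'
#' @param probs predicted probabilities in \[0, 1\].
#' @param labels observed labels.
#' @param n_bins number of equal-frequency bins (default 10, minimum 2).
#' @return tibble with `bin`, `n`, `mean_predicted`, `observed_fraction`.
#' @export
calibration_curve <- function(probs, labels, n_bins = 10) {
  if (n_bins < 2)
    stop_badx("n_bins must be at least 2", "badx_input_error")
  if (any(probs < 0 | probs > 1))
    stop_badx("probabilities must lie in [0, 1]", "badx_input_error")
  y <- label_to_binary(labels)
  br <- unique(quantile(probs, seq(0, 1, length.out = n_bins + 1), type = 7))
  bin <- if (length(br) < 3) rep(1L, length(probs))
         else cut(probs, br, include.lowest = TRUE, labels = FALSE)
  agg <- lapply(sort(unique(bin)), function(b) {
    i <- bin == b
    tibble::tibble(bin = b, n = sum(i), mean_predicted = mean(probs[i]),
                   observed_fraction = mean(y[i]))
  })
  do.call(rbind, agg)
}

#' Per-subgroup accuracy reports with a shared model and threshold
#'
#' Computes [confusion_metrics()] and AUC within each subgroup using the
#' same scores and the same decision threshold (the model is never refit per
#' group). Groups in which only one class occurs get confusion metrics but
#' no AUC (with a warning); empty groups are omitted with a warning.
#'
#' @param scores model scores/probabilities.
#' @param labels reference labels.
#' @param groups subgroup tag per patient (e.g. internal/external center).
#' @param threshold decision threshold for class calls.
#' @return named list of per-group lists, each with `n`, `report`
#'   (an `accuracy_report`) and `auc` (list or `NULL`).
#' @export
subgroup_report <- function(scores, labels, groups, threshold) {
  out <- list()
  for (g in unique(groups)) {
    i <- groups == g
    if (!any(i)) {
      warn_badx(sprintf("subgroup '%s' is empty; omitted", g),
                "badx_empty_subgroup")
      next
    }
    y <- label_to_binary(labels[i])
    rep_g <- confusion_metrics(scores[i] > threshold, y,
                               threshold = threshold)
    auc_g <- if (length(unique(y)) < 2) {
      warn_badx(sprintf("subgroup '%s' has one class; AUC omitted", g),
                "badx_single_class_subgroup")
      NULL
    } else {
      r <- roc_and_auc(scores[i], y)
      list(auc = r$auc, ci = r$ci)
    }
    out[[as.character(g)]] <- list(n = sum(i), report = rep_g, auc = auc_g)
  }
  out
}

fmt_median_iqr <- function(x) {
  q <- quantile(x, c(0.25, 0.5, 0.75), na.rm = TRUE, type = 7, names = FALSE)
  sprintf("%.1f (%.1f, %.1f)", q[2], q[1], q[3])
}

#' Descriptive comparison of two cohort tables
#'
#' For each shared column: categorical variables are compared by Pearson's
#' chi-squared test (no continuity correction) and summarized as n (%);
#' continuous variables by the Wilcoxon rank-sum test and summarized as
#' median (Q1, Q3). Empty or all-missing columns are skipped with a note.
#'
#' @param table_a,table_b data frames with a shared column schema.
#' @param variables columns to compare (default: all shared columns except
#'   `patient_id`).
#' @return tibble with `variable`, `summary_a`, `summary_b`, `test`,
#'   `p_value`.
#' @export
cohort_comparison <- function(table_a, table_b,
                              variables = NULL) {
  shared <- intersect(names(table_a), names(table_b))
  variables <- variables %||% setdiff(shared, "patient_id")
  rows <- list()
  for (v in variables) {
    a <- table_a[[v]]; b <- table_b[[v]]
    if (length(a) == 0 || length(b) == 0 ||
        all(is.na(a)) || all(is.na(b))) {
      rows[[v]] <- tibble::tibble(variable = v, summary_a = "skipped",
                                  summary_b = "skipped", test = "none",
                                  p_value = NA_real_)
      next
    }
    if (is.numeric(a) && !all(a %in% c(0, 1))) {
      p <- suppressWarnings(wilcox.test(a, b)$p.value)
      rows[[v]] <- tibble::tibble(
        variable = v, summary_a = fmt_median_iqr(a),
        summary_b = fmt_median_iqr(b), test = "wilcoxon", p_value = p)
    } else {
      af <- factor(a); bf <- factor(b, levels = levels(factor(c(a, b))))
      af <- factor(a, levels = levels(factor(c(a, b))))
      tab <- rbind(table(af), table(bf))
      p <- if (any(colSums(tab) == 0) || ncol(tab) < 2) 1
           else suppressWarnings(chisq.test(tab, correct = FALSE)$p.value)
      fmt <- function(x) {
        tt <- table(factor(x, levels = colnames(tab)))
        paste(sprintf("%s: %d (%.1f)", names(tt), as.integer(tt),
                      100 * as.integer(tt) / length(x)), collapse = "; ")
      }
      rows[[v]] <- tibble::tibble(
        variable = v, summary_a = fmt(a), summary_b = fmt(b),
        test = "chi-squared", p_value = p)
    }
  }
  do.call(rbind, rows)
}

#' Evaluate a trained model on a labelled, scored cohort
#'
#' Convenience wrapper producing the full per-cohort evaluation block:
#' AUC with DeLong CI, confusion metrics at the model threshold with exact
#' CIs, and the calibration curve.
#'
#' @param scores model probabilities for the cohort.
#' @param labels reference labels.
#' @param threshold decision threshold (class call is `score > threshold`).
#' @param n_bins calibration bins.
#' @return list with `n`, `auc` (list: auc, ci), `report`
#'   (an `accuracy_report`) and `calibration` (tibble).
#' @export
evaluate_scores <- function(scores, labels, threshold, n_bins = 10) {
  r <- roc_and_auc(scores, labels)
  list(
    n = length(scores),
    auc = list(auc = r$auc, ci = r$ci),
    report = confusion_metrics(scores > threshold, labels,
                               threshold = threshold),
    calibration = calibration_curve(pmin(1, pmax(0, scores)), labels, n_bins)
  )
}
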