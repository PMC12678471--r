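# The three diagnostic classifiers: serum MMP-7 alone, the image-based
# ultrasound model, and the combined model. Numerical features are min-max
# scaled to [0, 1] on the training data, variables are selected by
# cross-validated lasso (L1-penalized logistic regression), and the selected
# set is refit by unpenalized maximum-likelihood logistic regression; the
# probability cutoff defaults to the Youden-index maximum on training data.

label_to_binary <- function(labels) {
  if (is.logical(labels)) return(as.integer(labels))
  if (is.numeric(labels)) {
    if (!all(labels %in% c(0, 1)))
      stop_badx("numeric labels must be 0/1", "badx_input_error")
    return(as.integer(labels))
  }
  as.integer(labels == "BA")
}

feature_matrix <- function(features) {
  df <- as.data.frame(features)
  df$patient_id <- NULL
  if (!all(vapply(df, is.numeric, logical(1))))
    stop_badx("all feature columns must be numeric", "badx_input_error")
  as.matrix(df)
}

#' Fit 0--1 scaling bounds on training features
#'
#' Per-feature (min, max) learned on the training data. Features that are
#' constant in training carry no information and cannot be scaled; they are
#' dropped with a warning and are absent from the bounds.
#'
#' @param features training feature table or matrix (numeric columns;
#'   `patient_id` ignored).
#' @return a `scaling_bounds` object with named `min` and `max` vectors.
#' @export
fit_scaling <- function(features) {
  x <- feature_matrix(features)
  if (nrow(x) == 0) stop_badx("empty training set", "badx_input_error")
  mins <- apply(x, 2, min); maxs <- apply(x, 2, max)
  const <- maxs <= mins
  if (any(const))
    warn_badx(sprintf("dropping constant feature(s): %s",
                      paste(colnames(x)[const], collapse = ", ")),
              "badx_constant_feature")
  structure(list(min = mins[!const], max = maxs[!const]),
            class = "scaling_bounds")
}

#' Apply training scaling bounds to a feature table
#'
#' Maps each retained feature through `(x - min) / (max - min)`. Training
#' features land in \[0, 1\]; validation features are transformed with the
#' training bounds and deliberately NOT clipped, so out-of-range cases keep
#' their distance from the training hull instead of being silently distorted.
#'
#' @param bounds a `scaling_bounds` from [fit_scaling()].
#' @param features feature table or matrix containing the bounded features.
#' @return numeric matrix of scaled features (bounded features only).
#' @export
apply_scaling <- function(bounds, features) {
  x <- feature_matrix(features)
  miss <- setdiff(names(bounds$min), colnames(x))
  if (length(miss))
    stop_badx(sprintf("features missing from data: %s",
                      paste(miss, collapse = ", ")), "badx_schema_error")
  x <- x[, names(bounds$min), drop = FALSE]
  sweep(sweep(x, 2, bounds$min, "-"), 2, bounds$max - bounds$min, "/")
}

stratified_folds <- function(y, nfolds, seed) {
  foldid <- integer(length(y))
  with_seed(seed, {
    for (cls in unique(y)) {
      idx <- which(y == cls)
      foldid[idx] <- sample(rep_len(seq_len(nfolds), length(idx)))
    }
  })
  foldid
}

#' Select features by cross-validated lasso logistic regression
#'
#' L1-penalized logistic path (glmnet) with the penalty chosen at the
#' minimum of stratified cross-validated binomial deviance; returns the
#' features with nonzero coefficients at that penalty. Reduces model
#' complexity and guards against overfitting the high-dimensional ultrasound
#' feature set.
#'
#' @param scaled numeric matrix of scaled features.
#' @param y labels (`"BA"`/`"non-BA"`, logical, or 0/1).
#' @param lambda optional penalty grid, or a single fixed penalty (then no
#'   cross-validation is run).
#' @param nfolds folds for cross-validation (default 5, stratified).
#' @param seed fold-assignment seed.
#' @return list with `selected` (feature names), `lambda` (chosen penalty),
#'   `nfolds`, `seed`.
#' @export
lasso_select <- function(scaled, y, lambda = NULL, nfolds = 5, seed = 1) {
  y <- label_to_binary(y)
  if (length(unique(y)) < 2)
    stop_badx("both classes must be present", "badx_input_error")
  if (min(table(y)) < nfolds)
    stop_badx("need at least `nfolds` patients per class", "badx_input_error")
  x <- as.matrix(scaled)
  # glmnet requires >= 2 columns; pad a zero dummy for 1-feature inputs
  padded <- ncol(x) < 2
  if (padded) x <- cbind(x, .pad = 0)
  if (!is.null(lambda) && length(lambda) == 1) {
    fit <- glmnet::glmnet(x, y, family = "binomial", alpha = 1,
                          lambda = lambda)
    co <- as.matrix(coef(fit, s = lambda))
    chosen <- lambda
  } else {
    foldid <- stratified_folds(y, nfolds, seed)
    cv <- glmnet::cv.glmnet(x, y, family = "binomial", alpha = 1,
                            lambda = lambda, foldid = foldid,
                            type.measure = "deviance")
    co <- as.matrix(coef(cv, s = "lambda.min"))
    chosen <- cv$lambda.min
  }
  sel <- rownames(co)[co[, 1] != 0]
  list(selected = setdiff(sel, c("(Intercept)", ".pad")), lambda = chosen,
       nfolds = nfolds, seed = seed)
}

#' Fit an unpenalized logistic model on selected features
#'
#' Maximum-likelihood refit on the lasso-selected set (selection and
#' estimation are split, so the reported coefficients are not shrunken).
#' Under perfect separation the MLE diverges; the fit falls back to a
#' tiny-ridge-stabilized estimate with a classed warning.
#'
#' @param scaled numeric matrix of scaled features (training).
#' @param y labels.
#' @param features names of the selected features (possibly empty: the model
#'   is then intercept-only and predicts the training prevalence).
#' @return list with named `coefficients` (including `"(Intercept)"`) and a
#'   `converged` flag.
#' @export
fit_logistic <- function(scaled, y, features = colnames(scaled)) {
  y <- label_to_binary(y)
  if (length(features) == 0) {
    p <- mean(y)
    return(list(coefficients = c("(Intercept)" = log(p / (1 - p))),
                converged = TRUE))
  }
  x <- as.matrix(scaled)[, features, drop = FALSE]
  df <- data.frame(.y = y, x, check.names = FALSE)
  separated <- FALSE
  fit <- withCallingHandlers(
    glm(.y ~ ., data = df, family = binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1|did not converge",
                conditionMessage(w))) {
        separated <<- TRUE
        invokeRestart("muffleWarning")
      }
    }
  )
  co <- coef(fit)
  co[!is.finite(co)] <- 0  # aliased (collinear) features drop to zero
  if (separated || any(abs(co) > 50)) {
    warn_badx("separation detected; stabilizing with a tiny ridge penalty",
              "badx_separation")
    xr <- if (ncol(x) < 2) cbind(x, .pad = 0) else x
    rfit <- glmnet::glmnet(xr, y, family = "binomial", alpha = 0,
                           lambda = 1e-3)
    com <- as.matrix(coef(rfit, s = 1e-3))[, 1]
    co <- setNames(com, rownames(as.matrix(coef(rfit))))
    names(co)[1] <- "(Intercept)"
    co <- co[names(co) != ".pad"]
    return(list(coefficients = co, converged = FALSE))
  }
  names(co) <- c("(Intercept)", features)
  list(coefficients = co, converged = fit$converged)
}

#' Choose a probability decision threshold
#'
#' Default method maximizes the Youden index (sensitivity + specificity - 1)
#' over all cutpoints of the training scores by exhaustive enumeration of
#' midpoints between consecutive distinct scores; ties are broken toward
#' higher sensitivity (the lower cutpoint). A class call is `score >
#' threshold`.
#'
#' @param probs training scores/probabilities.
#' @param labels labels (both classes required).
#' @param method `"youden"` or `"fixed"`.
#' @param value the threshold when `method = "fixed"`.
#' @return numeric threshold.
#' @export
choose_threshold <- function(probs, labels, method = c("youden", "fixed"),
                             value = 0.5) {
  method <- match.arg(method)
  if (method == "fixed") return(value)
  y <- label_to_binary(labels)
  if (length(unique(y)) < 2)
    stop_badx("both classes must be present", "badx_input_error")
  s <- sort(unique(probs))
  cand <- c(s[1] - 1, if (length(s) > 1) (s[-1] + s[-length(s)]) / 2)
  j <- vapply(cand, function(t) {
    calls <- probs > t
    sens <- sum(calls & y == 1) / sum(y == 1)
    spec <- sum(!calls & y == 0) / sum(y == 0)
    sens + spec - 1
  }, numeric(1))
  best <- j >= max(j) - 1e-12
  min(cand[best])  # lowest cutpoint among ties -> highest sensitivity
}

#' Train a diagnostic model from a feature table
#'
#' The full training pipeline: median imputation of missing-view features
#' (medians stored for prediction time), 0--1 scaling, optional lasso
#' selection, unpenalized logistic refit, and threshold choice on the
#' training scores.
#'
#' @param features training feature table (numeric columns; `patient_id`
#'   ignored).
#' @param labels training labels (`"BA"`/`"non-BA"`, logical, or 0/1).
#' @param model_kind `"us_only"`, `"mmp7_only"` or `"combined"`.
#' @param select run lasso selection (default TRUE; FALSE fits all scaled
#'   features, used for the two-variable MMP-7 model).
#' @param lambda optional penalty grid or fixed penalty for [lasso_select()].
#' @param nfolds,seed cross-validation controls.
#' @param threshold_method,threshold_value passed to [choose_threshold()].
#' @return a `badx_model`: scaling bounds, selected features, coefficients on
#'   the scaled space, decision threshold, imputation medians, and training
#'   metadata.
#' @export
train_diagnostic_model <- function(features, labels,
                                   model_kind = c("us_only", "mmp7_only",
                                                  "combined"),
                                   select = TRUE, lambda = NULL,
                                   nfolds = 5, seed = 1,
                                   threshold_method = "youden",
                                   threshold_value = 0.5) {
  model_kind <- match.arg(model_kind)
  y <- label_to_binary(labels)
  medians <- feature_medians(features)
  features <- impute_features(features, medians)
  scaling <- suppressWarnings(fit_scaling(features))
  xs <- apply_scaling(scaling, features)
  sel <- if (select) lasso_select(xs, y, lambda = lambda, nfolds = nfolds,
                                  seed = seed)
         else list(selected = colnames(xs), lambda = NA_real_,
                   nfolds = NA_integer_, seed = seed)
  fit <- fit_logistic(xs, y, sel$selected)
  model <- structure(list(
    model_kind = model_kind,
    scaling = scaling,
    selected_features = sel$selected,
    coefficients = fit$coefficients,
    decision_threshold = 0.5,
    medians = medians,
    meta = list(lambda = sel$lambda, nfolds = sel$nfolds, seed = seed,
                converged = fit$converged, n_train = length(y),
                prevalence = mean(y))
  ), class = "badx_model")
  probs <- predict(model, features, type = "response")
  model$decision_threshold <- choose_threshold(probs, y,
                                               method = threshold_method,
                                               value = threshold_value)
  model
}

#' Augment a feature table with the serum-MMP-7 modality
#'
#' MMP-7 enters the models continuously as `log10(1 + concentration)`
#' together with an age-stratum indicator (`age <= 30` days), mirroring the
#' age-stratified positivity rule while keeping the marker's dynamic range.
#'
#' @param features ultrasound feature table (or `NULL` for an MMP-7-only
#'   table).
#' @param mmp7 serum concentrations (ng/mL), aligned with rows.
#' @param age_days ages in days, aligned with rows.
#' @return the augmented table with `mmp7_log10` and `age_le30` columns.
#' @export
add_mmp7_features <- function(features, mmp7, age_days) {
  extra <- tibble::tibble(mmp7_log10 = log10(1 + mmp7),
                          age_le30 = as.numeric(age_days <= 30))
  if (is.null(features)) return(extra)
  tibble::as_tibble(cbind(as.data.frame(features), extra))
}

#' Train the combined ultrasound + MMP-7 model
#'
#' Joins the assembled ultrasound features with the continuous MMP-7
#' transform and age-stratum indicator, then runs the standard pipeline
#' (scaling, lasso, logistic refit, Youden threshold). Patients with missing
#' MMP-7 cannot enter the combined model and are excluded with a warning
#' listing their ids.
#'
#' @param us_features assembled ultrasound feature table (with
#'   `patient_id`).
#' @param mmp7,age_days vectors aligned with `us_features` rows.
#' @param labels training labels aligned with rows.
#' @param ... passed to [train_diagnostic_model()].
#' @return a `badx_model` with `model_kind = "combined"`.
#' @export
build_combined <- function(us_features, mmp7, age_days, labels, ...) {
  keep <- is.finite(mmp7)
  if (any(!keep)) {
    ids <- if ("patient_id" %in% names(us_features))
      us_features$patient_id[!keep] else which(!keep)
    warn_badx(sprintf("excluding %d patient(s) without MMP-7 from combined training: %s",
                      sum(!keep), paste(ids, collapse = ", ")),
              "badx_missing_mmp7")
  }
  feats <- add_mmp7_features(us_features[keep, , drop = FALSE],
                             mmp7[keep], age_days[keep])
  train_diagnostic_model(feats, labels[keep], model_kind = "combined", ...)
}

#' Train the MMP-7-only logistic model
#'
#' Two-variable logistic model on `log10(1 + mmp7)` and the age stratum; no
#' lasso step (nothing to select). The binary age-stratified positivity rule
#' remains available separately via [mmp7_positive()].
#'
#' @inheritParams build_combined
#' @return a `badx_model` with `model_kind = "mmp7_only"`.
#' @export
build_mmp7_model <- function(mmp7, age_days, labels, ...) {
  feats <- add_mmp7_features(NULL, mmp7, age_days)
  train_diagnostic_model(feats, labels, model_kind = "mmp7_only",
                         select = FALSE, ...)
}

#' Predict BA probability and class call
#'
#' Missing features are imputed with the stored training medians, scaled
#' with the stored training bounds (no clipping), passed through the linear
#' score, and mapped by the logistic function; the class call is
#' `probability > decision_threshold`.
#'
#' @param object a `badx_model`.
#' @param newdata feature table containing the model's features.
#' @param type `"response"` (probability), `"class"` (`"BA"`/`"non-BA"`),
#'   or `"link"` (linear score).
#' @param ... unused.
#' @return numeric vector (or character vector for `type = "class"`).
#' @export
predict.badx_model <- function(object, newdata,
                               type = c("response", "class", "link"), ...) {
  type <- match.arg(type)
  newdata <- impute_features(as.data.frame(newdata), object$medians)
  xs <- apply_scaling(object$scaling, newdata)
  co <- object$coefficients
  feats <- setdiff(names(co), "(Intercept)")
  bad <- setdiff(feats, colnames(xs))
  if (length(bad))
    stop_badx(sprintf("model features not resolvable: %s",
                      paste(bad, collapse = ", ")), "badx_schema_error")
  score <- co[["(Intercept)"]] +
    if (length(feats)) drop(xs[, feats, drop = FALSE] %*% co[feats])
    else rep(0, nrow(xs))
  switch(type,
    link = unname(score),
    response = unname(stats::plogis(score)),
    class = ifelse(stats::plogis(score) > object$decision_threshold,
                   "BA", "non-BA")
  )
}

#' @export
print.badx_model <- function(x, ...) {
  cat(sprintf("<badx_model %s: %d selected feature(s), threshold %.3f>\n",
              x$model_kind, length(x$selected_features),
              x$decision_threshold))
  invisible(x)
}

#' Serialize a diagnostic model to JSON
#'
#' Full-precision JSON; [read_model()] round-trips to bit-identical
#' predictions.
#'
#' @param model a `badx_model`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  payload <- list(
    schema_version = 1L,
    model_kind = model$model_kind,
    scaling = list(min = as.list(model$scaling$min),
                   max = as.list(model$scaling$max)),
    selected_features = model$selected_features,
    coefficients = as.list(model$coefficients),
    decision_threshold = model$decision_threshold,
    medians = as.list(model$medians),
    meta = model$meta
  )
  # I(17) significant digits: doubles survive the round trip bit-for-bit
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' Read a serialized diagnostic model
#'
#' @param path JSON file written by [write_model()].
#' @return a `badx_model`.
#' @export
read_model <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(
    model_kind = p$model_kind,
    scaling = structure(list(min = unlist(p$scaling$min),
                             max = unlist(p$scaling$max)),
                        class = "scaling_bounds"),
    selected_features = as.character(p$selected_features),
    coefficients = unlist(p$coefficients),
    decision_threshold = p$decision_threshold,
    medians = unlist(p$medians),
    meta = p$meta
  ), class = "badx_model")
}
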