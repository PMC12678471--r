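test_that("min-max scaling maps training to [0,1] and never clips", {
  tr <- data.frame(f1 = c(2, 4, 6), f2 = c(0, 5, 10))
  b <- fit_scaling(tr)
  expect_equal(unname(apply_scaling(b, tr)[, "f1"]), c(0, 0.5, 1))
  # validation value 8 under training bounds (2, 6) -> 1.5, unclipped
  va <- data.frame(f1 = 8, f2 = -5)
  sc <- apply_scaling(b, va)
  expect_equal(unname(sc[1, "f1"]), 1.5)
  expect_equal(unname(sc[1, "f2"]), -0.5)
})

test_that("constant features are dropped from the scaling bounds", {
  tr <- data.frame(f1 = c(1, 2, 3), flat = c(7, 7, 7))
  expect_warning(b <- fit_scaling(tr), class = "badx_constant_feature")
  expect_named(b$min, "f1")
  expect_error(fit_scaling(data.frame(f1 = numeric(0))),
               class = "badx_input_error")
})

test_that("full shrinkage selects nothing", {
  set.seed(1)
  x <- matrix(runif(200), 50, 4, dimnames = list(NULL, paste0("f", 1:4)))
  y <- rep(c(0, 1), 25)
  sel <- lasso_select(x, y, lambda = 10)
  expect_length(sel$selected, 0)
  expect_error(lasso_select(x, rep(1, 50)), class = "badx_input_error")
})

test_that("lasso recovers planted informative features", {
  set.seed(42)
  n <- 500
  y <- rep(c(0, 1), each = n / 2)
  info <- sapply(1:2, function(i) rnorm(n, mean = 1.5 * y))
  noise <- matrix(rnorm(n * 20), n)
  x <- cbind(info, noise)
  colnames(x) <- c("inf1", "inf2", paste0("noise", 1:20))
  xs <- apply_scaling(fit_scaling(x), x)
  sel <- lasso_select(xs, y, seed = 7)$selected
  expect_true(all(c("inf1", "inf2") %in% sel))
  expect_lte(sum(grepl("^noise", sel)), 3)
})

test_that("selection at a fixed penalty is invariant to row duplication", {
  set.seed(5)
  x <- matrix(rnorm(300), 100, 3, dimnames = list(NULL, paste0("f", 1:3)))
  y <- as.integer(plogis(2 * x[, 1]) > runif(100))
  s1 <- lasso_select(x, y, lambda = 0.05)$selected
  s2 <- lasso_select(rbind(x, x), c(y, y), lambda = 0.05)$selected
  expect_identical(s1, s2)
})

test_that("the intercept-only model predicts the training prevalence", {
  set.seed(3)
  feats <- tibble::tibble(f1 = rnorm(40))
  y <- rep(c(0, 0, 0, 1), 10)
  m <- train_diagnostic_model(feats, y, "us_only", lambda = 10)
  expect_length(m$selected_features, 0)
  expect_equal(unname(predict(m, feats)), rep(0.25, 40), tolerance = 1e-9)
})

test_that("logistic refit matches the closed-form two-point solution", {
  # grouped data: at x = 0, 1 of 4 events; at x = 1, 3 of 4. The saturated
  # two-parameter fit gives intercept log(1/3), slope log(3) - log(1/3).
  x <- matrix(rep(c(0, 1), each = 4), ncol = 1,
              dimnames = list(NULL, "x"))
  y <- c(1, 0, 0, 0, 1, 1, 1, 0)
  fit <- fit_logistic(x, y)
  expect_equal(unname(fit$coefficients["(Intercept)"]), log(1 / 3),
               tolerance = 1e-6)
  expect_equal(unname(fit$coefficients["x"]), 2 * log(3), tolerance = 1e-6)
})

test_that("permuted labels yield near-null coefficients and AUC", {
  set.seed(11)
  n <- 2000
  x <- matrix(rnorm(n * 5), n, dimnames = list(NULL, paste0("f", 1:5)))
  y <- sample(rep(c(0, 1), n / 2))
  fit <- fit_logistic(x, y)
  expect_true(all(abs(fit$coefficients[-1]) < 0.2))
  probs <- plogis(fit$coefficients[1] + x %*% fit$coefficients[-1])
  expect_lt(abs(roc_and_auc(drop(probs), y)$auc - 0.5), 0.05)
})

test_that("separation triggers the ridge-stabilized fallback", {
  x <- matrix(c(rep(0, 10), rep(1, 10)), ncol = 1,
              dimnames = list(NULL, "x"))
  y <- rep(c(0, 1), each = 10)
  expect_warning(fit <- fit_logistic(x, y), class = "badx_separation")
  expect_false(fit$converged)
  expect_true(is.finite(fit$coefficients["x"]))
  expect_gt(fit$coefficients["x"], 0)
})

test_that("predictions are the logistic map of the hand-computed score", {
  model <- structure(list(
    model_kind = "us_only",
    scaling = structure(list(min = c(f1 = 0, f2 = 0),
                             max = c(f1 = 1, f2 = 1)),
                        class = "scaling_bounds"),
    selected_features = c("f1", "f2"),
    coefficients = c("(Intercept)" = 0.3, f1 = 1.2, f2 = -0.7),
    decision_threshold = 0.5,
    medians = c(f1 = 0.5, f2 = 0.5),
    meta = list()
  ), class = "badx_model")
  nd <- data.frame(f1 = 0.8, f2 = 0.25)
  expect_equal(predict(model, nd),
               plogis(0.3 + 1.2 * 0.8 - 0.7 * 0.25), tolerance = 1e-12)
  # all-zero coefficients: probability 1/2 regardless of inputs
  model$coefficients[] <- 0
  expect_equal(predict(model, nd), 0.5)
  expect_error(predict(model, data.frame(f1 = 1)),
               class = "badx_schema_error")
})

test_that("increasing a positively weighted feature never lowers the risk", {
  set.seed(8)
  feats <- tibble::tibble(f1 = rnorm(80), f2 = rnorm(80))
  y <- as.integer(plogis(1.5 * feats$f1) > runif(80))
  got <- suppressWarnings(train_diagnostic_model(feats, y, "us_only",
                                                 select = FALSE))
  co <- got$coefficients
  pos <- names(co)[-1][co[-1] > 0]
  expect_gt(length(pos), 0)
  base <- tibble::tibble(f1 = seq(-2, 2, length.out = 9), f2 = 0)
  for (f in pos) {
    bumped <- base; bumped[[f]] <- bumped[[f]] + 0.5
    expect_true(all(predict(got, bumped) >= predict(got, base)))
  }
})

test_that("Youden threshold matches exhaustive enumeration", {
  # perfectly separated scores
  t1 <- choose_threshold(c(0.1, 0.2, 0.8, 0.9), c(0, 0, 1, 1))
  expect_gte(t1, 0.2); expect_lt(t1, 0.8)
  calls <- c(0.1, 0.2, 0.8, 0.9) > t1
  expect_equal(sum(calls[3:4]), 2); expect_equal(sum(calls[1:2]), 0)
  # 6-point toy with one overlap
  s <- c(0.1, 0.3, 0.55, 0.5, 0.7, 0.9); y <- c(0, 0, 0, 1, 1, 1)
  thr <- choose_threshold(s, y)
  oracle <- youden_brute(s, y)
  j_at <- function(t) {
    sens <- mean(s[y == 1] > t); spec <- mean(s[y == 0] <= t)
    sens + spec - 1
  }
  expect_equal(j_at(thr), oracle$max_j, tolerance = 1e-12)
  expect_equal(thr, min(oracle$thresholds))  # tie-break: higher sensitivity
  expect_equal(choose_threshold(s, y, method = "fixed", value = 0.42), 0.42)
  expect_error(choose_threshold(s, rep(1, 6)), class = "badx_input_error")
})

test_that("models serialize to JSON and round-trip bit-for-bit", {
  set.seed(21)
  mmp7 <- rlnorm(60, log(20), 1)
  age <- sample(20:120, 60, TRUE)
  y <- as.integer(plogis(2 * (log10(1 + mmp7) - 1.3)) > runif(60))
  m <- suppressWarnings(build_mmp7_model(mmp7, age, y))
  path <- withr::local_tempfile(fileext = ".json")
  write_model(m, path)
  m2 <- read_model(path)
  nd <- add_mmp7_features(NULL, rlnorm(20, log(20), 1),
                          sample(20:120, 20, TRUE))
  expect_identical(predict(m, nd), predict(m2, nd))
  expect_identical(m2$decision_threshold, m$decision_threshold)
  expect_equal(m2$coefficients, m$coefficients)
})

test_that("patients without MMP-7 are excluded from combined training", {
  set.seed(9)
  feats <- tibble::tibble(patient_id = sprintf("P%02d", 1:60),
                          f1 = rnorm(60))
  y <- rep(c(0, 1), 30)
  mmp7 <- rlnorm(60, log(15) + 0.8 * y, 0.5)
  mmp7[c(3, 7)] <- NA
  expect_warning(
    m <- build_combined(feats, mmp7, rep(60, 60), y, select = FALSE),
    class = "badx_missing_mmp7")
  expect_equal(m$meta$n_train, 58)
})

test_that("ablating one modality reduces the combined model to the other", {
  scenes_null <- lapply(default_scene_configs(c(96, 96)), function(sc) {
    sc$class_effect <- list(ba = list(contrast = 1, size = 1),
                            non_ba = list(contrast = 1, size = 1))
    sc
  })
  flat_mmp7 <- list(ba = list(meanlog = log(15), sdlog = 0.8),
                    non_ba = list(meanlog = log(15), sdlog = 0.8))

  # MMP-7 non-informative: combined ~ ultrasound-only
  mk <- function(n, prev, seed, scenes, mmp7_params = NULL) {
    args <- list(n_patients = n, prevalence = prev, seed = seed)
    if (!is.null(mmp7_params)) args$mmp7_params <- mmp7_params
    cfg <- do.call(cohort_config, args)
    co <- generate_cohort(cfg)
    ims <- setNames(lapply(seq_len(n), function(i)
      generate_patient_images(i, co$label[i], seed, scenes)),
      co$patient_id)
    list(cohort = co, images = ims)
  }
  scenes <- default_scene_configs(c(96, 96))

  tr <- mk(120, 0.4, 301, scenes, flat_mmp7)
  va <- mk(200, 0.5, 302, scenes, flat_mmp7)
  got <- train_and_score(tr, va)
  a_us <- roc_and_auc(got$scores$us, got$labels)$auc
  a_cb <- roc_and_auc(got$scores$combined, got$labels)$auc
  expect_lt(abs(a_cb - a_us), 0.05)

  # ultrasound non-informative: combined ~ MMP-7-only
  tr2 <- mk(120, 0.4, 303, scenes_null)
  va2 <- mk(200, 0.5, 304, scenes_null)
  got2 <- train_and_score(tr2, va2)
  a_mm <- roc_and_auc(got2$scores$mmp7, got2$labels)$auc
  a_cb2 <- roc_and_auc(got2$scores$combined, got2$labels)$auc
  expect_lt(abs(a_cb2 - a_mm), 0.05)
})

test_that("training is deterministic given seeds", {
  set.seed(1)  # must not matter
  got <- gen_cohort_with_images(60, 0.4, seed = 55)
  f <- extract_cohort_features(got$images)
  m1 <- suppressWarnings(train_diagnostic_model(f, got$cohort$label,
                                                "us_only", seed = 2))
  set.seed(999)
  m2 <- suppressWarnings(train_diagnostic_model(f, got$cohort$label,
                                                "us_only", seed = 2))
  expect_identical(m1$coefficients, m2$coefficients)
  expect_identical(m1$decision_threshold, m2$decision_threshold)
  p1 <- withr::local_tempfile(fileext = ".json")
  p2 <- withr::local_tempfile(fileext = ".json")
  write_model(m1, p1); write_model(m2, p2)
  expect_identical(readLines(p1), readLines(p2))
})
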