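# Shared fixtures, built in code at test time.

# Generate a cohort together with its in-memory images.
gen_cohort_with_images <- function(n, prevalence, seed,
                                   scenes = default_scene_configs(),
                                   missing_view_rate = 0) {
  cfg <- cohort_config(n_patients = n, prevalence = prevalence, seed = seed,
                       missing_view_rate = missing_view_rate)
  co <- generate_cohort(cfg)
  ims <- lapply(seq_len(nrow(co)), function(i)
    generate_patient_images(i, co$label[i], seed, scenes,
                            missing_view_rate = missing_view_rate))
  names(ims) <- co$patient_id
  list(cohort = co, images = ims)
}

# Train the three models on one synthetic cohort and score a second.
train_and_score <- function(train, valid, seed = 1,
                            scenes = default_scene_configs()) {
  ftr <- extract_cohort_features(train$images)
  fva <- extract_cohort_features(valid$images)
  suppressWarnings({
    us <- train_diagnostic_model(ftr, train$cohort$label, "us_only",
                                 seed = seed)
    mm <- build_mmp7_model(train$cohort$mmp7_ng_ml, train$cohort$age_days,
                           train$cohort$label)
    cb <- build_combined(ftr, train$cohort$mmp7_ng_ml,
                         train$cohort$age_days, train$cohort$label,
                         seed = seed)
  })
  list(
    models = list(us = us, mmp7 = mm, combined = cb),
    labels = valid$cohort$label,
    scores = list(
      us = predict(us, fva),
      mmp7 = predict(mm, add_mmp7_features(NULL, valid$cohort$mmp7_ng_ml,
                                           valid$cohort$age_days)),
      combined = predict(cb, add_mmp7_features(fva, valid$cohort$mmp7_ng_ml,
                                               valid$cohort$age_days))
    )
  )
}

# A flat-background scene with a single ideal structure, no patient
# variability, used for segmentation ground-truth checks.
crisp_scene <- function(view = "gallbladder", seed = 1, image_size = c(128, 128),
                        background_std = 6, ...) {
  scene_config(view, image_size = image_size,
               background_std = background_std,
               patient_sd = list(size = 0, contrast = 0), seed = seed, ...)
}

# Build calls/labels vectors realizing a given confusion matrix.
confusion_vectors <- function(tp, fn, tn, fp) {
  list(
    calls = c(rep(1, tp), rep(0, fn), rep(0, tn), rep(1, fp)),
    labels = c(rep(1, tp + fn), rep(0, tn + fp))
  )
}
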