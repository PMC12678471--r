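# Synthetic cohorts and ultrasound-like phantom images.
#
# Real sonograms and patient data for infant cholestasis work-ups are not
# publicly deposited, so every downstream stage is exercised on synthetic
# material with known ground truth: two-class cohorts (biliary atresia vs
# other cholestatic disease) with class-separated serum MMP-7, and speckled
# grayscale images containing either a hypoechoic gallbladder-like ellipse or
# an echogenic triangular-cord-like structure.

VIEWS <- c("gallbladder", "tc_branches", "tc_transverse")

#' Cohort generator configuration
#'
#' Defaults emulate a training cohort of 187 infants with biliary-atresia
#' prevalence 29.9%. MMP-7 is modelled log-normally per class (a positive,
#' right-skewed biomarker); default class medians (8 vs 40 ng/mL) straddle
#' both age-stratified positivity thresholds and give a single-marker AUC
#' near 0.92. Ages are drawn uniformly on 20--120 days so both MMP-7 age
#' strata occur; eligibility is capped at 150 days.
#'
#' @param n_patients number of patients (>= 0).
#' @param prevalence probability that a patient is a BA case, in \[0,1\].
#' @param seed master seed; each patient draws from a stream derived from
#'   (seed, patient index) so subsets are reproducible.
#' @param mmp7_params per-class `list(meanlog, sdlog)` of the log-normal
#'   serum MMP-7 distribution (ng/mL).
#' @param age_params per-class discrete-uniform age range in days, within
#'   \[1, 150\].
#' @param biochem_params optional per-variable, per-class log-normal
#'   parameters for TB/DB/GGT/ALT/AST/TBA.
#' @param missing_view_rate per-view probability that a patient's image for
#'   that view is absent, in \[0,1).
#' @param centers character vector of center ids; patients are assigned
#'   uniformly at random.
#' @return a `cohort_config` list.
#' @export
cohort_config <- function(n_patients = 187,
                          prevalence = 0.299,
                          seed = 1,
                          mmp7_params = list(
                            ba     = list(meanlog = log(40), sdlog = 0.8),
                            non_ba = list(meanlog = log(8),  sdlog = 0.8)
                          ),
                          age_params = list(
                            ba     = list(min = 20, max = 120),
                            non_ba = list(min = 20, max = 120)
                          ),
                          biochem_params = default_biochem_params(),
                          missing_view_rate = 0,
                          centers = "C1") {
  cfg <- list(
    n_patients = n_patients, prevalence = prevalence, seed = seed,
    mmp7_params = mmp7_params, age_params = age_params,
    biochem_params = biochem_params, missing_view_rate = missing_view_rate,
    centers = centers
  )
  validate_cohort_config(cfg)
  structure(cfg, class = "cohort_config")
}

default_biochem_params <- function() {
  # Rough log-normal emulations of the biochemistry a cholestasis work-up
  # records; GGT carries a class signal (higher in BA), the rest do not.
  both <- function(meanlog, sdlog) {
    list(ba = list(meanlog = meanlog, sdlog = sdlog),
         non_ba = list(meanlog = meanlog, sdlog = sdlog))
  }
  list(
    tb  = both(log(140), 0.35),
    db  = both(log(100), 0.40),
    ggt = list(ba = list(meanlog = log(330), sdlog = 0.7),
               non_ba = list(meanlog = log(120), sdlog = 0.8)),
    alt = both(log(130), 0.7),
    ast = both(log(180), 0.65),
    tba = both(log(98), 0.4)
  )
}

validate_cohort_config <- function(cfg) {
  if (!is.numeric(cfg$n_patients) || length(cfg$n_patients) != 1 ||
      cfg$n_patients < 0 || cfg$n_patients != floor(cfg$n_patients))
    stop_badx("n_patients must be a non-negative integer", "badx_config_error")
  if (!is.numeric(cfg$prevalence) || cfg$prevalence < 0 || cfg$prevalence > 1)
    stop_badx("prevalence must lie in [0, 1]", "badx_config_error")
  if (cfg$missing_view_rate < 0 || cfg$missing_view_rate >= 1)
    stop_badx("missing_view_rate must lie in [0, 1)", "badx_config_error")
  for (cl in c("ba", "non_ba")) {
    if (cfg$mmp7_params[[cl]]$sdlog <= 0)
      stop_badx("mmp7 sdlog must be positive", "badx_config_error")
    ar <- cfg$age_params[[cl]]
    if (ar$min < 1 || ar$max > 150 || ar$min > ar$max)
      stop_badx("age range must lie within [1, 150] days", "badx_config_error")
  }
  invisible(cfg)
}

cohort_schema <- function() {
  c(patient_id = "character", age_days = "integer", mmp7_ng_ml = "numeric",
    label = "character", center_id = "character",
    tb = "numeric", db = "numeric", ggt = "numeric",
    alt = "numeric", ast = "numeric", tba = "numeric")
}

#' Generate a synthetic patient cohort
#'
#' Draws labels independently at the configured prevalence, then ages,
#' serum MMP-7 and biochemistry from the class-conditional distributions.
#' Deterministic given the config seed; patient `i` always receives the same
#' record regardless of `n_patients`.
#'
#' @param config a [cohort_config()].
#' @return a tibble with one row per patient (columns: patient_id, age_days,
#'   mmp7_ng_ml, label in \{"BA", "non-BA"\}, center_id, tb, db, ggt, alt,
#'   ast, tba).
#' @export
generate_cohort <- function(config) {
  validate_cohort_config(config)
  n <- as.integer(config$n_patients)
  sch <- cohort_schema()
  if (n == 0) {
    empty <- lapply(sch, function(tp) vector(tp, 0L))
    return(tibble::as_tibble(empty))
  }
  rows <- lapply(seq_len(n), function(i) {
    with_seed(derive_seed(config$seed, i), {
      is_ba <- runif(1) < config$prevalence
      cl <- if (is_ba) "ba" else "non_ba"
      ar <- config$age_params[[cl]]
      age <- ar$min + floor(runif(1) * (ar$max - ar$min + 1))
      mp <- config$mmp7_params[[cl]]
      mmp7 <- rlnorm(1, mp$meanlog, mp$sdlog)
      bio <- vapply(config$biochem_params, function(bp) {
        rlnorm(1, bp[[cl]]$meanlog, bp[[cl]]$sdlog)
      }, numeric(1))
      center <- config$centers[1 + floor(runif(1) * length(config$centers))]
      c(list(
        patient_id = sprintf("P%04d", i),
        age_days = as.integer(age),
        mmp7_ng_ml = mmp7,
        label = if (is_ba) "BA" else "non-BA",
        center_id = center
      ), as.list(bio))
    })
  })
  tbl <- do.call(rbind, lapply(rows, function(r) tibble::as_tibble(r)))
  tbl[, names(sch)]
}

#' Phantom image scene configuration
#'
#' Describes one synthetic ultrasound-like scene: Gaussian speckle on a
#' smooth background with a single embedded structure. The gallbladder view
#' embeds a hypoechoic (dark) ellipse; the two triangular-cord views embed an
#' echogenic (bright) triangle or elongated band. `class_effect` scales the
#' structure's contrast and size per class, which is the dial controlling how
#' separable the two classes are in image space: by default BA gallbladders
#' are smaller and fainter (atretic), and the triangular-cord structure is
#' strong in BA but weak otherwise. On top of the class effect, each
#' generated image draws per-patient log-normal multipliers on size and
#' contrast (`patient_sd`), emulating biological heterogeneity; without it
#' the classes would be trivially separable.
#'
#' @param view one of `"gallbladder"`, `"tc_branches"`, `"tc_transverse"`.
#' @param image_size `c(rows, cols)`, at least 32 x 32.
#' @param background_mean,background_std speckle parameters on the 0--255
#'   intensity scale (`background_std` > 0).
#' @param structure_contrast signed intensity offset of the structure
#'   relative to the background (negative = hypoechoic).
#' @param geometry parametric shape: `list(shape = "ellipse", a, b)`
#'   (semi-axes, px) or `list(shape = "triangle", base, height)` (px).
#' @param class_effect per-class `list(contrast, size)` multipliers.
#' @param patient_sd `list(size, contrast)` log-normal standard deviations
#'   of the per-patient variability multipliers.
#' @param seed integer stream seed.
#' @return a `scene_config` list.
#' @export
scene_config <- function(view,
                         image_size = c(128, 128),
                         background_mean = 90,
                         background_std = 12,
                         structure_contrast = NULL,
                         geometry = NULL,
                         class_effect = NULL,
                         patient_sd = list(size = 0.2, contrast = 0.35),
                         seed = 1) {
  view <- match.arg(view, VIEWS)
  defaults <- scene_defaults(view)
  cfg <- list(
    view = view, image_size = as.integer(image_size),
    background_mean = background_mean, background_std = background_std,
    structure_contrast = structure_contrast %||% defaults$structure_contrast,
    geometry = geometry %||% defaults$geometry,
    class_effect = class_effect %||% defaults$class_effect,
    patient_sd = patient_sd,
    seed = seed
  )
  validate_scene_config(cfg)
  structure(cfg, class = "scene_config")
}

scene_defaults <- function(view) {
  switch(view,
    gallbladder = list(
      structure_contrast = -45,
      geometry = list(shape = "ellipse", a = 26, b = 13),
      class_effect = list(ba = list(contrast = 0.8, size = 0.65),
                          non_ba = list(contrast = 1, size = 1))
    ),
    tc_branches = list(
      structure_contrast = 35,
      geometry = list(shape = "triangle", base = 44, height = 26),
      class_effect = list(ba = list(contrast = 1, size = 1),
                          non_ba = list(contrast = 0.55, size = 0.85))
    ),
    tc_transverse = list(
      structure_contrast = 35,
      geometry = list(shape = "ellipse", a = 34, b = 8),
      class_effect = list(ba = list(contrast = 1, size = 1),
                          non_ba = list(contrast = 0.55, size = 0.85))
    )
  )
}

validate_scene_config <- function(cfg) {
  if (any(cfg$image_size < 32))
    stop_badx("image_size must be at least 32 x 32", "badx_config_error")
  if (cfg$background_std <= 0)
    stop_badx("background_std must be positive", "badx_config_error")
  ext <- geometry_extent(cfg$geometry)
  if (2 * ext$half_r >= cfg$image_size[1] - 2 ||
      2 * ext$half_c >= cfg$image_size[2] - 2)
    stop_badx("structure geometry does not fit inside the image",
              "badx_config_error")
  invisible(cfg)
}

geometry_extent <- function(geom) {
  switch(geom$shape,
    ellipse = list(half_r = geom$b, half_c = geom$a),
    triangle = list(half_r = geom$height / 2, half_c = geom$base / 2),
    stop_badx(sprintf("unknown shape '%s'", geom$shape), "badx_config_error")
  )
}

#' Default scene configurations for the three informative views
#'
#' @param image_size `c(rows, cols)` shared by all views.
#' @return named list of [scene_config()] objects, one per view.
#' @export
default_scene_configs <- function(image_size = c(128, 128)) {
  setNames(lapply(VIEWS, scene_config, image_size = image_size), VIEWS)
}

#' Render a structure mask from stored geometry
#'
#' Pure function of (geometry, image size): the ground-truth mask of any
#' generated image can be reproduced exactly from the geometry recorded in
#' its ground-truth record. Pixels are 1-based matrix cells; a pixel belongs
#' to the structure when its center satisfies the shape inequality.
#'
#' @param geometry realized geometry: `list(shape, center = c(r, c), ...)`
#'   with `a`, `b` for ellipses or `base`, `height` for triangles (already
#'   scaled by any class size effect).
#' @param image_size `c(rows, cols)`.
#' @return binary 0/1 integer matrix.
#' @export
render_structure_mask <- function(geometry, image_size) {
  nr <- image_size[1]; nc <- image_size[2]
  r <- matrix(seq_len(nr), nr, nc)
  cc <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  r0 <- geometry$center[1]; c0 <- geometry$center[2]
  m <- switch(geometry$shape,
    ellipse = ((r - r0)^2 / geometry$b^2 + (cc - c0)^2 / geometry$a^2) <= 1,
    triangle = {
      h <- geometry$height; w <- geometry$base
      # isoceles triangle, apex up: apex (r0-h/2, c0), base corners
      # (r0+h/2, c0 +/- w/2)
      ax <- r0 - h / 2; base_r <- r0 + h / 2
      inside_v <- r >= ax & r <= base_r
      # allowed half-width grows linearly from 0 at the apex to w/2 at base
      halfw <- (r - ax) / h * (w / 2)
      inside_v & abs(cc - c0) <= halfw
    },
    stop_badx(sprintf("unknown shape '%s'", geometry$shape),
              "badx_config_error")
  )
  matrix(as.integer(m), nr, nc)
}

#' Generate one phantom ultrasound image with ground truth
#'
#' Background = smooth vertical gradient + Gaussian speckle around
#' `background_mean`; the structure adds `structure_contrast` (scaled by the
#' class contrast effect) inside its mask. Pixel values are clipped to
#' \[0, 255\] and rounded to integers so in-memory images round-trip exactly
#' through 8-bit PNG. Deterministic given `scene$seed`.
#'
#' @param scene a [scene_config()].
#' @param truth_label `"BA"` or `"non-BA"`; selects the class effect.
#' @return list with `image` (a raw [gray_image()]) and `truth`
#'   (`label`, `true_mask`, `true_crop` 0-based half-open
#'   `c(r0, c0, r1, c1)`, realized `geometry`).
#' @export
generate_image <- function(scene, truth_label = c("BA", "non-BA")) {
  truth_label <- match.arg(truth_label)
  validate_scene_config(scene)
  cl <- if (truth_label == "BA") "ba" else "non_ba"
  eff <- scene$class_effect[[cl]]
  nr <- scene$image_size[1]; nc <- scene$image_size[2]

  with_seed(scene$seed, {
    # per-patient biological variability on top of the class effect,
    # capped so the realized geometry still fits in the frame
    psd <- scene$patient_sd %||% list(size = 0, contrast = 0)
    size_mult <- if (psd$size > 0) rlnorm(1, 0, psd$size) else 1
    contrast_mult <- if (psd$contrast > 0) rlnorm(1, 0, psd$contrast) else 1
    base_ext <- geometry_extent(scene$geometry)
    max_size <- 0.98 * min((nr / 2 - 3) / base_ext$half_r,
                           (nc / 2 - 3) / base_ext$half_c)
    size_eff <- min(eff$size * size_mult, max_size)

    geom <- scene$geometry
    if (geom$shape == "ellipse") {
      geom$a <- geom$a * size_eff; geom$b <- geom$b * size_eff
    } else {
      geom$base <- geom$base * size_eff; geom$height <- geom$height * size_eff
    }
    ext <- geometry_extent(geom)
    # jitter the structure center, bounded so the geometry stays in-frame
    slack_r <- max(0, (nr - 1) / 2 - ext$half_r - 2)
    slack_c <- max(0, (nc - 1) / 2 - ext$half_c - 2)
    jr <- runif(1, -min(6, slack_r), min(6, slack_r))
    jc <- runif(1, -min(6, slack_c), min(6, slack_c))
    geom$center <- c((nr + 1) / 2 + jr, (nc + 1) / 2 + jc)

    mask <- render_structure_mask(geom, c(nr, nc))
    gradient <- matrix(seq(-3, 3, length.out = nr), nr, nc)
    speckle <- matrix(rnorm(nr * nc, 0, scene$background_std), nr, nc)
    v <- scene$background_mean + gradient + speckle +
      mask * scene$structure_contrast * eff$contrast * contrast_mult
    v[] <- round(pmin(255, pmax(0, v)))  # pmax(0, .) drops dim; assign in place

    idx <- which(mask == 1L, arr.ind = TRUE)
    pad <- 10L
    r0 <- max(0L, min(idx[, 1]) - 1L - pad); r1 <- min(nr, max(idx[, 1]) + pad)
    c0 <- max(0L, min(idx[, 2]) - 1L - pad); c1 <- min(nc, max(idx[, 2]) + pad)

    list(
      image = gray_image(v, state = "raw",
                         source_id = sprintf("synthetic_%s_seed%d",
                                             scene$view, scene$seed)),
      truth = list(label = truth_label, true_mask = mask,
                   true_crop = c(r0, c0, r1, c1), geometry = geom)
    )
  })
}

#' Generate the images and annotations of one patient, in memory
#'
#' One stream per (patient, view) derived from the master seed. Views are
#' independently dropped with probability `missing_view_rate`, exercising the
#' "at least one ROI visible" inclusion rule downstream.
#'
#' @param index patient index (drives the derived seeds).
#' @param label `"BA"` or `"non-BA"`.
#' @param master_seed cohort master seed.
#' @param scene_configs named list of scenes as from [default_scene_configs()].
#' @param missing_view_rate per-view dropout probability.
#' @return named list over views; each element is `NULL` (view missing) or
#'   `list(image, annotation, truth)` with `annotation` a [roi_annotation()]
#'   whose crop is the ground-truth box.
#' @export
generate_patient_images <- function(index, label, master_seed,
                                    scene_configs = default_scene_configs(),
                                    missing_view_rate = 0) {
  out <- setNames(vector("list", length(scene_configs)), names(scene_configs))
  for (k in seq_along(scene_configs)) {
    sc <- scene_configs[[k]]
    seed_k <- derive_seed(master_seed, index, salt = 1000L + k)
    dropped <- with_seed(derive_seed(master_seed, index, salt = 2000L + k),
                         runif(1) < missing_view_rate)
    if (dropped) next
    sc$seed <- seed_k
    gen <- generate_image(sc, label)
    out[[k]] <- list(
      image = gen$image,
      annotation = roi_annotation(sc$view, gen$truth$true_crop),
      truth = gen$truth
    )
  }
  out
}

#' Write a full synthetic dataset to disk
#'
#' Writes 8-bit grayscale PNGs (up to three views per patient), the cohort
#' CSV, ROI-annotation JSON, ground-truth JSON (labels, MMP-7, ages and the
#' realized structure geometry, from which masks re-render exactly), and a
#' manifest with MD5 checksums of every file.
#'
#' @param config a [cohort_config()] (its `missing_view_rate` drives view
#'   dropout).
#' @param scene_configs named list of [scene_config()]s.
#' @param out_dir output directory, created if needed.
#' @return the manifest, invisibly (also written as `manifest.json`).
#' @export
generate_dataset <- function(config,
                             scene_configs = default_scene_configs(),
                             out_dir) {
  cohort <- generate_cohort(config)
  img_dir <- file.path(out_dir, "images")
  dir.create(img_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(img_dir))
    stop_badx(sprintf("cannot create output directory '%s'", out_dir),
              "badx_io_error")

  annotations <- list()
  truths <- list()
  for (i in seq_len(nrow(cohort))) {
    pid <- cohort$patient_id[i]
    views <- generate_patient_images(
      i, cohort$label[i], config$seed, scene_configs,
      missing_view_rate = config$missing_view_rate
    )
    patient_truth <- list(patient_id = pid, label = cohort$label[i],
                          true_mmp7 = cohort$mmp7_ng_ml[i],
                          age_days = cohort$age_days[i], views = list())
    for (vw in names(views)) {
      v <- views[[vw]]
      if (is.null(v)) next
      rel <- file.path("images", sprintf("%s_%s.png", pid, vw))
      write_gray_png(v$image, file.path(out_dir, rel))
      annotations[[length(annotations) + 1]] <- list(
        patient_id = pid, view = vw, path = rel,
        crop = as.integer(v$annotation$crop)
      )
      patient_truth$views[[vw]] <- list(
        geometry = v$truth$geometry,
        image_size = dim(v$image$values),
        true_crop = as.integer(v$truth$true_crop)
      )
    }
    truths[[i]] <- patient_truth
  }

  write.csv(cohort, file.path(out_dir, "cohort.csv"), row.names = FALSE)
  jsonlite::write_json(annotations, file.path(out_dir, "annotations.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(truths, file.path(out_dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)

  files <- sort(setdiff(list.files(out_dir, recursive = TRUE),
                        "manifest.json"))
  sums <- unname(tools::md5sum(file.path(out_dir, files)))
  manifest <- list(
    n_patients = nrow(cohort), seed = config$seed,
    prevalence = config$prevalence,
    missing_view_rate = config$missing_view_rate,
    files = data.frame(path = files, md5 = sums, stringsAsFactors = FALSE)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(manifest)
}
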