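test_that("image files read back as grayscale matrices on the 0-255 scale", {
  d <- withr::local_tempdir()
  g <- file.path(d, "gray.png"); w <- file.path(d, "white.png")
  r <- file.path(d, "red.png")
  png::writePNG(matrix(100 / 255, 16, 16), g)
  png::writePNG(array(1, c(8, 8, 3)), w)
  png::writePNG(array(rep(c(1, 0, 0), each = 64), c(8, 8, 3)), r)
  expect_equal(read_gray(g)$values, matrix(100, 16, 16))
  expect_equal(read_gray(w)$values, matrix(255, 8, 8))
  # Rec. 601 luminance of pure red, by hand: 0.299 * 255 = 76.245
  expect_equal(read_gray(r)$values[1, 1], 76.245, tolerance = 1e-9)
  expect_error(read_gray(file.path(d, "missing.png")),
               class = "badx_input_error")
})

test_that("normalization hits mean 55 / IQR 40 and is idempotent", {
  set.seed(1)
  img <- gray_image(matrix(runif(128 * 128, 0, 255), 128), "raw")
  out <- normalize_intensity(img)
  expect_equal(mean(out$values), 55, tolerance = 1e-9)
  expect_equal(badx:::image_iqr(out$values), 40, tolerance = 1e-9)
  expect_equal(out$state, "normalized")
  twice <- normalize_intensity(out)
  expect_equal(twice$values, out$values, tolerance = 1e-9)
})

test_that("normalization matches the hand-computed 2x2 example", {
  # values {0,10,20,30}: mean 15; linear-interpolation quartiles Q1 = 7.5,
  # Q3 = 22.5, IQR 15; map x -> (x - 15)/15 * 40 + 55
  img <- gray_image(matrix(c(0, 20, 10, 30), 2), "raw")
  out <- normalize_intensity(img)
  expect_equal(out$values, matrix(c(15, 68 + 1 / 3, 41 + 2 / 3, 95), 2),
               tolerance = 1e-9)
})

test_that("degenerate (constant) images are refused with their source id", {
  img <- gray_image(matrix(7, 4, 4), "raw", source_id = "flat_probe")
  err <- expect_error(normalize_intensity(img),
                      class = "badx_degenerate_image")
  expect_match(conditionMessage(err), "flat_probe")
})

test_that("cropping takes the half-open submatrix with no resampling", {
  ramp <- gray_image(matrix(0:99, 10, 10, byrow = TRUE), "raw")
  full <- crop_roi(ramp, roi_annotation("gallbladder", c(0, 0, 10, 10)))
  expect_identical(full$values, ramp$values)
  px <- crop_roi(ramp, roi_annotation("gallbladder", c(0, 0, 1, 1)))
  expect_equal(px$values, matrix(0, 1, 1))
  sub <- crop_roi(ramp, roi_annotation("gallbladder", c(2, 3, 5, 9)))
  expect_equal(dim(sub$values), c(3, 6))
  # row-major ramp: value at (r, c) = 10 * r + c (0-based)
  expect_equal(sub$values[1, 1], 23)
  expect_equal(sub$values[3, 6], 48)
  expect_error(crop_roi(ramp, roi_annotation("gallbladder", c(0, 0, 11, 5))),
               class = "badx_annotation_error")
})

test_that("delineation recovers a high-contrast disk", {
  # dark disk, radius 20, centered in 128x128 bright noisy background
  set.seed(4)
  nr <- 128
  truth <- render_structure_mask(
    list(shape = "ellipse", center = c(64.5, 64.5), a = 20, b = 20),
    c(nr, nr))
  v <- 180 + matrix(rnorm(nr * nr, 0, 8), nr) - 90 * truth
  img <- normalize_intensity(gray_image(pmax(0, pmin(255, v)) + 0 * v, "raw"))
  ann <- roi_annotation("gallbladder", c(0, 0, nr, nr))
  m <- delineate_mask(img, ann)
  expect_s3_class(m, "binary_mask")
  expect_lt(abs(sum(m$values) - pi * 400) / (pi * 400), 0.10)
  cm <- which(m$values == 1, arr.ind = TRUE)
  expect_lt(max(abs(colMeans(cm) - 64.5)), 2)
  # boundary = mask minus erosion: a thin closed ring
  ring <- mask_boundary(m)
  expect_gt(sum(ring), 0)
  expect_lt(sum(ring), sum(m$values) / 2)
})

test_that("constant crops signal delineation failure", {
  img <- gray_image(matrix(55, 32, 32), "normalized")
  ann <- roi_annotation("gallbladder", c(0, 0, 32, 32))
  expect_warning(m <- delineate_mask(img, ann),
                 class = "badx_delineation_failure")
  expect_null(m)
})

test_that("only the largest connected component is kept", {
  set.seed(2)
  nr <- 96
  big <- render_structure_mask(
    list(shape = "ellipse", center = c(30, 30), a = 10, b = 10), c(nr, nr))
  small <- render_structure_mask(
    list(shape = "ellipse", center = c(75, 75), a = 4, b = 4), c(nr, nr))
  v <- 180 + matrix(rnorm(nr * nr, 0, 6), nr) - 90 * (big + small)
  img <- normalize_intensity(gray_image(pmax(0, pmin(255, v)) + 0 * v, "raw"))
  m <- delineate_mask(img, roi_annotation("gallbladder", c(0, 0, nr, nr)))
  expect_gt(sum(m$values * big) / sum(big), 0.8)
  expect_equal(sum(m$values * small), 0)
})

test_that("8-connectivity labelling merges diagonal touches", {
  m <- matrix(0L, 5, 5); m[1, 1] <- 1L; m[2, 2] <- 1L; m[4, 4] <- 1L
  lab8 <- badx:::label_components(m, 8)
  expect_equal(lab8[1, 1], lab8[2, 2])
  expect_false(lab8[4, 4] == lab8[1, 1])
  lab4 <- badx:::label_components(m, 4)
  expect_equal(length(unique(lab4[lab4 > 0])), 3)
})

test_that("view features match hand computations", {
  vals <- matrix(1:100, 10, 10, byrow = TRUE)
  crop <- gray_image(vals + 0, "normalized")
  mask_all <- structure(list(values = matrix(1L, 10, 10),
                             component_count = 1L), class = "binary_mask")
  f_all <- extract_view_features(crop, mask_all)$features
  # identity mask: ROI statistics equal whole-crop statistics exactly
  expect_equal(unname(f_all["roi_mean"]), unname(f_all["crop_mean"]))
  expect_equal(unname(f_all["roi_sd"]), unname(f_all["crop_sd"]))
  expect_equal(unname(f_all["area_ratio"]), 1)

  mask_row <- structure(list(values = rbind(rep(1L, 10),
                                            matrix(0L, 9, 10)),
                             component_count = 1L), class = "binary_mask")
  f <- extract_view_features(crop, mask_row)$features
  expect_equal(unname(f["roi_mean"]), 5.5)     # mean of 1..10
  expect_equal(unname(f["roi_median"]), 5.5)
  expect_equal(unname(f["area_abs"]), 10)
  expect_equal(unname(f["area_ratio"]), 0.1)
  # population std of 1..10
  expect_equal(unname(f["roi_sd"]), sqrt(mean((1:10 - 5.5)^2)))

  f0 <- extract_view_features(crop, mask_row, levels = c(0, 0.5, 1))$features
  expect_equal(unname(f0["roi_q00"]), 1)
  expect_equal(unname(f0["roi_q100"]), 10)
  expect_error(extract_view_features(crop, NULL), class = "badx_input_error")
})

test_that("extracted quantiles are monotone and areas consistent", {
  for (seed in 1:5) {
    g <- generate_image(scene_config("tc_transverse", seed = seed), "BA")
    img <- normalize_intensity(g$image)
    ann <- roi_annotation("tc_transverse", g$truth$true_crop)
    cr <- crop_roi(img, ann)
    m <- delineate_mask(cr, ann)
    f <- extract_view_features(cr, m, view = "tc_transverse")$features
    qs <- f[grep("^roi_q", names(f))]
    expect_true(all(diff(qs) >= 0))
    qs2 <- f[grep("^crop_q", names(f))]
    expect_true(all(diff(qs2) >= 0))
    expect_equal(unname(f["area_ratio"]) * length(cr$values),
                 unname(f["area_abs"]))
    expect_lte(f["area_abs"], length(cr$values))
  }
})

test_that("features are invariant to affine intensity rescaling", {
  g <- generate_image(scene_config("gallbladder", seed = 14), "BA")
  raw <- g$image$values
  affine <- gray_image(0.4 * raw + 30, "raw")
  ann <- roi_annotation("gallbladder", g$truth$true_crop)
  feats <- lapply(list(g$image, affine), function(im) {
    ni <- normalize_intensity(im)
    cr <- crop_roi(ni, ann)
    extract_view_features(cr, delineate_mask(cr, ann))$features
  })
  expect_equal(feats[[1]], feats[[2]], tolerance = 1e-6)
})

test_that("patient assembly tracks availability and imputes from medians", {
  g <- generate_image(scene_config("gallbladder", seed = 6), "BA")
  img <- normalize_intensity(g$image)
  ann <- roi_annotation("gallbladder", g$truth$true_crop)
  cr <- crop_roi(img, ann)
  vf <- extract_view_features(cr, delineate_mask(cr, ann),
                              view = "gallbladder")
  views <- list(gallbladder = vf, tc_branches = NULL, tc_transverse = NULL)

  row_na <- assemble_patient_features(views)
  expect_equal(unname(row_na[c("gallbladder_present", "tc_branches_present",
                               "tc_transverse_present")]), c(1, 0, 0))
  expect_true(all(is.na(row_na[grep("^tc_branches_(roi|crop|area)",
                                    names(row_na))])))

  med <- setNames(rep(12.5, length(row_na)), names(row_na))
  row_imp <- assemble_patient_features(views, medians = med)
  expect_true(all(row_imp[grep("^tc_branches_(roi|crop|area)",
                               names(row_imp))] == 12.5))
  # gallbladder features untouched by imputation
  expect_equal(row_imp[grep("^gallbladder_roi", names(row_imp))],
               row_na[grep("^gallbladder_roi", names(row_na))])

  err <- expect_error(
    assemble_patient_features(list(), patient_id = "P0042"),
    class = "badx_patient_excluded")
  expect_match(conditionMessage(err), "P0042")
})

test_that("cohort extraction excludes ROI-less patients, never silently", {
  got <- gen_cohort_with_images(30, 0.5, seed = 17, missing_view_rate = 0.6)
  feats <- extract_cohort_features(got$images)
  excluded <- attr(feats, "excluded")
  expect_equal(nrow(feats) + length(excluded), 30)
  expect_gt(length(excluded), 0)  # at rate 0.6^3 some patient loses all views
  expect_true(all(feats$gallbladder_present %in% c(0, 1)))
})

test_that("on-disk and in-memory pipelines agree", {
  d <- withr::local_tempdir()
  cfg <- cohort_config(n_patients = 4, seed = 19)
  scenes <- default_scene_configs(image_size = c(96, 96))
  generate_dataset(cfg, scenes, d)
  co <- generate_cohort(cfg)
  ims <- setNames(lapply(1:4, function(i)
    generate_patient_images(i, co$label[i], cfg$seed, scenes)),
    co$patient_id)
  f_mem <- extract_cohort_features(ims)
  f_disk <- extract_features_dir(d)
  expect_equal(as.data.frame(f_disk), as.data.frame(f_mem), tolerance = 1e-12)
})
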