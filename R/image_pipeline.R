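# Ultrasound image preprocessing and quantitative ROI feature extraction:
# grayscale conversion, intensity normalization to a fixed mean/IQR (to
# harmonize devices), manual-style ROI cropping, morphological boundary
# delineation to a binary mask, and grayscale/size/texture features.

#' Grayscale image container
#'
#' A real-valued intensity matrix with a provenance flag. Raw images lie on
#' the 8-bit \[0, 255\] scale; normalized images are unbounded reals.
#'
#' @param values numeric matrix, at least 2 x 2, finite.
#' @param state `"raw"` or `"normalized"`.
#' @param source_id identifier used in error messages.
#' @return a `gray_image` object.
#' @export
gray_image <- function(values, state = c("raw", "normalized"),
                       source_id = "image") {
  state <- match.arg(state)
  if (!is.matrix(values) || !is.numeric(values))
    stop_badx("image values must be a numeric matrix", "badx_input_error")
  if (nrow(values) < 2 || ncol(values) < 2)
    stop_badx("image must be at least 2 x 2", "badx_input_error")
  if (!all(is.finite(values)))
    stop_badx("image contains non-finite values", "badx_input_error")
  if (state == "raw" && (min(values) < 0 || max(values) > 255))
    stop_badx("raw image values must lie in [0, 255]", "badx_input_error")
  structure(list(values = values, state = state, source_id = source_id),
            class = "gray_image")
}

#' @export
print.gray_image <- function(x, ...) {
  cat(sprintf("<gray_image %s: %d x %d, %s, range [%.2f, %.2f]>\n",
              x$source_id, nrow(x$values), ncol(x$values), x$state,
              min(x$values), max(x$values)))
  invisible(x)
}

#' Read an image file as a grayscale matrix
#'
#' Reads 8-bit grayscale or RGB PNG (and TIFF when the tiff package is
#' available) onto the \[0, 255\] scale. RGB is collapsed with the Rec. 601
#' luminance weighting 0.299 R + 0.587 G + 0.114 B; an alpha channel is
#' ignored.
#'
#' @param path image file path.
#' @return a raw [gray_image()].
#' @export
read_gray <- function(path) {
  if (!file.exists(path))
    stop_badx(sprintf("image file '%s' not found", path), "badx_input_error")
  ext <- tolower(tools::file_ext(path))
  arr <- if (ext %in% c("tif", "tiff")) {
    if (!requireNamespace("tiff", quietly = TRUE))
      stop_badx("the tiff package is required to read TIFF files",
                "badx_input_error")
    tiff::readTIFF(path)
  } else {
    png::readPNG(path)
  }
  v <- if (length(dim(arr)) == 2) {
    arr
  } else if (dim(arr)[3] >= 3) {
    0.299 * arr[, , 1] + 0.587 * arr[, , 2] + 0.114 * arr[, , 3]
  } else {
    arr[, , 1]  # grayscale + alpha
  }
  gray_image(v * 255, state = "raw", source_id = basename(path))
}

#' Write a grayscale image as 8-bit PNG
#'
#' Values are clipped to \[0, 255\] and quantized only at write time;
#' in-memory normalized images are never clipped.
#'
#' @param img a [gray_image()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gray_png <- function(img, path) {
  v <- img$values
  v[v < 0] <- 0; v[v > 255] <- 255
  png::writePNG(round(v) / 255, path)
  invisible(path)
}

#' Intensity normalization configuration
#'
#' The normalization targets are fixed constants of the pipeline: every image
#' is mapped to pixel mean 55 and interquartile range 40 (0--255 intensity
#' units) so images from different ultrasound devices share one intensity
#' scale. The quartile interpolation rule is configurable because only the
#' targets, not the rule, are pinned down; the default is linear
#' interpolation between order statistics ([stats::quantile()] type 7).
#'
#' @param target_mean target pixel mean (default 55).
#' @param target_iqr target interquartile range (default 40, must be > 0).
#' @param quantile_type quartile rule, passed to [stats::quantile()].
#' @return a `norm_config` list.
#' @export
norm_config <- function(target_mean = 55, target_iqr = 40, quantile_type = 7) {
  if (target_iqr <= 0)
    stop_badx("target_iqr must be positive", "badx_config_error")
  structure(list(target_mean = target_mean, target_iqr = target_iqr,
                 quantile_type = quantile_type), class = "norm_config")
}

image_iqr <- function(values, quantile_type = 7) {
  q <- quantile(values, c(0.25, 0.75), type = quantile_type, names = FALSE)
  q[2] - q[1]
}

#' Normalize image intensities to a fixed mean and IQR
#'
#' Affine map `(x - mean(x)) / IQR(x) * target_iqr + target_mean`. The output
#' is stored as real values without clipping or rounding (clipping would
#' break the mean/IQR guarantee); after the map the pixel mean equals
#' `target_mean` and the IQR equals `target_iqr` exactly (to numerical
#' precision), and the operation is idempotent. Features computed from
#' normalized images are invariant to any positive affine rescaling of the
#' raw input, which is the point: it unifies images from different devices.
#'
#' @param img a [gray_image()].
#' @param cfg a [norm_config()].
#' @return a normalized [gray_image()].
#' @export
normalize_intensity <- function(img, cfg = norm_config()) {
  v <- img$values
  iqr <- image_iqr(v, cfg$quantile_type)
  if (iqr <= 0)
    stop_badx(sprintf("image '%s' is degenerate (IQR = 0); cannot normalize",
                      img$source_id), "badx_degenerate_image")
  out <- (v - mean(v)) / iqr * cfg$target_iqr + cfg$target_mean
  gray_image(out, state = "normalized", source_id = img$source_id)
}

#' ROI annotation
#'
#' A manual crop box plus the expected structure polarity for the view:
#' the fluid-filled gallbladder is hypoechoic (dark), the triangular-cord
#' fibrous tissue is echogenic (bright). Coordinates are 0-based, row-major,
#' half-open: the box `c(r0, c0, r1, c1)` covers rows `[r0, r1)` and columns
#' `[c0, c1)`.
#'
#' @param view one of `"gallbladder"`, `"tc_branches"`, `"tc_transverse"`.
#' @param crop integer box `c(r0, c0, r1, c1)`.
#' @param polarity `"dark_structure"` or `"bright_structure"`; defaults by
#'   view.
#' @return an `roi_annotation` object.
#' @export
roi_annotation <- function(view, crop, polarity = NULL) {
  view <- match.arg(view, VIEWS)
  polarity <- polarity %||%
    if (view == "gallbladder") "dark_structure" else "bright_structure"
  polarity <- match.arg(polarity, c("dark_structure", "bright_structure"))
  crop <- as.integer(crop)
  if (length(crop) != 4 || crop[1] >= crop[3] || crop[2] >= crop[4] ||
      any(crop[c(1, 2)] < 0))
    stop_badx("crop must be c(r0, c0, r1, c1) with r0 < r1, c0 < c1",
              "badx_annotation_error")
  structure(list(view = view, crop = crop, polarity = polarity),
            class = "roi_annotation")
}

#' Crop an image to an annotated ROI
#'
#' Pure submatrix extraction (no resampling) of rows `[r0, r1)` and columns
#' `[c0, c1)` of the 0-based half-open crop box.
#'
#' @param img a [gray_image()].
#' @param ann an [roi_annotation()].
#' @return a [gray_image()] of the cropped region, same state.
#' @export
crop_roi <- function(img, ann) {
  b <- ann$crop
  if (b[3] > nrow(img$values) || b[4] > ncol(img$values))
    stop_badx(sprintf("crop box [%s] exceeds image bounds %d x %d",
                      paste(b, collapse = ","), nrow(img$values),
                      ncol(img$values)), "badx_annotation_error")
  sub <- img$values[(b[1] + 1):b[3], (b[2] + 1):b[4], drop = FALSE]
  structure(list(values = sub, state = img$state,
                 source_id = paste0(img$source_id, ":", ann$view)),
            class = "gray_image")
}

#' Morphological delineation configuration
#'
#' Artifact choices for the boundary-delineation pipeline; all exposed.
#'
#' @param sigma Gaussian smoothing width in pixels (default 2).
#' @param brush_radius disk structuring-element radius in pixels (default 3).
#' @param connectivity neighbourhood for connected components; 8 (default)
#'   or 4.
#' @return a `morph_config` list.
#' @export
morph_config <- function(sigma = 2, brush_radius = 3, connectivity = 8) {
  if (!connectivity %in% c(4, 8))
    stop_badx("connectivity must be 4 or 8", "badx_config_error")
  structure(list(sigma = sigma, brush_radius = brush_radius,
                 connectivity = connectivity), class = "morph_config")
}

# Connected-component labelling. EBImage::bwlabel is 4-connected; for the
# default 8-connectivity, 4-connected labels that touch diagonally are merged
# with a small union-find pass over the diagonal adjacencies.
label_components <- function(mask, connectivity = 8) {
  lab <- matrix(as.integer(EBImage::bwlabel(mask > 0)), nrow(mask),
                ncol(mask))
  k <- max(lab)
  if (connectivity == 4 || k <= 1) return(lab)
  nr <- nrow(lab); nc <- ncol(lab)
  pair_list <- list(
    cbind(as.vector(lab[-nr, -nc]), as.vector(lab[-1, -1])),   # \ diagonal
    cbind(as.vector(lab[-nr, -1]), as.vector(lab[-1, -nc]))    # / diagonal
  )
  pairs <- do.call(rbind, pair_list)
  pairs <- pairs[pairs[, 1] > 0 & pairs[, 2] > 0 &
                 pairs[, 1] != pairs[, 2], , drop = FALSE]
  parent <- seq_len(k)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (r in seq_len(nrow(pairs))) {
    a <- find(pairs[r, 1]); b <- find(pairs[r, 2])
    if (a != b) parent[max(a, b)] <- min(a, b)
  }
  root <- vapply(seq_len(k), find, integer(1))
  root <- match(root, sort(unique(root)))
  lab[lab > 0] <- root[lab[lab > 0]]
  lab
}

delineation_failure <- function(ann, why) {
  warn_badx(sprintf("delineation failed for %s view: %s", ann$view, why),
            "badx_delineation_failure")
  NULL
}

#' Delineate the structure boundary in a cropped ROI
#'
#' Fixed-order morphological pipeline: Gaussian smoothing, global Otsu
#' threshold, polarity selection (keep pixels below the threshold for a dark
#' structure, above for a bright one), morphological opening then closing
#' with a disk structuring element, retention of the largest connected
#' component, and hole filling. The result is a single-component binary
#' mask; its boundary is recoverable as the mask minus its erosion
#' ([mask_boundary()]).
#'
#' On failure (near-constant crop, or an empty mask after post-processing)
#' the function returns `NULL` with a classed warning
#' (`badx_delineation_failure`); callers treat the view as missing, which
#' feeds the "at least one ROI visible" inclusion rule.
#'
#' @param cropped a normalized, cropped [gray_image()].
#' @param ann the [roi_annotation()] of the crop (supplies polarity).
#' @param cfg a [morph_config()].
#' @return a `binary_mask` (`values` 0/1 matrix, `component_count = 1`) or
#'   `NULL` on failure.
#' @export
delineate_mask <- function(cropped, ann, cfg = morph_config()) {
  v <- cropped$values
  rg <- range(v)
  if (diff(rg) < 1e-8)
    return(delineation_failure(ann, "constant crop, nothing to segment"))
  sm <- EBImage::gblur(v, sigma = cfg$sigma)
  th <- EBImage::otsu(EBImage::Image(sm), range = range(sm), levels = 256)
  m <- if (ann$polarity == "dark_structure") sm < th else sm > th
  brush <- EBImage::makeBrush(2 * cfg$brush_radius + 1, shape = "disc")
  m <- EBImage::opening(m, brush)
  m <- EBImage::closing(m, brush)
  m <- matrix(as.integer(m > 0), nrow(v), ncol(v))
  if (sum(m) == 0)
    return(delineation_failure(ann, "empty mask after morphology"))
  lab <- label_components(m, cfg$connectivity)
  sizes <- tabulate(lab[lab > 0])
  keep <- which.max(sizes)
  m <- matrix(as.integer(lab == keep), nrow(v), ncol(v))
  m <- matrix(as.integer(EBImage::fillHull(m) > 0), nrow(v), ncol(v))
  structure(list(values = m, component_count = 1L), class = "binary_mask")
}

#' Boundary of a binary mask
#'
#' The delineated boundary: mask minus its erosion by a 3 x 3 box.
#'
#' @param mask a `binary_mask` from [delineate_mask()].
#' @return 0/1 matrix of boundary pixels.
#' @export
mask_boundary <- function(mask) {
  m <- mask$values
  er <- EBImage::erode(m, EBImage::makeBrush(3, shape = "box"))
  matrix(as.integer(m - as.integer(er > 0) > 0), nrow(m), ncol(m))
}

#' Default quantile levels for grayscale features
#' @return numeric vector of levels.
#' @export
default_quantile_levels <- function() c(0.05, 0.10, 0.25, 0.50, 0.75, 0.90, 0.95)

pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

#' Extract quantitative features from a cropped ROI and its mask
#'
#' Three categories, computed for both the masked ROI and the whole crop:
#' grayscale features (quantiles at the configured levels, mean, median),
#' texture (standard deviation of pixel intensities, population convention,
#' i.e. divide by n), and size (absolute mask area in pixels and its ratio to
#' the crop area).
#'
#' @param cropped a cropped [gray_image()].
#' @param mask a `binary_mask` of the same shape.
#' @param levels quantile levels (default [default_quantile_levels()]).
#' @param view view label stored alongside the features.
#' @return a `view_features` object: `view` plus a named numeric `features`
#'   vector (`roi_q*`, `roi_mean`, `roi_median`, `roi_sd`, `crop_q*`,
#'   `crop_mean`, `crop_median`, `crop_sd`, `area_abs`, `area_ratio`).
#' @export
extract_view_features <- function(cropped, mask,
                                  levels = default_quantile_levels(),
                                  view = "gallbladder") {
  if (is.null(mask) || sum(mask$values) == 0)
    stop_badx("mask is empty; extract features only from a successful delineation",
              "badx_input_error")
  if (!all(dim(mask$values) == dim(cropped$values)))
    stop_badx("mask and crop shapes differ", "badx_input_error")
  v <- cropped$values
  roi <- v[mask$values == 1L]
  qname <- function(prefix) sprintf("%s_q%02d", prefix, round(100 * levels))
  feats <- c(
    setNames(quantile(roi, levels, type = 7, names = FALSE), qname("roi")),
    roi_mean = mean(roi), roi_median = median(roi), roi_sd = pop_sd(roi),
    setNames(quantile(v, levels, type = 7, names = FALSE), qname("crop")),
    crop_mean = mean(v), crop_median = median(v), crop_sd = pop_sd(v),
    area_abs = sum(mask$values), area_ratio = sum(mask$values) / length(v)
  )
  structure(list(view = view, features = feats), class = "view_features")
}

view_feature_names <- function(levels = default_quantile_levels()) {
  qn <- function(prefix) sprintf("%s_q%02d", prefix, round(100 * levels))
  c(qn("roi"), "roi_mean", "roi_median", "roi_sd",
    qn("crop"), "crop_mean", "crop_median", "crop_sd",
    "area_abs", "area_ratio")
}

#' Assemble one patient's per-view features into a single vector
#'
#' Concatenates the three views' features, prefixed by view, plus a per-view
#' availability indicator. Patients with no visible ROI in any view are
#' excluded (a classed error naming the patient, never a silent drop). A
#' missing view's features are `NA` unless training medians are supplied
#' (the default downstream policy: training-median imputation with the
#' indicator left at 0).
#'
#' @param views named list over `"gallbladder"`, `"tc_branches"`,
#'   `"tc_transverse"`; each a `view_features` or `NULL`.
#' @param medians optional named vector of training feature medians used to
#'   impute missing views (as from [feature_medians()]).
#' @param patient_id used in the exclusion signal.
#' @return named numeric vector: `<view>_<feature>` for every view and
#'   feature, plus `<view>_present` indicators.
#' @export
assemble_patient_features <- function(views, medians = NULL,
                                      patient_id = "patient") {
  present <- vapply(VIEWS, function(v) !is.null(views[[v]]), logical(1))
  if (!any(present))
    stop_badx(sprintf("patient %s has no visible ROI in any view; excluded",
                      patient_id), "badx_patient_excluded",
              patient_id = patient_id)
  fnames <- view_feature_names()
  out <- numeric(0)
  for (vw in VIEWS) {
    nm <- paste0(vw, "_", fnames)
    if (present[[vw]]) {
      f <- views[[vw]]$features[fnames]
      out <- c(out, setNames(as.numeric(f), nm))
    } else {
      vals <- if (is.null(medians)) rep(NA_real_, length(nm))
              else as.numeric(medians[nm])
      out <- c(out, setNames(vals, nm))
    }
  }
  c(out, setNames(as.numeric(present), paste0(VIEWS, "_present")))
}

#' Per-feature medians of a training feature table
#'
#' Medians over non-missing entries, used to impute features of missing
#' views at training and prediction time.
#'
#' @param features data frame / tibble of assembled features.
#' @return named numeric vector of medians (feature columns only).
#' @export
feature_medians <- function(features) {
  num <- vapply(features, is.numeric, logical(1))
  cols <- setdiff(names(features)[num], "patient_id")
  vapply(features[cols], function(x) median(x, na.rm = TRUE), numeric(1))
}

#' Impute missing view features with training medians
#'
#' @param features assembled feature table (may contain `NA` for missing
#'   views).
#' @param medians named medians from [feature_medians()] (computed on the
#'   training table if omitted).
#' @return the table with `NA`s replaced; availability indicators untouched.
#' @export
impute_features <- function(features, medians = feature_medians(features)) {
  for (nm in intersect(names(medians), names(features))) {
    x <- features[[nm]]
    x[is.na(x)] <- medians[[nm]]
    features[[nm]] <- x
  }
  features
}

#' Run the image pipeline over an in-memory patient image set
#'
#' For each patient and available view: normalize, crop to the annotated ROI,
#' delineate the mask, extract features. Views whose delineation fails are
#' treated as missing; patients with no usable view are excluded and listed
#' in the `excluded` attribute.
#'
#' @param patients named list (by patient id) of per-view lists as produced
#'   by [generate_patient_images()].
#' @param norm a [norm_config()].
#' @param morph a [morph_config()].
#' @param levels quantile levels.
#' @return tibble of assembled features, one row per included patient, with
#'   attribute `excluded` (character vector of excluded patient ids).
#' @export
extract_cohort_features <- function(patients, norm = norm_config(),
                                    morph = morph_config(),
                                    levels = default_quantile_levels()) {
  rows <- list(); excluded <- character(0)
  for (pid in names(patients)) {
    views <- setNames(vector("list", length(VIEWS)), VIEWS)
    for (vw in VIEWS) {
      entry <- patients[[pid]][[vw]]
      if (is.null(entry)) next
      feat <- tryCatch({
        img <- entry$image
        if (img$state == "raw") img <- normalize_intensity(img, norm)
        cr <- crop_roi(img, entry$annotation)
        msk <- withCallingHandlers(
          delineate_mask(cr, entry$annotation, morph),
          badx_delineation_failure = function(w) invokeRestart("muffleWarning")
        )
        if (is.null(msk)) NULL
        else extract_view_features(cr, msk, levels, view = vw)
      }, badx_degenerate_image = function(e) NULL)
      views[[vw]] <- feat
    }
    row <- tryCatch(assemble_patient_features(views, patient_id = pid),
                    badx_patient_excluded = function(e) NULL)
    if (is.null(row)) excluded <- c(excluded, pid)
    else rows[[pid]] <- row
  }
  tbl <- if (length(rows)) {
    tibble::as_tibble(do.call(rbind, rows))
  } else {
    tibble::tibble()
  }
  if (length(rows)) tbl <- tibble::add_column(tbl, patient_id = names(rows),
                                              .before = 1)
  attr(tbl, "excluded") <- excluded
  tbl
}

#' Run the image pipeline over a dataset directory
#'
#' Reads the annotation JSON and images written by [generate_dataset()] (or
#' any dataset following the same schema) and extracts assembled features.
#'
#' @param dir dataset directory containing `annotations.json` and `images/`.
#' @inheritParams extract_cohort_features
#' @return tibble as from [extract_cohort_features()].
#' @export
extract_features_dir <- function(dir, norm = norm_config(),
                                 morph = morph_config(),
                                 levels = default_quantile_levels()) {
  ann_path <- file.path(dir, "annotations.json")
  if (!file.exists(ann_path))
    stop_badx(sprintf("no annotations.json under '%s'", dir),
              "badx_input_error")
  anns <- jsonlite::read_json(ann_path, simplifyVector = FALSE)
  patients <- list()
  for (a in anns) {
    entry <- list(
      image = read_gray(file.path(dir, a$path)),
      annotation = roi_annotation(a$view, unlist(a$crop))
    )
    patients[[a$patient_id]][[a$view]] <- entry
  }
  extract_cohort_features(patients, norm, morph, levels)
}
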