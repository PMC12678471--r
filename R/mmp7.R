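# Serum MMP-7 measurement handling and the age-stratified positivity rule.
# MMP-7 (matrix metalloproteinase-7) is an ELISA-measured serum biomarker
# elevated in biliary atresia; assays run on 20-fold diluted serum in
# triplicate, with the replicate mean used for analysis.

#' Age-stratified MMP-7 positivity thresholds
#'
#' A positive result is a concentration strictly above 18 ng/mL for infants
#' older than 30 days, and strictly above 28.1 ng/mL for infants 30 days old
#' or younger (the higher cutoff reflects the physiologic neonatal elevation
#' of MMP-7).
#'
#' @param threshold_older cutoff (ng/mL) for age > `age_cut`.
#' @param threshold_younger cutoff (ng/mL) for age <= `age_cut`.
#' @param age_cut stratum boundary in days (the boundary age itself uses the
#'   younger-stratum cutoff).
#' @return an `mmp7_thresholds` list.
#' @export
mmp7_thresholds <- function(threshold_older = 18, threshold_younger = 28.1,
                            age_cut = 30) {
  if (threshold_older <= 0 || threshold_younger <= 0)
    stop_badx("thresholds must be positive", "badx_config_error")
  structure(list(threshold_older = threshold_older,
                 threshold_younger = threshold_younger,
                 age_cut = age_cut), class = "mmp7_thresholds")
}

#' Summarize replicate MMP-7 readings into one concentration
#'
#' Arithmetic mean of 1--3 replicates. Reported concentrations are assumed
#' to be final serum values; when readings are flagged as pre-dilution
#' instrument values, the dilution factor (default 20-fold) is applied to
#' back-calculate the serum concentration.
#'
#' @param replicate_values numeric vector of 1--3 concentrations (ng/mL),
#'   all >= 0.
#' @param dilution_factor positive dilution factor (default 20).
#' @param prediluted logical; `TRUE` when `replicate_values` are readings of
#'   the diluted sample, so the mean is multiplied by `dilution_factor`.
#' @return final serum concentration in ng/mL.
#' @export
summarize_replicates <- function(replicate_values, dilution_factor = 20,
                                 prediluted = FALSE) {
  if (length(replicate_values) < 1)
    stop_badx("at least one replicate is required", "badx_input_error")
  if (any(!is.finite(replicate_values)) || any(replicate_values < 0))
    stop_badx("replicate concentrations must be finite and >= 0",
              "badx_input_error")
  if (dilution_factor <= 0)
    stop_badx("dilution_factor must be positive", "badx_input_error")
  m <- mean(replicate_values)
  if (prediluted) m * dilution_factor else m
}

#' Age-stratified MMP-7 positivity
#'
#' Strict comparison against the stratum cutoff: age > 30 days uses
#' > 18 ng/mL, age <= 30 days uses > 28.1 ng/mL. Vectorized over patients.
#'
#' @param concentration serum MMP-7 in ng/mL (>= 0).
#' @param age_days age in days (>= 0).
#' @param thresholds an [mmp7_thresholds()].
#' @return logical vector of positivity flags.
#' @export
mmp7_positive <- function(concentration, age_days,
                          thresholds = mmp7_thresholds()) {
  n <- max(length(concentration), length(age_days))
  concentration <- rep_len(concentration, n)
  age_days <- rep_len(age_days, n)
  if (any(!is.finite(concentration)) || any(concentration < 0))
    stop_badx("concentration must be finite and >= 0", "badx_input_error")
  if (any(!is.finite(age_days)) || any(age_days < 0))
    stop_badx("age_days must be finite and >= 0", "badx_input_error")
  cut <- ifelse(age_days > thresholds$age_cut,
                thresholds$threshold_older, thresholds$threshold_younger)
  concentration > cut
}
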