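#' Configuration for the variability-metric suite
#'
#' Collects every tunable constant of the metric definitions in one place so
#' that the exact conventions used are auditable from any report.
#'
#' @param ideal_glucose_R Ideal glucose `R` for the M-value, mmol/l
#'   (default 5.6, i.e. 100 mg/dl).
#' @param hyper_threshold Upper limit of the target range for the
#'   hyperglycaemic index, mmol/l (default 7.8).
#' @param hypo_threshold Lower limit of the target range for the
#'   hypoglycaemic index, mmol/l (default 4.4).
#' @param igc_hyper_exponent,igc_hypo_exponent,igc_hyper_scale,igc_hypo_scale
#'   Constants of the hyper-/hypoglycaemic indices (Rodbard defaults
#'   a = 1.1, b = 2, c = 30, d = 30, applied on mg/dl excesses).
#' @param mage_smoothing Width (in samples) of the optional centred
#'   moving-average smoother applied before MAGE turning-point detection;
#'   0 or 1 disables it (default: none, 5-min CGM is already averaged).
#' @param sd_ddof Delta degrees of freedom for every SD in the suite:
#'   1 = sample SD (clinical convention, default), 0 = population SD.
#' @param conga_max_lag_hours Largest lag used by `conga_1_24()`
#'   (default 24).
#' @param m_value_correction Add the historical amplitude-correction term
#'   (range/20) to the M-value? Default `FALSE` (plain M_R).
#' @param j_index_unit,igc_unit Unit in which the J-index and IGC formulas
#'   are evaluated; both formulas are historically mg/dl-based and default
#'   to `"mg_per_dl"`.
#' @param min_completeness Minimum fraction of non-missing samples required
#'   to compute a profile (default 0.9).
#'
#' @return A list of class `metric_config`.
#' @export
metric_config <- function(ideal_glucose_R = 5.6,
                          hyper_threshold = 7.8,
                          hypo_threshold = 4.4,
                          igc_hyper_exponent = 1.1,
                          igc_hypo_exponent = 2.0,
                          igc_hyper_scale = 30,
                          igc_hypo_scale = 30,
                          mage_smoothing = 0,
                          sd_ddof = 1,
                          conga_max_lag_hours = 24L,
                          m_value_correction = FALSE,
                          j_index_unit = "mg_per_dl",
                          igc_unit = "mg_per_dl",
                          min_completeness = 0.9) {
  cfg <- list(ideal_glucose_R = ideal_glucose_R,
              hyper_threshold = hyper_threshold,
              hypo_threshold = hypo_threshold,
              igc_hyper_exponent = igc_hyper_exponent,
              igc_hypo_exponent = igc_hypo_exponent,
              igc_hyper_scale = igc_hyper_scale,
              igc_hypo_scale = igc_hypo_scale,
              mage_smoothing = mage_smoothing,
              sd_ddof = sd_ddof,
              conga_max_lag_hours = as.integer(conga_max_lag_hours),
              m_value_correction = isTRUE(m_value_correction),
              j_index_unit = match.arg(j_index_unit, c("mg_per_dl", "mmol_per_l")),
              igc_unit = match.arg(igc_unit, c("mg_per_dl", "mmol_per_l")),
              min_completeness = min_completeness)
  if (cfg$hypo_threshold >= cfg$hyper_threshold)
    stop("metric_config: hypo_threshold must be below hyper_threshold")
  pos <- c("ideal_glucose_R", "igc_hyper_exponent", "igc_hypo_exponent",
           "igc_hyper_scale", "igc_hypo_scale")
  for (p in pos) if (cfg[[p]] <= 0) stop("metric_config: ", p, " must be > 0")
  if (!cfg$sd_ddof %in% c(0, 1)) stop("metric_config: sd_ddof must be 0 or 1")
  if (cfg$min_completeness < 0 || cfg$min_completeness > 1)
    stop("metric_config: min_completeness must be in [0, 1]")
  structure(cfg, class = "metric_config")
}
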