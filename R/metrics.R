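#' Glycaemic standard deviation
#'
#' SD of all non-missing glucose values in the analysis window — the
#' reference variability measure against which the single-draw indices are
#' screened.
#'
#' @param trace A [glucose_trace()].
#' @param ddof Delta degrees of freedom: 1 = sample SD (default),
#'   0 = population SD.
#' @return SD in the trace's glucose unit.
#' @export
glycaemic_sd <- function(trace, ddof = 1) {
  v <- trace_values(trace)
  if (length(v) < 2) stop("glycaemic_sd: need >= 2 non-missing values")
  s <- stats::sd(v)
  if (ddof == 0) s <- s * sqrt((length(v) - 1) / length(v))
  s
}

#' Percent coefficient of variation
#'
#' `100 * SD / mean`; dimensionless, hence invariant to unit conversion.
#'
#' @inheritParams glycaemic_sd
#' @return %CV.
#' @export
percent_cv <- function(trace, ddof = 1) {
  m <- mean(trace_values(trace))
  if (m <= 0) stop("percent_cv: mean glucose must be positive")
  100 * glycaemic_sd(trace, ddof) / m
}

#' Glucose range
#'
#' Difference between the highest and lowest glucose values.
#'
#' @inheritParams glycaemic_sd
#' @return Range in the trace's glucose unit.
#' @export
glucose_range <- function(trace) {
  v <- trace_values(trace)
  if (!length(v)) stop("glucose_range: no non-missing values")
  max(v) - min(v)
}

#' Interquartile range
#'
#' 75th minus 25th percentile, using linear interpolation between closest
#' ranks (R quantile type 7); the convention is stated because IQR differs
#' across percentile definitions.
#'
#' @inheritParams glycaemic_sd
#' @return IQR in the trace's glucose unit.
#' @export
interquartile_range <- function(trace) {
  v <- trace_values(trace)
  if (length(v) < 4) stop("interquartile_range: need >= 4 non-missing values")
  q <- stats::quantile(v, c(0.25, 0.75), names = FALSE, type = 7)
  q[2] - q[1]
}

#' J-index
#'
#' `0.001 * (mean + SD)^2`, combining level and dispersion. The formula is
#' historically mg/dl-based; values are converted internally
#' (configurable via [metric_config()]).
#'
#' @inheritParams glycaemic_sd
#' @param config A [metric_config()].
#' @return Dimensionless J-index.
#' @export
j_index <- function(trace, config = metric_config()) {
  tr <- convert_units(trace, config$j_index_unit)
  v <- trace_values(tr)
  if (length(v) < 2) stop("j_index: need >= 2 non-missing values")
  0.001 * (mean(v) + glycaemic_sd(tr, config$sd_ddof))^2
}

#' M-value (M_R)
#'
#' Mean over samples of `|10 * log10(glucose / R)|^3`, penalising
#' dissociation from the ideal glucose `R` (default 5.6 mmol/l = 100
#' mg/dl). Invariant to converting glucose and `R` together. The plain
#' form is used by default; `m_value_correction` in [metric_config()] adds
#' the historical amplitude term `range / 20` (computed on mg/dl).
#'
#' @inheritParams j_index
#' @param R Ideal glucose in the same unit as the trace; defaults to the
#'   configured `ideal_glucose_R` converted to the trace's unit.
#' @return Dimensionless M-value (0 when the trace sits exactly at `R`).
#' @export
m_value <- function(trace, R = NULL, config = metric_config()) {
  if (is.null(R)) {
    R <- config$ideal_glucose_R
    if (trace$unit == "mg_per_dl") R <- R * MGDL_PER_MMOL
  }
  if (R <= 0) stop("m_value: R must be positive")
  v <- trace_values(trace)
  if (!length(v)) stop("m_value: no non-missing values")
  m <- mean(abs(10 * log10(v / R))^3)
  if (config$m_value_correction) {
    rng <- glucose_range(convert_units(trace, "mg_per_dl"))
    m <- m + rng / 20
  }
  m
}

#' Index of glycaemic control (IGC)
#'
#' Sum of the hyperglycaemic and hypoglycaemic indices: power sums of the
#' excess above the hyperglycaemia threshold (default 7.8 mmol/l) and the
#' shortfall below the hypoglycaemia threshold (default 4.4 mmol/l),
#' normalised by sample count and scale constants. Comparisons are strict:
#' samples exactly at a threshold contribute zero. Evaluated on mg/dl by
#' default (the scale on which the constants a = 1.1, b = 2, c = d = 30
#' were defined).
#'
#' @inheritParams j_index
#' @return A list with `igc`, `hyper_index` and `hypo_index`
#'   (all `>= 0`, `igc = hyper_index + hypo_index`).
#' @export
igc <- function(trace, config = metric_config()) {
  tr <- convert_units(trace, config$igc_unit)
  ultr <- config$hyper_threshold
  lltr <- config$hypo_threshold
  if (config$igc_unit == "mg_per_dl") {
    ultr <- ultr * MGDL_PER_MMOL
    lltr <- lltr * MGDL_PER_MMOL
  }
  v <- trace_values(tr)
  n <- length(v)
  if (!n) stop("igc: no non-missing values")
  hyper <- sum((v[v > ultr] - ultr)^config$igc_hyper_exponent) /
    (n * config$igc_hyper_scale)
  hypo <- sum((lltr - v[v < lltr])^config$igc_hypo_exponent) /
    (n * config$igc_hypo_scale)
  list(igc = hyper + hypo, hyper_index = hyper, hypo_index = hypo)
}

# centred moving average with shrinking edge windows
moving_average <- function(v, width) {
  h <- (width - 1) %/% 2
  n <- length(v)
  vapply(seq_len(n), function(i) mean(v[max(1, i - h):min(n, i + h)]), 0)
}

# Turning-point scan for MAGE.
# 1. collapse plateaus (runs of equal values keep their first sample);
# 2. interior turning points = sign changes of successive differences;
#    if fewer than 2 interior points exist, the first and last samples are
#    used as excursion termini (so a single step or ramp still counts);
# 3. oscillations smaller than the threshold are pruned: repeatedly take
#    the (leftmost) adjacent extremum pair with the smallest amplitude;
#    while that amplitude < threshold, delete the pair, after absorbing
#    each deleted extremum into its surviving same-type neighbour (keep
#    the more extreme value) when one exists.
# Returns indices into v of the surviving alternating extrema.
mage_extrema <- function(v, threshold) {
  keep <- c(TRUE, diff(v) != 0)
  idx <- which(keep)
  w <- v[idx]
  m <- length(w)
  if (m < 2) return(integer(0))
  d <- sign(diff(w))
  interior <- which(d[-length(d)] != d[-1]) + 1L
  ext <- if (length(interior) >= 2) interior else
    unique(c(1L, interior, m))
  repeat {
    k <- length(ext)
    if (k < 3) break
    a <- abs(diff(w[ext]))
    i <- which.min(a)            # leftmost smallest adjacent amplitude
    if (a[i] >= threshold) break
    j <- i + 1L
    j_is_max <- w[ext[j]] > w[ext[i]]
    if (i - 1L >= 1L) {          # ext[i-1] has ext[j]'s type
      cand <- c(ext[i - 1L], ext[j])
      ext[i - 1L] <- if (j_is_max) cand[which.max(w[cand])] else
        cand[which.min(w[cand])]
    }
    if (j + 1L <= k) {           # ext[j+1] has ext[i]'s type
      cand <- c(ext[i], ext[j + 1L])
      ext[j + 1L] <- if (j_is_max) cand[which.min(w[cand])] else
        cand[which.max(w[cand])]
    }
    ext <- ext[-c(i, j)]
  }
  idx[ext]
}

#' Mean amplitude of glycaemic excursions (MAGE)
#'
#' Average amplitude of glucose excursions (nadir-to-peak or
#' peak-to-nadir) whose amplitude exceeds 1 x the window SD, counted in
#' the direction (ascending or descending) set by the first qualifying
#' excursion — the classic Service convention. Turning points come from a
#' local-extremum scan with small-oscillation pruning (see the package
#' vignette for the exact algorithm); optional pre-smoothing via
#' `mage_smoothing` in [metric_config()].
#'
#' @inheritParams j_index
#' @return MAGE in the trace's glucose unit, with attributes
#'   `n_excursions` and `direction`. When no excursion exceeds 1 SD the
#'   value is `NA` with attribute `no_excursion = TRUE` (a flagged result,
#'   not an error).
#' @export
mage <- function(trace, config = metric_config()) {
  v <- trace_values(trace)
  if (length(v) < 3) stop("mage: need >= 3 non-missing samples")
  s <- glycaemic_sd(trace, config$sd_ddof)
  if (config$mage_smoothing > 1) v <- moving_average(v, config$mage_smoothing)
  no_exc <- structure(NA_real_, no_excursion = TRUE, n_excursions = 0L,
                      direction = NA_character_)
  if (s == 0) return(no_exc)
  ext <- mage_extrema(v, threshold = s)
  if (length(ext) < 2) return(no_exc)
  amps <- diff(v[ext])
  qual <- abs(amps) > s
  if (!any(qual)) return(no_exc)
  dir_sign <- sign(amps[which(qual)[1]])
  use <- qual & sign(amps) == dir_sign
  structure(mean(abs(amps[use])),
            no_excursion = FALSE, n_excursions = sum(use),
            direction = if (dir_sign > 0) "ascending" else "descending")
}

#' Mean of daily differences (MODD)
#'
#' Mean absolute difference between glucose values taken at the same clock
#' time on two consecutive days; requires a trace covering at least 48 h.
#' Pairs with either member missing are dropped.
#'
#' @inheritParams glycaemic_sd
#' @return MODD in the trace's glucose unit.
#' @export
modd <- function(trace) {
  steps <- as.integer(round(24 * 60 / trace$interval))
  n <- length(trace$values)
  if (n < 2 * steps)
    stop("modd: trace must cover at least 48 h (two aligned 24-h days)")
  v <- trace$values
  d <- abs(v[seq_len(n - steps) + steps] - v[seq_len(n - steps)])
  d <- d[!is.na(d)]
  if (!length(d)) stop("modd: no complete 24-h-apart pairs")
  mean(d)
}

#' Continuous overlapping net glycaemic action (CONGA)
#'
#' `conga_n()` is the SD of differences between values obtained exactly
#' `n_hours` apart; [conga_1_24()] averages `conga_n` over all integer
#' lags 1..24 h.
#'
#' @inheritParams glycaemic_sd
#' @param n_hours Lag in whole hours.
#' @return SD of the lagged differences, in the trace's glucose unit.
#' @export
conga_n <- function(trace, n_hours, ddof = 1) {
  k <- as.integer(round(n_hours * 60 / trace$interval))
  n <- length(trace$values)
  if (k < 1 || k >= n)
    stop(sprintf("conga_n: trace too short for a %g-h lag", n_hours))
  v <- trace$values
  d <- v[seq_len(n - k) + k] - v[seq_len(n - k)]
  d <- d[!is.na(d)]
  if (length(d) < 2) stop("conga_n: fewer than 2 complete lagged pairs")
  s <- stats::sd(d)
  if (ddof == 0) s <- s * sqrt((length(d) - 1) / length(d))
  s
}

#' @rdname conga_n
#' @param config A [metric_config()]; `conga_max_lag_hours` sets the last
#'   lag (default 24, i.e. the mean of exactly 24 `conga_n` values).
#' @export
conga_1_24 <- function(trace, config = metric_config()) {
  lags <- seq_len(config$conga_max_lag_hours)
  mean(vapply(lags, function(h) conga_n(trace, h, config$sd_ddof), 0))
}

#' Compute the full variability profile of a trace
#'
#' Runs every metric of the suite on one trace and returns them as a
#' single row. If the recording extends beyond `window_hours` past its
#' first midnight, the standard analysis window is selected first
#' (see [select_analysis_window()]); otherwise the trace is used as is.
#' Metrics whose preconditions the trace cannot meet (MODD and CONGA on
#' sub-48-h traces) are `NA`.
#'
#' @inheritParams j_index
#' @param window_hours Analysis window length for raw recordings
#'   (default 48).
#' @param auto_window Attempt window selection when the recording covers
#'   it (default `TRUE`).
#' @return A one-row [tibble::tibble()] with `subject_id`, `n_samples`,
#'   `completeness`, `mean_glucose`, `sd`, `percent_cv`, `range`, `iqr`,
#'   `j_index`, `mage`, `mage_excursions`, `m_value`, `igc`,
#'   `hyper_index`, `hypo_index`, `modd`, `conga_1_24` and the per-lag
#'   CONGA values as a list column `conga`.
#' @export
compute_profile <- function(trace, config = metric_config(),
                            window_hours = 48, auto_window = TRUE) {
  if (auto_window) {
    tr <- tryCatch(select_analysis_window(trace, window_hours),
                   error = function(e) trace)
  } else tr <- trace
  comp <- trace_completeness(tr)
  if (comp < config$min_completeness)
    stop(sprintf("compute_profile [%s]: completeness %.2f below minimum %.2f",
                 tr$subject_id, comp, config$min_completeness))
  wrap <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("compute_profile [%s]: %s", name, conditionMessage(e))))
  }
  n <- length(tr$values)
  steps_day <- as.integer(round(24 * 60 / tr$interval))
  g <- igc(tr, config)
  mg <- wrap("mage", mage(tr, config))
  can_modd <- n >= 2 * steps_day
  can_conga <- n > as.integer(round(config$conga_max_lag_hours * 60 / tr$interval)) + 1
  congas <- if (can_conga)
    vapply(seq_len(config$conga_max_lag_hours),
           function(h) conga_n(tr, h, config$sd_ddof), 0)
  else rep(NA_real_, config$conga_max_lag_hours)
  tibble::tibble(
    subject_id = tr$subject_id,
    n_samples = n,
    completeness = comp,
    mean_glucose = mean(trace_values(tr)),
    sd = wrap("sd", glycaemic_sd(tr, config$sd_ddof)),
    percent_cv = wrap("percent_cv", percent_cv(tr, config$sd_ddof)),
    range = wrap("range", glucose_range(tr)),
    iqr = wrap("iqr", interquartile_range(tr)),
    j_index = wrap("j_index", j_index(tr, config)),
    mage = as.numeric(mg),
    mage_excursions = attr(mg, "n_excursions"),
    m_value = wrap("m_value", m_value(tr, config = config)),
    igc = g$igc,
    hyper_index = g$hyper_index,
    hypo_index = g$hypo_index,
    modd = if (can_modd) wrap("modd", modd(tr)) else NA_real_,
    conga_1_24 = if (can_conga) mean(congas) else NA_real_,
    conga = list(congas)
  )
}
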