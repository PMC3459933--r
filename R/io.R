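#' Read CGM traces from CSV
#'
#' Canonical dialect: columns `timestamp` (ISO-8601), `glucose`, optional
#' `unit` and `subject_id` (long format, one trace per subject). Device
#' dialect (`dialect = "device"`): separate `date` (`MM/DD/YY`) and
#' `time` (`HH:MM:SS`) columns. Timestamps must lie on a regular grid:
#' gaps that are exact multiples of the sampling interval become missing
#' samples; any other spacing is a dialect error naming the offending
#' rows. No resampling or imputation is ever performed.
#'
#' @param path CSV file path.
#' @param unit Glucose unit when the file has no `unit` column
#'   (default `"mmol_per_l"`).
#' @param dialect `"canonical"` or `"device"`.
#' @param interval Expected sampling interval in minutes; `NULL` infers
#'   it as the smallest observed spacing.
#' @return A single [glucose_trace()] or, for long-format files, a named
#'   list of them.
#' @export
read_cgm_csv <- function(path, unit = "mmol_per_l",
                         dialect = c("canonical", "device"),
                         interval = NULL) {
  dialect <- match.arg(dialect)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (dialect == "device") {
    if (!all(c("date", "time") %in% names(df)))
      stop("read_cgm_csv: device dialect needs 'date' and 'time' columns in ", path)
    df$timestamp <- as.POSIXct(paste(df$date, df$time),
                               format = "%m/%d/%y %H:%M:%S", tz = "UTC")
  } else {
    if (!"timestamp" %in% names(df))
      stop("read_cgm_csv: missing 'timestamp' column in ", path)
    df$timestamp <- as.POSIXct(df$timestamp, tz = "UTC")
  }
  if (!"glucose" %in% names(df))
    stop("read_cgm_csv: missing 'glucose' column in ", path)
  if (anyNA(df$timestamp))
    stop(sprintf("read_cgm_csv: unparseable timestamp at row(s) %s of %s",
                 paste(utils::head(which(is.na(df$timestamp)), 5), collapse = ", "),
                 path))
  if ("unit" %in% names(df)) {
    u <- unique(df$unit)
    if (length(u) != 1) stop("read_cgm_csv: mixed units in ", path)
    unit <- u
  }
  unit <- match.arg(unit, c("mmol_per_l", "mg_per_dl"))
  build <- function(sub, id) {
    sub <- sub[order(sub$timestamp), ]
    if (nrow(sub) < 2) stop("read_cgm_csv: subject ", id, " has < 2 samples")
    dmin <- as.numeric(diff(sub$timestamp), units = "mins")
    iv <- if (is.null(interval)) min(dmin) else interval
    steps <- dmin / iv
    bad <- which(abs(steps - round(steps)) > 1e-6 | steps < 1 - 1e-6)
    if (length(bad))
      stop(sprintf(
        "read_cgm_csv: irregular timestamp spacing (not a multiple of %g min) after row(s) %s of %s",
        iv, paste(utils::head(bad, 5), collapse = ", "), path))
    n <- as.integer(round(sum(round(steps)))) + 1L
    values <- rep(NA_real_, n)
    values[cumsum(c(1L, as.integer(round(steps))))] <- sub$glucose
    glucose_trace(values, start = sub$timestamp[1], interval = iv,
                  unit = unit, subject_id = id)
  }
  if ("subject_id" %in% names(df)) {
    out <- lapply(split(df, df$subject_id), function(s)
      build(s, s$subject_id[1]))
    if (length(out) == 1) out[[1]] else out
  } else {
    build(df, sub("[.][^.]*$", "", basename(path)))
  }
}

#' Write a trace to canonical CGM CSV
#' @param trace A [glucose_trace()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cgm_csv <- function(trace, path) {
  keep <- !trace$missing_mask
  utils::write.csv(
    data.frame(subject_id = trace$subject_id,
               timestamp = format(trace_times(trace)[keep], "%Y-%m-%d %H:%M:%S"),
               glucose = trace$values[keep],
               unit = trace$unit),
    path, row.names = FALSE)
  invisible(path)
}

# short stable fingerprint of a config object, for report provenance
config_fingerprint <- function(config) {
  flat <- unlist(config, use.names = TRUE)
  flat <- flat[order(names(flat))]
  fnv1a32(paste(names(flat), flat, sep = "=", collapse = ";"))
}

#' Read a cohort table from CSV
#'
#' Expected columns include `subject_id`, `ga_percent`, `hba1c_value`,
#' `hba1c_standard`, `fpg_mmol_l`, `fcpr_nmol_l`, `fcpr_below_limit` and
#' covariates. HbA1c is converted to NGSP %, FCPR floored at the
#' detection limit, and the two single-draw indices derived.
#'
#' @param path CSV file path.
#' @return A [tibble::tibble()] with derived `hba1c_ngsp`,
#'   `ga_a1c_ratio` and `fcpr_index` columns.
#' @export
read_cohort_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "ga_percent", "hba1c_value", "hba1c_standard",
            "fpg_mmol_l", "fcpr_nmol_l")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("read_cohort_csv: missing column(s) ", paste(miss, collapse = ", "),
         " in ", path)
  if (!nrow(df)) stop("read_cohort_csv: empty cohort in ", path)
  if (anyDuplicated(df$subject_id))
    stop("read_cohort_csv: duplicated subject_id in ", path)
  for (col in c("ga_percent", "fpg_mmol_l")) {
    bad <- which(!is.finite(df[[col]]) | df[[col]] <= 0)
    if (length(bad))
      stop(sprintf("read_cohort_csv: non-positive %s at row(s) %s of %s",
                   col, paste(utils::head(bad, 5), collapse = ", "), path))
  }
  if (!"fcpr_below_limit" %in% names(df)) df$fcpr_below_limit <- FALSE
  fl <- Map(floor_fcpr, df$fcpr_nmol_l, as.logical(df$fcpr_below_limit))
  df$fcpr_nmol_l <- vapply(fl, `[[`, 0, "fcpr")
  df$fcpr_below_limit <- vapply(fl, `[[`, TRUE, "below_limit")
  df$hba1c_ngsp <- mapply(convert_hba1c, df$hba1c_value, df$hba1c_standard,
                          MoreArgs = list(to = "ngsp_percent"))
  df$ga_a1c_ratio <- ga_a1c_ratio(df$ga_percent, df$hba1c_ngsp)
  df$fcpr_index <- fcpr_index(df$fcpr_nmol_l, df$fpg_mmol_l)
  tibble::as_tibble(df)
}

#' Write the per-subject variability profile table
#'
#' One row per subject with every profile field, completeness and the
#' metric-config fingerprint, so the conventions behind each number are
#' auditable from the file alone.
#'
#' @param profiles A tibble of [compute_profile()] rows (list columns are
#'   dropped) or a `cgm_cohort`.
#' @param path Output path (`.tsv` or `.csv` by extension).
#' @param config The [metric_config()] used.
#' @return `path`, invisibly.
#' @export
write_profile_table <- function(profiles, path, config = metric_config()) {
  if (inherits(profiles, "cgm_cohort")) profiles <- profiles$cohort
  profiles <- profiles[, !vapply(profiles, is.list, TRUE)]
  profiles$config_fingerprint <- config_fingerprint(config)
  sep <- if (grepl("[.]tsv$", path)) "\t" else ","
  utils::write.table(profiles, path, sep = sep, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Write an analysis report as JSON
#'
#' Serialises pipeline results together with the seed, config
#' fingerprints and the method conventions in force (SD ddof, MAGE
#' turning-point convention, IGC constants, HbA1c harmonisation), so
#' every numerical choice is auditable from the output.
#'
#' @param results A named list of results (coerced via
#'   [jsonlite::toJSON()] rules; `lm` fits and traces should be removed
#'   first).
#' @param path Output `.json` path.
#' @param metric_cfg,seed Provenance fields.
#' @return `path`, invisibly.
#' @export
write_report <- function(results, path, metric_cfg = metric_config(),
                         seed = NULL) {
  payload <- list(
    methods = list(
      sd_ddof = metric_cfg$sd_ddof,
      percentile_rule = "linear interpolation between closest ranks (type 7)",
      mage = "interior turning points, small-oscillation pruning at 1 SD, direction of first qualifying excursion",
      igc_constants = list(a = metric_cfg$igc_hyper_exponent,
                           b = metric_cfg$igc_hypo_exponent,
                           c = metric_cfg$igc_hyper_scale,
                           d = metric_cfg$igc_hypo_scale,
                           unit = metric_cfg$igc_unit),
      m_value_correction = metric_cfg$m_value_correction,
      hba1c_harmonisation = "NGSP% = JDS% + 0.4; IFCC = 10.93 x NGSP% - 23.50",
      multiple_testing = "none; p-values are raw"),
    config_fingerprint = config_fingerprint(metric_cfg),
    seed = seed,
    results = results)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  invisible(path)
}

#' Read and validate a run configuration file
#'
#' A single YAML (or JSON) file holding `metric`, `generator` and
#' `analysis` sections plus `seed`, `paths` and `log_level`. Unknown
#' top-level or section keys are rejected by name — no silent defaults
#' for typos.
#'
#' @param path YAML/JSON config path.
#' @return A list with `metric` ([metric_config()]), `generator`
#'   ([generator_config()]), `analysis` (list), `paths`, `seed`,
#'   `log_level`.
#' @export
read_run_config <- function(path) {
  raw <- if (grepl("[.]json$", path)) jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  known <- c("metric", "generator", "analysis", "paths", "seed", "log_level")
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop("read_run_config: unknown key(s): ", paste(unknown, collapse = ", "))
  check_args <- function(sub, fn, name) {
    if (is.null(sub)) return(list())
    bad <- setdiff(names(sub), names(formals(fn)))
    if (length(bad))
      stop("read_run_config: unknown ", name, " key(s): ",
           paste(bad, collapse = ", "))
    sub
  }
  metric <- do.call(metric_config, check_args(raw$metric, metric_config, "metric"))
  gen_args <- check_args(raw$generator, generator_config, "generator")
  if (!is.null(raw$seed) && is.null(gen_args$seed)) gen_args$seed <- raw$seed
  list(metric = metric,
       generator = do.call(generator_config, gen_args),
       analysis = if (is.null(raw$analysis)) list() else raw$analysis,
       paths = raw$paths,
       seed = raw$seed,
       log_level = if (is.null(raw$log_level)) "info" else raw$log_level)
}
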