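#' Floor fasting C-peptide at the assay detection limit
#'
#' Values below the detection limit of the C-peptide immunoassay (0.001
#' nmol/l), or samples flagged as below-limit, are replaced by the
#' approximate value 0.001 nmol/l with a provenance flag.
#'
#' @param raw FCPR in nmol/l (`NA` allowed only when `below_limit` is
#'   `TRUE`).
#' @param below_limit Logical: was the measurement reported as below the
#'   assay limit?
#' @param limit Detection limit in nmol/l (default 0.001).
#' @return A list with `fcpr` (nmol/l) and `below_limit` (logical flag,
#'   `TRUE` whenever the stored value is the floored limit).
#' @export
floor_fcpr <- function(raw, below_limit = FALSE, limit = 0.001) {
  if (isTRUE(below_limit) || (!is.na(raw) && raw < limit))
    return(list(fcpr = limit, below_limit = TRUE))
  if (is.na(raw) || raw < 0) stop("floor_fcpr: need a non-negative FCPR or a below-limit flag")
  list(fcpr = raw, below_limit = FALSE)
}

#' Glycated albumin to HbA1c ratio
#'
#' GA (%) divided by HbA1c in NGSP percent. Elevated ratios indicate
#' recent and/or fluctuating hyperglycaemia (GA glycates an order of
#' magnitude faster than haemoglobin).
#'
#' @param ga_percent Glycated albumin, %.
#' @param hba1c_ngsp_percent HbA1c, NGSP %.
#' @return Dimensionless ratio.
#' @export
ga_a1c_ratio <- function(ga_percent, hba1c_ngsp_percent) {
  if (any(ga_percent <= 0) || any(hba1c_ngsp_percent <= 0))
    stop("ga_a1c_ratio: GA and HbA1c must be positive")
  ga_percent / hba1c_ngsp_percent
}

#' Fasting C-peptide index
#'
#' FCPR (nmol/l) over fasting plasma glucose (mmol/l) times 100 — a basal
#' beta-cell function index. The nmol/l-over-mmol/l pairing is fixed; the
#' ng/ml-over-mg/dl variant found elsewhere in the literature is
#' deliberately not used.
#'
#' @param fcpr FCPR in nmol/l (floored, see [floor_fcpr()]).
#' @param fpg Fasting plasma glucose in mmol/l.
#' @return Dimensionless index (`FCPR / FPG * 100`).
#' @export
fcpr_index <- function(fcpr, fpg) {
  if (any(fpg <= 0)) stop("fcpr_index: FPG must be positive")
  if (any(fcpr < 0)) stop("fcpr_index: FCPR must be non-negative")
  fcpr / fpg * 100
}

#' Convert HbA1c between reporting standards
#'
#' Supported standards: `"jds_percent"` (Japan Diabetes Society %),
#' `"ngsp_percent"` (NGSP %), `"ifcc_mmol_mol"` (IFCC mmol/mol).
#' Conversions use the harmonisation constants
#' `NGSP% = JDS% + 0.4` and `IFCC = 10.93 x NGSP% - 23.50`; they are
#' exactly invertible.
#'
#' @param value HbA1c value(s) in the `from` standard.
#' @param from,to Standard names as above.
#' @return Value(s) in the `to` standard.
#' @export
#' @examples
#' convert_hba1c(8.9, "ngsp_percent", "ifcc_mmol_mol") # ~73.8
convert_hba1c <- function(value, from, to) {
  stds <- c("jds_percent", "ngsp_percent", "ifcc_mmol_mol")
  from <- match.arg(from, stds)
  to <- match.arg(to, stds)
  rng <- if (from == "ifcc_mmol_mol") c(9, 200) else c(3, 20)
  if (any(value < rng[1] | value > rng[2]))
    stop(sprintf("convert_hba1c: value outside plausible %s range [%g, %g]",
                 from, rng[1], rng[2]))
  ngsp <- switch(from,
                 jds_percent = value + 0.4,
                 ngsp_percent = value,
                 ifcc_mmol_mol = (value + 23.50) / 10.93)
  switch(to,
         jds_percent = ngsp - 0.4,
         ngsp_percent = ngsp,
         ifcc_mmol_mol = 10.93 * ngsp - 23.50)
}

#' Classify a subject into a predicted variability-risk group
#'
#' High predicted variability requires *both* GA/A1c ratio at or above the
#' ratio cutoff and FCPR index below the index cutoff; low predicted
#' variability requires both reversed; anything else is indeterminate.
#' Boundary handling follows the printed inequalities: ratio exactly at
#' the cutoff is high-side (>=), index exactly at the cutoff is low-side
#' (<).
#'
#' @param ratio GA/A1c ratio(s).
#' @param index FCPR index value(s).
#' @param ratio_cutoff,index_cutoff Operating cutoffs (defaults 2.8 and
#'   3.0).
#' @return A list with `group` (character vector:
#'   `"high_variability"`, `"low_variability"` or `"indeterminate"`),
#'   the inputs and the cutoffs used.
#' @export
classify_risk <- function(ratio, index, ratio_cutoff = 2.8, index_cutoff = 3.0) {
  if (any(!is.finite(ratio)) || any(!is.finite(index)))
    stop("classify_risk: inputs must be finite")
  group <- ifelse(ratio >= ratio_cutoff & index < index_cutoff, "high_variability",
           ifelse(ratio < ratio_cutoff & index >= index_cutoff, "low_variability",
                  "indeterminate"))
  list(group = group, ga_a1c_ratio = ratio, fcpr_index = index,
       ratio_cutoff = ratio_cutoff, index_cutoff = index_cutoff)
}
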