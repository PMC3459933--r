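# code a 2-level factor/character/logical column as 0/1 for correlation
code_binary <- function(x) {
  if (is.numeric(x)) return(x)
  if (is.logical(x)) return(as.numeric(x))
  lv <- sort(unique(as.character(x)))
  if (length(lv) != 2) return(NULL)
  as.numeric(as.character(x) == lv[2])
}

#' Univariate screening against glycaemic SD
#'
#' Pearson correlation (point-biserial for 0/1-coded binary factors) of
#' each candidate factor with the response, with two-sided p-values —
#' the univariate stage of the published analysis chain. No
#' multiple-testing correction is applied (none was in the source
#' analysis); p-values are raw.
#'
#' @param table Cohort table.
#' @param response Response column name (default `"sd"`).
#' @param factors Character vector of factor columns; default: every
#'   numeric or binary column except the response and `subject_id`.
#' @return A [tibble::tibble()] with `factor`, `n`, `r`, `p_value`.
#' @export
univariate_screen <- function(table, response = "sd", factors = NULL) {
  if (is.null(table[[response]]))
    stop("univariate_screen: response column not found")
  if (is.null(factors)) {
    factors <- setdiff(names(table), c(response, "subject_id"))
    factors <- factors[vapply(factors, function(f)
      !is.null(code_binary(table[[f]])), TRUE)]
  }
  y <- table[[response]]
  rows <- lapply(factors, function(f) {
    x <- code_binary(table[[f]])
    if (is.null(x)) stop("univariate_screen: column '", f,
                         "' is neither numeric nor binary")
    ok <- stats::complete.cases(x, y)
    ct <- stats::cor.test(x[ok], y[ok])
    tibble::tibble(factor = f, n = sum(ok),
                   r = unname(ct$estimate), p_value = ct$p.value)
  })
  do.call(rbind, rows)
}

# R^2 computed directly (summary.lm warns on perfect fits)
lm_r2 <- function(fit, y) 1 - sum(stats::residuals(fit)^2) / sum((y - mean(y))^2)

# partial F-test p-value for adding `term` to the model with `base` terms
partial_f <- function(df, response, base, term) {
  f0 <- if (length(base))
    stats::as.formula(paste(response, "~", paste(base, collapse = "+")))
  else stats::as.formula(paste(response, "~ 1"))
  f1 <- stats::as.formula(paste(response, "~",
                                paste(c(base, term), collapse = "+")))
  m0 <- stats::lm(f0, data = df)
  m1 <- stats::lm(f1, data = df)
  rss0 <- sum(stats::residuals(m0)^2)
  rss1 <- sum(stats::residuals(m1)^2)
  df1 <- m1$df.residual
  if (rss1 <= .Machine$double.eps * rss0)
    return(c(F = Inf, p = 0))
  Fv <- (rss0 - rss1) / (rss1 / df1)
  c(F = Fv, p = stats::pf(Fv, 1, df1, lower.tail = FALSE))
}

#' Stepwise multiple linear regression
#'
#' Forward selection with backward elimination on partial F-statistics:
#' at each step the candidate with the smallest entry p-value joins the
#' model if below `p_enter`, then any retained term whose removal
#' p-value exceeds `p_remove` is dropped (worst first). Reports, per
#' retained factor, the model R-squared at its entry step, the
#' standardized coefficient, partial F and p-value in the final model.
#'
#' @param table Cohort table.
#' @param response Response column name.
#' @param candidates Candidate factor columns (numeric or binary; binary
#'   factors are 0/1-coded).
#' @param p_enter,p_remove Entry and removal thresholds (defaults 0.05
#'   and 0.10; `p_remove >= p_enter` avoids cycling).
#' @return A list of class `stepwise_result`: `selected`, `table`
#'   (tibble: term, entry_r2, beta, beta_std, F, p_value), `r_squared`
#'   of the final model, `model` (the `lm` fit, `NULL` if nothing
#'   entered).
#' @export
stepwise_regression <- function(table, response, candidates,
                                p_enter = 0.05, p_remove = 0.10) {
  df <- as.data.frame(table)[, c(response, candidates)]
  for (cn in candidates) {
    coded <- code_binary(df[[cn]])
    if (is.null(coded)) stop("stepwise_regression: column '", cn,
                             "' is neither numeric nor binary")
    df[[cn]] <- coded
  }
  df <- df[stats::complete.cases(df), ]
  if (nrow(df) <= length(candidates) + 2)
    stop("stepwise_regression: need n > number of candidates + 2")
  selected <- character(0)
  entry_r2 <- numeric(0)
  for (iter in seq_len(100)) {
    changed <- FALSE
    remaining <- setdiff(candidates, selected)
    if (length(remaining)) {
      ps <- vapply(remaining, function(cd)
        partial_f(df, response, selected, cd)[["p"]], 0)
      if (min(ps) < p_enter) {
        term <- remaining[which.min(ps)]
        selected <- c(selected, term)
        fit <- stats::lm(stats::as.formula(
          paste(response, "~", paste(selected, collapse = "+"))), data = df)
        entry_r2 <- c(entry_r2,
                      stats::setNames(lm_r2(fit, df[[response]]), term))
        changed <- TRUE
      }
    }
    repeat {
      if (!length(selected)) break
      ps <- vapply(selected, function(tm)
        partial_f(df, response, setdiff(selected, tm), tm)[["p"]], 0)
      if (max(ps) > p_remove) {
        drop <- selected[which.max(ps)]
        selected <- setdiff(selected, drop)
        entry_r2 <- entry_r2[names(entry_r2) != drop]
        changed <- TRUE
      } else break
    }
    if (!changed) break
  }
  if (!length(selected)) {
    return(structure(list(selected = character(0),
                          table = tibble::tibble(term = character(0),
                                                 entry_r2 = numeric(0),
                                                 beta = numeric(0),
                                                 beta_std = numeric(0),
                                                 F = numeric(0),
                                                 p_value = numeric(0)),
                          r_squared = 0, model = NULL),
                     class = "stepwise_result"))
  }
  fit <- stats::lm(stats::as.formula(
    paste(response, "~", paste(selected, collapse = "+"))), data = df)
  sy <- stats::sd(df[[response]])
  stats_tab <- do.call(rbind, lapply(selected, function(tm) {
    fp <- partial_f(df, response, setdiff(selected, tm), tm)
    tibble::tibble(term = tm,
                   entry_r2 = unname(entry_r2[tm]),
                   beta = unname(stats::coef(fit)[tm]),
                   beta_std = unname(stats::coef(fit)[tm]) *
                     stats::sd(df[[tm]]) / sy,
                   F = fp[["F"]], p_value = fp[["p"]])
  }))
  structure(list(selected = selected, table = stats_tab,
                 r_squared = lm_r2(fit, df[[response]]), model = fit),
            class = "stepwise_result")
}

#' @export
print.stepwise_result <- function(x, ...) {
  cat(sprintf("<stepwise_result> %d term(s) retained, R^2 = %.3f\n",
              length(x$selected), x$r_squared))
  if (length(x$selected)) print(x$table)
  invisible(x)
}

#' Compare baseline characteristics between two groups
#'
#' Mirrors the standard cohort-characteristics table: chi-squared tests
#' for categorical variables, unpaired equal-variance two-sided t-tests
#' for continuous ones. A contingency table with a zero margin falls
#' back to Fisher's exact test with a note.
#'
#' @param table Cohort table.
#' @param group_column Name of a two-level grouping column.
#' @param variables Columns to compare; default: all except the group
#'   column and `subject_id`.
#' @return A [tibble::tibble()]: `variable`, `test`, `statistic`,
#'   `p_value`, `note`.
#' @export
group_compare <- function(table, group_column, variables = NULL) {
  g <- as.character(table[[group_column]])
  lv <- sort(unique(g))
  if (length(lv) != 2) stop("group_compare: group column must have 2 levels")
  if (any(base::table(g) < 2)) stop("group_compare: each group needs n >= 2")
  if (is.null(variables))
    variables <- setdiff(names(table), c(group_column, "subject_id"))
  rows <- lapply(variables, function(vn) {
    x <- table[[vn]]
    if (is.numeric(x)) {
      tt <- stats::t.test(x[g == lv[1]], x[g == lv[2]], var.equal = TRUE)
      tibble::tibble(variable = vn, test = "t", statistic = unname(tt$statistic),
                     p_value = tt$p.value, note = "unpaired, equal variance")
    } else {
      tab <- base::table(as.character(x), g)
      if (any(rowSums(tab) == 0) || any(colSums(tab) == 0) ||
          nrow(tab) < 2) {
        ft <- tryCatch(stats::fisher.test(tab), error = function(e) NULL)
        tibble::tibble(variable = vn, test = "fisher",
                       statistic = NA_real_,
                       p_value = if (is.null(ft)) NA_real_ else ft$p.value,
                       note = "degenerate table: exact-test fallback")
      } else {
        ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
        tibble::tibble(variable = vn, test = "chisq",
                       statistic = unname(ct$statistic),
                       p_value = ct$p.value, note = "no continuity correction")
      }
    }
  })
  do.call(rbind, rows)
}

#' Default glucose band edges
#'
#' Bands (mmol/l): <2.2 (below device range), 2.2-4.4 (hypoglycaemia),
#' 4.4-5.6, 5.6-7.8 (normoglycaemic range), 7.8-10.0, 10.0-15.6,
#' 15.6-18.8, >=18.8. Intervals are left-closed, right-open.
#'
#' @return Numeric vector of interior band edges.
#' @export
glucose_bands <- function() c(2.2, 4.4, 5.6, 7.8, 10.0, 15.6, 18.8)

#' Time distribution across glucose bands
#'
#' Fraction of (non-missing) 48-h recording time each subject spends in
#' each glucose band; fractions sum to 1 per trace.
#'
#' @param trace A [glucose_trace()] (converted to mmol/l internally).
#' @param edges Interior band edges in mmol/l (default [glucose_bands()]).
#' @return Named numeric vector of fractions, one per band.
#' @export
band_distribution <- function(trace, edges = glucose_bands()) {
  v <- trace_values(convert_units(trace, "mmol_per_l"))
  if (!length(v)) stop("band_distribution: no non-missing values")
  breaks <- c(-Inf, edges, Inf)
  lab <- c(paste0("<", edges[1]),
           paste(utils::head(edges, -1), utils::tail(edges, -1), sep = "-"),
           paste0(">=", edges[length(edges)]))
  counts <- table(cut(v, breaks = breaks, right = FALSE, labels = lab))
  stats::setNames(as.numeric(counts) / length(v), lab)
}

#' Compare per-band time fractions between two groups
#'
#' Unpaired equal-variance two-sided t-test per band on the per-subject
#' time fractions, with significance flags at 0.05 and 0.01 (raw
#' p-values, no multiplicity correction).
#'
#' @param group_a,group_b Lists of [glucose_trace()]s, or numeric
#'   matrices of per-subject band fractions (subjects in rows).
#' @param edges Interior band edges (default [glucose_bands()]).
#' @return A [tibble::tibble()]: `band`, `mean_a`, `sem_a`, `mean_b`,
#'   `sem_b`, `p_value`, `sig_05`, `sig_01`.
#' @export
compare_band_distributions <- function(group_a, group_b,
                                       edges = glucose_bands()) {
  as_mat <- function(g) {
    if (is.matrix(g)) return(g)
    do.call(rbind, lapply(g, band_distribution, edges = edges))
  }
  A <- as_mat(group_a); B <- as_mat(group_b)
  if (nrow(A) < 2 || nrow(B) < 2)
    stop("compare_band_distributions: each group needs >= 2 subjects")
  rows <- lapply(seq_len(ncol(A)), function(j) {
    p <- if (stats::sd(A[, j]) == 0 && stats::sd(B[, j]) == 0)
      NA_real_
    else stats::t.test(A[, j], B[, j], var.equal = TRUE)$p.value
    tibble::tibble(band = colnames(A)[j],
                   mean_a = mean(A[, j]), sem_a = stats::sd(A[, j]) / sqrt(nrow(A)),
                   mean_b = mean(B[, j]), sem_b = stats::sd(B[, j]) / sqrt(nrow(B)),
                   p_value = p,
                   sig_05 = !is.na(p) && p < 0.05,
                   sig_01 = !is.na(p) && p < 0.01)
  })
  do.call(rbind, rows)
}
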