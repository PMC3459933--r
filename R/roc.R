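#' ROC area under the curve with Hanley-McNeil confidence interval
#'
#' AUC is computed from mid-ranks (the Mann-Whitney statistic divided by
#' `n_pos * n_neg`), which equals the trapezoidal area over all
#' thresholds with ties counted as one half. The 95% CI uses the
#' Hanley-McNeil standard error; the p-value tests AUC = 0.5 by normal
#' approximation.
#'
#' @param scores Numeric predictor values.
#' @param labels Logical (or 0/1) outcome, `TRUE` = positive class.
#' @param direction `"greater"` if higher scores indicate the positive
#'   class (default), `"less"` for negatively oriented predictors such as
#'   the FCPR index.
#' @param conf_level Confidence level for the CI (default 0.95).
#' @return A list of class `roc_result`: `auc`, `ci95`, `se`, `p_value`,
#'   `n_pos`, `n_neg`, `direction`.
#' @export
roc_auc <- function(scores, labels, direction = c("greater", "less"),
                    conf_level = 0.95) {
  direction <- match.arg(direction)
  labels <- as.logical(labels)
  if (anyNA(scores) || anyNA(labels)) stop("roc_auc: NA in scores or labels")
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0 || n0 == 0) stop("roc_auc: both classes must be non-empty")
  s <- if (direction == "less") -scores else scores
  r <- rank(s)
  auc <- (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  q1 <- auc / (2 - auc)
  q2 <- 2 * auc^2 / (1 + auc)
  se <- sqrt((auc * (1 - auc) + (n1 - 1) * (q1 - auc^2) +
                (n0 - 1) * (q2 - auc^2)) / (n1 * n0))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  ci <- pmin(1, pmax(0, auc + c(-1, 1) * z * se))
  p <- if (se > 0) 2 * stats::pnorm(-abs((auc - 0.5) / se)) else
    as.numeric(auc == 0.5)
  structure(list(auc = auc, ci95 = ci, se = se, p_value = p,
                 n_pos = n1, n_neg = n0, direction = direction),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> AUC %.4f (95%% CI %.4f-%.4f), P = %.3g, n = %d/%d (%s)\n",
              x$auc, x$ci95[1], x$ci95[2], x$p_value, x$n_pos, x$n_neg,
              x$direction))
  invisible(x)
}

#' Operating cutoff maximising Youden's J
#'
#' Sweeps every observed score as a candidate cutoff and returns the one
#' maximising `sensitivity + specificity - 1`. Ties are broken toward the
#' more sensitive (lower oriented) cutoff. The decision rule is reported
#' explicitly: `score >= cutoff` predicts positive for
#' `direction = "greater"`, `score <= cutoff` for `direction = "less"`.
#'
#' @inheritParams roc_auc
#' @return A list: `cutoff` (original scale), `rule`, `sensitivity` and
#'   `specificity` (%), `youden_j`.
#' @export
youden_cutoff <- function(scores, labels, direction = c("greater", "less")) {
  direction <- match.arg(direction)
  labels <- as.logical(labels)
  s <- if (direction == "less") -scores else scores
  cand <- sort(unique(s))
  sens <- vapply(cand, function(c0) mean(s[labels] >= c0), 0)
  spec <- vapply(cand, function(c0) mean(s[!labels] < c0), 0)
  j <- sens + spec - 1
  best <- which(j == max(j))[1]            # leftmost = most sensitive
  cutoff <- if (direction == "less") -cand[best] else cand[best]
  list(cutoff = cutoff,
       rule = if (direction == "less") "score <= cutoff" else "score >= cutoff",
       sensitivity = 100 * sens[best], specificity = 100 * spec[best],
       youden_j = j[best])
}

#' Serial-cutoff ROC sweep over the SD dichotomisation threshold
#'
#' Reproduces the serial-cutoff procedure used to derive single-draw
#' index cutoffs: for each glycaemic-SD threshold on a grid over the
#' observed SD range, subjects are dichotomised into low/high-variability
#' classes and the AUC of the candidate index is computed; the SD
#' threshold yielding the highest AUC is retained (ties broken toward the
#' lower threshold) and the index's operating cutoff at that threshold is
#' chosen by Youden's J. Because the threshold is optimised on the same
#' data, the maximised AUC is optimistic; `n_permutations > 0` quantifies
#' this against a permutation null of the index column.
#'
#' @param table A cohort table (data frame / tibble).
#' @param index_column Name of the index column (e.g. `"ga_a1c_ratio"`).
#' @param sd_column Name of the glycaemic SD column (default `"sd"`).
#' @param direction Orientation of the index (see [roc_auc()]).
#' @param grid_step SD grid step in mmol/l (default 0.1).
#' @param sd_grid Optional explicit grid of SD thresholds.
#' @param min_class_frac Minimum fraction of subjects required on each
#'   side of a candidate SD threshold (default 0.1, at least 2 subjects):
#'   thresholds in the extreme tails dichotomise into classes too small
#'   for a stable AUC and are excluded from the sweep.
#' @param n_permutations Permutations for the optimism assessment
#'   (default 0 = off).
#' @return A list of class `cutoff_sweep`: the best `roc` result plus
#'   `sd_threshold`, `index_cutoff`, `rule`, `sensitivity`,
#'   `specificity`, the full `sweep` tibble (threshold, auc) and, when
#'   permutations were run, `null_auc`, `optimism` (mean null maximised
#'   AUC minus 0.5), `p_permutation` and `optimistic` flag.
#' @export
cutoff_sweep <- function(table, index_column, sd_column = "sd",
                         direction = c("greater", "less"),
                         grid_step = 0.1, sd_grid = NULL,
                         min_class_frac = 0.1, n_permutations = 0) {
  direction <- match.arg(direction)
  sdv <- table[[sd_column]]
  x <- table[[index_column]]
  if (is.null(sdv) || is.null(x))
    stop("cutoff_sweep: missing column(s) in table")
  if (is.null(sd_grid)) {
    sd_grid <- seq(ceiling(min(sdv) / grid_step) * grid_step,
                   floor(max(sdv) / grid_step) * grid_step, by = grid_step)
  }
  n_min <- max(2, ceiling(min_class_frac * length(sdv)))
  sd_grid <- sd_grid[vapply(sd_grid, function(t0)
    sum(sdv >= t0) >= n_min && sum(sdv < t0) >= n_min, TRUE)]
  if (!length(sd_grid))
    stop("cutoff_sweep: no SD threshold leaves at least ", n_min,
         " subjects in each class")
  max_auc <- function(xv) {
    aucs <- vapply(sd_grid, function(t0)
      roc_auc(xv, sdv >= t0, direction)$auc, 0)
    list(aucs = aucs, best = which.max(aucs))  # which.max: lowest threshold wins ties
  }
  obs <- max_auc(x)
  best_t <- sd_grid[obs$best]
  labels <- sdv >= best_t
  roc <- roc_auc(x, labels, direction)
  yj <- youden_cutoff(x, labels, direction)
  out <- list(roc = roc, sd_threshold = best_t, index_cutoff = yj$cutoff,
              rule = yj$rule, sensitivity = yj$sensitivity,
              specificity = yj$specificity,
              n_pos = roc$n_pos, n_neg = roc$n_neg,
              sweep = tibble::tibble(sd_threshold = sd_grid, auc = obs$aucs))
  if (n_permutations > 0) {
    null_auc <- vapply(seq_len(n_permutations), function(i) {
      p <- max_auc(sample(x))
      p$aucs[p$best]
    }, 0)
    out$null_auc <- null_auc
    out$optimism <- mean(null_auc) - 0.5
    out$p_permutation <- mean(null_auc >= roc$auc)
    out$optimistic <- out$optimism > 0
  }
  structure(out, class = "cutoff_sweep")
}

#' @export
print.cutoff_sweep <- function(x, ...) {
  cat(sprintf(
    "<cutoff_sweep> best AUC %.4f at SD threshold %.1f mmol/l; index cutoff %.3g (%s), sens %.0f%%, spec %.0f%%\n",
    x$roc$auc, x$sd_threshold, x$index_cutoff, x$rule,
    x$sensitivity, x$specificity))
  if (!is.null(x$optimism))
    cat(sprintf("  permutation null: mean maximised AUC %.3f (optimism +%.3f), P_perm = %.3f\n",
                0.5 + x$optimism, x$optimism, x$p_permutation))
  invisible(x)
}

#' Combined-criterion analysis of the two single-draw indices
#'
#' Classifies subjects by the joint rule (GA/A1c ratio >= `ratio_cutoff`
#' AND FCPR index < `index_cutoff` = predicted high variability; both
#' reversed = predicted low; else indeterminate), contrasts glycaemic SD
#' between the two definite groups with an unpaired equal-variance
#' t-test, and computes a combined ROC on the definite subset using the
#' number of satisfied high-risk criteria (0/1/2 — here 0 or 2 by
#' construction of the subset) as score against the SD dichotomisation at
#' `sd_threshold` (chosen by a sweep when `NULL`).
#'
#' @param table Cohort table with columns `ga_a1c_ratio`, `fcpr_index`
#'   and the SD column.
#' @param ratio_cutoff,index_cutoff Operating cutoffs (defaults 2.8, 3.0).
#' @param sd_column Glycaemic SD column name.
#' @param sd_threshold SD dichotomisation threshold for the combined ROC;
#'   `NULL` sweeps a 0.1 mmol/l grid on the definite subset.
#' @param grid_step Sweep grid step when `sd_threshold` is `NULL`.
#' @return A list: `group` (per-subject classification), `n_high`,
#'   `n_low`, `n_indeterminate`, `group_stats` (mean +/- SD of glycaemic
#'   SD per definite group), `t_test` (or `NULL` with `degenerate = TRUE`
#'   when a definite group has < 2 subjects), `roc`, `sd_threshold`.
#' @export
combined_criterion_analysis <- function(table, ratio_cutoff = 2.8,
                                        index_cutoff = 3.0,
                                        sd_column = "sd",
                                        sd_threshold = NULL,
                                        grid_step = 0.1) {
  cls <- classify_risk(table$ga_a1c_ratio, table$fcpr_index,
                       ratio_cutoff, index_cutoff)
  g <- cls$group
  sdv <- table[[sd_column]]
  hi <- sdv[g == "high_variability"]
  lo <- sdv[g == "low_variability"]
  out <- list(group = g,
              n_high = length(hi), n_low = length(lo),
              n_indeterminate = sum(g == "indeterminate"),
              ratio_cutoff = ratio_cutoff, index_cutoff = index_cutoff,
              group_stats = tibble::tibble(
                group = c("high_variability", "low_variability"),
                n = c(length(hi), length(lo)),
                sd_mean = c(mean(hi), mean(lo)),
                sd_sd = c(stats::sd(hi), stats::sd(lo))),
              degenerate = length(hi) < 2 || length(lo) < 2)
  if (out$degenerate) {
    out$t_test <- NULL
    out$roc <- NULL
    return(out)
  }
  out$t_test <- stats::t.test(hi, lo, var.equal = TRUE)
  def <- g != "indeterminate"
  score <- (table$ga_a1c_ratio[def] >= ratio_cutoff) +
    (table$fcpr_index[def] < index_cutoff)
  sdd <- sdv[def]
  if (is.null(sd_threshold)) {
    grid <- seq(ceiling(min(sdd) / grid_step) * grid_step,
                floor(max(sdd) / grid_step) * grid_step, by = grid_step)
    grid <- grid[vapply(grid, function(t0)
      any(sdd >= t0) && any(sdd < t0), TRUE)]
    aucs <- vapply(grid, function(t0)
      roc_auc(score, sdd >= t0)$auc, 0)
    sd_threshold <- grid[which.max(aucs)]
  }
  out$sd_threshold <- sd_threshold
  out$roc <- roc_auc(score, sdd >= sd_threshold)
  out
}
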