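# Independent brute-force oracles: each metric re-derived directly from its
# definition with plain loops, sharing no code with the package internals.

o_mean <- function(v) sum(v) / length(v)

o_sd <- function(v, ddof = 1) {
  m <- o_mean(v)
  sqrt(sum((v - m)^2) / (length(v) - ddof))
}

o_cv <- function(v, ddof = 1) 100 * o_sd(v, ddof) / o_mean(v)

o_range <- function(v) max(v) - min(v)

# linear interpolation between closest ranks, written out by hand
o_percentile <- function(v, p) {
  vs <- sort(v)
  h <- (length(vs) - 1) * p
  lo <- floor(h)
  vs[lo + 1] + (h - lo) * (vs[min(lo + 2, length(vs))] - vs[lo + 1])
}

o_iqr <- function(v) o_percentile(v, 0.75) - o_percentile(v, 0.25)

o_j_index <- function(v_mgdl, ddof = 1)
  0.001 * (o_mean(v_mgdl) + o_sd(v_mgdl, ddof))^2

o_m_value <- function(v, R) o_mean(abs(10 * log10(v / R))^3)

o_igc <- function(v, ultr, lltr, a = 1.1, b = 2, cc = 30, d = 30) {
  hyper <- 0; hypo <- 0
  for (x in v) {
    if (x > ultr) hyper <- hyper + (x - ultr)^a
    if (x < lltr) hypo <- hypo + (lltr - x)^b
  }
  list(hyper = hyper / (length(v) * cc), hypo = hypo / (length(v) * d))
}

o_modd <- function(v, steps_per_day) {
  tot <- 0; k <- 0
  for (t in seq_len(length(v) - steps_per_day)) {
    a <- v[t]; b <- v[t + steps_per_day]
    if (!is.na(a) && !is.na(b)) { tot <- tot + abs(b - a); k <- k + 1 }
  }
  tot / k
}

o_conga <- function(v, lag_steps, ddof = 1) {
  d <- c()
  for (t in seq_len(length(v) - lag_steps)) {
    a <- v[t]; b <- v[t + lag_steps]
    if (!is.na(a) && !is.na(b)) d <- c(d, b - a)
  }
  o_sd(d, ddof)
}

# MAGE oracle: a literal, loop-based transcription of the documented
# algorithm (plateau collapse; interior turning points, endpoints only when
# fewer than 2; smallest-amplitude pair pruning with same-type absorption;
# qualifying amplitudes > 1 SD counted in the first qualifying direction).
o_mage <- function(v, ddof = 1) {
  s <- o_sd(v, ddof)
  if (s == 0) return(NA_real_)
  w <- v[1]
  for (i in 2:length(v)) if (v[i] != w[length(w)]) w <- c(w, v[i])
  m <- length(w)
  if (m < 2) return(NA_real_)
  interior <- c()
  if (m >= 3) for (i in 2:(m - 1)) {
    dl <- sign(w[i] - w[i - 1]); dr <- sign(w[i + 1] - w[i])
    if (dl != dr) interior <- c(interior, i)
  }
  ext <- if (length(interior) >= 2) interior else unique(c(1, interior, m))
  repeat {
    k <- length(ext)
    if (k < 3) break
    amps <- abs(w[ext[-1]] - w[ext[-k]])
    i <- 1
    for (q in seq_along(amps)) if (amps[q] < amps[i]) i <- q
    if (amps[i] >= s) break
    j <- i + 1
    j_is_max <- w[ext[j]] > w[ext[i]]
    if (i - 1 >= 1) {
      cand <- c(ext[i - 1], ext[j])
      pick <- if (j_is_max) which(w[cand] == max(w[cand]))[1] else
        which(w[cand] == min(w[cand]))[1]
      ext[i - 1] <- cand[pick]
    }
    if (j + 1 <= k) {
      cand <- c(ext[i], ext[j + 1])
      pick <- if (j_is_max) which(w[cand] == min(w[cand]))[1] else
        which(w[cand] == max(w[cand]))[1]
      ext[j + 1] <- cand[pick]
    }
    ext <- ext[-c(i, j)]
  }
  if (length(ext) < 2) return(NA_real_)
  amps <- w[ext[-1]] - w[ext[-length(ext)]]
  qual <- abs(amps) > s
  if (!any(qual)) return(NA_real_)
  dir_sign <- sign(amps[which(qual)[1]])
  use <- qual & sign(amps) == dir_sign
  o_mean(abs(amps[use]))
}

# AUC oracle: concordant-pair count with half-credit for ties
o_auc <- function(scores, labels) {
  pos <- scores[labels]; neg <- scores[!labels]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# random positive glucose-like trace for property tests
random_trace <- function(n, seed = NULL, unit = "mmol_per_l") {
  if (!is.null(seed)) set.seed(seed)
  v <- pmax(cumsum(rnorm(n, 0, 0.6)) + 9 + rnorm(n, 0, 0.3), 0.5)
  glucose_trace(v, "2024-03-01 00:00:00", unit = unit,
                subject_id = paste0("rt", n))
}
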