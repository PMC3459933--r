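#' D'Agostino-Pearson omnibus normality test
#'
#' Combines the D'Agostino skewness z-test and the Anscombe-Glynn
#' kurtosis z-test into the omnibus statistic `K2 = Zs^2 + Zk^2`, referred
#' to a chi-squared distribution with 2 degrees of freedom.
#'
#' @param values Numeric sample, `n >= 8` after removing `NA`.
#' @return A list with `K2`, `p_value`, `z_skewness`, `z_kurtosis`, `n`.
#' @export
dagostino_pearson <- function(values) {
  x <- values[!is.na(values)]
  n <- length(x)
  if (n < 8) stop("dagostino_pearson: need n >= 8")
  if (stats::sd(x) == 0) stop("dagostino_pearson: sample is constant")
  m <- mean(x)
  m2 <- mean((x - m)^2)
  m3 <- mean((x - m)^3)
  m4 <- mean((x - m)^4)

  # skewness z (D'Agostino 1970)
  b1 <- m3 / m2^1.5
  y <- b1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  beta2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  W2 <- -1 + sqrt(2 * (beta2 - 1))
  delta <- 1 / sqrt(log(sqrt(W2)))
  alpha <- sqrt(2 / (W2 - 1))
  zs <- delta * log(y / alpha + sqrt((y / alpha)^2 + 1))

  # kurtosis z (Anscombe & Glynn 1983)
  b2 <- m4 / m2^2
  eb2 <- 3 * (n - 1) / (n + 1)
  vb2 <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
  xk <- (b2 - eb2) / sqrt(vb2)
  sb1 <- 6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
    sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
  A <- 6 + 8 / sb1 * (2 / sb1 + sqrt(1 + 4 / sb1^2))
  zk <- ((1 - 2 / (9 * A)) -
           ((1 - 2 / A) / (1 + xk * sqrt(2 / (A - 4))))^(1 / 3)) /
    sqrt(2 / (9 * A))

  K2 <- zs^2 + zk^2
  list(K2 = K2, p_value = stats::pchisq(K2, df = 2, lower.tail = FALSE),
       z_skewness = zs, z_kurtosis = zk, n = n)
}
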