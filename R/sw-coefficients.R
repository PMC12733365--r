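## Shapiro & Wilk (1965, Biometrika 52:591-611, Table 5) weights a_{n-i+1}
## for the W statistic, n = 3..20. Each row lists the m = floor(n/2) upper
## weights; the lower half is the antisymmetric mirror and the middle weight
## (odd n) is 0. Normalization: sum over the full weight vector of a^2 = 1.
.sw_table_1965 <- list(
  `3`  = c(0.7071),
  `4`  = c(0.6872, 0.1677),
  `5`  = c(0.6646, 0.2413),
  `6`  = c(0.6431, 0.2806, 0.0875),
  `7`  = c(0.6233, 0.3031, 0.1401),
  `8`  = c(0.6052, 0.3164, 0.1743, 0.0561),
  `9`  = c(0.5888, 0.3244, 0.1976, 0.0947),
  `10` = c(0.5739, 0.3291, 0.2141, 0.1224, 0.0399),
  `11` = c(0.5601, 0.3315, 0.2260, 0.1429, 0.0695),
  `12` = c(0.5475, 0.3325, 0.2347, 0.1586, 0.0922, 0.0303),
  `13` = c(0.5359, 0.3325, 0.2412, 0.1707, 0.1099, 0.0539),
  `14` = c(0.5251, 0.3318, 0.2460, 0.1802, 0.1240, 0.0727, 0.0240),
  `15` = c(0.5150, 0.3306, 0.2495, 0.1878, 0.1353, 0.0880, 0.0433),
  `16` = c(0.5056, 0.3290, 0.2521, 0.1939, 0.1447, 0.1005, 0.0593, 0.0196),
  `17` = c(0.4968, 0.3273, 0.2540, 0.1988, 0.1524, 0.1109, 0.0725, 0.0359),
  `18` = c(0.4886, 0.3253, 0.2553, 0.2027, 0.1587, 0.1197, 0.0837, 0.0496, 0.0163),
  `19` = c(0.4808, 0.3232, 0.2561, 0.2059, 0.1641, 0.1271, 0.0932, 0.0612, 0.0303),
  `20` = c(0.4734, 0.3211, 0.2565, 0.2085, 0.1686, 0.1334, 0.1013, 0.0711, 0.0422, 0.0140)
)

#' Shapiro-Wilk W coefficients
#'
#' Weights for the numerator of the generalized W statistic (see [sw_w()]).
#' For n up to 20 the original published small-sample coefficients are
#' embedded; for 21-50 unavailable table cells are replaced by Royston's
#' polynomial-corrected Blom-score weights, which closely approximate the
#' optimal coefficients. The source is recorded in the `"source"` attribute
#' (`"table"` or `"approximation"`).
#'
#' @param n sample size, 3 to 50.
#' @return numeric vector of the `floor(n/2)` upper weights, largest first.
#' @examples
#' sw_coefficients(3)   # 0.7071 = 1/sqrt(2)
#' @export
sw_coefficients <- function(n) {
  if (n < 3 || n > 50) stop("W coefficients are defined for n between 3 and 50")
  n <- as.integer(n)
  key <- as.character(n)
  if (!is.null(.sw_table_1965[[key]]))
    return(structure(.sw_table_1965[[key]], source = "table"))
  a <- .royston_weights(n)
  structure(a[n:(n - n %/% 2 + 1)], source = "approximation")
}

## Royston (1992/1995, AS R94) polynomial-corrected weights for the full
## Royston W, valid for n >= 4 (used here for n >= 12).
.royston_weights <- function(n) {
  m <- stats::qnorm((seq_len(n) - 0.375) / (n + 0.25))
  ssm <- sum(m^2)
  c0 <- m / sqrt(ssm)
  u <- 1 / sqrt(n)
  a_n <- c0[n] + 0.221157 * u - 0.147981 * u^2 - 2.071190 * u^3 +
    4.434685 * u^4 - 2.706056 * u^5
  if (n > 5) {
    a_n1 <- c0[n - 1] + 0.042981 * u - 0.293762 * u^2 - 1.752461 * u^3 +
      5.682633 * u^4 - 3.582633 * u^5
    phi <- (ssm - 2 * m[n]^2 - 2 * m[n - 1]^2) / (1 - 2 * a_n^2 - 2 * a_n1^2)
    a <- m / sqrt(phi)
    a[n] <- a_n; a[1] <- -a_n
    a[n - 1] <- a_n1; a[2] <- -a_n1
  } else {
    phi <- (ssm - 2 * m[n]^2) / (1 - 2 * a_n^2)
    a <- m / sqrt(phi)
    a[n] <- a_n; a[1] <- -a_n
  }
  a
}
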