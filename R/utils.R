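# Shared numerical helpers.  All probability mass aggregation in this package
# goes through additive accumulation of positive terms (log_add_exp /
# linear-space sums of non-negative weights); differences of log-probabilities
# are never formed, so rounding error is purely additive.

#' Numerically stable log(exp(a) + exp(b))
#'
#' Elementwise log-space addition. `-Inf` represents a zero term and is the
#' identity element.
#'
#' @param a,b numeric vectors of log-scale values (recycled).
#' @return numeric vector of `log(exp(a) + exp(b))`.
#' @export
log_add_exp <- function(a, b) {
  m <- pmax(a, b)
  out <- m + log1p(exp(pmin(a, b) - m))
  out[is.infinite(m) & m < 0] <- -Inf
  out
}

#' Numerically stable log of a sum of exponentials
#'
#' @param x numeric vector of log-scale values.
#' @return `log(sum(exp(x)))` as a scalar.
#' @export
log_sum_exp <- function(x) {
  if (length(x) == 0L) return(-Inf)
  m <- max(x)
  if (is.infinite(m) && m < 0) return(-Inf)
  m + log(sum(exp(x - m)))
}

#' Log multinomial coefficient
#'
#' `log( n! / (k1! k2! ... ) )` where `counts` must sum to `n`.
#'
#' @param n total count.
#' @param counts non-negative integer parts summing to `n`.
#' @return log of the multinomial coefficient.
#' @export
lmultinom <- function(n, counts) {
  stopifnot(sum(counts) == n, all(counts >= 0))
  lfactorial(n) - sum(lfactorial(counts))
}

# Exact multinomial coefficient with a representability guard: integers are
# exact in doubles only below 2^53.
multinom_exact <- function(n, counts) {
  lv <- lmultinom(n, counts)
  if (lv > log(2^53)) {
    stop("multinomial coefficient exceeds the exactly representable integer ",
         "range; use the log-space variant", call. = FALSE)
  }
  round(exp(lv))
}

# Checked exact-integer arithmetic on doubles (used by the cubic-algorithm
# recursion, which requires exact arithmetic).
.chk_exact <- function(x, what = "value") {
  if (any(abs(x) >= 2^53)) {
    stop("exact-arithmetic overflow (", what,
         " exceeds 2^53); parameters are outside the exact domain",
         call. = FALSE)
  }
  x
}
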