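#' 3x3 contingency table of a joint ternary classification
#'
#' Cross-tabulates two aligned ternary classifications. Rows correspond to
#' the fixed classification (margins `q`), columns to the randomized one
#' (margins `n`); both are indexed in the order `+`, `-`, `0`.
#'
#' @param c_fixed,c_random aligned [ternary_classification()] vectors.
#' @return an object of class `contingency3`: a 3x3 integer matrix with
#'   dimnames `+,-,0` and a `margins` attribute.
#' @examples
#' a <- ternary_classification(c(1, 1, -1, 0, 0))
#' b <- ternary_classification(c(1, 0, -1, 0, 0))
#' contingency_table(a, b)
#' @export
contingency_table <- function(c_fixed, c_random) {
  if (length(c_fixed) != length(c_random)) {
    stop("classifications must have equal length", call. = FALSE)
  }
  lev <- c(1L, -1L, 0L)
  m <- table(factor(unclass(c_fixed), levels = lev),
             factor(unclass(c_random), levels = lev))
  m <- matrix(as.integer(m), 3L, 3L,
              dimnames = list(c("+", "-", "0"), c("+", "-", "0")))
  as_contingency3(m)
}

#' Construct a contingency table from its nine counts
#'
#' @param counts a 3x3 matrix of non-negative counts; rows are the fixed
#'   classification levels and columns the randomized levels, both in the
#'   order `+`, `-`, `0`.
#' @return a `contingency3` object.
#' @export
as_contingency3 <- function(counts) {
  m <- matrix(as.integer(counts), 3L, 3L,
              dimnames = list(c("+", "-", "0"), c("+", "-", "0")))
  if (anyNA(m) || any(m < 0)) {
    stop("contingency counts must be non-negative integers", call. = FALSE)
  }
  q <- rowSums(m)
  n <- colSums(m)
  marg <- tdp_margins(q[1], q[2], q[3], n[1], n[2], n[3])
  structure(m, margins = marg, class = c("contingency3", "matrix", "array"))
}

#' @export
print.contingency3 <- function(x, ...) {
  cat("3x3 joint classification table (rows: fixed, cols: randomized)\n")
  print(matrix(x, 3L, 3L, dimnames = dimnames(x)))
  invisible(x)
}

#' Agreement score of a contingency table
#'
#' The score awards +1 per correct prediction (both classifications `+`, or
#' both `-`), -1 per incorrect prediction (one `+`, the other `-`) and 0
#' otherwise, i.e. `n[+,+] + n[-,-] - n[+,-] - n[-,+]`. It equals the dot
#' product of the two underlying ternary vectors.
#'
#' @param table a `contingency3` object.
#' @return integer score.
#' @export
tdp_score <- function(table) {
  stopifnot(inherits(table, "contingency3"))
  as.integer(table[1L, 1L] + table[2L, 2L] - table[1L, 2L] - table[2L, 1L])
}

# Validate that a table is consistent with the given margins.
check_margins <- function(table, margins) {
  m <- attr(table, "margins")
  if (!identical(unname(m$q), unname(margins$q)) ||
      !identical(unname(m$n), unname(margins$n))) {
    stop("table margins do not match the supplied margins", call. = FALSE)
  }
  invisible(TRUE)
}

#' Number of randomized classifications producing a table
#'
#' Counts the arrangements of the randomized classification that yield the
#' given joint table with the fixed classification: a product of one
#' multinomial coefficient per row,
#' `multinom(q_s; n_s+, n_s-, n_s0)` over rows `s` in `+`, `-`, `0`.
#'
#' @param table a `contingency3` object.
#' @return the exact count as a double (guarded to stay in the exactly
#'   representable integer range; use [log_d_value()] beyond it).
#' @seealso [log_d_value()], [d_tot()]
#' @export
d_value <- function(table) {
  stopifnot(inherits(table, "contingency3"))
  q <- rowSums(table)
  prod(vapply(1:3, function(i) multinom_exact(q[i], table[i, ]), 0))
}

#' Log-space D-value
#'
#' @inheritParams d_value
#' @return `log(d_value(table))`, accurate to ~1e-12 relative.
#' @export
log_d_value <- function(table) {
  stopifnot(inherits(table, "contingency3"))
  q <- rowSums(table)
  sum(vapply(1:3, function(i) lmultinom(q[i], table[i, ]), 0))
}

#' Total number of randomized classifications
#'
#' `multinom(T; n+, n-, n0)`: the number of arrangements of the randomized
#' classification, i.e. the normalizing constant of the ternary dot product
#' distribution. Equals the sum of [d_value()] over all feasible tables.
#'
#' @param margins a [tdp_margins()] object.
#' @return exact count as a double (guarded; see [log_d_tot()]).
#' @export
d_tot <- function(margins) {
  stopifnot(inherits(margins, "tdp_margins"))
  multinom_exact(margins$T, margins$n)
}

#' Log-space total count
#'
#' @inheritParams d_tot
#' @return `log(d_tot(margins))`.
#' @export
log_d_tot <- function(margins) {
  stopifnot(inherits(margins, "tdp_margins"))
  lmultinom(margins$T, margins$n)
}
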