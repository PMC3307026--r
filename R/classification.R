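#' Ternary classification of a ground set
#'
#' A ternary classification assigns each element of a ground set (typically
#' the measurable gene-transcript nodes of a causal graph) a value in
#' \{-1, 0, +1\}: downregulated, unchanged, or upregulated.
#'
#' @param values integer-like vector with entries in \{-1, 0, 1\}.
#' @param ids optional character vector of element identifiers, parallel to
#'   `values`. Defaults to no identifiers.
#' @return an object of class `ternary_classification`: an integer vector
#'   with optional `names` carrying the ids.
#' @examples
#' ternary_classification(c(1, -1, 0), ids = c("a", "b", "c"))
#' @export
ternary_classification <- function(values, ids = NULL) {
  v <- as.integer(values)
  if (anyNA(v) || !all(v %in% c(-1L, 0L, 1L))) {
    stop("classification values must all be in {-1, 0, 1}", call. = FALSE)
  }
  if (!is.null(ids)) {
    ids <- as.character(ids)
    if (length(ids) != length(v)) {
      stop("`ids` must be parallel to `values`", call. = FALSE)
    }
    if (anyDuplicated(ids)) stop("duplicate ids in classification", call. = FALSE)
    names(v) <- ids
  }
  structure(v, class = "ternary_classification")
}

#' @export
print.ternary_classification <- function(x, ...) {
  cat("Ternary classification of", length(x), "elements:",
      sum(x == 1L), "up,", sum(x == -1L), "down,", sum(x == 0L), "unchanged\n")
  invisible(x)
}

# Margin counts (+, -, 0) of a classification, in that order.
margin_counts <- function(x) {
  c(pos = sum(x == 1L), neg = sum(x == -1L), zero = sum(x == 0L))
}

#' Margin parameters of the ternary dot product problem
#'
#' Holds the fixed counts of +1, -1 and 0 entries for the experimental
#' classification (`q`) and for the randomized predicted classification
#' (`n`). Both triples must sum to the same ground-set size `T`.
#'
#' @param q_plus,q_minus,q_zero non-negative counts for the fixed
#'   classification.
#' @param n_plus,n_minus,n_zero non-negative counts for the classification
#'   being randomized.
#' @return an object of class `tdp_margins`: a list with integer vectors `q`
#'   and `n` (each named `pos`, `neg`, `zero`) and the total `T`.
#' @examples
#' tdp_margins(2, 1, 2, 1, 1, 3)
#' @export
tdp_margins <- function(q_plus, q_minus, q_zero, n_plus, n_minus, n_zero) {
  q <- as.integer(c(pos = q_plus, neg = q_minus, zero = q_zero))
  n <- as.integer(c(pos = n_plus, neg = n_minus, zero = n_zero))
  names(q) <- names(n) <- c("pos", "neg", "zero")
  if (anyNA(q) || anyNA(n) || any(q < 0) || any(n < 0)) {
    stop("margin counts must be non-negative integers", call. = FALSE)
  }
  if (sum(q) != sum(n)) {
    stop("q and n margins must sum to the same ground-set size", call. = FALSE)
  }
  structure(list(q = q, n = n, T = sum(q)), class = "tdp_margins")
}

#' Margins of a pair of classifications
#'
#' @param c_fixed the fixed (experimental) classification.
#' @param c_random the classification whose arrangement is randomized
#'   (predicted).
#' @return a [tdp_margins()] object.
#' @export
margins_of <- function(c_fixed, c_random) {
  if (length(c_fixed) != length(c_random)) {
    stop("classifications must have equal length", call. = FALSE)
  }
  q <- margin_counts(c_fixed)
  n <- margin_counts(c_random)
  tdp_margins(q[1], q[2], q[3], n[1], n[2], n[3])
}

#' @export
print.tdp_margins <- function(x, ...) {
  cat("TDP margins (T = ", x$T, "): q = (", paste(x$q, collapse = ", "),
      "), n = (", paste(x$n, collapse = ", "), ")\n", sep = "")
  invisible(x)
}
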