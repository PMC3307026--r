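#' Score distribution objects
#'
#' The exact probability mass function of the agreement score `S` between a
#' fixed ternary classification and a uniformly random arrangement of a
#' second one. Constructed by the distribution algorithms
#' ([tdp_exhaustive()], [tdp_quartic()], [tdp_thresholded()]).
#'
#' @param score integer vector of supported scores.
#' @param prob probabilities for each score.
#' @param margins the [tdp_margins()] the distribution refers to.
#' @param method character label of the producing algorithm.
#' @param tail_bound upper bound on the total probability mass discarded by
#'   thresholding (0 for exact algorithms).
#' @param stats optional list of work counters.
#' @return an object of class `tdp_distribution`: a data.frame with columns
#'   `score` and `prob`, sorted by increasing score.
#' @export
tdp_distribution_object <- function(score, prob, margins, method,
                                    tail_bound = 0, stats = NULL) {
  ord <- order(score)
  out <- data.frame(score = as.integer(score[ord]), prob = prob[ord])
  structure(out,
            margins = margins, method = method,
            tail_bound = tail_bound, stats = stats,
            class = c("tdp_distribution", "data.frame"))
}

#' @export
print.tdp_distribution <- function(x, ...) {
  m <- attr(x, "margins")
  cat("Ternary dot product distribution (", attr(x, "method"), ")\n", sep = "")
  cat("  T = ", m$T, ", q = (", paste(m$q, collapse = ","),
      "), n = (", paste(m$n, collapse = ","), ")\n", sep = "")
  cat("  support: ", min(x$score), "..", max(x$score),
      "  total mass: ", format(sum(x$prob), digits = 12), "\n", sep = "")
  if (attr(x, "tail_bound") > 0) {
    cat("  discarded tail mass < ", format(attr(x, "tail_bound"), digits = 3),
        "\n", sep = "")
  }
  invisible(x)
}

#' Right-tail p-value of an observed score
#'
#' Inclusive right tail: `P(S >= s_obs)` under the distribution, the standard
#' exact-test convention.
#'
#' @param dist a `tdp_distribution`.
#' @param s_obs observed integer score.
#' @return the p-value.
#' @examples
#' d <- tdp_exhaustive(tdp_margins(2, 1, 2, 1, 1, 3))
#' pvalue_right_tail(d, 1)  # 0.4
#' @export
pvalue_right_tail <- function(dist, s_obs) {
  stopifnot(inherits(dist, "tdp_distribution"))
  sum(dist$prob[dist$score >= s_obs])
}

# Enumerate all feasible top-left 2x2 assignments (i = n++, j = n+-,
# k = n-+, l = n--) for the given margins, vectorized. Returns a data.frame
# with the four cells and the implied outer cells.
feasible_tables <- function(margins) {
  q <- margins$q; n <- margins$n
  i <- 0:min(q[1], n[1])
  j <- 0:min(q[1], n[2])
  k <- 0:min(q[2], n[1])
  l <- 0:min(q[2], n[2])
  g <- expand.grid(i = i, j = j, k = k, l = l)
  g <- g[g$i + g$j <= q[1] & g$k + g$l <= q[2] &
           g$i + g$k <= n[1] & g$j + g$l <= n[2], , drop = FALSE]
  n0p <- n[1] - g$i - g$k
  n0m <- n[2] - g$j - g$l
  n00 <- q[3] - n0p - n0m
  keep <- n00 >= 0
  g <- g[keep, , drop = FALSE]
  g$np0 <- q[1] - g$i - g$j
  g$nm0 <- q[2] - g$k - g$l
  g$n0p <- n0p[keep]
  g$n0m <- n0m[keep]
  g$n00 <- n00[keep]
  g
}

#' Exhaustive exact distribution (brute-force reference)
#'
#' Enumerates every feasible 3x3 contingency table, aggregates the exact
#' counts [d_value()] by score and normalizes by [d_tot()]. All arithmetic is
#' exact (integer counts; one final division), so this serves as the
#' independent reference for the faster algorithms. Refuses problems with
#' more than `cap` total arrangements.
#'
#' @param margins a [tdp_margins()] object.
#' @param cap maximum permitted [d_tot()] (default 1e7).
#' @return a `tdp_distribution`.
#' @examples
#' tdp_exhaustive(tdp_margins(2, 1, 2, 1, 1, 3))
#' @export
tdp_exhaustive <- function(margins, cap = 1e7) {
  stopifnot(inherits(margins, "tdp_margins"))
  dtot <- exp(log_d_tot(margins))
  if (dtot > cap) {
    stop("d_tot = ", format(dtot), " exceeds the exhaustive-enumeration cap (",
         format(cap), ")", call. = FALSE)
  }
  dtot <- d_tot(margins)
  g <- feasible_tables(margins)
  q <- margins$q
  # exact row multinomials via exact binomials (all values are small here)
  dvals <- choose(q[1], g$i) * choose(q[1] - g$i, g$j) *
    choose(q[2], g$k) * choose(q[2] - g$k, g$l) *
    choose(q[3], g$n0p) * choose(q[3] - g$n0p, g$n0m)
  .chk_exact(dvals, "D-value")
  s <- g$i + g$l - g$j - g$k
  agg <- rowsum(dvals, s)
  tdp_distribution_object(as.integer(rownames(agg)), agg[, 1] / dtot,
                          margins, method = "exhaustive")
}
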