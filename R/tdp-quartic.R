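#' Quartic-time exact distribution
#'
#' Visits every feasible assignment of the top-left 2x2 block
#' (`n++`, `n+-`, `n-+`, `n--`) of the contingency table; the remaining five
#' cells are implied by the margins. Work scales as the product
#' `n+ * n- * q+ * q-`. All D-values are evaluated in log space from shared
#' log-factorial decompositions of the three row multinomials (so each table
#' costs O(1) amortized), normalized by the global maximum D-value so that
#' every accumulated weight lies in (0, 1], and finally rescaled by the total
#' count. Weights are only ever added, never subtracted.
#'
#' @param margins a [tdp_margins()] object.
#' @return a `tdp_distribution`.
#' @examples
#' tdp_quartic(tdp_margins(2, 1, 2, 1, 1, 3))
#' @export
tdp_quartic <- function(margins) {
  stopifnot(inherits(margins, "tdp_margins"))
  q <- margins$q; n <- margins$n; Tn <- margins$T
  lf <- lfactorial(0:max(Tn, 1L))  # lf[x + 1] == log(x!)
  log_dmax <- global_max_d(margins)$log_d
  log_dtot <- log_d_tot(margins)

  # column-margin factor over (a, b) = (n++ + n-+, n+- + n--):
  # row "0" multinomial with cells n0+ = n+ - a, n0- = n- - b, n00
  a <- 0:n[1]; b <- 0:n[2]
  n00 <- q[3] - outer(n[1] - a, n[2] - b, "+")
  cmat <- lf[q[3] + 1] - outer(lf[n[1] - a + 1], lf[n[2] - b + 1], "+") -
    ifelse(n00 >= 0, lf[pmax(n00, 0) + 1], Inf)

  # row "-" multinomial over (k, l) = (n-+, n--)
  kfull <- min(q[2], n[1]); lfull <- min(q[2], n[2])
  k <- 0:kfull; l <- 0:lfull
  nm0 <- q[2] - outer(k, l, "+")
  bmat <- lf[q[2] + 1] - outer(lf[k + 1], lf[l + 1], "+") -
    ifelse(nm0 >= 0, lf[pmax(nm0, 0) + 1], Inf)

  offset <- Tn + 1L
  acc <- numeric(2L * Tn + 1L)
  for (i in 0:min(q[1], n[1])) {
    for (j in 0:min(q[1] - i, n[2])) {
      A <- lf[q[1] + 1] - lf[i + 1] - lf[j + 1] - lf[q[1] - i - j + 1]
      kmax <- min(q[2], n[1] - i); lmax <- min(q[2], n[2] - j)
      nr <- kmax + 1L; nc <- lmax + 1L
      logd <- A + bmat[1:nr, 1:nc, drop = FALSE] +
        cmat[i + (1:nr), j + (1:nc), drop = FALSE]
      w <- exp(logd - log_dmax)
      d <- rep(0:lmax, each = nr) - rep(0:kmax, times = nc)
      agg <- rowsum(as.vector(w), d)           # rows ordered -kmax .. lmax
      s <- (i - j) + as.integer(rownames(agg))
      acc[s + offset] <- acc[s + offset] + agg[, 1]
    }
  }
  keep <- which(acc > 0)
  tdp_distribution_object(keep - offset,
                          acc[keep] * exp(log_dmax - log_dtot),
                          margins, method = "quartic")
}
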