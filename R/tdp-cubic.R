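# Cubic-algorithm machinery: the inner sum F[n] of the aggregated D-value
# rewriting, its direct exact evaluation, and a three-term-deep (four-term)
# linear recursion on F[n] with polynomial coefficients. The recursion is a
# research extra: as the direct tests show, it must be run in exact
# arithmetic (consecutive F-values shrink geometrically, so floating-point
# evaluation cancels catastrophically), which is why the thresholded
# algorithm is the production path.

#' Parameters of the cubic-algorithm inner sum
#'
#' The aggregated rewriting of the D-values groups tables by
#' `gamma1 = n++ + n--` and `gamma2 = n-+ + n+-` and reduces the inner sum
#' over `t = n+-` to `F[n] = sum_k C(n,k) C(v-n, w-k) C(x-n, y-k)` with
#' `n = gamma2`, `k = t`, `v = q+ + q- - gamma1`, `w = q+ - s`,
#' `x = n+ + n- - gamma1`, `y = n- - gamma1 + s` (where `s = n++`).
#'
#' @param v,w,x,y non-negative integer parameters of the sum.
#' @return an object of class `cubic_params`.
#' @seealso [cubic_params_from_margins()] for the substitution from margins.
#' @export
cubic_params <- function(v, w, x, y) {
  p <- list(v = as.integer(v), w = as.integer(w),
            x = as.integer(x), y = as.integer(y))
  if (anyNA(p) || p$v < 0 || p$x < 0) {
    stop("cubic parameters v and x must be non-negative integers",
         call. = FALSE)
  }
  structure(p, class = "cubic_params")
}

#' Cubic parameters from margins and aggregation variables
#'
#' @param margins a [tdp_margins()] object.
#' @param gamma1 value of `n++ + n--`.
#' @param s value of `n++`.
#' @return a `cubic_params` object.
#' @export
cubic_params_from_margins <- function(margins, gamma1, s) {
  stopifnot(inherits(margins, "tdp_margins"))
  q <- margins$q; n <- margins$n
  cubic_params(v = q[1] + q[2] - gamma1, w = q[1] - s,
               x = n[1] + n[2] - gamma1, y = n[2] - gamma1 + s)
}

#' Direct exact evaluation of the inner sum F[n]
#'
#' `F[n] = sum_k C(n,k) C(v-n, w-k) C(x-n, y-k)`, evaluated term by term in
#' exact integer arithmetic. Binomials with a negative lower index, or lower
#' index exceeding the upper, are zero. The standard-binomial regime requires
#' `v - n >= 0` and `x - n >= 0`; outside it the binomial convention is not
#' well defined and the function refuses.
#'
#' @param p a [cubic_params()] object.
#' @param n the index of the sum (non-negative integer).
#' @return the exact value of `F[n]` as a double (guarded below 2^53).
#' @examples
#' f_direct(cubic_params(20, 10, 10, 5), 0)  # choose(20,10) * choose(10,5)
#' @export
f_direct <- function(p, n) {
  stopifnot(inherits(p, "cubic_params"))
  n <- as.integer(n)
  if (n < 0) stop("n must be non-negative", call. = FALSE)
  if (p$v - n < 0 || p$x - n < 0) {
    stop("parameters outside the standard-binomial regime (need v - n >= 0 ",
         "and x - n >= 0)", call. = FALSE)
  }
  k <- 0:n
  terms <- choose(n, k) * choose(p$v - n, p$w - k) * choose(p$x - n, p$y - k)
  .chk_exact(terms, "F[n] term")
  s <- sum(round(terms))
  .chk_exact(s, "F[n]")
  s
}

# All F values on the feasible range 0..min(v, x).
.f_all <- function(p) {
  vapply(0:min(p$v, p$x), function(n) f_direct(p, n), 0)
}

# Evaluate the coefficient polynomials at n: coef is a (order+1) x (deg+1)
# matrix of exact integers; returns the vector P_j(n), exactness-checked.
.poly_eval <- function(coef, n) {
  deg <- ncol(coef) - 1L
  pw <- .chk_exact(n^(0:deg), "n^p")
  .chk_exact(drop(coef %*% pw), "polynomial coefficient value")
}

# Derive exact integer polynomial coefficients of a linear recurrence
# sum_j P_j(n) F[n+j] = 0 (order at most 3) holding at every feasible n. The
# homogeneous system (rows: n; columns: coefficients of n^p F[n+j]) is solved
# in floating point; each candidate null vector is rationalized by continued
# fractions and then verified EXACTLY at every feasible index before
# acceptance. On short feasible ranges the exactly recoverable relation can
# have trailing zero coefficient polynomials; it is then re-verified over the
# longer range its effective order allows, and used at that order.
.derive_recurrence <- function(p, order = 3L, max_deg = 5L) {
  fvals <- .f_all(p)
  n_hi <- length(fvals) - 1L - order
  if (n_hi < 0) {
    stop("feasible range too short for an order-", order, " recursion",
         call. = FALSE)
  }
  for (deg in 0:max_deg) {
    found <- list()
    for (ord in c(order, order - 1L, order - 2L)) {
      if (ord < 1L) next
      ns <- 0:(length(fvals) - 1L - ord)
      ncoef <- (ord + 1L) * (deg + 1L)
      M <- matrix(0, length(ns), ncoef)
      for (j in 0:ord) {
        for (pw in 0:deg) {
          M[, j * (deg + 1L) + pw + 1L] <- ns^pw * fvals[ns + j + 1L]
        }
      }
      basis <- .nullspace_rref(M)
      if (is.null(basis)) next
      for (ci in seq_len(ncol(basis))) {
        z <- .rationalize_vector(basis[, ci])
        if (is.null(z)) next
        coef <- matrix(z, ord + 1L, deg + 1L, byrow = TRUE)
        eff <- max(which(rowSums(coef != 0) > 0)) - 1L
        if (eff < 1L) next
        coef <- coef[1:(eff + 1L), , drop = FALSE]
        ns_eff <- 0:(length(fvals) - 1L - eff)
        if (!.verify_recurrence(coef, fvals, ns_eff)) next
        n_singular <- sum(vapply(ns_eff, function(n) {
          .poly_eval(coef, n)[eff + 1L] == 0
        }, TRUE))
        found[[length(found) + 1L]] <- list(coef = coef,
                                            n_singular = n_singular)
      }
    }
    if (length(found)) {
      # prefer no singular leading-coefficient points, then highest order
      sing <- vapply(found, function(f) f$n_singular, 1L)
      ords <- vapply(found, function(f) nrow(f$coef), 1L)
      return(found[[order(sing, -ords)[1L]]]$coef)
    }
  }
  stop("could not derive an exactly verifiable recursion for these ",
       "parameters; they are outside the exact-derivation domain",
       call. = FALSE)
}

# Floating-point reduced-row-echelon nullspace. The canonical (free variable
# = 1) basis vectors of these small systems have small rational entries,
# which continued fractions can recover; exactness is guaranteed afterwards
# by .verify_recurrence, never by this step.
.nullspace_rref <- function(M, tol = 1e-7) {
  nc <- ncol(M); nr <- nrow(M)
  colscale <- apply(abs(M), 2, max)
  colscale[colscale == 0] <- 1
  M <- sweep(M, 2, colscale, "/")
  piv <- integer(0)
  r <- 1L
  for (cc in seq_len(nc)) {
    if (r > nr) break
    i <- which.max(abs(M[r:nr, cc])) + r - 1L
    if (abs(M[i, cc]) < tol) next
    if (i != r) M[c(i, r), ] <- M[c(r, i), ]
    M[r, ] <- M[r, ] / M[r, cc]
    for (k in seq_len(nr)) {
      if (k != r && M[k, cc] != 0) M[k, ] <- M[k, ] - M[k, cc] * M[r, ]
    }
    piv <- c(piv, cc)
    r <- r + 1L
  }
  free <- setdiff(seq_len(nc), piv)
  if (length(free) == 0L) return(NULL)
  basis <- matrix(0, nc, length(free))
  qrp <- if (length(piv)) qr(M[, piv, drop = FALSE]) else NULL
  for (fi in seq_along(free)) {
    basis[free[fi], fi] <- 1
    if (length(piv)) {
      # canonical solve with iterative refinement for extra accuracy
      rhs <- -M[, free[fi]]
      sol <- qr.coef(qrp, rhs)
      for (it in 1:3) {
        resid <- rhs - drop(M[, piv, drop = FALSE] %*% sol)
        sol <- sol + qr.coef(qrp, resid)
      }
      basis[piv, fi] <- sol
    }
    # undo the column scaling, then renormalize so the free coordinate is 1
    basis[, fi] <- basis[, fi] / colscale
    basis[, fi] <- basis[, fi] / basis[free[fi], fi]
  }
  basis
}

# Continued-fraction rationalization of a float vector into a primitive
# integer vector, or NULL on failure.
.rationalize_vector <- function(vec, max_den = 3e5, tol = 1e-9) {
  a <- max(abs(vec))
  if (a == 0) return(NULL)
  vec <- vec / a
  num <- den <- numeric(length(vec))
  for (i in seq_along(vec)) {
    r <- .best_rational(vec[i], max_den, tol)
    if (is.null(r)) return(NULL)
    num[i] <- r[1]; den[i] <- r[2]
  }
  L <- 1
  for (d in unique(den)) {
    L <- L / .gcd_exact(L, d) * d
    if (L > 2^40) return(NULL)
  }
  z <- round(num * (L / den))
  g <- 0
  for (e in z) g <- .gcd_exact(g, abs(e))
  if (g == 0) return(NULL)
  z / g
}

.best_rational <- function(x, max_den, tol) {
  if (abs(x) < tol) return(c(0, 1))
  p0 <- 0; q0 <- 1; p1 <- 1; q1 <- 0; r <- x
  for (it in 1:64) {
    a <- floor(r)
    p2 <- a * p1 + p0; q2 <- a * q1 + q0
    if (q2 > max_den) break
    p0 <- p1; q0 <- q1; p1 <- p2; q1 <- q2
    if (abs(p1 / q1 - x) < tol * max(1, abs(x))) {
      return(c(p1, q1))
    }
    if (abs(r - a) < 1e-12) break
    r <- 1 / (r - a)
  }
  if (q1 >= 1 && abs(p1 / q1 - x) < tol * max(1, abs(x))) return(c(p1, q1))
  NULL
}

.gcd_exact <- function(a, b) {
  while (b != 0) { t <- a %% b; a <- b; b <- t }
  a
}

# Exact verification: sum_j P_j(n) F[n+j] == 0 at every n in ns, with every
# intermediate integer below 2^53 (else the domain guard trips).
.verify_recurrence <- function(coef, fvals, ns) {
  order <- nrow(coef) - 1L
  for (n in ns) {
    pj <- tryCatch(.poly_eval(coef, n), error = function(e) NULL)
    if (is.null(pj)) return(FALSE)
    terms <- pj * fvals[n + 0:order + 1L]
    if (any(abs(terms) >= 2^53) || abs(sum(abs(terms))) >= 2^53) return(FALSE)
    if (sum(terms) != 0) return(FALSE)
  }
  TRUE
}

#' Extend F[n] by its exact linear recursion
#'
#' Derives (per parameter set, at run time) a linear recursion of order at
#' most three with integer polynomial coefficients satisfied by `F[n]` on
#' its whole feasible range, verifies it exactly against [f_direct()] at
#' every feasible index, and then uses it to extend three consecutive seed
#' values. All arithmetic is exact integer arithmetic (guarded below 2^53);
#' no floating-point mode is offered, because consecutive F-values shrink by
#' roughly a factor of two and a floating recursion cancels
#' catastrophically. On short feasible ranges the exactly recoverable
#' relation may have effective order below three (it is then re-verified
#' over the longer range that order allows); isolated zeros of the leading
#' coefficient polynomial are bridged by direct evaluation. Parameter sets
#' whose recursion coefficients cannot be recovered and verified within the
#' exact window are refused with an error.
#'
#' @param p a [cubic_params()] object.
#' @param seeds three consecutive exact values `F[n_start .. n_start + 2]`,
#'   as produced by [f_direct()].
#' @param n_start index of the first seed (default 0).
#' @param n_end last index to produce; must stay within the feasible range
#'   `n <= min(v, x)`.
#' @return numeric vector of exact values `F[n_start .. n_end]`.
#' @examples
#' p <- cubic_params(20, 10, 10, 5)
#' seeds <- sapply(0:2, function(n) f_direct(p, n))
#' f_recursion(p, seeds, n_end = 10)
#' @export
f_recursion <- function(p, seeds, n_start = 0L, n_end) {
  stopifnot(inherits(p, "cubic_params"), length(seeds) == 3L)
  n_start <- as.integer(n_start); n_end <- as.integer(n_end)
  n_max <- min(p$v, p$x)
  if (n_end > n_max) {
    stop("n_end exceeds the feasible range (n <= min(v, x) = ", n_max, ")",
         call. = FALSE)
  }
  if (n_end < n_start + 2L) return(seeds[1:(n_end - n_start + 1L)])
  coef <- .derive_recurrence(p)
  ord <- nrow(coef) - 1L
  out <- numeric(n_end - n_start + 1L)
  out[1:3] <- .chk_exact(round(seeds), "seed")
  for (i in 4:(n_end - n_start + 1L)) {
    n <- (i - 1L) - ord + n_start   # relation producing F at index i
    pj <- .poly_eval(coef, n)
    if (pj[ord + 1L] == 0) {
      # singular step: the leading polynomial vanishes here, so this index
      # is bridged by direct evaluation
      out[i] <- f_direct(p, i - 1L + n_start)
      next
    }
    terms <- .chk_exact(pj[1:ord] * out[(i - ord):(i - 1L)],
                        "recursion term")
    num <- -sum(terms)
    .chk_exact(num, "recursion numerator")
    val <- num / pj[ord + 1L]
    if (val != round(val)) {
      stop("recursion step did not yield an exact integer; seeds are ",
           "inconsistent with the derived recursion", call. = FALSE)
    }
    out[i] <- val
  }
  out
}
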