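# Thresholded ternary-dot-product algorithms: contingency tables are grouped
# into one-parameter families (fixed row and column sums of the top-left 2x2
# block) and two-parameter superfamilies (fixed row sums only); a family whose
# maximum D-value falls below a threshold relative to the global maximum is
# discarded whole, and surviving families are swept outward from their
# maximizing table until the D-value drops below threshold.

#' Family of contingency tables with fixed 2x2 block margins
#'
#' A family fixes the row sums (`r_plus`, `r_minus`) and column sums
#' (`c_plus`, `c_minus`) of the top-left 2x2 block of the contingency table;
#' one degree of freedom remains, parameterized by `u = n++`.
#'
#' @param r_plus,r_minus row sums of the 2x2 block.
#' @param c_plus,c_minus column sums of the 2x2 block.
#' @param margins the enclosing [tdp_margins()].
#' @return an object of class `tdp_family` with the block sums, their total
#'   `t`, the valid range `u_min:u_max` of `u`, and the implied outer cells.
#' @export
family_spec <- function(r_plus, r_minus, c_plus, c_minus, margins) {
  stopifnot(inherits(margins, "tdp_margins"))
  rp <- as.integer(r_plus); rm <- as.integer(r_minus)
  cp <- as.integer(c_plus); cm <- as.integer(c_minus)
  if (rp + rm != cp + cm) {
    stop("2x2 block row and column sums must have equal totals", call. = FALSE)
  }
  q <- margins$q; n <- margins$n
  outer_cells <- c(np0 = q[1] - rp, nm0 = q[2] - rm,
                   n0p = n[1] - cp, n0m = n[2] - cm)
  n00 <- q[3] - (n[1] - cp) - (n[2] - cm)
  u_min <- max(0L, cp - rm)
  u_max <- min(rp, cp)
  if (any(c(rp, rm, cp, cm) < 0) || any(outer_cells < 0) || n00 < 0 ||
      u_min > u_max) {
    stop("family is empty: implied cells are negative", call. = FALSE)
  }
  structure(list(r_plus = rp, r_minus = rm, c_plus = cp, c_minus = cm,
                 t = rp + rm, u_min = u_min, u_max = u_max,
                 outer = c(outer_cells, n00 = n00), margins = margins),
            class = "tdp_family")
}

# log D within a family as a function of u (vectorized over u).
family_log_d <- function(fam, u) {
  q <- fam$margins$q
  con <- lfactorial(q[1]) + lfactorial(q[2]) + lfactorial(q[3]) -
    sum(lfactorial(fam$outer))
  con - lfactorial(u) - lfactorial(fam$r_plus - u) -
    lfactorial(fam$c_plus - u) - lfactorial(fam$r_minus - fam$c_plus + u)
}

#' Multiplicative change in D upon decrementing u
#'
#' The exact ratio `D[u - 1] / D[u]` within a family:
#' `u (r- - c+ + u) / ((r+ - u + 1)(c+ - u + 1))`. Both numerator and
#' denominator are monic quadratics in `u`, so the ratio crosses 1 exactly
#' once; D increases up to that crossing and decreases beyond it.
#'
#' @param u value of `n++`; both `u` and `u - 1` must lie in the family range.
#' @param fam a [family_spec()].
#' @return the ratio as a numeric value.
#' @export
delta_d <- function(u, fam) {
  stopifnot(inherits(fam, "tdp_family"))
  if (u - 1 < fam$u_min || u > fam$u_max) {
    stop("u and u - 1 must both be feasible in the family", call. = FALSE)
  }
  u * (fam$r_minus - fam$c_plus + u) /
    ((fam$r_plus - u + 1) * (fam$c_plus - u + 1))
}

#' Maximizing value of u within a family
#'
#' The D-value within a family is unimodal in `u`; the crossing point of the
#' monic quadratics in [delta_d()] is `u* = (r+ + 1)(c+ + 1)/(t + 2)`, and
#' the integer maximizer is its floor (or ceiling), clamped to the valid
#' range.
#'
#' @param fam a [family_spec()].
#' @return the integer `u` maximizing the D-value in the family.
#' @export
family_opt_u <- function(fam) {
  stopifnot(inherits(fam, "tdp_family"))
  ustar <- (fam$r_plus + 1) * (fam$c_plus + 1) / (fam$t + 2)
  cand <- unique(pmin(pmax(c(floor(ustar), ceiling(ustar)), fam$u_min),
                      fam$u_max))
  u <- cand[which.max(family_log_d(fam, cand))]
  # one-step hill climb as a guard against boundary rounding
  repeat {
    moved <- FALSE
    for (v in c(u - 1L, u + 1L)) {
      if (v >= fam$u_min && v <= fam$u_max &&
          family_log_d(fam, v) > family_log_d(fam, u)) {
        u <- v; moved <- TRUE
      }
    }
    if (!moved) break
  }
  as.integer(u)
}

#' Global maximum D-value table
#'
#' Finds a feasible contingency table attaining (up to the greedy search) the
#' maximum D-value over all tables with the given margins. The table is
#' seeded by proportional fill `n[s,t] ~ q_s * n_t / T` with
#' largest-remainder rounding so that both margins are met exactly, then
#' improved by greedy single-unit 2x2 rotations until no move increases D.
#'
#' @param margins a [tdp_margins()] object.
#' @return a list with elements `table` (a `contingency3`) and `log_d`.
#' @export
global_max_d <- function(margins) {
  stopifnot(inherits(margins, "tdp_margins"))
  q <- as.numeric(margins$q); n <- as.numeric(margins$n); Tn <- margins$T
  if (Tn == 0) {
    return(list(table = as_contingency3(matrix(0L, 3, 3)), log_d = 0))
  }
  P <- outer(q, n) / Tn
  m <- floor(P)
  rd <- q - rowSums(m); cd <- n - colSums(m)
  while (sum(rd) > 0) {
    R <- P - m
    R[rd == 0, ] <- -Inf
    R[, cd == 0] <- -Inf
    idx <- arrayInd(which.max(R), dim(R))
    m[idx] <- m[idx] + 1
    rd[idx[1]] <- rd[idx[1]] - 1
    cd[idx[2]] <- cd[idx[2]] - 1
  }
  logd <- function(m) sum(lfactorial(q)) - sum(lfactorial(m))
  cur <- logd(m)
  repeat {
    best <- cur; bm <- NULL
    for (r1 in 1:3) for (r2 in 1:3) for (c1 in 1:3) for (c2 in 1:3) {
      if (r1 == r2 || c1 == c2 || m[r1, c2] == 0 || m[r2, c1] == 0) next
      m2 <- m
      m2[r1, c1] <- m2[r1, c1] + 1; m2[r2, c2] <- m2[r2, c2] + 1
      m2[r1, c2] <- m2[r1, c2] - 1; m2[r2, c1] <- m2[r2, c1] - 1
      v <- logd(m2)
      if (v > best + 1e-12) { best <- v; bm <- m2 }
    }
    if (is.null(bm)) break
    m <- bm; cur <- best
  }
  list(table = as_contingency3(m), log_d = cur)
}

#' Threshold configuration for the pruned algorithms
#'
#' @param epsilon relative pruning threshold: families whose maximum D-value
#'   falls below `epsilon * safety_factor * D_max` are discarded. The default
#'   is machine-epsilon scale.
#' @param safety_factor extra slack applied to the threshold; absorbs the
#'   rounding slack of the proportional-fill superfamily bound, which is a
#'   heuristic rather than a proven maximum.
#' @return an object of class `tdp_threshold_config`.
#' @export
threshold_config <- function(epsilon = 1e-16, safety_factor = 1e-2) {
  if (!(epsilon * safety_factor > 0 && epsilon * safety_factor < 1)) {
    stop("need 0 < epsilon * safety_factor < 1", call. = FALSE)
  }
  structure(list(epsilon = epsilon, safety_factor = safety_factor),
            class = "tdp_threshold_config")
}

# sum over c in a:b of min(R, c); 0 when b < a
.sum_min <- function(R, a, b) {
  m <- pmin(b, R)
  s1 <- ifelse(m >= a, (m * (m + 1) - (a - 1) * a) / 2, 0)
  a2 <- pmax(a, R + 1)
  s2 <- ifelse(b >= a2, R * (b - a2 + 1), 0)
  s1 + s2
}

# sum over c in a:b of max(0, c - M); 0 when b < a
.sum_excess <- function(M, a, b) {
  a2 <- pmax(a, M + 1)
  ifelse(b >= a2, ((b - M) * (b - M + 1) - (a2 - 1 - M) * (a2 - M)) / 2, 0)
}

#' Thresholded distribution (family and superfamily pruning)
#'
#' Computes the ternary dot product distribution while discarding families of
#' contingency tables whose maximum D-value is negligible relative to the
#' global maximum. With `superfamilies = FALSE` the algorithm checks each
#' one-parameter 2x2-block family; with `superfamilies = TRUE` (the default,
#' and the production path) it first bounds entire two-parameter superfamilies
#' in which only the 2x2 block row sums are fixed, eliminating whole swaths of
#' families with a single check — a large saving in the sparse regimes typical
#' of expression data. Surviving families are swept outward from their
#' maximizing table until the D-value drops below threshold.
#'
#' Scores never touched by a surviving table are absent from the returned
#' support; their combined mass is bounded by the `tail_bound` attribute
#' (`epsilon * D_max * #discarded tables / D_tot`).
#'
#' @param margins a [tdp_margins()] object.
#' @param config a [threshold_config()].
#' @param superfamilies logical; prune superfamilies before families.
#' @return a `tdp_distribution`; attribute `stats` carries the work counters
#'   `threshold_checks`, `sweep_steps`, `families_skipped`, `tables_skipped`
#'   and (superfamily mode) `superfamily_checks`, `superfamilies_skipped`.
#' @examples
#' tdp_thresholded(tdp_margins(2, 1, 2, 1, 1, 3))
#' @export
tdp_thresholded <- function(margins, config = threshold_config(),
                            superfamilies = TRUE) {
  stopifnot(inherits(margins, "tdp_margins"),
            inherits(config, "tdp_threshold_config"))
  q <- margins$q; n <- margins$n; Tn <- margins$T
  lf <- lfactorial(0:max(Tn, 1L))
  log_dmax <- global_max_d(margins)$log_d
  log_dtot <- log_d_tot(margins)
  thr <- log(config$epsilon) + log(config$safety_factor) + log_dmax

  np <- n[1]; nm <- n[2]; tot_pm <- np + nm
  t_min <- max(0L, tot_pm - q[3])
  rp_max <- min(q[1], tot_pm); rm_max <- min(q[2], tot_pm)

  offset <- Tn + 1L
  logacc <- rep(-Inf, 2L * Tn + 1L)
  st <- list(threshold_checks = 0, sweep_steps = 0, families_skipped = 0,
             tables_skipped = 0, superfamily_checks = 0,
             superfamilies_skipped = 0)

  # count of tables in all families of superfamily (rp, rm) [vectorized in rm]
  sf_table_count <- function(rp, rm) {
    t <- rp + rm
    a <- pmax(0L, t - nm); b <- pmin(np, t)
    ifelse(b < a, 0,
           .sum_min(rp, a, b) - .sum_excess(rm, a, b) + (b - a + 1))
  }

  # process all families (vector of c+ values) of one superfamily
  process_superfamily <- function(rp, rm) {
    t <- rp + rm
    cps <- seq.int(max(0L, t - nm), min(np, t))
    if (length(cps) == 0L) return(invisible())
    n0p <- np - cps; n0m <- nm - (t - cps)
    n00 <- q[3] - tot_pm + t
    con <- lf[q[1] + 1] + lf[q[2] + 1] + lf[q[3] + 1] -
      lf[q[1] - rp + 1] - lf[q[2] - rm + 1] - lf[n00 + 1]
    base <- con - lf[n0p + 1] - lf[n0m + 1]
    u_min <- pmax(0L, cps - rm); u_max <- pmin(rp, cps)
    h <- function(u) -(lf[u + 1] + lf[rp - u + 1] + lf[cps - u + 1] +
                         lf[rm - cps + u + 1])
    u0 <- pmin(pmax(floor((rp + 1) * (cps + 1) / (t + 2)), u_min), u_max)
    u1 <- pmin(u0 + 1L, u_max)
    h0 <- h(u0); h1 <- h(u1)
    u_opt <- ifelse(h1 > h0, u1, u0)
    fam_max <- base + pmax(h0, h1)
    st$threshold_checks <<- st$threshold_checks + length(cps)
    surv <- fam_max >= thr
    st$families_skipped <<- st$families_skipped + sum(!surv)
    st$tables_skipped <<- st$tables_skipped +
      sum((u_max - u_min + 1)[!surv])
    for (fi in which(surv)) {
      cp <- cps[fi]; b0 <- base[fi]; uo <- u_opt[fi]
      umin <- u_min[fi]; umax <- u_max[fi]
      sc0 <- rm - rp - 2L * cp
      for (dir in c(1L, -1L)) {
        u <- if (dir == 1L) uo else uo - 1L
        while ((dir == 1L && u <= umax) || (dir == -1L && u >= umin)) {
          uu <- if (dir == 1L) u:min(u + 63L, umax) else u:max(u - 63L, umin)
          ld <- b0 - (lf[uu + 1] + lf[rp - uu + 1] + lf[cp - uu + 1] +
                        lf[rm - cp + uu + 1])
          st$sweep_steps <<- st$sweep_steps + length(uu)
          ok <- ld >= thr
          if (any(ok)) {
            idx <- 4L * uu[ok] + sc0 + offset
            logacc[idx] <<- log_add_exp(logacc[idx], ld[ok] - log_dmax)
          }
          if (any(!ok)) {  # unimodal: once below threshold, stays below
            st$tables_skipped <<- st$tables_skipped +
              (if (dir == 1L) umax - max(uu) else min(uu) - umin)
            break
          }
          u <- u + dir * 64L
        }
      }
    }
    invisible()
  }

  for (rp in 0:rp_max) {
    rm_lo <- max(0L, t_min - rp); rm_hi <- min(rm_max, tot_pm - rp)
    if (rm_lo > rm_hi) next
    rms <- seq.int(rm_lo, rm_hi)
    if (superfamilies && tot_pm > 0L) {
      t <- rp + rms
      n00 <- q[3] - tot_pm + t
      mpp <- rp * np / tot_pm;  mpm <- rp * nm / tot_pm
      mmp <- rms * np / tot_pm; mmm <- rms * nm / tot_pm
      m0p <- (tot_pm - t) * np / tot_pm; m0m <- (tot_pm - t) * nm / tot_pm
      bound <- lf[q[1] + 1] + lf[q[2] + 1] + lf[q[3] + 1] -
        lf[q[1] - rp + 1] - lf[q[2] - rms + 1] - lf[n00 + 1] -
        (lgamma(mpp + 1) + lgamma(mpm + 1) + lgamma(mmp + 1) +
           lgamma(mmm + 1) + lgamma(m0p + 1) + lgamma(m0m + 1))
      st$superfamily_checks <- st$superfamily_checks + length(rms)
      surv <- bound >= thr
      st$superfamilies_skipped <- st$superfamilies_skipped + sum(!surv)
      st$tables_skipped <- st$tables_skipped +
        sum(sf_table_count(rp, rms[!surv]))
      rms <- rms[surv]
    }
    for (rm in rms) process_superfamily(rp, rm)
  }

  keep <- which(is.finite(logacc))
  tail_bound <- config$epsilon * exp(log_dmax - log_dtot) * st$tables_skipped
  tdp_distribution_object(keep - offset,
                          exp(logacc[keep] + log_dmax - log_dtot),
                          margins,
                          method = if (superfamilies) "superfamily-thresholded"
                                   else "family-thresholded",
                          tail_bound = tail_bound, stats = st)
}

#' Ternary dot product distribution (front end)
#'
#' Dispatches to one of the algorithms computing the exact distribution of
#' the agreement score.
#'
#' @param margins a [tdp_margins()] object.
#' @param method `"superfamily"` (default; thresholded, superfamily pruning),
#'   `"family"` (thresholded, per-family pruning), `"quartic"` (all tables),
#'   or `"exhaustive"` (brute-force reference, small problems only).
#' @param epsilon,safety_factor threshold parameters, see
#'   [threshold_config()].
#' @return a `tdp_distribution`.
#' @export
tdp_distribution <- function(margins,
                             method = c("superfamily", "family", "quartic",
                                        "exhaustive"),
                             epsilon = 1e-16, safety_factor = 1e-2) {
  method <- match.arg(method)
  switch(method,
         superfamily = tdp_thresholded(margins,
                                       threshold_config(epsilon, safety_factor),
                                       superfamilies = TRUE),
         family = tdp_thresholded(margins,
                                  threshold_config(epsilon, safety_factor),
                                  superfamilies = FALSE),
         quartic = tdp_quartic(margins),
         exhaustive = tdp_exhaustive(margins))
}
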