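test_that("the exhaustive reference reproduces hand-enumerated laws", {
  d <- tdp_exhaustive(tdp_margins(2, 1, 2, 1, 1, 3))
  expect_equal(d$score, -2:2)
  expect_equal(d$prob, c(2, 6, 4, 6, 2) / 20)

  pm <- tdp_exhaustive(tdp_margins(2, 1, 2, 0, 0, 5))
  expect_equal(pm$score, 0L)
  expect_equal(pm$prob, 1)

  hyp <- tdp_exhaustive(tdp_margins(2, 0, 3, 2, 0, 3))
  expect_equal(hyp$prob, dhyper(0:2, 2, 3, 2))

  expect_error(tdp_exhaustive(tdp_margins(40, 40, 40, 40, 40, 40)),
               "cap")
})

test_that("quartic and thresholded algorithms match the reference exactly", {
  # grid over margins at selected ground-set sizes, exhaustive per size
  for (Tn in c(2, 5, 8)) {
    cs <- margin_compositions(Tn)
    for (i in seq_len(nrow(cs))) for (j in seq_len(nrow(cs))) {
      m <- tdp_margins(cs[i, 1], cs[i, 2], cs[i, 3],
                       cs[j, 1], cs[j, 2], cs[j, 3])
      o <- tdp_exhaustive(m)
      for (d in list(tdp_quartic(m),
                     tdp_thresholded(m, superfamilies = FALSE),
                     tdp_thresholded(m, superfamilies = TRUE))) {
        expect_identical(d$score, o$score)
        expect_lt(dist_deviation(o, d)["rel"], 1e-10)
      }
    }
  }
})

test_that("degenerate margins reduce to the hypergeometric law", {
  set.seed(31)
  for (i in 1:50) {
    qp <- sample(0:8, 1); q0 <- sample(0:10, 1)
    np <- sample(0:(qp + q0), 1)
    m <- tdp_margins(qp, 0, q0, np, 0, qp + q0 - np)
    for (d in list(tdp_quartic(m), tdp_thresholded(m))) {
      expect_equal(d$prob, dhyper(d$score, qp, q0, np), tolerance = 1e-10)
    }
  }
})

test_that("margins with no zero class exercise the degenerate start cell", {
  m <- tdp_margins(3, 3, 0, 3, 3, 0)  # q0 + n0 - T + 1 <= 0
  o <- tdp_exhaustive(m)
  expect_lt(dist_deviation(o, tdp_quartic(m))["rel"], 1e-10)
  expect_lt(dist_deviation(o, tdp_thresholded(m))["rel"], 1e-10)
})

test_that("mirror symmetry: swapping n+ and n- negates the score", {
  set.seed(41)
  for (i in 1:20) {
    q <- as.vector(stats::rmultinom(1, 15, c(1, 1, 2)))
    n <- as.vector(stats::rmultinom(1, 15, c(1, 1, 2)))
    a <- tdp_thresholded(tdp_margins(q[1], q[2], q[3], n[1], n[2], n[3]))
    b <- tdp_thresholded(tdp_margins(q[1], q[2], q[3], n[2], n[1], n[3]))
    expect_equal(a$score, -rev(b$score))
    expect_equal(a$prob, rev(b$prob), tolerance = 1e-12)
  }
})

test_that("family optimizer and D-ratio agree with exact enumeration", {
  m <- tdp_margins(2, 1, 2, 2, 1, 2)
  fam <- family_spec(2, 1, 2, 1, m)
  expect_identical(family_opt_u(fam), 1L)
  expect_equal(delta_d(2, fam), 2)

  # single-point family: u is forced to k
  m2 <- tdp_margins(3, 2, 3, 3, 2, 3)
  fam2 <- family_spec(3, 0, 3, 0, m2)
  expect_identical(fam2$u_min, 3L)
  expect_identical(family_opt_u(fam2), 3L)

  # flat symmetric pair
  m3 <- tdp_margins(2, 2, 2, 2, 2, 2)
  fam3 <- family_spec(1, 1, 1, 1, m3)
  expect_equal(delta_d(1, fam3), 1)

  expect_error(family_spec(5, 0, 5, 0, tdp_margins(2, 1, 2, 1, 1, 3)),
               "empty")
})

test_that("delta_d equals the exact ratio of neighboring D-values", {
  set.seed(51)
  checked <- 0
  while (checked < 30) {
    q <- as.vector(stats::rmultinom(1, 12, c(1, 1, 1)))
    n <- as.vector(stats::rmultinom(1, 12, c(1, 1, 1)))
    m <- tdp_margins(q[1], q[2], q[3], n[1], n[2], n[3])
    rp <- sample(0:q[1], 1); rm <- sample(0:q[2], 1)
    t <- rp + rm
    cp_rng <- max(0, t - n[2]):min(n[1], t)
    cp <- sample(cp_rng, 1)
    fam <- tryCatch(family_spec(rp, rm, cp, t - cp, m),
                    error = function(e) NULL)
    if (is.null(fam) || fam$u_min >= fam$u_max) next
    rng <- (fam$u_min + 1):fam$u_max
    u <- if (length(rng) == 1L) rng else sample(rng, 1)
    tab_at <- function(u) {
      mm <- matrix(0L, 3, 3)
      mm[1, 1] <- u; mm[1, 2] <- rp - u
      mm[2, 1] <- cp - u; mm[2, 2] <- rm - cp + u
      mm[1, 3] <- q[1] - rp; mm[2, 3] <- q[2] - rm
      mm[3, 1] <- n[1] - cp; mm[3, 2] <- n[2] - (t - cp)
      mm[3, 3] <- q[3] - mm[3, 1] - mm[3, 2]
      as_contingency3(mm)
    }
    expect_equal(delta_d(u, fam),
                 d_value(tab_at(u - 1)) / d_value(tab_at(u)))
    checked <- checked + 1
  }
})

test_that("global_max_d attains the exhaustive maximum", {
  for (marg in list(tdp_margins(1, 1, 1, 1, 1, 1),
                    tdp_margins(4, 4, 8, 4, 4, 8),
                    tdp_margins(3, 0, 5, 2, 2, 4))) {
    gm <- global_max_d(marg)
    g <- causalsig:::feasible_tables(marg)
    q <- marg$q
    dvals <- choose(q[1], g$i) * choose(q[1] - g$i, g$j) *
      choose(q[2], g$k) * choose(q[2] - g$k, g$l) *
      choose(q[3], g$n0p) * choose(q[3] - g$n0p, g$n0m)
    expect_gte(gm$log_d, log(max(dvals)) - 1e-9)
  }
  # unique table when everything is in the zero class
  gm0 <- global_max_d(tdp_margins(0, 0, 6, 0, 0, 6))
  expect_equal(gm0$log_d, 0)
})

test_that("an extreme threshold keeps only the peak families", {
  m <- tdp_margins(6, 6, 12, 6, 6, 12)
  d <- tdp_thresholded(m, threshold_config(epsilon = 1, safety_factor = 0.99))
  expect_lt(sum(d$prob), 1)
  peak_score <- tdp_score(global_max_d(m)$table)
  expect_true(peak_score %in% d$score)
  expect_gt(attr(d, "stats")$families_skipped, 0)
})

test_that("superfamily pruning spends fewer threshold checks when sparse", {
  m <- tdp_margins(32, 32, 1600, 32, 32, 1600)  # n0 = 50 n+
  a <- tdp_thresholded(m, superfamilies = FALSE)
  b <- tdp_thresholded(m, superfamilies = TRUE)
  sa <- attr(a, "stats"); sb <- attr(b, "stats")
  expect_lt(sb$threshold_checks + sb$superfamily_checks, sa$threshold_checks)
  expect_identical(a$score, b$score)
  expect_lt(dist_deviation(a, b)["rel"], 1e-10)
})

test_that("pruned tables are all below the safety-scaled threshold", {
  # exhaustive soundness audit at small sizes: recompute every table's
  # D-value and check that anything the thresholded run could have skipped
  # really is negligible at the advertised bound
  eps <- 1e-3; sf <- 1e-1
  for (Tn in c(6, 9)) {
    cs <- margin_compositions(Tn)
    set.seed(Tn)
    pick <- sample(nrow(cs), 5)
    for (i in pick) for (j in pick) {
      m <- tdp_margins(cs[i, 1], cs[i, 2], cs[i, 3],
                       cs[j, 1], cs[j, 2], cs[j, 3])
      d <- tdp_thresholded(m, threshold_config(eps, sf))
      o <- tdp_exhaustive(m)
      thr_mass <- eps * sf * exp(global_max_d(m)$log_d - log_d_tot(m))
      miss <- merge(as.data.frame(o), as.data.frame(d), by = "score",
                    all.x = TRUE)
      miss[is.na(miss)] <- 0
      # any mass the pruned run failed to accumulate must come from tables
      # individually below the threshold
      dropped <- miss[, 2] - miss[, 3]
      tables_per_score <- table(
        with(causalsig:::feasible_tables(m), i + l - j - k))
      expect_true(all(dropped <= thr_mass *
                        as.numeric(tables_per_score[as.character(miss$score)])
                      + 1e-12))
    }
  }
})

test_that("pmfs are normalized across algorithms and margins", {
  set.seed(61)
  for (i in 1:15) {
    q <- as.vector(stats::rmultinom(1, 30, c(1, 1, 3)))
    n <- as.vector(stats::rmultinom(1, 30, c(1, 1, 3)))
    m <- tdp_margins(q[1], q[2], q[3], n[1], n[2], n[3])
    expect_equal(sum(tdp_quartic(m)$prob), 1, tolerance = 1e-9)
    expect_equal(sum(tdp_thresholded(m)$prob), 1, tolerance = 1e-9)
    expect_equal(sum(tdp_thresholded(m, superfamilies = FALSE)$prob), 1,
                 tolerance = 1e-9)
  }
})

test_that("per-family sweep work grows subquarticly", {
  steps <- sapply(c(16, 32, 64, 128), function(N) {
    m <- tdp_margins(N, N, 5 * N, N, N, 5 * N)
    attr(tdp_thresholded(m, superfamilies = FALSE), "stats")$sweep_steps
  })
  ratios <- steps[-1] / steps[-length(steps)]
  expect_true(all(ratios < 2^3.5))
})

test_that("f_direct evaluates the inner sum exactly", {
  expect_equal(f_direct(cubic_params(20, 10, 10, 5), 0), 46558512)
  expect_equal(f_direct(cubic_params(20, 10, 10, 5), 0),
               choose(20, 10) * choose(10, 5))
  expect_equal(f_direct(cubic_params(7, 3, 9, 4), 0),
               choose(7, 3) * choose(9, 4))
  expect_equal(f_direct(cubic_params(4, 2, 3, 1), 1), 9)
  expect_error(f_direct(cubic_params(20, 10, 10, 5), 11),
               "standard-binomial regime")
})

test_that("the derived recursion reproduces f_direct exactly", {
  grid <- list(c(20, 10, 10, 5), c(12, 6, 9, 4), c(15, 7, 11, 5),
               c(10, 5, 10, 5), c(16, 8, 12, 6), c(13, 6, 13, 6),
               c(8, 4, 8, 4))
  for (ps in grid) {
    p <- cubic_params(ps[1], ps[2], ps[3], ps[4])
    n_max <- min(ps[1], ps[3])
    seeds <- vapply(0:2, function(n) f_direct(p, n), 0)
    expect_identical(f_recursion(p, seeds, n_end = n_max),
                     vapply(0:n_max, function(n) f_direct(p, n), 0))
  }
})

test_that("the recursion carries a zero tail and respects its domain", {
  p <- cubic_params(20, 2, 10, 8)  # F[n] = 0 for n >= 5
  seeds <- vapply(0:2, function(n) f_direct(p, n), 0)
  vals <- f_recursion(p, seeds, n_end = 10)
  expect_identical(vals[6:11], rep(0, 6))
  expect_error(f_recursion(p, seeds, n_end = 11), "feasible range")
})
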