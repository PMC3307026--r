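#' Randomization chain configuration
#'
#' @param gamma iteration multiplier: the chain performs `gamma * |E|`
#'   proposals (restarts included). Default 100, sufficient in practice for
#'   mixing; convergence diagnostics on large sparse networks suggest much
#'   smaller values already suffice.
#' @param k0 initial number of proposals between connectivity checks.
#' @param q_plus,q_minus multiplicative interval updates: after a successful
#'   connectivity check the interval K grows by the factor `1 + q_plus`;
#'   after a failure it shrinks by `1 - q_minus` and the graph reverts to the
#'   last saved state. Defaults follow the Viger-Latapy heuristic.
#' @param seed optional RNG seed; a fixed seed makes the run reproducible.
#' @return an object of class `randomization_config`.
#' @export
randomization_config <- function(gamma = 100, k0 = 50, q_plus = 0.131,
                                 q_minus = 0.076, seed = NULL) {
  stopifnot(gamma >= 1, k0 >= 1, q_plus > 0, q_minus > 0, q_minus < 1)
  structure(list(gamma = gamma, k0 = k0, q_plus = q_plus, q_minus = q_minus,
                 seed = seed),
            class = "randomization_config")
}

#' Randomize a signed digraph preserving its degree signature
#'
#' Markov-chain randomization by same-sign edge switches and triangle flips.
#' Each proposal draws two distinct edges uniformly at random; illegal
#' proposals restart. Weak connectivity (a global property) is verified only
#' every K proposals: on success the state is saved and K grows, on failure
#' the graph reverts to the last saved state and K shrinks (dynamic-interval
#' heuristic). The returned graph has the same signed degree signature as the
#' input, is simple, and is weakly connected.
#'
#' @param g a simple, weakly connected [signed_digraph()] with >= 2 edges.
#' @param config a [randomization_config()].
#' @return list with `graph` (the randomized graph) and `stats`, a list of
#'   run statistics: `proposals`, `accepted_switches`, `accepted_flips`,
#'   `connectivity_checks`, `connectivity_failures`, obstacle encounter
#'   counts (`strong_quadrilaterals`, `strong_triangles`,
#'   `flippable_triangles`) and the trace `k_trace` of check intervals.
#' @export
randomize <- function(g, config = randomization_config()) {
  stopifnot(inherits(g, "signed_digraph"),
            inherits(config, "randomization_config"))
  ne <- length(g$from)
  if (ne < 2L) stop("graph must have at least two edges", call. = FALSE)
  if (!is_weakly_connected(g)) {
    stop("input graph must be weakly connected", call. = FALSE)
  }
  if (!is.null(config$seed)) set.seed(config$seed)

  st <- chain_state(g)
  saved <- state_snapshot(st)
  total <- ceiling(config$gamma * ne)
  K <- config$k0
  since_check <- 0L
  stats <- list(proposals = 0L, accepted_switches = 0L, accepted_flips = 0L,
                connectivity_checks = 0L, connectivity_failures = 0L,
                strong_quadrilaterals = 0L, strong_triangles = 0L,
                flippable_triangles = 0L, k_trace = numeric(0))

  run_check <- function() {
    stats$connectivity_checks <<- stats$connectivity_checks + 1L
    if (uf_connected(st$from, st$to, st$nv)) {
      saved <<- state_snapshot(st)
      K <<- K * (1 + config$q_plus)
    } else {
      stats$connectivity_failures <<- stats$connectivity_failures + 1L
      state_restore(st, saved)
      K <<- max(1, K * (1 - config$q_minus))
    }
    stats$k_trace <<- c(stats$k_trace, K)
    since_check <<- 0L
  }

  for (it in seq_len(total)) {
    idx <- sample.int(ne, 2L)
    res <- chain_propose(st, idx[1L], idx[2L])
    stats$proposals <- stats$proposals + 1L
    if (res$applied) {
      if (res$type == "switch") {
        stats$accepted_switches <- stats$accepted_switches + 1L
      } else {
        stats$accepted_flips <- stats$accepted_flips + 1L
      }
    }
    if (!is.na(res$obstacle)) {
      if (res$obstacle == "strong_quadrilateral") {
        stats$strong_quadrilaterals <- stats$strong_quadrilaterals + 1L
      } else {
        stats$strong_triangles <- stats$strong_triangles + 1L
      }
    }
    if (isTRUE(res$flippable)) {
      stats$flippable_triangles <- stats$flippable_triangles + 1L
    }
    since_check <- since_check + 1L
    if (since_check >= round(K)) run_check()
  }
  if (since_check > 0L) run_check()
  if (!uf_connected(st$from, st$to, st$nv)) state_restore(st, saved)

  list(graph = state_graph(st, g), stats = stats)
}

#' Sample chain states with per-move connectivity enforcement
#'
#' Runs the randomization chain with a connectivity check after every
#' accepted move (reverting immediately on failure), recording the canonical
#' key of the current state at a fixed thinning interval. Because proposals
#' are symmetric and rejections keep the chain in place, the stationary
#' distribution is uniform over the states reachable by legal moves; this
#' sampler supports empirical uniformity diagnostics against
#' [enumerate_state_space()].
#'
#' @param g a simple, weakly connected [signed_digraph()].
#' @param n_samples number of state keys to record.
#' @param thin proposals between recorded samples.
#' @param burn_in proposals discarded before recording.
#' @param seed optional RNG seed.
#' @return character vector of `n_samples` canonical state keys.
#' @export
chain_states <- function(g, n_samples, thin = 1L, burn_in = 0L, seed = NULL) {
  stopifnot(inherits(g, "signed_digraph"))
  if (!is_weakly_connected(g)) {
    stop("input graph must be weakly connected", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  ne <- length(g$from)
  st <- chain_state(g)
  saved <- state_snapshot(st)
  out <- character(n_samples)
  rec <- 0L
  it <- 0L
  while (rec < n_samples) {
    it <- it + 1L
    idx <- sample.int(ne, 2L)
    res <- chain_propose(st, idx[1L], idx[2L])
    if (res$applied) {
      if (uf_connected(st$from, st$to, st$nv)) {
        saved <- state_snapshot(st)
      } else {
        state_restore(st, saved)
      }
    }
    if (it > burn_in && (it - burn_in) %% thin == 0L) {
      rec <- rec + 1L
      out[rec] <- state_key(st)
    }
  }
  out
}

#' Enumerate the state space of degree-preserving randomizations
#'
#' Exhaustively lists every simple, weakly connected signed digraph on the
#' same vertex set with the same signed degree signature as `g`, by
#' backtracking over ordered vertex pairs. This is the brute-force reference
#' for chain diagnostics; some members may be unreachable by switches and
#' flips alone (a 3-swap would be required), which is why uniformity tests
#' first verify move-connectivity of the state space.
#'
#' @param g a [signed_digraph()].
#' @param max_edges refuse graphs with more edges than this (default 12).
#' @return character vector of canonical keys (see [canonical_key()]) of all
#'   members of the state space.
#' @export
enumerate_state_space <- function(g, max_edges = 12L) {
  stopifnot(inherits(g, "signed_digraph"))
  ne <- length(g$from)
  if (ne > max_edges) {
    stop("graph has ", ne, " edges, above the enumeration cap (", max_edges,
         ")", call. = FALSE)
  }
  sig <- degree_signature(g)
  nv <- nrow(sig)
  pairs <- which(outer(seq_len(nv), seq_len(nv), "!="), arr.ind = TRUE)
  pairs <- pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]
  out_p <- sig[, "out_plus"]; out_m <- sig[, "out_minus"]
  in_p <- sig[, "in_plus"]; in_m <- sig[, "in_minus"]
  results <- character(0)
  edges_from <- integer(ne); edges_to <- integer(ne); edges_sign <- integer(ne)

  recurse <- function(pi, k, op, om, ip, im) {
    if (pi > nrow(pairs)) {
      if (all(op == 0L) && all(om == 0L)) {
        if (uf_connected(edges_from[seq_len(k)], edges_to[seq_len(k)], nv)) {
          gg <- g
          gg$from <- edges_from[seq_len(k)]
          gg$to <- edges_to[seq_len(k)]
          gg$sign <- edges_sign[seq_len(k)]
          results <<- c(results, canonical_key(gg))
        }
      }
      return(invisible())
    }
    a <- pairs[pi, 1]; b <- pairs[pi, 2]
    # prune: remaining out-degree of a must fit in remaining pairs from a
    rem_a <- sum(pairs[pi:nrow(pairs), 1] == a)
    if (op[a] + om[a] > rem_a) return(invisible())
    # option: no edge a -> b
    recurse(pi + 1L, k, op, om, ip, im)
    # option: positive edge
    if (op[a] > 0L && ip[b] > 0L) {
      edges_from[k + 1L] <<- a; edges_to[k + 1L] <<- b
      edges_sign[k + 1L] <<- 1L
      op2 <- op; ip2 <- ip; op2[a] <- op2[a] - 1L; ip2[b] <- ip2[b] - 1L
      recurse(pi + 1L, k + 1L, op2, om, ip2, im)
    }
    # option: negative edge
    if (om[a] > 0L && im[b] > 0L) {
      edges_from[k + 1L] <<- a; edges_to[k + 1L] <<- b
      edges_sign[k + 1L] <<- -1L
      om2 <- om; im2 <- im; om2[a] <- om2[a] - 1L; im2[b] <- im2[b] - 1L
      recurse(pi + 1L, k + 1L, op, om2, ip, im2)
    }
    invisible()
  }
  recurse(1L, 0L, out_p, out_m, in_p, in_m)
  sort(unique(results))
}

# All graphs reachable from g by one legal (connectivity-preserving) move;
# used to verify that the move graph over a state space is connected.
neighbor_states <- function(g) {
  ne <- length(g$from)
  keys <- character(0)
  for (i in 1:(ne - 1L)) for (j in (i + 1L):ne) {
    for (ord in list(c(i, j), c(j, i))) {
      st <- chain_state(g)
      res <- chain_propose(st, ord[1], ord[2])
      if (res$applied && uf_connected(st$from, st$to, st$nv)) {
        keys <- c(keys, state_key(st))
      }
    }
  }
  sort(unique(keys))
}
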