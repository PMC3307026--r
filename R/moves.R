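# Local moves of the randomization Markov chain: same-sign edge switches and
# same-sign triangle flips, both of which preserve the signed degree
# signature and simplicity.

# Apply one proposal to a mutable chain state, given two distinct edge
# indices. Returns a list(type, applied, reason, obstacle) where obstacle is
# NA or one of "strong_quadrilateral", "strong_triangle", and flippable is
# TRUE when a legal triangle flip was identified.
chain_propose <- function(st, i1, i2) {
  s <- st$sign[i1]
  if (s != st$sign[i2]) {
    return(list(type = "restart", applied = FALSE, reason = "sign mismatch",
                obstacle = NA_character_, flippable = FALSE))
  }
  a <- st$from[i1]; b <- st$to[i1]; cc <- st$from[i2]; d <- st$to[i2]
  shared <- (a == cc) + (a == d) + (b == cc) + (b == d)
  if (shared == 0L) {
    # edge switch: (a,b),(c,d) -> (a,d),(c,b)
    if (st$adj[a, d] != 0L || st$adj[cc, b] != 0L) {
      obst <- if (st$adj[a, d] == -s && st$adj[cc, b] == -s)
        "strong_quadrilateral" else NA_character_
      return(list(type = "switch", applied = FALSE,
                  reason = "would create a parallel edge", obstacle = obst,
                  flippable = FALSE))
    }
    st$adj[a, b] <- 0L; st$adj[cc, d] <- 0L
    st$eidx[a, b] <- 0L; st$eidx[cc, d] <- 0L
    st$adj[a, d] <- s; st$adj[cc, b] <- s
    st$eidx[a, d] <- i1; st$eidx[cc, b] <- i2
    st$to[i1] <- d; st$to[i2] <- b
    return(list(type = "switch", applied = TRUE, reason = NA_character_,
                obstacle = NA_character_, flippable = FALSE))
  }
  if (shared == 1L && (b == cc || d == a)) {
    # consecutive edges of a potential directed triangle
    if (b == cc) { va <- a; vb <- b; vc <- d } else { va <- cc; vb <- a; vc <- b }
    # cycle va -> vb -> vc -> va; need the closing edge with the same sign
    if (st$adj[vc, va] == s) {
      return(apply_flip(st, va, vb, vc, s))
    }
  }
  list(type = "restart", applied = FALSE,
       reason = "edges do not form a switchable pair or a same-sign triangle",
       obstacle = NA_character_, flippable = FALSE)
}

# Flip the same-sign directed 3-cycle (a,b),(b,c),(c,a) in place if legal.
apply_flip <- function(st, a, b, cc, s) {
  if (st$adj[a, cc] != 0L || st$adj[cc, b] != 0L || st$adj[b, a] != 0L) {
    obst <- if (st$adj[a, cc] == -s && st$adj[cc, b] == -s &&
                st$adj[b, a] == -s) "strong_triangle" else NA_character_
    return(list(type = "flip", applied = FALSE,
                reason = "reversed cycle blocked by existing edges",
                obstacle = obst, flippable = FALSE))
  }
  e1 <- st$eidx[a, b]; e2 <- st$eidx[b, cc]; e3 <- st$eidx[cc, a]
  st$adj[a, b] <- 0L; st$adj[b, cc] <- 0L; st$adj[cc, a] <- 0L
  st$eidx[a, b] <- 0L; st$eidx[b, cc] <- 0L; st$eidx[cc, a] <- 0L
  st$adj[a, cc] <- s; st$adj[cc, b] <- s; st$adj[b, a] <- s
  st$eidx[a, cc] <- e1; st$eidx[cc, b] <- e3; st$eidx[b, a] <- e2
  st$to[e1] <- cc
  st$from[e2] <- b; st$to[e2] <- a
  st$from[e3] <- cc; st$to[e3] <- b
  list(type = "flip", applied = TRUE, reason = NA_character_,
       obstacle = NA_character_, flippable = TRUE)
}

resolve_edge <- function(g, e) {
  if (is.numeric(e) && length(e) == 1L) {
    if (e < 1 || e > length(g$from)) stop("edge index out of range",
                                          call. = FALSE)
    return(as.integer(e))
  }
  if (length(e) == 2L) {
    fi <- match(as.character(e[1]), g$vertices)
    ti <- match(as.character(e[2]), g$vertices)
    hit <- which(g$from == fi & g$to == ti)
    if (length(hit) == 1L) return(hit)
  }
  stop("edge not present in the graph", call. = FALSE)
}

#' Same-sign edge switch
#'
#' Replaces edges `(a, b)` and `(c, d)` by `(a, d)` and `(c, b)`. Applied
#' only if the two edges have equal sign and neither `(a, d)` nor `(c, b)`
#' exists in either sign (which also excludes self-edges); otherwise the move
#' is rejected with a reason. Degree signature and simplicity are preserved.
#'
#' @param g a [signed_digraph()].
#' @param e1,e2 edges: integer index into [edge_table()] or a `c(from, to)`
#'   character pair.
#' @return list with `graph` (the new graph, or the input if rejected),
#'   `applied`, `reason` and `obstacle` (`"strong_quadrilateral"` when the
#'   switch was blocked by both crossing edges of opposite sign).
#' @export
edge_switch <- function(g, e1, e2) {
  stopifnot(inherits(g, "signed_digraph"))
  i1 <- resolve_edge(g, e1); i2 <- resolve_edge(g, e2)
  if (i1 == i2) stop("e1 and e2 must be distinct edges", call. = FALSE)
  st <- chain_state(g)
  a <- st$from[i1]; b <- st$to[i1]; cc <- st$from[i2]; d <- st$to[i2]
  if (st$sign[i1] != st$sign[i2]) {
    return(list(graph = g, applied = FALSE, reason = "sign mismatch",
                obstacle = NA_character_))
  }
  if ((a == cc) + (a == d) + (b == cc) + (b == d) > 0L) {
    return(list(graph = g, applied = FALSE, reason = "edges share an endpoint",
                obstacle = NA_character_))
  }
  res <- chain_propose(st, i1, i2)
  list(graph = if (res$applied) state_graph(st, g) else g,
       applied = res$applied, reason = res$reason, obstacle = res$obstacle)
}

#' Same-sign triangle flip
#'
#' Replaces the directed 3-cycle `(a,b), (b,c), (c,a)` (all of sign `sign`)
#' by the reversed cycle `(a,c), (c,b), (b,a)` with the same sign. Applied
#' only if none of the reversed edges exists in either sign.
#'
#' @param g a [signed_digraph()].
#' @param a,b,c vertex ids of the cycle, in cycle order.
#' @param sign common sign of the cycle edges.
#' @return list with `graph`, `applied`, `reason`, `obstacle`
#'   (`"strong_triangle"` when the reversed cycle exists with opposite sign).
#' @export
triangle_flip <- function(g, a, b, c, sign = 1L) {
  stopifnot(inherits(g, "signed_digraph"))
  s <- parse_sign(sign)
  ia <- match(as.character(a), g$vertices)
  ib <- match(as.character(b), g$vertices)
  ic <- match(as.character(c), g$vertices)
  if (anyNA(c(ia, ib, ic))) stop("unknown vertex", call. = FALSE)
  st <- chain_state(g)
  have <- c(st$adj[ia, ib], st$adj[ib, ic], st$adj[ic, ia])
  if (any(have == 0L)) stop("cycle edges missing from the graph",
                            call. = FALSE)
  if (!all(have == s)) {
    return(list(graph = g, applied = FALSE,
                reason = "not a same-sign directed triangle",
                obstacle = NA_character_))
  }
  res <- apply_flip(st, ia, ib, ic, s)
  list(graph = if (res$applied) state_graph(st, g) else g,
       applied = res$applied, reason = res$reason, obstacle = res$obstacle)
}

#' Propose one chain move
#'
#' Picks two distinct edges uniformly at random (or uses the given pair) and
#' classifies the proposal the way the randomization chain does: edges of
#' different sign restart; disjoint edges propose an edge switch; edges
#' sharing one endpoint that belong to a same-sign directed triangle propose
#' a triangle flip; every failed check is a restart.
#'
#' @param g a [signed_digraph()].
#' @param edges optional integer pair of edge indices (sampled when omitted).
#' @return list with `type` (`"switch"`, `"flip"` or `"restart"`), `edges`,
#'   `applied`, `reason`, `obstacle`, and `graph` (new graph when applied).
#' @export
propose_move <- function(g, edges = NULL) {
  stopifnot(inherits(g, "signed_digraph"))
  ne <- length(g$from)
  if (ne < 2L) stop("need at least two edges", call. = FALSE)
  if (is.null(edges)) edges <- sample.int(ne, 2L)
  stopifnot(length(edges) == 2L, edges[1] != edges[2])
  st <- chain_state(g)
  res <- chain_propose(st, as.integer(edges[1]), as.integer(edges[2]))
  list(type = if (res$applied) res$type else "restart",
       edges = as.integer(edges), applied = res$applied,
       reason = res$reason, obstacle = res$obstacle,
       graph = if (res$applied) state_graph(st, g) else g)
}

#' Count local obstacle structures
#'
#' Exhaustively counts, by local search: strong quadrilaterals (a same-sign
#' edge pair `(a,b)`, `(c,d)` on four distinct vertices whose crossing edges
#' `(a,d)`, `(c,b)` both exist with the opposite sign — blocking the switch
#' although the sign-swapped graph is a valid randomization); strong
#' triangles (a positive directed 3-cycle whose reversed cycle exists with
#' negative sign — blocking both flips); and flippable triangles (same-sign
#' directed 3-cycles whose flip is legal). Intended for small graphs and
#' diagnostics.
#'
#' @param g a [signed_digraph()].
#' @return list with counts `strong_quadrilaterals`, `strong_triangles`,
#'   `flippable_triangles`.
#' @export
detect_obstacles <- function(g) {
  stopifnot(inherits(g, "signed_digraph"))
  st <- chain_state(g)
  ne <- length(g$from)
  sq <- 0L
  if (ne >= 2L) {
    # each strong quadrilateral is counted once, from its positive edge pair
    for (i in 1:(ne - 1L)) for (j in (i + 1L):ne) {
      if (st$sign[i] != 1L || st$sign[j] != 1L) next
      a <- st$from[i]; b <- st$to[i]; cc <- st$from[j]; d <- st$to[j]
      if ((a == cc) + (a == d) + (b == cc) + (b == d) > 0L) next
      if (st$adj[a, d] == -1L && st$adj[cc, b] == -1L) sq <- sq + 1L
    }
  }
  strong_tri <- 0L; flippable <- 0L
  nv <- st$nv
  if (nv >= 3L) {
    # vertex triples a < b < cc; the two cyclic orientations cover each
    # directed 3-cycle exactly once
    for (a in 1:nv) for (b in 1:nv) for (cc in 1:nv) {
      if (a >= b || b >= cc) next
      for (perm in list(c(a, b, cc), c(a, cc, b))) {
        va <- perm[1]; vb <- perm[2]; vc <- perm[3]
        s <- st$adj[va, vb]
        if (s != 0L && st$adj[vb, vc] == s && st$adj[vc, va] == s) {
          rev_s <- c(st$adj[va, vc], st$adj[vc, vb], st$adj[vb, va])
          if (all(rev_s == 0L)) flippable <- flippable + 1L
          if (s == 1L && all(rev_s == -1L)) strong_tri <- strong_tri + 1L
        }
      }
    }
  }
  list(strong_quadrilaterals = sq, strong_triangles = strong_tri,
       flippable_triangles = flippable)
}

#' Flip a strong triangle using auxiliary edges
#'
#' Demonstrates that a strong triangle is not a true obstacle in a large
#' sparse graph: given three positive auxiliary edges pairwise disjoint and
#' disjoint from the triangle, a fixed sequence of nine legal moves (three
#' opening switches, one triangle flip, three closing switches, two restoring
#' switches) swaps the signs of the two triangle orientations and restores
#' the auxiliary edges. Not a chain move — a diagnostic construction.
#'
#' @param g a [signed_digraph()] containing a strong triangle with positive
#'   cycle `(a,b), (b,c), (c,a)`.
#' @param triangle character vector `c(a, b, c)` in positive-cycle order.
#' @param aux list of three character pairs `c(a1,a2), c(b1,b2), c(c1,c2)`:
#'   positive edges pairwise disjoint and disjoint from the triangle.
#' @return the transformed `signed_digraph`.
#' @export
flip_strong_triangle_aux <- function(g, triangle, aux) {
  stopifnot(inherits(g, "signed_digraph"), length(triangle) == 3L,
            length(aux) == 3L)
  verts <- unlist(aux)
  if (length(unique(c(verts, triangle))) != 9L) {
    stop("auxiliary edges must be pairwise disjoint and disjoint from the ",
         "triangle", call. = FALSE)
  }
  a <- triangle[1]; b <- triangle[2]; cc <- triangle[3]
  a1 <- aux[[1]][1]; a2 <- aux[[1]][2]
  b1 <- aux[[2]][1]; b2 <- aux[[2]][2]
  c1 <- aux[[3]][1]; c2 <- aux[[3]][2]
  do_switch <- function(g, e1, e2, phase) {
    r <- edge_switch(g, e1, e2)
    if (!r$applied) {
      stop("illegal move during ", phase, ": ", r$reason, call. = FALSE)
    }
    r$graph
  }
  # Opening
  g <- do_switch(g, c(a, b), c(c1, c2), "opening")
  g <- do_switch(g, c(b, cc), c(a1, a2), "opening")
  g <- do_switch(g, c(cc, a), c(b1, b2), "opening")
  # Flipping: the (previously blocked) negative cycle a -> c -> b -> a
  r <- triangle_flip(g, a, cc, b, sign = -1L)
  if (!r$applied) stop("illegal move during flipping: ", r$reason,
                       call. = FALSE)
  g <- r$graph
  # Closing
  g <- do_switch(g, c(a1, cc), c(a, c2), "closing")
  g <- do_switch(g, c(b1, a), c(b, a2), "closing")
  g <- do_switch(g, c(c1, b), c(cc, b2), "closing")
  # Restoring
  g <- do_switch(g, c(b1, a2), c(c1, b2), "restoring")
  g <- do_switch(g, c(c1, a2), c(a1, c2), "restoring")
  g
}
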