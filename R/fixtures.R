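# Seeded generators of classifications and connected signed digraphs, so that
# every module is testable without external data.

#' Generate a random ternary classification with fixed margins
#'
#' A uniformly random arrangement of the prescribed counts of +1, -1 and 0
#' over the ground set — exactly the null model of the ternary dot product
#' distribution.
#'
#' @param n_plus,n_minus,n_zero counts of each value.
#' @param seed optional RNG seed (deterministic output per seed).
#' @param ids optional element ids.
#' @return a [ternary_classification()].
#' @export
gen_classification <- function(n_plus, n_minus, n_zero, seed = NULL,
                               ids = NULL) {
  if (!is.null(seed)) set.seed(seed)
  vals <- sample(rep(c(1L, -1L, 0L), times = c(n_plus, n_minus, n_zero)))
  ternary_classification(vals, ids = ids)
}

#' Generate a connected simple signed digraph
#'
#' Builds a random spanning tree first (guaranteeing weak connectivity by
#' construction), with random edge orientations and signs drawn to meet the
#' requested sign-stratified counts, then adds the remaining arcs by
#' rejection sampling of duplicate ordered pairs and self-loops.
#'
#' @param n_vertices number of vertices (labelled `v1`, `v2`, ...).
#' @param n_pos,n_neg number of positive and negative edges; the total must
#'   be at least `n_vertices - 1` (connectivity) and at most
#'   `n_vertices * (n_vertices - 1)` (simplicity).
#' @param seed optional RNG seed.
#' @return a [signed_digraph()].
#' @export
gen_connected_signed_graph <- function(n_vertices, n_pos, n_neg,
                                       seed = NULL) {
  ne <- n_pos + n_neg
  if (ne < n_vertices - 1L) {
    stop("too few edges for a connected graph", call. = FALSE)
  }
  if (ne > n_vertices * (n_vertices - 1L)) {
    stop("too many edges for a simple digraph", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  signs <- sample(rep(c(1L, -1L), times = c(n_pos, n_neg)))
  from <- integer(ne); to <- integer(ne)
  # random spanning tree: attach each new vertex to a uniform earlier one,
  # with random edge orientation
  order_v <- sample.int(n_vertices)
  for (i in seq_len(n_vertices - 1L)) {
    u <- order_v[i + 1L]
    w <- order_v[sample.int(i, 1L)]
    if (stats::runif(1) < 0.5) { from[i] <- u; to[i] <- w }
    else { from[i] <- w; to[i] <- u }
  }
  k <- n_vertices - 1L
  guard <- 0L
  while (k < ne) {
    u <- sample.int(n_vertices, 1L); w <- sample.int(n_vertices, 1L)
    guard <- guard + 1L
    if (guard > 1e6) stop("rejection sampling failed; graph too dense",
                          call. = FALSE)
    if (u == w) next
    if (any(from[seq_len(k)] == u & to[seq_len(k)] == w)) next
    k <- k + 1L
    from[k] <- u; to[k] <- w
  }
  v <- paste0("v", seq_len(n_vertices))
  signed_digraph(v[from], v[to], signs, vertices = v)
}
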