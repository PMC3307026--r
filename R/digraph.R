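#' Simple signed directed graph
#'
#' A causal graph: vertices are biological entities, a directed edge
#' `(a, b)` with sign +1 (-1) means `a` up- (down-) regulates `b`.
#' Self-edges are disallowed and there is at most one edge per ordered vertex
#' pair regardless of sign; anti-parallel pairs (`a -> b` and `b -> a`) are
#' allowed.
#'
#' @param from,to vertex identifiers (character) or indices into `vertices`.
#' @param sign edge signs: one of `1`, `-1`, `"+"`, `"-"`, `"1"`, `"-1"` per
#'   edge.
#' @param vertices optional character vector of all vertex ids (isolated
#'   vertices are kept); inferred from the edges when omitted.
#' @param transcript optional logical vector flagging which vertices are
#'   measurable transcripts (used when scoring hypotheses); default all.
#' @return an object of class `signed_digraph`.
#' @examples
#' g <- signed_digraph(c("a", "b"), c("b", "c"), c("+", "-"))
#' @export
signed_digraph <- function(from, to, sign, vertices = NULL,
                           transcript = NULL) {
  sgn <- parse_sign(sign)
  from <- as.character(from); to <- as.character(to)
  stopifnot(length(from) == length(to), length(from) == length(sgn))
  if (is.null(vertices)) {
    vertices <- sort(unique(c(from, to)))
  } else {
    vertices <- as.character(vertices)
    if (!all(c(from, to) %in% vertices)) {
      stop("edge endpoints must be listed in `vertices`", call. = FALSE)
    }
  }
  fi <- match(from, vertices); ti <- match(to, vertices)
  if (any(fi == ti)) stop("self-edges are not allowed", call. = FALSE)
  if (anyDuplicated(cbind(fi, ti))) {
    stop("parallel edges are not allowed (at most one edge per ordered pair)",
         call. = FALSE)
  }
  if (is.null(transcript)) transcript <- rep(TRUE, length(vertices))
  stopifnot(length(transcript) == length(vertices))
  structure(list(vertices = vertices, from = fi, to = ti,
                 sign = as.integer(sgn), transcript = as.logical(transcript)),
            class = "signed_digraph")
}

parse_sign <- function(sign) {
  s <- ifelse(sign %in% list("+", "1", 1, "+1"), 1L,
              ifelse(sign %in% list("-", "-1", -1), -1L, NA_integer_))
  if (anyNA(s)) stop("edge signs must be +1 or -1", call. = FALSE)
  s
}

#' @export
print.signed_digraph <- function(x, ...) {
  cat("Signed digraph:", length(x$vertices), "vertices,",
      sum(x$sign == 1L), "positive /", sum(x$sign == -1L),
      "negative edges\n")
  invisible(x)
}

#' Edge table of a signed digraph
#'
#' @param g a [signed_digraph()].
#' @return data.frame with character columns `from`, `to` and integer `sign`.
#' @export
edge_table <- function(g) {
  stopifnot(inherits(g, "signed_digraph"))
  data.frame(from = g$vertices[g$from], to = g$vertices[g$to],
             sign = g$sign, stringsAsFactors = FALSE)
}

#' Signed degree signature
#'
#' Per-vertex positive and negative in- and out-degrees; the invariant
#' preserved by graph randomization.
#'
#' @param g a [signed_digraph()].
#' @return integer matrix with one row per vertex and columns `out_plus`,
#'   `out_minus`, `in_plus`, `in_minus`.
#' @export
degree_signature <- function(g) {
  stopifnot(inherits(g, "signed_digraph"))
  nv <- length(g$vertices)
  m <- cbind(
    out_plus  = tabulate(g$from[g$sign == 1L], nv),
    out_minus = tabulate(g$from[g$sign == -1L], nv),
    in_plus   = tabulate(g$to[g$sign == 1L], nv),
    in_minus  = tabulate(g$to[g$sign == -1L], nv))
  rownames(m) <- g$vertices
  m
}

#' Weak connectivity
#'
#' TRUE iff the shadow graph obtained by ignoring edge signs and directions
#' has a single connected component. Computed by union-find.
#'
#' @param g a [signed_digraph()].
#' @return logical.
#' @export
is_weakly_connected <- function(g) {
  stopifnot(inherits(g, "signed_digraph"))
  uf_connected(g$from, g$to, length(g$vertices))
}

uf_connected <- function(from, to, nv) {
  if (nv <= 1L) return(TRUE)
  parent <- seq_len(nv)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (e in seq_along(from)) {
    a <- find(from[e]); b <- find(to[e])
    if (a != b) parent[a] <- b
  }
  length(unique(vapply(seq_len(nv), find, 1L))) == 1L
}

# Sign of the edge a -> b (vertex indices), or 0 if absent.
edge_sign_at <- function(g, a, b) {
  hit <- which(g$from == a & g$to == b)
  if (length(hit) == 0L) 0L else g$sign[hit[1L]]
}

#' Canonical key of a signed digraph
#'
#' A string identifying the graph's edge set (with signs) uniquely given the
#' vertex set; used to compare chain states against enumerated state spaces.
#'
#' @param g a [signed_digraph()].
#' @return character scalar.
#' @export
canonical_key <- function(g) {
  stopifnot(inherits(g, "signed_digraph"))
  paste(sort(paste0(g$from, ">", g$to, ":", g$sign)), collapse = ";")
}

# --- internal mutable chain state -----------------------------------------

# adjacency/edge-index matrices allow O(1) existence checks and updates
chain_state <- function(g) {
  nv <- length(g$vertices)
  adj <- matrix(0L, nv, nv)
  eidx <- matrix(0L, nv, nv)
  adj[cbind(g$from, g$to)] <- g$sign
  eidx[cbind(g$from, g$to)] <- seq_along(g$from)
  env <- new.env(parent = emptyenv())
  env$from <- g$from; env$to <- g$to; env$sign <- g$sign
  env$adj <- adj; env$eidx <- eidx; env$nv <- nv
  env
}

state_snapshot <- function(st) {
  list(from = st$from, to = st$to, sign = st$sign,
       adj = st$adj, eidx = st$eidx)
}

state_restore <- function(st, snap) {
  st$from <- snap$from; st$to <- snap$to; st$sign <- snap$sign
  st$adj <- snap$adj; st$eidx <- snap$eidx
  invisible(st)
}

state_graph <- function(st, g) {
  out <- g
  out$from <- st$from; out$to <- st$to; out$sign <- st$sign
  out
}

state_key <- function(st) {
  paste(sort(paste0(st$from, ">", st$to, ":", st$sign)), collapse = ";")
}
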