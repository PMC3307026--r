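# Shared fixtures and comparison helpers, all built in code.

# all compositions of Tn into three non-negative parts
margin_compositions <- function(Tn) {
  g <- expand.grid(a = 0:Tn, b = 0:Tn)
  g <- g[g$a + g$b <= Tn, , drop = FALSE]
  cbind(g$a, g$b, Tn - g$a - g$b)
}

# worst absolute and relative pmf deviation between two distributions,
# restricted to scores where either probability exceeds `floor`
dist_deviation <- function(a, b, floor = 1e-12) {
  m <- merge(as.data.frame(a), as.data.frame(b), by = "score", all = TRUE)
  m[is.na(m)] <- 0
  keep <- pmax(m[, 2], m[, 3]) >= floor
  if (!any(keep)) return(c(abs = 0, rel = 0))
  c(abs = max(abs(m[keep, 2] - m[keep, 3])),
    rel = max(abs(m[keep, 2] - m[keep, 3]) / pmax(m[keep, 2], m[keep, 3])))
}

# strong quadrilateral: (a,b)+, (c,d)+ with crossing (a,d)-, (c,b)-
strong_quadrilateral_graph <- function() {
  signed_digraph(c("a", "c", "a", "c"), c("b", "d", "d", "b"),
                 c(1, 1, -1, -1))
}

# strong triangle: positive 3-cycle a->b->c->a with its reversal negative
strong_triangle_graph <- function() {
  signed_digraph(c("a", "b", "c", "a", "c", "b"),
                 c("b", "c", "a", "c", "b", "a"),
                 c(1, 1, 1, -1, -1, -1))
}

# strong triangle plus three disjoint positive auxiliary edges
strong_triangle_aux_graph <- function() {
  signed_digraph(
    from = c("a", "b", "c", "a", "c", "b", "a1", "b1", "c1"),
    to   = c("b", "c", "a", "c", "b", "a", "a2", "b2", "c2"),
    sign = c(1, 1, 1, -1, -1, -1, 1, 1, 1))
}

# directed path a -> b -> c -> d, all positive
path_graph <- function() {
  signed_digraph(c("a", "b", "c"), c("b", "c", "d"), c(1, 1, 1))
}

# parse a canonical state key back into a graph over the template's vertices
graph_from_key <- function(key, template) {
  parts <- strsplit(strsplit(key, ";", fixed = TRUE)[[1]], "[>:]")
  g <- template
  g$from <- as.integer(vapply(parts, `[`, "", 1))
  g$to <- as.integer(vapply(parts, `[`, "", 2))
  g$sign <- as.integer(vapply(parts, `[`, "", 3))
  g
}
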