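# Plain-text readers and writers: classification TSVs and signed-graph edge
# lists (TSV and a SIF-like dialect).

#' Read a ternary classification from TSV
#'
#' Two tab-separated columns: `id`, `value`. Values may be `-1`, `0`, `1` or
#' the case-insensitive aliases `down`, `none`, `up`.
#'
#' @param path file path.
#' @param header file has a header line (default FALSE).
#' @return a [ternary_classification()].
#' @export
read_classification <- function(path, header = FALSE) {
  d <- utils::read.table(path, sep = "\t", header = header,
                         colClasses = "character", quote = "",
                         comment.char = "")
  if (ncol(d) < 2L) stop("expected two columns: id, value", call. = FALSE)
  raw <- tolower(trimws(d[[2]]))
  val <- ifelse(raw %in% c("1", "+1", "up"), 1L,
                ifelse(raw %in% c("-1", "down"), -1L,
                       ifelse(raw %in% c("0", "none"), 0L, NA_integer_)))
  if (anyNA(val)) {
    stop("unrecognized classification value(s): ",
         paste(unique(d[[2]][is.na(val)]), collapse = ", "), call. = FALSE)
  }
  ternary_classification(val, ids = trimws(d[[1]]))
}

#' Write a ternary classification to TSV
#'
#' @param x a [ternary_classification()] with ids.
#' @param path output path.
#' @export
write_classification <- function(x, path) {
  stopifnot(inherits(x, "ternary_classification"), !is.null(names(x)))
  utils::write.table(data.frame(id = names(x), value = as.integer(x)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
}

#' Read a signed digraph from a TSV edge list
#'
#' Three tab-separated columns: `source`, `target`, `sign`, with sign one of
#' `+`, `-`, `1`, `-1`.
#'
#' @param path file path.
#' @param header file has a header line (default FALSE).
#' @return a [signed_digraph()].
#' @export
read_graph_tsv <- function(path, header = FALSE) {
  d <- utils::read.table(path, sep = "\t", header = header,
                         colClasses = "character", quote = "",
                         comment.char = "")
  if (ncol(d) < 3L) stop("expected three columns: source, target, sign",
                         call. = FALSE)
  signed_digraph(trimws(d[[1]]), trimws(d[[2]]), trimws(d[[3]]))
}

#' Read a signed digraph from a SIF-like file
#'
#' Whitespace-separated lines `source relation target`; the relation is
#' mapped to an edge sign through `relation_map`.
#'
#' @param path file path.
#' @param relation_map named integer vector mapping relation words to signs.
#' @return a [signed_digraph()].
#' @export
read_sif <- function(path,
                     relation_map = c(activates = 1L, increases = 1L,
                                      inhibits = -1L, decreases = -1L)) {
  d <- utils::read.table(path, header = FALSE, colClasses = "character",
                         quote = "", comment.char = "")
  if (ncol(d) < 3L) stop("expected three columns: source relation target",
                         call. = FALSE)
  rel <- tolower(trimws(d[[2]]))
  sgn <- unname(relation_map[rel])
  if (anyNA(sgn)) {
    stop("unmapped relation(s): ",
         paste(unique(rel[is.na(sgn)]), collapse = ", "), call. = FALSE)
  }
  signed_digraph(trimws(d[[1]]), trimws(d[[3]]), sgn)
}

#' Write a signed digraph as a TSV edge list
#'
#' @param g a [signed_digraph()].
#' @param path output path.
#' @export
write_graph_tsv <- function(g, path) {
  et <- edge_table(g)
  et$sign <- ifelse(et$sign == 1L, "+", "-")
  utils::write.table(et, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
}

#' Write a score distribution as TSV
#'
#' Columns `score`, `probability`, `right_tail_p` (the inclusive right tail
#' at each supported score).
#'
#' @param dist a `tdp_distribution`.
#' @param path output path.
#' @export
write_distribution_tsv <- function(dist, path) {
  stopifnot(inherits(dist, "tdp_distribution"))
  rt <- rev(cumsum(rev(dist$prob)))
  utils::write.table(
    data.frame(score = dist$score, probability = dist$prob,
               right_tail_p = rt),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = TRUE)
}
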