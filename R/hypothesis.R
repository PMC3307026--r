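#' An upstream-regulator hypothesis
#'
#' A hypothesis is a graph vertex together with a perturbation direction:
#' upregulation (+1) or downregulation (-1) of the entity.
#'
#' @param vertex vertex id.
#' @param direction +1 or -1.
#' @return an object of class `csg_hypothesis`.
#' @export
hypothesis <- function(vertex, direction = 1L) {
  direction <- as.integer(direction)
  stopifnot(direction %in% c(-1L, 1L))
  structure(list(vertex = as.character(vertex), direction = direction),
            class = "csg_hypothesis")
}

#' @export
print.csg_hypothesis <- function(x, ...) {
  cat("Hypothesis: ", x$vertex, if (x$direction == 1L) "+" else "-", "\n",
      sep = "")
  invisible(x)
}

#' Predicted classification under a hypothesis
#'
#' Traces shortest directed paths from the hypothesis vertex and predicts
#' each reachable transcript node's regulation as the hypothesis direction
#' times the product of edge signs along a shortest path. Nodes not reachable
#' within `max_depth` are predicted unchanged (0). When several equally short
#' paths disagree in sign, the node is predicted 0 and flagged as conflicted
#' (attribute `conflicted`).
#'
#' @param g a [signed_digraph()].
#' @param h a [hypothesis()].
#' @param max_depth maximum path length considered downstream (default 1,
#'   i.e. direct targets only; `Inf` for unlimited depth).
#' @return a [ternary_classification()] over the transcript nodes of `g`
#'   (ids = vertex names), with a logical attribute `conflicted`.
#' @export
predict_classification <- function(g, h, max_depth = 1L) {
  stopifnot(inherits(g, "signed_digraph"), inherits(h, "csg_hypothesis"),
            max_depth >= 1)
  v0 <- match(h$vertex, g$vertices)
  if (is.na(v0)) stop("hypothesis vertex not in graph", call. = FALSE)
  nv <- length(g$vertices)
  # sign masks: bit 1 = reachable with path sign +, bit 2 = path sign -
  mask <- integer(nv)
  dist <- rep(NA_integer_, nv)
  dist[v0] <- 0L
  frontier <- v0
  fmask <- c(1L)  # sign + at the root (direction applied at the end)
  mask[v0] <- 1L
  depth <- 0L
  out_by <- split(seq_along(g$from), g$from)
  while (length(frontier) > 0L && depth < max_depth) {
    depth <- depth + 1L
    nxt_mask <- integer(nv)
    for (fi in seq_along(frontier)) {
      u <- frontier[fi]
      eids <- out_by[[as.character(u)]]
      for (e in eids) {
        z <- g$to[e]
        m <- if (g$sign[e] == 1L) fmask[fi] else
          bitwAnd(fmask[fi], 1L) * 2L + bitwAnd(fmask[fi], 2L) %/% 2L
        if (is.na(dist[z])) {
          dist[z] <- depth
          nxt_mask[z] <- bitwOr(nxt_mask[z], m)
        } else if (dist[z] == depth) {
          nxt_mask[z] <- bitwOr(nxt_mask[z], m)
        }
      }
    }
    reached <- which(nxt_mask != 0L)
    mask[reached] <- bitwOr(mask[reached], nxt_mask[reached])
    frontier <- reached
    fmask <- nxt_mask[reached]
  }
  val <- integer(nv)
  conflicted <- logical(nv)
  plus_only <- mask == 1L
  minus_only <- mask == 2L
  both <- mask == 3L
  val[plus_only] <- h$direction
  val[minus_only] <- -h$direction
  conflicted[both] <- TRUE
  val[v0] <- 0L  # the perturbed entity itself is not a downstream prediction
  conflicted[v0] <- FALSE
  keep <- g$transcript
  structure(ternary_classification(val[keep], ids = g$vertices[keep]),
            conflicted = conflicted[keep])
}

#' Score a hypothesis against an experimental classification
#'
#' A prediction is correct when the predicted and experimental signs are both
#' `+` or both `-`; incorrect when one is `+` and the other `-`; ambiguous
#' otherwise. The score is `correct - incorrect`.
#'
#' @param predicted,experimental aligned [ternary_classification()] objects
#'   over the transcript nodes (matched by ids when present).
#' @return list with `correct`, `incorrect`, `ambiguous` counts and `score`.
#' @export
score_hypothesis <- function(predicted, experimental) {
  al <- align_classifications(experimental, predicted)
  tab <- contingency_table(al$a, al$b)
  list(correct = as.integer(tab[1, 1] + tab[2, 2]),
       incorrect = as.integer(tab[1, 2] + tab[2, 1]),
       ambiguous = as.integer(sum(tab) - tab[1, 1] - tab[2, 2] -
                                tab[1, 2] - tab[2, 1]),
       score = tdp_score(tab))
}

align_classifications <- function(a, b) {
  if (!is.null(names(a)) && !is.null(names(b))) {
    if (!setequal(names(a), names(b))) {
      stop("classifications cover different ground sets", call. = FALSE)
    }
    b <- ternary_classification(b[match(names(a), names(b))],
                                ids = names(a))
  } else if (length(a) != length(b)) {
    stop("classifications must have equal length", call. = FALSE)
  }
  list(a = a, b = b)
}

#' Exact p-value of a hypothesis score
#'
#' Right-tail p-value of the observed agreement score under the ternary dot
#' product null: the experimental classification is held fixed and the
#' predicted one is rearranged uniformly at random with its margin counts
#' preserved.
#'
#' @inheritParams score_hypothesis
#' @param method distribution algorithm, see [tdp_distribution()].
#' @return the p-value.
#' @export
tdp_pvalue <- function(predicted, experimental, method = "superfamily") {
  al <- align_classifications(experimental, predicted)
  marg <- margins_of(al$a, al$b)
  s_obs <- sum(unclass(al$a) * unclass(al$b))
  dist <- tdp_distribution(marg, method = method)
  pvalue_right_tail(dist, s_obs)
}

#' Empirical p-value over graph randomizations
#'
#' The proportion of degree-preserving randomized graphs on which the
#' hypothesis scores at least as well as on the actual graph (ties count
#' against the hypothesis). A zero count is reported as the bound `1/R` with
#' attribute `upper_bound = TRUE`, conventionally printed as `< 1/R`.
#'
#' @param g the actual [signed_digraph()].
#' @param h a [hypothesis()].
#' @param experimental experimental [ternary_classification()] over the
#'   transcript nodes of `g`.
#' @param replicates list of randomized `signed_digraph`s sharing the vertex
#'   set and degree signature of `g`.
#' @param max_depth prediction depth, see [predict_classification()].
#' @return numeric p-value (or upper bound, flagged by the `upper_bound`
#'   attribute).
#' @export
empirical_pvalue <- function(g, h, experimental, replicates, max_depth = 1L) {
  stopifnot(inherits(g, "signed_digraph"), length(replicates) >= 1L)
  sig <- degree_signature(g)
  for (r in replicates) {
    if (!identical(r$vertices, g$vertices) ||
        !identical(degree_signature(r), sig)) {
      stop("replicates must share the vertex set and degree signature of g",
           call. = FALSE)
    }
  }
  obs <- score_hypothesis(predict_classification(g, h, max_depth),
                          experimental)$score
  rep_scores <- vapply(replicates, function(r) {
    score_hypothesis(predict_classification(r, h, max_depth),
                     experimental)$score
  }, 0L)
  hits <- sum(rep_scores >= obs)
  R <- length(replicates)
  if (hits == 0L) {
    structure(1 / R, upper_bound = TRUE)
  } else {
    hits / R
  }
}

#' Competition ranking of hypothesis scores
#'
#' Sorts by score descending; tied scores share the same rank and the next
#' rank is skipped accordingly (four hypotheses tied at the 7th-best score
#' all get rank 7).
#'
#' @param scores numeric vector of hypothesis scores.
#' @return integer vector of ranks, parallel to `scores`.
#' @export
competition_rank <- function(scores) {
  vapply(scores, function(s) 1L + sum(scores > s), 1L)
}

#' Score and rank a set of hypotheses
#'
#' Runs the full workflow: predict downstream regulation for each hypothesis,
#' score it against the experimental classification, attach the exact ternary
#' dot product p-value and (when replicate graphs are supplied) the empirical
#' graph-randomization p-value, and rank by score.
#'
#' @param g a [signed_digraph()].
#' @param experimental experimental classification of the transcript nodes.
#' @param hypotheses list of [hypothesis()] objects; default: every vertex in
#'   both directions.
#' @param max_depth prediction depth.
#' @param method ternary dot product algorithm.
#' @param replicates optional list of randomized graphs for empirical
#'   p-values.
#' @return data.frame with columns `rank`, `hypothesis`, `direction`,
#'   `correct`, `incorrect`, `ambiguous`, `score`, `tdp_p` and (with
#'   replicates) `empirical_p` and `empirical_p_is_bound`, sorted by rank.
#' @export
score_hypotheses <- function(g, experimental, hypotheses = NULL,
                             max_depth = 1L, method = "superfamily",
                             replicates = NULL) {
  stopifnot(inherits(g, "signed_digraph"))
  if (is.null(hypotheses)) {
    hypotheses <- c(lapply(g$vertices, hypothesis, direction = 1L),
                    lapply(g$vertices, hypothesis, direction = -1L))
  }
  rows <- lapply(hypotheses, function(h) {
    pred <- predict_classification(g, h, max_depth)
    sc <- score_hypothesis(pred, experimental)
    p <- tdp_pvalue(pred, experimental, method = method)
    out <- data.frame(hypothesis = h$vertex, direction = h$direction,
                      correct = sc$correct, incorrect = sc$incorrect,
                      ambiguous = sc$ambiguous, score = sc$score, tdp_p = p)
    if (!is.null(replicates)) {
      ep <- empirical_pvalue(g, h, experimental, replicates, max_depth)
      out$empirical_p <- as.numeric(ep)
      out$empirical_p_is_bound <- isTRUE(attr(ep, "upper_bound"))
    }
    out
  })
  res <- do.call(rbind, rows)
  res$rank <- competition_rank(res$score)
  res <- res[order(res$rank, res$hypothesis), ]
  rownames(res) <- NULL
  res[, c("rank", setdiff(names(res), "rank"))]
}
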