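# Consensus tree construction.
#
# Four variants over a gene tree collection:
#   * bootstrap-based majority rule: clusters whose mode-C weight (average
#     branch support over ALL n trees) exceeds the cutoff; at cutoff >= 50
#     these are provably pairwise compatible,
#   * bootstrap-based extended majority rule: the majority set, then a greedy
#     pass adding remaining compatible clusters in decreasing weight order,
#   * bootstrap-based Nelson: maximum-total-weight clique(s) of the cluster
#     compatibility graph; with several optimal cliques only their common
#     clusters are kept and the rest are reported as ambiguous,
#   * weight-based extended majority rule: pure greedy accretion over an
#     already ranked cluster list (any weighting mode).

consensus_result <- function(tree, included, ambiguous, method) {
  structure(list(tree = tree, included = included, ambiguous = ambiguous,
                 method = method),
            class = "consensus_result")
}

#' @export
print.consensus_result <- function(x, ...) {
  cat("<consensus_result> method ", x$method, ": ", nrow(x$included),
      " clusters", if (nrow(x$ambiguous)) paste0(", ", nrow(x$ambiguous),
                                                 " ambiguous"), "\n", sep = "")
  cat(write_newick(x$tree), "\n")
  invisible(x)
}

empty_ranked <- function(ranked) ranked[integer(0), , drop = FALSE]

result_from_rows <- function(ranked, rows, method, ambiguous_rows = integer(0)) {
  taxa <- attr(ranked, "taxa")
  inc <- ranked[rows, , drop = FALSE]
  tree <- tree_from_clusters(inc$key, taxa, inc$weight)
  consensus_result(tree, inc, ranked[ambiguous_rows, , drop = FALSE], method)
}

# greedy compatibility pass over ranked rows, optionally starting from a set
greedy_accept <- function(ranked, start = integer(0), candidates = NULL,
                          max_splits = Inf) {
  acc <- start
  keys_acc <- ranked$key[acc]
  cand <- candidates %||% setdiff(seq_len(nrow(ranked)), start)
  for (i in cand) {
    if (length(acc) >= max_splits) break
    k <- ranked$key[i]
    if (k %in% keys_acc) next
    if (all(vapply(keys_acc, function(a) keys_compatible(a, k), TRUE))) {
      acc <- c(acc, i)
      keys_acc <- c(keys_acc, k)
    }
  }
  acc
}

#' Bootstrap-based majority rule consensus tree
#'
#' Includes every cluster whose average branch support over all trees in the
#' collection (mode-C weight) is strictly greater than `cutoff` percent.
#' Above 50 the retained clusters are automatically pairwise compatible;
#' below 50 compatibility is enforced greedily in decreasing weight order.
#'
#' @param coll a [gene_tree_collection()]; branch supports required.
#' @param cutoff percent threshold (default 50).
#' @return a `consensus_result` (fields `tree`, `included`, `ambiguous`,
#'   `method`).
#' @export
bootstrap_majority <- function(coll, cutoff = 50) {
  ranked <- rank_clusters(coll, "C")
  hit <- which(ranked$weight > cutoff)
  rows <- if (cutoff >= 50) hit else greedy_accept(ranked, candidates = hit)
  result_from_rows(ranked, rows, "bm")
}

#' Bootstrap-based extended majority rule consensus tree
#'
#' Starts from the bootstrap-based majority set and then considers the
#' remaining clusters in decreasing order of their total support sums,
#' gradually adding those compatible with the current consensus until the
#' tree is fully resolved or the list is exhausted.
#'
#' @inheritParams bootstrap_majority
#' @return a `consensus_result`.
#' @export
bootstrap_extended_majority <- function(coll, cutoff = 50) {
  ranked <- rank_clusters(coll, "C")
  hit <- which(ranked$weight > cutoff)
  start <- if (cutoff >= 50) hit else greedy_accept(ranked, candidates = hit)
  m <- length(attr(ranked, "taxa"))
  rows <- greedy_accept(ranked, start = start, max_splits = m - 3L)
  result_from_rows(ranked, rows, "bem")
}

#' Bootstrap-based Nelson consensus tree
#'
#' Builds the compatibility graph of all clusters (replicated or not), scores
#' each clique by the sum of its cluster weights, and finds every clique of
#' maximum total score by exact search.  A single optimum defines the tree; with
#' several optima only clusters common to all of them are kept and the
#' symmetric-difference clusters are reported as ambiguous.
#'
#' @inheritParams bootstrap_majority
#' @param max_candidates refuse instances with more distinct clusters than
#'   this (the maximum-weight clique problem is NP-hard; default 64).
#' @return a `consensus_result` with possibly nonempty `ambiguous`.
#' @export
nelson_consensus <- function(coll, max_candidates = 64) {
  ranked <- rank_clusters(coll, "C")
  k <- nrow(ranked)
  if (k > max_candidates)
    stop(k, " candidate clusters exceed the exact clique search cap (",
         max_candidates, ")")
  if (k == 0) return(result_from_rows(ranked, integer(0), "nelson"))
  cliques <- max_weight_cliques(compat_matrix(ranked$key), ranked$weight)
  common <- Reduce(intersect, cliques)
  ambiguous <- setdiff(Reduce(union, cliques), common)
  result_from_rows(ranked, common, "nelson", ambiguous)
}

# All maximum-total-weight cliques of the graph given by adjacency `adj`
# (positive vertex weights), via depth-first branch and bound.  Returns a
# list of integer vertex sets.
max_weight_cliques <- function(adj, w, tol = 1e-9) {
  n <- length(w)
  ord <- order(-w)
  best <- -Inf
  out <- list()
  rec <- function(clique, cand, total) {
    if (!length(cand)) {
      if (total > best + tol) { best <<- total; out <<- list(clique) }
      else if (abs(total - best) <= tol) out <<- c(out, list(clique))
      return()
    }
    if (total + sum(w[cand]) < best - tol) return()
    v <- cand[1L]
    rec(c(clique, v), cand[-1L][adj[v, cand[-1L]]], total + w[v])
    # skip v only if the remainder can still reach or tie the optimum
    if (total + sum(w[cand[-1L]]) >= best - tol) rec(clique, cand[-1L], total)
  }
  rec(integer(0), ord, 0)
  # dedupe (the same clique can be reached along different branches)
  sig <- vapply(out, function(s) paste(sort(s), collapse = ","), "")
  out <- out[!duplicated(sig)]
  # zero-weight vertices can tie a clique with its own subsets: keep only
  # inclusion-maximal optima (cliques in the graph-theoretic sense)
  keep <- vapply(seq_along(out), function(i)
    !any(vapply(seq_along(out), function(j)
      j != i && length(out[[i]]) < length(out[[j]]) &&
        all(out[[i]] %in% out[[j]]), TRUE)), TRUE)
  out[keep]
}

#' Weight-based extended majority rule consensus tree
#'
#' Greedy accretion over an already ranked cluster list: clusters are taken
#' from the top and added when compatible with everything accepted so far,
#' stopping once the tree is fully resolved (m - 3 internal branches) or the
#' list is exhausted.
#'
#' @param ranked a [rank_clusters()] result (any weighting mode).
#' @return a `consensus_result`.
#' @export
weighted_extended_majority <- function(ranked) {
  if (!inherits(ranked, "ranked_clusters")) stop("need a rank_clusters() result")
  m <- length(attr(ranked, "taxa"))
  rows <- greedy_accept(ranked, max_splits = m - 3L)
  result_from_rows(ranked, rows, "wem")
}
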