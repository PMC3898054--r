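# Overall cluster weights.
#
# For cluster i over a collection of n trees, with sigma_ij = 1 when the
# cluster occurs in tree j, W(C_ij) its branch support there and W(T_j) the
# tree weight:
#   mode "C" :  W_i = sum_j sigma_ij W(C_ij)          / n
#   mode "T" :  W_i = sum_j sigma_ij W(T_j)           / n
#   mode "CT":  W_i = sum_j sigma_ij W(C_ij) W(T_j)   / n
# n is always the total number of trees, including those lacking the cluster.
# Supports are on the percent scale; no renormalization across modes.  A
# branch present in a tree but carrying no support contributes 0 to the
# support sums (its presence still counts for sigma_ij).

# distinct canonical keys with presence and per-tree support matrices
collection_cluster_table <- function(coll) {
  n <- coll$n
  keys <- character(); side <- character()
  sup <- matrix(NA_real_, 0, n)
  present <- matrix(FALSE, 0, n)
  for (j in seq_len(n)) {
    cl <- extract_clusters(coll$trees[[j]], coll$taxa)
    new <- !(cl$key %in% keys)
    if (any(new)) {
      keys <- c(keys, cl$key[new])
      side <- c(side, cl$side[new])  # designated side of first occurrence
      sup <- rbind(sup, matrix(NA_real_, sum(new), n))
      present <- rbind(present, matrix(FALSE, sum(new), n))
    }
    idx <- match(cl$key, keys)
    sup[cbind(idx, j)] <- cl$support
    present[cbind(idx, j)] <- TRUE
  }
  rownames(sup) <- rownames(present) <- keys
  list(keys = keys, side = side, support = sup, present = present)
}

weight_from_supports <- function(sup_row, present, weights, n, mode) {
  s <- ifelse(is.na(sup_row), 0, sup_row)
  switch(mode,
    C  = sum(s[present]) / n,
    T  = sum(weights[present]) / n,
    CT = sum(s[present] * weights[present]) / n)
}

check_mode_inputs <- function(coll, mode) {
  if (mode %in% c("C", "CT") && !collection_has_supports(coll))
    stop("mode ", mode, " requires branch supports on every tree; ",
         "use mode 'T' for support-free trees")
  if (mode %in% c("T", "CT") && is.null(coll$weights))
    stop("mode ", mode, " requires per-tree weights")
  invisible(TRUE)
}

#' Overall weight of one cluster across a gene tree collection
#'
#' @param cl an [nc_cluster()] or character vector of taxon labels.
#' @param coll a [gene_tree_collection()].
#' @param mode `"C"` (branch supports only), `"T"` (tree weights only) or
#'   `"CT"` (both).
#' @return list of class `weighted_cluster`: `cluster`, `weight` (percent
#'   scale), `mode`, `member_trees` (indices j with sigma_ij = 1),
#'   `per_tree_support`.
#' @export
cluster_weight <- function(cl, coll, mode = c("C", "T", "CT")) {
  mode <- match.arg(mode)
  if (!inherits(cl, "nc_cluster")) cl <- nc_cluster(cl, coll$taxa)
  check_mode_inputs(coll, mode)
  tab <- collection_cluster_table(coll)
  key <- cluster_key(cl)
  i <- match(key, tab$keys)
  if (is.na(i)) stop("cluster occurs in no tree of the collection")
  w <- coll$weights %||% rep(1, coll$n)
  member <- which(tab$present[i, ])
  structure(list(cluster = cl,
                 weight = weight_from_supports(tab$support[i, ],
                                               tab$present[i, ], w,
                                               coll$n, mode),
                 mode = mode, member_trees = member,
                 per_tree_support = tab$support[i, member]),
            class = "weighted_cluster")
}

#' @export
print.weighted_cluster <- function(x, ...) {
  cat("<weighted_cluster> {",
      paste(x$cluster$taxa[x$cluster$side], collapse = ","),
      "} weight ", format(x$weight, digits = 6), " (mode ", x$mode,
      ", in ", length(x$member_trees), " trees)\n", sep = "")
  invisible(x)
}

#' Rank all clusters of a collection by overall weight
#'
#' Every distinct cluster found in at least one tree appears once, ordered by
#' decreasing weight; ties break by larger member-tree count, then by
#' lexicographically smaller canonical key.
#'
#' @inheritParams cluster_weight
#' @return data.frame of class `ranked_clusters` with columns `key`, `side`,
#'   `size`, `weight`, `n_member`; attributes `taxa`, `mode`,
#'   `support_matrix` and `presence_matrix` (clusters x trees).
#' @export
rank_clusters <- function(coll, mode = c("C", "T", "CT")) {
  mode <- match.arg(mode)
  check_mode_inputs(coll, mode)
  tab <- collection_cluster_table(coll)
  n <- coll$n
  w <- coll$weights %||% rep(1, n)
  weight <- vapply(seq_along(tab$keys), function(i)
    weight_from_supports(tab$support[i, ], tab$present[i, ], w, n, mode), 0)
  n_member <- vapply(seq_along(tab$keys), function(i)
    sum(tab$present[i, ]), 1L)
  size <- vapply(tab$keys, function(k) sum(key_to_side(k)), 1L)
  df <- data.frame(key = tab$keys, side = tab$side, size = unname(size),
                   weight = weight, n_member = n_member,
                   stringsAsFactors = FALSE)
  ord <- order(-df$weight, -df$n_member, df$key)
  df <- df[ord, , drop = FALSE]
  rownames(df) <- NULL
  attr(df, "taxa") <- coll$taxa
  attr(df, "mode") <- mode
  attr(df, "support_matrix") <- tab$support[ord, , drop = FALSE]
  attr(df, "presence_matrix") <- tab$present[ord, , drop = FALSE]
  class(df) <- c("ranked_clusters", "data.frame")
  df
}

#' Export a ranked cluster table as TSV
#'
#' Columns: taxa of the cluster side, weight, mode, then one per-tree support
#' column per collection member.
#'
#' @param ranked a [rank_clusters()] result.
#' @param path output file.
#' @export
write_cluster_table <- function(ranked, path) {
  taxa <- attr(ranked, "taxa")
  sup <- attr(ranked, "support_matrix")
  lab <- vapply(ranked$side, function(s)
    paste(taxa[key_to_side(s)], collapse = ","), "")
  out <- data.frame(taxa = lab,
                    weight = round(ranked$weight, 4),
                    mode = attr(ranked, "mode"),
                    stringsAsFactors = FALSE)
  if (!is.null(sup) && nrow(sup)) {
    colnames(sup) <- paste0("tree", seq_len(ncol(sup)))
    out <- cbind(out, as.data.frame(sup, row.names = NULL))
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
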