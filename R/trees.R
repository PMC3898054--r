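# Tree data model and split machinery.
#
# Trees are `ape::phylo` objects decorated with attributes:
#   - "taxa": the ordered taxon set fixing cluster bit positions,
#   - "has_supports": whether internal branches carry supports,
# with per-internal-node supports kept in `node.label` on a 0-100 percent
# scale (posterior probabilities are rescaled at parse time).

`%||%` <- function(a, b) if (is.null(a)) b else a

resolve_taxa <- function(phy, taxa = NULL) {
  taxa <- taxa %||% attr(phy, "taxa") %||% sort(phy$tip.label)
  check_taxa(taxa)
  if (!setequal(taxa, phy$tip.label))
    stop("tree tips do not match the taxon set")
  taxa
}

#' Parse a Newick string into a supported phylogeny
#'
#' Internal-node labels are read as branch supports.  Posterior probabilities
#' (scale `"probability"`, or auto-detected when all values are <= 1) are
#' rescaled to the internal 0-100 percent scale.  A `[&support=..]` comment
#' dialect is accepted via `dialect = "comment"`.
#'
#' @param text a Newick string (single tree, terminated by `;`).
#' @param support_scale one of `"auto"`, `"percent"`, `"probability"`,
#'   `"none"`.
#' @param taxa optional established taxon order; the tree must contain exactly
#'   these labels.  When `NULL` the taxon order is taken from the tree itself.
#' @param dialect `"label"` (supports as internal node labels, default) or
#'   `"comment"` (`[&support=..]` annotations).
#' @return an `ape::phylo` with attributes `taxa` and `has_supports`.
#' @examples
#' t3 <- parse_newick("((x:1,u:1)90:1,(z:1,w:1)100:1,y:1);")
#' extract_clusters(t3)
#' @export
parse_newick <- function(text,
                         support_scale = c("auto", "percent", "probability", "none"),
                         taxa = NULL,
                         dialect = c("label", "comment")) {
  support_scale <- match.arg(support_scale)
  dialect <- match.arg(dialect)
  if (dialect == "comment")
    text <- gsub("\\[&support=([0-9.eE+-]+)\\]", "\\1", text)
  phy <- tryCatch(ape::read.tree(text = text),
                  error = function(e) stop("malformed Newick: ", conditionMessage(e)))
  if (is.null(phy)) stop("malformed Newick input")
  if (anyDuplicated(phy$tip.label))
    stop("duplicate leaf labels: ",
         paste(unique(phy$tip.label[duplicated(phy$tip.label)]), collapse = ", "))
  if (length(phy$tip.label) < 3)
    stop("a phylogeny needs at least 3 taxa")
  if (!is.null(taxa)) {
    check_taxa(taxa)
    if (!setequal(taxa, phy$tip.label))
      stop("taxon set mismatch with the established taxon order")
  } else {
    taxa <- phy$tip.label
  }
  sup <- rep(NA_real_, phy$Nnode)
  if (support_scale != "none" && !is.null(phy$node.label)) {
    sup <- suppressWarnings(as.numeric(phy$node.label))
    if (support_scale == "auto") {
      fin <- sup[is.finite(sup)]
      support_scale <- if (length(fin) && all(fin <= 1)) "probability" else "percent"
    }
    if (support_scale == "probability") sup <- sup * 100
  }
  phy$node.label <- ifelse(is.na(sup), "", format(sup, trim = TRUE, digits = 10))
  attr(phy, "taxa") <- taxa
  attr(phy, "has_supports") <- any(is.finite(sup))
  phy
}

#' Write a phylogeny to Newick, supports as internal node labels
#'
#' @param phy an `ape::phylo` (supports in `node.label`).
#' @param file optional path; when `NULL` the Newick string is returned.
#' @return the Newick string, invisibly when written to `file`.
#' @export
write_newick <- function(phy, file = NULL) {
  s <- ape::write.tree(phy)
  if (is.null(file)) return(s)
  writeLines(s, file)
  invisible(s)
}

# logical membership matrix (nodes x taxa) of tip descendants per node
node_sides <- function(phy, taxa) {
  m <- length(phy$tip.label)
  pos <- match(phy$tip.label, taxa)
  nn <- max(phy$edge)
  S <- matrix(FALSE, nn, length(taxa))
  S[cbind(seq_len(m), pos)] <- TRUE
  po <- ape::reorder.phylo(phy, "postorder")
  for (k in seq_len(nrow(po$edge))) {
    p <- po$edge[k, 1L]; ch <- po$edge[k, 2L]
    S[p, ] <- S[p, ] | S[ch, ]
  }
  S
}

#' Extract the nontrivial clusters (splits) of a tree with their supports
#'
#' One row per internal branch; trivial splits (single leaf or all-but-one)
#' are excluded.  The designated `side` records the descendant side of the
#' branch as the tree is written, which orients SPR-based tests; the canonical
#' `key` identifies the bipartition irrespective of orientation.
#'
#' @param phy an `ape::phylo`.
#' @param taxa taxon order (defaults to the tree's `taxa` attribute).
#' @return data.frame with columns `key`, `side` (bitstrings), `size`,
#'   `support` (percent, `NA` when absent), and attribute `taxa`.
#' @export
extract_clusters <- function(phy, taxa = NULL) {
  taxa <- resolve_taxa(phy, taxa)
  m <- length(taxa)
  S <- node_sides(phy, taxa)
  nlab <- phy$node.label
  internal <- phy$edge[, 2L] > m
  out <- list()
  seen <- character()
  for (ch in phy$edge[internal, 2L]) {
    side <- S[ch, ]
    sz <- sum(side)
    if (sz < 2L || sz > m - 2L) next
    key <- canon_key(side)
    sup <- NA_real_
    if (!is.null(nlab)) {
      v <- suppressWarnings(as.numeric(nlab[ch - m]))
      if (is.finite(v)) sup <- v
    }
    if (key %in% seen) {
      # complementary root-child branches describe one split; keep a support
      i <- match(key, seen)
      if (is.na(out[[i]]$support) && !is.na(sup)) out[[i]]$support <- sup
      next
    }
    seen <- c(seen, key)
    out[[length(out) + 1L]] <- list(key = key, side = side_key(side),
                                    size = sz, support = sup)
  }
  df <- if (length(out)) {
    data.frame(key = vapply(out, `[[`, "", "key"),
               side = vapply(out, `[[`, "", "side"),
               size = vapply(out, function(x) as.integer(x$size), 1L),
               support = vapply(out, `[[`, 0, "support"),
               stringsAsFactors = FALSE)
  } else {
    data.frame(key = character(), side = character(), size = integer(),
               support = numeric(), stringsAsFactors = FALSE)
  }
  attr(df, "taxa") <- taxa
  df
}

# named numeric: canonical key -> support
split_supports <- function(phy, taxa = NULL) {
  cl <- extract_clusters(phy, taxa)
  stats::setNames(cl$support, cl$key)
}

#' Build the unique tree displaying a compatible set of clusters
#'
#' The classical tree-popping construction: canonical sides (excluding the
#' first taxon) of a pairwise compatible split set form a laminar family,
#' which is assembled into a (possibly multifurcating) unrooted tree.
#'
#' @param keys character vector of canonical split keys (or list of
#'   [nc_cluster()]s); may be empty, giving the star tree.
#' @param taxa ordered taxon set.
#' @param supports optional numeric vector parallel to `keys`, written as
#'   internal node labels.
#' @return an `ape::phylo` whose nontrivial split set equals `keys`.
#' @export
tree_from_clusters <- function(keys, taxa, supports = NULL) {
  check_taxa(taxa)
  m <- length(taxa)
  if (m < 3) stop("need at least 3 taxa")
  if (is.list(keys)) keys <- vapply(keys, cluster_key, "")
  if (anyDuplicated(keys)) {
    keep <- !duplicated(keys)
    keys <- keys[keep]
    if (!is.null(supports)) supports <- supports[keep]
  }
  sides <- lapply(keys, key_to_side)
  k <- length(sides)
  if (k >= 2) {
    for (i in seq_len(k - 1)) for (j in (i + 1):k) {
      si <- sides[[i]]; sj <- sides[[j]]
      if (any(si & sj) && !all(sj[si]) && !all(si[sj]))
        stop("incompatible cluster set: {", paste(taxa[si], collapse = ","),
             "} vs {", paste(taxa[sj], collapse = ","), "}")
    }
  }
  sizes <- vapply(sides, sum, 1L)
  ord <- order(sizes, decreasing = TRUE)
  # parent[i]: index (in ord-sorted list) of smallest side strictly containing i
  sides <- sides[ord]; sizes <- sizes[ord]
  sup <- if (is.null(supports)) rep(NA_real_, k) else supports[ord]
  parent <- integer(k)
  for (i in seq_len(k)) {
    parent[i] <- 0L
    if (i > 1) for (j in (i - 1):1) {
      if (sizes[j] > sizes[i] && all(sides[[j]][sides[[i]]])) { parent[i] <- j; break }
    }
  }
  tip_parent <- integer(m)  # 0 = root
  for (t in seq_len(m)) {
    best <- 0L; bsz <- m + 1L
    for (i in seq_len(k)) if (sides[[i]][t] && sizes[i] < bsz) { best <- i; bsz <- sizes[i] }
    tip_parent[t] <- best
  }
  lab <- function(s) if (is.na(s)) "" else format(s, trim = TRUE, digits = 10)
  build <- function(node) {
    kids_c <- which(parent == node)
    kids_t <- which(tip_parent == node)
    parts <- c(vapply(kids_c, function(i) paste0(build(i), lab(sup[i])), ""),
               taxa[kids_t])
    paste0("(", paste(parts, collapse = ","), ")")
  }
  txt <- paste0(build(0L), ";")
  phy <- ape::read.tree(text = txt)
  attr(phy, "taxa") <- taxa
  attr(phy, "has_supports") <- !is.null(supports) && any(is.finite(sup))
  phy
}

#' Robinson-Foulds topological distance
#'
#' Size of the symmetric difference of the nontrivial split sets of two trees
#' over the same taxon set.
#'
#' @param t1,t2 `ape::phylo` objects on one taxon set.
#' @param taxa taxon order (defaults from `t1`).
#' @return nonnegative integer.
#' @export
rf_distance <- function(t1, t2, taxa = NULL) {
  taxa <- resolve_taxa(t1, taxa)
  if (!setequal(taxa, t2$tip.label)) stop("taxon set mismatch")
  k1 <- extract_clusters(t1, taxa)$key
  k2 <- extract_clusters(t2, taxa)$key
  length(setdiff(k1, k2)) + length(setdiff(k2, k1))
}

# every edge side of the tree, both orientations, deduplicated
all_sides <- function(phy, taxa) {
  m <- length(taxa)
  S <- node_sides(phy, taxa)
  res <- list(); seen <- character()
  for (ch in phy$edge[, 2L]) {
    for (side in list(S[ch, ], !S[ch, ])) {
      sz <- sum(side)
      if (sz < 1L || sz > m - 1L) next
      kk <- side_key(side)
      if (kk %in% seen) next
      seen <- c(seen, kk)
      res[[length(res) + 1L]] <- side
    }
  }
  res
}

# edge sides of the tree restricted to the complement of clade P
# (= edge sides of T \ P), both orientations, deduplicated
sides_after_prune <- function(sides, P) {
  R <- !P
  res <- list(); seen <- character()
  for (s in sides) {
    b <- s & R
    sz <- sum(b)
    if (sz < 1L || sz >= sum(R)) next
    kk <- side_key(b)
    if (kk %in% seen) next
    seen <- c(seen, kk)
    res[[length(res) + 1L]] <- b
  }
  res
}

#' Subtree prune and regraft (SPR) on an unrooted topology
#'
#' Prunes the subtree spanned by `prune` (which must be one side of a branch
#' of `phy`) and reattaches it on the branch of the pruned tree identified by
#' `regraft`.  Branch lengths are discarded; supports of splits unchanged by
#' the move are preserved, all others become absent.
#'
#' @param phy an `ape::phylo`.
#' @param prune cluster/labels/logical: the leaf set of the pruned subtree.
#' @param regraft cluster/labels/logical over the remaining taxa: one side of
#'   the target branch in the pruned tree.
#' @param taxa taxon order.
#' @return an `ape::phylo` on the same taxon set.
#' @export
spr_move <- function(phy, prune, regraft, taxa = NULL) {
  taxa <- resolve_taxa(phy, taxa)
  m <- length(taxa)
  P <- as_side(prune, taxa)
  sides <- all_sides(phy, taxa)
  skeys <- vapply(sides, side_key, "")
  if (!(side_key(P) %in% skeys))
    stop("prune set is not a subtree of the tree")
  if (sum(!P) < 2) stop("cannot prune: fewer than 2 taxa would remain")
  R <- !P
  A <- as_side(regraft, taxa)
  if (any(A & P)) stop("regraft branch lies inside the pruned subtree")
  sidesR <- sides_after_prune(sides, P)
  rkeys <- vapply(sidesR, side_key, "")
  if (!(side_key(A) %in% rkeys))
    stop("regraft target is not a branch of the pruned tree")
  old <- split_supports(phy, taxa)
  new_sides <- list()
  add <- function(s) new_sides[[length(new_sides) + 1L]] <<- s
  # splits internal to the pruned subtree are untouched
  for (s in sides) if (all(P[s]) && sum(s) >= 2 && sum(s) < sum(P)) add(s)
  # branches of T\P: the moved subtree joins the side holding the regraft point
  for (B in sidesR) {
    if (identical(B, A) || identical(B, R & !A)) next
    gains <- all(B[A]) || all(B[R & !A])
    add(if (gains) B | P else B)
  }
  add(A)
  add(A | P)
  add(P)
  keys <- character(); sups <- numeric()
  for (s in new_sides) {
    sz <- sum(s)
    if (sz < 2L || sz > m - 2L) next
    kk <- canon_key(s)
    if (kk %in% keys) next
    keys <- c(keys, kk)
    sups <- c(sups, if (kk %in% names(old)) unname(old[kk]) else NA_real_)
  }
  tree_from_clusters(keys, taxa, sups)
}

#' All SPR neighbours of a tree
#'
#' Enumerates every prune/regraft combination (pruned subtree = any branch
#' side, regraft = any branch of the pruned tree) and drops moves that
#' reproduce the original topology.
#'
#' @inheritParams spr_move
#' @return list of `ape::phylo` neighbours (may contain topological
#'   duplicates reached by different moves).
#' @export
all_spr_neighbors <- function(phy, taxa = NULL) {
  taxa <- resolve_taxa(phy, taxa)
  orig <- sort(extract_clusters(phy, taxa)$key)
  sides <- all_sides(phy, taxa)
  out <- list()
  for (P in sides) {
    if (sum(!P) < 2) next
    sidesR <- sides_after_prune(sides, P)
    rkeys <- vapply(sidesR, side_key, "")
    done <- character()
    for (A in sidesR) {
      # A and its complement in R name the same branch
      ck <- min(side_key(A), side_key((!P) & !A))
      if (ck %in% done) next
      done <- c(done, ck)
      tr <- spr_move(phy, P, A, taxa)
      if (!identical(sort(extract_clusters(tr, taxa)$key), orig))
        out[[length(out) + 1L]] <- tr
    }
  }
  out
}

# All one-move realizations of cluster side C on tree `phy`: prune a proper
# subtree P of C and regraft it next to the remainder C \ P.  Returns a list
# of records (P, stationary, tree); empty when no single induced SPR creates
# the cluster.
cluster_realizations <- function(cside, phy, taxa) {
  m <- length(taxa)
  sides <- all_sides(phy, taxa)
  out <- list(); seen <- character()
  for (P in sides) {
    if (!all(cside[P]) || sum(P) >= sum(cside)) next  # need P proper subset of C
    if (sum(!P) < 2) next
    tgt <- cside & !P
    sidesR <- sides_after_prune(sides, P)
    rkeys <- vapply(sidesR, side_key, "")
    A <- if (side_key(tgt) %in% rkeys) tgt
         else if (side_key((!P) & !tgt) %in% rkeys) (!P) & !tgt
         else NULL
    if (is.null(A)) next
    pk <- side_key(P)
    if (pk %in% seen) next
    seen <- c(seen, pk)
    out[[length(out) + 1L]] <-
      list(P = P, stationary = tgt, tree = spr_move(phy, P, A, taxa))
  }
  out
}

#' Test first-degree incompatibility of a cluster with a tree
#'
#' A cluster has the first degree of incompatibility with a tree when a single
#' SPR move induced by the cluster -- pruning a proper subtree of the
#' cluster's designated side and regrafting it next to the remainder of that
#' side -- turns the tree into one displaying the cluster.  A cluster
#' compatible with every split of the tree is not incompatible at all and
#' yields `FALSE`.
#'
#' @param cl an [nc_cluster()] (its designated side orients the test).
#' @param phy an `ape::phylo`.
#' @param taxa taxon order.
#' @return logical scalar.
#' @export
first_degree_incompatible <- function(cl, phy, taxa = NULL) {
  taxa <- resolve_taxa(phy, taxa)
  cside <- as_side(cl, taxa)
  ck <- canon_key(cside)
  ks <- extract_clusters(phy, taxa)$key
  if (ck %in% ks) return(FALSE)
  incomp <- any(!vapply(ks, function(k) keys_compatible(ck, k), TRUE))
  if (!incomp) return(FALSE)
  length(cluster_realizations(cside, phy, taxa)) > 0
}
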