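# Shared fixtures and independent oracles.

FIG_TAXA <- c("x", "y", "z", "w", "u")

# the three-tree worked example: supports 40/100, 45/100, 90/100
fig_trees <- function(weights = c(1, 1, 1)) {
  t1 <- parse_newick("((x:1,y:1)40:1,(z:1,w:1)100:1,u:1);", taxa = FIG_TAXA)
  t2 <- parse_newick("((x:1,y:1)45:1,(z:1,w:1)100:1,u:1);", taxa = FIG_TAXA)
  t3 <- parse_newick("((x:1,u:1)90:1,(z:1,w:1)100:1,y:1);", taxa = FIG_TAXA)
  gene_tree_collection(list(t1, t2, t3), weights = weights, taxa = FIG_TAXA)
}

# random supported binary tree on m taxa (supports uniform on [lo, hi])
random_supported_tree <- function(m, taxa = NULL, lo = 5, hi = 100) {
  taxa <- taxa %||% sprintf("s%02d", seq_len(m))
  phy <- ape::rtree(m, rooted = FALSE, tip.label = sample(taxa))
  keys <- netcons::extract_clusters(structure(phy, taxa = taxa))$key
  netcons::tree_from_clusters(keys, taxa,
                              stats::runif(length(keys), lo, hi))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

split_set <- function(phy, taxa = NULL) sort(extract_clusters(phy, taxa)$key)

# ---- independent oracles ------------------------------------------------

# brute-force first-degree test: enumerate every SPR move induced by the
# cluster (pruned subtree a proper subset of the designated side), apply it,
# and look for the cluster's bipartition in the result
oracle_first_degree <- function(members, phy, taxa) {
  cside <- taxa %in% members
  ck <- cluster_key(nc_cluster(members, taxa))
  if (ck %in% extract_clusters(phy, taxa)$key) return(FALSE)
  comp <- all(vapply(extract_clusters(phy, taxa)$key, function(k)
    are_compatible(nc_cluster(members, taxa),
                   nc_cluster(netcons:::key_to_side(k), taxa)), TRUE))
  if (comp) return(FALSE)
  S <- netcons:::node_sides(phy, taxa)
  m <- length(taxa)
  for (ch in phy$edge[, 2]) for (P in list(S[ch, ], !S[ch, ])) {
    if (!all(cside[P]) || sum(P) >= sum(cside) || sum(P) < 1) next
    if (sum(!P) < 2) next
    sidesR <- netcons:::sides_after_prune(netcons:::all_sides(phy, taxa), P)
    for (A in sidesR) {
      tr <- spr_move(phy, P, A, taxa)
      if (ck %in% extract_clusters(tr, taxa)$key) return(TRUE)
    }
  }
  FALSE
}

# exhaustive maximum-weight compatible subset by bitmask dynamic programming
oracle_max_weight_clique <- function(keys, w) {
  n <- length(keys)
  stopifnot(n <= 16)
  adj <- netcons:::compat_matrix(keys)
  nmask <- bitwShiftL(1L, n)
  best <- -Inf; arg <- integer(0)
  for (s in seq_len(nmask) - 1L) {
    mem <- which(bitwAnd(s, bitwShiftL(1L, seq_len(n) - 1L)) > 0L)
    if (length(mem) >= 2 && !all(adj[mem, mem])) next
    tot <- sum(w[mem])
    if (tot > best + 1e-9) { best <- tot; arg <- list(mem) }
    else if (abs(tot - best) <= 1e-9) arg <- c(arg, list(mem))
  }
  # inclusion-maximal optima only
  keep <- vapply(seq_along(arg), function(i)
    !any(vapply(seq_along(arg), function(j)
      j != i && length(arg[[i]]) < length(arg[[j]]) &&
        all(arg[[i]] %in% arg[[j]]), TRUE)), TRUE)
  list(weight = best, cliques = arg[keep])
}

# random collection of supported trees sharing a taxon set
random_collection <- function(n_trees, m, lo = 5, hi = 100) {
  taxa <- sprintf("s%02d", seq_len(m))
  gene_tree_collection(
    lapply(seq_len(n_trees), function(i) random_supported_tree(m, taxa, lo, hi)),
    taxa = taxa)
}
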