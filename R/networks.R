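# Explicit weighted consensus networks.
#
# A network is a backbone tree (weight-based consensus tree, or a supplied
# rooted species tree) plus an ordered list of weighted reticulation
# branches.  Candidate clusters are taken in decreasing weight order; a
# candidate is admitted when it has the FIRST degree of incompatibility with
# the current network state (the backbone with all previously accepted SPR
# interpretations applied) and its weight reaches the cutoff.  Each admitted
# cluster C is realized as an SPR joining two pieces C1, C2 (C = C1 u C2);
# the transfer direction follows the cumulative Robinson-Foulds rule: the
# orientation whose realized tree is closer (weighted by tree supports) to
# the gene trees containing C wins, a tie is reported as undirected.

#' Configuration for network building
#'
#' @param cutoff minimum overall cluster weight (percent) for a reticulation
#'   to be retained; default 10.
#' @param max_reticulations optional cap on the number of reticulation
#'   branches (default unlimited).
#' @param weight_mode `"C"`, `"T"` or `"CT"` (see [cluster_weight()]).
#' @param allow_undirected when `FALSE`, direction ties are broken
#'   deterministically (donor = lexicographically smaller piece) instead of
#'   being reported as undirected.
#' @return list of class `network_config`.
#' @export
network_config <- function(cutoff = 10, max_reticulations = Inf,
                           weight_mode = c("C", "T", "CT"),
                           allow_undirected = TRUE) {
  weight_mode <- match.arg(weight_mode)
  if (!is.numeric(cutoff) || cutoff <= 0 || cutoff > 100)
    stop("cutoff must lie in (0, 100]")
  structure(list(cutoff = cutoff, max_reticulations = max_reticulations,
                 weight_mode = weight_mode,
                 allow_undirected = isTRUE(allow_undirected)),
            class = "network_config")
}

empty_retic <- function() {
  data.frame(order = integer(), donor = character(), recipient = character(),
             donor_taxa = character(), recipient_taxa = character(),
             direction = character(), weight = numeric(),
             interval_start = integer(), interval_end = integer(),
             stringsAsFactors = FALSE)
}

consensus_network <- function(backbone, reticulations, cutoff, taxa,
                              state = backbone) {
  structure(list(backbone = backbone, reticulations = reticulations,
                 cutoff = cutoff, taxa = taxa, state = state),
            class = "consensus_network")
}

#' @export
print.consensus_network <- function(x, ...) {
  cat("<consensus_network> backbone ", length(x$taxa), " taxa, ",
      nrow(x$reticulations), " reticulation(s), cutoff ", x$cutoff, "%\n",
      sep = "")
  cat(write_newick(x$backbone), "\n")
  if (nrow(x$reticulations))
    print(x$reticulations[, c("order", "donor_taxa", "recipient_taxa",
                              "direction", "weight")])
  invisible(x)
}

# per-tree split key sets, computed once per collection
collection_split_cache <- function(coll) {
  lapply(coll$trees, function(t) extract_clusters(t, coll$taxa)$key)
}

# weighted cumulative RF of `tree` against the gene trees containing split
# `key`; weights default to 1 per tree
cumulative_rf <- function(tree, key, coll, cache = NULL) {
  cache <- cache %||% collection_split_cache(coll)
  w <- coll$weights %||% rep(1, coll$n)
  tkeys <- extract_clusters(tree, coll$taxa)$key
  tot <- 0; any_tree <- FALSE
  for (j in seq_len(coll$n)) {
    ks <- cache[[j]]
    if (!(key %in% ks)) next
    any_tree <- TRUE
    tot <- tot + w[j] *
      (length(setdiff(tkeys, ks)) + length(setdiff(ks, tkeys)))
  }
  if (!any_tree) NA_real_ else tot
}

#' Infer the direction of a reticulation branch between two backbone clusters
#'
#' Let T1 be the tree obtained by the SPR interpreting a transfer from `c1`
#' to `c2` (the recipient subtree `c2` moves next to the donor `c1`) and T2
#' the opposite interpretation.  Cumulative Robinson-Foulds distances D1, D2
#' are computed between each interpretation and all gene trees containing
#' C = c1 u c2, weighted by the tree supports.  D1 < D2 gives `"forward"`
#' (`c1` donor), D1 > D2 `"backward"`, a tie `"undirected"`.
#'
#' @param backbone an `ape::phylo`; `c1`, `c2` must be branch sides of it.
#' @param c1,c2 clusters/labels/logical sides over `taxa`, disjoint.
#' @param coll the gene tree collection providing evidence.
#' @param taxa taxon order.
#' @return character scalar with attributes `d1`, `d2`; attribute
#'   `no_evidence = TRUE` (and value `"undirected"`) when no gene tree
#'   contains C.
#' @export
find_direction <- function(backbone, c1, c2, coll, taxa = NULL) {
  taxa <- resolve_taxa(backbone, taxa)
  s1 <- as_side(c1, taxa); s2 <- as_side(c2, taxa)
  if (any(s1 & s2)) stop("c1 and c2 must be disjoint")
  key <- canon_key(s1 | s2)
  t1 <- spr_move(backbone, s2, s1, taxa)  # transfer c1 -> c2
  t2 <- spr_move(backbone, s1, s2, taxa)  # transfer c2 -> c1
  d1 <- cumulative_rf(t1, key, coll)
  d2 <- cumulative_rf(t2, key, coll)
  if (is.na(d1)) {
    res <- "undirected"
    attr(res, "no_evidence") <- TRUE
    warning("no gene tree contains the union cluster; direction undirected")
    return(res)
  }
  res <- if (d1 < d2) "forward" else if (d1 > d2) "backward" else "undirected"
  attr(res, "d1") <- d1
  attr(res, "d2") <- d2
  res
}

taxa_label <- function(side, taxa) paste(taxa[side], collapse = ",")

# Shared reticulation-adding loop (Algorithms 1 and 3).  `trusted` says the
# designated cluster sides come from rooted trees; otherwise both
# orientations of a candidate are searched for single-SPR realizations.
add_reticulations <- function(backbone, ranked, coll, cfg,
                              trusted = FALSE, intervals = NULL) {
  taxa <- attr(ranked, "taxa")
  cache <- collection_split_cache(coll)
  state <- backbone
  edges <- empty_retic()
  for (i in seq_len(nrow(ranked))) {
    if (nrow(edges) >= cfg$max_reticulations) break
    wt <- ranked$weight[i]
    if (wt < cfg$cutoff) break  # ranked is sorted, nothing below can pass
    key <- ranked$key[i]
    st <- extract_clusters(state, taxa)$key
    if (key %in% st) next  # present in the current state: no conflict
    if (all(vapply(st, function(k) keys_compatible(key, k), TRUE))) next
    side <- key_to_side(ranked$side[i])
    realz <- cluster_realizations(side, state, taxa)
    if (!trusted)
      realz <- c(realz, cluster_realizations(!side, state, taxa))
    if (!length(realz)) next  # second or higher degree of incompatibility
    # score realizations by weighted cumulative RF against the gene trees
    # containing the cluster, then group into unordered piece pairs
    for (k in seq_along(realz)) {
      realz[[k]]$d <- cumulative_rf(realz[[k]]$tree, key, coll, cache)
      if (is.na(realz[[k]]$d)) realz[[k]]$d <- 0
      realz[[k]]$pair <- paste(sort(c(side_key(realz[[k]]$P),
                                      side_key(realz[[k]]$stationary))),
                               collapse = "|")
      realz[[k]]$span <- sum(realz[[k]]$P) + sum(realz[[k]]$stationary)
    }
    pairs <- split(realz, vapply(realz, `[[`, "", "pair"))
    score <- vapply(pairs, function(p) min(vapply(p, `[[`, 0, "d")), 0)
    span <- vapply(pairs, function(p) p[[1]]$span, 0)
    best <- pairs[[order(score, span, names(pairs))[1]]]
    ds <- vapply(best, `[[`, 0, "d")
    mkeys <- vapply(best, function(r) side_key(r$P), "")
    sel <- best[[order(ds, mkeys)[1]]]
    tie <- length(best) == 2 && abs(ds[1] - ds[2]) < 1e-9
    donor <- sel$stationary; recipient <- sel$P
    direction <- if (length(best) == 2 && !tie) "forward"
                 else if (tie && cfg$allow_undirected) "undirected"
                 else "forward"
    if (tie && !cfg$allow_undirected) {
      # deterministic tie-break: donor = lexicographically smaller piece
      if (side_key(donor) > side_key(recipient)) {
        tmp <- donor; donor <- recipient; recipient <- tmp
        sel <- best[[which(mkeys == side_key(recipient))[1]]]
      }
    }
    iv <- if (!is.null(intervals)) intervals(key) else
      list(list(start = NA_integer_, end = NA_integer_))
    for (span_iv in iv) {
      edges <- rbind(edges, data.frame(
        order = nrow(edges) + 1L,
        donor = side_key(donor), recipient = side_key(recipient),
        donor_taxa = taxa_label(donor, taxa),
        recipient_taxa = taxa_label(recipient, taxa),
        direction = direction, weight = wt,
        interval_start = span_iv$start, interval_end = span_iv$end,
        stringsAsFactors = FALSE))
    }
    state <- sel$tree
  }
  list(edges = edges, state = state)
}

#' Build an explicit weighted consensus network from gene trees (Algorithm 1)
#'
#' Builds the weight-based extended majority rule consensus tree as the
#' backbone, then adds the remaining clusters with weight at or above the
#' cutoff that have first-degree incompatibility with the evolving network
#' state as directed reticulation branches.
#'
#' @param coll a [gene_tree_collection()] (at least 2 trees).
#' @param cfg a [network_config()].
#' @return a `consensus_network`: `backbone`, `reticulations` (data frame:
#'   order, donor, recipient, direction, weight, interval), `cutoff`, `taxa`.
#' @export
build_network_from_genetrees <- function(coll, cfg = network_config()) {
  if (coll$n < 2) stop("need at least 2 gene trees")
  ranked <- rank_clusters(coll, cfg$weight_mode)
  backbone <- weighted_extended_majority(ranked)$tree
  res <- add_reticulations(backbone, ranked, coll, cfg,
                           trusted = collection_rooted(coll))
  consensus_network(backbone, res$edges, cfg$cutoff, coll$taxa, res$state)
}

#' Build a horizontal gene transfer network on a species tree (Algorithm 3)
#'
#' The rooted species tree is the fixed backbone; gene tree clusters are
#' weighted and ranked, and those with first-degree incompatibility above the
#' cutoff become directed transfer branches.
#'
#' @param species a rooted `ape::phylo` on the collection's taxon set.
#' @inheritParams build_network_from_genetrees
#' @return a `consensus_network` whose backbone splits are exactly the
#'   species tree's.
#' @export
build_hgt_network <- function(species, coll, cfg = network_config()) {
  if (!ape::is.rooted(species)) stop("the species tree must be rooted")
  if (!setequal(species$tip.label, coll$taxa))
    stop("species tree taxa do not match the gene tree collection")
  attr(species, "taxa") <- coll$taxa
  ranked <- rank_clusters(coll, cfg$weight_mode)
  res <- add_reticulations(species, ranked, coll, cfg,
                           trusted = collection_rooted(coll))
  consensus_network(species, res$edges, cfg$cutoff, coll$taxa, res$state)
}

#' Write the reticulation branches of a network as TSV
#'
#' Columns: order, donor taxa, recipient taxa, direction, weight,
#' interval start/end (1-based inclusive, `NA` for whole-gene events).
#'
#' @param net a `consensus_network`.
#' @param path output file.
#' @export
write_reticulations_tsv <- function(net, path) {
  df <- net$reticulations[, c("order", "donor_taxa", "recipient_taxa",
                              "direction", "weight",
                              "interval_start", "interval_end")]
  df$weight <- round(df$weight, 4)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Extended Newick (eNewick) export of a consensus network
#'
#' Best-effort representation: each reticulation whose recipient side is a
#' clade of the backbone is written as a `#H` hybrid node under its tree
#' parent, with a second `#H` reference attached under the donor branch.
#' Edges whose pieces are not backbone clades (they arose on an already
#' modified network state) are dropped with a warning.
#'
#' @param net a `consensus_network`.
#' @return a single eNewick string.
#' @export
as_enewick <- function(net) {
  taxa <- net$taxa
  bb <- extract_clusters(net$backbone, taxa)
  keys <- bb$key
  hybrids <- list()   # side_key(recipient) -> label
  refs <- list()      # side_key(donor) -> character vector of labels
  dropped <- 0L
  for (i in seq_len(nrow(net$reticulations))) {
    r <- net$reticulations[i, ]
    rec <- key_to_side(r$recipient); don <- key_to_side(r$donor)
    ok <- function(s) sum(s) == 1 || canon_key(s) %in% keys
    if (!ok(rec) || !ok(don)) { dropped <- dropped + 1L; next }
    lab <- paste0("#H", r$order)
    hybrids[[side_key(rec)]] <- lab
    refs[[side_key(don)]] <- c(refs[[side_key(don)]], lab)
  }
  if (dropped)
    warning(dropped, " reticulation(s) not representable on the backbone ",
            "were dropped from the eNewick export")
  sides <- lapply(keys, key_to_side)
  sizes <- vapply(sides, sum, 1L)
  ord <- order(sizes, decreasing = TRUE)
  sides <- sides[ord]; sizes <- sizes[ord]
  k <- length(sides)
  parent <- integer(k)
  for (i in seq_len(k)) {
    parent[i] <- 0L
    if (i > 1) for (j in (i - 1):1)
      if (sizes[j] > sizes[i] && all(sides[[j]][sides[[i]]])) { parent[i] <- j; break }
  }
  m <- length(taxa)
  tip_parent <- vapply(seq_len(m), function(t) {
    best <- 0L; bsz <- m + 1L
    for (i in seq_len(k)) if (sides[[i]][t] && sizes[i] < bsz) { best <- i; bsz <- sizes[i] }
    best
  }, 1L)
  decorate <- function(txt, side) {
    sk <- side_key(side)
    if (!is.null(hybrids[[sk]])) txt <- paste0(txt, hybrids[[sk]])
    for (ref in refs[[sk]])  # hybrid edge leaves from a node on this branch
      txt <- paste0("(", txt, ",", ref, ")")
    txt
  }
  build <- function(node) {
    kids_c <- which(parent == node)
    kids_t <- which(tip_parent == node)
    parts <- c(
      vapply(kids_c, function(i) decorate(build(i), sides[[i]]), ""),
      vapply(kids_t, function(t) {
        s <- rep(FALSE, m); s[t] <- TRUE
        decorate(taxa[t], s)
      }, ""))
    paste0("(", paste(parts, collapse = ","), ")")
  }
  paste0(build(0L), ";")
}
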