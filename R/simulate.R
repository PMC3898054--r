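# Simulation protocol: random binary trees with exponential branch lengths,
# multiplicative clock noise 1 + a*x with x ~ Exp(1), HKY+Gamma sequence
# evolution, and injection of recombination blocks (a recipient clade's
# alignment columns over an interval are re-evolved as if the clade attached
# next to a donor branch), plus TP/FP scoring of recovered reticulations.

#' Simulation settings
#'
#' @param n_taxa leaves of the generating tree (16-64 typical).
#' @param seq_length alignment length in sites (default 400).
#' @param noise_a clock-deviation intensity a in the 1 + a*x branch scaling
#'   (default 0.8).
#' @param hky_tstv transition/transversion ratio (default 2.0).
#' @param gamma_shape shape of the per-site Gamma rate distribution
#'   (default 1.0).
#' @param n_events number of recombination events to inject.
#' @param event_fraction block length as a fraction of `seq_length`
#'   (default 0.3); `n_events * event_fraction` must be at most 1.
#' @param br_rate rate of the exponential branch-length distribution
#'   (default 40, i.e. mean 0.025 substitutions/site per branch, keeping
#'   root-to-tip divergence moderate; the source protocol leaves the scale
#'   unstated and larger means saturate the alignments).
#' @param base_freqs stationary base frequencies (A, C, G, T; equal by
#'   default).
#' @param seed integer master seed.
#' @return list of class `simulation_config`.
#' @export
simulation_config <- function(n_taxa = 16, seq_length = 400, noise_a = 0.8,
                              hky_tstv = 2.0, gamma_shape = 1.0,
                              n_events = 1, event_fraction = 0.3,
                              br_rate = 40, base_freqs = rep(0.25, 4),
                              seed = 1) {
  stopifnot(n_taxa >= 4, seq_length > 0, noise_a >= 0, hky_tstv > 0,
            gamma_shape > 0, n_events >= 0, br_rate > 0,
            length(base_freqs) == 4, abs(sum(base_freqs) - 1) < 1e-8)
  if (n_events * event_fraction > 1)
    stop("recombination blocks do not fit within the alignment")
  structure(as.list(environment()), class = "simulation_config")
}

#' Random binary unrooted tree with exponential branch lengths
#'
#' Random-splitting topology (depth grows logarithmically in the number of
#' leaves) with independent exponential branch lengths.
#'
#' @param n_taxa number of leaves (>= 4).
#' @param seed integer seed.
#' @param br_rate exponential rate for branch lengths.
#' @return an unrooted `ape::phylo`, tips `t01`, `t02`, ...
#' @export
random_tree <- function(n_taxa, seed, br_rate = 40) {
  if (n_taxa < 4) stop("need at least 4 taxa")
  local_seed(seed, {
    phy <- ape::rtree(n_taxa, rooted = FALSE,
                      tip.label = sprintf("t%02d", seq_len(n_taxa)))
    phy$edge.length <- stats::rexp(nrow(phy$edge), rate = br_rate)
    attr(phy, "taxa") <- sort(phy$tip.label)
    attr(phy, "has_supports") <- FALSE
    phy
  })
}

#' Deviate branch lengths from the molecular clock
#'
#' Every branch length is multiplied by an independent 1 + a*x with
#' x ~ Exp(1); a = 0 leaves the tree unchanged.
#'
#' @param phy an `ape::phylo` with branch lengths.
#' @param a noise intensity (>= 0).
#' @param seed integer seed.
#' @return the rescaled tree.
#' @export
apply_clock_noise <- function(phy, a = 0.8, seed = 1) {
  if (a < 0) stop("a must be nonnegative")
  if (a == 0) return(phy)
  local_seed(seed, {
    phy$edge.length <- phy$edge.length *
      (1 + a * stats::rexp(length(phy$edge.length)))
    phy
  })
}

hky_rate_matrix <- function(tstv, freqs) {
  # convert the expected TS/TV ratio into kappa for these frequencies
  kappa <- tstv * (freqs[1] + freqs[3]) * (freqs[2] + freqs[4]) /
    (freqs[1] * freqs[3] + freqs[2] * freqs[4])
  Q <- matrix(0, 4, 4, dimnames = list(DNA_BASES, DNA_BASES))
  for (i in 1:4) for (j in 1:4) {
    if (i == j) next
    ts <- (i %in% c(1, 3) && j %in% c(1, 3)) ||
          (i %in% c(2, 4) && j %in% c(2, 4))
    Q[i, j] <- if (ts) kappa * freqs[j] else freqs[j]
  }
  diag(Q) <- -rowSums(Q)
  mu <- -sum(freqs * diag(Q))   # scale to one expected substitution per unit
  Q / mu
}

# eigendecomposition bundle of the HKY rate matrix
hky_eigen <- function(tstv, base_freqs) {
  eg <- eigen(hky_rate_matrix(tstv, base_freqs))
  list(V = Re(eg$vectors), Vinv = Re(solve(eg$vectors)),
       lam = Re(eg$values))
}

# evolve parent states (integer codes) along one branch of length t_br with
# per-site rate multipliers r; consumes RNG
sim_branch <- function(hk, parent_states, t_br, r) {
  n <- length(parent_states)
  E <- exp(outer(hk$lam, t_br * r))           # 4 x n
  child <- integer(n)
  for (s in 1:4) {
    idx <- which(parent_states == s)
    if (!length(idx)) next
    W <- hk$V[s, ] * E[, idx, drop = FALSE]
    probs <- crossprod(hk$Vinv, W)            # t(Vinv) %*% W
    probs[probs < 0] <- 0
    probs <- sweep(probs, 2, colSums(probs), "/")
    cs <- apply(probs, 2, cumsum)
    if (is.null(dim(cs))) dim(cs) <- c(4L, 1L)
    u <- stats::runif(length(idx))
    child[idx] <- 1L + colSums(sweep(cs, 2, u, "<"))
  }
  child
}

#' Evolve sequences along a tree under HKY + Gamma
#'
#' Site-independent simulation down the tree: per-site rate multipliers are
#' drawn from a Gamma distribution with mean 1 (continuous, not
#' discretized), the root sequence from the stationary frequencies, and each
#' branch applies the HKY transition probabilities for its length times the
#' site rate.  The returned alignment carries the full ancestral state
#' matrix and the site rates as attributes `node_states` / `site_rates`,
#' which [inject_recombination()] uses to transplant blocks consistently.
#'
#' @param phy an `ape::phylo` with nonnegative branch lengths.
#' @param n_sites number of sites to generate.
#' @param tstv transition/transversion ratio (default 2.0).
#' @param gamma_shape Gamma shape for across-site rate variation; `Inf`
#'   disables rate variation.
#' @param base_freqs stationary frequencies (A, C, G, T).
#' @param seed integer seed.
#' @param rates optional fixed per-site rate multipliers (overrides the
#'   Gamma draw).
#' @return an [nc_msa()] of the tip sequences.
#' @export
evolve_hky <- function(phy, n_sites, tstv = 2.0, gamma_shape = 1.0,
                       base_freqs = rep(0.25, 4), seed = 1, rates = NULL) {
  if (is.null(phy$edge.length) || any(phy$edge.length < 0))
    stop("tree must carry nonnegative branch lengths")
  hk <- hky_eigen(tstv, base_freqs)
  m <- length(phy$tip.label)
  local_seed(seed, {
    r <- rates %||%
      (if (is.finite(gamma_shape))
         stats::rgamma(n_sites, shape = gamma_shape, rate = gamma_shape)
       else rep(1, n_sites))
    nn <- max(phy$edge)
    states <- matrix(NA_integer_, nn, n_sites)
    root <- m + 1L
    states[root, ] <- sample.int(4L, n_sites, replace = TRUE,
                                 prob = base_freqs)
    po <- ape::reorder.phylo(phy, "postorder")
    for (k in rev(seq_len(nrow(po$edge)))) {  # preorder: parents first
      states[po$edge[k, 2L], ] <-
        sim_branch(hk, states[po$edge[k, 1L], ], po$edge.length[k], r)
    }
    seqmat <- matrix(DNA_BASES[states[seq_len(m), ]], m, n_sites)
    rownames(seqmat) <- phy$tip.label
    msa <- nc_msa(seqmat[order(rownames(seqmat)), , drop = FALSE],
                  alphabet = "DNA")
    attr(msa, "node_states") <- states
    attr(msa, "site_rates") <- r
    msa
  })
}

#' Inject recombination blocks into a simulated alignment
#'
#' For each event a recipient clade and a disjoint donor branch are chosen
#' (or supplied).  Over the event's interval only the recipient clade's
#' columns are replaced: they are re-evolved from the donor branch's
#' ancestral sequence down the recipient subtree, under the same site rates
#' as the original alignment -- the donor-attachment reading of an
#' intragenic transfer.  Blocks are placed disjointly.
#'
#' @param msa the original [nc_msa()] produced by [evolve_hky()] on `phy`
#'   (its `node_states` / `site_rates` attributes are required).
#' @param phy the generating tree (with branch lengths).
#' @param events an integer event count (donors/recipients/intervals are
#'   sampled), or a data.frame with columns `donor`, `recipient`
#'   (comma-separated taxon labels) and `start`, `end`; a supplied
#'   recipient must be a clade of `phy` as written.
#' @param cfg a [simulation_config()] supplying block fraction and HKY
#'   settings.
#' @param seed integer seed.
#' @return list with `msa` (modified alignment) and `truth`: data.frame
#'   `donor`, `recipient` (side keys over the alignment's taxon order),
#'   `donor_taxa`, `recipient_taxa`, `start`, `end`.
#' @export
inject_recombination <- function(msa, phy, events, cfg = simulation_config(),
                                 seed = 1) {
  taxa <- rownames(msa)
  attr(phy, "taxa") <- taxa
  L <- ncol(msa)
  truth <- data.frame(donor = character(), recipient = character(),
                      donor_taxa = character(), recipient_taxa = character(),
                      start = integer(), end = integer(),
                      stringsAsFactors = FALSE)
  if (is.numeric(events) && length(events) == 1 && events == 0)
    return(list(msa = msa, truth = truth))
  states <- attr(msa, "node_states")
  rates <- attr(msa, "site_rates")
  if (is.null(states) || is.null(rates))
    stop("inject_recombination needs the ancestral states kept by ",
         "evolve_hky(); pass its alignment unmodified")
  splits <- extract_clusters(phy, taxa)$key
  S <- node_sides(phy, taxa)
  m <- length(taxa)
  ntip <- length(phy$tip.label)
  # recipient candidates: clades as written (a child side of some branch)
  clade_nodes <- unique(phy$edge[, 2L])
  clade_ok <- clade_nodes[vapply(clade_nodes, function(v) {
    p <- sum(S[v, ]); p >= 1 && p <= m - 2 && m - p >= 3
  }, TRUE)]
  sides <- all_sides(phy, taxa)
  spec <- NULL
  if (is.data.frame(events)) {
    spec <- events
  } else {
    B <- floor(cfg$event_fraction * L)
    k <- as.integer(events)
    if (k * B > L) stop("blocks do not fit: ", k, " x ", B, " > ", L)
    spec <- local_seed(derive_seed(seed, 1L), {
      free <- L - k * B
      gaps <- sort(sample.int(free + 1L, k, replace = TRUE)) - 1L
      starts <- (seq_len(k) - 1L) * B + gaps + 1L
      recs <- list(); dons <- list()
      for (i in seq_len(k)) {
        tries <- 0L
        repeat {
          tries <- tries + 1L
          if (tries > 1000L)
            stop("could not sample a valid donor/recipient pair")
          P <- S[clade_ok[sample.int(length(clade_ok), 1)], ]
          cand <- Filter(function(D) !any(D & P) && sum(D | P) <= m - 2 &&
                           !(canon_key(D | P) %in% splits), sides)
          if (!length(cand)) next
          D <- cand[[sample.int(length(cand), 1)]]
          recs[[i]] <- P; dons[[i]] <- D
          break
        }
      }
      data.frame(donor = vapply(dons, function(s) taxa_label(s, taxa), ""),
                 recipient = vapply(recs, function(s) taxa_label(s, taxa), ""),
                 start = starts, end = starts + B - 1L,
                 stringsAsFactors = FALSE)
    })
  }
  hk <- hky_eigen(cfg$hky_tstv, cfg$base_freqs)
  out <- unclass(msa)
  for (i in seq_len(nrow(spec))) {
    D <- as_side(strsplit(spec$donor[i], ",")[[1]], taxa)
    P <- as_side(strsplit(spec$recipient[i], ",")[[1]], taxa)
    if (any(D & P)) stop("donor and recipient overlap in event ", i)
    same_rec <- truth$recipient == side_key(P)
    if (any(same_rec & truth$start <= spec$end[i] & truth$end >= spec$start[i]))
      stop("overlapping blocks on one recipient are not allowed")
    # recipient clade root and its stem length
    v_idx <- which(vapply(seq_len(nrow(phy$edge)), function(k)
      identical(S[phy$edge[k, 2L], ], P), TRUE))
    if (!length(v_idx))
      stop("recipient {", spec$recipient[i], "} is not a clade of the tree")
    v <- phy$edge[v_idx[1], 2L]
    stem_len <- phy$edge.length[v_idx[1]]
    # donor attachment: the tree node on the donor side of its branch
    d_node <- NA_integer_
    for (k in seq_len(nrow(phy$edge))) {
      if (identical(S[phy$edge[k, 2L], ], D)) { d_node <- phy$edge[k, 2L]; break }
      if (identical(!S[phy$edge[k, 2L], ], D)) { d_node <- phy$edge[k, 1L]; break }
    }
    if (is.na(d_node))
      stop("donor {", spec$donor[i], "} is not a branch side of the tree")
    blk <- spec$start[i]:spec$end[i]
    rb <- rates[blk]
    in_clade <- vapply(seq_len(nrow(states)), function(nd)
      all(P[S[nd, ]]) && any(S[nd, ]), TRUE)
    local_seed(derive_seed(seed, 100L + i), {
      blk_states <- matrix(NA_integer_, nrow(states), length(blk))
      blk_states[v, ] <- sim_branch(hk, states[d_node, blk], stem_len, rb)
      po <- ape::reorder.phylo(phy, "postorder")
      for (k in rev(seq_len(nrow(po$edge)))) {
        par <- po$edge[k, 1L]; ch <- po$edge[k, 2L]
        if (ch == v || !in_clade[ch] || !in_clade[par]) next
        blk_states[ch, ] <- sim_branch(hk, blk_states[par, ],
                                       po$edge.length[k], rb)
      }
      for (tip in which(in_clade[seq_len(ntip)])) {
        out[phy$tip.label[tip], blk] <- DNA_BASES[blk_states[tip, ]]
      }
    })
    truth <- rbind(truth, data.frame(
      donor = side_key(D), recipient = side_key(P),
      donor_taxa = spec$donor[i], recipient_taxa = spec$recipient[i],
      start = as.integer(spec$start[i]), end = as.integer(spec$end[i]),
      stringsAsFactors = FALSE))
  }
  res <- nc_msa(out, alphabet = attr(msa, "alphabet"))
  list(msa = res, truth = truth)
}

#' Simulate a complete dataset
#'
#' Runs the whole generator chain: random tree, clock noise, HKY+Gamma
#' alignment, recombination-block injection.
#'
#' @param cfg a [simulation_config()].
#' @return list with `tree` (noisy generating tree), `msa`, `truth`.
#' @export
simulate_dataset <- function(cfg = simulation_config()) {
  tr <- random_tree(cfg$n_taxa, derive_seed(cfg$seed, 11L), cfg$br_rate)
  tr <- apply_clock_noise(tr, cfg$noise_a, derive_seed(cfg$seed, 12L))
  msa <- evolve_hky(tr, cfg$seq_length, tstv = cfg$hky_tstv,
                    gamma_shape = cfg$gamma_shape,
                    base_freqs = cfg$base_freqs,
                    seed = derive_seed(cfg$seed, 13L))
  inj <- inject_recombination(msa, tr, cfg$n_events, cfg,
                              seed = derive_seed(cfg$seed, 14L))
  list(tree = tr, msa = inj$msa, truth = inj$truth)
}

#' Score detected reticulations against simulated truth
#'
#' A detected edge is a true positive when its donor and recipient branches
#' both equal a (not yet matched) simulated event's branches; direction is
#' respected for directed detections, while an undirected detection matches
#' either orientation.  Everything else is a false positive.
#'
#' @param truth the `truth` data.frame from [inject_recombination()].
#' @param found reticulation data.frame of a `consensus_network` (or the
#'   network itself).
#' @return list of class `evaluation_result`: `tp`, `fp`, `matches`
#'   (per-detection record).
#' @export
score_detections <- function(truth, found) {
  if (inherits(found, "consensus_network")) found <- found$reticulations
  ck <- function(k) canon_key(key_to_side(k))
  used <- rep(FALSE, nrow(truth))
  tp <- 0L; fp <- 0L
  rec <- character(nrow(found))
  for (i in seq_len(nrow(found))) {
    hit <- FALSE
    for (j in seq_len(nrow(truth))) {
      if (used[j]) next
      dd <- ck(found$donor[i]) == ck(truth$donor[j]) &&
            ck(found$recipient[i]) == ck(truth$recipient[j])
      rv <- ck(found$donor[i]) == ck(truth$recipient[j]) &&
            ck(found$recipient[i]) == ck(truth$donor[j])
      ok <- if (identical(found$direction[i], "undirected")) dd || rv else dd
      if (ok) { used[j] <- TRUE; hit <- TRUE; rec[i] <- paste0("tp:", j); break }
    }
    if (hit) tp <- tp + 1L else { fp <- fp + 1L; rec[i] <- "fp" }
  }
  structure(list(tp = tp, fp = fp, matches = rec),
            class = "evaluation_result")
}

#' @export
print.evaluation_result <- function(x, ...) {
  cat("<evaluation_result> TP ", x$tp, ", FP ", x$fp, "\n", sep = "")
  invisible(x)
}
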