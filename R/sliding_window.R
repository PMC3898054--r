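# Sliding-window detection of intragenic recombination / partial transfers.
#
# Trees are inferred per alignment window; each window tree plays the role of
# one tree of weight 1 in the cluster-weight equations (n = number of
# windows).  Clusters that conflict with the backbone at the first degree of
# incompatibility and reach the weight cutoff become reticulation branches
# annotated with the merged interval span of their supporting windows.

#' Sliding-window specification
#'
#' @param width_fraction window width as a fraction of the alignment length,
#'   in (0, 1].
#' @param step progress step in sites (default 5).
#' @param min_width smallest informative window accepted, in sites
#'   (default 20).
#' @param drop_partial drop (rather than clip) a final partial placement.
#' @return list of class `window_spec`.
#' @export
window_spec <- function(width_fraction, step = 5, min_width = 20,
                        drop_partial = FALSE) {
  if (width_fraction <= 0 || width_fraction > 1)
    stop("width_fraction must lie in (0, 1]")
  if (step < 1) stop("step must be a positive integer")
  structure(list(width_fraction = width_fraction, step = as.integer(step),
                 min_width = as.integer(min_width),
                 drop_partial = isTRUE(drop_partial)),
            class = "window_spec")
}

#' Enumerate window placements over an alignment
#'
#' Full-width windows advance by `step`; when they do not reach the end of
#' the alignment one final placement clipped to the last site is appended
#' (unless `drop_partial`).
#'
#' @param len alignment length in sites (or an [nc_msa()]).
#' @param spec a [window_spec()].
#' @return data.frame with 1-based inclusive `start`, `end`.
#' @export
enumerate_windows <- function(len, spec) {
  if (inherits(len, "nc_msa")) len <- ncol(len)
  width <- floor(spec$width_fraction * len)
  if (width > len) stop("window wider than the alignment")
  if (width < spec$min_width)
    stop("window of ", width, " sites is below the minimum informative ",
         "width (", spec$min_width, ")")
  starts <- seq.int(1L, len - width + 1L, by = spec$step)
  ends <- starts + width - 1L
  if (ends[length(ends)] < len && !spec$drop_partial) {
    starts <- c(starts, starts[length(starts)] + spec$step)
    ends <- c(ends, len)
  }
  data.frame(start = as.integer(starts), end = as.integer(ends))
}

# merge overlapping or adjacent 1-based inclusive intervals
merge_intervals <- function(start, end) {
  o <- order(start, end)
  start <- start[o]; end <- end[o]
  ms <- start[1]; me <- end[1]
  out_s <- integer(); out_e <- integer()
  for (i in seq_along(start)[-1]) {
    if (start[i] <= me + 1L) me <- max(me, end[i])
    else { out_s <- c(out_s, ms); out_e <- c(out_e, me); ms <- start[i]; me <- end[i] }
  }
  data.frame(start = c(out_s, ms), end = c(out_e, me))
}

#' Merge per-window detections of one or more clusters into reticulation
#' records
#'
#' Hits of the same cluster in overlapping or adjacent windows are merged to
#' the union span; disjoint spans stay separate events.  The merged weight is
#' the maximum over contributing windows (or the mean via `rule = "mean"`).
#'
#' @param hits data.frame with columns `key`, `start`, `end`, `weight`.
#' @param rule `"max"` (default) or `"mean"`.
#' @return data.frame with columns `key`, `interval_start`, `interval_end`,
#'   `weight`; one row per merged event.
#' @export
merge_window_detections <- function(hits, rule = c("max", "mean")) {
  rule <- match.arg(rule)
  out <- NULL
  for (k in unique(hits$key)) {
    h <- hits[hits$key == k, , drop = FALSE]
    iv <- merge_intervals(h$start, h$end)
    for (i in seq_len(nrow(iv))) {
      inside <- h$start <= iv$end[i] & h$end >= iv$start[i]
      w <- if (rule == "max") max(h$weight[inside]) else mean(h$weight[inside])
      out <- rbind(out, data.frame(key = k, interval_start = iv$start[i],
                                   interval_end = iv$end[i], weight = w,
                                   stringsAsFactors = FALSE))
    }
  }
  out %||% data.frame(key = character(), interval_start = integer(),
                      interval_end = integer(), weight = numeric())
}

#' Build a recombination / partial-transfer network by sliding-window
#' scanning (Algorithm 2)
#'
#' A tree with supports is inferred for every window placement.  When a
#' species tree is supplied it is the backbone; otherwise the weight-based
#' extended majority rule consensus of the whole-alignment inference is used.
#' Window-tree clusters are pooled (each window = one tree of weight 1,
#' n = number of windows), weighted, ranked, and admitted as interval-
#' annotated reticulations exactly as in the gene-tree network algorithm.
#'
#' @param msa an [nc_msa()].
#' @param spec a [window_spec()].
#' @param cfg a [network_config()].
#' @param backbone optional species tree (`ape::phylo` on the same taxa).
#' @param infer inference contract `(msa, seed) -> supported phylo`; default
#'   [nj_inference()] with 100 bootstrap replicates.
#' @param seed integer seed driving all per-window inference.
#' @return a `consensus_network`; attribute `windows` records the
#'   placements, attribute `failed_windows` any skipped ones.
#' @export
build_recombination_network <- function(msa, spec, cfg = network_config(),
                                        backbone = NULL, infer = NULL,
                                        seed = 1) {
  infer <- infer %||% nj_inference()
  taxa <- rownames(msa)
  win <- enumerate_windows(ncol(msa), spec)
  trees <- list(); spans <- list(); failed <- integer()
  for (i in seq_len(nrow(win))) {
    tr <- tryCatch(
      infer(msa_slice(msa, win$start[i]:win$end[i]), derive_seed(seed, i)),
      error = function(e) NULL)
    if (is.null(tr)) { failed <- c(failed, i); next }
    attr(tr, "taxa") <- taxa
    trees[[length(trees) + 1L]] <- tr
    spans[[length(spans) + 1L]] <- c(win$start[i], win$end[i])
  }
  if (!length(trees)) stop("tree inference failed on every window")
  wcoll <- gene_tree_collection(trees, taxa = taxa)
  if (is.null(backbone)) {
    whole <- infer(msa, derive_seed(seed, 0L))
    attr(whole, "taxa") <- taxa
    ranked1 <- rank_clusters(gene_tree_collection(list(whole), taxa = taxa), "C")
    backbone <- weighted_extended_majority(ranked1)$tree
  } else {
    if (!setequal(backbone$tip.label, taxa))
      stop("backbone taxa do not match the alignment")
    attr(backbone, "taxa") <- taxa
  }
  ranked <- rank_clusters(wcoll, cfg$weight_mode)
  presence <- attr(ranked, "presence_matrix")
  intervals <- function(key) {
    j <- which(presence[match(key, ranked$key), ])
    iv <- merge_intervals(vapply(spans[j], `[`, 1, 1),
                          vapply(spans[j], `[`, 1, 2))
    lapply(seq_len(nrow(iv)), function(i)
      list(start = iv$start[i], end = iv$end[i]))
  }
  res <- add_reticulations(backbone, ranked, wcoll, cfg,
                           trusted = FALSE, intervals = intervals)
  net <- consensus_network(backbone, res$edges, cfg$cutoff, taxa, res$state)
  attr(net, "windows") <- win
  attr(net, "failed_windows") <- failed
  net
}
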