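# Distance-based fallback inference: p-distance / JC69 / K2P matrices,
# neighbor joining (via ape's implementation) and nonparametric bootstrap
# supports, so the pipeline runs without any external tree program.

DNA_BASES <- c("A", "C", "G", "T")

# integer coding of a DNA alignment: A=1 C=2 G=3 T=4, NA elsewhere
encode_dna <- function(msa) {
  x <- match(unclass(msa), DNA_BASES)
  dim(x) <- dim(msa)
  rownames(x) <- rownames(msa)
  x
}

# pairwise counts via indicator matrix products: returns list with `valid`
# (comparable sites), `mismatch`, `ts` (transitions), for DNA codes
pair_counts <- function(code) {
  V <- !is.na(code)
  mode(V) <- "numeric"
  ind <- lapply(1:4, function(b) {
    M <- (code == b & !is.na(code))
    mode(M) <- "numeric"
    M
  })
  valid <- V %*% t(V)
  match_ <- Reduce(`+`, lapply(ind, function(M) M %*% t(M)))
  ts <- ind[[1]] %*% t(ind[[3]]) + ind[[3]] %*% t(ind[[1]]) +
        ind[[2]] %*% t(ind[[4]]) + ind[[4]] %*% t(ind[[2]])
  list(valid = valid, mismatch = valid - match_, ts = ts)
}

# DNA distance matrix from an integer-coded alignment (fast path shared by
# distance_matrix and the bootstrap loop)
dist_from_code <- function(code, model, taxa) {
  cnt <- pair_counts(code)
  if (any(cnt$valid[upper.tri(cnt$valid)] < 1))
    stop("a sequence pair has no comparable site")
  p <- cnt$mismatch / cnt$valid
  d <- p
  sat <- NULL
  bad <- matrix(FALSE, nrow(code), nrow(code))
  if (model == "JC69") {
    arg <- 1 - 4 * p / 3
    bad <- arg <= 0
    d <- ifelse(bad, p, -0.75 * log(pmax(arg, 1e-12)))
  } else if (model == "K2P") {
    P <- cnt$ts / cnt$valid
    Q <- p - P
    a1 <- 1 - 2 * P - Q
    a2 <- 1 - 2 * Q
    bad <- a1 <= 0 | a2 <= 0
    d <- ifelse(bad, p,
                -0.5 * log(pmax(a1, 1e-12)) - 0.25 * log(pmax(a2, 1e-12)))
  }
  if (model != "p" && any(bad[upper.tri(bad)])) {
    idx <- which(bad & upper.tri(bad), arr.ind = TRUE)
    sat <- cbind(taxa[idx[, 1]], taxa[idx[, 2]])
    warning(nrow(sat), " saturated pair(s) fell back to the p-distance")
  }
  diag(d) <- 0
  dimnames(d) <- list(taxa, taxa)
  attr(d, "saturated") <- sat
  d
}

#' Pairwise distance matrix from an alignment
#'
#' Supported models: `"p"` (proportion of differing sites; DNA or amino
#' acid), `"JC69"` and `"K2P"` (DNA).  Sites with a gap or ambiguity in
#' either sequence of a pair are excluded for that pair.  Pairs saturated
#' beyond the model's range fall back to the p-distance and are flagged in
#' the `saturated` attribute.
#'
#' @param msa an [nc_msa()].
#' @param model `"p"`, `"JC69"` or `"K2P"`.
#' @return symmetric numeric matrix with taxon dimnames; attribute
#'   `saturated` lists flagged pairs (two-column matrix).
#' @export
distance_matrix <- function(msa, model = c("p", "JC69", "K2P")) {
  model <- match.arg(model)
  if (nrow(msa) < 3) stop("need at least 3 sequences")
  taxa <- rownames(msa)
  if (attr(msa, "alphabet") == "AA") {
    if (model != "p") stop("model ", model, " requires DNA sequences")
    ch <- unclass(msa)
    ok <- ch != "-" & ch != "?" & ch != "X"
    V <- ok; mode(V) <- "numeric"
    valid <- V %*% t(V)
    aas <- unique(ch[ok])
    match_ <- Reduce(`+`, lapply(aas, function(a) {
      M <- (ch == a & ok); mode(M) <- "numeric"; M %*% t(M)
    }))
    mism <- valid - match_
    if (any(valid[upper.tri(valid)] < 1))
      stop("a sequence pair has no comparable site")
    d <- mism / valid
  } else {
    return(dist_from_code(encode_dna(msa), model, taxa))
  }
  diag(d) <- 0
  dimnames(d) <- list(taxa, taxa)
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Thin wrapper around `ape::nj()` that validates the input and decorates the
#' result with the taxon order; on an additive (tree-metric) matrix the
#' generating topology is recovered exactly.
#'
#' @param d symmetric nonnegative matrix with taxon dimnames (>= 3 taxa).
#' @param taxa taxon order for downstream cluster work (defaults to row
#'   order of `d`).
#' @return an unrooted `ape::phylo`.
#' @export
nj_tree <- function(d, taxa = NULL) {
  if (!is.matrix(d) || nrow(d) != ncol(d) || !isTRUE(all.equal(d, t(d))))
    stop("distance matrix must be symmetric")
  if (nrow(d) < 3) stop("need at least 3 taxa")
  phy <- ape::nj(d)
  attr(phy, "taxa") <- taxa %||% rownames(d)
  attr(phy, "has_supports") <- FALSE
  phy
}

#' Neighbor-joining tree with bootstrap supports
#'
#' Infers the point-estimate NJ topology, then resamples alignment columns
#' `replicates` times; the support of each split of the point tree is the
#' percentage of replicate trees containing it.
#'
#' @param msa an [nc_msa()].
#' @param model distance model, see [distance_matrix()].
#' @param replicates bootstrap replicate count (default 100).
#' @param seed integer seed; resampling is fully reproducible.
#' @return an `ape::phylo` topology with percent supports as node labels.
#' @export
bootstrap_supports <- function(msa, model = "JC69", replicates = 100,
                               seed = 1) {
  if (replicates < 1) stop("replicates must be >= 1")
  taxa <- rownames(msa)
  dna <- attr(msa, "alphabet") == "DNA" && model != "p"
  code <- if (dna) encode_dna(msa) else NULL
  point <- nj_tree(if (dna) dist_from_code(code, model, taxa)
                   else distance_matrix(msa, model), taxa)
  keys <- extract_clusters(point, taxa)$key
  hits <- stats::setNames(numeric(length(keys)), keys)
  L <- ncol(msa)
  local_seed(seed, {
    for (b in seq_len(replicates)) {
      cols <- sample.int(L, L, replace = TRUE)
      d <- suppressWarnings(
        if (dna) dist_from_code(code[, cols, drop = FALSE], model, taxa)
        else distance_matrix(msa_slice(msa, cols), model))
      rep_tree <- nj_tree(d, taxa)
      rk <- extract_clusters(rep_tree, taxa)$key
      hit <- keys %in% rk
      hits[hit] <- hits[hit] + 1
    }
  })
  sup <- 100 * hits / replicates
  tree_from_clusters(keys, taxa, unname(sup))
}

#' Tree-inference contract factory for the sliding-window scan
#'
#' Returns a function `(msa, seed) -> supported phylo` running NJ with
#' bootstrap supports under the given settings.
#'
#' @inheritParams bootstrap_supports
#' @return a function of `(msa, seed)`.
#' @export
nj_inference <- function(model = "JC69", replicates = 100) {
  function(msa, seed) bootstrap_supports(msa, model, replicates, seed)
}
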