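# Gene tree collections: n trees on one taxon set with optional per-tree
# weights W(T_j).  The taxon order of the first tree fixes cluster bit
# positions for the whole collection.

#' Bundle gene trees into a collection
#'
#' @param trees list of `ape::phylo` objects on one taxon set.
#' @param weights optional nonnegative per-tree weights W(T_j); either all or
#'   none must be supplied.  Trees produced by one inference method
#'   conventionally share that method's total weight (caller's contract).
#' @param taxa taxon order; defaults to the first tree's.
#' @return object of class `gene_tree_collection`: list with `trees`,
#'   `weights` (or `NULL`), `taxa`, `n`.
#' @export
gene_tree_collection <- function(trees, weights = NULL, taxa = NULL) {
  if (!length(trees)) stop("empty tree collection")
  taxa <- taxa %||% attr(trees[[1]], "taxa") %||% trees[[1]]$tip.label
  check_taxa(taxa)
  for (i in seq_along(trees)) {
    if (!setequal(trees[[i]]$tip.label, taxa))
      stop("tree ", i, " does not match the collection taxon set")
    attr(trees[[i]], "taxa") <- taxa
  }
  if (!is.null(weights)) {
    if (length(weights) != length(trees) || any(!is.finite(weights)) ||
        any(weights < 0))
      stop("weights must be one finite nonnegative value per tree")
  }
  structure(list(trees = trees, weights = weights, taxa = taxa,
                 n = length(trees)),
            class = "gene_tree_collection")
}

#' @export
print.gene_tree_collection <- function(x, ...) {
  cat("<gene_tree_collection> ", x$n, " trees on ", length(x$taxa), " taxa",
      if (!is.null(x$weights)) " (weighted)", "\n", sep = "")
  invisible(x)
}

#' Read a gene tree list file
#'
#' One Newick per line (or `;`-separated); a line may start with a
#' `weight=<float>` token followed by a tab to supply the tree weight W(T_j).
#'
#' @param path file path.
#' @param support_scale passed to [parse_newick()].
#' @return a [gene_tree_collection()].
#' @export
read_gene_trees <- function(path, support_scale = "auto") {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("no trees in ", path)
  weights <- rep(NA_real_, 0)
  trees <- list(); taxa <- NULL
  for (ln in lines) {
    w <- NA_real_
    if (grepl("^weight=", ln)) {
      parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
      w <- as.numeric(sub("^weight=", "", parts[1]))
      ln <- paste(parts[-1], collapse = "\t")
    }
    for (one in strsplit(ln, "(?<=;)", perl = TRUE)[[1]]) {
      one <- trimws(one)
      if (!nzchar(one)) next
      tr <- parse_newick(one, support_scale = support_scale, taxa = taxa)
      if (is.null(taxa)) taxa <- attr(tr, "taxa")
      trees[[length(trees) + 1L]] <- tr
      weights <- c(weights, w)
    }
  }
  has_w <- !is.na(weights)
  if (any(has_w) && !all(has_w))
    stop("either all trees or none must carry a weight= token")
  gene_tree_collection(trees, weights = if (all(has_w)) weights else NULL,
                       taxa = taxa)
}

#' Write a gene tree collection to a tree list file
#'
#' @param coll a [gene_tree_collection()].
#' @param path output file.
#' @export
write_gene_trees <- function(coll, path) {
  lines <- vapply(seq_len(coll$n), function(i) {
    nwk <- write_newick(coll$trees[[i]])
    if (!is.null(coll$weights))
      paste0("weight=", format(coll$weights[i], trim = TRUE), "\t", nwk)
    else nwk
  }, "")
  writeLines(lines, path)
  invisible(path)
}

# does every tree in the collection carry branch supports?
collection_has_supports <- function(coll) {
  all(vapply(coll$trees, function(t) isTRUE(attr(t, "has_supports")), TRUE))
}

# are all member trees rooted as written (basal bifurcation)?
collection_rooted <- function(coll) {
  all(vapply(coll$trees, ape::is.rooted, TRUE))
}
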