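# Bipartition (cluster/split) algebra over a fixed, ordered taxon set.
#
# A cluster is one side of a bipartition of the taxon set, stored as a logical
# membership vector whose positions follow the taxon order.  Identity,
# compatibility and Robinson-Foulds arithmetic always use the *canonical* key
# (the side not containing the first taxon) so that the two orientations of a
# split compare equal; the designated side is kept alongside because SPR-based
# incompatibility degrees and reticulation endpoints are orientation-sensitive.

#' Create a cluster (split side) on an ordered taxon set
#'
#' @param members character vector of taxon labels forming the cluster side,
#'   or a logical membership vector over `taxa`.
#' @param taxa ordered character vector of all taxon labels; the order fixes
#'   bit positions for canonicalization.
#' @return An object of class `nc_cluster`: a list with `taxa` and logical
#'   `side`.
#' @examples
#' cl <- nc_cluster(c("x", "y"), c("x", "y", "z", "w", "u"))
#' cluster_key(cl)
#' @export
nc_cluster <- function(members, taxa) {
  check_taxa(taxa)
  if (is.logical(members)) {
    if (length(members) != length(taxa))
      stop("logical membership vector must have one entry per taxon")
    side <- members
  } else {
    bad <- setdiff(members, taxa)
    if (length(bad))
      stop("cluster members not in taxon set: ", paste(bad, collapse = ", "))
    side <- taxa %in% members
  }
  if (!any(side) || all(side))
    stop("a cluster must be a proper nonempty subset of the taxon set")
  structure(list(taxa = taxa, side = side), class = "nc_cluster")
}

#' @export
print.nc_cluster <- function(x, ...) {
  cat("<cluster> {", paste(x$taxa[x$side], collapse = ","), "} of ",
      length(x$taxa), " taxa\n", sep = "")
  invisible(x)
}

check_taxa <- function(taxa) {
  if (!is.character(taxa) || anyDuplicated(taxa) || any(!nzchar(taxa)))
    stop("taxa must be unique non-empty labels")
  invisible(taxa)
}

# bitstring of a logical side, e.g. "01100"
side_key <- function(side) paste(as.integer(side), collapse = "")

# canonical key: the orientation that excludes taxon #1
canon_key <- function(side) {
  if (side[1L]) side <- !side
  side_key(side)
}

key_to_side <- function(key) {
  as.integer(charToRaw(key)) == 0x31  # '1'
}

#' Canonical identity key of a cluster
#'
#' Two clusters describing the two sides of the same bipartition share one
#' canonical key (the side that excludes the first taxon).
#' @param cl an [nc_cluster()] or a logical side vector.
#' @return character scalar.
#' @export
cluster_key <- function(cl) {
  if (inherits(cl, "nc_cluster")) canon_key(cl$side) else canon_key(cl)
}

as_side <- function(cl, taxa) {
  if (inherits(cl, "nc_cluster")) {
    if (!identical(cl$taxa, taxa))
      stop("cluster defined on a different taxon set")
    cl$side
  } else if (is.logical(cl)) {
    if (length(cl) != length(taxa)) stop("side vector length mismatch")
    cl
  } else if (is.character(cl) && all(nchar(cl) == 1L | cl %in% taxa)) {
    taxa %in% cl
  } else stop("cannot interpret cluster specification")
}

#' Test split compatibility of two clusters
#'
#' Two splits can coexist in one tree exactly when at least one of the four
#' pairwise side intersections is empty; on canonical sides (both excluding
#' taxon one) this reduces to disjointness or nesting.
#'
#' @param a,b clusters ([nc_cluster()]), logical side vectors, or taxon label
#'   vectors interpreted over `taxa`.
#' @param taxa taxon order; required when `a`/`b` are not `nc_cluster`s.
#' @return logical scalar.
#' @export
are_compatible <- function(a, b, taxa = NULL) {
  if (is.null(taxa)) {
    if (inherits(a, "nc_cluster")) taxa <- a$taxa
    else stop("taxa required")
  }
  sa <- as_side(a, taxa); sb <- as_side(b, taxa)
  if (sa[1L]) sa <- !sa
  if (sb[1L]) sb <- !sb
  !any(sa & sb) || all(sb[sa]) || all(sa[sb])
}

# vectorized compatibility of canonical key strings
keys_compatible <- function(k1, k2) {
  s1 <- key_to_side(k1); s2 <- key_to_side(k2)
  !any(s1 & s2) || all(s2[s1]) || all(s1[s2])
}

# pairwise compatibility matrix for a character vector of canonical keys
compat_matrix <- function(keys) {
  n <- length(keys)
  sides <- lapply(keys, key_to_side)
  m <- matrix(TRUE, n, n)
  if (n < 2) return(m)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    si <- sides[[i]]; sj <- sides[[j]]
    ok <- !any(si & sj) || all(sj[si]) || all(si[sj])
    m[i, j] <- m[j, i] <- ok
  }
  m
}
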