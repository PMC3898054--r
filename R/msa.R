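# Multiple sequence alignments: a character matrix (taxa x sites) with a
# declared alphabet.  FASTA is read through ape; the relaxed PHYLIP dialect
# (name and sequence separated by whitespace, free name length) is parsed
# here because ape's PHYLIP reader expects the strict fixed-width layout.

#' Construct an alignment object
#'
#' @param seqs named character vector of equal-length sequences, or a
#'   character matrix (taxa x sites) with rownames.
#' @param alphabet `"DNA"`, `"AA"` or `"auto"` (detected from the residues).
#' @return object of class `nc_msa`: character matrix with attribute
#'   `alphabet`.
#' @export
nc_msa <- function(seqs, alphabet = c("auto", "DNA", "AA")) {
  alphabet <- match.arg(alphabet)
  if (is.matrix(seqs)) {
    mat <- toupper(seqs)
  } else {
    if (is.null(names(seqs)) || anyDuplicated(names(seqs)))
      stop("sequences must carry unique names")
    lens <- nchar(seqs)
    if (length(unique(lens)) != 1)
      stop("all sequences must have the same length")
    mat <- t(vapply(seqs, function(s) strsplit(toupper(s), "")[[1]],
                    character(lens[1])))
  }
  if (is.null(rownames(mat))) stop("alignment rows must be named by taxon")
  check_taxa(rownames(mat))
  if (alphabet == "auto") {
    res <- mat[mat != "-" & mat != "?" & mat != "N"]
    dna_frac <- mean(res %in% c("A", "C", "G", "T", "U"))
    alphabet <- if (is.nan(dna_frac) || dna_frac >= 0.9) "DNA" else "AA"
  }
  structure(mat, alphabet = alphabet, class = c("nc_msa", "matrix"))
}

#' @export
print.nc_msa <- function(x, ...) {
  cat("<nc_msa> ", nrow(x), " sequences x ", ncol(x), " sites (",
      attr(x, "alphabet"), ")\n", sep = "")
  invisible(x)
}

# column subsetting preserving class and alphabet
msa_slice <- function(msa, cols) {
  structure(unclass(msa)[, cols, drop = FALSE],
            alphabet = attr(msa, "alphabet"), class = class(msa))
}

#' Read an alignment from FASTA or relaxed PHYLIP
#'
#' @param path file path.
#' @param format `"auto"` (sniffed from the first character), `"fasta"` or
#'   `"phylip"`.
#' @param alphabet passed to [nc_msa()].
#' @return an [nc_msa()].
#' @export
read_msa <- function(path, format = c("auto", "fasta", "phylip"),
                     alphabet = "auto") {
  format <- match.arg(format)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty alignment file: ", path)
  if (format == "auto")
    format <- if (startsWith(trimws(lines[1]), ">")) "fasta" else "phylip"
  if (format == "fasta") {
    bin <- ape::read.FASTA(path, type = "AA")  # raw bytes; alphabet resolved below
    seqs <- vapply(as.character(bin), function(x) paste(x, collapse = ""), "")
    return(nc_msa(seqs, alphabet))
  }
  hdr <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  n <- as.integer(hdr[1]); L <- as.integer(hdr[2])
  if (is.na(n) || is.na(L)) stop("malformed PHYLIP header")
  body <- lines[-1]
  # relaxed sequential layout: each record starts with a name token; a
  # record's sequence may continue on following unnamed lines
  seqs <- character(); names_ <- character(); cur <- NULL
  for (ln in body) {
    toks <- strsplit(trimws(ln), "\\s+")[[1]]
    if (is.null(cur) || nchar(gsub("\\s", "", cur)) >= L) {
      if (!is.null(cur)) { seqs <- c(seqs, cur) }
      names_ <- c(names_, toks[1])
      cur <- paste(toks[-1], collapse = "")
    } else {
      cur <- paste0(cur, paste(toks, collapse = ""))
    }
  }
  if (!is.null(cur)) seqs <- c(seqs, cur)
  if (length(seqs) != n || any(nchar(seqs) != L))
    stop("PHYLIP body does not match its header (", n, " x ", L, ")")
  names(seqs) <- names_
  nc_msa(seqs, alphabet)
}

#' Write an alignment as FASTA
#'
#' @param msa an [nc_msa()].
#' @param path output file.
#' @export
write_msa_fasta <- function(msa, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(msa))) {
    writeLines(paste0(">", rownames(msa)[i]), con)
    writeLines(paste(unclass(msa)[i, ], collapse = ""), con)
  }
  invisible(path)
}
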