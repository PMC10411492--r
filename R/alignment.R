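#' Construct a nucleotide alignment
#'
#' An alignment is a character matrix of upper-case nucleotide symbols
#' (`A`, `C`, `G`, `T`, gap `-`, missing `N`) with unique taxon row names.
#' When `codon_frame` is `TRUE` the number of columns must be divisible by
#' three and column `i` is interpreted as codon position `(i - 1) %% 3 + 1`.
#'
#' @param mat character matrix (rows = taxa, columns = sites) or a named
#'   character vector of equal-length sequence strings.
#' @param codon_frame logical; defaults to `TRUE` when the length is a
#'   multiple of three.
#' @return an object of class `dna_alignment` (a character matrix with a
#'   `codon_frame` attribute).
#' @export
new_alignment <- function(mat, codon_frame = NULL) {
  if (is.character(mat) && is.null(dim(mat))) {
    if (is.null(names(mat))) stop("sequence vector must be named by taxon")
    lens <- nchar(mat)
    if (length(unique(lens)) > 1L)
      stop("alignment error: sequences have unequal lengths")
    mat <- do.call(rbind, strsplit(mat, ""))
  }
  if (!is.matrix(mat) || !is.character(mat))
    stop("alignment must be a character matrix")
  if (is.null(rownames(mat))) stop("alignment rows must be named by taxon")
  if (anyDuplicated(rownames(mat)))
    stop("input error: duplicate taxon names in alignment")
  mat[] <- toupper(mat)
  mat[mat == "?"] <- "N"
  if (is.null(codon_frame)) codon_frame <- (ncol(mat) %% 3L == 0L)
  if (codon_frame && ncol(mat) %% 3L != 0L)
    stop("input error: codon_frame set but length not divisible by 3")
  structure(mat, codon_frame = codon_frame, class = c("dna_alignment", "matrix"))
}

#' @export
print.dna_alignment <- function(x, ...) {
  cat(sprintf("<dna_alignment> %d taxa x %d bp%s\n", nrow(x), ncol(x),
              if (isTRUE(attr(x, "codon_frame"))) " (codon frame)" else ""))
  invisible(x)
}

#' Taxa of an alignment
#' @param aln a `dna_alignment`.
#' @return character vector of taxon names.
#' @export
aln_taxa <- function(aln) rownames(aln)

#' Alignment length in base pairs
#' @param aln a `dna_alignment`.
#' @export
aln_length <- function(aln) ncol(aln)

#' Read an aligned FASTA file
#'
#' Sequences must be non-empty and of equal length; duplicate taxon names
#' are rejected.
#'
#' @param path path to a FASTA file.
#' @param codon_frame passed to [new_alignment()].
#' @return a `dna_alignment`.
#' @export
read_fasta <- function(path, codon_frame = NULL) {
  if (!file.exists(path)) stop("input error: no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  hdr <- grepl("^>", lines)
  if (!any(hdr)) stop("input error: not a FASTA file: ", path)
  id <- cumsum(hdr)
  taxa <- sub("^>\\s*", "", lines[hdr])
  taxa <- sub("\\s.*$", "", taxa)
  seqs <- vapply(split(lines[!hdr], id[!hdr]), paste, "", collapse = "")
  if (any(nchar(seqs) == 0L)) stop("input error: empty sequence in ", path)
  names(seqs) <- taxa
  new_alignment(seqs, codon_frame = codon_frame)
}

#' Write an alignment as wrapped FASTA
#'
#' @param aln a `dna_alignment`.
#' @param path output path.
#' @param width line-wrap width (columns).
#' @export
write_fasta <- function(aln, path, width = 80L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (tx in rownames(aln)) {
    s <- paste(aln[tx, ], collapse = "")
    chunks <- substring(s, seq(1L, nchar(s), width),
                        pmin(seq(1L, nchar(s), width) + width - 1L, nchar(s)))
    writeLines(c(paste0(">", tx), chunks), con)
  }
  invisible(path)
}

#' Drop a taxon's sequence from an alignment
#'
#' @param aln a `dna_alignment`.
#' @param taxon taxon name(s) to remove.
#' @return the reduced alignment; columns are unchanged.
#' @export
prune_sequence <- function(aln, taxon) {
  miss <- setdiff(taxon, rownames(aln))
  if (length(miss)) stop("input error: taxon not in alignment: ",
                         paste(miss, collapse = ", "))
  keep <- setdiff(rownames(aln), taxon)
  new_alignment(aln[keep, , drop = FALSE], codon_frame = attr(aln, "codon_frame"))
}

#' Concatenate loci into a supermatrix with a partition scheme
#'
#' Taxa absent from a locus are padded with `N`. The partition scheme uses
#' 1-based inclusive column ranges in locus order (RAxML convention).
#'
#' @param loci named list of `dna_alignment` objects.
#' @return list with `alignment` (the supermatrix) and `partitions`
#'   (data frame: locus, start, end).
#' @export
concatenate_loci <- function(loci) {
  if (is.null(names(loci)) || any(!nzchar(names(loci))))
    names(loci) <- sprintf("locus%d", seq_along(loci))
  taxa <- sort(unique(unlist(lapply(loci, rownames))))
  lens <- vapply(loci, ncol, 0L)
  total <- sum(lens)
  sm <- matrix("N", nrow = length(taxa), ncol = total, dimnames = list(taxa, NULL))
  end <- cumsum(lens)
  start <- end - lens + 1L
  for (i in seq_along(loci)) {
    a <- loci[[i]]
    sm[rownames(a), start[i]:end[i]] <- unclass(a)
  }
  list(alignment = new_alignment(sm, codon_frame = all(lens %% 3L == 0L)),
       partitions = data.frame(locus = names(loci), start = start, end = end,
                               row.names = NULL))
}

#' Write a RAxML-style partition file
#'
#' @param partitions data frame as returned by [concatenate_loci()].
#' @param path output path.
#' @export
write_partitions <- function(partitions, path) {
  writeLines(sprintf("DNA, %s = %d-%d", partitions$locus,
                     partitions$start, partitions$end), path)
  invisible(path)
}

#' Subset an alignment by codon position
#'
#' @param aln a codon-framed `dna_alignment`.
#' @param keep integer vector of codon positions to keep (subset of 1:3).
#' @return the column-subset alignment, in original column order.
#' @export
codon_subset <- function(aln, keep = c(1L, 2L)) {
  if (ncol(aln) %% 3L != 0L)
    stop("input error: alignment length not divisible by 3")
  keep <- sort(unique(as.integer(keep)))
  if (!all(keep %in% 1:3)) stop("input error: codon positions must be in 1:3")
  pos <- ((seq_len(ncol(aln)) - 1L) %% 3L) + 1L
  sub <- unclass(aln)[, pos %in% keep, drop = FALSE]
  new_alignment(sub, codon_frame = length(keep) == 3L)
}

#' Codon position of each alignment column
#' @param aln a codon-framed `dna_alignment`.
#' @return integer vector in 1:3.
#' @export
codon_positions <- function(aln) {
  if (ncol(aln) %% 3L != 0L)
    stop("input error: alignment length not divisible by 3")
  ((seq_len(ncol(aln)) - 1L) %% 3L) + 1L
}

# Integer coding used by the likelihood engine: A,C,G,T -> 0..3, other -> 4.
encode_alignment <- function(aln) {
  m <- matrix(4L, nrow(aln), ncol(aln), dimnames = dimnames(aln))
  for (i in seq_along(c("A", "C", "G", "T")))
    m[unclass(aln) == c("A", "C", "G", "T")[i]] <- i - 1L
  m
}

# Collapse identical site columns into patterns; returns codes (taxa x
# npatterns), weights, and the pattern index of each original site.
site_patterns <- function(codes) {
  key <- apply(codes, 2L, paste, collapse = ",")
  u <- !duplicated(key)
  idx <- match(key, key[u])
  list(codes = codes[, u, drop = FALSE],
       weights = as.numeric(tabulate(idx, nbins = sum(u))),
       index = idx)
}
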