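#' Multiple sequence alignments
#'
#' A `plast_aln` is a lightweight container for a multiple sequence alignment:
#' an ordered set of equal-length gapped DNA strings with taxon labels. It is
#' the common currency of the diversity, selection and marker modules.
#'
#' @param seqs Character vector of equal-length aligned sequences
#'   (`A/C/G/T/N/-` plus IUPAC ambiguity codes, which are treated as `N` by
#'   the statistics), or a named vector, a `Biostrings::DNAStringSet`, or a
#'   character matrix (rows = taxa, one character per cell).
#' @param ids Taxon labels; defaults to names of `seqs` or `seq1..seqN`.
#' @return A `plast_aln` object.
#' @export
#' @examples
#' aln <- as_alignment(c(a = "ACGT", b = "ACGA"))
#' aln_length(aln)
as_alignment <- function(seqs, ids = NULL) {
  if (inherits(seqs, "plast_aln")) return(seqs)
  if (inherits(seqs, "DNAStringSet")) {
    ids <- ids %||% names(seqs)
    seqs <- as.character(seqs)
  }
  if (is.matrix(seqs)) {
    ids <- ids %||% rownames(seqs)
    seqs <- apply(seqs, 1L, paste, collapse = "")
  }
  stopifnot(is.character(seqs))
  ids <- ids %||% names(seqs) %||% paste0("seq", seq_along(seqs))
  seqs <- toupper(unname(seqs))
  if (length(seqs) < 2L) stop("an alignment needs at least 2 sequences", call. = FALSE)
  L <- unique(nchar(seqs))
  if (length(L) != 1L) stop("aligned sequences must all have the same length", call. = FALSE)
  if (anyDuplicated(ids)) stop("duplicate sequence ids in alignment", call. = FALSE)
  structure(list(ids = as.character(ids), seqs = seqs, length = L),
            class = "plast_aln")
}

#' @export
print.plast_aln <- function(x, ...) {
  cat(sprintf("<plast_aln> %d sequences x %d columns\n", length(x$ids), x$length))
  shown <- head(seq_along(x$ids), 6L)
  for (i in shown) {
    s <- x$seqs[i]
    cat(sprintf("  %-20s %s%s\n", x$ids[i],
                substr(s, 1L, min(50L, nchar(s))),
                if (nchar(s) > 50L) "..." else ""))
  }
  if (length(x$ids) > 6L) cat(sprintf("  ... %d more\n", length(x$ids) - 6L))
  invisible(x)
}

#' @rdname as_alignment
#' @param aln A `plast_aln`.
#' @export
aln_length <- function(aln) as_alignment(aln)$length

#' @rdname as_alignment
#' @export
aln_ids <- function(aln) as_alignment(aln)$ids

# character matrix view (rows = taxa); the workhorse representation for
# column statistics. IUPAC ambiguity codes other than N are folded to N here.
aln_mat <- function(aln) {
  aln <- as_alignment(aln)
  m <- matrix(unlist(strsplit(aln$seqs, "", fixed = TRUE), use.names = FALSE),
              nrow = length(aln$seqs), byrow = TRUE)
  rownames(m) <- aln$ids
  if (any(grepl("[^ACGTN-]", aln$seqs, perl = TRUE))) {
    amb <- !(m %in% c("A", "C", "G", "T", "-", "N"))
    m[amb] <- "N"
  }
  m
}

# subset columns, keeping ids
aln_slice <- function(aln, cols) {
  aln <- as_alignment(aln)
  m <- aln_mat(aln)[, cols, drop = FALSE]
  as_alignment(apply(m, 1L, paste, collapse = ""), ids = aln$ids)
}

#' Read/write aligned FASTA
#'
#' Thin wrappers over [Biostrings::readDNAStringSet()] /
#' [Biostrings::writeXStringSet()] returning/consuming `plast_aln`.
#'
#' @param path FASTA file path.
#' @return `read_alignment()` returns a `plast_aln`; `write_alignment()`
#'   returns `path` invisibly.
#' @export
read_alignment <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  as_alignment(ss, ids = sub("\\s.*$", "", names(ss)))
}

#' @rdname read_alignment
#' @param aln A `plast_aln`.
#' @export
write_alignment <- function(aln, path) {
  aln <- as_alignment(aln)
  ss <- Biostrings::DNAStringSet(setNames(aln$seqs, aln$ids))
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}
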