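# Low-level DNA string helpers shared across modules.
#
# Sequences are plain upper-case character scalars over the IUPAC alphabet;
# heavy per-base work converts to character vectors or raw once and stays
# vectorised. Reverse-complementation delegates to Biostrings.

DNA_BASES <- c("A", "C", "G", "T")

# IUPAC code -> set of concrete bases it covers
iupac_sets <- function() {
  if (is.null(.plastdiv_cache$iupac_sets)) {
    m <- Biostrings::IUPAC_CODE_MAP
    .plastdiv_cache$iupac_sets <- lapply(strsplit(unname(m), ""), identity) |>
      setNames(names(m))
  }
  .plastdiv_cache$iupac_sets
}

# minimal IUPAC code covering a set of concrete bases
iupac_code_for <- function(bases) {
  if (is.null(.plastdiv_cache$iupac_rev)) {
    sets <- iupac_sets()
    key <- vapply(sets, function(b) paste(sort(b), collapse = ""), "")
    .plastdiv_cache$iupac_rev <- setNames(names(sets), key)
  }
  code <- .plastdiv_cache$iupac_rev[[paste(sort(unique(bases)), collapse = "")]]
  if (is.null(code)) stop("no IUPAC code for base set: ", paste(bases, collapse = ","))
  code
}

# logical lookup compat[primer_char, template_char]: does the primer symbol
# accept the (possibly ambiguous) template symbol? Degenerate primer semantics:
# compatible iff the template symbol's base set intersects the primer's.
iupac_compat_matrix <- function() {
  if (is.null(.plastdiv_cache$iupac_compat)) {
    sets <- iupac_sets()
    codes <- names(sets)
    m <- matrix(FALSE, length(codes), length(codes), dimnames = list(codes, codes))
    for (p in codes) for (t in codes) {
      m[p, t] <- length(intersect(sets[[p]], sets[[t]])) > 0L
    }
    .plastdiv_cache$iupac_compat <- m
  }
  .plastdiv_cache$iupac_compat
}

#' Reverse-complement DNA strings
#'
#' IUPAC-aware reverse complement of one or more DNA strings.
#'
#' @param x Character vector of DNA strings (IUPAC alphabet, `-` allowed).
#' @return Character vector of the same length.
#' @export
#' @examples
#' revcomp("ACGTN")
revcomp <- function(x) {
  stopifnot(is.character(x))
  has_gap <- grepl("-", x, fixed = TRUE)
  if (any(has_gap)) {
    # DNAStringSet handles '-' but complement() refuses it; swap through a
    # placeholder so gapped alignment rows can be flipped too.
    x <- chartr("-", "+", x)
    out <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
    return(unname(chartr("+", "-", out)))
  }
  unname(as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x))))
}

complement_chars <- function(v) {
  chartr("ACGTRYSWKMBDHVN", "TGCAYRSWMKVHDBN", v)
}

# split a single string into a character vector of single characters
chars <- function(s) strsplit(s, "", fixed = TRUE)[[1]]

# validate a DNA string, returning invisibly; names the offending character
check_dna <- function(s, allow = names(Biostrings::IUPAC_CODE_MAP), what = "sequence") {
  pat <- paste0("[^", paste(allow, collapse = ""), "]")
  if (grepl(pat, s, perl = TRUE)) {
    bad <- setdiff(unique(chars(s)), allow)
    stop(sprintf("non-IUPAC character(s) in %s: %s", what, paste(bad, collapse = " ")),
         call. = FALSE)
  }
  invisible(s)
}

# circular substring: 1-based closed coordinates, end may exceed length
circ_substr <- function(s, start, end) {
  n <- nchar(s)
  if (end <= n) return(substr(s, start, end))
  paste0(substr(s, start, n), substr(s, 1L, end - n))
}

# rotate a circular sequence so that position `start` becomes base 1
rotate_seq <- function(s, start) {
  n <- nchar(s)
  start <- ((start - 1L) %% n) + 1L
  if (start == 1L) return(s)
  paste0(substr(s, start, n), substr(s, 1L, start - 1L))
}

random_dna <- function(n, gc = 0.37) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
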