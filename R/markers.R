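# Hotspot-to-barcode marker design: ungapped marker alignments, IUPAC
# consensus, degenerate primer pairs, in-silico PCR, discriminatory power.

#' Extract an ungapped marker alignment around a hotspot
#'
#' Takes a `flank`-sized window centred on the hotspot midpoint (clipped to
#' the alignment), then drops every column containing a gap, yielding the
#' ungapped marker alignment used for barcode evaluation.
#'
#' @param aln Whole [as_alignment()] alignment.
#' @param hotspot A length-2 numeric `c(start, end)` or one row of a
#'   [detect_hotspots()] tibble.
#' @param flank Window width in alignment columns (default 1000).
#' @param name Marker name.
#' @return A `plast_marker`: a `plast_aln` with attributes `name`,
#'   `window` (clipped window coordinates on the source alignment),
#'   `windowed_length` and `ungapped_length`.
#' @export
extract_marker_alignment <- function(aln, hotspot, flank = 1000L, name = "marker") {
  aln <- as_alignment(aln)
  if (is.data.frame(hotspot)) hotspot <- c(hotspot$start[1], hotspot$end[1])
  stopifnot(length(hotspot) == 2L)
  if (hotspot[1] < 1L || hotspot[2] > aln$length) {
    stop("hotspot interval outside alignment", call. = FALSE)
  }
  mid <- floor((hotspot[1] + hotspot[2]) / 2)
  w1 <- max(1L, as.integer(mid - floor(flank / 2) + 1L))
  w2 <- min(aln$length, w1 + flank - 1L)
  w1 <- max(1L, w2 - flank + 1L)  # re-clip at the right edge
  m <- aln_mat(aln)[, w1:w2, drop = FALSE]
  gapcol <- colSums(m == "-") > 0L
  if (all(gapcol)) stop("marker window empty after gap-column removal", call. = FALSE)
  out <- as_alignment(apply(m[, !gapcol, drop = FALSE], 1L, paste, collapse = ""),
                      ids = aln$ids)
  attr(out, "name") <- name
  attr(out, "window") <- c(w1, w2)
  attr(out, "windowed_length") <- w2 - w1 + 1L
  attr(out, "ungapped_length") <- out$length
  class(out) <- c("plast_marker", class(out))
  out
}

#' Marker diversity and discrimination statistics
#'
#' Delegates to the diversity module: haplotype count and diversity, pi and
#' site-class counts for a marker (or marker combination) alignment.
#'
#' @param marker A marker alignment ([extract_marker_alignment()] /
#'   [combine_markers()] or any `plast_aln`).
#' @return One-row tibble as [diversity_summary()], with a `marker` column.
#' @export
marker_stats <- function(marker) {
  marker <- as_alignment(marker)
  nm <- attr(marker, "name", exact = TRUE) %||% "marker"
  out <- diversity_summary(marker)
  dplyr::bind_cols(tibble(marker = nm), out[, setdiff(names(out), "region")])
}

#' Combine markers by concatenation
#'
#' Column-wise concatenation of two or more markers over the same taxa; the
#' haplotype partition of the result is the common refinement of the input
#' partitions, so discriminatory power can only increase.
#'
#' @param ... Marker alignments, or a single list of them.
#' @param name Name for the combined marker.
#' @return A `plast_marker` of length equal to the sum of input lengths.
#' @export
combine_markers <- function(..., name = NULL) {
  markers <- list(...)
  if (length(markers) == 1L && !inherits(markers[[1]], "plast_aln") &&
      is.list(markers[[1]])) {
    markers <- markers[[1]]
  }
  markers <- lapply(markers, as_alignment)
  ids <- markers[[1]]$ids
  for (m in markers[-1]) {
    if (!identical(sort(m$ids), sort(ids))) {
      stop("markers cover different taxon sets", call. = FALSE)
    }
  }
  seqs <- vapply(seq_along(ids), function(i) {
    paste(vapply(markers, function(m) m$seqs[match(ids[i], m$ids)], ""), collapse = "")
  }, "")
  out <- as_alignment(seqs, ids = ids)
  attr(out, "name") <- name %||%
    paste(vapply(markers, function(m) attr(m, "name", exact = TRUE) %||% "marker", ""), collapse = "+")
  attr(out, "ungapped_length") <- out$length
  class(out) <- c("plast_marker", class(out))
  out
}

#' IUPAC consensus sequence
#'
#' Per column: if the modal base reaches the threshold frequency the modal
#' base is emitted; otherwise the minimal IUPAC code covering every base
#' whose frequency exceeds `1 - threshold`. Gap and `N` characters never
#' enter the consensus (columns of only gaps/N emit `N`).
#'
#' @param aln An (ungapped, typically) [as_alignment()] alignment.
#' @param threshold Consensus threshold in `(0.5, 1]` (default 0.95).
#' @return A single IUPAC DNA string.
#' @export
#' @examples
#' consensus_sequence(as_alignment(c("AG", "AG", "AT")), threshold = 0.95)
consensus_sequence <- function(aln, threshold = 0.95) {
  aln <- as_alignment(aln)
  m <- aln_mat(aln)
  counts <- rbind(
    A = colSums(m == "A"), C = colSums(m == "C"),
    G = colSums(m == "G"), T = colSums(m == "T")
  )
  tot <- colSums(counts)
  vapply(seq_len(ncol(counts)), function(j) {
    if (tot[j] == 0L) return("N")
    fr <- counts[, j] / tot[j]
    if (max(fr) >= threshold) return(names(which.max(fr)))
    cover <- names(fr)[fr > (1 - threshold)]
    if (length(cover) == 0L) cover <- names(which.max(fr))
    iupac_code_for(cover)
  }, "") |> paste(collapse = "")
}

primer_degeneracy <- function(primer) {
  prod(vapply(chars(primer), function(ch) length(iupac_sets()[[ch]]), 0))
}

#' Design a degenerate primer pair around a target
#'
#' Scans the flanks of `target` for primer windows on the marker consensus,
#' minimising IUPAC degeneracy subject to: total degeneracy <= `max_degeneracy`,
#' the three 3'-terminal bases unambiguous and 100% conserved across the
#' alignment, and GC fraction within `gc_range`. The forward primer lies
#' upstream of the target; the reverse primer is the reverse complement of
#' the downstream consensus window (reported 5' to 3' on the opposite
#' strand). The expected amplicon range is the min/max inter-primer span
#' across the aligned rows (ungapped row coordinates).
#'
#' @param marker Marker alignment (ungapped).
#' @param target `c(start, end)` interval (marker columns) the amplicon must
#'   contain.
#' @param primer_len Length-2 range of primer lengths to consider.
#' @param threshold Consensus threshold handed to [consensus_sequence()].
#' @param max_degeneracy Maximum product of per-base IUPAC set sizes.
#' @param gc_range Admissible GC fraction of the consensus window.
#' @return A `primer_pair`: list with `forward`, `reverse` (IUPAC strings),
#'   `fwd_window`, `rev_window` (marker columns), `amplicon_range`.
#' @export
design_primer_pair <- function(marker, target, primer_len = c(18L, 30L),
                               threshold = 0.95, max_degeneracy = 16,
                               gc_range = c(0.3, 0.7)) {
  marker <- as_alignment(marker)
  cons <- consensus_sequence(marker, threshold)
  cv <- chars(cons)
  m <- aln_mat(marker)
  L <- marker$length
  stopifnot(length(target) == 2L, target[1] >= 1L, target[2] <= L)
  conserved <- vapply(seq_len(L), function(j) {
    b <- unique(m[, j])
    length(b) == 1L && b %in% DNA_BASES
  }, TRUE)
  deg1 <- vapply(cv, function(ch) length(iupac_sets()[[ch]]), 0)
  gc1 <- cv %in% c("G", "C", "S")
  scan_side <- function(lo, hi, side) {
    # candidate windows [s, s + len - 1] fully within [lo, hi]
    best <- NULL
    for (len in seq.int(primer_len[1], primer_len[2])) {
      if (hi - lo + 1L < len) next
      for (s in lo:(hi - len + 1L)) {
        e <- s + len - 1L
        three_prime <- if (side == "fwd") (e - 2L):e else s:(s + 2L)
        if (!all(conserved[three_prime])) next
        win_deg <- prod(deg1[s:e])
        if (win_deg > max_degeneracy) next
        gc <- mean(gc1[s:e])
        if (gc < gc_range[1] || gc > gc_range[2]) next
        cand <- list(s = s, e = e, deg = win_deg, len = len)
        if (is.null(best) || cand$deg < best$deg ||
            (cand$deg == best$deg &&
             (if (side == "fwd") cand$s > best$s else cand$s < best$s))) {
          best <- cand
        }
      }
    }
    best
  }
  fwd <- scan_side(1L, target[1] - 1L, "fwd")
  if (is.null(fwd)) {
    stop("no admissible forward primer window upstream of the target ",
         "(degeneracy/3'-conservation/GC constraints unmet)", call. = FALSE)
  }
  rev <- scan_side(target[2] + 1L, L, "rev")
  if (is.null(rev)) {
    stop("no admissible reverse primer window downstream of the target ",
         "(degeneracy/3'-conservation/GC constraints unmet)", call. = FALSE)
  }
  # amplicon span per row, in ungapped row coordinates
  spans <- vapply(seq_along(marker$ids), function(i) {
    row <- m[i, ]
    keep <- row != "-"
    cum <- cumsum(keep)
    cum[rev$e] - cum[fwd$s] + 1L
  }, 0)
  structure(list(
    forward = substr(cons, fwd$s, fwd$e),
    reverse = revcomp(substr(cons, rev$s, rev$e)),
    fwd_window = c(fwd$s, fwd$e),
    rev_window = c(rev$s, rev$e),
    amplicon_range = c(min(spans), max(spans))
  ), class = "primer_pair")
}

#' @export
print.primer_pair <- function(x, ...) {
  cat("<primer_pair>\n")
  cat(sprintf("  forward  5'-%s-3' (cols %d-%d)\n", x$forward,
              x$fwd_window[1], x$fwd_window[2]))
  cat(sprintf("  reverse  5'-%s-3' (cols %d-%d)\n", x$reverse,
              x$rev_window[1], x$rev_window[2]))
  cat(sprintf("  expected amplicon %d-%d bp\n",
              x$amplicon_range[1], x$amplicon_range[2]))
  invisible(x)
}

# mismatch profile of an IUPAC primer laid on a concrete template window;
# returns logical vector (TRUE = mismatch), 5'->3' in primer orientation
primer_mismatches <- function(primer, window) {
  compat <- iupac_compat_matrix()
  p <- chars(primer)
  t <- chars(window)
  !compat[cbind(p, t)]
}

find_bindings <- function(primer, template_v, template_str, max_mm) {
  # candidate start positions where the primer binds with <= max_mm mismatches
  np <- nchar(primer)
  n <- length(template_v)
  if (n < np) return(tibble(start = integer(), mm = integer(), profile = list()))
  compat <- iupac_compat_matrix()
  p <- chars(primer)
  # vectorised: mismatch count per offset via per-position logical shifts
  mm <- integer(n - np + 1L)
  for (q in seq_len(np)) {
    ok <- compat[p[q], template_v[q:(q + n - np)]]
    mm <- mm + !ok
    # early abandon is not worth it in vectorised form
  }
  hits <- which(mm <= max_mm)
  tibble(start = hits, mm = unname(mm[hits]),
         profile = lapply(hits, function(s) {
           primer_mismatches(primer, substr(template_str, s, s + np - 1L))
         }))
}

#' In-silico PCR
#'
#' Predicts amplification of a primer pair on a template under explicit
#' stringency rules. A primer binding passes `stringent` when it has at most
#' 1 total mismatch and no mismatch in the 3 3'-terminal bases; it passes
#' `relaxed` with at most 3 total mismatches and at most 1 mismatch in the 5
#' 3'-terminal bases. IUPAC codes in primers match any compatible template
#' base with zero penalty. Amplification succeeds when a passing
#' forward/reverse binding pair yields a product length within
#' `[0.5, 2] x` the expected amplicon range; the shortest admissible
#' product is reported.
#'
#' @param pair A [design_primer_pair()] result (or a list with `forward`,
#'   `reverse` and optionally `amplicon_range`).
#' @param template Template DNA string.
#' @param stringency `"stringent"` or `"relaxed"`.
#' @param id Template id echoed into the result.
#' @return One-row tibble: `id`, `stringency`, `success`, `amplicon_length`,
#'   `fwd_mismatches`, `rev_mismatches`, `fwd_mm3` / `rev_mm3` (3'-window
#'   mismatch counts under the active rule).
#' @export
insilico_pcr <- function(pair, template, stringency = c("stringent", "relaxed"),
                         id = NA_character_) {
  stringency <- match.arg(stringency)
  template <- toupper(template)
  max_mm <- if (stringency == "stringent") 1L else 3L
  w3 <- if (stringency == "stringent") 3L else 5L
  max_mm3 <- if (stringency == "stringent") 0L else 1L
  tv <- chars(template)
  rc_template <- revcomp(template)
  rcv <- chars(rc_template)
  n <- length(tv)
  passes <- function(b) {
    tail_mm <- vapply(b$profile, function(pr) sum(tail(pr, w3)), 0L)
    b[b$mm <= max_mm & tail_mm <= max_mm3, , drop = FALSE]
  }
  fb <- passes(find_bindings(pair$forward, tv, template, max_mm))
  rb <- passes(find_bindings(pair$reverse, rcv, rc_template, max_mm))
  fail <- tibble(id = id, stringency = stringency, success = FALSE,
                 amplicon_length = NA_integer_,
                 fwd_mismatches = NA_integer_, rev_mismatches = NA_integer_,
                 fwd_mm3 = NA_integer_, rev_mm3 = NA_integer_)
  if (nrow(fb) == 0L || nrow(rb) == 0L) return(fail)
  np_r <- nchar(pair$reverse)
  # reverse primer binds the minus strand; its 5' end maps to plus-strand
  # position n - start + 1, the amplicon runs fwd 5' -> rev 5'
  exp_range <- pair$amplicon_range %||% c(1L, n)
  lo <- floor(0.5 * exp_range[1])
  hi <- ceiling(2 * exp_range[2])
  best <- NULL
  for (i in seq_len(nrow(fb))) {
    f5 <- fb$start[i]
    for (j in seq_len(nrow(rb))) {
      r5 <- n - rb$start[j] + 1L
      len <- r5 - f5 + 1L
      if (len < nchar(pair$forward) + np_r) next
      if (len < lo || len > hi) next
      if (is.null(best) || len < best$len) {
        best <- list(len = len, f = fb[i, ], r = rb[j, ])
      }
    }
  }
  if (is.null(best)) return(fail)
  tibble(id = id, stringency = stringency, success = TRUE,
         amplicon_length = best$len,
         fwd_mismatches = best$f$mm, rev_mismatches = best$r$mm,
         fwd_mm3 = sum(tail(best$f$profile[[1]], w3)),
         rev_mm3 = sum(tail(best$r$profile[[1]], w3)))
}

#' Discriminatory power by exact-sequence search
#'
#' For every query marker sequence, finds all database sequences with 100%
#' identity (exact full-length match). A query scores a unique hit at a
#' given level (species, or a coarser group such as tribe) when every match
#' shares its label at that level; resolution is the fraction of taxa with
#' unique hits.
#'
#' @param seqs Named character vector (taxon id -> marker sequence); the
#'   database is the same set unless `db` is given.
#' @param groups Optional named character vector mapping taxon id -> group
#'   (e.g. tribe) for group-level resolution.
#' @param db Optional database (named character vector); defaults to `seqs`.
#' @return A list with `per_taxon` (tibble: `id`, `n_matches`,
#'   `species_unique`, `group_unique`), `species_resolution` and
#'   `group_resolution` (percentages).
#' @export
discriminatory_power <- function(seqs, groups = NULL, db = NULL) {
  db <- db %||% seqs
  if (length(db) == 0L) stop("empty database", call. = FALSE)
  per <- purrr::imap_dfr(seqs, function(s, id) {
    hits <- names(db)[db == s]
    sp_unique <- length(hits) > 0L && all(hits == id)
    gr_unique <- if (is.null(groups)) NA else {
      length(hits) > 0L && all(groups[hits] == groups[[id]])
    }
    tibble(id = id, n_matches = length(hits),
           species_unique = sp_unique, group_unique = gr_unique)
  })
  list(
    per_taxon = per,
    species_resolution = 100 * mean(per$species_unique),
    group_resolution = if (is.null(groups)) NA_real_ else 100 * mean(per$group_unique)
  )
}
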