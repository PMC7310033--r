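# SSR and long-sequence-repeat (LSR) landscapes.
#
# Definitions follow the comparative-plastome convention: SSRs are perfect
# tandem repeats of a 2-6 bp unit repeated at least three times
# (mononucleotide runs excluded); LSRs are exact repeats of an 11-100 bp unit
# whose copies are separated by spacers of at most 50 bp, in direct (tandem /
# spaced) or inverted (hairpin / palindromic) arrangement, with copies lying
# inside SSR loci removed.

# lexicographically smallest rotation of a repeat unit
canonical_motif <- function(unit) {
  v <- chars(unit)
  rots <- vapply(seq_along(v), function(i) {
    paste(c(v[i:length(v)], if (i > 1) v[1:(i - 1)]), collapse = "")
  }, "")
  min(rots)
}

# is the unit a repetition of a shorter unit?
is_primitive_unit <- function(unit) {
  u <- nchar(unit)
  for (d in seq_len(u - 1)) {
    if (u %% d != 0) next
    if (all(strsplit(gsub(sprintf("(.{%d})", d), "\\1 ", unit), " ")[[1]] ==
            substr(unit, 1, d))) {
      return(FALSE)
    }
  }
  TRUE
}

#' Find simple sequence repeats (microsatellites)
#'
#' Scans a DNA string for maximal perfect tandem repeats with unit length
#' `unit_range` (default 2-6 bp) repeated at least `min_repeats` times.
#' Mononucleotide runs are never reported, repeat motifs are reported as
#' their lexicographically smallest rotation, and a run explainable by
#' several unit lengths is reported once at the smallest (primitive) unit.
#'
#' @param seq DNA string.
#' @param unit_range Length-2 integer vector, smallest and largest unit.
#' @param min_repeats Minimum number of complete repeat units.
#' @return A tibble with one row per SSR locus: `start`, `end` (1-based
#'   closed), `unit`, `motif` (canonical rotation), `unit_len`, `n_repeats`.
#' @export
#' @examples
#' find_ssrs("GGATATATCC")
find_ssrs <- function(seq, unit_range = c(2L, 6L), min_repeats = 3L) {
  seq <- toupper(seq)
  v <- chars(seq)
  n <- length(v)
  out <- list()
  for (u in seq.int(unit_range[1], unit_range[2])) {
    if (n < u * min_repeats) next
    eq <- v[seq_len(n - u)] == v[(u + 1L):n]
    r <- rle(eq)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- which(r$values & (r$lengths + u) >= u * min_repeats)
    last_end <- -1L
    for (k in keep) {
      t0 <- starts[k]
      run <- r$lengths[k]
      n_rep <- (run + u) %/% u
      unit <- substr(seq, t0, t0 + u - 1L)
      if (!is_primitive_unit(unit)) next
      s1 <- t0
      e1 <- t0 + u * n_rep - 1L
      if (s1 <= last_end) {  # rare same-unit overlap; keep the earlier locus
        next
      }
      last_end <- e1
      out[[length(out) + 1L]] <- tibble(
        start = s1, end = e1, unit = unit,
        motif = canonical_motif(unit), unit_len = u, n_repeats = n_rep
      )
    }
  }
  if (length(out) == 0L) {
    return(tibble(start = integer(), end = integer(), unit = character(),
                  motif = character(), unit_len = integer(), n_repeats = integer()))
  }
  dplyr::arrange(dplyr::bind_rows(out), .data$start, .data$unit_len)
}

# Merge direct-repeat pair/array hits that share the same unit string into
# copy groups by greedy left-to-right chaining: copies are sorted by start
# and joined while consecutive spacers stay within max_spacer.
chain_direct_copies <- function(direct, max_spacer) {
  if (length(direct) == 0L) return(direct)
  units <- vapply(direct, function(l) l$unit, "")
  out <- list()
  for (u in unique(units)) {
    cs <- unlist(lapply(direct[units == u], function(l) l$cs))
    ce <- unlist(lapply(direct[units == u], function(l) l$ce))
    o <- order(cs)
    cs <- cs[o]; ce <- ce[o]
    keep <- !duplicated(cs)
    cs <- cs[keep]; ce <- ce[keep]
    chain_s <- cs[1]; chain_e <- ce[1]
    flush <- function(s, e) {
      if (length(s) >= 2L) {
        out[[length(out) + 1L]] <<- list(unit = u, cs = s, ce = e, inverted = FALSE)
      }
    }
    for (q in seq_along(cs)[-1]) {
      gap <- cs[q] - chain_e[length(chain_e)] - 1L
      if (gap >= 0L && gap <= max_spacer) {
        chain_s <- c(chain_s, cs[q]); chain_e <- c(chain_e, ce[q])
      } else if (gap < 0L) {
        next  # overlapping same-unit copy; keep the earlier one
      } else {
        flush(chain_s, chain_e)
        chain_s <- cs[q]; chain_e <- ce[q]
      }
    }
    flush(chain_s, chain_e)
  }
  out
}

#' Find long sequence repeats
#'
#' Detects exact repeats with unit length 11-100 bp whose copies are
#' separated by at most `max_spacer` bp, using seed-and-extend on exact
#' k-mer matches (k = the minimum unit length). Direct repeats are reported
#' as `tandem` (zero spacer) or `spaced`; inverted copies are `hairpin`
#' unless the unit is its own reverse complement, in which case the locus is
#' `palindromic`. Copies falling inside SSR loci are removed; a locus is
#' reported only if it is maximal (not extendable with 100% identity).
#'
#' @param seq DNA string.
#' @param unit_range Allowed unit lengths.
#' @param max_spacer Maximum distance between consecutive copies.
#' @param ssr_loci Optional [find_ssrs()] result on the same sequence used to
#'   drop copies lying inside SSR intervals.
#' @return A tibble with one row per LSR locus: `start`, `end`, `unit`,
#'   `unit_len`, `n_copies`, `arrangement` (`tandem`/`spaced`/`hairpin`/
#'   `palindromic`), and list-columns `copy_start`, `copy_end`, `spacer`.
#' @export
find_lsrs <- function(seq, unit_range = c(11L, 100L), max_spacer = 50L,
                      ssr_loci = NULL) {
  seq <- toupper(seq)
  v <- chars(seq)
  n <- length(v)
  kmin <- unit_range[1]
  kmax <- unit_range[2]
  empty <- tibble(start = integer(), end = integer(), unit = character(),
                  unit_len = integer(), n_copies = integer(),
                  arrangement = character(),
                  copy_start = list(), copy_end = list(), spacer = list())
  if (n < 2L * kmin) return(empty)
  k <- kmin
  win <- kmax + max_spacer  # maximum seed offset worth extending

  # integer k-mer codes (base 5; windows containing non-ACGT never match)
  dig <- match(v, DNA_BASES)      # NA for N etc.
  cdig <- match(complement_chars(v), DNA_BASES)
  dig0 <- ifelse(is.na(dig), 4, dig - 1)
  cdig0 <- ifelse(is.na(cdig), 4, cdig - 1)
  nk <- n - k + 1L
  code <- numeric(nk)
  rccode <- numeric(nk)             # code of revcomp of the window
  for (q in 0:(k - 1L)) {
    code <- code + dig0[(1L + q):(nk + q)] * 5^q
    rccode <- rccode + cdig0[(1L + q):(nk + q)] * 5^(k - 1L - q)
  }
  badwin <- stats::filter(as.numeric(is.na(dig)), rep(1, k), sides = 1)
  badwin <- c(badwin[k:length(badwin)]) > 0
  code[badwin] <- NA
  rccode[badwin] <- NA
  m_eq <- function(a, b) !is.na(dig[a]) && v[a] == v[b] && !is.na(dig[b])
  m_rc <- function(a, b) {
    !is.na(dig[a]) && !is.na(dig[b]) && v[a] == complement_chars(v[b])
  }

  # ---- direct repeats: diagonal runs where code[i] == code[i + d] ----
  direct <- list()
  for (d in seq.int(1L, min(win, nk - 1L))) {
    hits <- which(code[seq_len(nk - d)] == code[(1L + d):nk])
    if (length(hits) == 0L) next
    last_b <- -1L
    for (i in hits) {
      if (i <= last_b) next  # inside an already-extended run on this diagonal
      a <- i
      while (a > 1L && m_eq(a - 1L, a - 1L + d)) a <- a - 1L
      b <- i + k - 1L
      while (b + d < n && m_eq(b + 1L, b + 1L + d)) b <- b + 1L
      last_b <- b
      rl <- b - a + 1L
      if (rl < kmin) next
      if (rl <= d) {
        if (rl > kmax) next
        sp <- d - rl
        if (sp > max_spacer) next
        direct[[length(direct) + 1L]] <- list(
          unit = substr(seq, a, a + rl - 1L),
          cs = c(a, a + d), ce = c(a + rl - 1L, a + d + rl - 1L),
          inverted = FALSE
        )
      } else {
        if (d < kmin || d > kmax) next
        ncp <- rl %/% d + 1L
        cs <- a + d * (seq_len(ncp) - 1L)
        direct[[length(direct) + 1L]] <- list(
          unit = substr(seq, a, a + d - 1L),
          cs = cs, ce = cs + d - 1L, inverted = FALSE
        )
      }
    }
  }

  # ---- inverted repeats: anti-diagonal runs where code[i] == rccode[j],
  # i.e. s[i..i+k-1] == revcomp(s[j..j+k-1]) ----
  inverted <- list()
  seen_cc <- new.env(parent = emptyenv())
  for (d in seq.int(0L, min(2L * kmax + max_spacer, nk - 1L))) {
    j <- seq_len(nk - d)
    hits <- which(code[j] == rccode[j + d])
    if (length(hits) == 0L) next
    for (i in hits) {
      jj <- i + d
      cc <- i + jj + k - 1L  # anti-diagonal: positions t pair with cc - t
      key <- as.character(cc)
      # clamp the seed to the left half of the anti-diagonal (reflect first
      # if it lies entirely right of the centre)
      lo <- i
      hi <- i + k - 1L
      half <- (cc - 1L) %/% 2L
      if (lo > half) {
        lo2 <- cc - hi
        hi <- cc - lo
        lo <- lo2
      }
      hi <- min(hi, half)
      if (lo > hi) next
      prev_a <- seen_cc[[key]]
      if (!is.null(prev_a) && lo >= prev_a[1] && hi <= prev_a[2]) next
      a <- lo
      while (a > 1L && cc - (a - 1L) <= n && m_rc(a - 1L, cc - a + 1L)) a <- a - 1L
      b <- hi
      while (b + 1L <= n && cc - (b + 1L) >= 1L && 2L * (b + 1L) < cc &&
             m_rc(b + 1L, cc - b - 1L)) {
        b <- b + 1L
      }
      seen_cc[[key]] <- c(a, b)
      arm <- b - a + 1L
      if (arm < kmin || arm > kmax) next
      a2 <- cc - b
      sp <- a2 - b - 1L
      if (sp < 0L || sp > max_spacer) next
      inverted[[length(inverted) + 1L]] <- list(
        unit = substr(seq, a, b),
        cs = c(a, a2), ce = c(b, cc - a), inverted = TRUE
      )
    }
  }

  # ---- greedy left-to-right chaining of same-unit direct copies ----
  direct <- chain_direct_copies(direct, max_spacer)
  inverted <- unique(inverted)
  loci <- c(direct, inverted)
  if (length(loci) == 0L) return(empty)

  # drop copies lying inside SSR intervals; a locus needs >= 2 surviving copies
  if (!is.null(ssr_loci) && nrow(ssr_loci) > 0L) {
    loci <- purrr::keep(purrr::map(loci, function(l) {
      inside <- vapply(seq_along(l$cs), function(q) {
        any(ssr_loci$start <= l$cs[q] & ssr_loci$end >= l$ce[q])
      }, TRUE)
      l$cs <- l$cs[!inside]; l$ce <- l$ce[!inside]
      l
    }), function(l) length(l$cs) >= 2L)
    if (length(loci) == 0L) return(empty)
  }

  out <- purrr::map_dfr(loci, function(l) {
    ord <- order(l$cs)
    cs <- l$cs[ord]; ce <- l$ce[ord]
    spacers <- if (length(cs) > 1L) cs[-1L] - ce[-length(ce)] - 1L else integer()
    arrangement <- if (l$inverted) {
      if (identical(revcomp(l$unit), l$unit)) "palindromic" else "hairpin"
    } else {
      if (all(spacers == 0L)) "tandem" else "spaced"
    }
    tibble(
      start = cs[1], end = ce[length(ce)], unit = l$unit,
      unit_len = nchar(l$unit), n_copies = length(cs),
      arrangement = arrangement,
      copy_start = list(cs), copy_end = list(ce), spacer = list(spacers)
    )
  })
  out <- dplyr::distinct(out, .data$start, .data$end, .data$unit_len,
                         .data$arrangement, .keep_all = TRUE)
  dplyr::arrange(out, .data$start, .data$end)
}

#' Annotate repeat loci with genic context and quadripartite region
#'
#' Assigns each repeat locus a genic context (`CDS`, `intron`, `rRNA/tRNA`,
#' or `IGR`) by containment of the locus midpoint, and a quadripartite
#' region (`LSC`/`IRA`/`SSC`/`IRB`); loci spanning a region boundary go to
#' the region containing the larger fraction of the locus (ties to the
#' earlier region). Because IRb is a mirror of IRa, region-level repeat
#' statistics count a single IR copy: by default loci assigned to `IRB` are
#' dropped (`ir_policy = "ira_only"`).
#'
#' @param loci A [find_ssrs()] or [find_lsrs()] tibble.
#' @param record A [plastome()] with features and partition.
#' @param ir_policy `"ira_only"` (drop IRB loci) or `"both"`.
#' @return `loci` with `context` and `region` columns filled.
#' @export
annotate_repeat_context <- function(loci, record, ir_policy = c("ira_only", "both")) {
  ir_policy <- match.arg(ir_policy)
  stopifnot(inherits(record, "plastome"))
  if (is.null(record$partition)) stop("record has no quadripartite partition", call. = FALSE)
  part <- record$partition
  feats <- record$features
  if (nrow(loci) == 0L) {
    loci$context <- character()
    loci$region <- character()
    return(loci)
  }
  mid <- (loci$start + loci$end) %/% 2L
  context <- vapply(mid, function(p) {
    if (!is.null(feats) && nrow(feats) > 0L) {
      hit <- feats[feats$start <= p & feats$end >= p, ]
      if (nrow(hit) > 0L) {
        kinds <- hit$kind
        if ("CDS" %in% kinds) return("CDS")
        if ("intron" %in% kinds) return("intron")
        if (any(kinds %in% c("tRNA", "rRNA"))) return("rRNA/tRNA")
      }
    }
    "IGR"
  }, "")
  region <- vapply(seq_len(nrow(loci)), function(r) {
    ov <- pmin(loci$end[r], part$end) - pmax(loci$start[r], part$start) + 1L
    ov[ov < 0L] <- 0L
    best <- which(ov == max(ov))
    if (length(best) > 1L) best <- best[which.min(part$start[best])]
    part$region[best]
  }, "")
  loci$context <- context
  loci$region <- region
  if (ir_policy == "ira_only") loci <- loci[loci$region != "IRB", ]
  loci
}

#' Cross-genome repeat polymorphism
#'
#' Homologises repeat loci detected independently in each genome by
#' projecting their intervals onto whole-genome alignment columns and
#' merging loci whose projections overlap, then tabulates the per-genome
#' repeat count (SSR) or copy number (LSR). A genome without the locus is
#' recorded as count 0. A homologous locus is polymorphic when at least two
#' distinct per-genome values occur.
#'
#' @param per_genome_loci Named list (genome id -> [find_ssrs()]/[find_lsrs()]
#'   tibble in that genome's own coordinates).
#' @param aln Whole-genome [as_alignment()] containing every genome id.
#' @return A tibble with one row per homologous locus: `locus_id`,
#'   `col_start`, `col_end` (alignment columns), `motif`, `status`
#'   (`monomorphic`/`polymorphic`), and a list-column `counts` (named
#'   integer vector, one entry per genome).
#' @export
repeat_polymorphism <- function(per_genome_loci, aln) {
  aln <- as_alignment(aln)
  ids <- names(per_genome_loci)
  missing_ids <- setdiff(ids, aln$ids)
  if (length(missing_ids) > 0L) {
    stop("genome(s) absent from alignment: ", paste(missing_ids, collapse = ", "),
         call. = FALSE)
  }
  m <- aln_mat(aln)
  # per genome: ungapped position -> alignment column
  posmap <- lapply(ids, function(g) which(m[g, ] != "-"))
  names(posmap) <- ids
  proj <- purrr::imap_dfr(per_genome_loci, function(loci, g) {
    if (nrow(loci) == 0L) return(tibble())
    count <- if ("n_repeats" %in% names(loci)) loci$n_repeats else loci$n_copies
    tibble(
      genome = g,
      col_start = posmap[[g]][loci$start],
      col_end = posmap[[g]][loci$end],
      motif = if ("motif" %in% names(loci)) loci$motif else loci$unit,
      count = as.integer(count)
    )
  })
  if (nrow(proj) == 0L) {
    return(tibble(locus_id = integer(), col_start = integer(), col_end = integer(),
                  motif = character(), status = character(), counts = list()))
  }
  proj <- dplyr::arrange(proj, .data$col_start, .data$col_end)
  # sweep-merge overlapping projected intervals into homologous loci
  cluster <- integer(nrow(proj))
  cur <- 0L
  cur_end <- -1L
  for (r in seq_len(nrow(proj))) {
    if (proj$col_start[r] > cur_end) {
      cur <- cur + 1L
      cur_end <- proj$col_end[r]
    } else {
      cur_end <- max(cur_end, proj$col_end[r])
    }
    cluster[r] <- cur
  }
  proj$cluster <- cluster
  purrr::map_dfr(split(proj, proj$cluster), function(d) {
    counts <- setNames(rep(0L, length(ids)), ids)
    agg <- tapply(d$count, d$genome, sum)  # a genome may hold split copies
    counts[names(agg)] <- as.integer(agg)
    tibble(
      locus_id = d$cluster[1],
      col_start = min(d$col_start),
      col_end = max(d$col_end),
      motif = names(sort(table(d$motif), decreasing = TRUE))[1],
      status = if (length(unique(counts)) >= 2L) "polymorphic" else "monomorphic",
      counts = list(counts)
    )
  })
}
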