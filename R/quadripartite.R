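# Quadripartite structure: IR detection, canonical orientation, junctions.
#
# The inverted-repeat pair is found by seed-and-extend: exact k-mer matches
# between the sequence and its reverse complement anchor candidate
# anti-diagonals, which are then extended allowing a configurable mismatch
# fraction. Circularity is handled by searching on the doubled sequence.

#' Detect the quadripartite plastome structure
#'
#' Finds the longest pair of inverted repeats of at least `min_ir` bp with
#' identity at least `1 - max_mismatch_frac` (N counts as a mismatch); the
#' two copies define IRa/IRb, the longer single-copy interval between them
#' is the LSC and the shorter the SSC. IRa is the copy that follows the LSC
#' clockwise. Ties in repeat length break to the smallest start coordinate.
#'
#' @param rec A [plastome()] (circular).
#' @param min_ir Minimum IR length in bp.
#' @param max_mismatch_frac Maximum tolerated mismatch fraction within the IR.
#' @param k Seed k-mer length for the anchor phase.
#' @return A partition tibble (`region`, `start`, `end`, `length`); `end`
#'   may exceed the sequence length for a region wrapping the origin.
#' @export
detect_quadripartite <- function(rec, min_ir = 10000L, max_mismatch_frac = 0.001,
                                 k = 31L) {
  stopifnot(inherits(rec, "plastome"))
  s <- rec$seq
  n <- nchar(s)
  if (n < 2L * min_ir) {
    stop("no quadripartite structure: sequence shorter than 2 * min_ir", call. = FALSE)
  }
  s2 <- paste0(s, s)
  v2 <- chars(s2)
  comp2 <- complement_chars(v2)
  n2 <- 2L * n
  km <- substring(s2, seq_len(n2 - k + 1L), k:(n2))
  stride <- max(50L, min_ir %/% 20L)
  seed_pos <- seq.int(1L, n, by = stride)
  rck <- revcomp(km[seed_pos])
  hit <- which(km %in% rck)
  if (length(hit) == 0L) {
    stop("no quadripartite structure: no inverted repeat >= ", min_ir, " bp",
         call. = FALSE)
  }
  # anti-diagonal constants c = i + j + k - 1 for every seed pair (i, j);
  # remember one seed position per anti-diagonal
  lookup <- split(seed_pos, rck)
  seed_of <- list()
  for (j in hit) {
    is <- lookup[[km[j]]]
    if (is.null(is)) next
    for (i in is) {
      cc <- i + j + k - 1L
      key <- as.character(cc)
      if (is.null(seed_of[[key]]) || i < seed_of[[key]]) seed_of[[key]] <- i
    }
  }
  best <- NULL
  for (key in names(seed_of)) {
    cc <- as.integer(key)
    i <- seed_of[[key]]
    t_max <- min((cc - 1L) %/% 2L, n2, cc - 1L)
    t_min <- max(1L, cc - n2)
    if (t_max - t_min + 1L < min_ir) next
    if (i < t_min || i + k - 1L > t_max) next
    res <- extend_ir_seed(v2, comp2, cc, i, i + k - 1L, t_min, t_max,
                          max_mismatch_frac)
    a <- res[1]; b <- res[2]
    arm <- b - a + 1L
    if (arm < min_ir) next
    if (b >= cc - b) next
    # both copies and both single-copy gaps must fit on the circle
    if ((cc - b - 1L) - b < 1L) next
    if (n - 2L * arm - ((cc - b - 1L) - b) < 1L) next
    cand <- list(a = a, b = b, c = cc, arm = arm)
    if (is.null(best) || cand$arm > best$arm ||
        (cand$arm == best$arm && ((cand$a - 1L) %% n) < ((best$a - 1L) %% n))) {
      best <- cand
    }
  }
  if (is.null(best)) {
    stop("no quadripartite structure: no inverted repeat >= ", min_ir, " bp",
         call. = FALSE)
  }
  a <- best$a; b <- best$b; cc <- best$c
  ir1 <- c(a, b)                 # first copy on the doubled sequence
  ir2 <- c(cc - b, cc - a)       # second copy
  gap1 <- ir2[1] - ir1[2] - 1L                 # between copy1 end and copy2 start
  gap2 <- n - 2L * best$arm - gap1             # the wrap-around gap
  if (gap1 <= 0L || gap2 <= 0L) {
    stop("no quadripartite structure: inverted repeats leave no single-copy regions",
         call. = FALSE)
  }
  # map to circular coordinates in [1, n]
  norm1 <- function(p) ((p - 1L) %% n) + 1L
  mk <- function(start, len) c(start = norm1(start), end = norm1(start) + len - 1L)
  # region order around the circle: copy1, gap1, copy2, gap2 (wrapping)
  if (gap1 >= gap2) {
    # gap1 is the LSC => the copy *after* the LSC clockwise is copy2
    lsc <- mk(ir1[2] + 1L, gap1)
    ira <- mk(ir2[1], best$arm)
    ssc <- mk(ir2[2] + 1L, gap2)
    irb <- mk(ir1[1], best$arm)
  } else {
    lsc <- mk(ir2[2] + 1L, gap2)
    ira <- mk(ir1[1], best$arm)
    ssc <- mk(ir1[2] + 1L, gap1)
    irb <- mk(ir2[1], best$arm)
  }
  tibble(
    region = c("LSC", "IRA", "SSC", "IRB"),
    start = as.integer(unname(c(lsc[1], ira[1], ssc[1], irb[1]))),
    end = as.integer(unname(c(lsc[2], ira[2], ssc[2], irb[2]))),
    length = as.integer(unname(
      c(lsc[2] - lsc[1], ira[2] - ira[1], ssc[2] - ssc[1], irb[2] - irb[1]) + 1L))
  )
}

# Anchored seed extension along anti-diagonal `cc` (positions t pair with
# cc - t). Extension proceeds through exact matches; a short mismatch run
# (<= gap_max) is crossed only when immediately followed by `anchor`
# consecutive matches and the overall mismatch fraction stays within `frac`.
# This recovers exact boundaries on identical repeats (a random flank cannot
# produce an anchor) while tolerating sparse interior mismatches.
extend_ir_seed <- function(v2, comp2, cc, lo, hi, t_min, t_max, frac,
                           anchor = 25L, gap_max = 5L) {
  m_at <- function(t) v2[t] == comp2[cc - t]
  mism <- 0L
  step <- function(from, dir, other_end) {
    pos <- from
    repeat {
      nxt <- pos + dir
      if (nxt < t_min || nxt > t_max) break
      if (m_at(nxt)) {
        pos <- nxt
        next
      }
      # try to cross a mismatch run ending in an exact anchor
      g <- 1L
      while (g <= gap_max) {
        probe <- pos + dir * (g + 1L)
        if (probe < t_min || probe > t_max) break
        if (m_at(probe)) break
        g <- g + 1L
      }
      anchor_start <- pos + dir * (g + 1L)
      anchor_end <- anchor_start + dir * (anchor - 1L)
      if (anchor_end < t_min || anchor_end > t_max) break
      arm_now <- abs(pos - other_end) + 1L
      if ((mism + g) > floor(frac * (arm_now + g + anchor))) break
      if (!all(vapply(seq.int(anchor_start, anchor_end, by = dir), m_at, TRUE))) break
      mism <<- mism + g
      pos <- anchor_end
    }
    pos
  }
  b <- step(hi, +1L, lo)
  a <- step(lo, -1L, b)
  # right end is additionally capped so the two copies cannot touch
  while (b >= cc - b) b <- b - 1L
  c(a, b)
}

region_interval <- function(partition, region) {
  r <- partition[partition$region == region, ]
  c(start = r$start, end = r$end)
}

# extract region sequence, honouring wrap-around ends
region_seq <- function(rec, region) {
  iv <- region_interval(rec$partition, region)
  circ_substr(rec$seq, iv[1], iv[2])
}

#' Canonicalize a plastome record
#'
#' Rotates (and if necessary complements) the sequence so the region order is
#' LSC, IRa, SSC, IRb with the LSC starting at base 1. Of the two
#' whole-genome orientations the one with the lexicographically smaller LSC
#' string is kept, making canonicalization an involution (the canonical form
#' of a genome and of its reverse complement coincide). The SSC strand is
#' chosen to match `reference` when provided (higher identity to the
#' reference SSC), otherwise the lexicographically smaller of the two SSC
#' orientations. Feature coordinates are remapped through every transform.
#'
#' @param rec A [plastome()].
#' @param partition Optional precomputed [detect_quadripartite()] partition;
#'   detected when missing.
#' @param reference Optional canonical `plastome` used to pick the SSC strand.
#' @param ... Passed to [detect_quadripartite()] when detection is needed.
#' @return The canonicalized `plastome` with its `partition` set.
#' @export
canonicalize <- function(rec, partition = NULL, reference = NULL, ...) {
  stopifnot(inherits(rec, "plastome"))
  partition <- partition %||% rec$partition %||% detect_quadripartite(rec, ...)
  rec1 <- rotate_plastome(rec, partition)
  rc <- revcomp_plastome(rec)
  rec2 <- rotate_plastome(rc, detect_quadripartite(rc, ...))
  lsc1 <- region_seq(rec1, "LSC")
  lsc2 <- region_seq(rec2, "LSC")
  out <- if (lsc2 < lsc1) rec2 else rec1
  # SSC strand
  ssc <- region_seq(out, "SSC")
  ssc_rc <- revcomp(ssc)
  flip <- if (!is.null(reference)) {
    ref_ssc <- region_seq(reference, "SSC")
    ident <- function(x) {
      L <- min(nchar(x), nchar(ref_ssc))
      mean(chars(substr(x, 1, L)) == chars(substr(ref_ssc, 1, L)))
    }
    ident(ssc_rc) > ident(ssc)
  } else {
    ssc_rc < ssc
  }
  if (flip) out <- flip_ssc(out)
  out
}

# rotate so LSC starts at base 1; remap features; set canonical partition
rotate_plastome <- function(rec, partition) {
  n <- seq_length(rec)
  lsc <- region_interval(partition, "LSC")
  off <- lsc[1] - 1L
  seq2 <- rotate_seq(rec$seq, lsc[1])
  f <- rec$features
  if (nrow(f) > 0L) {
    shift <- function(p) ((p - 1L - off) %% n) + 1L
    ns <- shift(f$start)
    ne <- shift(f$end)
    # parts that wrap after rotation keep start <= end by construction of
    # plastome genes (no feature longer than the genome)
    wrap <- ne < ns
    if (any(wrap)) {
      # split is not attempted; keep the wrapped interval on the circle
      ne[wrap] <- ne[wrap] + n
    }
    f$start <- ns
    f$end <- ne
  }
  lens <- setNames(partition$length, partition$region)
  starts <- cumsum(c(1L, lens[c("LSC", "IRA", "SSC")]))
  part <- tibble(
    region = c("LSC", "IRA", "SSC", "IRB"),
    start = as.integer(starts),
    end = as.integer(starts + lens[c("LSC", "IRA", "SSC", "IRB")] - 1L),
    length = as.integer(lens[c("LSC", "IRA", "SSC", "IRB")])
  )
  plastome(rec$id, seq2, rec$taxon, f, part)
}

revcomp_plastome <- function(rec) {
  n <- seq_length(rec)
  f <- rec$features
  if (nrow(f) > 0L) {
    # circular mapping: position p -> n - ((p - 1) mod n); a feature wrapping
    # the origin stays a wrapping interval after complementation
    mp <- function(p) n - ((p - 1L) %% n)
    s2 <- mp(f$end)
    e2 <- mp(f$start)
    wrap <- e2 < s2
    e2[wrap] <- e2[wrap] + n
    f$start <- s2
    f$end <- e2
    f$strand <- ifelse(f$strand == "+", "-", "+")
  }
  plastome(rec$id, revcomp(rec$seq), rec$taxon, f, NULL)
}

flip_ssc <- function(rec) {
  iv <- region_interval(rec$partition, "SSC")
  a <- iv[1]; b <- iv[2]
  seg <- substr(rec$seq, a, b)
  seq2 <- paste0(substr(rec$seq, 1, a - 1L), revcomp(seg),
                 substr(rec$seq, b + 1L, seq_length(rec)))
  f <- rec$features
  if (nrow(f) > 0L) {
    inside <- f$start >= a & f$end <= b
    straddle <- (f$start < a & f$end >= a) | (f$start <= b & f$end > b)
    if (any(straddle)) {
      warning("feature part(s) straddling the SSC boundary left unmapped: ",
              paste(unique(f$name[straddle]), collapse = ", "), call. = FALSE)
    }
    s2 <- a + b - f$end[inside]
    e2 <- a + b - f$start[inside]
    f$start[inside] <- s2
    f$end[inside] <- e2
    f$strand[inside] <- ifelse(f$strand[inside] == "+", "-", "+")
  }
  plastome(rec$id, seq2, rec$taxon, f, rec$partition)
}

#' Junction report
#'
#' For each genome and each of the four region junctions (LSC/IRa, IRa/SSC,
#' SSC/IRb, IRb/LSC) reports the nearest feature on each side, its distance
#' to the junction, and any feature spanning the junction together with how
#' far it extends into the adjacent region.
#'
#' @param recs A list of partitioned, annotated [plastome()] records (or one
#'   record).
#' @return A tibble with one row per genome x junction: `id`, `junction`,
#'   `position` (last base of the left region), `left_feature`, `left_dist`,
#'   `right_feature`, `right_dist`, `spanning_feature`, `span_left_bp`,
#'   `span_right_bp`.
#' @export
junction_report <- function(recs) {
  if (inherits(recs, "plastome")) recs <- list(recs)
  purrr::map_dfr(recs, function(rec) {
    if (is.null(rec$partition)) {
      stop("record ", rec$id, " has no partition; run detect_quadripartite()",
           call. = FALSE)
    }
    n <- seq_length(rec)
    p <- rec$partition
    get_end <- function(region) p$end[p$region == region]
    junctions <- tibble(
      junction = c("LSC-IRA", "IRA-SSC", "SSC-IRB", "IRB-LSC"),
      position = c(get_end("LSC"), get_end("IRA"), get_end("SSC"), get_end("IRB"))
    )
    junctions$position <- ((junctions$position - 1L) %% n) + 1L
    f <- rec$features
    purrr::map_dfr(seq_len(nrow(junctions)), function(i) {
      pos <- junctions$position[i]  # junction sits between pos and pos+1
      row <- tibble(id = rec$id, junction = junctions$junction[i], position = pos,
                    left_feature = NA_character_, left_dist = NA_integer_,
                    right_feature = NA_character_, right_dist = NA_integer_,
                    spanning_feature = NA_character_,
                    span_left_bp = NA_integer_, span_right_bp = NA_integer_)
      if (nrow(f) == 0L) return(row)
      # circular signed distances from the junction boundary
      dist_fw <- function(x) (x - pos - 1L) %% n       # boundary -> start, clockwise
      dist_bw <- function(x) (pos - x) %% n            # end -> boundary
      span <- f$start <= pos & f$end > pos
      if (any(span)) {
        j <- which(span)[1]
        row$spanning_feature <- f$name[j]
        row$span_left_bp <- pos - f$start[j] + 1L
        row$span_right_bp <- f$end[j] - pos
      }
      left_d <- dist_bw(f$end)
      left_d[span] <- NA
      if (any(!is.na(left_d))) {
        j <- which.min(left_d)
        row$left_feature <- f$name[j]
        row$left_dist <- as.integer(left_d[j])
      }
      right_d <- dist_fw(f$start)
      right_d[span] <- NA
      if (any(!is.na(right_d))) {
        j <- which.min(right_d)
        row$right_feature <- f$name[j]
        row$right_dist <- as.integer(right_d[j])
      }
      row
    })
  })
}

#' Extract a locus across records
#'
#' Extracts per-taxon sequences for a named gene (spliced CDS on the coding
#' strand), an intergenic spacer between two adjacent genes (on the forward
#' strand), or an explicit interval. For a `plast_aln` input with an
#' explicit interval, the column slice is returned per row.
#'
#' @param recs List of annotated [plastome()] records, or a [as_alignment()]
#'   alignment (interval extraction only).
#' @param locus A gene name (`"accD"`), a length-2 character vector of
#'   adjacent gene names (`c("trnH", "psbA")`), or `list(start =, end =)`.
#' @return A tibble: `id`, `locus`, `length`, `seq`.
#' @export
extract_locus <- function(recs, locus) {
  if (inherits(recs, "plast_aln")) {
    stopifnot(is.list(locus), !is.null(locus$start), !is.null(locus$end))
    aln <- recs
    sl <- aln_slice(aln, locus$start:locus$end)
    return(tibble(id = sl$ids, locus = sprintf("%d-%d", locus$start, locus$end),
                  length = nchar(sl$seqs), seq = sl$seqs))
  }
  if (inherits(recs, "plastome")) recs <- list(recs)
  lab <- if (is.character(locus)) paste(locus, collapse = "-") else
    sprintf("%d-%d", locus$start, locus$end)
  if (is.character(locus) && length(locus) == 1L) {
    miss <- purrr::keep(recs, function(r) !locus %in% r$features$name)
    if (length(miss) > 0L) {
      stop("gene ", locus, " absent in record(s): ",
           paste(vapply(miss, function(r) r$id, ""), collapse = ", "), call. = FALSE)
    }
    return(purrr::map_dfr(recs, function(r) {
      fp <- r$features[r$features$name == locus & r$features$kind != "intron", ]
      fp <- fp[order(fp$part), ]
      pieces <- vapply(seq_len(nrow(fp)), function(q) {
        circ_substr(r$seq, fp$start[q], fp$end[q])
      }, "")
      s <- if (fp$strand[1] == "-") {
        paste(revcomp(pieces), collapse = "")
      } else {
        paste(pieces, collapse = "")
      }
      tibble(id = r$id, locus = lab, length = nchar(s), seq = s)
    }))
  }
  if (is.character(locus) && length(locus) == 2L) {
    return(purrr::map_dfr(recs, function(r) {
      f <- r$features
      for (g in locus) {
        if (!g %in% f$name) stop("gene ", g, " absent in record ", r$id, call. = FALSE)
      }
      span <- function(g) {
        fg <- f[f$name == g, ]
        c(min(fg$start), max(fg$end))
      }
      s1 <- span(locus[1]); s2 <- span(locus[2])
      lo <- if (s1[2] < s2[1]) s1 else s2
      hi <- if (s1[2] < s2[1]) s2 else s1
      if (lo[2] >= hi[1]) stop("genes ", lab, " overlap in record ", r$id, call. = FALSE)
      between <- f$name[!(f$name %in% locus) & f$kind != "intron" &
                          f$start > lo[2] & f$end < hi[1]]
      if (length(between) > 0L) {
        stop("genes ", lab, " are not adjacent in record ", r$id,
             " (intervening: ", paste(unique(between), collapse = ","), ")",
             call. = FALSE)
      }
      s <- substr(r$seq, lo[2] + 1L, hi[1] - 1L)
      # orient the spacer from the first-named gene towards the second, so
      # extraction commutes with whole-genome reverse complementation
      if (identical(lo, s2)) s <- revcomp(s)
      tibble(id = r$id, locus = lab, length = nchar(s), seq = s)
    }))
  }
  stopifnot(is.list(locus), !is.null(locus$start), !is.null(locus$end))
  purrr::map_dfr(recs, function(r) {
    s <- circ_substr(r$seq, locus$start, locus$end)
    tibble(id = r$id, locus = lab, length = nchar(s), seq = s)
  })
}
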