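#' Classify alignment columns
#'
#' Labels every column of an alignment as `monomorphic`, `singleton`,
#' `parsimony_informative`, or `excluded`. A column is excluded when it
#' contains any gap (`-`) or missing base (`N`; other IUPAC ambiguity codes
#' are treated as `N`). Among the remaining columns, a site is
#' parsimony-informative when at least two alleles are each carried by at
#' least two sequences; a variable site that is not parsimony-informative is
#' a singleton site.
#'
#' @param aln A [as_alignment()] alignment (>= 2 rows).
#' @return A tibble with one row per column: `site`, `class`,
#'   `excluded_reason` (`"gap"`, `"missing"` or `NA`).
#' @export
#' @examples
#' classify_sites(as_alignment(c("ACGT", "ACGA", "ACGA", "ACGT")))
classify_sites <- function(aln) {
  aln <- as_alignment(aln)
  cls <- site_class_info(aln)
  tibble(
    site = seq_len(aln$length),
    class = cls$class,
    excluded_reason = cls$reason
  )
}

# internal: vectorised site classification.
# Returns list(class, reason, counts (4 x L base counts), included (logical))
site_class_info <- function(aln) {
  m <- aln_mat(aln)
  n <- nrow(m)
  has_gap <- colSums(m == "-") > 0L
  has_n <- colSums(m == "N") > 0L
  counts <- rbind(
    A = colSums(m == "A"), C = colSums(m == "C"),
    G = colSums(m == "G"), T = colSums(m == "T")
  )
  included <- !(has_gap | has_n)
  n_alleles <- colSums(counts > 0L)
  pi_site <- n_alleles >= 2L & colSums(counts >= 2L) >= 2L
  cls <- rep("monomorphic", ncol(m))
  cls[n_alleles >= 2L] <- "singleton"
  cls[pi_site] <- "parsimony_informative"
  cls[!included] <- "excluded"
  reason <- rep(NA_character_, ncol(m))
  reason[has_n] <- "missing"
  reason[has_gap] <- "gap"  # gap wins when both occur
  reason[included] <- NA_character_
  list(class = cls, reason = reason, counts = counts, included = included)
}

#' Nucleotide diversity (pi)
#'
#' Average number of nucleotide differences per site between two sequences,
#' over all unordered sequence pairs. Under the default complete-deletion
#' mode every column containing a gap or `N` is excluded for all pairs;
#' under pairwise deletion each pair is compared on the columns where both
#' members carry a concrete base.
#'
#' @inheritParams classify_sites
#' @param deletion `"complete"` (default) or `"pairwise"`.
#' @return pi as a single number in `[0, 1]`.
#' @export
#' @examples
#' nucleotide_diversity(as_alignment(c("AAAAAAAAAA", "AAAAAAAAAT")))
nucleotide_diversity <- function(aln, deletion = c("complete", "pairwise")) {
  aln <- as_alignment(aln)
  deletion <- match.arg(deletion)
  m <- aln_mat(aln)
  n <- nrow(m)
  npairs <- n * (n - 1) / 2
  if (deletion == "complete") {
    info <- site_class_info(aln)
    if (!any(info$included)) stop("no comparable sites", call. = FALSE)
    counts <- info$counts[, info$included, drop = FALSE]
    # per-column total pairwise differences: sum_{a<b} n_a n_b
    dcol <- (n^2 - colSums(counts^2)) / 2
    return(sum(dcol) / (npairs * ncol(counts)))
  }
  ok <- m %in% DNA_BASES
  dim(ok) <- dim(m)
  tot <- 0
  any_sites <- FALSE
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    comp <- ok[i, ] & ok[j, ]
    ns <- sum(comp)
    if (ns == 0L) stop("no comparable sites for pair ", aln$ids[i], "/", aln$ids[j],
                       call. = FALSE)
    any_sites <- TRUE
    tot <- tot + sum(m[i, comp] != m[j, comp]) / ns
  }
  if (!any_sites) stop("no comparable sites", call. = FALSE)
  tot / npairs
}

#' Haplotype statistics
#'
#' Collapses sequences into haplotypes on the non-excluded columns (so indel
#' variation does not split haplotypes unless `include_gaps = TRUE`, which
#' treats the gap character as a fifth allele and only drops columns with
#' `N`). Haplotype diversity uses the small-sample correction
#' `Hd = n/(n-1) * (1 - sum(p_i^2))`.
#'
#' @inheritParams classify_sites
#' @param include_gaps Treat `-` as a fifth character state.
#' @return A list with `n_haplotypes`, `haplotype_diversity`, and
#'   `assignment`, a tibble mapping each sequence id to a haplotype index
#'   (numbered in order of first appearance).
#' @export
haplotype_stats <- function(aln, include_gaps = FALSE) {
  aln <- as_alignment(aln)
  m <- aln_mat(aln)
  if (include_gaps) {
    keep <- colSums(m == "N") == 0L
  } else {
    keep <- site_class_info(aln)$included
  }
  key <- if (any(keep)) {
    apply(m[, keep, drop = FALSE], 1L, paste, collapse = "")
  } else {
    rep("", nrow(m))
  }
  hap <- match(key, unique(key))
  n <- length(hap)
  p <- tabulate(hap) / n
  H <- length(p)
  Hd <- if (H == 1L) 0 else (n / (n - 1)) * (1 - sum(p^2))
  list(
    n_haplotypes = H,
    haplotype_diversity = Hd,
    assignment = tibble(id = aln$ids, haplotype = hap)
  )
}

#' Region-level diversity summary
#'
#' One-row summary of an alignment (or an alignment slice such as a
#' quadripartite region): site-class counts, nucleotide diversity, and
#' haplotype statistics. The parsimony-informative percentage uses the full
#' (gapped) alignment length as denominator.
#'
#' @inheritParams nucleotide_diversity
#' @param region Optional label stored in the `region` column.
#' @return A one-row tibble: `region`, `n_seq`, `aln_length`,
#'   `n_excluded_sites`, `n_variable`, `n_singleton`, `n_pi`, `pct_pi`, `pi`,
#'   `n_haplotypes`, `haplotype_diversity`.
#' @export
diversity_summary <- function(aln, region = NA_character_,
                              deletion = c("complete", "pairwise")) {
  aln <- as_alignment(aln)
  deletion <- match.arg(deletion)
  cls <- site_class_info(aln)$class
  hp <- haplotype_stats(aln)
  tibble(
    region = region,
    n_seq = length(aln$ids),
    aln_length = aln$length,
    n_excluded_sites = sum(cls == "excluded"),
    n_variable = sum(cls %in% c("singleton", "parsimony_informative")),
    n_singleton = sum(cls == "singleton"),
    n_pi = sum(cls == "parsimony_informative"),
    pct_pi = 100 * sum(cls == "parsimony_informative") / aln$length,
    pi = nucleotide_diversity(aln, deletion),
    n_haplotypes = hp$n_haplotypes,
    haplotype_diversity = hp$haplotype_diversity
  )
}

#' Per-region diversity summary in one pass
#'
#' Computes the Table-2-style per-region polymorphism summary (site-class
#' counts, pi, haplotype statistics) for a set of column intervals — e.g.
#' the quadripartite regions of a whole-plastome alignment — using a single
#' pass over the alignment. Intervals sharing a region label (such as the
#' two IR copies) are combined into one row.
#'
#' @inheritParams classify_sites
#' @param regions Tibble with columns `region`, `start`, `end` (alignment
#'   columns, 1-based closed).
#' @param whole Also emit a first row summarising the full alignment.
#' @return A tibble like [diversity_summary()], one row per region label.
#' @export
region_diversity_summary <- function(aln, regions, whole = TRUE) {
  aln <- as_alignment(aln)
  m <- aln_mat(aln)
  n <- nrow(m)
  npairs <- n * (n - 1) / 2
  info <- site_class_info(aln)
  dcol <- (n^2 - colSums(info$counts^2)) / 2
  one <- function(cols, label) {
    cls <- info$class[cols]
    inc <- info$included[cols]
    m_inc <- sum(inc)
    if (m_inc == 0L) stop("no comparable sites in region ", label, call. = FALSE)
    pi <- sum(dcol[cols][inc]) / (npairs * m_inc)
    keep <- cols[inc]
    key <- apply(m[, keep, drop = FALSE], 1L, paste, collapse = "")
    hap <- match(key, unique(key))
    p <- tabulate(hap) / n
    H <- length(p)
    tibble(
      region = label, n_seq = n, aln_length = length(cols),
      n_excluded_sites = sum(cls == "excluded"),
      n_variable = sum(cls %in% c("singleton", "parsimony_informative")),
      n_singleton = sum(cls == "singleton"),
      n_pi = sum(cls == "parsimony_informative"),
      pct_pi = 100 * sum(cls == "parsimony_informative") / length(cols),
      pi = pi,
      n_haplotypes = H,
      haplotype_diversity = if (H == 1L) 0 else (n / (n - 1)) * (1 - sum(p^2))
    )
  }
  out <- list()
  if (whole) out[["whole"]] <- one(seq_len(aln$length), "whole")
  for (lab in unique(regions$region)) {
    rr <- regions[regions$region == lab, ]
    cols <- unlist(lapply(seq_len(nrow(rr)), function(i) rr$start[i]:rr$end[i]))
    out[[lab]] <- one(cols, lab)
  }
  dplyr::bind_rows(out)
}

#' Sliding-window nucleotide diversity
#'
#' Computes pi in sliding windows over the alignment (defaults: 1 kb windows,
#' 100 bp steps). Window coordinates are alignment coordinates; exclusion of
#' gap/N columns is window-local, i.e. pi for a window is computed on the
#' included columns of that slice only.
#'
#' @inheritParams classify_sites
#' @param window Window width in alignment columns.
#' @param step Step between window starts.
#' @return A tibble of class `plast_windows` with columns `start`, `end`
#'   (1-based closed), `mid`, `n_included`, `pi`; attributes `window` and
#'   `step`.
#' @export
sliding_window_pi <- function(aln, window = 1000L, step = 100L) {
  aln <- as_alignment(aln)
  L <- aln$length
  if (L < window) {
    stop(sprintf("alignment length %d is shorter than window %d; choose a smaller window",
                 L, window), call. = FALSE)
  }
  info <- site_class_info(aln)
  n <- length(aln$ids)
  npairs <- n * (n - 1) / 2
  dcol <- (n^2 - colSums(info$counts^2)) / 2
  dcol[!info$included] <- 0
  inc <- as.numeric(info$included)
  cum_d <- c(0, cumsum(dcol))
  cum_i <- c(0, cumsum(inc))
  starts <- as.integer(seq.int(1L, L - window + 1L, by = step))
  ends <- as.integer(starts + window - 1L)
  m_inc <- cum_i[ends + 1L] - cum_i[starts]
  dsum <- cum_d[ends + 1L] - cum_d[starts]
  pi <- ifelse(m_inc > 0, dsum / (npairs * m_inc), NA_real_)
  out <- tibble(
    start = starts, end = ends, mid = (starts + ends) / 2,
    n_included = as.integer(m_inc), pi = pi
  )
  attr(out, "window") <- as.integer(window)
  attr(out, "step") <- as.integer(step)
  class(out) <- c("plast_windows", class(out))
  out
}

#' Divergence hotspots from a window profile
#'
#' Merges maximal runs of consecutive windows whose pi exceeds the threshold
#' into hotspot intervals. When a feature table is supplied, each hotspot is
#' labelled with the names of overlapping genes/intergenic loci.
#'
#' @param profile A [sliding_window_pi()] result.
#' @param threshold pi cutoff (default 0.006); windows with `pi > threshold`
#'   are hotspot windows.
#' @param features Optional tibble with columns `name`, `start`, `end`
#'   (alignment coordinates) used to label hotspots.
#' @return A tibble with one row per hotspot: `start`, `end`, `n_windows`,
#'   `max_pi`, `loci` (comma-separated labels or `NA`).
#' @export
detect_hotspots <- function(profile, threshold = 0.006, features = NULL) {
  stopifnot(all(c("start", "end", "pi") %in% names(profile)))
  hot <- !is.na(profile$pi) & profile$pi > threshold
  if (!any(hot)) {
    return(tibble(start = integer(), end = integer(), n_windows = integer(),
                  max_pi = numeric(), loci = character()))
  }
  r <- rle(hot)
  idx_end <- cumsum(r$lengths)
  idx_start <- idx_end - r$lengths + 1L
  runs <- which(r$values)
  out <- purrr::map_dfr(runs, function(k) {
    i <- idx_start[k]:idx_end[k]
    tibble(
      start = min(profile$start[i]),
      end = max(profile$end[i]),
      n_windows = length(i),
      max_pi = max(profile$pi[i])
    )
  })
  out$loci <- NA_character_
  if (!is.null(features) && nrow(out) > 0L) {
    out$loci <- vapply(seq_len(nrow(out)), function(k) {
      ov <- features$start <= out$end[k] & features$end >= out$start[k]
      if (!any(ov)) NA_character_ else paste(unique(features$name[ov]), collapse = ",")
    }, "")
  }
  out
}

#' Pairwise identity matrix
#'
#' Percent identity between every pair of aligned sequences, computed with
#' pairwise deletion: columns where either member carries a gap or `N` are
#' dropped for that pair. The diagonal is 100.
#'
#' @inheritParams classify_sites
#' @return A symmetric numeric matrix (percent, `[0, 100]`) with sequence ids
#'   as dimnames.
#' @export
pairwise_identity <- function(aln) {
  aln <- as_alignment(aln)
  m <- aln_mat(aln)
  n <- nrow(m)
  ok <- m %in% DNA_BASES
  dim(ok) <- dim(m)
  out <- matrix(100, n, n, dimnames = list(aln$ids, aln$ids))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    comp <- ok[i, ] & ok[j, ]
    ns <- sum(comp)
    val <- if (ns == 0L) NA_real_ else 100 * sum(m[i, comp] == m[j, comp]) / ns
    out[i, j] <- out[j, i] <- val
  }
  out
}

#' Neighbor-joining tree from a distance matrix
#'
#' Convenience grouping tree over a symmetric distance matrix (for identity
#' matrices use `100 - identity`). Negative branch lengths produced by the
#' NJ algorithm are clamped to zero. Tie handling is deterministic in the
#' input label order.
#'
#' @param d Symmetric numeric distance matrix with dimnames.
#' @return A Newick string (also invisibly carries the `phylo` object as
#'   attribute `tree`).
#' @export
nj_tree <- function(d) {
  d <- as.matrix(d)
  if (!isSymmetric(unname(d), tol = 1e-8)) {
    stop("distance matrix must be symmetric", call. = FALSE)
  }
  tr <- ape::nj(as.dist(d))
  tr$edge.length[tr$edge.length < 0] <- 0
  nwk <- ape::write.tree(tr)
  attr(nwk, "tree") <- tr
  nwk
}

#' @importFrom stats as.dist
NULL
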