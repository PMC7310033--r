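#' Prepare codon pairs from a coding-sequence alignment
#'
#' Splits an in-frame codon alignment into one codon pair per unordered taxon
#' pair, masking codons that cannot enter the Ka/Ks estimators: codons
#' containing a gap or `N` in either member, terminal stop codons (stripped),
#' and internal stop codons remaining after masking (masked with a warning).
#'
#' @param aln A [as_alignment()] alignment of CDS sequences whose columns are
#'   in frame (length divisible by 3).
#' @return A tibble with one row per unordered pair: `id1`, `id2`, and a
#'   list-column `pair` of codon-pair objects consumed by [kaks_ng86()] and
#'   [kaks_yn00()].
#' @export
prepare_codon_pairs <- function(aln) {
  aln <- as_alignment(aln)
  if (aln$length %% 3 != 0) {
    stop("alignment length ", aln$length, " not divisible by 3; not in frame",
         call. = FALSE)
  }
  n <- length(aln$ids)
  idx <- which(upper.tri(matrix(TRUE, n, n)), arr.ind = TRUE)
  purrr::map_dfr(seq_len(nrow(idx)), function(k) {
    i <- idx[k, 1]; j <- idx[k, 2]
    tibble(id1 = aln$ids[i], id2 = aln$ids[j],
           pair = list(codon_pair(aln$seqs[i], aln$seqs[j])))
  })
}

#' @rdname prepare_codon_pairs
#' @param seq1,seq2 Two equal-length in-frame CDS strings.
#' @export
codon_pair <- function(seq1, seq2) {
  seq1 <- toupper(seq1); seq2 <- toupper(seq2)
  if (nchar(seq1) != nchar(seq2)) stop("codon pair sequences differ in length", call. = FALSE)
  c1 <- split_codons(seq1)
  c2 <- split_codons(seq2)
  gcmap <- genetic_code()
  clean <- function(cc) !grepl("[^ACGT]", cc)
  masked <- !(clean(c1) & clean(c2))
  aa1 <- ifelse(masked, NA, unname(gcmap[c1]))
  aa2 <- ifelse(masked, NA, unname(gcmap[c2]))
  nc <- length(c1)
  # strip terminal stop codons
  if (nc > 0 && !masked[nc] && (aa1[nc] == "*" || aa2[nc] == "*")) {
    c1 <- c1[-nc]; c2 <- c2[-nc]; masked <- masked[-nc]
    aa1 <- aa1[-nc]; aa2 <- aa2[-nc]
  }
  internal_stop <- !masked & (aa1 == "*" | aa2 == "*")
  if (any(internal_stop, na.rm = TRUE)) {
    warning(sum(internal_stop), " internal stop codon(s) masked", call. = FALSE)
    masked <- masked | internal_stop
  }
  structure(list(codons1 = c1, codons2 = c2, masked = masked),
            class = "codon_pair")
}

#' Truncate a CDS at its first in-frame stop codon
#'
#' Helper for frameshifted genes (e.g. a single-base indel creating a
#' premature stop): returns the open reading frame up to, and excluding, the
#' first stop codon so the truncated CDS can still enter the pairwise Ka/Ks
#' screen.
#'
#' @param seq A CDS string (length need not be a multiple of 3; trailing
#'   partial codon is dropped).
#' @return The truncated in-frame CDS string.
#' @export
truncate_cds_at_stop <- function(seq) {
  seq <- toupper(seq)
  n3 <- (nchar(seq) %/% 3) * 3
  cod <- split_codons(substr(seq, 1L, n3))
  gcmap <- genetic_code()
  aa <- ifelse(grepl("[^ACGT]", cod), "X", unname(gcmap[cod]))
  stop_at <- which(aa == "*")
  if (length(stop_at) == 0L) return(substr(seq, 1L, n3))
  paste(cod[seq_len(stop_at[1] - 1L)], collapse = "")
}

ks_status <- function(ka, ks, saturated) {
  if (saturated) "saturated" else if (!is.na(ks) && ks == 0) "Ks_zero" else "ok"
}

jc_correct <- function(p) {
  if (p >= 0.75) return(NA_real_)
  -0.75 * log(1 - 4 * p / 3)
}

# K80 correction from transition proportion P and transversion proportion Q
k80_correct <- function(P, Q) {
  a1 <- 1 - 2 * P - Q
  a2 <- 1 - 2 * Q
  if (a1 <= 0 || a2 <= 0) return(NA_real_)
  -0.5 * log(a1) - 0.25 * log(a2)
}

kaks_row <- function(method, pair, S, N, Sd, Nd, ka, ks, kappa, saturated) {
  status <- ks_status(ka, ks, saturated)
  tibble(
    method = method,
    n_codons = sum(!pair$masked),
    S = S, N = N, Sd = Sd, Nd = Nd,
    ka = ka, ks = ks,
    omega = if (status == "ok" && !is.na(ks) && ks > 0) ka / ks else NA_real_,
    kappa = kappa,
    status = status
  )
}

#' Pairwise Ka/Ks by the Nei-Gojobori (1986) method
#'
#' Counts synonymous (S) and non-synonymous (N) sites per codon by the
#' 1/3-fraction rule under the standard genetic code (mutations to stop
#' codons disregarded), averages multi-hit codon differences over all
#' minimal mutational pathways that avoid stop codons, and applies the
#' Jukes-Cantor correction to the difference proportions.
#'
#' @param pair A [codon_pair()] (or the `pair` list-column element from
#'   [prepare_codon_pairs()]).
#' @return A one-row tibble: `method`, `n_codons`, `S`, `N`, `Sd`, `Nd`,
#'   `ka`, `ks`, `omega`, `kappa` (`NA` for NG86), `status`
#'   (`ok`/`Ks_zero`/`saturated`). `omega` is defined only for status `ok`;
#'   pairs with `Ks = 0` report status `Ks_zero`, never an infinite ratio.
#' @export
kaks_ng86 <- function(pair) {
  stopifnot(inherits(pair, "codon_pair"))
  keep <- !pair$masked
  if (!any(keep)) stop("no included codons", call. = FALSE)
  c1 <- pair$codons1[keep]
  c2 <- pair$codons2[keep]
  st <- ng86_site_table()
  S <- (sum(st[c1, ]) + sum(st[c2, ])) / 2
  N <- 3 * length(c1) - S
  pt <- codon_path_tables()
  ij <- cbind(match(c1, rownames(pt$syn_ts)), match(c2, colnames(pt$syn_ts)))
  Sd <- sum(pt$syn_ts[ij]) + sum(pt$syn_tv[ij])
  Nd <- sum(pt$non_ts[ij]) + sum(pt$non_tv[ij])
  ps <- if (S > 0) Sd / S else 0
  pn <- if (N > 0) Nd / N else 0
  ks <- jc_correct(ps)
  ka <- jc_correct(pn)
  saturated <- is.na(ks) || is.na(ka)
  kaks_row("NG86", pair, S, N, Sd, Nd, ka, ks, NA_real_, saturated)
}

# kappa (ts/tv rate ratio) from fourfold-degenerate and nondegenerate sites,
# K80-corrected; positions enter a class only when both codons agree on it.
estimate_kappa <- function(pair) {
  keep <- !pair$masked
  c1 <- pair$codons1[keep]
  c2 <- pair$codons2[keep]
  deg <- codon_degeneracy_table()
  b1 <- matrix(unlist(strsplit(c1, ""), use.names = FALSE), ncol = 3, byrow = TRUE)
  b2 <- matrix(unlist(strsplit(c2, ""), use.names = FALSE), ncol = 3, byrow = TRUE)
  d1 <- deg[c1, , drop = FALSE]
  d2 <- deg[c2, , drop = FALSE]
  est_one <- function(cls) {
    sel <- d1 == cls & d2 == cls
    n <- sum(sel)
    if (n < 10) return(c(kappa = NA_real_, n = n))
    x <- b1[sel]; y <- b2[sel]
    diff <- x != y
    P <- sum(diff & is_transition(x, y)) / n
    Q <- sum(diff & !is_transition(x, y)) / n
    a1 <- 1 - 2 * P - Q
    a2 <- 1 - 2 * Q
    if (a1 <= 0 || a2 <= 0) return(c(kappa = NA_real_, n = n))
    ats <- -0.5 * log(a1) + 0.25 * log(a2)
    btv <- -0.25 * log(a2)
    if (btv <= 0) return(c(kappa = NA_real_, n = n))
    c(kappa = max(ats / btv, 1e-3), n = n)
  }
  e4 <- est_one(4L)
  e0 <- est_one(0L)
  ks <- c(e4["kappa"], e0["kappa"])
  ws <- c(e4["n"], e0["n"])
  ok <- !is.na(ks)
  if (!any(ok)) return(NA_real_)
  sum(ks[ok] * ws[ok]) / sum(ws[ok])
}

#' Pairwise Ka/Ks by the Yang-Nielsen (2000) approximate method
#'
#' Approximate maximum-likelihood-flavoured pairwise estimator: the
#' transition/transversion ratio kappa is estimated from fourfold-degenerate
#' and nondegenerate sites with a K80 correction; synonymous and
#' non-synonymous site counts are weighted by kappa and (optionally) by
#' observed codon frequencies; difference counts are pathway-averaged and
#' split into transitions/transversions so that Ks and Ka each receive a
#' K80-style (HKY-flavoured) multiple-hit correction. Site counts and
#' distances are iterated to convergence (successive Ka and Ks changing by
#' `< 1e-8`, at most 100 iterations).
#'
#' @inheritParams kaks_ng86
#' @param kappa Fix kappa instead of estimating it (e.g. `1` for the NG86
#'   limit). When estimation fails for lack of variation, kappa falls back
#'   to 1 with a warning.
#' @param codon_freqs `"observed"` (default) weights mutation targets by the
#'   codon frequencies observed in the pair; `"uniform"` weights all sense
#'   targets equally. With `kappa = 1` and uniform frequencies the site
#'   counts reduce to NG86's.
#' @return Same shape as [kaks_ng86()], with the kappa estimate filled in.
#' @export
kaks_yn00 <- function(pair, kappa = NULL, codon_freqs = c("observed", "uniform")) {
  stopifnot(inherits(pair, "codon_pair"))
  codon_freqs <- match.arg(codon_freqs)
  keep <- !pair$masked
  if (!any(keep)) stop("no included codons", call. = FALSE)
  c1 <- pair$codons1[keep]
  c2 <- pair$codons2[keep]
  if (is.null(kappa)) {
    kappa <- estimate_kappa(pair)
    if (is.na(kappa)) {
      warning("not enough variation to estimate kappa; fixed to 1", call. = FALSE)
      kappa <- 1
    }
  }
  sc <- sense_codons()
  freq <- if (codon_freqs == "observed") {
    f <- (tabulate(match(c1, sc), length(sc)) + tabulate(match(c2, sc), length(sc)))
    f <- f / sum(f)
    # flat prior mass keeps unseen mutation targets reachable
    (f + 1 / length(sc)) / 2
  } else {
    rep(1 / length(sc), length(sc))
  }
  names(freq) <- sc
  wf <- function(from, to, b_from, b_to) {
    (if (is_transition(b_from, b_to)) kappa else 1) * freq[[to]]
  }
  site_tab <- t(vapply(sc, codon_site_fractions, numeric(3), weight_fun = wf))
  pt <- codon_path_tables()
  ij <- cbind(match(c1, sc), match(c2, sc))
  sd_ts <- sum(pt$syn_ts[ij]); sd_tv <- sum(pt$syn_tv[ij])
  nd_ts <- sum(pt$non_ts[ij]); nd_tv <- sum(pt$non_tv[ij])
  Sd <- sd_ts + sd_tv
  Nd <- nd_ts + nd_tv
  S <- (sum(site_tab[c1, ]) + sum(site_tab[c2, ])) / 2
  N <- 3 * length(c1) - S
  ka_prev <- Inf; ks_prev <- Inf
  ka <- ks <- NA_real_
  saturated <- FALSE
  for (iter in seq_len(100L)) {
    ks <- if (S > 0) k80_correct(sd_ts / S, sd_tv / S) else NA_real_
    ka <- if (N > 0) k80_correct(nd_ts / N, nd_tv / N) else NA_real_
    if (is.na(ks) || is.na(ka)) { saturated <- TRUE; break }
    if (abs(ks - ks_prev) < 1e-8 && abs(ka - ka_prev) < 1e-8) break
    ks_prev <- ks; ka_prev <- ka
    # site counts depend on kappa and codon frequencies only, so the
    # iteration settles as soon as the distances reproduce themselves
  }
  if (saturated) {
    # report last finite iterate where available
    ks <- if (is.na(ks)) ks_prev else ks
    ka <- if (is.na(ka)) ka_prev else ka
    if (!is.finite(ks)) ks <- NA_real_
    if (!is.finite(ka)) ka <- NA_real_
  }
  if (!saturated && Sd == 0 && Nd == 0) { ka <- 0; ks <- 0 }
  kaks_row("YN00", pair, S, N, Sd, Nd, ka, ks, kappa, saturated)
}

#' Pairwise Ka/Ks table for a set of gene alignments
#'
#' Runs the chosen estimator on every unordered taxon pair of every gene and
#' returns the long, plot-ready table behind [gene_selection_summary()].
#'
#' @param gene_alns Named list of in-frame codon alignments (one per gene).
#' @param method `"yn00"` (default) or `"ng86"`.
#' @return A tibble: `gene`, `id1`, `id2`, plus the estimator columns.
#' @export
kaks_pairwise_table <- function(gene_alns, method = c("yn00", "ng86")) {
  method <- match.arg(method)
  stopifnot(is.list(gene_alns), !is.null(names(gene_alns)))
  fun <- if (method == "yn00") kaks_yn00 else kaks_ng86
  purrr::imap_dfr(gene_alns, function(aln, gene) {
    aln <- as_alignment(aln)
    if (length(aln$ids) < 2L) {
      warning("gene ", gene, " has fewer than 2 sequences; skipped", call. = FALSE)
      return(tibble())
    }
    pairs <- prepare_codon_pairs(aln)
    res <- purrr::map_dfr(pairs$pair, fun)
    dplyr::bind_cols(tibble(gene = gene, id1 = pairs$id1, id2 = pairs$id2), res)
  })
}

#' Per-gene selection summary
#'
#' Screens genes for departures from purifying selection the way comparative
#' plastome studies do: mean pairwise omega (pairs with `Ks = 0` are excluded
#' from the mean and counted separately), nucleotide diversity, identical
#' site percentage, and mean pairwise similarity, ranked by pi. Genes whose
#' mean omega exceeds `flag_threshold` are flagged as candidates for relaxed
#' or positive selection.
#'
#' @inheritParams kaks_pairwise_table
#' @param flag_threshold Mean-omega cutoff for the `candidate` flag.
#' @return A tibble with one row per gene: `gene`, `aln_length`, `n_seq`,
#'   `mean_similarity`, `pct_identical_sites`, `pi`, `n_haplotypes`,
#'   `n_variable`, `n_singleton`, `n_pi`, `mean_omega`, `n_pairs_ok`,
#'   `n_pairs_ks_zero`, `candidate`; the long pairwise table is attached as
#'   attribute `pairs` (for box plots, see [plot_omega()]).
#' @export
gene_selection_summary <- function(gene_alns, method = c("yn00", "ng86"),
                                   flag_threshold = 0.5) {
  method <- match.arg(method)
  keep <- vapply(gene_alns, function(a) length(as_alignment(a)$ids) >= 2L, TRUE)
  if (!all(keep)) {
    warning("skipping gene(s) with fewer than 2 sequences: ",
            paste(names(gene_alns)[!keep], collapse = ", "), call. = FALSE)
  }
  gene_alns <- gene_alns[keep]
  long <- kaks_pairwise_table(gene_alns, method)
  per_gene <- purrr::imap_dfr(gene_alns, function(aln, gene) {
    aln <- as_alignment(aln)
    ds <- diversity_summary(aln)
    idm <- pairwise_identity(aln)
    cls <- site_class_info(aln)$class
    tibble(
      gene = gene,
      aln_length = aln$length,
      n_seq = ds$n_seq,
      mean_similarity = mean(idm[upper.tri(idm)]),
      pct_identical_sites = 100 * sum(cls == "monomorphic") / aln$length,
      pi = ds$pi,
      n_haplotypes = ds$n_haplotypes,
      n_variable = ds$n_variable,
      n_singleton = ds$n_singleton,
      n_pi = ds$n_pi
    )
  })
  omega_stats <- long %>%
    dplyr::group_by(.data$gene) %>%
    dplyr::summarise(
      mean_omega = if (any(.data$status == "ok")) {
        mean(.data$omega[.data$status == "ok"])
      } else NA_real_,
      n_pairs_ok = sum(.data$status == "ok"),
      n_pairs_ks_zero = sum(.data$status == "Ks_zero"),
      .groups = "drop"
    )
  out <- dplyr::left_join(per_gene, omega_stats, by = "gene") %>%
    dplyr::mutate(candidate = !is.na(.data$mean_omega) &
                    .data$mean_omega > flag_threshold) %>%
    dplyr::arrange(dplyr::desc(.data$pi))
  attr(out, "pairs") <- long
  out
}
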