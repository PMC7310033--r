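# Synthetic plastome clades with known truth.
#
# The generator emulates the statistical structure of a small congeneric
# plastome panel: a ~151 kb circular quadripartite genome (LSC ~83 kb,
# SSC ~18.3 kb, IR ~24.95 kb), region-specific substitution rates
# (SSC > LSC >> IR), two planted coding hotspots (accD-like and ycf1-like)
# carrying an exact, known haplotype structure, planted SSR/LSR loci with
# per-taxon copy-number polymorphism, and an optional single-base deletion
# creating a premature stop in a named gene. Taxa evolve along a scaled
# coalescent tree; IR mutations are applied to a single scaffold copy and
# mirrored, so IRa and IRb stay exact reverse complements. The true
# alignment is emitted from the known homology, so no external aligner is
# involved.

#' Simulation specification
#'
#' Builds the parameter object consumed by [simulate_clade()]. Region
#' substitution rates are on the expected-pi scale: the clade tree is scaled
#' to mean pairwise distance 1, so a region's expected nucleotide diversity
#' equals its rate. Planted hotspots carry an exact haplotype structure
#' (`k` allele classes defined by nested substitutions at
#' `sites_per_step` positions per class) instead of background
#' substitutions, so their haplotype counts and window-diversity excess are
#' known truth.
#'
#' @param seed Integer seed; the seed fully determines the output.
#' @param n_taxa Number of taxa (default 16).
#' @param lsc_len,ssc_len,ir_len Region lengths in bp.
#' @param rates Named vector of per-region expected-pi rates
#'   (`IR`, `LSC`, `SSC`).
#' @param hotspot_k Named integer vector: planted haplotype classes per
#'   hotspot locus.
#' @param sites_per_step Planted substitutions distinguishing consecutive
#'   haplotype classes.
#' @param hotspot_multiplier Rate multiplier for hotspots without planted
#'   haplotype structure.
#' @param premature_stops Tibble (`gene`, `taxon`) of single-base deletions
#'   to inject (1-based taxon index), creating a frameshift.
#' @param tree Optional fixed Newick string; default draws a random
#'   coalescent tree.
#' @return A `sim_spec` list.
#' @export
simulation_spec <- function(seed = 1L, n_taxa = 16L,
                            lsc_len = 83000L, ssc_len = 18300L, ir_len = 24950L,
                            rates = c(IR = 6e-4, LSC = 3e-3, SSC = 5e-3),
                            hotspot_k = c(accD = 4L, ycf1 = 6L),
                            sites_per_step = 8L,
                            hotspot_multiplier = 6,
                            premature_stops = tibble(gene = "rpoA", taxon = 3L),
                            tree = NULL) {
  stopifnot(n_taxa >= 2L, all(rates >= 0), all(c("IR", "LSC", "SSC") %in% names(rates)))
  hotspot_k <- pmin(hotspot_k, n_taxa)  # cannot plant more classes than taxa
  genes <- default_gene_table(lsc_len, ssc_len, ir_len)
  hotspots <- default_hotspot_table(genes)
  repeats <- default_repeat_table(lsc_len, ssc_len, ir_len)
  spec <- structure(list(
    seed = as.integer(seed), n_taxa = as.integer(n_taxa),
    lsc_len = as.integer(lsc_len), ssc_len = as.integer(ssc_len),
    ir_len = as.integer(ir_len),
    rates = rates, genes = genes, hotspots = hotspots, repeats = repeats,
    hotspot_k = hotspot_k, sites_per_step = as.integer(sites_per_step),
    hotspot_multiplier = hotspot_multiplier,
    premature_stops = premature_stops, tree = tree
  ), class = "sim_spec")
  validate_sim_spec(spec)
  spec
}

validate_sim_spec <- function(spec) {
  g <- spec$genes
  h <- spec$hotspots
  for (i in seq_len(nrow(h))) {
    gi <- g[g$name == h$gene[i], ]
    if (nrow(gi) == 0L || h$start[i] < gi$start || h$end[i] > gi$end) {
      stop("hotspot ", h$name[i], " outside its host gene/region", call. = FALSE)
    }
  }
  L0 <- spec$lsc_len + spec$ir_len + spec$ssc_len
  r <- spec$repeats
  if (any(r$anc_end > L0)) stop("planted repeat outside the genome", call. = FALSE)
  # planted repeats must not touch genes or hotspots, and IR repeats must be
  # monomorphic so the IR stays length-constant across taxa
  for (i in seq_len(nrow(r))) {
    if (any(r$anc_start[i] <= g$end & r$anc_end[i] >= g$start)) {
      stop("planted repeat ", r$name[i], " overlaps a gene", call. = FALSE)
    }
    if (r$region[i] == "IR" && r$copy_min[i] != r$copy_max[i]) {
      stop("IR repeat ", r$name[i], " must be monomorphic", call. = FALSE)
    }
  }
  ps <- spec$premature_stops
  if (nrow(ps) > 0L) {
    if (any(!ps$gene %in% g$name)) stop("premature-stop gene not in gene table", call. = FALSE)
    if (any(ps$taxon < 1L | ps$taxon > spec$n_taxa)) {
      stop("premature-stop taxon index out of range", call. = FALSE)
    }
  }
  invisible(spec)
}

# Synthetic gene complement. Scaffold coordinates: LSC = [1, lsc],
# IRA = [lsc+1, lsc+ir], SSC = [lsc+ir+1, lsc+ir+ssc]. rps19 deliberately
# overhangs 7 bp into IRa, mirroring the junction biology of real plastomes;
# the trnH-psbA spacer is exactly 357 bp.
default_gene_table <- function(lsc, ssc, ir) {
  off_ir <- lsc
  off_ssc <- lsc + ir
  g <- tibble::tribble(
    ~name,   ~kind,  ~strand, ~start,                     ~len,
    "trnH",  "tRNA", "+",     50L,                        75L,
    "psbA",  "CDS",  "-",     482L,                       1062L,
    "rps16", "CDS",  "-",     as.integer(0.06 * lsc),     819L,
    "rbcL",  "CDS",  "+",     as.integer(0.67 * lsc),     1425L,
    "accD",  "CDS",  "+",     as.integer(0.71 * lsc),     1488L,
    "rpoA",  "CDS",  "-",     as.integer(0.94 * lsc),     1014L,
    "rps19", "CDS",  "-",     lsc - 277L,                 285L,
    "rrn16", "rRNA", "+",     as.integer(off_ir + 0.2 * ir),  1491L,
    "ndhB",  "CDS",  "+",     as.integer(off_ir + 0.4 * ir),  1533L,
    "ndhF",  "CDS",  "-",     off_ssc + 500L,             2241L,
    "ycf1",  "CDS",  "+",     as.integer(off_ssc + 0.6 * ssc), 5331L
  )
  g$end <- g$start + g$len - 1L
  g$region <- ifelse(g$start > off_ssc, "SSC", ifelse(g$start > off_ir, "IR", "LSC"))
  g
}

default_hotspot_table <- function(genes) {
  accd <- genes[genes$name == "accD", ]
  ycf1 <- genes[genes$name == "ycf1", ]
  tibble(
    name = c("accD", "ycf1"),
    gene = c("accD", "ycf1"),
    start = c(accd$start + 600L, ycf1$start + 600L),
    end = c(accd$start + 875L, ycf1$start + 1099L)  # 276 bp and 500 bp cores
  )
}

default_repeat_table <- function(lsc, ssc, ir) {
  off_ir <- lsc
  off_ssc <- lsc + ir
  r <- tibble::tribble(
    ~name,        ~type, ~unit_len, ~copy_min, ~copy_max, ~spacer_len, ~pos,
    "ssr_AT",     "SSR", 2L,        5L,        8L,        0L,          2200L,
    "ssr_AAG",    "SSR", 3L,        4L,        6L,        0L,          as.integer(0.30 * lsc),
    "lsr_tandem", "LSR", 18L,       2L,        4L,        0L,          as.integer(0.50 * lsc),
    "ssr_TA_ir",  "SSR", 2L,        6L,        6L,        0L,          as.integer(off_ir + 0.1 * ir),
    "ssr_ATT",    "SSR", 3L,        4L,        7L,        0L,          off_ssc + 4000L,
    "lsr_spaced", "LSR", 14L,       2L,        3L,        10L,         off_ssc + 9000L
  )
  r$unit <- c("AT", "AAG", NA, "TA", "ATT", NA)  # LSR units drawn at build time
  r$region <- ifelse(r$pos > off_ssc, "SSC", ifelse(r$pos > off_ir, "IR", "LSC"))
  r$anc_start <- r$pos
  # ancestral copy number = copy_max, so the ancestor reserves the widest block
  r$anc_end <- r$pos +
    r$unit_len * r$copy_max + r$spacer_len * (r$copy_max - 1L) - 1L
  r
}

# random CDS: ATG + random sense codons + TAA, planted on the coding strand
random_cds <- function(len) {
  stopifnot(len %% 3 == 0, len >= 9)
  sc <- setdiff(sense_codons(), "ATG")
  paste0("ATG",
         paste(sample(sc, len / 3 - 2, replace = TRUE), collapse = ""),
         "TAA")
}

#' Simulate a plastome clade with known truth
#'
#' Generates an annotated ancestral genome, evolves taxa along a scaled
#' coalescent tree with region- and hotspot-specific substitution rates,
#' plants repeat copy-number polymorphism and hotspot haplotype structure,
#' mirrors the IR, and emits the true alignment from the known homology.
#'
#' @param spec A [simulation_spec()].
#' @return A list: `records` (named list of [plastome()]), `alignment`
#'   (`plast_aln` whose first columns map 1:1 onto ancestor scaffold
#'   coordinates, followed by the mirrored IRb block), and `truth` — a list
#'   with `tree` (Newick), `region_rates`, `regions` (alignment-coordinate
#'   intervals), `hotspots`, `haplotypes` (per taxon x planted locus),
#'   `repeats` (per-taxon copy counts), `premature_stops`.
#' @export
simulate_clade <- function(spec = simulation_spec()) {
  stopifnot(inherits(spec, "sim_spec"))
  set.seed(spec$seed)
  lsc <- spec$lsc_len; ir <- spec$ir_len; ssc <- spec$ssc_len
  L0 <- lsc + ir + ssc
  taxa <- sprintf("t%02d", seq_len(spec$n_taxa))

  # ---- ancestral scaffold ----
  anc <- random_dna(L0)
  genes <- spec$genes
  for (i in seq_len(nrow(genes))) {
    gseq <- if (genes$kind[i] == "CDS") random_cds(genes$len[i]) else
      random_dna(genes$len[i])
    if (genes$strand[i] == "-") gseq <- revcomp(gseq)
    substr(anc, genes$start[i], genes$end[i]) <- gseq
  }
  reps <- spec$repeats
  reps$unit <- vapply(seq_len(nrow(reps)), function(i) {
    if (!is.na(reps$unit[i])) reps$unit[i] else random_dna(reps$unit_len[i])
  }, "")
  # one spacer sequence per inter-copy gap (distinct, so spaced repeats do
  # not degenerate into a longer-unit tandem periodicity)
  reps$spacer_seqs <- lapply(seq_len(nrow(reps)), function(i) {
    if (reps$spacer_len[i] > 0L && reps$copy_max[i] > 1L) {
      replicate(reps$copy_max[i] - 1L, random_dna(reps$spacer_len[i]))
    } else {
      character(0)
    }
  })
  rep_string <- function(i, copies) {
    if (copies == 0L) return("")
    u <- reps$unit[i]
    if (copies == 1L) return(u)
    sp <- reps$spacer_seqs[[i]]
    if (length(sp) == 0L) return(strrep(u, copies))
    paste0(paste0(u, sp[seq_len(copies - 1L)], collapse = ""), u)
  }
  for (i in seq_len(nrow(reps))) {
    substr(anc, reps$anc_start[i], reps$anc_end[i]) <- rep_string(i, reps$copy_max[i])
  }
  # guard bases flanking each planted repeat break chance continuation of
  # the unit periodicity, so detected maximal runs equal the planted counts
  for (i in seq_len(nrow(reps))) {
    u <- reps$unit_len[i] + reps$spacer_len[i]
    s0 <- reps$anc_start[i]; e0 <- reps$anc_end[i]
    if (s0 > 1L) {
      forb <- substr(anc, s0 + u - 1L, s0 + u - 1L)
      substr(anc, s0 - 1L, s0 - 1L) <- setdiff(DNA_BASES, forb)[1]
    }
    if (e0 < L0) {
      forb <- substr(anc, e0 - u + 1L, e0 - u + 1L)
      substr(anc, e0 + 1L, e0 + 1L) <- setdiff(DNA_BASES, forb)[1]
    }
  }

  # ---- tree, scaled to mean pairwise distance 1 ----
  tr <- if (!is.null(spec$tree)) ape::read.tree(text = spec$tree) else
    ape::rcoal(spec$n_taxa, tip.label = taxa)
  if (!setequal(tr$tip.label, taxa)) tr$tip.label <- taxa[seq_len(spec$n_taxa)]
  d <- ape::cophenetic.phylo(tr)
  tr$edge.length <- tr$edge.length / mean(d[upper.tri(d)])

  # ---- per-site rates ----
  region_of <- c(rep("LSC", lsc), rep("IR", ir), rep("SSC", ssc))
  rate <- unname(spec$rates[region_of])
  hs <- spec$hotspots
  planted <- hs$name %in% names(spec$hotspot_k)
  for (i in seq_len(nrow(hs))) {
    rate[hs$start[i]:hs$end[i]] <-
      if (planted[i]) 0 else rate[hs$start[i]:hs$end[i]] * spec$hotspot_multiplier
  }
  for (i in seq_len(nrow(reps))) {
    # repeat blocks (and their guard bases) stay substitution-free
    rate[max(1L, reps$anc_start[i] - 1L):min(L0, reps$anc_end[i] + 1L)] <- 0
  }

  # ---- substitutions along the tree ----
  tips <- evolve_on_tree(chars(anc), tr, rate)

  # ---- planted hotspot haplotype classes ----
  hap_truth <- list()
  for (locus in names(spec$hotspot_k)) {
    k <- spec$hotspot_k[[locus]]
    iv <- hs[hs$name == locus, ]
    if (nrow(iv) == 0L) stop("hotspot_k names a locus not in the hotspot table")
    grp <- stats::cutree(stats::hclust(as.dist(d[taxa, taxa]), method = "average"), k = k)
    grp <- match(grp, unique(grp[taxa]))  # renumber in taxon order
    names(grp) <- taxa
    m <- spec$sites_per_step
    sites <- sort(sample(iv$start:iv$end, (k - 1L) * m))
    flip <- c(A = "C", C = "A", G = "T", T = "G")
    for (g in 2L:k) {
      sel <- sites[seq_len((g - 1L) * m)]
      for (tx in taxa[grp == g]) {
        tips[[tx]][sel] <- flip[tips[[tx]][sel]]
      }
    }
    hap_truth[[locus]] <- tibble(taxon = taxa, locus = locus,
                                 haplotype = unname(grp[taxa]))
  }

  # ---- variable blocks (repeat copy numbers, premature-stop deletions) ----
  blocks <- purrr::map_dfr(seq_len(nrow(reps)), function(i) {
    copies <- if (reps$copy_min[i] == reps$copy_max[i]) {
      rep(reps$copy_min[i], spec$n_taxa)
    } else {
      sample(reps$copy_min[i]:reps$copy_max[i], spec$n_taxa, replace = TRUE)
    }
    tibble(name = reps$name[i], start = reps$anc_start[i], end = reps$anc_end[i],
           strings = list(vapply(copies, function(cp) rep_string(i, cp), "")),
           counts = list(setNames(copies, taxa)))
  })
  ps <- spec$premature_stops
  if (nrow(ps) > 0L) {
    ps_blocks <- purrr::map_dfr(seq_len(nrow(ps)), function(i) {
      gi <- genes[genes$name == ps$gene[i], ]
      pos <- gi$start + 90L  # interior single-base deletion -> frameshift
      base <- substr(anc, pos, pos)
      strs <- rep(base, spec$n_taxa)
      strs[ps$taxon[i]] <- ""
      tibble(name = paste0("del_", ps$gene[i]), start = pos, end = pos,
             strings = list(strs), counts = list(NULL))
    })
    blocks <- dplyr::bind_rows(blocks, ps_blocks)
  }
  blocks <- dplyr::arrange(blocks, .data$start)

  # ---- assemble per-taxon genomes and the true alignment ----
  build_taxon <- function(ti) {
    v <- tips[[taxa[ti]]]
    plain <- character(0)  # genome pieces
    gapped <- character(0) # alignment pieces
    cursor <- 1L
    for (b in seq_len(nrow(blocks))) {
      s <- blocks$start[b]; e <- blocks$end[b]
      if (cursor < s) {
        const <- paste(v[cursor:(s - 1L)], collapse = "")
        plain <- c(plain, const); gapped <- c(gapped, const)
      }
      bt <- blocks$strings[[b]][ti]
      width <- e - s + 1L
      plain <- c(plain, bt)
      gapped <- c(gapped, paste0(bt, strrep("-", width - nchar(bt))))
      cursor <- e + 1L
    }
    if (cursor <= L0) {
      const <- paste(v[cursor:L0], collapse = "")
      plain <- c(plain, const); gapped <- c(gapped, const)
    }
    list(plain = paste(plain, collapse = ""), gapped = paste(gapped, collapse = ""))
  }
  built <- lapply(seq_len(spec$n_taxa), build_taxon)

  # per-taxon region lengths (IR is constant by construction)
  delta_in <- function(ti, lo, hi) {
    sel <- blocks$start >= lo & blocks$end <= hi
    if (!any(sel)) return(0L)
    sum(vapply(which(sel), function(b) {
      nchar(blocks$strings[[b]][ti]) - (blocks$end[b] - blocks$start[b] + 1L)
    }, 0L))
  }
  records <- list()
  rows <- character(spec$n_taxa)
  for (ti in seq_len(spec$n_taxa)) {
    lsc_t <- lsc + delta_in(ti, 1L, lsc)
    ir_t <- ir + delta_in(ti, lsc + 1L, lsc + ir)
    ssc_t <- ssc + delta_in(ti, lsc + ir + 1L, L0)
    plain <- built[[ti]]$plain
    ira_seq <- substr(plain, lsc_t + 1L, lsc_t + ir_t)
    genome <- paste0(plain, revcomp(ira_seq))
    gapped <- built[[ti]]$gapped
    # IRb block of the alignment mirrors the (gap-free) IRa columns
    ira_cols <- substr(gapped, lsc + 1L, lsc + ir)
    rows[ti] <- paste0(gapped, revcomp(ira_cols))
    # features remapped through the per-taxon block offsets
    shift_at <- function(p) {
      sel <- blocks$end < p
      if (!any(sel)) return(0L)
      sum(vapply(which(sel), function(b) {
        nchar(blocks$strings[[b]][ti]) - (blocks$end[b] - blocks$start[b] + 1L)
      }, 0L))
    }
    f <- genes
    f$start2 <- f$start + vapply(f$start, shift_at, 0L)
    f$end2 <- f$end + vapply(f$end + 1L, shift_at, 0L)
    feats <- tibble(
      feature_id = paste0(f$name, ".", f$kind, ".", seq_len(nrow(f))),
      name = f$name, kind = f$kind, strand = f$strand, part = 1L,
      start = f$start2, end = f$end2
    )
    part <- tibble(
      region = c("LSC", "IRA", "SSC", "IRB"),
      start = as.integer(cumsum(c(1L, lsc_t, ir_t, ssc_t))),
      end = as.integer(cumsum(c(lsc_t, ir_t, ssc_t, ir_t))),
      length = as.integer(c(lsc_t, ir_t, ssc_t, ir_t))
    )
    records[[taxa[ti]]] <- plastome(taxa[ti], genome, taxa[ti], feats, part)
  }
  alignment <- as_alignment(rows, ids = taxa)

  L_aln <- alignment$length
  truth <- list(
    tree = ape::write.tree(tr),
    region_rates = spec$rates,
    regions = tibble(
      region = c("LSC", "IRA", "SSC", "IRB"),
      start = c(1L, lsc + 1L, lsc + ir + 1L, L0 + 1L),
      end = c(lsc, lsc + ir, L0, L_aln)
    ),
    hotspots = dplyr::mutate(hs, planted_k =
      ifelse(hs$name %in% names(spec$hotspot_k),
             as.integer(spec$hotspot_k[hs$name]), NA_integer_)),
    haplotypes = dplyr::bind_rows(hap_truth),
    repeats = dplyr::mutate(
      blocks[!startsWith(blocks$name, "del_"), c("name", "start", "end", "counts")],
      polymorphic = vapply(.data$counts, function(x) length(unique(x)) > 1L, TRUE)
    ),
    premature_stops = ps
  )
  list(records = records, alignment = alignment, truth = truth)
}

# Jukes-Cantor substitutions down the tree: per edge, each site mutates with
# probability 1 - exp(-r * len); mutated sites draw a uniformly different base.
evolve_on_tree <- function(root_chars, tr, rate) {
  n_tip <- length(tr$tip.label)
  n_node <- n_tip + tr$Nnode
  seqs <- vector("list", n_node)
  root <- n_tip + 1L
  seqs[[root]] <- root_chars
  # preorder over edges
  ord <- order(tr$edge[, 1])
  edges <- tr$edge[ord, , drop = FALSE]
  lens <- tr$edge.length[ord]
  # ensure parents appear before children: traverse repeatedly (tree is small)
  done <- rep(FALSE, n_node)
  done[root] <- TRUE
  remaining <- seq_len(nrow(edges))
  others <- matrix(c("C", "G", "T", "A", "G", "T", "A", "C", "T", "A", "C", "G"),
                   nrow = 4, byrow = TRUE,
                   dimnames = list(c("A", "C", "G", "T"), NULL))
  while (length(remaining) > 0L) {
    prog <- FALSE
    for (k in remaining) {
      p <- edges[k, 1]; ch <- edges[k, 2]
      if (!done[p]) next
      v <- seqs[[p]]
      pmut <- pmin(1 - exp(-rate * lens[k]), 0.75)
      idx <- which(stats::runif(length(v)) < pmut)
      if (length(idx) > 0L) {
        v[idx] <- others[cbind(match(v[idx], DNA_BASES),
                               sample.int(3L, length(idx), replace = TRUE))]
      }
      seqs[[ch]] <- v
      done[ch] <- TRUE
      remaining <- setdiff(remaining, k)
      prog <- TRUE
    }
    if (!prog) stop("malformed tree edges")
  }
  setNames(seqs[seq_len(n_tip)], tr$tip.label)
}

#' Simulate a codon sequence pair under a known omega
#'
#' Evolves a pair of in-frame coding sequences under a symmetric 61-state
#' codon substitution process with transition/transversion ratio `kappa` and
#' non-synonymous/synonymous rate ratio `omega` (stop codons unreachable).
#' The rate matrix is scaled so `t` is the expected number of substitutions
#' per codon separating the pair; each lineage evolves `t/2` from a uniform
#' random ancestor.
#'
#' @param omega Non-synonymous/synonymous rate ratio (>= 0).
#' @param kappa Transition/transversion rate ratio (> 0).
#' @param n_codons Number of codons.
#' @param t Pairwise distance in expected substitutions per codon.
#' @param seed Optional seed.
#' @param ancestor Optional ancestral CDS string (in-frame, sense codons
#'   only); drawn uniformly at random when `NULL`. Lets several taxa be
#'   evolved from one common ancestor.
#' @return A list with `seq1`, `seq2` (DNA strings) and `ancestor`.
#' @export
codon_simulate <- function(omega, kappa = 1, n_codons = 1000L, t = 0.2,
                           seed = NULL, ancestor = NULL) {
  stopifnot(omega >= 0, kappa > 0, t >= 0)
  if (!is.null(seed)) set.seed(seed)
  sc <- sense_codons()
  key <- paste0("codonP_", signif(omega, 10), "_", signif(kappa, 10), "_",
                signif(t, 10))
  P <- .plastdiv_cache[[key]]
  if (is.null(P)) {
    k <- length(sc)
    Q <- matrix(0, k, k, dimnames = list(sc, sc))
    gcmap <- genetic_code()
    for (i in seq_len(k)) {
      bi <- chars(sc[i])
      for (p in 1:3) for (b in setdiff(DNA_BASES, bi[p])) {
        nb <- bi; nb[p] <- b
        cj <- paste(nb, collapse = "")
        if (gcmap[[cj]] == "*") next
        r <- if (is_transition(bi[p], b)) kappa else 1
        if (gcmap[[cj]] != gcmap[[sc[i]]]) r <- r * omega
        Q[i, cj] <- r
      }
    }
    diag(Q) <- -rowSums(Q)
    mu <- mean(-diag(Q))
    if (mu > 0) Q <- Q / mu
    # Q is symmetric (uniform stationary distribution), so use eigen
    e <- eigen(Q, symmetric = TRUE)
    P <- e$vectors %*% diag(exp(e$values * t / 2)) %*% t(e$vectors)
    P[P < 0] <- 0
    P <- P / rowSums(P)
    dimnames(P) <- list(sc, sc)
    .plastdiv_cache[[key]] <- P
  }
  anc <- if (is.null(ancestor)) {
    sample(sc, n_codons, replace = TRUE)
  } else {
    cods <- split_codons(toupper(ancestor))
    stopifnot(all(cods %in% sc))
    cods
  }
  n_codons <- length(anc)
  draw <- function() {
    out <- character(n_codons)
    for (cd in unique(anc)) {
      at <- which(anc == cd)
      out[at] <- sample(sc, length(at), replace = TRUE, prob = P[cd, ])
    }
    out
  }
  list(seq1 = paste(draw(), collapse = ""),
       seq2 = paste(draw(), collapse = ""),
       ancestor = paste(anc, collapse = ""))
}

#' Write a simulated clade to disk
#'
#' Emits per-taxon FASTA and GFF3, the true alignment (aligned FASTA), the
#' true tree (Newick) and truth tables (TSV) into a directory.
#'
#' @param sim A [simulate_clade()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_clade <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (rec in sim$records) {
    Biostrings::writeXStringSet(
      Biostrings::DNAStringSet(setNames(rec$seq, rec$id)),
      file.path(dir, paste0(rec$id, ".fasta")))
    write_gff3(rec, file.path(dir, paste0(rec$id, ".gff3")))
  }
  write_alignment(sim$alignment, file.path(dir, "alignment.fasta"))
  writeLines(sim$truth$tree, file.path(dir, "tree.nwk"))
  utils::write.table(sim$truth$haplotypes, file.path(dir, "haplotypes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  hs <- sim$truth$hotspots
  utils::write.table(hs, file.path(dir, "hotspots.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
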