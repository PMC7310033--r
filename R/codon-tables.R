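# Codon-level lookup tables for the Ka/Ks estimators.
#
# Everything here derives from the standard genetic code (plastid CDS use the
# universal code) and is built once per session, then cached. Tables:
#   * per-codon synonymous site fractions at each position (NG86 1/3-rule,
#     mutations to stop codons excluded from the denominator);
#   * per codon pair, pathway-averaged difference counts split into
#     synonymous/non-synonymous x transition/transversion.

genetic_code <- function(code = "standard") {
  stopifnot(identical(code, "standard"))
  Biostrings::GENETIC_CODE
}

sense_codons <- function() {
  gc <- genetic_code()
  names(gc)[gc != "*"]
}

codon_aa <- function(codon) unname(genetic_code()[codon])

is_transition <- function(b1, b2) {
  (b1 == "A" & b2 == "G") | (b1 == "G" & b2 == "A") |
    (b1 == "C" & b2 == "T") | (b1 == "T" & b2 == "C")
}

# For one codon: 3-vector of synonymous site fractions per position and the
# per-position count of synonymous / non-stop mutations; optional weights
# w(mutation) allow the YN00 kappa/frequency-weighted variant.
codon_site_fractions <- function(codon, weight_fun = NULL) {
  gc <- genetic_code()
  aa <- gc[[codon]]
  b <- chars(codon)
  fs <- numeric(3)
  for (p in 1:3) {
    targets <- setdiff(DNA_BASES, b[p])
    wsum <- 0
    wsyn <- 0
    for (t in targets) {
      nb <- b
      nb[p] <- t
      nc <- paste(nb, collapse = "")
      if (gc[[nc]] == "*") next  # mutations to stops disregarded
      w <- if (is.null(weight_fun)) 1 else weight_fun(codon, nc, b[p], t)
      wsum <- wsum + w
      if (gc[[nc]] == aa) wsyn <- wsyn + w
    }
    fs[p] <- if (wsum > 0) wsyn / wsum else 0
  }
  fs
}

# 61 x 3 matrix of NG86 synonymous site fractions (uniform weights)
ng86_site_table <- function() {
  if (is.null(.plastdiv_cache$ng86_sites)) {
    sc <- sense_codons()
    m <- t(vapply(sc, codon_site_fractions, numeric(3)))
    rownames(m) <- sc
    .plastdiv_cache$ng86_sites <- m
  }
  .plastdiv_cache$ng86_sites
}

# Degeneracy class of each codon position: 0 (nondegenerate: no synonymous
# change), 4 (fourfold: all three changes synonymous), 2 otherwise.
codon_degeneracy_table <- function() {
  if (is.null(.plastdiv_cache$degeneracy)) {
    gc <- genetic_code()
    sc <- sense_codons()
    m <- matrix(2L, length(sc), 3, dimnames = list(sc, NULL))
    for (codon in sc) {
      aa <- gc[[codon]]
      b <- chars(codon)
      for (p in 1:3) {
        nsyn <- 0L
        ntot <- 0L
        for (t in setdiff(DNA_BASES, b[p])) {
          nb <- b
          nb[p] <- t
          nc <- paste(nb, collapse = "")
          ntot <- ntot + 1L
          if (gc[[nc]] == aa) nsyn <- nsyn + 1L
        }
        m[codon, p] <- if (nsyn == ntot) 4L else if (nsyn == 0L) 0L else 2L
      }
    }
    .plastdiv_cache$degeneracy <- m
  }
  .plastdiv_cache$degeneracy
}

# Pathway-averaged differences for every ordered sense-codon pair.
# Minimal mutational paths between the two codons are enumerated; paths that
# pass through a stop codon are excluded (all paths are kept if every path
# hits a stop). Steps are classified syn/nonsyn and ts/tv, then averaged
# over permissible paths. Returns four 61 x 61 matrices.
codon_path_tables <- function() {
  if (!is.null(.plastdiv_cache$path_tables)) return(.plastdiv_cache$path_tables)
  gc <- genetic_code()
  sc <- sense_codons()
  k <- length(sc)
  syn_ts <- syn_tv <- non_ts <- non_tv <- matrix(0, k, k, dimnames = list(sc, sc))
  perms <- list(
    `1` = list(1L),
    `2` = list(c(1L, 2L), c(2L, 1L)),
    `3` = list(c(1L, 2L, 3L), c(1L, 3L, 2L), c(2L, 1L, 3L),
               c(2L, 3L, 1L), c(3L, 1L, 2L), c(3L, 2L, 1L))
  )
  for (i in seq_len(k)) {
    ci <- chars(sc[i])
    for (j in seq_len(k)) {
      if (i == j) next
      cj <- chars(sc[j])
      dpos <- which(ci != cj)
      nd <- length(dpos)
      paths <- perms[[as.character(nd)]]
      acc <- matrix(0, 0, 4)
      acc_all <- matrix(0, 0, 4)
      for (ord in paths) {
        cur <- ci
        step <- c(0, 0, 0, 0)  # syn_ts syn_tv non_ts non_tv
        through_stop <- FALSE
        for (p in dpos[ord]) {
          nxt <- cur
          nxt[p] <- cj[p]
          aa1 <- gc[[paste(cur, collapse = "")]]
          aa2 <- gc[[paste(nxt, collapse = "")]]
          if (aa2 == "*" || aa1 == "*") through_stop <- TRUE
          syn <- !through_stop && aa1 == aa2
          ts <- is_transition(cur[p], nxt[p])
          idx <- if (aa1 == aa2 && aa1 != "*" && aa2 != "*") {
            if (ts) 1L else 2L
          } else {
            if (ts) 3L else 4L
          }
          step[idx] <- step[idx] + 1
          cur <- nxt
        }
        acc_all <- rbind(acc_all, step)
        if (!through_stop) acc <- rbind(acc, step)
      }
      use <- if (nrow(acc) > 0) acc else acc_all
      avg <- colMeans(use)
      syn_ts[i, j] <- avg[1]; syn_tv[i, j] <- avg[2]
      non_ts[i, j] <- avg[3]; non_tv[i, j] <- avg[4]
    }
  }
  .plastdiv_cache$path_tables <- list(syn_ts = syn_ts, syn_tv = syn_tv,
                                      non_ts = non_ts, non_tv = non_tv)
  .plastdiv_cache$path_tables
}

# split a DNA string into codons
split_codons <- function(s) {
  n <- nchar(s)
  if (n %% 3 != 0) stop("coding sequence length not divisible by 3", call. = FALSE)
  substring(s, seq(1L, n, 3L), seq(3L, n, 3L))
}
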