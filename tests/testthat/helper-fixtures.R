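# Shared fixtures and independent reference (oracle) implementations.
# Oracles are deliberately written as plain brute-force code, separate from
# the package's optimised paths.

.fixture_cache <- new.env(parent = emptyenv())

# one default 16-taxon clade, built once per test session
default_sim <- function() {
  if (is.null(.fixture_cache$sim)) {
    .fixture_cache$sim <- simulate_clade(simulation_spec(seed = 20240101 %% 1000L))
  }
  .fixture_cache$sim
}

small_sim <- function() {
  if (is.null(.fixture_cache$small_sim)) {
    .fixture_cache$small_sim <- simulate_clade(simulation_spec(seed = 7L, n_taxa = 6L))
  }
  .fixture_cache$small_sim
}

rand_dna <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# deterministic base different from every character in `avoid`
pick_diff <- function(avoid) {
  setdiff(c("A", "C", "G", "T"), strsplit(avoid, "")[[1]])[1]
}

# quadripartite genome with guard bases so chance extension at the planted
# IR boundaries is impossible (each boundary-adjacent pair is made to
# mismatch under the inverted-repeat pairing)
guarded_quadripartite <- function(lsc_n = 30000, ir_n = 11000, ssc_n = 7000) {
  lsc <- rand_dna(lsc_n)
  ira <- rand_dna(ir_n)
  ssc <- rand_dna(ssc_n)
  # pairing partners across each boundary (base b never equals comp(b)):
  #   left of IRa start: lsc[end] vs comp(lsc[1]) (circular)
  substr(lsc, nchar(lsc), nchar(lsc)) <- substr(lsc, 1, 1)
  #   right of IRa end: ssc[1] vs comp(ssc[end])
  substr(ssc, 1, 1) <- substr(ssc, nchar(ssc), nchar(ssc))
  list(seq = paste0(lsc, ira, ssc, revcomp(ira)),
       lsc = nchar(lsc), ir = nchar(ira), ssc = nchar(ssc))
}

random_alignment <- function(n, L, p_var = 0.05, p_gap = 0.01, p_n = 0.005) {
  base <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
  rows <- vapply(seq_len(n), function(i) {
    v <- base
    mut <- runif(L) < p_var
    v[mut] <- sample(c("A", "C", "G", "T"), sum(mut), replace = TRUE)
    gap <- runif(L) < p_gap
    v[gap] <- "-"
    nn <- runif(L) < p_n
    v[nn] <- "N"
    paste(v, collapse = "")
  }, "")
  as_alignment(rows, ids = sprintf("s%02d", seq_len(n)))
}

# ---- diversity oracles (complete deletion) ----

oracle_included_cols <- function(m) {
  apply(m, 2, function(col) all(col %in% c("A", "C", "G", "T")))
}

oracle_pi <- function(aln) {
  m <- sapply(strsplit(as_alignment(aln)$seqs, ""), identity)
  m <- t(m)
  keep <- oracle_included_cols(m)
  if (!any(keep)) stop("no sites")
  m <- m[, keep, drop = FALSE]
  n <- nrow(m)
  tot <- 0
  cnt <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    tot <- tot + sum(m[i, ] != m[j, ]) / ncol(m)
    cnt <- cnt + 1
  }
  tot / cnt
}

oracle_site_classes <- function(aln) {
  m <- t(sapply(strsplit(as_alignment(aln)$seqs, ""), identity))
  apply(m, 2, function(col) {
    if (any(!col %in% c("A", "C", "G", "T"))) return("excluded")
    tab <- table(col)
    if (length(tab) == 1) return("monomorphic")
    if (sum(tab >= 2) >= 2) return("parsimony_informative")
    "singleton"
  })
}

oracle_haplotypes <- function(aln) {
  m <- t(sapply(strsplit(as_alignment(aln)$seqs, ""), identity))
  keep <- oracle_included_cols(m)
  key <- apply(m[, keep, drop = FALSE], 1, paste, collapse = "")
  n <- length(key)
  tab <- table(key)
  p <- as.numeric(tab) / n
  H <- length(tab)
  list(H = H, Hd = if (H == 1) 0 else n / (n - 1) * (1 - sum(p^2)))
}

# ---- NG86 site-count oracle: exhaustive 9-mutation enumeration ----

oracle_ng86_sites <- function(codon) {
  gc <- Biostrings::GENETIC_CODE
  aa <- gc[[codon]]
  s <- 0
  for (p in 1:3) {
    muts <- character(0)
    for (b in c("A", "C", "G", "T")) {
      if (b == substr(codon, p, p)) next
      cand <- codon
      substr(cand, p, p) <- b
      muts <- c(muts, cand)
    }
    aas <- gc[muts]
    valid <- aas != "*"
    if (any(valid)) s <- s + sum(aas[valid] == aa) / sum(valid)
  }
  s
}

# ---- SSR oracle: quadratic scan ----

oracle_ssrs <- function(seq, unit_range = c(2, 6), min_repeats = 3) {
  v <- strsplit(seq, "")[[1]]
  n <- length(v)
  primitive <- function(u) {
    lu <- nchar(u)
    for (dd in seq_len(lu - 1)) {
      if (lu %% dd == 0 &&
          identical(strrep(substr(u, 1, dd), lu / dd), u)) return(FALSE)
    }
    TRUE
  }
  res <- list()
  for (u in unit_range[1]:unit_range[2]) {
    taken_until <- 0
    i <- 1
    while (i + u * min_repeats - 1 <= n) {
      # count repeats of v[i..i+u-1] starting at i
      reps <- 1
      while (i + (reps + 1) * u - 1 <= n &&
             identical(v[(i + reps * u):(i + (reps + 1) * u - 1)],
                       v[i:(i + u - 1)])) {
        reps <- reps + 1
      }
      if (reps >= min_repeats) {
        unit <- paste(v[i:(i + u - 1)], collapse = "")
        # maximality: not left-extendable by one more unit period
        left_ext <- i > 1 && v[i - 1] == v[i - 1 + u]
        if (!left_ext && primitive(unit) && i > taken_until) {
          res[[length(res) + 1]] <- data.frame(
            start = i, end = i + u * reps - 1, unit = unit, unit_len = u,
            n_repeats = reps, stringsAsFactors = FALSE)
          taken_until <- i + u * reps - 1
        }
        i <- i + 1
      } else {
        i <- i + 1
      }
    }
  }
  if (length(res) == 0) {
    return(data.frame(start = integer(), end = integer(), unit = character(),
                      unit_len = integer(), n_repeats = integer()))
  }
  out <- do.call(rbind, res)
  out[order(out$start, out$unit_len), , drop = FALSE]
}

# ---- LSR oracle: exhaustive per-offset / per-anti-diagonal run scan ----

oracle_lsrs <- function(seq, unit_range = c(11, 100), max_spacer = 50) {
  v <- strsplit(seq, "")[[1]]
  n <- length(v)
  kmin <- unit_range[1]; kmax <- unit_range[2]
  comp <- chartr("ACGT", "TGCA", v)
  copies <- list()   # direct copies keyed by unit string
  inv <- list()
  # direct: maximal runs per offset
  for (d in 1:min(kmax + max_spacer, n - 1)) {
    eq <- v[1:(n - d)] == v[(1 + d):n]
    r <- rle(eq)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
    for (k in which(r$values)) {
      a <- starts[k]; rl <- r$lengths[k]
      if (rl < kmin) next
      if (rl <= d) {
        if (rl > kmax || d - rl > max_spacer) next
        u <- paste(v[a:(a + rl - 1)], collapse = "")
        copies[[u]] <- rbind(copies[[u]],
                             c(a, a + rl - 1), c(a + d, a + d + rl - 1))
      } else {
        if (d < kmin || d > kmax) next
        ncp <- rl %/% d + 1
        u <- paste(v[a:(a + d - 1)], collapse = "")
        for (q in 0:(ncp - 1)) {
          copies[[u]] <- rbind(copies[[u]], c(a + q * d, a + q * d + d - 1))
        }
      }
    }
  }
  direct <- list()
  for (u in names(copies)) {
    cp <- unique(copies[[u]])
    cp <- cp[order(cp[, 1]), , drop = FALSE]
    # greedy chain
    cur <- list(cp[1, ])
    flush_chain <- function(cur) {
      if (length(cur) >= 2) {
        s <- vapply(cur, `[`, 0, 1); e <- vapply(cur, `[`, 0, 2)
        direct[[length(direct) + 1]] <<- data.frame(
          start = s[1], end = e[length(e)], unit = u, unit_len = nchar(u),
          n_copies = length(cur),
          arrangement = if (all(s[-1] - e[-length(e)] - 1 == 0)) "tandem" else "spaced",
          stringsAsFactors = FALSE)
      }
    }
    if (nrow(cp) > 1) for (q in 2:nrow(cp)) {
      gap <- cp[q, 1] - cur[[length(cur)]][2] - 1
      if (gap >= 0 && gap <= max_spacer) {
        cur[[length(cur) + 1]] <- cp[q, ]
      } else if (gap < 0) {
        next
      } else {
        flush_chain(cur); cur <- list(cp[q, ])
      }
    }
    flush_chain(cur)
  }
  # inverted: maximal runs per anti-diagonal, left half only
  for (cc in 2:(2 * n)) {
    tmax <- min((cc - 1) %/% 2, n)
    tmin <- max(1, cc - n)
    if (tmax - tmin + 1 < kmin) next
    tt <- tmin:tmax
    ok <- v[tt] == comp[cc - tt]
    r <- rle(ok)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
    for (k in which(r$values)) {
      a <- tt[starts[k]]; b <- tt[ends[k]]
      arm <- b - a + 1
      if (arm < kmin || arm > kmax) next
      sp <- (cc - b) - b - 1
      if (sp < 0 || sp > max_spacer) next
      u <- paste(v[a:b], collapse = "")
      inv[[length(inv) + 1]] <- data.frame(
        start = a, end = cc - a, unit = u, unit_len = arm, n_copies = 2,
        arrangement = if (identical(revcomp(u), u)) "palindromic" else "hairpin",
        stringsAsFactors = FALSE)
    }
  }
  out <- rbind(do.call(rbind, direct), do.call(rbind, inv))
  if (is.null(out)) {
    return(data.frame(start = integer(), end = integer(), unit = character(),
                      unit_len = integer(), n_copies = integer(),
                      arrangement = character()))
  }
  out <- unique(out)
  out[order(out$start, out$end), , drop = FALSE]
}

lsr_key <- function(df) {
  if (nrow(df) == 0) return(character(0))
  sort(paste(df$start, df$end, df$unit_len, df$n_copies, df$arrangement))
}
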