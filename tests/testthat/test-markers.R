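test_that("marker extraction centres, clips, and drops gap columns", {
  set.seed(51)
  aln <- random_alignment(8, 2000, p_gap = 0)
  # gap-free window: marker length equals the window
  mk <- extract_marker_alignment(aln, c(990, 1010), flank = 500)
  expect_equal(aln_length(mk), 500L)
  expect_equal(attr(mk, "windowed_length"), 500L)
  # window with gap columns: length = window - gap columns
  m <- plastdiv:::aln_mat(aln)
  m[3, 995:1004] <- "-"
  aln_g <- as_alignment(m)
  mk2 <- extract_marker_alignment(aln_g, c(990, 1010), flank = 500)
  expect_equal(aln_length(mk2), 500L - 10L)
  expect_equal(attr(mk2, "ungapped_length"), 490L)
  # hotspot at the alignment edge: clipped, no error
  mk3 <- extract_marker_alignment(aln, c(10, 30), flank = 500)
  expect_equal(attr(mk3, "window")[1], 1L)
  expect_equal(aln_length(mk3), 500L)
  expect_error(extract_marker_alignment(aln, c(1900, 2100)), "outside")
  # all-gap window errors
  m2 <- plastdiv:::aln_mat(aln)
  m2[1, ] <- "-"
  expect_error(extract_marker_alignment(as_alignment(m2), c(990, 1010), 100),
               "gap-column removal")
})

test_that("marker statistics delegate to the diversity module", {
  # constant marker
  mk <- as_alignment(rep(strrep("ACGT", 50), 6), ids = paste0("t", 1:6))
  st <- marker_stats(mk)
  expect_equal(st$n_haplotypes, 1L)
  expect_equal(st$pi, 0)
  sim <- default_sim()
  hs <- sim$truth$hotspots
  iv <- hs[hs$name == "accD", ]
  mk2 <- plastdiv:::aln_slice(sim$alignment, iv$start:iv$end)
  expect_equal(marker_stats(mk2)$n_haplotypes, iv$planted_k)
})

test_that("combining markers refines haplotype partitions", {
  # disjoint partitions {AB|CD} and {AC|BD} refine to four classes
  m1 <- as_alignment(c(A = "AAAA", B = "AAAA", C = "AAAT", D = "AAAT"))
  m2 <- as_alignment(c(A = "GGGG", B = "GGGC", C = "GGGG", D = "GGGC"))
  comb <- combine_markers(m1, m2)
  expect_equal(aln_length(comb), 8L)
  expect_equal(haplotype_stats(comb)$n_haplotypes, 4L)
  # combining a marker with itself changes nothing
  same <- combine_markers(m1, m1)
  expect_equal(haplotype_stats(same)$n_haplotypes,
               haplotype_stats(m1)$n_haplotypes)
  # lengths add
  expect_equal(aln_length(combine_markers(m1, m2, m1)), 12L)
  # H(combined) >= max of individual H over random markers
  set.seed(52)
  for (i in 1:10) {
    a <- random_alignment(6, 60, p_gap = 0, p_n = 0)
    b <- random_alignment(6, 80, p_gap = 0, p_n = 0)
    b$ids <- a$ids
    hc <- haplotype_stats(combine_markers(a, b))$n_haplotypes
    expect_gte(hc, max(haplotype_stats(a)$n_haplotypes,
                       haplotype_stats(b)$n_haplotypes))
  }
  # taxon set mismatch errors
  m3 <- as_alignment(c(A = "GG", B = "GG", E = "GC", D = "GC"))
  expect_error(combine_markers(m1, m3), "taxon")
})

test_that("consensus follows the threshold frequency arithmetic", {
  # 31 A + 1 G at 96.9% >= 95% -> plain A
  col_a <- c(rep("A", 31), "G")
  # 30 A + 2 G at 93.75% < 95% -> R
  col_r <- c(rep("A", 30), "G", "G")
  aln <- as_alignment(paste0(col_a, col_r, "C"))
  expect_equal(consensus_sequence(aln, threshold = 0.95), "ARC")
  # identical rows -> that row
  same <- as_alignment(rep("ACGTT", 5))
  expect_equal(consensus_sequence(same), "ACGTT")
  # a rare allele below 1 - threshold does not enter the code
  col <- c(rep("A", 97), rep("G", 2), "T")  # G 2% < 5%, T 1% < 5%
  aln2 <- as_alignment(paste0(col))
  expect_equal(consensus_sequence(aln2, 0.95), "A")
  # gaps never appear in the consensus
  aln3 <- as_alignment(c("A-", "AC", "AC"))
  expect_false(grepl("-", consensus_sequence(aln3)))
})

test_that("primer design enforces degeneracy, 3' conservation, and GC bounds", {
  set.seed(53)
  core <- rand_dna(300)
  flank_l <- rand_dna(120)
  flank_r <- rand_dna(120)
  rows <- vapply(1:8, function(i) {
    v <- strsplit(core, "")[[1]]
    mut <- sample(300, 25)
    v[mut] <- sample(c("A", "C", "G", "T"), 25, replace = TRUE)
    paste0(flank_l, paste(v, collapse = ""), flank_r)
  }, "")
  mk <- as_alignment(rows, ids = paste0("t", 1:8))
  pp <- design_primer_pair(mk, target = c(121, 420))
  td <- tidy(pp)
  expect_true(all(td$degeneracy <= 16))
  expect_true(all(td$length >= 18 & td$length <= 30))
  # forward 3'-terminal trinucleotide is unambiguous and fully conserved
  m <- plastdiv:::aln_mat(mk)
  f3 <- (pp$fwd_window[2] - 2):pp$fwd_window[2]
  expect_true(all(apply(m[, f3, drop = FALSE], 2,
                        function(col) length(unique(col)) == 1L)))
  expect_false(grepl("[^ACGT]", substr(pp$forward, nchar(pp$forward) - 2,
                                       nchar(pp$forward))))
  # reverse primer is the reverse complement of its consensus window
  cons <- consensus_sequence(mk)
  expect_equal(pp$reverse,
               revcomp(substr(cons, pp$rev_window[1], pp$rev_window[2])))
  # a 90% column is avoided or covered by ambiguity, never in the 3' tail
  # (implied by the two constraints above); unsatisfiable flanks error
  bad <- as_alignment(vapply(1:8, function(i) rand_dna(80), ""),
                      ids = paste0("x", 1:8))
  expect_error(design_primer_pair(bad, target = c(35, 45)), "primer")
})

test_that("fully conserved flanks give degeneracy-1 primers that amplify", {
  set.seed(54)
  template <- rand_dna(400)
  rows <- vapply(1:6, function(i) {
    v <- strsplit(template, "")[[1]]
    mid <- 150:250
    mut <- sample(mid, 12)
    v[mut] <- sample(c("A", "C", "G", "T"), 12, replace = TRUE)
    paste(v, collapse = "")
  }, "")
  mk <- as_alignment(rows, ids = paste0("t", 1:6))
  pp <- design_primer_pair(mk, target = c(150, 250))
  expect_equal(tidy(pp)$degeneracy, c(1, 1))
  for (i in 1:6) {
    res <- insilico_pcr(pp, rows[i], "stringent", id = mk$ids[i])
    expect_true(res$success)
    expect_gte(res$amplicon_length, pp$amplicon_range[1] * 0.5)
  }
})

test_that("in-silico PCR applies the stringency rules exactly", {
  set.seed(55)
  fwd <- rand_dna(20)
  rev_site <- rand_dna(20)
  insert <- rand_dna(160)
  template <- paste0(rand_dna(30), fwd, insert, rev_site, rand_dna(30))
  pair <- list(forward = fwd, reverse = revcomp(rev_site),
               amplicon_range = c(200, 200))
  # exact primers amplify under both stringencies
  expect_true(insilico_pcr(pair, template, "stringent")$success)
  expect_true(insilico_pcr(pair, template, "relaxed")$success)
  # one mismatch at the forward 3'-terminal base: fail stringent, pass relaxed
  fwd_mut <- fwd
  last <- substr(fwd_mut, 20, 20)
  substr(fwd_mut, 20, 20) <- setdiff(c("A", "C", "G", "T"), last)[1]
  pair2 <- list(forward = fwd_mut, reverse = revcomp(rev_site),
                amplicon_range = c(200, 200))
  expect_false(insilico_pcr(pair2, template, "stringent")$success)
  r <- insilico_pcr(pair2, template, "relaxed")
  expect_true(r$success)
  expect_equal(r$fwd_mismatches, 1L)
  # two interior mismatches: fail stringent (total > 1), pass relaxed
  fwd_mut2 <- fwd
  for (p in c(5, 9)) {
    substr(fwd_mut2, p, p) <-
      setdiff(c("A", "C", "G", "T"), substr(fwd_mut2, p, p))[1]
  }
  pair3 <- list(forward = fwd_mut2, reverse = revcomp(rev_site),
                amplicon_range = c(200, 200))
  expect_false(insilico_pcr(pair3, template, "stringent")$success)
  expect_true(insilico_pcr(pair3, template, "relaxed")$success)
  # an IUPAC code compatible with the template counts zero mismatches
  fwd_r <- fwd
  base1 <- substr(fwd, 1, 1)
  substr(fwd_r, 1, 1) <- if (base1 %in% c("A", "G")) "R" else "Y"
  pair4 <- list(forward = fwd_r, reverse = revcomp(rev_site),
                amplicon_range = c(200, 200))
  r4 <- insilico_pcr(pair4, template, "stringent")
  expect_true(r4$success)
  expect_equal(r4$fwd_mismatches, 0L)
  # product length must stay within [0.5, 2] x the expected range
  pair5 <- list(forward = fwd, reverse = revcomp(rev_site),
                amplicon_range = c(900, 900))
  expect_false(insilico_pcr(pair5, template, "relaxed")$success)
})

test_that("discriminatory power counts unique and cross hits per level", {
  seqs <- c(sp1 = "AAAA", sp2 = "CCCC", sp3 = "GGGG", sp4 = "GGGG")
  groups <- c(sp1 = "tribeA", sp2 = "tribeA", sp3 = "tribeB", sp4 = "tribeB")
  dp <- discriminatory_power(seqs, groups)
  # sp3/sp4 share a sequence: species cross-hit, group unique hit
  expect_equal(dp$species_resolution, 50)
  expect_equal(dp$group_resolution, 100)
  expect_false(dp$per_taxon$species_unique[3])
  expect_true(dp$per_taxon$group_unique[3])
  # all distinct -> 100% species resolution
  dp2 <- discriminatory_power(c(a = "AA", b = "CC", c = "GG", d = "TT"))
  expect_equal(dp2$species_resolution, 100)
  # three of four query taxa unique against a larger database -> 75%
  dp3 <- discriminatory_power(
    c(a = "AA", b = "CC", c = "GG", d = "TT"),
    db = c(a = "AA", b = "CC", c = "GG", d = "TT", e = "TT"))
  expect_equal(dp3$species_resolution, 75)
  expect_error(discriminatory_power(character(0), db = character(0)), "empty")
})
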