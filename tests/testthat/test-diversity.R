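test_that("site classification matches exhaustive column enumeration", {
  aln <- as_alignment(c("AAA", "AAA", "AAA"))
  expect_equal(classify_sites(aln)$class, rep("monomorphic", 3))

  aln <- as_alignment(c("ACGT", "ACGA", "ACGA", "ACGT"))
  cls <- classify_sites(aln)
  expect_equal(cls$class[4], "parsimony_informative")
  expect_equal(cls$class[1:3], rep("monomorphic", 3))

  # three alleles, none carried twice -> singleton
  aln <- as_alignment(c("AC", "AG", "AA"))
  expect_equal(classify_sites(aln)$class[2], "singleton")

  # gap and N columns are excluded, with a reason
  aln <- as_alignment(c("A-GN", "ACGA", "ACGA"))
  cls <- classify_sites(aln)
  expect_equal(cls$class[c(2, 4)], c("excluded", "excluded"))
  expect_equal(cls$excluded_reason[c(2, 4)], c("gap", "missing"))

  expect_error(classify_sites(c("ACGT")), "at least 2")
})

test_that("pi matches single-pair arithmetic and the all-pairs brute force", {
  expect_equal(nucleotide_diversity(as_alignment(rep("ACGTACGTAC", 5))), 0)
  expect_equal(nucleotide_diversity(
    as_alignment(c("AAAAAAAAAA", "AAAAAAAAAT"))), 0.1)

  set.seed(21)
  for (i in 1:25) {
    aln <- random_alignment(sample(3:10, 1), sample(40:200, 1))
    expect_equal(nucleotide_diversity(aln), oracle_pi(aln), tolerance = 1e-12)
  }
  expect_error(nucleotide_diversity(as_alignment(c("--", "AA"))),
               "no comparable sites")
})

test_that("haplotype statistics match the closed forms", {
  aln <- as_alignment(rep("ACGT", 4))
  h <- haplotype_stats(aln)
  expect_equal(h$n_haplotypes, 1L)
  expect_equal(h$haplotype_diversity, 0)

  # two haplotypes at 2/2: Hd = (4/3)(1 - 1/2) = 2/3
  aln <- as_alignment(c("AAAA", "AAAA", "AAAT", "AAAT"))
  h <- haplotype_stats(aln)
  expect_equal(h$n_haplotypes, 2L)
  expect_equal(h$haplotype_diversity, 2 / 3, tolerance = 1e-12)

  # all distinct: Hd = (4/3)(1 - 4/16) = 1
  aln <- as_alignment(c("AAAA", "AAAC", "AAAG", "AACT"))
  h <- haplotype_stats(aln)
  expect_equal(h$n_haplotypes, 4L)
  expect_equal(h$haplotype_diversity, 1, tolerance = 1e-12)

  # indel variation does not split haplotypes unless gaps are a fifth state
  aln <- as_alignment(c("AA-A", "AACA", "AACA"))
  expect_equal(haplotype_stats(aln)$n_haplotypes, 1L)
  expect_equal(haplotype_stats(aln, include_gaps = TRUE)$n_haplotypes, 2L)
})

test_that("sliding windows follow the closed-form count and localise signal", {
  set.seed(22)
  base <- rand_dna(1200)
  rows <- c(base, base, base, base)
  # one polymorphic column at 550 (two alleles, 2x2)
  v <- strsplit(rows, "")
  for (i in 3:4) v[[i]][550] <- setdiff(c("A", "C", "G", "T"), v[[i]][550])[1]
  aln <- as_alignment(vapply(v, paste, "", collapse = ""))
  prof <- sliding_window_pi(aln, window = 1000, step = 100)
  expect_equal(nrow(prof), floor((1200 - 1000) / 100) + 1)
  hot <- prof$pi > 0
  covers <- prof$start <= 550 & prof$end >= 550
  expect_identical(hot, covers)

  # constant alignment: all windows zero
  caln <- as_alignment(c(base, base))
  expect_true(all(sliding_window_pi(caln, 1000, 100)$pi == 0))

  # window = step = L reproduces global pi
  aln2 <- random_alignment(6, 500)
  prof2 <- sliding_window_pi(aln2, window = 500, step = 500)
  expect_equal(nrow(prof2), 1L)
  expect_equal(prof2$pi, nucleotide_diversity(aln2), tolerance = 1e-12)

  expect_error(sliding_window_pi(aln2, window = 600), "smaller window")
})

test_that("hotspot detection merges runs and labels overlapping loci", {
  prof <- tibble::tibble(
    start = seq(1, 901, by = 100), end = seq(100, 1000, by = 100),
    mid = (start + end) / 2,
    pi = c(0, 0.01, 0.012, 0, 0, 0.007, 0, 0, 0, 0)
  )
  hs <- detect_hotspots(prof, threshold = 0.006)
  expect_equal(nrow(hs), 2L)
  expect_equal(hs$start, c(101, 501))
  expect_equal(hs$n_windows, c(2L, 1L))
  feats <- tibble::tibble(name = c("geneA", "geneB"),
                          start = c(150, 2000), end = c(260, 2100))
  hs2 <- detect_hotspots(prof, threshold = 0.006, features = feats)
  expect_equal(hs2$loci[1], "geneA")
  expect_true(is.na(hs2$loci[2]))
  # all-zero profile -> empty result
  prof$pi <- 0
  expect_equal(nrow(detect_hotspots(prof)), 0L)
})

test_that("region summary equals independent per-region recomputation", {
  sim <- small_sim()
  aln <- sim$alignment
  regions <- sim$truth$regions
  regions$region <- sub("^I.*", "IR", regions$region)
  rds <- region_diversity_summary(aln, regions)
  expect_equal(rds$region, c("whole", "LSC", "IR", "SSC"))
  for (lab in c("LSC", "SSC")) {
    rr <- regions[regions$region == lab, ]
    sl <- plastdiv:::aln_slice(aln, rr$start:rr$end)
    expect_equal(rds$pi[rds$region == lab], nucleotide_diversity(sl),
                 tolerance = 1e-12)
    expect_equal(rds$n_haplotypes[rds$region == lab],
                 haplotype_stats(sl)$n_haplotypes)
  }
  expect_equal(rds$n_variable, rds$n_singleton + rds$n_pi)
  expect_equal(rds$pct_pi, 100 * rds$n_pi / rds$aln_length)
})

test_that("statistics are invariant under row order and reverse complement", {
  set.seed(23)
  aln <- random_alignment(8, 300)
  perm <- sample(seq_along(aln$ids))
  aln_p <- as_alignment(aln$seqs[perm], ids = aln$ids[perm])
  aln_rc <- as_alignment(revcomp(aln$seqs), ids = aln$ids)
  expect_equal(nucleotide_diversity(aln_p), nucleotide_diversity(aln))
  expect_equal(nucleotide_diversity(aln_rc), nucleotide_diversity(aln))
  expect_equal(haplotype_stats(aln_p)$n_haplotypes,
               haplotype_stats(aln)$n_haplotypes)
  expect_equal(haplotype_stats(aln_rc)$n_haplotypes,
               haplotype_stats(aln)$n_haplotypes)
  cs <- table(classify_sites(aln)$class)
  expect_equal(as.list(table(classify_sites(aln_rc)$class)), as.list(cs))
})

test_that("pairwise identity uses pairwise deletion and is symmetric", {
  aln <- as_alignment(c(a = "ACGTACGTAC", b = "ACGTACGTAC"))
  expect_equal(pairwise_identity(aln)["a", "b"], 100)
  aln <- as_alignment(c(a = "ACGTACGTAC", b = "ACGTACGTAT"))
  expect_equal(pairwise_identity(aln)["a", "b"], 90)
  # gap columns drop out per pair
  aln <- as_alignment(c(a = "AC-TACGTAC", b = "ACGTACGTAT"))
  expect_equal(pairwise_identity(aln)["a", "b"], 100 * 8 / 9)
  set.seed(24)
  m <- pairwise_identity(random_alignment(7, 200))
  expect_true(isSymmetric(unname(m)))
  expect_true(all(diag(m) == 100))
})

test_that("neighbor joining recovers an additive tree and flags bad input", {
  # distances from a known 4-taxon additive tree:
  # ((a:1,b:2):1,(c:3,d:4):1) with internal edge 2 (split ab|cd)
  d <- matrix(c(0, 3, 6, 7,
                3, 0, 7, 8,
                6, 7, 0, 7,
                7, 8, 7, 0), 4, 4,
              dimnames = list(letters[1:4], letters[1:4]))
  nwk <- nj_tree(d)
  tr <- attr(nwk, "tree")
  dd <- ape::cophenetic.phylo(tr)[letters[1:4], letters[1:4]]
  expect_equal(unname(dd), unname(d), tolerance = 1e-9)
  # 3 taxa: the unique unrooted topology
  d3 <- matrix(c(0, 2, 3, 2, 0, 3, 3, 3, 0), 3, 3,
               dimnames = list(c("x", "y", "z"), c("x", "y", "z")))
  expect_match(nj_tree(d3), "x|y|z")
  # identical pair -> zero-length cherry
  aln <- as_alignment(c(p = "ACGTACGTAC", q = "ACGTACGTAC", r = "TTTTACGTAC"))
  dm <- 100 - pairwise_identity(aln)
  trq <- attr(nj_tree(dm), "tree")
  dpq <- ape::cophenetic.phylo(trq)["p", "q"]
  expect_equal(unname(dpq), 0)
  bad <- d
  bad[1, 2] <- 99
  expect_error(nj_tree(bad), "symmetric")
})
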