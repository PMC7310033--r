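test_that("SSR finder handles the canonical small cases", {
  # one AT x3 locus at positions 3..8
  got <- find_ssrs("GGATATATCC")
  expect_equal(nrow(got), 1L)
  expect_equal(got$motif, "AT")
  expect_equal(got$n_repeats, 3L)
  expect_equal(c(got$start, got$end), c(3L, 8L))
  # two repeats only -> nothing
  expect_equal(nrow(find_ssrs("ATAT")), 0L)
  # mononucleotide runs are excluded (unit 1 not in range, AA unit not primitive)
  expect_equal(nrow(find_ssrs("AAAAAA")), 0L)
  expect_equal(nrow(find_ssrs("CCAAAAAAACC")), 0L)
  # motif is the smallest rotation
  expect_equal(find_ssrs("GGTATATACC")$motif, "AT")
  # a partial trailing unit is trimmed: 2 full repeats only -> not reported
  expect_equal(nrow(find_ssrs("GACGACGA")), 0L)
  expect_equal(find_ssrs("GACGACGAC")$n_repeats, 3L)
})

test_that("SSR finder equals the quadratic oracle on random strings", {
  set.seed(41)
  for (i in 1:60) {
    n <- sample(100:800, 1)
    s <- rand_dna(n, alphabet = c("A", "C", "G", "T", "A", "T"))
    if (i %% 2 == 0) {
      u <- rand_dna(sample(2:6, 1))
      ins <- strrep(u, sample(3:7, 1))
      pos <- sample(10:(n - 10), 1)
      s <- paste0(substr(s, 1, pos), ins, substr(s, pos + 1, n))
    }
    a <- find_ssrs(s)
    b <- oracle_ssrs(s)
    expect_identical(
      sort(paste(a$start, a$end, a$unit_len, a$n_repeats)),
      sort(paste(b$start, b$end, b$unit_len, b$n_repeats)),
      label = paste("SSR oracle seed", i))
  }
})

test_that("reported SSR intervals never overlap at the same unit length", {
  set.seed(42)
  for (i in 1:20) {
    s <- rand_dna(1500, alphabet = c("A", "T", "A", "T", "C", "G"))
    loci <- find_ssrs(s)
    for (u in unique(loci$unit_len)) {
      li <- loci[loci$unit_len == u, ]
      if (nrow(li) < 2) next
      li <- li[order(li$start), ]
      expect_true(all(li$start[-1] > li$end[-nrow(li)]))
    }
  }
})

test_that("LSR finder handles planted direct, spaced, and inverted repeats", {
  set.seed(43)
  u12 <- rand_dna(12)
  # spaced direct pair with a 10 bp spacer; flanking guard bases stop chance
  # extension of the exact match beyond the planted copies
  sp <- rand_dna(10)
  f1 <- paste0(rand_dna(29), pick_diff(substr(sp, 10, 10)))
  f2 <- paste0(pick_diff(substr(sp, 1, 1)), rand_dna(29))
  s <- paste0(f1, u12, sp, u12, f2)
  got <- find_lsrs(s)
  expect_equal(nrow(got), 1L)
  expect_equal(got$arrangement, "spaced")
  expect_equal(got$n_copies, 2L)
  expect_equal(got$unit_len, 12L)
  # same pair with a 60 bp spacer -> nothing
  s2 <- paste0(rand_dna(30), u12, rand_dna(60), u12, rand_dna(30))
  expect_equal(nrow(find_lsrs(s2)), 0L)
  # 14 bp unit followed by its reverse complement -> hairpin
  u14 <- rand_dna(14)
  s3 <- paste0(rand_dna(30), u14, revcomp(u14), rand_dna(30))
  got3 <- find_lsrs(s3)
  expect_true("hairpin" %in% got3$arrangement)
  # self-reverse-complementary arm -> palindromic (guarded boundaries)
  y <- rand_dna(11)
  arm <- paste0(y, revcomp(y))
  sp4 <- paste0("A", rand_dna(18), "C")
  s4 <- paste0(rand_dna(29), "A", arm, sp4, arm, "C", rand_dna(29))
  got4 <- find_lsrs(s4)
  expect_true("palindromic" %in% got4$arrangement)
  # three copies with distinct spacers chain into one locus; guard the
  # spacer/flank boundary characters so every pairwise match is exactly u14
  sp1 <- paste0("A", rand_dna(7), "C")
  sp2 <- paste0("C", rand_dna(11), "T")
  s5 <- paste0(rand_dna(19), "G", u14, sp1, u14, sp2, u14, "G", rand_dna(19))
  got5 <- find_lsrs(s5)
  expect_true(any(got5$n_copies == 3L & got5$unit_len == 14L))
})

test_that("LSR finder equals the exhaustive oracle on random strings", {
  set.seed(44)
  for (i in 1:50) {
    n <- sample(150:400, 1)
    s <- rand_dna(n)
    if (i %% 2 == 0) {
      u <- rand_dna(sample(11:25, 1))
      second <- if (i %% 4 == 0) revcomp(u) else u
      ins <- paste0(u, rand_dna(sample(0:50, 1)), second)
      pos <- sample(10:(n - 10), 1)
      s <- paste0(substr(s, 1, pos), ins, substr(s, pos + 1, n))
    }
    expect_identical(lsr_key(find_lsrs(s)), lsr_key(oracle_lsrs(s)),
                     label = paste("LSR oracle seed", i))
  }
})

test_that("copies inside SSR loci are removed from LSRs", {
  set.seed(45)
  # an 12 bp word made of an AT microsatellite: (AT)x6 twice with a spacer
  ssr_word <- strrep("AT", 6)
  s <- paste0(rand_dna(30), ssr_word, rand_dna(20), ssr_word, rand_dna(30))
  ssr <- find_ssrs(s)
  expect_gt(nrow(ssr), 0L)
  with_filter <- find_lsrs(s, ssr_loci = ssr)
  expect_false(any(vapply(seq_len(nrow(with_filter)), function(k) {
    any(ssr$start <= with_filter$copy_start[[k]] &
          ssr$end >= with_filter$copy_end[[k]])
  }, TRUE)))
})

test_that("reverse-complementing the genome preserves direct LSR counts", {
  set.seed(46)
  u <- rand_dna(15)
  s <- paste0(rand_dna(40), u, rand_dna(12), u, rand_dna(40),
              u, rand_dna(25), u, rand_dna(40))
  a <- find_lsrs(s)
  b <- find_lsrs(revcomp(s))
  expect_equal(sum(a$arrangement %in% c("tandem", "spaced")),
               sum(b$arrangement %in% c("tandem", "spaced")))
  expect_equal(nrow(a), nrow(b))
})

test_that("context and region annotation follow midpoint and majority rules", {
  part <- tibble::tibble(region = c("LSC", "IRA", "SSC", "IRB"),
                         start = c(1L, 1001L, 1501L, 2001L),
                         end = c(1000L, 1500L, 2000L, 2500L),
                         length = c(1000L, 500L, 500L, 500L))
  feats <- tibble::tibble(
    feature_id = c("g1.CDS.1", "g2.intron.2", "g3.tRNA.3"),
    name = c("g1", "g2", "g3"), kind = c("CDS", "intron", "tRNA"),
    strand = "+", part = 1L,
    start = c(100L, 300L, 500L), end = c(200L, 400L, 600L))
  set.seed(47)
  rec <- plastome("r", rand_dna(2500), features = feats, partition = part)
  loci <- tibble::tibble(
    start = c(120L, 320L, 520L, 700L, 1600L, 970L),
    end = c(140L, 340L, 540L, 720L, 1620L, 1020L),
    unit_len = 2L, n_repeats = 3L)
  ann <- annotate_repeat_context(loci, rec)
  expect_equal(ann$context, c("CDS", "intron", "rRNA/tRNA", "IGR", "IGR", "IGR"))
  # locus straddling LSC/IRA at 51/50 bp goes to LSC (majority, tie -> earlier)
  expect_equal(ann$region, c("LSC", "LSC", "LSC", "LSC", "SSC", "LSC"))
  # IRB loci are dropped under the single-IR-copy policy, kept with "both"
  loci_irb <- tibble::tibble(start = 2100L, end = 2120L,
                             unit_len = 2L, n_repeats = 3L)
  expect_equal(nrow(annotate_repeat_context(loci_irb, rec)), 0L)
  expect_equal(annotate_repeat_context(loci_irb, rec, ir_policy = "both")$region,
               "IRB")
  # missing partition errors
  rec2 <- plastome("q", rand_dna(100))
  expect_error(annotate_repeat_context(loci, rec2), "partition")
})

test_that("repeat polymorphism homologises loci through the alignment", {
  sim <- default_sim()
  per <- lapply(sim$records, function(r) find_ssrs(r$seq))
  poly <- repeat_polymorphism(per, sim$alignment)
  truth <- sim$truth$repeats
  truth <- truth[grepl("^ssr", truth$name), ]
  for (i in seq_len(nrow(truth))) {
    hit <- poly[poly$col_start <= truth$end[i] & poly$col_end >= truth$start[i], ]
    expect_gt(nrow(hit), 0L)
    expect_equal(hit$status[1],
                 if (truth$polymorphic[i]) "polymorphic" else "monomorphic",
                 label = truth$name[i])
    # per-genome counts match the planted copy numbers
    planted <- truth$counts[[i]]
    got <- hit$counts[[1]][names(planted)]
    expect_equal(unname(got), unname(planted), label = truth$name[i])
  }
  # invariant: polymorphic iff >= 2 distinct per-genome values
  expect_true(all(vapply(seq_len(nrow(poly)), function(k) {
    (length(unique(poly$counts[[k]])) >= 2) ==
      (poly$status[k] == "polymorphic")
  }, TRUE)))
  # a genome missing from the alignment is an error
  expect_error(repeat_polymorphism(setNames(per[1], "zzz"), sim$alignment),
               "absent")
})

test_that("a locus deleted in one genome is polymorphic with count zero", {
  set.seed(48)
  flank1 <- rand_dna(40)
  flank2 <- rand_dna(40)
  ssr <- strrep("AGT", 5)
  with_locus <- paste0(flank1, ssr, flank2)
  without <- paste0(flank1, strrep("-", nchar(ssr)), flank2)
  aln <- as_alignment(c(g1 = with_locus, g2 = without, g3 = with_locus))
  per <- list(g1 = find_ssrs(with_locus), g2 = find_ssrs(paste0(flank1, flank2)),
              g3 = find_ssrs(with_locus))
  poly <- repeat_polymorphism(per, aln)
  expect_equal(nrow(poly), 1L)
  expect_equal(poly$status, "polymorphic")
  expect_equal(unname(poly$counts[[1]][c("g1", "g2", "g3")]), c(5L, 0L, 5L))
})
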