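# IR detection uses a scaled-down quadripartite genome (30 kb LSC, 11 kb IR,
# 7 kb SSC) with guard bases at the planted boundaries so chance extension by
# a matching flank base cannot occur; boundaries are then known exactly.

test_that("planted quadripartite boundaries are recovered exactly", {
  set.seed(101)
  g <- guarded_quadripartite()
  rec <- plastome("g1", g$seq)
  p <- detect_quadripartite(rec, min_ir = 5000)
  expect_equal(p$region, c("LSC", "IRA", "SSC", "IRB"))
  expect_equal(p$length, c(g$lsc, g$ir, g$ssc, g$ir))
  expect_equal(p$start[p$region == "IRA"], g$lsc + 1L)
  expect_equal(p$end[p$region == "SSC"], g$lsc + g$ir + g$ssc)
  # the four intervals tile the full circle
  expect_equal(sum(p$length), nchar(g$seq))
})

test_that("detection is invariant under circular rotation", {
  set.seed(102)
  g <- guarded_quadripartite()
  p0 <- detect_quadripartite(plastome("a", g$seq), min_ir = 5000)
  for (rot in c(123L, 12345L, nchar(g$seq) - 7L)) {
    p1 <- detect_quadripartite(plastome("b", rotate_seq(g$seq, rot)),
                               min_ir = 5000)
    expect_equal(p1$length, p0$length)
  }
})

test_that("sequences without a long inverted repeat are rejected", {
  set.seed(103)
  expect_error(detect_quadripartite(plastome("r", rand_dna(60000)),
                                    min_ir = 5000),
               "no quadripartite structure")
  expect_error(detect_quadripartite(plastome("s", rand_dna(6000)),
                                    min_ir = 5000),
               "no quadripartite structure")
})

test_that("interior IR mismatches within tolerance do not break detection", {
  set.seed(104)
  g <- guarded_quadripartite()
  # three scattered substitutions inside IRb (identity still >= 1 - 1e-3)
  s <- g$seq
  irb_start <- g$lsc + g$ir + g$ssc
  for (off in c(2000L, 5000L, 8000L)) {
    pos <- irb_start + off
    old <- substr(s, pos, pos)
    substr(s, pos, pos) <- setdiff(c("A", "C", "G", "T"), old)[1]
  }
  p <- detect_quadripartite(plastome("m", s), min_ir = 5000,
                            max_mismatch_frac = 0.001)
  expect_equal(p$length[p$region == "IRA"], g$ir)
})

test_that("canonicalization is idempotent and an involution", {
  sim <- small_sim()
  rec <- sim$records[[2]]
  c1 <- canonicalize(rec)
  expect_identical(canonicalize(c1)$seq, c1$seq)
  c2 <- canonicalize(revcomp_plastome(rec))
  expect_identical(c2$seq, c1$seq)
  # region order after canonicalization is LSC, IRA, SSC, IRB from base 1
  expect_equal(c1$partition$start[1], 1L)
  expect_equal(c1$partition$region, c("LSC", "IRA", "SSC", "IRB"))
})

test_that("canonicalization remaps features so re-extraction is unchanged", {
  sim <- small_sim()
  rec <- sim$records[[1]]
  c1 <- canonicalize(rec)
  for (g in c("rbcL", "accD", "ndhF")) {
    expect_identical(extract_locus(list(c1), g)$seq,
                     extract_locus(list(rec), g)$seq)
  }
  # flipping the SSC reverse-complements the segment but preserves gene
  # sequences through coordinate remapping
  fl <- plastdiv:::flip_ssc(c1)
  ssc_iv <- c1$partition[c1$partition$region == "SSC", ]
  expect_identical(substr(fl$seq, ssc_iv$start, ssc_iv$end),
                   revcomp(substr(c1$seq, ssc_iv$start, ssc_iv$end)))
  expect_identical(extract_locus(list(fl), "ndhF")$seq,
                   extract_locus(list(c1), "ndhF")$seq)
})

test_that("SSC orientation follows the reference when one is provided", {
  sim <- small_sim()
  ref <- canonicalize(sim$records[[1]])
  rec <- canonicalize(sim$records[[2]], reference = ref)
  ssc_of <- function(r) {
    iv <- r$partition[r$partition$region == "SSC", ]
    substr(r$seq, iv$start, iv$end)
  }
  ref_ssc <- ssc_of(ref)
  got <- ssc_of(rec)
  ident <- function(a, b) {
    L <- min(nchar(a), nchar(b))
    mean(strsplit(substr(a, 1, L), "")[[1]] == strsplit(substr(b, 1, L), "")[[1]])
  }
  expect_gt(ident(got, ref_ssc), ident(revcomp(got), ref_ssc))
})

test_that("junction report finds the junction-spanning gene with its overhang", {
  sim <- small_sim()
  jr <- junction_report(sim$records[[1]])
  expect_equal(nrow(jr), 4L)
  row <- jr[jr$junction == "LSC-IRA", ]
  expect_equal(row$spanning_feature, "rps19")
  expect_equal(row$span_right_bp, 7L)
  # a partitionless record is an error
  bare <- plastome("x", rand_dna(1000))
  expect_error(junction_report(bare), "no partition")
})

test_that("junctions without nearby features report distances only", {
  part <- tibble::tibble(region = c("LSC", "IRA", "SSC", "IRB"),
                         start = c(1L, 4001L, 6001L, 8001L),
                         end = c(4000L, 6000L, 8000L, 10000L),
                         length = c(4000L, 2000L, 2000L, 2000L))
  feats <- tibble::tibble(feature_id = "gA.CDS.1", name = "gA", kind = "CDS",
                          strand = "+", part = 1L, start = 100L, end = 400L)
  set.seed(105)
  rec <- plastome("j", rand_dna(10000), features = feats, partition = part)
  jr <- junction_report(rec)
  row <- jr[jr$junction == "IRA-SSC", ]
  expect_true(is.na(row$spanning_feature))
  expect_equal(row$left_feature, "gA")
  expect_equal(row$left_dist, 6000L - 400L)
})

test_that("locus extraction handles spacers, minus strands, and errors", {
  sim <- small_sim()
  recs <- sim$records
  # planted trnH-psbA spacer is exactly 357 bp in every taxon
  sp <- extract_locus(recs, c("trnH", "psbA"))
  expect_true(all(sp$length == 357L))
  # minus-strand gene comes back on the coding strand
  ndhf <- extract_locus(recs, "ndhF")
  expect_true(all(substr(ndhf$seq, 1, 3) == "ATG"))
  rec1 <- recs[[1]]
  f <- rec1$features[rec1$features$name == "ndhF", ]
  manual <- revcomp(substr(rec1$seq, f$start, f$end))
  expect_identical(ndhf$seq[1], manual)
  # spliced two-part gene: length equals the sum of its parts
  two <- rec1
  two$features <- rbind(two$features,
    tibble::tibble(feature_id = "two.CDS.99", name = "twoexon", kind = "CDS",
                   strand = "+", part = 1:2,
                   start = c(500L, 901L), end = c(700L, 1000L)))
  got <- extract_locus(list(two), "twoexon")
  expect_equal(got$length, (700 - 500 + 1) + (1000 - 901 + 1))
  expect_identical(got$seq, paste0(substr(two$seq, 500, 700),
                                   substr(two$seq, 901, 1000)))
  # absent gene and non-adjacent pair are errors
  expect_error(extract_locus(recs, "nosuchgene"), "absent")
  expect_error(extract_locus(recs, c("trnH", "rps16")), "not adjacent")
})

test_that("locus extraction commutes with canonicalization", {
  sim <- small_sim()
  recs <- sim$records[1:3]
  canon <- lapply(recs, canonicalize)
  expect_identical(extract_locus(recs, "accD")$seq,
                   extract_locus(canon, "accD")$seq)
  expect_identical(extract_locus(recs, c("trnH", "psbA"))$seq,
                   extract_locus(canon, c("trnH", "psbA"))$seq)
})
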