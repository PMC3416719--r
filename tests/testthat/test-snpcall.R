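cfg_default <- filter_config()

test_that("contig eligibility gate sits exactly at the stated thresholds", {
  a_ok <- make_aln(rand_seq(100), rep(strrep("A", 100), 10))
  expect_true(eligible_contig(a_ok, cfg_default))
  a_short <- make_aln(rand_seq(99), rep(strrep("A", 99), 50))
  expect_false(eligible_contig(a_short, cfg_default))
  a_shallow <- make_aln(rand_seq(5000), rep(strrep("A", 5000), 9))
  expect_false(eligible_contig(a_shallow, cfg_default))
})

test_that("column tallies respect the strict quality threshold and gaps", {
  a <- make_aln("ACGT", rep("ACGT", 10))
  expect_equal(column_alleles(a, 1), c(A = 10L))

  qm <- matrix(30L, nrow = 10, ncol = 4)
  qm[9:10, 2] <- 15L
  reads <- c(rep("ACGT", 8), rep("AGGT", 2))
  a2 <- make_aln("ACGT", reads, read_qual = qm)
  expect_equal(column_alleles(a2, 2), c(C = 8L))

  a3 <- make_aln("ACGT", c(rep("ACGT", 7), rep("A-GT", 3)))
  expect_equal(column_alleles(a3, 2), c(C = 7L, gap = 3L))

  # quality exactly at the threshold does not pass (strict inequality)
  a4 <- make_aln("ACGT", rep("ACGT", 5), read_qual = 20)
  expect_equal(length(column_alleles(a4, 1)), 0)

  expect_error(column_alleles(a, 5), "outside")
})

test_that("homopolymer exclusion covers runs longer than 4 and their edges", {
  cons <- paste0("CGTCG", "CAAAAAG", "TCGTC")  # run of 5 A at 7..11
  for (p in 6:12)  # run plus both adjacent positions
    expect_true(homopolymer_excluded(cons, p, cfg_default))
  expect_false(homopolymer_excluded(cons, 5, cfg_default))
  expect_false(homopolymer_excluded(cons, 13, cfg_default))

  cons4 <- paste0("CGTCG", "CAAAAG", "TCGTC")  # run of exactly 4
  for (p in 6:11) expect_false(homopolymer_excluded(cons4, p, cfg_default))

  # position immediately 3' of a 6-base run (hand-listed exclusion zone)
  cons6 <- paste0("GT", strrep("C", 6), "ATGTA")
  expect_true(homopolymer_excluded(cons6, 9, cfg_default))   # adjacent 3'
  expect_true(homopolymer_excluded(cons6, 2, cfg_default))   # adjacent 5'
  expect_false(homopolymer_excluded(cons6, 1, cfg_default))
  expect_false(homopolymer_excluded(cons6, 10, cfg_default))
})

test_that("flank test needs 20 existing high-quality bases on each side", {
  a <- make_aln(rand_seq(1000), rep(strrep("A", 1000), 10))
  expect_false(flank_ok(a, 20, cfg_default))   # only 19 bp upstream
  expect_true(flank_ok(a, 21, cfg_default))
  expect_true(flank_ok(a, 980, cfg_default))
  expect_false(flank_ok(a, 981, cfg_default))  # only 19 bp downstream

  cq <- rep(40L, 1000); cq[505] <- 10L
  a2 <- make_aln(rand_seq(1000), rep(strrep("A", 1000), 10), cons_qual = 40)
  a2$consensus_quality <- cq
  expect_false(flank_ok(a2, 500, cfg_default))
  expect_false(flank_ok(a2, 524, cfg_default))
  expect_true(flank_ok(a2, 526, cfg_default))

  cons_n <- rand_seq(1000)
  substr(cons_n, 510, 510) <- "N"
  a3 <- make_aln(cons_n, rep(strrep("A", 1000), 10))
  expect_false(flank_ok(a3, 500, cfg_default))
})

test_that("transition/transversion classification is correct and symmetric", {
  expect_equal(classify_substitution("A", "G"), "Ti")
  expect_equal(classify_substitution("C", "T"), "Ti")
  for (pair in list(c("A", "C"), c("A", "T"), c("G", "C"), c("G", "T")))
    expect_equal(classify_substitution(pair[1], pair[2]), "Tv")
  for (a in c("A", "C", "G", "T")) for (b in c("A", "C", "G", "T"))
    if (a != b)
      expect_identical(classify_substitution(a, b),
                       classify_substitution(b, a))
  expect_error(classify_substitution("A", "A"), "differ")
  expect_error(classify_substitution("A", "X"), "A,C,G,T")
})

test_that("a monomorphic contig yields no calls", {
  cons <- rand_seq(500)
  a <- make_aln(cons, rep(cons, 20))
  expect_equal(nrow(call_snps(a, cfg_default)), 0)
})

test_that("a planted biallelic site is called with correct counts and class", {
  fx <- single_snp_fixture(pos = 500, minor_count = 3, depth = 30)
  calls <- call_snps(fx$aln, cfg_default)
  expect_equal(nrow(calls), 1)
  expect_equal(calls$position, 500)
  expect_equal(calls$major_allele, fx$major)
  expect_equal(calls$minor_allele, fx$minor)
  expect_equal(calls$minor_count, 3L)
  expect_equal(calls$major_count, 27L)
  expect_equal(calls$maf, 0.1)
  expect_equal(calls$substitution_class,
               classify_substitution(fx$major, fx$minor))
})

test_that("triallelic and gap-bearing columns are excluded", {
  fx <- single_snp_fixture(pos = 500, minor_count = 3, depth = 30)
  a <- fx$aln
  # make a second column triallelic: 2 reads each of two non-consensus bases
  p <- 300
  major <- substr(a$consensus, p, p)
  alts <- setdiff(c("A", "C", "G", "T"), major)
  for (j in 5:6) substr(a$reads[[j]]$seq, p, p) <- alts[1]
  for (j in 7:8) substr(a$reads[[j]]$seq, p, p) <- alts[2]
  # and a third column with a substitution plus gaps
  p2 <- 700
  for (j in 9:10) substr(a$reads[[j]]$seq, p2, p2) <-
      setdiff(c("A", "C", "G", "T"), substr(a$consensus, p2, p2))[1]
  for (j in 11:12) substr(a$reads[[j]]$seq, p2, p2) <- "-"
  calls <- call_snps(a, cfg_default)
  expect_equal(calls$position, 500)
})

test_that("minor-allele support works as an OR of frequency and count", {
  # 2 minor reads out of 200: maf = 0.01 -> passes via both arms
  fx <- single_snp_fixture(pos = 500, minor_count = 2, depth = 200)
  expect_equal(nrow(call_snps(fx$aln, cfg_default)), 1)
  # 1 minor read out of 150: maf < 0.01 and count < 2 -> rejected
  fx1 <- single_snp_fixture(pos = 500, minor_count = 1, depth = 150)
  expect_equal(nrow(call_snps(fx1$aln, cfg_default)), 0)
  # 1 minor read out of 30: maf 0.033 >= 0.01 -> called on the MAF arm
  fx2 <- single_snp_fixture(pos = 500, minor_count = 1, depth = 30)
  expect_equal(nrow(call_snps(fx2$aln, cfg_default)), 1)
})

test_that("an exact tie takes the lexicographically later base as minor", {
  fx <- single_snp_fixture(pos = 500, minor_count = 15, depth = 30)
  calls <- call_snps(fx$aln, cfg_default)
  expect_equal(nrow(calls), 1)
  expect_equal(calls$minor_allele, max(fx$major, fx$minor))
  expect_equal(calls$major_allele, min(fx$major, fx$minor))
  expect_equal(calls$maf, 0.5)
})

test_that("call sets are invariant under read reordering", {
  cfg <- alignment_sim_config(n_contigs = 3, snp_rate_per_kb = 3, seed = 77)
  sim <- simulate_alignments(cfg)
  for (a in sim$alignments) {
    b <- a
    b$reads <- rev(b$reads)
    expect_equal(call_snps(a, cfg_default), call_snps(b, cfg_default))
  }
})

test_that("Ti and Tv calls partition the call set", {
  cfg <- alignment_sim_config(n_contigs = 6, snp_rate_per_kb = 3, seed = 13)
  sim <- simulate_alignments(cfg)
  calls <- call_snps_all(sim$alignments)
  expect_true(all(calls$substitution_class %in% c("Ti", "Tv")))
  expect_equal(sum(calls$substitution_class == "Ti") +
                 sum(calls$substitution_class == "Tv"), nrow(calls))
})

test_that("malformed alignments are rejected at construction", {
  expect_error(
    contig_alignment("c", "ACGT", rep(40L, 4),
                     list(list(read_id = "r", start = 2, seq = "CGTA",
                               qual = rep(30L, 4)))),
    "outside")
  expect_error(contig_alignment("c", "ACGU", rep(40L, 4), list()),
               "A,C,G,T,N")
})

test_that("caller matches the brute-force oracle on adversarial alignments", {
  set.seed(906)
  cfgs <- list(
    list(cfg = filter_config(min_contig_length = 40),
         args = list(min_len = 40)),
    list(cfg = filter_config(min_contig_length = 40, flank_len = 5,
                             min_base_quality = 25),
         args = list(min_len = 40, flank = 5, minq = 25)))
  for (i in 1:60) {
    a <- rand_alignment(sprintf("rc%03d", i))
    ch <- cfgs[[(i %% 2) + 1]]
    got <- call_snps(a, ch$cfg)
    want <- do.call(oracle_call_snps, c(list(a), ch$args))
    rownames(got) <- NULL
    expect_equal(got, want, info = sprintf("alignment %d", i))
  }
})
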