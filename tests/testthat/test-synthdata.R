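test_that("a variation-free configuration yields no events and clean reads", {
  cfg <- alignment_sim_config(n_contigs = 5, snp_rate_per_kb = 0,
                              base_error_rate = 0, seed = 11)
  sim <- simulate_alignments(cfg)
  expect_equal(nrow(sim$truth$snps), 0)
  expect_equal(nrow(sim$truth$decoys), 0)
  for (a in sim$alignments)
    for (rd in a$reads) expect_identical(rd$seq, a$consensus)
})

test_that("the simulator is byte-identical under a fixed seed", {
  cfg <- alignment_sim_config(n_contigs = 8, snp_rate_per_kb = 2,
                              indel_decoy_rate = 0.5, edge_decoy_rate = 0.5,
                              seed = 33)
  s1 <- simulate_alignments(cfg)
  s2 <- simulate_alignments(cfg)
  expect_identical(s1, s2)
  ct <- count_sim_config(n_contigs = 500, seed = 9)
  expect_identical(simulate_count_table(ct), simulate_count_table(ct))
})

test_that("contig i does not depend on how many contigs are simulated", {
  cfg5 <- alignment_sim_config(n_contigs = 5, snp_rate_per_kb = 1, seed = 21)
  cfg2 <- alignment_sim_config(n_contigs = 2, snp_rate_per_kb = 1, seed = 21)
  s5 <- simulate_alignments(cfg5)
  s2 <- simulate_alignments(cfg2)
  expect_identical(s5$alignments[[2]], s2$alignments[[2]])
})

test_that("planted SNPs are recoverable by direct column counting", {
  cfg <- alignment_sim_config(n_contigs = 12, snp_rate_per_kb = 2, seed = 5)
  sim <- simulate_alignments(cfg)
  tr <- sim$truth$snps
  expect_gt(nrow(tr), 5)
  for (i in seq_len(nrow(tr))) {
    a <- sim$alignments[[tr$contig_id[i]]]
    counts <- column_alleles(a, tr$pos[i])
    expect_equal(unname(counts[tr$minor[i]]), tr$minor_count[i])
    expect_true(counts[tr$major[i]] >= counts[tr$minor[i]])
    expect_true(tr$pos[i] >= 1 && tr$pos[i] <= nchar(a$consensus))
  }
})

test_that("truth positions and labels respect the configuration", {
  cfg <- alignment_sim_config(n_contigs = 10, snp_rate_per_kb = 1,
                              prop_coding = 1, seed = 2)
  sim <- simulate_alignments(cfg)
  expect_true(all(sim$labels$class == "coding"))
  dec <- sim$truth$decoys
  expect_equal(nrow(dec), 0)  # no decoy rates set
  lens <- vapply(sim$alignments, function(a) nchar(a$consensus), 0L)
  deps <- vapply(sim$alignments, function(a) length(a$reads), 0L)
  expect_true(all(lens >= 100 & lens <= 5400))
  expect_true(all(deps >= 10 & deps <= 315))
})

test_that("invalid configurations fail naming the offending field", {
  expect_error(alignment_sim_config(prop_coding = 1.5), "prop_coding")
  expect_error(alignment_sim_config(snp_rate_per_kb = -1), "snp_rate_per_kb")
  expect_error(count_sim_config(dispersion_alpha = -0.1), "dispersion_alpha")
  expect_error(count_sim_config(true_beta = 1:3), "true_beta")
  expect_error(
    simulate_alignments(alignment_sim_config(
      length_dist = list(dist = "wiggle"))), "unknown distribution")
})

test_that("null count model is Poisson(1) in the zero-dispersion limit", {
  cfg <- count_sim_config(n_contigs = 10000, true_beta = c(0, 0, 0, 0),
                          dispersion_alpha = 0, seed = 14)
  tab <- simulate_count_table(cfg)
  expect_lt(abs(mean(tab$n_snp) - 1), 0.05)
  expect_lt(abs(var(tab$n_snp) - 1), 0.1)
})

test_that("simulated counts match NB2 moments at large n", {
  b0 <- 0.6
  cfg <- count_sim_config(n_contigs = 20000, true_beta = c(b0, 0, 0, 0),
                          dispersion_alpha = 0.5, prop_coding = 0,
                          seed = 8)
  tab <- simulate_count_table(cfg)
  mu <- exp(b0)
  expect_lt(abs(mean(tab$n_snp) - mu) / mu, 0.03)
  expect_lt(abs(var(tab$n_snp) - (mu + 0.5 * mu^2)) / (mu + 0.5 * mu^2),
            0.10)
  expect_true(all(tab$n_snp == tab$n_ti + tab$n_tv))
})

test_that("coding fraction and transition split follow their parameters", {
  cfg <- count_sim_config(n_contigs = 5000, prop_coding = 1, ti_prop = 0.64,
                          seed = 4)
  tab <- simulate_count_table(cfg)
  expect_true(all(tab$cnc == 1))
  expect_lt(abs(sum(tab$n_ti) / sum(tab$n_snp) - 0.64), 0.03)
})

test_that("flat config files round-trip and reject unknown keys", {
  f <- withr::local_tempfile(fileext = ".cfg")
  writeLines(c("type = count", "n_contigs = 50",
               "true_beta = -1.0, 0.0002, 0.015, -0.1",
               "dispersion_alpha = 0.4", "seed = 7",
               "length_dist.dist = uniform", "length_dist.min = 501",
               "length_dist.max = 5354"), f)
  cfg <- read_sim_config(f)
  expect_s3_class(cfg, "count_sim_config")
  expect_equal(cfg$n_contigs, 50L)
  expect_equal(cfg$true_beta[3], 0.015)
  expect_equal(cfg$length_dist$dist, "uniform")
  writeLines(c("type = count", "n_contigz = 50"), f)
  expect_error(read_sim_config(f), "n_contigz")
})
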