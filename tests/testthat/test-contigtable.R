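mk_calls <- function(contig_id, classes) {
  data.frame(contig_id = contig_id,
             position = seq_along(classes) * 50 + 100,
             major_allele = "A", minor_allele = "G",
             major_count = 10L, minor_count = 2L, maf = 2 / 12,
             substitution_class = classes)
}

meta3 <- data.frame(contig_id = c("c1", "c2", "c3"),
                    length = c(800L, 1200L, 90L),
                    depth = c(20L, 15L, 50L))
labels3 <- data.frame(contig_id = c("c1", "c2", "c3"),
                      class = c("coding", "noncoding", "coding"))

test_that("per-contig counts aggregate calls; zero-call contigs keep rows", {
  calls <- mk_calls(rep("c1", 4), c("Ti", "Ti", "Ti", "Tv"))
  tab <- build_table(calls, meta3, labels3)
  expect_equal(nrow(tab), 2)  # c3 fails the 100 bp gate
  r1 <- tab[tab$contig_id == "c1", ]
  expect_equal(c(r1$n_snp, r1$n_ti, r1$n_tv), c(4L, 3L, 1L))
  r2 <- tab[tab$contig_id == "c2", ]
  expect_equal(c(r2$n_snp, r2$n_ti, r2$n_tv), c(0L, 0L, 0L))
  expect_equal(tab$cnc, c(1L, 0L))
  expect_true(all(tab$n_snp == tab$n_ti + tab$n_tv))
})

test_that("a missing coding label is a labeled error", {
  calls <- mk_calls("c1", "Ti")
  expect_error(build_table(calls, meta3, labels3[1, ]), "c2")
})

test_that("table counts on simulated data equal truth-table tallies", {
  cfg <- alignment_sim_config(n_contigs = 10, snp_rate_per_kb = 2,
                              triallelic_decoy_rate = 0.5, seed = 17)
  sim <- simulate_alignments(cfg)
  calls <- call_snps_all(sim$alignments)
  tab <- build_table(calls, alignment_metadata(sim$alignments), sim$labels)
  truth_n <- table(factor(sim$truth$snps$contig_id,
                          levels = tab$contig_id))
  expect_equal(tab$n_snp, as.integer(truth_n))
})

test_that("long-contig subsetting is a boundary-correct, idempotent filter", {
  tab <- data.frame(contig_id = paste0("c", 1:4),
                    length = c(100L, 500L, 501L, 502L),
                    depth = 10L, cnc = 1L, n_snp = 1:4,
                    n_ti = c(1L, 1L, 2L, 2L), n_tv = c(0L, 1L, 1L, 2L))
  lg <- subset_long(tab)
  expect_equal(lg$length, c(501L, 502L))
  expect_equal(subset_long(lg), lg)
  expect_equal(subset_long(tab, 100), tab)
  s_all <- summarize_contigs(tab); s_long <- summarize_contigs(lg)
  expect_true(all(s_long$total_snp <= s_all$total_snp))
  expect_true(all(s_long$n_contigs <= s_all$n_contigs))
})

test_that("summaries conserve totals under the coding-class partition", {
  cfg <- count_sim_config(n_contigs = 400, seed = 23)
  tab <- simulate_count_table(cfg)
  s <- summarize_contigs(tab)
  tot <- s[s$group == "total", ]
  parts <- s[s$group != "total", ]
  for (col in c("n_contigs", "total_snp", "total_ti", "total_tv"))
    expect_equal(tot[[col]], sum(parts[[col]]))
  one <- summarize_contigs(tab[1, ])
  expect_equal(one$mean_length[1], tab$length[1])
  expect_equal(one$total_snp[1], tab$n_snp[1])
  expect_error(summarize_contigs(tab[0, ]), "empty")
})

test_that("Ti/Tv ratio is a guarded quotient", {
  expect_equal(titv_ratio(5, 5), 1)
  expect_equal(round(titv_ratio(9, 5), 1), 1.8)
  expect_error(titv_ratio(3, 0), "zero")
})

test_that("pearson matches the textbook formula and handles nulls", {
  set.seed(55)
  tab <- data.frame(contig_id = paste0("c", 1:200),
                    length = round(runif(200, 501, 5000)),
                    depth = round(runif(200, 10, 300)), cnc = 1L,
                    n_snp = rpois(200, 2))
  tab$n_ti <- rbinom(200, tab$n_snp, 0.64); tab$n_tv <- tab$n_snp - tab$n_ti
  ct <- snp_cor(tab, "length", "n_snp")
  expect_equal(ct$r, oracle_pearson(tab$length, tab$n_snp),
               tolerance = 1e-12)
  # exact linear dependence
  tab2 <- tab; tab2$n_snp <- 2L * tab2$length
  expect_equal(snp_cor(tab2, "length", "n_snp")$r, 1)
  # independent covariate at large n stays near zero
  big <- simulate_count_table(count_sim_config(
    n_contigs = 10000, true_beta = c(0, 0, 0, 0), seed = 61))
  expect_lt(abs(snp_cor(big, "length", "n_snp")$r), 0.05)
  # positive depth effect in the generating model shows up as r > 0
  dep <- simulate_count_table(count_sim_config(
    n_contigs = 3000, true_beta = c(-1, 0, 0.0146, 0), seed = 62))
  cd <- snp_cor(dep, "depth", "n_snp")
  expect_gt(cd$r, 0)
  expect_lt(cd$p, 0.001)
  # degenerate variance errors out
  tab3 <- tab; tab3$n_snp <- 1L
  expect_error(snp_cor(tab3, "length", "n_snp"), "degenerate")
  expect_error(snp_cor(tab[1:2, ], "length", "n_snp"), "3 records")
})
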