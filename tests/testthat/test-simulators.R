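# Synthetic-data generators: determinism, structural guarantees, sampling
# expectations.

test_that("fixture pools satisfy the design's ITAM structure", {
  expect_true(all(vapply(fx_small$poolA, `[[`, 0L, "itam_count") == 0L))
  expect_true(all(vapply(fx_small$poolB, `[[`, 0L, "itam_count") == 1L))
  down_aa <- sub("\\*$", "", as.character(Biostrings::translate(
    Biostrings::DNAStringSet(fx_small$chassis$downstream_const))))
  expect_equal(itam_count(down_aa), 2L)
  # deterministic under seed
  again <- make_fixture_pools(3, 4, seed = 42)
  expect_identical(again, fx_small)
  # a different seed gives different sequences
  other <- make_fixture_pools(3, 4, seed = 43)
  expect_false(identical(other$poolA[[1]]$nt_seq, fx_small$poolA[[1]]$nt_seq))
})

test_that("error-free scCAR reads match their templates exactly", {
  cfg <- read_sim_config(n_cells = 30, whitelist_size = 60,
                         multi_car_fraction = 0, sub_rate = 0,
                         revcomp_fraction = 0, seed = 5)
  sim <- simulate_sccar_reads(lib_small, fx_small$chassis, cfg)
  ch <- fx_small$chassis
  u <- ch$upstream_const
  const5 <- substring(u, nchar(u) - 19, nchar(u))
  anchor <- substring(ch$downstream_const, 1, 24)
  labels <- vapply(lib_small, `[[`, "", "label")
  # every read embeds its cell's true insert between the constant flanks
  truth_of <- setNames(sim$truth$variant, sim$truth$barcode)
  for (i in seq_len(nrow(sim$reads))) {
    seq <- sim$reads$seq[i]
    bc <- substr(seq, 23, 38)  # after the 22-nt adapter
    v <- lib_small[[match(truth_of[bc], labels)]]
    expect_equal(substr(seq, 51, nchar(seq)),
                 paste0(const5, v$domain_a$nt_seq, ch$linker,
                        v$domain_b$nt_seq, anchor))
  }
  # seed-stable
  sim2 <- simulate_sccar_reads(lib_small, fx_small$chassis, cfg)
  expect_identical(sim2$reads, sim$reads)
})

test_that("multi-CAR truth cells follow the binomial expectation", {
  cfg <- read_sim_config(n_cells = 1000, whitelist_size = 1500,
                         multi_car_fraction = 0.04, sub_rate = 0, seed = 8)
  sim <- simulate_sccar_reads(lib_small, fx_small$chassis, cfg)
  n_multi <- sum(sim$truth$multi)
  expect_lt(abs(n_multi - 40), 4 * sqrt(1000 * 0.04 * 0.96))
  expect_true(all(sim$truth$variant2[sim$truth$multi] !=
                    sim$truth$variant[sim$truth$multi]))
})

test_that("plasmid amplicons follow their abundance weights", {
  sim <- simulate_plasmid_reads(lib_small, fx_small$chassis,
                                n_reads = 12000, seed = 2)
  counts <- table(sim$truth)
  # uniform abundance over 12 variants: multinomial expectation 1000 each
  expect_true(all(abs(counts - 1000) < 4 * sqrt(12000 * (1 / 12) * (11 / 12))))
  # zero-error reads are exact substrings of the variant ORFs
  labels <- vapply(lib_small, `[[`, "", "label")
  orfs <- vapply(lib_small, `[[`, "", "orf_nt")
  for (i in 1:50) {
    s <- sim$reads$seq[i]
    orf <- orfs[match(sim$truth[i], labels)]
    hit <- grepl(s, orf, fixed = TRUE) ||
      grepl(as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(s))), orf, fixed = TRUE)
    expect_true(hit)
  }
  # single-variant abundance
  ab <- c(1, rep(0, 11))
  one <- simulate_plasmid_reads(lib_small, fx_small$chassis, abundance = ab,
                                n_reads = 50, seed = 3)
  expect_true(all(one$truth == lib_small[[1]]$label))
  expect_error(simulate_plasmid_reads(lib_small, fx_small$chassis,
                                      n_reads = 0), "n_reads")
})

test_that("simulated count matrices are seed-stable and pass their own QC", {
  cfg <- expr_sim_config(n_variants = 4, cells_per_variant = 50,
                         cells_per_control = 50, seed = 21)
  sim <- simulate_expression(cfg)
  sim2 <- simulate_expression(cfg)
  expect_identical(as.matrix(sim$counts$counts), as.matrix(sim2$counts$counts))
  qc <- qc_filter(sim$counts)
  expect_gte(ncol(qc$counts$counts) / ncol(sim$counts$counts), 0.95)
  # planted propensity rows are respected in expectation: positive controls
  # sit mostly in CIC clusters, negatives mostly outside
  pos_cl <- sim$truth$cluster[sim$truth$group == "pos_28z"]
  neg_cl <- sim$truth$cluster[sim$truth$group == "neg_TCRminus"]
  expect_gt(mean(pos_cl %in% cfg$cic_clusters_truth), 0.75)
  expect_lt(mean(neg_cl %in% cfg$cic_clusters_truth), 0.20)
})

test_that("expression config validates propensity rows", {
  bad <- matrix(1 / 8, nrow = 5, ncol = 8)
  expect_error(expr_sim_config(n_variants = 2, variant_propensity = bad),
               "stochastic")
  # a propensity matrix that contradicts the declared CIC set is rejected
  ok_dim <- default_propensity_for_test(2, 8, 1:5)
  expect_error(expr_sim_config(n_variants = 2, variant_propensity = ok_dim,
                               cic_clusters_truth = 1:3),
               "plant")
})
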