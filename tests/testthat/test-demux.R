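# Barcode matching, read calling, cell assignment and diversity reporting.

test_that("barcode matching follows the unique-neighbour rule", {
  wl <- c("AAAA", "CCCC", "GGGG", "AAAT")
  expect_equal(match_barcode("AAAAGGGG", wl), "AAAA")       # exact
  expect_equal(match_barcode("CCCG", wl), "CCCC")           # unique 1-mm
  expect_true(is.na(match_barcode("AAAG", wl)))             # AAAA vs AAAT tie
  expect_true(is.na(match_barcode("CTGA", wl)))             # nothing close
  expect_true(is.na(match_barcode("CCCG", wl, max_mismatch = 0)))
  expect_error(match_barcode("AAAA", c("AA", "AAAA")), "mixed")
  expect_error(match_barcode("AAAA", character(0)), "non-empty")
})

test_that("error-free reads are called exactly, in either orientation", {
  cfg <- read_sim_config(n_cells = 40, whitelist_size = 80,
                         multi_car_fraction = 0, sub_rate = 0, seed = 12)
  sim <- simulate_sccar_reads(lib_small, fx_small$chassis, cfg)
  calls <- call_reads(sim$reads, fx_small$poolA, fx_small$poolB,
                      fx_small$chassis, whitelist = sim$whitelist)
  expect_true(all(calls$status == "ok"))
  expect_true(all(calls$score_a == 1) && all(calls$score_b == 1))
  # orientation invariance: reverse-complementing every read changes nothing
  rc_reads <- sim$reads
  rc_reads$seq <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(rc_reads$seq)))
  rc_calls <- call_reads(rc_reads, fx_small$poolA, fx_small$poolB,
                         fx_small$chassis, whitelist = sim$whitelist)
  expect_equal(rc_calls[, -1], calls[, -1])
})

test_that("single reads with substitutions are still called correctly", {
  v <- lib_small[[5]]
  ch <- fx_small$chassis
  u <- ch$upstream_const
  template <- paste0(substring(u, nchar(u) - 19, nchar(u)),
                     v$domain_a$nt_seq, ch$linker, v$domain_b$nt_seq,
                     substring(ch$downstream_const, 1, 24))
  set.seed(31)
  noisy <- carforge:::inject_errors(template, 0.02, 0, 0)
  call <- call_variant_read(noisy, fx_small$poolA, fx_small$poolB, ch)
  expect_equal(call$status, "ok")
  expect_equal(call$domain_a, v$domain_a$id)
  expect_equal(call$domain_b, v$domain_b$id)
  expect_gte(call$score_a, 0.95)
  # a read with no anchor region at all
  miss <- call_variant_read(strrep("ACGT", 40), fx_small$poolA,
                            fx_small$poolB, ch)
  expect_equal(miss$status, "no_anchor")
})

test_that("equidistant chimeric domains are flagged ambiguous", {
  ch <- fx_small$chassis
  da <- fx_small$poolA[[1]]
  b1 <- fx_small$poolB[[1]]$nt_seq
  b2 <- fx_small$poolB[[2]]$nt_seq
  # chimera: first half of B1 spliced onto the second half of B2, truncated
  # to equal halves so the two references score equally
  half <- 3 * (min(nchar(b1), nchar(b2)) %/% 6)
  chim <- paste0(substr(b1, 1, half),
                 substr(b2, nchar(b2) - half + 1, nchar(b2)))
  read <- paste0(substring(ch$upstream_const, nchar(ch$upstream_const) - 19),
                 da$nt_seq, ch$linker, chim,
                 substring(ch$downstream_const, 1, 24))
  call <- call_variant_read(read, fx_small$poolA, fx_small$poolB, ch)
  expect_equal(call$status, "ambiguous_domain")
})

test_that("cell assignment applies the UMI floor and strict multi rule", {
  mk_call <- function(bc, umi, a, b)
    data.frame(read_id = "r", barcode = bc, umi = umi, domain_a = a,
               domain_b = b, score_a = 1, score_b = 1, status = "ok")
  # 5 UMIs of A1-B1 and 1 UMI of A2-B2: multi under the strict default,
  # single (majority variant) once the noise floor removes the 1-UMI variant
  calls <- rbind(
    do.call(rbind, lapply(1:5, function(i)
      mk_call("CELL1", paste0("U", i), "A1", "B1"))),
    mk_call("CELL1", "U9", "A2", "B2"))
  strict <- demux_cells(calls, min_umis_per_variant = 1)
  expect_equal(strict$cells$status, "multi")
  expect_equal(strict$summary[["multi_rate"]], 1)
  floored <- demux_cells(calls, min_umis_per_variant = 2)
  expect_equal(floored$cells$status, "single")
  expect_equal(floored$cells$variant, "A1-B1")
  # dominance rescue (optional rule)
  dom <- demux_cells(calls, min_umis_per_variant = 1, dominance_ratio = 4)
  expect_equal(dom$cells$status, "single")
  # rates always sum to 1; empty input reports NA rates
  expect_equal(sum(strict$summary), 1)
  empty <- demux_cells(calls[0, ])
  expect_true(all(is.na(empty$summary)))
})

test_that("demultiplexing recovers an error-free truth table exactly", {
  cfg <- read_sim_config(n_cells = 150, whitelist_size = 300,
                         multi_car_fraction = 0, sub_rate = 0, seed = 17)
  sim <- simulate_sccar_reads(lib_small, fx_small$chassis, cfg)
  calls <- call_reads(sim$reads, fx_small$poolA, fx_small$poolB,
                      fx_small$chassis, whitelist = sim$whitelist)
  dx <- demux_cells(calls)
  expect_equal(dx$summary[["single_rate"]], 1)
  m <- merge(dx$cells, sim$truth, by = "barcode")
  expect_equal(nrow(m), 150L)
  expect_true(all(m$variant.x == m$variant.y))
  expect_equal(sum(dx$summary), 1)
})

test_that("diversity report: completeness, evenness and their invariances", {
  ids_a <- c("A1", "A2"); ids_b <- c("B1", "B2")
  full <- data.frame(domain_a = rep(ids_a, each = 2),
                     domain_b = rep(ids_b, 2))
  rep1 <- library_completeness(full, ids_a, ids_b)
  expect_equal(rep1$completeness, 1)
  expect_equal(rep1$evenness, 1)
  # omitting one combination
  rep2 <- library_completeness(full[-4, ], ids_a, ids_b)
  expect_equal(rep2$n_observed, 3L)
  expect_equal(rep2$completeness, 0.75)
  # single observed combination: evenness 0 by convention
  rep3 <- library_completeness(full[1, ], ids_a, ids_b)
  expect_equal(rep3$evenness, 0)
  # evenness invariant under label permutation
  perm <- full[-4, ]
  perm$domain_a <- ifelse(perm$domain_a == "A1", "A2", "A1")
  expect_equal(library_completeness(perm, ids_a, ids_b)$evenness,
               rep2$evenness)
  # completeness monotone non-decreasing when reads are added
  grow <- library_completeness(rbind(full[-4, ], full[4, ]), ids_a, ids_b)
  expect_gte(grow$completeness, rep2$completeness)
  # foreign ids warn and are excluded from the matrix
  expect_warning(
    fr <- library_completeness(rbind(full, data.frame(domain_a = "AX",
                                                      domain_b = "B1")),
                               ids_a, ids_b),
    "foreign")
  expect_equal(fr$n_foreign, 1L)
  expect_equal(sum(fr$combination_counts), 4L)
})
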