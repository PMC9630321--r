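# Library design: ITAM scanning, Type IIS digestion, assembly, enumeration.

test_that("itam_scan handles the canonical cases", {
  expect_equal(nrow(itam_scan("AAAAAA")), 0L)
  # one full motif, spacer 7
  hit <- itam_scan("YAALAAAAAAAYAAI")
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$start, 1L)
  expect_equal(hit$end, 15L)
  expect_equal(hit$spacer, 7L)
  # half-sites too far apart for the spacer bounds
  expect_equal(itam_count("YAALAAAAAAAAAAAAAAAYAAI", 6, 12), 0L)
  # fixture tCD3Z segment carries exactly two motifs
  down_aa <- sub("\\*$", "",
                 Biostrings::translate(Biostrings::DNAStringSet(
                   fx_small$chassis$downstream_const)) |> as.character())
  expect_equal(itam_count(down_aa), 2L)
  expect_error(itam_scan("YAXL!"), "invalid amino-acid")
  expect_error(itam_scan(""), "non-empty")
})

test_that("itam_scan agrees with a regex enumeration oracle", {
  set.seed(99)
  alpha <- c("A", "G", "L", "I", "Y", "S", "T", "P", "E", "K")
  for (i in 1:500) {
    aa <- paste(sample(alpha, sample(20:80, 1), replace = TRUE),
                collapse = "")
    expect_equal(itam_count(aa), itam_regex_oracle(aa), info = aa)
  }
})

test_that("typeIIs digestion respects enzyme geometry on both strands", {
  enz <- aarI()
  # single site, + strand: CACCTGC then 4 nt, cut leaves a 4-nt overhang
  seq1 <- paste0("AAAAAAAAAA", "CACCTGC", "GGGG", "TTCA", "CCCCCCCCCC")
  fr <- typeIIs_digest(seq1, enz)
  expect_length(fr, 2L)
  expect_equal(fr[[1]]$oh3, "TTCA")
  expect_equal(fr[[2]]$oh5, "TTCA")
  expect_equal(paste0(fr[[1]]$seq, fr[[2]]$seq), seq1)
  # single site on the - strand cuts upstream of the recognition sequence
  seq2 <- paste0("CCCCCCCCCC", "ACGT", "GGGG", "GCAGGTG", "AAAAAAAAAA")
  fr2 <- typeIIs_digest(seq2, enz)
  expect_length(fr2, 2L)
  expect_equal(fr2[[2]]$oh5, "ACGT")
  expect_error(typeIIs_digest("ACGTACGTACGT", enz), "no-site")
})

test_that("chassis cassette digests into three fragments with the designed overhangs", {
  ch <- fx_small$chassis
  vec <- paste0(ch$upstream_const, ch$cassette, ch$downstream_const)
  fr <- typeIIs_digest(vec, ch$enzyme)
  expect_length(fr, 3L)
  expect_equal(fr[[1]]$oh3, ch$oh_left)
  expect_equal(fr[[3]]$oh5, ch$oh_right)
  # middle fragment is the throw-away stuffer piece
  expect_true(grepl(ch$enzyme$recognition, fr[[2]]$seq, fixed = TRUE))
})

test_that("assembly produces in-frame three-ITAM ORFs and enforces pool order", {
  v <- assemble_variant(fx_small$chassis, fx_small$poolA[[1]],
                        fx_small$poolB[[1]])
  expect_equal(v$label, "A1-B1")
  expect_equal(v$total_itams, 3L)
  expect_equal(v$orf_nt,
               paste0(fx_small$chassis$upstream_const,
                      fx_small$poolA[[1]]$nt_seq, fx_small$chassis$linker,
                      fx_small$poolB[[1]]$nt_seq,
                      fx_small$chassis$downstream_const))
  expect_match(v$orf_aa, "\\*$")
  expect_equal(lengths(regmatches(v$orf_aa, gregexpr("\\*", v$orf_aa))), 1L)
  # pool order is enforced
  expect_error(assemble_variant(fx_small$chassis, fx_small$poolB[[1]],
                                fx_small$poolB[[2]]),
               "pool A")
  # a 1-nt deletion breaks the frame and is caught, naming the domain
  broken <- fx_small$poolA[[2]]
  broken$nt_seq <- substr(broken$nt_seq, 1, nchar(broken$nt_seq) - 1)
  expect_error(assemble_variant(fx_small$chassis, broken, fx_small$poolB[[1]]),
               "frameshift.*A2")
  # overhang mismatch is an assembly error
  wrong_oh <- fx_small$poolA[[2]]
  wrong_oh$oh5 <- "AAAA"
  expect_error(assemble_variant(fx_small$chassis, wrong_oh,
                                fx_small$poolB[[1]]),
               "overhang mismatch")
})

test_that("enumeration yields |A| x |B| distinct validated variants", {
  expect_length(lib_small, 12L)
  labels <- vapply(lib_small, `[[`, "", "label")
  expect_equal(anyDuplicated(labels), 0L)
  expect_true(all(vapply(lib_small, `[[`, 0L, "total_itams") == 3L))
  # property: |library| == |A| * |B| across pool sizes
  for (sz in list(c(1, 1), c(2, 3), c(5, 2))) {
    fx <- make_fixture_pools(sz[1], sz[2], seed = sz[1] * 10 + sz[2])
    expect_length(enumerate_library(fx$poolA, fx$poolB, fx$chassis),
                  sz[1] * sz[2])
  }
  # duplicate ids rejected
  dup <- fx_small$poolA
  dup[[2]]$id <- dup[[1]]$id
  expect_error(enumerate_library(dup, fx_small$poolB, fx_small$chassis),
               "duplicate")
})

test_that("digestion of re-amplified variants recovers both inserts exactly", {
  ch <- fx_small$chassis
  for (v in lib_small) {
    fr <- typeIIs_digest(reamplify_insert(v, ch), ch$enzyme)
    expect_length(fr, 3L)
    insert <- fr[[2]]
    expect_equal(insert$oh5, ch$oh_left)
    expect_equal(insert$oh3, ch$oh_right)
    # split the released insert at the known linker offset: domain A and B
    # are recovered byte-exactly
    la <- nchar(v$domain_a$nt_seq)
    expect_equal(substr(insert$seq, 5, 4 + la), v$domain_a$nt_seq)
    expect_equal(substr(insert$seq, 5 + la + nchar(ch$linker),
                        nchar(insert$seq)), v$domain_b$nt_seq)
  }
})

test_that("pool templates release chassis-compatible fragments that reassemble", {
  ch <- fx_small$chassis
  da <- fx_small$poolA[[3]]
  db <- fx_small$poolB[[2]]
  fa <- typeIIs_digest(domain_template(da, ch), ch$enzyme)[[2]]
  fb <- typeIIs_digest(domain_template(db, ch), ch$enzyme)[[2]]
  expect_equal(fa$seq, paste0(ch$oh_left, da$nt_seq))
  expect_equal(fb$seq, paste0(ch$linker, db$nt_seq))
  u <- ch$upstream_const
  lig <- ligate_fragments(list(
    list(seq = substr(u, 1, nchar(u) - 4), oh5 = "", oh3 = ch$oh_left),
    fb, fa,  # order scrambled on purpose: overhangs direct the chain
    list(seq = ch$downstream_const, oh5 = ch$oh_right, oh3 = "")))
  expect_equal(lig$seq,
               assemble_variant(ch, da, db)$orf_nt)
})

test_that("library FASTA writing round-trips", {
  path <- withr::local_tempfile(fileext = ".fasta")
  write_library_fasta(lib_small, path)
  back <- read_fasta(path)
  expect_length(back, 12L)
  expect_equal(unname(back),
               vapply(lib_small, `[[`, "", "orf_nt"))
  expect_equal(names(back), vapply(lib_small, `[[`, "", "label"))
  expect_error(write_library_fasta(list(), path), "empty")
})
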