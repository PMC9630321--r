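# Shared fixtures, built once per test run.

fx_small <- make_fixture_pools(nA = 3, nB = 4, seed = 42)
lib_small <- enumerate_library(fx_small$poolA, fx_small$poolB,
                               fx_small$chassis)

# Full-size (15 x 12) fixture library, built lazily and cached: several test
# files need it and generation takes a few seconds.
.fx_cache <- new.env(parent = emptyenv())
fixture_full <- function() {
  if (is.null(.fx_cache$fx)) {
    .fx_cache$fx <- make_fixture_pools(nA = 15, nB = 12, seed = 7)
    .fx_cache$lib <- enumerate_library(.fx_cache$fx$poolA, .fx_cache$fx$poolB,
                                       .fx_cache$fx$chassis)
  }
  .fx_cache
}

# Small deterministic count object for QC boundary tests: cell j detects
# exactly `detected[j]` genes and has exactly `mt_pct[j]` percent
# mitochondrial counts (mt_pct must be integer; each detected non-mito gene
# gets 100 - mt_pct counts and one mito gene the exact remainder).
toy_counts <- function(detected, mt_pct, n_genes = 11000, n_mito = 10) {
  stopifnot(length(detected) == length(mt_pct),
            all(mt_pct == round(mt_pct)))
  n_cells <- length(detected)
  genes <- c(sprintf("MT-%d", seq_len(n_mito)),
             sprintf("G%05d", seq_len(n_genes - n_mito)))
  m <- matrix(0L, nrow = n_genes, ncol = n_cells,
              dimnames = list(genes, sprintf("cell%02d", seq_len(n_cells))))
  for (j in seq_len(n_cells)) {
    n_nm <- detected[j] - (mt_pct[j] > 0)  # non-mito detected genes
    per_gene <- if (mt_pct[j] > 0) 100L - as.integer(mt_pct[j]) else 1L
    m[n_mito + seq_len(n_nm), j] <- per_gene
    if (mt_pct[j] > 0) {
      m[1L, j] <- as.integer(mt_pct[j]) * n_nm  # pct = mt/(mt+nm) exact
    }
  }
  car_counts(m)
}

default_propensity_for_test <- function(n_variants, n_clusters, cic) {
  carforge:::default_propensity(n_variants, n_clusters, cic)
}

# Brute-force pair-counting ARI oracle: iterates over all C(n,2) cell pairs.
ari_oracle <- function(p1, p2) {
  n <- length(p1)
  n11 <- n00 <- n10 <- n01 <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      same1 <- p1[i] == p1[j]
      same2 <- p2[i] == p2[j]
      if (same1 && same2) n11 <- n11 + 1
      else if (!same1 && !same2) n00 <- n00 + 1
      else if (same1) n10 <- n10 + 1
      else n01 <- n01 + 1
    }
  }
  total <- n11 + n00 + n10 + n01
  expected <- (n11 + n10) * (n11 + n01) / total
  max_idx <- ((n11 + n10) + (n11 + n01)) / 2
  if (max_idx == expected) return(1)
  (n11 - expected) / (max_idx - expected)
}

# Left-greedy regex oracle for the ITAM motif (independent of the scanner's
# manual loop): lazy spacer quantifier + gregexpr gives left-greedy,
# non-overlapping, shortest-spacer matches.
itam_regex_oracle <- function(aa, smin = 6, smax = 12) {
  pat <- sprintf("Y[A-Z]{2}[LI][A-Z]{%d,%d}?Y[A-Z]{2}[LI]", smin, smax)
  m <- gregexpr(pat, aa, perl = TRUE)[[1]]
  if (m[1] == -1) 0L else length(m)
}
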