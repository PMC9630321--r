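# Simulation of barcoded long-read CAR amplicons (scCAR-seq) and plasmid-level
# library amplicons. Read layout, 5'->3' from the barcode end:
#   adapter | cell barcode | UMI | upstream constant tail | domain A | linker |
#   domain B | downstream anchor
# The upstream tail is the last 20 nt of the chassis upstream constant region
# and the anchor the first 24 nt of the downstream (Strep-tag-proximal)
# constant region, so the variable region between them is exactly
# domainA + linker + domainB.

SCCAR_ADAPTER <- "CTACACGACGCTCTTCCGATCT"  # Illumina TruSeq Read 1

sccar_flanks <- function(chassis, tail_len = 20L, anchor_len = 24L) {
  u <- chassis$upstream_const
  list(adapter = SCCAR_ADAPTER,
       const5 = substring(u, nchar(u) - tail_len + 1L, nchar(u)),
       anchor = substring(chassis$downstream_const, 1L, anchor_len),
       linker = chassis$linker)
}

#' Configuration for the scCAR-seq read simulator
#'
#' Defaults model a 10X Chromium v3 run (16-nt cell barcodes, 12-nt UMIs)
#' sequenced by a long-read instrument: each cell emits at least one read,
#' with a negative-binomial number of CAR molecules per cell, a small
#' fraction of cells carrying two distinct CAR integrations, per-base
#' substitution/insertion/deletion errors, and reads emitted in either
#' orientation (50/50).
#'
#' @param n_cells Number of simulated cells.
#' @param whitelist_size Size of the barcode whitelist (>= `n_cells`).
#' @param barcode_len,umi_len Barcode and UMI lengths in nt.
#' @param reads_per_cell_mean,reads_per_cell_dispersion Negative-binomial
#'   mean and dispersion (size = 1/dispersion) of molecules per cell;
#'   truncated below at 1.
#' @param variant_abundance Per-variant probability vector (sums to 1);
#'   `NULL` for uniform.
#' @param multi_car_fraction Fraction of cells carrying two distinct
#'   variants.
#' @param sub_rate,ins_rate,del_rate Per-base error probabilities.
#' @param revcomp_fraction Fraction of reads emitted reverse-complemented.
#' @param seed Integer seed.
#' @return Object of class `read_sim_config`.
#' @export
read_sim_config <- function(n_cells = 2000L, whitelist_size = 3000L,
                            barcode_len = 16L, umi_len = 12L,
                            reads_per_cell_mean = 10,
                            reads_per_cell_dispersion = 0.5,
                            variant_abundance = NULL,
                            multi_car_fraction = 0.04,
                            sub_rate = 0.02, ins_rate = 0, del_rate = 0,
                            revcomp_fraction = 0.5, seed = 1L) {
  stopifnot(n_cells >= 1L, whitelist_size >= n_cells,
            barcode_len >= 4L, umi_len >= 4L,
            reads_per_cell_mean > 0)
  for (p in c(multi_car_fraction, sub_rate, ins_rate, del_rate,
              revcomp_fraction)) {
    if (p < 0 || p > 1) stop("probabilities must lie in [0, 1]")
  }
  if (!is.null(variant_abundance)) {
    if (any(variant_abundance < 0) ||
        abs(sum(variant_abundance) - 1) > 1e-8) {
      stop("variant_abundance must be non-negative and sum to 1")
    }
  }
  structure(as.list(environment()), class = "read_sim_config")
}

# Inject per-base substitution/insertion/deletion errors into one sequence.
inject_errors <- function(seq, sub_rate, ins_rate, del_rate) {
  if (sub_rate == 0 && ins_rate == 0 && del_rate == 0) return(seq)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  n <- length(chars)
  sub_at <- runif(n) < sub_rate
  if (any(sub_at)) {
    chars[sub_at] <- vapply(chars[sub_at], function(b)
      sample(setdiff(DNA_BASES, b), 1L), "")
  }
  if (del_rate > 0) {
    keep <- runif(length(chars)) >= del_rate
    chars <- chars[keep]
  }
  if (ins_rate > 0) {
    ins_at <- which(runif(length(chars)) < ins_rate)
    if (length(ins_at) > 0L) {
      for (i in rev(ins_at)) {
        chars <- append(chars, sample(DNA_BASES, 1L), after = i)
      }
    }
  }
  paste(chars, collapse = "")
}

random_barcodes <- function(n, len) {
  out <- character(0)
  while (length(out) < n) {
    new <- vapply(seq_len(n - length(out)), function(i) random_dna(len), "")
    out <- unique(c(out, new))
  }
  out[seq_len(n)]
}

#' Simulate barcoded scCAR-seq long reads
#'
#' Emits one read per CAR cDNA molecule with the layout described above,
#' injecting sequencing errors and orientation flips, together with a
#' per-cell truth table.
#'
#' @param library A `car_library` from [enumerate_library()].
#' @param chassis The [car_chassis()] the library was assembled on.
#' @param cfg A [read_sim_config()].
#' @param fastq_path Optional path; when given the reads are also written as
#'   FASTQ (constant Q20 qualities) and the whitelist alongside as
#'   `<fastq_path>.whitelist.txt`.
#' @return `list(reads, truth, whitelist)`: `reads` is a data.frame
#'   (`id`, `seq`, `qual`), `truth` one row per cell (`barcode`, `variant`,
#'   `variant2` (NA unless multi-CAR), `multi`, `n_reads`).
#' @export
simulate_sccar_reads <- function(library, chassis, cfg,
                                 fastq_path = NULL) {
  stopifnot(length(library) >= 1L, inherits(cfg, "read_sim_config"))
  labels <- vapply(library, `[[`, "", "label")
  abund <- cfg$variant_abundance %||% rep(1 / length(labels), length(labels))
  if (length(abund) != length(labels)) {
    stop("variant_abundance length (", length(abund),
         ") does not match library size (", length(labels), ")")
  }
  fl <- sccar_flanks(chassis)
  inserts <- vapply(library, function(v)
    paste0(v$domain_a$nt_seq, chassis$linker, v$domain_b$nt_seq), "")
  with_seed(cfg$seed, {
    whitelist <- random_barcodes(cfg$whitelist_size, cfg$barcode_len)
    cell_bc <- sample(whitelist, cfg$n_cells)
    v1 <- sample(seq_along(labels), cfg$n_cells, replace = TRUE, prob = abund)
    multi <- runif(cfg$n_cells) < cfg$multi_car_fraction
    if (length(labels) == 1L) multi[] <- FALSE
    v2 <- rep(NA_integer_, cfg$n_cells)
    if (any(multi)) {
      v2[multi] <- vapply(v1[multi], function(i)
        sample(seq_along(labels)[-i], 1L), 0L)
    }
    n_reads <- pmax(1L, rnbinom(cfg$n_cells, mu = cfg$reads_per_cell_mean,
                                size = 1 / cfg$reads_per_cell_dispersion))
    cell_of_read <- rep.int(seq_len(cfg$n_cells), n_reads)
    total <- length(cell_of_read)
    # molecule-level variant choice: multi-CAR cells emit from both variants
    take2 <- multi[cell_of_read] & runif(total) < 0.5
    vid <- ifelse(take2, v2[cell_of_read], v1[cell_of_read])
    umis <- vapply(seq_len(total), function(i) random_dna(cfg$umi_len), "")
    templ <- paste0(fl$adapter, cell_bc[cell_of_read], umis, fl$const5,
                    inserts[vid], fl$anchor)
    seqs <- vapply(templ, inject_errors, "", sub_rate = cfg$sub_rate,
                   ins_rate = cfg$ins_rate, del_rate = cfg$del_rate,
                   USE.NAMES = FALSE)
    flip <- runif(total) < cfg$revcomp_fraction
    if (any(flip)) seqs[flip] <- revcomp(seqs[flip])
    reads <- data.frame(id = sprintf("read_%06d", seq_len(total)),
                        seq = seqs,
                        qual = strrep("5", nchar(seqs)))
    truth <- data.frame(barcode = cell_bc,
                        variant = labels[v1],
                        variant2 = ifelse(multi, labels[v2], NA_character_),
                        multi = multi,
                        n_reads = n_reads)
    if (!is.null(fastq_path)) {
      write_fastq(reads, fastq_path)
      writeLines(whitelist, paste0(fastq_path, ".whitelist.txt"))
    }
    list(reads = reads, truth = truth, whitelist = whitelist)
  })
}

#' Simulate plasmid-level library amplicons (no cell barcodes)
#'
#' Models long-read sequencing of the pooled plasmid library after cloning:
#' abundance-weighted amplicon reads spanning the variable region with its
#' constant flanks, with optional per-base errors and orientation flips.
#'
#' @inheritParams simulate_sccar_reads
#' @param abundance Per-variant probability vector (`NULL` for uniform; set
#'   entries to zero to emulate dropout of combinations).
#' @param n_reads Number of reads (>= 1).
#' @param sub_rate,ins_rate,del_rate Per-base error probabilities.
#' @param revcomp_fraction Fraction of reverse-complemented reads.
#' @param seed Integer seed.
#' @param fasta_path Optional output FASTA path.
#' @return `list(reads, truth)`: `reads` data.frame (`id`, `seq`), `truth`
#'   the per-read variant label.
#' @export
simulate_plasmid_reads <- function(library, chassis, abundance = NULL,
                                   n_reads = 10000L, sub_rate = 0,
                                   ins_rate = 0, del_rate = 0,
                                   revcomp_fraction = 0.5, seed = 1L,
                                   fasta_path = NULL) {
  if (n_reads < 1L) stop("n_reads must be >= 1")
  labels <- vapply(library, `[[`, "", "label")
  abund <- abundance %||% rep(1 / length(labels), length(labels))
  if (length(abund) != length(labels)) {
    stop("abundance length does not match library size")
  }
  abund <- abund / sum(abund)
  fl <- sccar_flanks(chassis)
  inserts <- vapply(library, function(v)
    paste0(v$domain_a$nt_seq, chassis$linker, v$domain_b$nt_seq), "")
  with_seed(seed, {
    vid <- sample(seq_along(labels), n_reads, replace = TRUE, prob = abund)
    templ <- paste0(fl$const5, inserts[vid], fl$anchor)
    seqs <- vapply(templ, inject_errors, "", sub_rate = sub_rate,
                   ins_rate = ins_rate, del_rate = del_rate,
                   USE.NAMES = FALSE)
    flip <- runif(n_reads) < revcomp_fraction
    if (any(flip)) seqs[flip] <- revcomp(seqs[flip])
    reads <- data.frame(id = sprintf("amp_%06d", seq_len(n_reads)),
                        seq = seqs)
    if (!is.null(fasta_path)) {
      write_fasta(setNames(reads$seq, reads$id), fasta_path)
    }
    list(reads = reads, truth = labels[vid])
  })
}
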