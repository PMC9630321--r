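#' Construct a signaling-domain record
#'
#' A signaling domain is an in-frame intracellular gene segment belonging to
#' pool A (co-stimulatory, no ITAM), pool B (single-ITAM) or the constant
#' chassis (the truncated CD3-zeta two-ITAM segment). The constructor
#' validates frame, translation, absence of internal stop codons, and that
#' the scanned ITAM count matches the pool's expectation.
#'
#' @param id Short label, e.g. `"CD28"` or `"FCGR2A"`.
#' @param pool One of `"A"`, `"B"`, `"CONST"`.
#' @param nt_seq In-frame DNA sequence (length divisible by 3, no stop).
#' @param oh5,oh3 Optional 4-nt flank overhangs carried by the domain's
#'   digested cloning fragment; checked against the chassis at assembly.
#' @param spacer_min,spacer_max ITAM spacer bounds passed to [itam_scan()].
#' @return An object of class `signaling_domain` with fields `id`, `pool`,
#'   `nt_seq`, `aa_seq`, `itam_count`, `oh5`, `oh3`.
#' @export
signaling_domain <- function(id, pool, nt_seq, oh5 = NULL, oh3 = NULL,
                             spacer_min = 6L, spacer_max = 12L) {
  pool <- match.arg(pool, c("A", "B", "CONST"))
  nt_seq <- toupper(nt_seq)
  stopifnot(grepl("^[ACGT]+$", nt_seq))
  if (nchar(nt_seq) %% 3L != 0L) {
    stop("frameshift: domain ", id, " length ", nchar(nt_seq),
         " not divisible by 3")
  }
  aa <- translate_dna(nt_seq)
  if (grepl("*", aa, fixed = TRUE)) {
    stop("internal stop codon in domain ", id)
  }
  n_itam <- itam_count(aa, spacer_min, spacer_max)
  expected <- c(A = 0L, B = 1L, CONST = 2L)[[pool]]
  if (n_itam != expected) {
    stop("domain ", id, " (pool ", pool, ") has ", n_itam,
         " ITAM(s); expected ", expected)
  }
  structure(list(id = id, pool = pool, nt_seq = nt_seq, aa_seq = aa,
                 itam_count = n_itam, oh5 = oh5, oh3 = oh3),
            class = "signaling_domain")
}

#' Construct a CAR chassis with a Type IIS cloning cassette
#'
#' The chassis is the constant part of every CAR variant: an upstream
#' constant region (signal peptide, scFv, tags, hinge/transmembrane — here
#' any in-frame ORF prefix starting with ATG), a cloning cassette carrying
#' two outward-facing recognition sites of a Type IIS enzyme around a
#' stuffer, a minimal linker joining the two variable domains, and a
#' downstream constant region (the truncated CD3-zeta segment bearing two
#' ITAMs, ending in a stop codon).
#'
#' Digestion of the chassis excises the stuffer together with both
#' recognition sites and exposes two distinct 4-nt overhangs: the last
#' `overhang_len` bases of the upstream region (the A-side junction) and the
#' first bases of the downstream region (the B-side junction). The first
#' bases of the linker form the middle A/B junction, so ligation of one
#' pool-A and one pool-B fragment reconstitutes, in order,
#' `upstream + domainA + linker + domainB + downstream`.
#'
#' @param upstream_const In-frame DNA starting with ATG; its last
#'   `overhang_len` nt are the A-side overhang.
#' @param linker Linker DNA (length divisible by 3 and >= overhang length);
#'   its first `overhang_len` nt are the A/B junction overhang.
#' @param downstream_const In-frame DNA ending with a single stop codon,
#'   containing exactly two ITAMs; its first `overhang_len` nt are the B-side
#'   overhang.
#' @param stuffer Throw-away DNA between the two recognition sites.
#' @param enzyme An [enzyme_def()]; default [aarI()].
#' @param spacer_min,spacer_max ITAM spacer bounds.
#' @return Object of class `car_chassis` with the cassette assembled and the
#'   three junction overhangs exposed as `oh_left`, `oh_mid`, `oh_right`.
#' @export
car_chassis <- function(upstream_const, linker, downstream_const,
                        stuffer = "GCTTACGGATTCACGTTAGC", enzyme = aarI(),
                        spacer_min = 6L, spacer_max = 12L) {
  upstream_const <- toupper(upstream_const)
  linker <- toupper(linker)
  downstream_const <- toupper(downstream_const)
  ov <- enzyme$overhang_len
  stopifnot(nchar(upstream_const) %% 3L == 0L,
            nchar(linker) %% 3L == 0L,
            nchar(downstream_const) %% 3L == 0L,
            nchar(linker) >= ov,
            startsWith(upstream_const, "ATG"))
  up_aa <- translate_dna(upstream_const)
  if (grepl("*", up_aa, fixed = TRUE)) stop("stop codon in upstream_const")
  down_aa <- translate_dna(downstream_const)
  if (!grepl("\\*$", down_aa) || lengths(regmatches(down_aa, gregexpr("\\*", down_aa))) != 1L) {
    stop("downstream_const must end with exactly one stop codon")
  }
  n_itam <- itam_count(sub("\\*$", "", down_aa), spacer_min, spacer_max)
  if (n_itam != 2L) {
    stop("downstream constant (tCD3Z segment) must carry exactly 2 ITAMs, found ",
         n_itam)
  }
  oh_left <- substring(upstream_const,
                       nchar(upstream_const) - ov + 1L, nchar(upstream_const))
  oh_mid <- substring(linker, 1L, ov)
  oh_right <- substring(downstream_const, 1L, ov)
  ohs <- c(oh_left, oh_mid, oh_right)
  if (anyDuplicated(ohs) || any(outer(ohs, revcomp(ohs), "=="))) {
    stop("junction overhangs must be pairwise distinct and non-complementary")
  }
  # Outward-facing sites: a bottom-strand site cutting back into the upstream
  # junction and a top-strand site cutting forward into the downstream one.
  spacer <- strrep("A", enzyme$cut_offset_top)
  cassette <- paste0(spacer, revcomp(enzyme$recognition), stuffer,
                     enzyme$recognition, spacer)
  vec <- paste0(upstream_const, cassette, downstream_const)
  cuts <- typeIIs_cuts(vec, enzyme)
  if (nrow(cuts) != 2L) {
    stop("chassis must contain exactly two recognition sites; found ",
         nrow(cuts), " (check constant regions for internal sites)")
  }
  if (!identical(sort(cuts$overhang), sort(c(oh_left, oh_right)))) {
    stop("cassette cut overhangs do not match the designed junctions")
  }
  structure(list(upstream_const = upstream_const, cassette = cassette,
                 downstream_const = downstream_const, linker = linker,
                 enzyme = enzyme, oh_left = oh_left, oh_mid = oh_mid,
                 oh_right = oh_right, spacer_min = as.integer(spacer_min),
                 spacer_max = as.integer(spacer_max)),
            class = "car_chassis")
}

# PCR-template pads flanking pool fragments; free of AarI-class sites.
TEMPLATE_PAD <- "GTCAGTCAGTCA"

#' Build the cloning PCR template for a domain (pool A or B)
#'
#' Pool fragments are amplified with flanks that place a recognition site on
#' each side facing inward, so that digestion releases the insert with the
#' chassis-compatible overhangs: pool-A inserts are released as
#' `oh_left + domain`, exposing the linker junction, and pool-B inserts as
#' `linker + domain`, exposing the downstream junction.
#'
#' @param domain A [signaling_domain()].
#' @param chassis A [car_chassis()].
#' @return DNA string of the template.
#' @export
domain_template <- function(domain, chassis) {
  enz <- chassis$enzyme
  spacer <- strrep("A", enz$cut_offset_top)
  core <- switch(domain$pool,
    A = paste0(chassis$oh_left, domain$nt_seq, chassis$oh_mid),
    B = paste0(chassis$linker, domain$nt_seq, chassis$oh_right),
    stop("templates are built for pool A or B domains only"))
  paste0(TEMPLATE_PAD, enz$recognition, spacer, core, spacer,
         revcomp(enz$recognition), TEMPLATE_PAD)
}

#' Assemble one CAR variant from a pool-A and a pool-B domain
#'
#' Performs the overhang-directed four-part ligation (upstream vector arm,
#' pool-A insert, linker+pool-B insert, downstream vector arm) and validates
#' the product: in frame, one terminal stop codon, and a total of exactly
#' three ITAMs (none from pool A, one from pool B, two from the retained
#' truncated CD3-zeta segment).
#'
#' @param chassis A [car_chassis()].
#' @param da Pool-A [signaling_domain()].
#' @param db Pool-B [signaling_domain()].
#' @return Object of class `car_variant`: `label` (`"A-B"`), `domain_a`,
#'   `domain_b`, `orf_nt`, `orf_aa`, `total_itams`.
#' @export
assemble_variant <- function(chassis, da, db) {
  stopifnot(inherits(chassis, "car_chassis"))
  if (!identical(da$pool, "A")) {
    stop("precondition: first domain must be from pool A (got pool ",
         da$pool, " for ", da$id, ")")
  }
  if (!identical(db$pool, "B")) {
    stop("precondition: second domain must be from pool B (got pool ",
         db$pool, " for ", db$id, ")")
  }
  chk <- function(d, oh5, oh3) {
    if ((!is.null(d$oh5) && d$oh5 != oh5) || (!is.null(d$oh3) && d$oh3 != oh3)) {
      stop("assembly error: overhang mismatch for domain ", d$id)
    }
  }
  chk(da, chassis$oh_left, chassis$oh_mid)
  chk(db, chassis$oh_mid, chassis$oh_right)
  for (d in list(da, db)) {
    if (nchar(d$nt_seq) %% 3L != 0L) {
      stop("frameshift: domain ", d$id, " is not a multiple of 3 nt")
    }
    if (grepl("*", translate_dna(d$nt_seq), fixed = TRUE)) {
      stop("internal stop codon in domain ", d$id)
    }
  }
  u <- chassis$upstream_const
  ov <- nchar(chassis$oh_left)
  frags <- list(
    list(seq = substring(u, 1L, nchar(u) - ov), oh5 = "",
         oh3 = chassis$oh_left),
    list(seq = paste0(chassis$oh_left, da$nt_seq), oh5 = chassis$oh_left,
         oh3 = chassis$oh_mid),
    list(seq = paste0(chassis$linker, db$nt_seq), oh5 = chassis$oh_mid,
         oh3 = chassis$oh_right),
    list(seq = chassis$downstream_const, oh5 = chassis$oh_right, oh3 = "")
  )
  orf <- ligate_fragments(frags, first = 1L)$seq
  if (nchar(orf) %% 3L != 0L) stop("assembled ORF out of frame")
  aa <- translate_dna(orf)
  stops <- gregexpr("*", aa, fixed = TRUE)[[1]]
  if (length(stops) != 1L || stops[1] != nchar(aa)) {
    stop("validation error: internal stop codon in assembled ORF of ",
         da$id, "-", db$id)
  }
  total <- itam_count(sub("\\*$", "", aa), chassis$spacer_min,
                      chassis$spacer_max)
  if (total != 3L) {
    stop("validation error: variant ", da$id, "-", db$id, " carries ", total,
         " ITAMs; the design conserves exactly 3")
  }
  structure(list(label = paste0(da$id, "-", db$id), domain_a = da,
                 domain_b = db, orf_nt = orf, orf_aa = aa,
                 total_itams = total),
            class = "car_variant")
}

#' Enumerate the full shuffled library
#'
#' Assembles every (pool A, pool B) combination, pool-A index major, pool-B
#' index minor, validating each variant. With the study's 15 pool-A and 12
#' pool-B domains this yields the 180-variant library.
#'
#' @param poolA,poolB Lists of [signaling_domain()] objects with unique ids.
#' @param chassis A [car_chassis()].
#' @return List of `car_variant` objects of length `|A| * |B|`, with class
#'   `car_library`.
#' @export
enumerate_library <- function(poolA, poolB, chassis) {
  stopifnot(length(poolA) >= 1L, length(poolB) >= 1L)
  ids_a <- vapply(poolA, `[[`, "", "id")
  ids_b <- vapply(poolB, `[[`, "", "id")
  if (anyDuplicated(ids_a) || anyDuplicated(ids_b)) {
    stop("duplicate domain ids within a pool")
  }
  out <- vector("list", length(poolA) * length(poolB))
  k <- 1L
  for (da in poolA) {
    for (db in poolB) {
      out[[k]] <- assemble_variant(chassis, da, db)
      k <- k + 1L
    }
  }
  labels <- vapply(out, `[[`, "", "label")
  if (anyDuplicated(labels)) stop("duplicate variant labels in library")
  structure(out, class = "car_library")
}

#' Tabulate a library as a manifest data.frame
#' @param variants A `car_library` or list of `car_variant`s.
#' @return data.frame with label, domain ids, ORF length and ITAM count.
#' @export
variant_manifest <- function(variants) {
  data.frame(
    label = vapply(variants, `[[`, "", "label"),
    domain_a = vapply(variants, function(v) v$domain_a$id, ""),
    domain_b = vapply(variants, function(v) v$domain_b$id, ""),
    orf_length = vapply(variants, function(v) nchar(v$orf_nt), 0L),
    itam_count = vapply(variants, function(v) v$total_itams, 0L)
  )
}

#' Write library ORFs to FASTA
#'
#' One record per variant, header = variant label. Re-reading with
#' [read_fasta()] reproduces the sequences exactly.
#' @param variants A `car_library` or list of `car_variant`s.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_library_fasta <- function(variants, path) {
  if (length(variants) == 0L) stop("empty variant list")
  seqs <- Biostrings::DNAStringSet(vapply(variants, `[[`, "", "orf_nt"))
  names(seqs) <- vapply(variants, `[[`, "", "label")
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}
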