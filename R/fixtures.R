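# Seeded fixture generators. The real domain and chassis nucleotide sequences
# of the study library are not public, so the generators build stand-in pools
# that satisfy every structural constraint of the design: pool-A domains carry
# no ITAM, pool-B domains exactly one, the retained truncated CD3-zeta chassis
# segment exactly two, all segments are in frame and free of internal stops,
# and no sequence or junction contains a stray Type IIS recognition site that
# would break digestion/ligation.

AA_NO_Y <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N",
             "P", "Q", "R", "S", "T", "V", "W")  # all standard aa but Y

POOL_A_NAMES <- c("CD28", "CD137", "ICOS", "CD27", "OX40", "CD30", "CD150",
                  "CD84", "CD2", "CD226", "FCRL6", "CD244", "LAG3", "TIM1",
                  "CD357")
POOL_B_NAMES <- c("FCGR2A", "DAP12", "CD79B", "CD79A", "CD3G", "CD3D", "CD3E",
                  "FCER1G", "LMP2", "K1", "GP", "CD3Z1")

# Random background amino acids containing no tyrosine (hence no ITAM).
aa_background <- function(n) paste(sample(AA_NO_Y, n, TRUE), collapse = "")

# One canonical ITAM: Yxx[LI] x7 Yxx[LI] (15 aa), tyrosine-free elsewhere.
plant_itam <- function() {
  paste0("Y", aa_background(2), sample(c("L", "I"), 1),
         aa_background(7),
         "Y", aa_background(2), sample(c("L", "I"), 1))
}

# Reverse-translate with random synonymous codons (seeded by the caller).
reverse_translate <- function(aa) {
  codons <- split(names(Biostrings::GENETIC_CODE),
                  unname(Biostrings::GENETIC_CODE))
  chars <- strsplit(aa, "", fixed = TRUE)[[1]]
  paste(vapply(chars, function(a) {
    opts <- codons[[a]]
    if (length(opts) == 1L) opts else sample(opts, 1L)
  }, ""), collapse = "")
}

contains_site <- function(x, enzyme) {
  grepl(enzyme$recognition, x, fixed = TRUE) |
    grepl(revcomp(enzyme$recognition), x, fixed = TRUE)
}

#' Generate seeded fixture domain pools and a chassis
#'
#' Builds `nA` pool-A domains (ITAM-free co-stimulatory segments), `nB`
#' pool-B domains (single planted ITAM each) and a chassis whose downstream
#' constant region is a two-ITAM truncated CD3-zeta stand-in, all
#' deterministic under `seed`. Every domain is validated through
#' [signaling_domain()] and its cloning template through [typeIIs_digest()];
#' junctions of every (A,B) pair are additionally screened so that the full
#' library digests and re-ligates cleanly.
#'
#' With the study's pool sizes (`nA = 15`, `nB = 12`) enumeration yields the
#' 180-variant library. Domain ids are `A1..AnA` / `B1..BnB`, or receptor-style
#' names for the first 15/12 when `named = TRUE`.
#'
#' @param nA,nB Pool sizes (>= 1).
#' @param seed Integer seed.
#' @param enzyme Type IIS enzyme definition, default [aarI()].
#' @param linker Minimal linker DNA joining domain A to domain B (in frame,
#'   default 6 nt encoding Gly-Ser).
#' @param named Use receptor-style domain names where available.
#' @param aa_len_range Range of domain lengths in amino acids.
#' @return `list(poolA, poolB, chassis)`.
#' @export
make_fixture_pools <- function(nA = 15L, nB = 12L, seed = 7L,
                               enzyme = aarI(), linker = "GGATCC",
                               named = FALSE, aa_len_range = c(30L, 60L)) {
  stopifnot(nA >= 1L, nB >= 1L)
  with_seed(seed, {
    chassis <- local({
      repeat {
        up <- paste0("ATG", reverse_translate(aa_background(29L)))
        down_aa <- paste0(aa_background(5L), plant_itam(), aa_background(6L),
                          plant_itam(), aa_background(24L))
        down <- paste0(reverse_translate(down_aa), "TAA")
        if (contains_site(up, enzyme) || contains_site(down, enzyme) ||
            contains_site(linker, enzyme)) next
        ch <- tryCatch(
          car_chassis(up, linker, down, enzyme = enzyme),
          error = function(e) NULL)
        if (!is.null(ch)) break
      }
      ch
    })
    gen_domain <- function(pool, id) {
      repeat {
        len <- sample(aa_len_range[1]:aa_len_range[2], 1L)
        aa <- if (pool == "A") {
          aa_background(len)
        } else {
          left <- sample(3L:(len - 18L), 1L)
          paste0(aa_background(left), plant_itam(),
                 aa_background(len - left - 15L))
        }
        nt <- reverse_translate(aa)
        d <- tryCatch({
          oh <- if (pool == "A") c(chassis$oh_left, chassis$oh_mid) else
            c(chassis$oh_mid, chassis$oh_right)
          signaling_domain(id, pool, nt, oh5 = oh[1], oh3 = oh[2])
        }, error = function(e) NULL)
        if (is.null(d)) next
        tmpl <- domain_template(d, chassis)
        if (nrow(typeIIs_cuts(tmpl, enzyme)) != 2L) next
        return(d)
      }
    }
    ids_a <- if (named) c(POOL_A_NAMES, paste0("A", seq_len(max(0, nA - 15L)) + 15L))[seq_len(nA)]
      else paste0("A", seq_len(nA))
    ids_b <- if (named) c(POOL_B_NAMES, paste0("B", seq_len(max(0, nB - 12L)) + 12L))[seq_len(nB)]
      else paste0("B", seq_len(nB))
    poolA <- lapply(ids_a, function(id) gen_domain("A", id))
    poolB <- lapply(ids_b, function(id) gen_domain("B", id))
    # No recognition site may arise across any A|linker|B junction, or the
    # re-amplified variants would not digest cleanly.
    repeat {
      tails <- vapply(poolA, function(d)
        substr(d$nt_seq, max(1L, nchar(d$nt_seq) - 5L), nchar(d$nt_seq)), "")
      heads <- vapply(poolB, function(d) substr(d$nt_seq, 1L, 6L), "")
      centers <- outer(tails, heads, function(t, h)
        paste0(t, chassis$linker, h))
      bad <- which(matrix(contains_site(centers, enzyme), nrow = length(poolA)),
                   arr.ind = TRUE)
      if (nrow(bad) == 0L) break
      for (j in unique(bad[, 2])) {
        poolB[[j]] <- gen_domain("B", ids_b[j])
      }
    }
    list(poolA = poolA, poolB = poolB, chassis = chassis)
  })
}

#' Re-amplify a variant's insert with cassette flanks
#'
#' Models PCR re-amplification of an assembled variant's variable region with
#' primers that restore the two inward-facing recognition sites, so that
#' digestion releases the combined insert
#' `oh_left + domainA + linker + domainB` exactly — the round-trip identity
#' used to validate the library design.
#' @param variant A `car_variant`.
#' @param chassis The [car_chassis()] it was assembled on.
#' @return DNA string of the flanked amplicon.
#' @export
reamplify_insert <- function(variant, chassis) {
  enz <- chassis$enzyme
  spacer <- strrep("A", enz$cut_offset_top)
  paste0(TEMPLATE_PAD, enz$recognition, spacer,
         chassis$oh_left, variant$domain_a$nt_seq, chassis$linker,
         variant$domain_b$nt_seq, chassis$oh_right,
         spacer, revcomp(enz$recognition), TEMPLATE_PAD)
}
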