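# scCAR-seq demultiplexing: orientation resolution, barcode correction,
# anchor location, domain calling by best-identity alignment against the
# pool references, UMI collapse and per-cell variant assignment.

#' Match a read's barcode window against a whitelist
#'
#' Returns the unique whitelist barcode within Hamming distance
#' `max_mismatch` of the first `nchar(whitelist[1])` bases of `read_prefix`;
#' `NA` when no candidate or more than one candidate exists (the 10X
#' unique-neighbour convention).
#'
#' @param read_prefix Read sequence starting at the barcode.
#' @param whitelist Character vector of equal-length barcodes.
#' @param max_mismatch Maximum Hamming distance (default 1).
#' @return The corrected barcode, or `NA_character_`.
#' @export
match_barcode <- function(read_prefix, whitelist, max_mismatch = 1L) {
  if (length(whitelist) == 0L) stop("whitelist must be non-empty")
  blen <- unique(nchar(whitelist))
  if (length(blen) != 1L) stop("whitelist barcodes have mixed lengths")
  obs <- substr(read_prefix, 1L, blen)
  if (nchar(obs) < blen) return(NA_character_)
  if (obs %in% whitelist) return(obs)
  if (max_mismatch < 1L) return(NA_character_)
  ham <- hamming_to_all(obs, whitelist)
  hits <- whitelist[ham <= max_mismatch]
  if (length(hits) == 1L) hits else NA_character_
}

hamming_to_all <- function(obs, whitelist) {
  oc <- utf8ToInt(obs)
  m <- vapply(whitelist, function(w) sum(utf8ToInt(w) != oc), 0L)
  unname(m)
}

# Batch barcode correction: exact hash first, then unique-neighbour lookup of
# all single-mismatch variants (max_mismatch 0 or 1; larger values fall back
# to a full Hamming scan per read).
correct_barcodes <- function(observed, whitelist, max_mismatch = 1L) {
  blen <- unique(nchar(whitelist))
  if (length(blen) != 1L) stop("whitelist barcodes have mixed lengths")
  out <- whitelist[match(observed, whitelist)]
  todo <- which(is.na(out) & nchar(observed) == blen)
  if (max_mismatch >= 1L && length(todo) > 0L) {
    for (i in todo) {
      if (max_mismatch == 1L) {
        obs <- observed[i]
        neigh <- character(3L * blen)
        k <- 0L
        for (p in seq_len(blen)) {
          b <- substr(obs, p, p)
          for (alt in setdiff(DNA_BASES, b)) {
            k <- k + 1L
            neigh[k] <- paste0(substr(obs, 1L, p - 1L), alt,
                               substr(obs, p + 1L, blen))
          }
        }
        hits <- unique(neigh[neigh %in% whitelist])
        if (length(hits) == 1L) out[i] <- hits
      } else {
        out[i] <- match_barcode(observed[i], whitelist, max_mismatch)
      }
    }
  }
  out
}

# Locate the first occurrence of `pattern` in every sequence of `sset`:
# vectorized mismatch-only scan first, then a per-read scan allowing indels
# for the sequences it missed. Returns an n x 2 matrix (start, end), NA rows
# when not found.
locate_first_batch <- function(pattern, sset, max_mismatch) {
  n <- length(sset)
  out <- matrix(NA_integer_, nrow = n, ncol = 2L)
  mi <- Biostrings::vmatchPattern(pattern, sset, max.mismatch = max_mismatch)
  st <- Biostrings::startIndex(mi)
  en <- Biostrings::endIndex(mi)
  hit <- lengths(st) > 0L
  out[hit, 1L] <- vapply(st[hit], `[[`, 0L, 1L)
  out[hit, 2L] <- vapply(en[hit], `[[`, 0L, 1L)
  for (i in which(!hit)) {
    m <- Biostrings::matchPattern(pattern, sset[[i]],
                                  max.mismatch = max_mismatch,
                                  with.indels = TRUE)
    if (length(m) > 0L) {
      out[i, ] <- c(Biostrings::start(m)[1], Biostrings::end(m)[1])
    }
  }
  out
}

# k-mer index of a reference pool: unique k-mers mapped to the single
# reference containing them (k-mers shared between references are dropped).
kmer_index <- function(refs_chr, k = 11L) {
  kmers <- lapply(refs_chr, function(r) {
    L <- nchar(r)
    if (L < k) character(0) else unique(substring(r, 1:(L - k + 1L), k:L))
  })
  kv <- unlist(kmers, use.names = FALSE)
  rid <- rep.int(seq_along(refs_chr), lengths(kmers))
  dup <- kv %in% kv[duplicated(kv)]
  list(kmers = kv[!dup], ref = rid[!dup], k = k)
}

# Top-2 candidate references per region by shared-k-mer count.
kmer_top2 <- function(regions, index, n_refs) {
  t(vapply(regions, function(reg) {
    if (is.na(reg) || nchar(reg) < index$k) return(c(1L, min(2L, n_refs)))
    L <- nchar(reg)
    rk <- substring(reg, 1:(L - index$k + 1L), index$k:L)
    cnt <- tabulate(index$ref[match(rk, index$kmers)], nbins = n_refs)
    ord <- order(cnt, decreasing = TRUE)
    c(ord[1], if (n_refs > 1L) ord[2] else ord[1])
  }, integer(2), USE.NAMES = FALSE))
}

#' Call the CAR variant of each read
#'
#' For every read: resolve orientation (the reverse complement is tried when
#' the downstream anchor is not found on the forward strand), locate the
#' adapter and extract/correct the cell barcode and UMI (skipped for
#' barcode-free plasmid amplicons), extract the variable region between the
#' upstream constant tail and the downstream anchor, and call domain A and
#' domain B by best-identity alignment against their pools. A call is
#' `ambiguous_domain` when the two best identities are closer than
#' `tie_margin`, and below `min_identity` the domain is left uncalled.
#'
#' @param reads data.frame with `id` and `seq` (e.g. from [read_fastq()] or
#'   the simulators).
#' @param poolA,poolB Lists of [signaling_domain()] objects (the references).
#' @param chassis The [car_chassis()] (provides flank sequences).
#' @param whitelist Barcode whitelist; `NULL` for barcode-free amplicons.
#' @param max_mismatch Barcode Hamming tolerance (default 1).
#' @param min_identity Minimum alignment identity per domain (default 0.85).
#' @param tie_margin Minimum identity gap between the two best references
#'   (default 0.02).
#' @param umi_len UMI length in nt (default 12, 10X v3).
#' @return data.frame (one row per read): `read_id`, `barcode`, `umi`,
#'   `domain_a`, `domain_b`, `score_a`, `score_b`, `status` in
#'   `ok | no_barcode | ambiguous_domain | no_anchor`.
#' @export
call_reads <- function(reads, poolA, poolB, chassis, whitelist = NULL,
                       max_mismatch = 1L, min_identity = 0.85,
                       tie_margin = 0.02, umi_len = 12L) {
  n <- nrow(reads)
  fl <- sccar_flanks(chassis)
  refsA <- Biostrings::DNAStringSet(
    setNames(vapply(poolA, `[[`, "", "nt_seq"),
             vapply(poolA, `[[`, "", "id")))
  refsB <- Biostrings::DNAStringSet(
    setNames(vapply(poolB, `[[`, "", "nt_seq"),
             vapply(poolB, `[[`, "", "id")))
  # exact-insert fast path
  exact_map <- new.env(parent = emptyenv(), size = length(refsA) * length(refsB))
  for (a in names(refsA)) for (b in names(refsB)) {
    assign(paste0(as.character(refsA[[a]]), fl$linker,
                  as.character(refsB[[b]])), c(a, b), envir = exact_map)
  }
  submat <- Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -3)
  anchor_mm <- max(2L, round(0.2 * nchar(fl$anchor)))
  const5_mm <- max(2L, round(0.2 * nchar(fl$const5)))
  adapter_mm <- max(2L, round(0.2 * nchar(SCCAR_ADAPTER)))
  has_bc <- !is.null(whitelist)
  out <- data.frame(read_id = reads$id,
                    barcode = NA_character_, umi = NA_character_,
                    domain_a = NA_character_, domain_b = NA_character_,
                    score_a = NA_real_, score_b = NA_real_,
                    status = "no_anchor")
  # orientation: a read is flipped when the anchor is only found on the
  # reverse complement
  set <- Biostrings::DNAStringSet(reads$seq)
  anchor_loc <- locate_first_batch(fl$anchor, set, anchor_mm)
  need_rc <- is.na(anchor_loc[, 1])
  if (any(need_rc)) {
    rcs <- Biostrings::reverseComplement(set[need_rc])
    loc_rc <- locate_first_batch(fl$anchor, rcs, anchor_mm)
    found_rc <- !is.na(loc_rc[, 1])
    idx <- which(need_rc)[found_rc]
    oriented <- as.character(set)
    oriented[idx] <- as.character(rcs)[found_rc]
    set <- Biostrings::DNAStringSet(oriented)
    anchor_loc[idx, ] <- loc_rc[found_rc, , drop = FALSE]
  }
  seqs <- as.character(set)
  c5_loc <- locate_first_batch(fl$const5, set, const5_mm)
  has_region <- !is.na(anchor_loc[, 1]) & !is.na(c5_loc[, 2]) &
    c5_loc[, 2] + 1L < anchor_loc[, 1]
  regions <- rep(NA_character_, n)
  regions[has_region] <- substring(seqs[has_region],
                                   c5_loc[has_region, 2] + 1L,
                                   anchor_loc[has_region, 1] - 1L)
  if (has_bc) {
    bl <- nchar(whitelist[1])
    ad_loc <- locate_first_batch(fl$adapter, set, adapter_mm)
    has_ad <- !is.na(ad_loc[, 2])
    bc_obs <- rep(NA_character_, n)
    bc_obs[has_ad] <- substring(seqs[has_ad], ad_loc[has_ad, 2] + 1L,
                                ad_loc[has_ad, 2] + bl)
    umi <- rep(NA_character_, n)
    umi[has_ad] <- substring(seqs[has_ad], ad_loc[has_ad, 2] + bl + 1L,
                             ad_loc[has_ad, 2] + bl + umi_len)
    out$umi <- umi
    out$barcode <- correct_barcodes(bc_obs, whitelist, max_mismatch)
  }
  # exact-insert fast path, then k-mer-prescreened best-identity alignment
  exact <- lapply(regions, function(r)
    if (is.na(r)) NULL else get0(r, envir = exact_map))
  is_exact <- !vapply(exact, is.null, TRUE)
  out$domain_a[is_exact] <- vapply(exact[is_exact], `[[`, "", 1L)
  out$domain_b[is_exact] <- vapply(exact[is_exact], `[[`, "", 2L)
  out$score_a[is_exact] <- 1
  out$score_b[is_exact] <- 1
  out$status[is_exact] <- "ok"
  todo <- which(has_region & !is_exact)
  if (length(todo) > 0L) {
    aln_pool <- function(refs_set, idx_top2, subj_set) {
      a1 <- Biostrings::pairwiseAlignment(
        refs_set[idx_top2[, 1]], subj_set, type = "global-local",
        substitutionMatrix = submat, gapOpening = 6, gapExtension = 3)
      id1 <- Biostrings::nmatch(a1) / Biostrings::width(refs_set)[idx_top2[, 1]]
      if (length(refs_set) > 1L) {
        a2 <- Biostrings::pairwiseAlignment(
          refs_set[idx_top2[, 2]], subj_set, type = "global-local",
          substitutionMatrix = submat, gapOpening = 6, gapExtension = 3)
        id2 <- Biostrings::nmatch(a2) /
          Biostrings::width(refs_set)[idx_top2[, 2]]
      } else {
        id2 <- rep(-Inf, length(id1))
      }
      take1 <- id1 >= id2
      list(id = names(refs_set)[ifelse(take1, idx_top2[, 1], idx_top2[, 2])],
           score = pmax(id1, id2),
           ambiguous = is.finite(id2) & abs(id1 - id2) < tie_margin)
    }
    subj <- Biostrings::DNAStringSet(regions[todo])
    idxA <- kmer_index(as.character(refsA))
    idxB <- kmer_index(as.character(refsB))
    topA <- kmer_top2(regions[todo], idxA, length(refsA))
    topB <- kmer_top2(regions[todo], idxB, length(refsB))
    ca <- aln_pool(refsA, topA, subj)
    cb <- aln_pool(refsB, topB, subj)
    out$score_a[todo] <- ca$score
    out$score_b[todo] <- cb$score
    amb <- ca$ambiguous | cb$ambiguous
    pass <- !amb & ca$score >= min_identity & cb$score >= min_identity
    out$domain_a[todo[pass]] <- ca$id[pass]
    out$domain_b[todo[pass]] <- cb$id[pass]
    out$status[todo] <- ifelse(pass, "ok", "ambiguous_domain")
  }
  if (has_bc) {
    ok_no_bc <- out$status == "ok" & is.na(out$barcode)
    out$status[ok_no_bc] <- "no_barcode"
  }
  out
}

#' Call a single read (convenience wrapper over [call_reads()])
#' @inheritParams call_reads
#' @param read_seq One read sequence.
#' @return One-row data.frame as in [call_reads()].
#' @export
call_variant_read <- function(read_seq, poolA, poolB, chassis,
                              whitelist = NULL, max_mismatch = 1L,
                              min_identity = 0.85, tie_margin = 0.02) {
  call_reads(data.frame(id = "read_1", seq = read_seq), poolA, poolB,
             chassis, whitelist, max_mismatch, min_identity, tie_margin)
}

#' Assign a CAR variant to each cell barcode
#'
#' UMIs are collapsed per (barcode, variant); variants supported by fewer
#' than `min_umis_per_variant` UMIs are dropped as noise; each cell is then
#' labelled `single` (exactly one variant remains — the cell's assignment),
#' `multi` (two or more distinct constructs seen: discarded, as in a strict
#' pooled-screen analysis) or `unassigned`.
#'
#' @param read_calls data.frame from [call_reads()].
#' @param min_umis_per_variant UMI support floor per variant (default 1,
#'   strict behaviour).
#' @param dominance_ratio Optional: when set (e.g. 5), a would-be multi cell
#'   whose top variant has at least `dominance_ratio` times the UMI support
#'   of the runner-up is rescued as `single`. Default `NULL` (off).
#' @return `list(cells, summary)`: `cells` has one row per barcode
#'   (`barcode`, `variant`, `status`, `n_reads`, `n_umis`,
#'   `n_distinct_variants`), `summary` the single/multi/unassigned rates
#'   (which sum to 1; `NA` on empty input).
#' @export
demux_cells <- function(read_calls, min_umis_per_variant = 1L,
                        dominance_ratio = NULL) {
  ok <- read_calls[read_calls$status == "ok" & !is.na(read_calls$barcode), ,
                   drop = FALSE]
  all_bc <- unique(read_calls$barcode[!is.na(read_calls$barcode)])
  if (length(all_bc) == 0L) {
    return(list(cells = data.frame(barcode = character(0),
                                   variant = character(0),
                                   status = character(0),
                                   n_reads = integer(0),
                                   n_umis = integer(0),
                                   n_distinct_variants = integer(0)),
                summary = c(single_rate = NA_real_, multi_rate = NA_real_,
                            unassigned_rate = NA_real_)))
  }
  ok$variant <- paste0(ok$domain_a, "-", ok$domain_b)
  cells <- lapply(all_bc, function(bc) {
    sub <- ok[ok$barcode == bc, , drop = FALSE]
    if (nrow(sub) == 0L) {
      return(data.frame(barcode = bc, variant = NA_character_,
                        status = "unassigned", n_reads = 0L, n_umis = 0L,
                        n_distinct_variants = 0L))
    }
    umis <- tapply(sub$umi, sub$variant, function(u) length(unique(u)))
    umis <- sort(umis, decreasing = TRUE)
    kept <- umis[umis >= min_umis_per_variant]
    nvar <- length(kept)
    status <- if (nvar == 0L) "unassigned" else if (nvar == 1L) "single"
      else "multi"
    if (status == "multi" && !is.null(dominance_ratio) &&
        kept[1] >= dominance_ratio * kept[2]) {
      status <- "single"
      kept <- kept[1]
      nvar <- 1L
    }
    data.frame(barcode = bc,
               variant = if (status == "single") names(kept)[1]
                         else NA_character_,
               status = status,
               n_reads = nrow(sub),
               n_umis = sum(umis),
               n_distinct_variants = nvar)
  })
  cells <- do.call(rbind, cells)
  tab <- table(factor(cells$status,
                      levels = c("single", "multi", "unassigned")))
  rates <- as.numeric(tab) / nrow(cells)
  list(cells = cells,
       summary = c(single_rate = rates[1], multi_rate = rates[2],
                   unassigned_rate = rates[3]))
}

#' Library diversity report from variant calls
#'
#' Counts every called (A, B) combination, giving the completeness
#' (observed / possible combinations) and evenness (Shannon entropy of the
#' observed counts normalised by `log(n_observed)`; 1 iff all observed
#' counts are equal, defined as 0 when a single combination is observed).
#'
#' @param calls data.frame with `domain_a` and `domain_b` columns (rows with
#'   a `status` column are filtered to `status == "ok"` first).
#' @param poolA_ids,poolB_ids The full pool id lists.
#' @return Object of class `diversity_report`: `combination_counts` (A x B
#'   integer matrix), `n_observed`, `n_possible`, `completeness`, `evenness`,
#'   `n_foreign`.
#' @export
library_completeness <- function(calls, poolA_ids, poolB_ids) {
  if (!is.null(calls$status)) {
    calls <- calls[calls$status == "ok", , drop = FALSE]
  }
  foreign <- !(calls$domain_a %in% poolA_ids) |
    !(calls$domain_b %in% poolB_ids)
  if (any(foreign)) {
    warning(sum(foreign), " call(s) with ids outside the pools; ",
            "counted as foreign")
  }
  calls <- calls[!foreign, , drop = FALSE]
  counts <- table(factor(calls$domain_a, levels = poolA_ids),
                  factor(calls$domain_b, levels = poolB_ids))
  counts <- matrix(as.integer(counts), nrow = length(poolA_ids),
                   dimnames = list(poolA_ids, poolB_ids))
  obs <- counts[counts > 0]
  n_obs <- length(obs)
  n_pos <- length(poolA_ids) * length(poolB_ids)
  evenness <- if (n_obs <= 1L) 0 else {
    p <- obs / sum(obs)
    -sum(p * log(p)) / log(n_obs)
  }
  structure(list(combination_counts = counts,
                 n_observed = n_obs, n_possible = n_pos,
                 completeness = n_obs / n_pos,
                 evenness = evenness,
                 n_foreign = sum(foreign)),
            class = "diversity_report")
}

#' @method print diversity_report
#' @export
print.diversity_report <- function(x, ...) {
  cat("diversity_report: ", x$n_observed, "/", x$n_possible,
      " combinations observed (completeness ",
      sprintf("%.4f", x$completeness), ", evenness ",
      sprintf("%.4f", x$evenness), ")\n", sep = "")
  invisible(x)
}
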