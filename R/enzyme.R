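#' Define a Type IIS restriction enzyme
#'
#' Type IIS enzymes cut outside their (non-palindromic) recognition site,
#' leaving single-stranded overhangs whose sequence is programmable — the
#' basis of ordered Golden Gate assembly. Cut geometry follows the usual
#' `SITE(top/bottom)` notation: the top strand is cut `cut_offset_top`
#' nucleotides downstream of the recognition site's 3' end, the bottom strand
#' `cut_offset_bottom` nucleotides downstream, so the overhang length is
#' `cut_offset_bottom - cut_offset_top` (a 5' overhang when positive).
#'
#' @param name Enzyme name.
#' @param recognition Recognition sequence, top strand, 5'->3'.
#' @param cut_offset_top,cut_offset_bottom Cut distances in nucleotides
#'   downstream of the recognition site on the top and bottom strands.
#' @return An object of class `enzyme_def`.
#' @examples
#' aar1 <- enzyme_def("AarI", "CACCTGC", 4, 8)  # 4-nt 5' overhangs
#' @export
enzyme_def <- function(name, recognition, cut_offset_top, cut_offset_bottom) {
  recognition <- toupper(recognition)
  stopifnot(nchar(recognition) > 0,
            grepl("^[ACGT]+$", recognition))
  if (cut_offset_bottom - cut_offset_top <= 0) {
    stop("overhang length must be positive (cut_offset_bottom > cut_offset_top)")
  }
  structure(list(name = name,
                 recognition = recognition,
                 cut_offset_top = as.integer(cut_offset_top),
                 cut_offset_bottom = as.integer(cut_offset_bottom),
                 overhang_len = as.integer(cut_offset_bottom - cut_offset_top)),
            class = "enzyme_def")
}

#' Default AarI definition: CACCTGC(4/8), 4-nt 5' overhangs.
#' @export
aarI <- function() enzyme_def("AarI", "CACCTGC", 4L, 8L)

# Internal: 0-based top-strand cut positions and their overhang strings for
# every recognition site on either strand of `seq`.
typeIIs_cuts <- function(seq, enzyme) {
  n <- nchar(seq)
  rec <- enzyme$recognition
  rlen <- nchar(rec)
  subj <- Biostrings::DNAString(seq)
  plus <- Biostrings::start(Biostrings::matchPattern(rec, subj))
  minus <- Biostrings::start(Biostrings::matchPattern(revcomp(rec), subj))
  cuts <- data.frame(cut = integer(0), strand = character(0),
                     site_start = integer(0))
  for (s in plus) {   # site reads 5'->3' on top strand; cuts downstream
    cut <- (s - 1L) + rlen + enzyme$cut_offset_top
    cuts <- rbind(cuts, data.frame(cut = cut, strand = "+", site_start = s))
  }
  for (s in minus) {  # site on bottom strand; cuts upstream in top coordinates
    cut <- (s - 1L) - enzyme$cut_offset_bottom
    cuts <- rbind(cuts, data.frame(cut = cut, strand = "-", site_start = s))
  }
  if (nrow(cuts) > 0L) {
    bad <- cuts$cut < 0L | cuts$cut + enzyme$overhang_len > n
    if (any(bad)) {
      warning(sum(bad), " site(s) cut beyond the sequence ends; skipped")
      cuts <- cuts[!bad, , drop = FALSE]
    }
    cuts <- cuts[order(cuts$cut), , drop = FALSE]
    if (anyDuplicated(cuts$cut)) {
      warning("overlapping sites produce coincident cuts; digest performed left-to-right")
      cuts <- cuts[!duplicated(cuts$cut), , drop = FALSE]
    }
  }
  cuts$overhang <- if (nrow(cuts) == 0L) character(0) else
    substring(seq, cuts$cut + 1L, cuts$cut + enzyme$overhang_len)
  cuts
}

#' Digest a sequence with a Type IIS enzyme
#'
#' Finds every recognition site on both strands, computes the double-strand
#' cut positions from the enzyme geometry and partitions the top strand at
#' those positions. Each junction's single-stranded 5' overhang is recorded:
#' a fragment's `oh5` is the overhang its own 5' end carries (its first
#' `overhang_len` bases, single-stranded) and `oh3` is the overhang its 3' end
#' is compatible with (the first bases of the fragment to its right). Two
#' fragments ligate, left then right, when `left$oh3 == right$oh5`, and the
#' ligated top strand is the plain concatenation of the two fragment
#' sequences.
#'
#' @param seq DNA sequence (character scalar).
#' @param enzyme An [enzyme_def()].
#' @param circular Is the molecule circular? If so the two terminal pieces are
#'   joined across the origin.
#' @return A list of fragments, each `list(seq, oh5, oh3, start, end)` with
#'   0-based half-open top-strand coordinates. Terminal blunt ends of a linear
#'   molecule carry `oh5`/`oh3` of `""`.
#' @export
typeIIs_digest <- function(seq, enzyme, circular = FALSE) {
  seq <- toupper(seq)
  stopifnot(grepl("^[ACGT]+$", seq))
  cuts <- typeIIs_cuts(seq, enzyme)
  if (nrow(cuts) == 0L) {
    stop("no-site: no ", enzyme$name, " recognition site in sequence")
  }
  n <- nchar(seq)
  pos <- cuts$cut
  oh <- cuts$overhang
  frag <- function(start, end, oh5, oh3) {
    list(seq = substring(seq, start + 1L, end), oh5 = oh5, oh3 = oh3,
         start = start, end = end)
  }
  out <- list()
  if (circular) {
    k <- length(pos)
    for (i in seq_len(k)) {
      j <- if (i == k) 1L else i + 1L
      s <- pos[i]; e <- pos[j]
      sq <- if (e > s) substring(seq, s + 1L, e) else
        paste0(substring(seq, s + 1L, n), substring(seq, 1L, e))
      out[[i]] <- list(seq = sq, oh5 = oh[i], oh3 = oh[j], start = s, end = e)
    }
  } else {
    bounds <- c(0L, pos, n)
    oh5s <- c("", oh)
    oh3s <- c(oh, "")
    for (i in seq_len(length(bounds) - 1L)) {
      out[[i]] <- frag(bounds[i], bounds[i + 1L], oh5s[i], oh3s[i])
    }
  }
  out
}

#' Ligate fragments by overhang complementarity
#'
#' Orders fragments into the unique chain in which every junction's 3'
#' overhang matches the next fragment's 5' overhang, then concatenates the
#' top strands. The chain starts at `first` if given, otherwise at the unique
#' fragment whose 5' overhang no other fragment's 3' overhang matches.
#'
#' @param fragments List of fragments as produced by [typeIIs_digest()] (or
#'   built directly: `list(seq=, oh5=, oh3=)`).
#' @param first Optional index of the left-most fragment.
#' @return `list(seq, path)` — ligated top strand and the fragment order.
#' @export
ligate_fragments <- function(fragments, first = NULL) {
  k <- length(fragments)
  stopifnot(k >= 2L)
  oh5 <- vapply(fragments, `[[`, "", "oh5")
  oh3 <- vapply(fragments, `[[`, "", "oh3")
  if (is.null(first)) {
    # left-most fragment: blunt 5' end, or a 5' overhang no other fragment's
    # 3' end can ligate to
    cand <- which(vapply(seq_len(k), function(i)
      oh5[i] == "" || !(oh5[i] %in% oh3[-i]), TRUE))
    if (length(cand) != 1L) {
      stop("ambiguous ligation: cannot identify a unique left-most fragment")
    }
    first <- cand
  }
  path <- first
  used <- rep(FALSE, k); used[first] <- TRUE
  cur <- first
  while (length(path) < k) {
    nxt <- which(!used & nzchar(oh5) & oh5 == oh3[cur])
    if (length(nxt) == 0L) {
      stop("overhang mismatch: no fragment ligates after fragment ", cur,
           " (3' overhang ", oh3[cur], ")")
    }
    if (length(nxt) > 1L) {
      stop("ambiguous ligation: overhang ", oh3[cur],
           " matches several fragments")
    }
    path <- c(path, nxt)
    used[nxt] <- TRUE
    cur <- nxt
  }
  list(seq = paste(vapply(fragments[path], `[[`, "", "seq"), collapse = ""),
       path = path)
}
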