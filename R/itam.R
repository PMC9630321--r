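#' Scan an amino-acid sequence for ITAMs
#'
#' An immunoreceptor tyrosine-based activation motif (ITAM) is modelled as two
#' `Yxx[L/I]` half-sites separated by a spacer of `spacer_min` to `spacer_max`
#' residues. Matches are found by a left-to-right scan: at each position the
#' shortest spacer that completes a motif is taken and scanning resumes after
#' the match, so reported motifs are non-overlapping and left-greedy.
#'
#' @param aa_seq Amino-acid sequence, uppercase one-letter codes.
#' @param spacer_min,spacer_max Inclusive bounds on the number of residues
#'   between the two `Yxx[L/I]` half-sites (defaults 6 and 12).
#' @return A data.frame with one row per motif: `start`, `end` (1-based,
#'   inclusive) and `spacer`. Zero rows when no motif is present. The ITAM
#'   count of a sequence is `nrow(itam_scan(...))`.
#' @examples
#' itam_scan("AAAAAA")                      # no tyrosine -> 0 motifs
#' itam_scan("YAALAAAAAAAYAAI")             # one motif, spacer 7
#' @export
itam_scan <- function(aa_seq, spacer_min = 6L, spacer_max = 12L) {
  stopifnot(length(aa_seq) == 1L, is.character(aa_seq))
  if (nchar(aa_seq) == 0L) stop("aa_seq must be non-empty")
  if (spacer_min < 0L || spacer_max < spacer_min) {
    stop("invalid spacer bounds")
  }
  chars <- strsplit(aa_seq, "", fixed = TRUE)[[1]]
  bad <- setdiff(unique(chars), AA_ALPHABET)
  if (length(bad) > 0L) {
    stop("invalid amino-acid character(s): ", paste(bad, collapse = ", "))
  }
  n <- length(chars)
  half_at <- function(i) {
    # Yxx[LI] starting at position i (1-based)?
    i + 3L <= n && chars[i] == "Y" && chars[i + 3L] %in% c("L", "I")
  }
  hits <- list()
  i <- 1L
  while (i <= n - 3L) {
    if (half_at(i)) {
      matched <- FALSE
      for (sp in spacer_min:spacer_max) {
        j <- i + 4L + sp        # start of second half-site
        if (j + 3L > n) break
        if (half_at(j)) {
          hits[[length(hits) + 1L]] <- c(start = i, end = j + 3L, spacer = sp)
          i <- j + 4L           # resume after the full motif
          matched <- TRUE
          break
        }
      }
      if (!matched) i <- i + 1L
    } else {
      i <- i + 1L
    }
  }
  if (length(hits) == 0L) {
    return(data.frame(start = integer(0), end = integer(0),
                      spacer = integer(0)))
  }
  as.data.frame(do.call(rbind, hits))
}

#' Count ITAMs in an amino-acid sequence
#'
#' Convenience wrapper around [itam_scan()].
#' @inheritParams itam_scan
#' @return Integer motif count.
#' @export
itam_count <- function(aa_seq, spacer_min = 6L, spacer_max = 12L) {
  nrow(itam_scan(aa_seq, spacer_min, spacer_max))
}
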