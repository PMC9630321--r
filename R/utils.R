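#' @importFrom methods is
#' @importFrom stats median prcomp pnorm p.adjust rbinom rnbinom runif
#'   rlnorm var sd cor quantile setNames aggregate
#' @importFrom utils write.table read.table head
NULL

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring the
# caller's stream afterwards so that seeded generators do not perturb user code.
with_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  code
}

DNA_BASES <- c("A", "C", "G", "T")

random_dna <- function(n) {
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

translate_dna <- function(nt) {
  if (nchar(nt) %% 3L != 0L) {
    stop("sequence length not divisible by 3; cannot translate in frame 0")
  }
  as.character(Biostrings::translate(Biostrings::DNAStringSet(nt)))
}

# Amino-acid alphabet used for validation (20 standard + stop symbol).
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N",
                 "P", "Q", "R", "S", "T", "V", "W", "Y")

`%||%` <- function(a, b) if (is.null(a)) b else a
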