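#' Read a FASTA file
#'
#' Thin wrapper over Biostrings that tolerates multi-line records and CRLF
#' line endings and reports parse failures with the offending file.
#' @param path FASTA file.
#' @return Named character vector of sequences (names = record ids up to the
#'   first whitespace). Empty files yield a zero-length vector.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (file.size(path) == 0L) return(setNames(character(0), character(0)))
  set <- tryCatch(Biostrings::readDNAStringSet(path, format = "fasta"),
                  error = function(e) stop("FASTA parse error in ", path, ": ",
                                           conditionMessage(e)))
  out <- as.character(set)
  names(out) <- sub("\\s.*$", "", names(set))
  out
}

#' Write sequences to FASTA
#' @param seqs Named character vector of DNA sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  set <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read a FASTQ file (4-line records, Phred+33)
#' @param path FASTQ file.
#' @return data.frame with columns `id`, `seq`, `qual`.
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- sub("\r$", "", lines)
  while (length(lines) > 0L && !nzchar(lines[length(lines)])) {
    lines <- lines[-length(lines)]
  }
  if (length(lines) == 0L) {
    return(data.frame(id = character(0), seq = character(0),
                      qual = character(0)))
  }
  if (length(lines) %% 4L != 0L) {
    stop("FASTQ parse error in ", path, ": truncated record near line ",
         length(lines))
  }
  idx <- seq(1L, length(lines), by = 4L)
  if (!all(startsWith(lines[idx], "@")) ||
      !all(startsWith(lines[idx + 2L], "+"))) {
    bad <- idx[which(!startsWith(lines[idx], "@"))[1]]
    stop("FASTQ parse error in ", path, ": malformed record at line ",
         if (is.na(bad)) idx[which(!startsWith(lines[idx + 2L], "+"))[1]] + 2L
         else bad)
  }
  data.frame(id = sub("^@", "", sub("\\s.*$", "", lines[idx])),
             seq = lines[idx + 1L],
             qual = lines[idx + 3L])
}

#' Write a FASTQ file (Phred+33)
#' @param reads data.frame with columns `id`, `seq` and optionally `qual`
#'   (default constant Q20, i.e. "5").
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  qual <- reads$qual %||% strrep("5", nchar(reads$seq))
  con <- file(path, "wb")  # binary: byte-stable across platforms
  on.exit(close(con))
  writeLines(paste0("@", reads$id, "\n", reads$seq, "\n+\n", qual),
             con, sep = "\n")
  invisible(path)
}

#' Bundle a gene-by-cell count matrix with its metadata
#'
#' Lightweight container used throughout the screen-analysis functions:
#' a sparse integer matrix (genes in rows, cells in columns), gene ids,
#' cell barcodes, per-cell metadata and a per-gene mitochondrial flag.
#'
#' @param counts Matrix or sparse Matrix, genes x cells, non-negative
#'   integers.
#' @param genes Gene identifiers (rownames used when missing).
#' @param barcodes Cell barcodes (colnames used when missing).
#' @param meta Per-cell metadata data.frame (one row per cell); a `barcode`
#'   column is added/checked. Typical columns: `variant`, `group`, `donor`.
#' @param mito Logical per-gene mitochondrial flag; by default genes named
#'   with an `MT-` prefix.
#' @return Object of class `car_counts`.
#' @export
car_counts <- function(counts, genes = rownames(counts),
                       barcodes = colnames(counts), meta = NULL,
                       mito = grepl("^MT-", genes)) {
  counts <- methods::as(methods::as(methods::as(
    Matrix::Matrix(counts, sparse = TRUE), "dMatrix"),
    "generalMatrix"), "CsparseMatrix")
  if (is.null(genes) || is.null(barcodes)) {
    stop("gene ids and cell barcodes are required")
  }
  if (length(genes) != nrow(counts) || length(barcodes) != ncol(counts)) {
    stop("dimension mismatch between matrix and id lists")
  }
  if (any(counts@x < 0) || any(counts@x != round(counts@x))) {
    stop("counts must be non-negative integers")
  }
  rownames(counts) <- genes
  colnames(counts) <- barcodes
  if (is.null(meta)) meta <- data.frame(barcode = barcodes)
  if (!"barcode" %in% names(meta)) meta <- cbind(barcode = barcodes, meta)
  if (nrow(meta) != ncol(counts) || !identical(meta$barcode, barcodes)) {
    stop("metadata rows must align with cell barcodes")
  }
  structure(list(counts = counts, genes = genes, barcodes = barcodes,
                 meta = meta, mito = mito),
            class = "car_counts")
}

#' @method print car_counts
#' @export
print.car_counts <- function(x, ...) {
  cat("car_counts: ", length(x$genes), " genes x ", length(x$barcodes),
      " cells (", sum(x$mito), " mitochondrial genes flagged)\n", sep = "")
  invisible(x)
}

#' @export
dim.car_counts <- function(x) dim(x$counts)

# Subset cells of a car_counts object by barcode or index.
subset_cells <- function(cc, cells) {
  if (is.character(cells)) cells <- match(cells, cc$barcodes)
  car_counts(cc$counts[, cells, drop = FALSE], cc$genes,
             cc$barcodes[cells], cc$meta[cells, , drop = FALSE],
             cc$mito)
}

#' Read a 10X-style MTX triplet directory
#'
#' Expects `matrix.mtx` (MatrixMarket coordinate format, 1-based indices),
#' `features.tsv` and `barcodes.tsv`, plus an optional `metadata.tsv` keyed
#' by barcode. Dimensions are cross-checked against the id files.
#' @param dir Directory containing the triplet.
#' @return A [car_counts()] object.
#' @export
read_mtx <- function(dir) {
  mtx <- file.path(dir, "matrix.mtx")
  feats <- file.path(dir, "features.tsv")
  bcs <- file.path(dir, "barcodes.tsv")
  for (f in c(mtx, feats, bcs)) {
    if (!file.exists(f)) stop("missing MTX triplet file: ", f)
  }
  m <- Matrix::readMM(mtx)
  features <- read.table(feats, sep = "\t", header = FALSE,
                         colClasses = "character")
  barcodes <- readLines(bcs)
  if (nrow(m) != nrow(features)) {
    stop("dimension mismatch: matrix has ", nrow(m), " rows but features.tsv ",
         nrow(features))
  }
  if (ncol(m) != length(barcodes)) {
    stop("dimension mismatch: matrix has ", ncol(m), " columns but ",
         "barcodes.tsv ", length(barcodes))
  }
  meta_path <- file.path(dir, "metadata.tsv")
  meta <- if (file.exists(meta_path)) {
    read.table(meta_path, sep = "\t", header = TRUE,
               colClasses = "character")
  } else NULL
  if (!is.null(meta)) {
    if (!identical(meta$barcode, barcodes)) {
      meta <- meta[match(barcodes, meta$barcode), , drop = FALSE]
    }
    rownames(meta) <- NULL
  }
  car_counts(m, features[[1]], barcodes, meta)
}

#' Write a [car_counts()] object as a 10X-style MTX triplet
#'
#' Genes are rows and cells columns (10X convention); nonzeros round-trip
#' exactly through [read_mtx()]. Metadata is written alongside as
#' `metadata.tsv`.
#' @param cc A [car_counts()] object.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_mtx <- function(cc, dir) {
  stopifnot(inherits(cc, "car_counts"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(cc$counts, file.path(dir, "matrix.mtx"))
  writeLines(paste(cc$genes, cc$genes, "Gene Expression", sep = "\t"),
             file.path(dir, "features.tsv"))
  writeLines(cc$barcodes, file.path(dir, "barcodes.tsv"))
  write.table(cc$meta, file.path(dir, "metadata.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(dir)
}

# Deterministic TSV writer used by reports (fixed float formatting).
write_tsv_report <- function(df, path, digits = 6) {
  num <- vapply(df, is.numeric, TRUE) & !vapply(df, is.integer, TRUE)
  df[num] <- lapply(df[num], function(x) signif(x, digits))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
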