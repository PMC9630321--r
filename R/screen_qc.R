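#' Quality-control filter for cells
#'
#' Keeps cells with `min_genes < detected genes < max_genes` (strict
#' inequalities) and a mitochondrial read percentage strictly below
#' `max_mt_pct`. Cells sitting exactly on a threshold are removed.
#'
#' @param cc A [car_counts()] object with mitochondrial genes flagged.
#' @param min_genes,max_genes Open bounds on the number of detected genes
#'   (defaults 500 and 10000).
#' @param max_mt_pct Open upper bound on the mitochondrial percentage of
#'   total counts (default 15); set to `Inf` to disable.
#' @return `list(counts, removed)`: the filtered [car_counts()] and a named
#'   integer vector of per-rule violation counts (`low_genes`, `high_genes`,
#'   `high_mito`; a cell may violate several rules).
#' @export
qc_filter <- function(cc, min_genes = 500, max_genes = 10000,
                      max_mt_pct = 15) {
  stopifnot(inherits(cc, "car_counts"))
  if (is.finite(max_mt_pct) && !any(cc$mito)) {
    stop("configuration error: no mitochondrial genes flagged but ",
         "max_mt_pct is finite")
  }
  detected <- Matrix::colSums(cc$counts > 0)
  total <- Matrix::colSums(cc$counts)
  mt_pct <- if (any(cc$mito)) {
    100 * Matrix::colSums(cc$counts[cc$mito, , drop = FALSE]) /
      pmax(total, 1)
  } else rep(0, ncol(cc$counts))
  low <- detected <= min_genes
  high <- detected >= max_genes
  mito_bad <- mt_pct >= max_mt_pct
  keep <- !(low | high | mito_bad)
  list(counts = subset_cells(cc, which(keep)),
       removed = c(low_genes = sum(low), high_genes = sum(high),
                   high_mito = sum(mito_bad)))
}

#' Log-normalize counts
#'
#' Per cell: `x' = ln(1 + scale * x / total)`, the standard log
#' normalization with a scale factor (default 10,000). Zeros stay zero, so
#' sparsity is preserved; zero-count cells are excluded with a warning.
#'
#' @param x A [car_counts()] or a genes-x-cells (sparse) matrix.
#' @param scale Scale factor (default 1e4).
#' @return Sparse genes-x-cells matrix of normalized values.
#' @export
lognormalize <- function(x, scale = 1e4) {
  m <- if (inherits(x, "car_counts")) x$counts else
    methods::as(Matrix::Matrix(x, sparse = TRUE), "CsparseMatrix")
  totals <- Matrix::colSums(m)
  if (any(totals == 0)) {
    warning(sum(totals == 0), " zero-count cell(s) excluded")
    m <- m[, totals > 0, drop = FALSE]
    totals <- totals[totals > 0]
  }
  norm <- m
  norm@x <- log1p(scale * m@x / rep.int(totals, diff(m@p)))
  norm
}

#' Subsample cells per variant and per negative control group
#'
#' Caps each library variant at `per_variant` cells and each control group
#' (metadata `group` starting with `neg_`) at `per_control`, sampling
#' without replacement under `seed`; groups under the cap keep all cells.
#'
#' @param cc A [car_counts()] whose metadata has `variant` and `group`.
#' @param per_variant Cap per CAR variant (default 250).
#' @param per_control Cap per negative control group (default 500).
#' @param seed Integer seed.
#' @return Subsetted [car_counts()].
#' @export
subsample_cells <- function(cc, per_variant = 250L, per_control = 500L,
                            seed = 1L) {
  stopifnot(inherits(cc, "car_counts"), "variant" %in% names(cc$meta))
  group <- cc$meta$group %||% rep("variant", nrow(cc$meta))
  key <- ifelse(startsWith(group, "neg_"), group, cc$meta$variant)
  cap <- ifelse(startsWith(group, "neg_"), per_control, per_variant)
  with_seed(seed, {
    keep <- unlist(lapply(split(seq_along(key), key), function(idx) {
      k <- cap[idx[1]]
      if (length(idx) <= k) idx else sort(sample(idx, k))
    }), use.names = FALSE)
  })
  subset_cells(cc, sort(keep))
}
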