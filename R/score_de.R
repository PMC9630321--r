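# Pseudo-bulk aggregation, PCA embedding, rank-based gene-set scoring and
# Wilcoxon rank-sum differential expression.

#' Pseudo-bulk: per-group mean of normalized expression
#'
#' @param norm Genes-x-cells normalized matrix.
#' @param groups Group label per cell (e.g. CAR variant).
#' @return Dense groups-x-genes matrix of mean normalized expression.
#' @export
pseudobulk <- function(norm, groups) {
  stopifnot(length(groups) == ncol(norm))
  groups <- as.factor(groups)
  if (any(table(groups) == 0L)) groups <- droplevels(groups)
  ind <- Matrix::sparseMatrix(i = seq_along(groups),
                              j = as.integer(groups),
                              x = 1, dims = c(length(groups),
                                              nlevels(groups)))
  sums <- as.matrix(norm %*% ind)
  means <- sweep(sums, 2L, as.numeric(table(groups)), "/")
  colnames(means) <- levels(groups)
  t(means)
}

#' Centered PCA embedding
#'
#' @param m Samples-x-features matrix (e.g. a [pseudobulk()] result).
#' @param n_components Number of components (capped at `min(dim) - 1`).
#' @return `list(scores, var_explained)`: scores are samples x components,
#'   `var_explained` the per-component fraction of total variance
#'   (non-increasing, summing to <= 1).
#' @export
pca_embed <- function(m, n_components = 10L) {
  m <- as.matrix(m)
  if (nrow(m) < 2L) stop("PCA needs at least 2 samples")
  n_components <- min(n_components, nrow(m) - 1L, ncol(m))
  p <- prcomp(m, center = TRUE, scale. = FALSE)
  total_var <- sum(p$sdev^2)
  list(scores = p$x[, seq_len(n_components), drop = FALSE],
       var_explained = (p$sdev^2 / total_var)[seq_len(n_components)])
}

#' Rank-based per-cell gene-set scores
#'
#' For each cell, all genes are ranked by decreasing expression (average
#' ranks on ties) and ranks capped at `r_max + 1`; the signature's
#' Mann-Whitney U statistic `U' = sum(rank) - n(n+1)/2` is turned into a
#' score `1 - U'/(n * r_max)`, clipped to `[0, 1]`. A score near 1 means the
#' signature genes sit at the very top of the cell's expression ranking.
#'
#' @param norm Genes-x-cells normalized matrix.
#' @param gene_sets Named list of gene-id vectors, or a single character
#'   vector (treated as one set named `"set"`).
#' @param r_max Rank cap (default 1500).
#' @return Cells-x-sets matrix of scores. Sets with no gene present in the
#'   matrix give `NA` with a warning.
#' @export
geneset_score <- function(norm, gene_sets, r_max = 1500L) {
  if (!is.list(gene_sets)) gene_sets <- list(set = gene_sets)
  if (is.null(names(gene_sets))) {
    names(gene_sets) <- paste0("set", seq_along(gene_sets))
  }
  idx_sets <- lapply(gene_sets, function(gs) {
    idx <- match(gs, rownames(norm))
    idx[!is.na(idx)]
  })
  empty <- lengths(idx_sets) == 0L
  if (any(empty)) {
    warning("gene set(s) with no gene in the matrix: ",
            paste(names(gene_sets)[empty], collapse = ", "))
  }
  n_cells <- ncol(norm)
  out <- matrix(NA_real_, nrow = n_cells, ncol = length(gene_sets),
                dimnames = list(colnames(norm), names(gene_sets)))
  dense <- as.matrix(norm)
  for (j in seq_len(n_cells)) {
    r <- rank(-dense[, j], ties.method = "average")
    r <- pmin(r, r_max + 1)
    for (s in which(!empty)) {
      idx <- idx_sets[[s]]
      n <- length(idx)
      u <- sum(r[idx]) - n * (n + 1) / 2
      out[j, s] <- min(1, max(0, 1 - u / (n * r_max)))
    }
  }
  out
}

#' Summarise gene-set scores per variant with fold change vs a benchmark
#'
#' @param scores Cells-x-sets score matrix from [geneset_score()].
#' @param groups Group (variant) label per cell.
#' @param benchmark Group used as the fold-change reference (its own fold
#'   change is exactly 1).
#' @return data.frame with `group`, `set`, `mean_score`, `fold_change`.
#' @export
geneset_summary <- function(scores, groups, benchmark) {
  stopifnot(length(groups) == nrow(scores), benchmark %in% groups)
  means <- apply(scores, 2L, function(s) tapply(s, groups, mean))
  if (is.null(dim(means))) {
    means <- matrix(means, nrow = 1,
                    dimnames = list(unique(groups), colnames(scores)))
  }
  bench <- means[benchmark, ]
  out <- expand.grid(group = rownames(means), set = colnames(means),
                     stringsAsFactors = FALSE)
  out$mean_score <- as.vector(means)
  out$fold_change <- as.vector(sweep(means, 2L, bench, "/"))
  out
}

#' Wilcoxon rank-sum differential expression between two cell groups
#'
#' Two-sided Mann-Whitney U test per gene with normal approximation and tie
#' correction, Benjamini-Hochberg adjustment across tested genes. Genes are
#' pre-filtered on detection fraction (`min_pct` in either group) and
#' absolute log fold change (natural log of expression means, pseudocount
#' 1).
#'
#' @param norm Genes-x-cells normalized matrix.
#' @param cells_a,cells_b Disjoint barcode vectors (or column indices) of
#'   the two groups, each of size >= 3.
#' @param min_pct Minimum detection fraction in at least one group
#'   (default 0.1).
#' @param logfc_threshold Minimum absolute log fold change (default 0.25).
#' @return data.frame: `gene`, `avg_logFC`, `pct_a`, `pct_b`, `statistic`
#'   (U for group A), `p_val`, `p_adj`; one row per tested gene, ordered by
#'   p-value.
#' @export
rank_sum_de <- function(norm, cells_a, cells_b, min_pct = 0.1,
                        logfc_threshold = 0.25) {
  to_idx <- function(x) if (is.character(x)) match(x, colnames(norm)) else x
  ia <- to_idx(cells_a); ib <- to_idx(cells_b)
  if (anyNA(ia) || anyNA(ib)) stop("unknown cell barcodes")
  if (length(intersect(ia, ib)) > 0L) stop("cell groups overlap")
  if (length(ia) < 3L || length(ib) < 3L) {
    stop("both groups need at least 3 cells")
  }
  a <- as.matrix(norm[, ia, drop = FALSE])
  b <- as.matrix(norm[, ib, drop = FALSE])
  pct_a <- rowMeans(a > 0)
  pct_b <- rowMeans(b > 0)
  lfc <- log(rowMeans(expm1(a)) + 1) - log(rowMeans(expm1(b)) + 1)
  tested <- which(pmax(pct_a, pct_b) >= min_pct & abs(lfc) >= logfc_threshold)
  if (length(tested) == 0L) {
    return(data.frame(gene = character(0), avg_logFC = numeric(0),
                      pct_a = numeric(0), pct_b = numeric(0),
                      statistic = numeric(0), p_val = numeric(0),
                      p_adj = numeric(0)))
  }
  na <- ncol(a); nb <- ncol(b); n <- na + nb
  res <- t(vapply(tested, function(g) {
    r <- rank(c(a[g, ], b[g, ]))
    u <- sum(r[seq_len(na)]) - na * (na + 1) / 2
    ties <- table(r)
    tie_term <- sum(ties^3 - ties) / (n * (n - 1))
    sigma2 <- na * nb / 12 * ((n + 1) - tie_term)
    if (sigma2 <= 0) return(c(u, 1))  # all values tied
    z <- (u - na * nb / 2) / sqrt(sigma2)
    c(u, min(1, 2 * pnorm(-abs(z))))
  }, numeric(2)))
  out <- data.frame(gene = rownames(norm)[tested],
                    avg_logFC = lfc[tested],
                    pct_a = pct_a[tested], pct_b = pct_b[tested],
                    statistic = res[, 1],
                    p_val = res[, 2],
                    p_adj = p.adjust(res[, 2], method = "BH"))
  out[order(out$p_val), , drop = FALSE]
}
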