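# Unsupervised clustering of normalized expression: highly-variable gene
# selection, scaling (with optional nuisance regression), PCA, kNN graph,
# modularity community detection; plus the adjusted Rand index and the
# subsample-and-recluster stability protocol.

# Standardized-dispersion HVG selection: dispersion = var/mean, z-scored
# within 20 gene-mean bins.
select_hvg <- function(norm, n_hvg) {
  mu <- Matrix::rowMeans(norm)
  ex2 <- Matrix::rowMeans(norm^2)
  n <- ncol(norm)
  v <- (ex2 - mu^2) * n / max(1, n - 1)
  disp <- ifelse(mu > 0, v / mu, 0)
  bins <- cut(rank(mu, ties.method = "first"), breaks = 20, labels = FALSE)
  z <- disp
  for (b in unique(bins)) {
    idx <- bins == b
    s <- sd(disp[idx])
    z[idx] <- (disp[idx] - mean(disp[idx])) / if (is.na(s) || s == 0) 1 else s
  }
  order(z, decreasing = TRUE)[seq_len(min(n_hvg, nrow(norm)))]
}

#' Cluster cells on a kNN graph of PCA space
#'
#' Selects the top `n_hvg` variable genes (standardized dispersion),
#' z-scales them (clipped at 10), optionally regresses out nuisance
#' covariates (e.g. cell-cycle scores) by least squares, embeds cells with
#' PCA, builds an unweighted Euclidean k-nearest-neighbour graph and
#' partitions it by Louvain modularity optimisation. Deterministic under
#' `seed`.
#'
#' @param norm Genes-x-cells normalized matrix (see [lognormalize()]).
#' @param n_hvg Number of highly-variable genes (default 2000, capped at the
#'   gene count).
#' @param n_pcs Number of principal components (default 30; reduced with a
#'   warning when the matrix is smaller).
#' @param k_neighbors Neighbours per cell (default 20).
#' @param resolution Louvain resolution parameter (default 1).
#' @param nuisance Optional cells-x-q matrix of covariates to regress out of
#'   the scaled data.
#' @param seed Integer seed for the community detection.
#' @return Integer cluster labels `0..K-1`, named by cell barcode.
#' @export
cluster_cells <- function(norm, n_hvg = 2000L, n_pcs = 30L,
                          k_neighbors = 20L, resolution = 1,
                          nuisance = NULL, seed = 1L) {
  n_cells <- ncol(norm)
  if (n_cells < k_neighbors + 1L) {
    stop("need at least k_neighbors + 1 cells (", k_neighbors + 1L, ")")
  }
  hvg <- select_hvg(norm, n_hvg)
  x <- t(as.matrix(norm[hvg, , drop = FALSE]))  # cells x genes
  x <- scale(x)
  x[is.na(x)] <- 0
  x[x > 10] <- 10
  x[x < -10] <- -10
  if (!is.null(nuisance)) {
    nuisance <- as.matrix(nuisance)
    stopifnot(nrow(nuisance) == n_cells)
    fit <- stats::lm.fit(cbind(1, nuisance), x)
    x <- fit$residuals
  }
  max_pcs <- min(nrow(x) - 1L, ncol(x) - 1L)
  if (n_pcs > max_pcs) {
    warning("reducing n_pcs from ", n_pcs, " to ", max_pcs)
    n_pcs <- max_pcs
  }
  pcs <- prcomp(x, center = TRUE, scale. = FALSE, rank. = n_pcs)$x
  d <- as.matrix(stats::dist(pcs))
  diag(d) <- Inf
  nn <- apply(d, 1L, function(r) order(r)[seq_len(k_neighbors)])
  edges <- rbind(rep(seq_len(n_cells), each = k_neighbors), as.vector(nn))
  g <- igraph::simplify(igraph::graph_from_edgelist(t(edges),
                                                    directed = FALSE))
  memb <- with_seed(seed, igraph::membership(
    igraph::cluster_louvain(g, resolution = resolution)))
  out <- as.integer(memb) - 1L
  names(out) <- colnames(norm)
  out
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected pair-counting agreement:
#' `ARI = (sum_ij C(n_ij,2) - E) / (M - E)` with
#' `E = sum_i C(a_i,2) * sum_j C(b_j,2) / C(n,2)` and
#' `M = (sum_i C(a_i,2) + sum_j C(b_j,2)) / 2`. Symmetric, 1 for identical
#' partitions (up to label permutation), ~0 for independent ones.
#'
#' @param p1,p2 Cluster label vectors over the same cells. Named vectors are
#'   aligned by name; otherwise they must have equal length.
#' @return The ARI (scalar).
#' @export
ari <- function(p1, p2) {
  if (!is.null(names(p1)) && !is.null(names(p2))) {
    common <- intersect(names(p1), names(p2))
    if (length(common) != length(p1) || length(common) != length(p2)) {
      stop("partitions cover different cell sets")
    }
    p2 <- p2[names(p1)]
  } else if (length(p1) != length(p2)) {
    stop("partitions cover different cell sets")
  }
  n <- length(p1)
  tab <- table(p1, p2)
  ch2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(ch2(tab))
  a <- sum(ch2(rowSums(tab)))
  b <- sum(ch2(colSums(tab)))
  e <- a * b / ch2(n)
  m <- (a + b) / 2
  if (m == e) return(1)  # degenerate: both partitions trivial
  (sum_ij - e) / (m - e)
}

#' Clustering stability under repeated subsampling
#'
#' Runs `iters` independent rounds of [subsample_cells()] followed by
#' [cluster_cells()] (each round with its own derived seed) and computes the
#' ARI between every pair of rounds on the cells retained in both.
#'
#' @param cc A [car_counts()] with variant/group metadata.
#' @param iters Number of rounds (>= 2).
#' @param per_variant,per_control Subsampling caps (see
#'   [subsample_cells()]).
#' @param seed Base seed; round `i` uses `seed + i`.
#' @param ... Passed to [cluster_cells()].
#' @return `list(ari, summary)`: the `C(iters, 2)` pairwise ARI values
#'   (NA with a warning for empty intersections) and `c(min, median)`.
#' @export
stability <- function(cc, iters = 50L, per_variant = 250L,
                      per_control = 500L, seed = 1L, ...) {
  if (iters < 2L) stop("iters must be >= 2")
  parts <- vector("list", iters)
  for (i in seq_len(iters)) {
    sub <- subsample_cells(cc, per_variant, per_control, seed = seed + i)
    norm <- lognormalize(sub)
    parts[[i]] <- cluster_cells(norm, seed = seed + i, ...)
  }
  pairs <- utils::combn(iters, 2L)
  aris <- apply(pairs, 2L, function(pr) {
    common <- intersect(names(parts[[pr[1]]]), names(parts[[pr[2]]]))
    if (length(common) == 0L) {
      warning("empty cell intersection for a pair of iterations")
      return(NA_real_)
    }
    ari(parts[[pr[1]]][common], parts[[pr[2]]][common])
  })
  list(ari = aris,
       summary = c(min = min(aris, na.rm = TRUE),
                   median = median(aris, na.rm = TRUE)))
}
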