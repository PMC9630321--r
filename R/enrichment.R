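# Per-variant cluster enrichment and CAR-induced-cluster (CIC) detection.
# A CIC is a transcriptional cluster strongly enriched in stimulated
# benchmark CAR T cells and depleted in negative controls; the fraction of a
# variant's cells falling into CICs is the screen's per-variant activity
# measure.

#' Per-variant cluster fraction matrix
#'
#' `f[v, c]` is the fraction of variant-`v` cells assigned to cluster `c`;
#' rows sum to 1. Library variants need at least `min_cells` cells to be
#' reported; control groups are always included.
#'
#' @param metadata Per-cell data.frame with `barcode`, `variant` and `group`
#'   (control cells carry their group name in `variant`).
#' @param partition Cluster labels named by barcode (see
#'   [cluster_cells()]); metadata is restricted to cells present in it.
#' @param min_cells Minimum cells per library variant (default 50).
#' @return Object of class `enrichment_matrix`: `f` (variants x clusters),
#'   `n_cells`, `clusters`, and a `cic_flags` slot filled by
#'   [detect_cics()].
#' @export
cluster_fractions <- function(metadata, partition, min_cells = 50L) {
  keep <- metadata$barcode %in% names(partition)
  metadata <- metadata[keep, , drop = FALSE]
  cl <- partition[metadata$barcode]
  clusters <- sort(unique(as.integer(partition)))
  tab <- table(metadata$variant, factor(cl, levels = clusters))
  n_cells <- rowSums(tab)
  group_of <- metadata$group[match(rownames(tab), metadata$variant)]
  is_control <- group_of != "variant"
  keep_rows <- is_control | n_cells >= min_cells
  tab <- tab[keep_rows, , drop = FALSE]
  n_cells <- n_cells[keep_rows]
  f <- sweep(unclass(tab), 1L, pmax(n_cells, 1L), "/")
  structure(list(f = f, n_cells = n_cells, clusters = clusters,
                 cic_flags = NULL),
            class = "enrichment_matrix")
}

#' Detect CAR-induced clusters
#'
#' Cluster `c` is a CIC iff the mean fraction of positive-control cells in
#' it is at least `min_ratio` times the mean fraction of negative-control
#' cells AND the negative-control mean is at most `max_neg_fraction`. A zero
#' negative mean with a positive positive mean counts as infinitely
#' enriched.
#'
#' @param em An [cluster_fractions()] result.
#' @param pos_groups,neg_groups Row names of the benchmark-positive and
#'   negative control groups (defaults `pos_28z`/`pos_BBz` and
#'   `neg_TCRminus`/`neg_unstim`).
#' @param min_ratio Minimum positive/negative enrichment ratio (default 2).
#' @param max_neg_fraction Maximum mean negative-control fraction
#'   (default 0.05).
#' @return The input `enrichment_matrix` with `cic_flags` (named logical per
#'   cluster) and `cic_clusters` (the flagged cluster ids) filled in.
#' @export
detect_cics <- function(em, pos_groups = c("pos_28z", "pos_BBz"),
                        neg_groups = c("neg_TCRminus", "neg_unstim"),
                        min_ratio = 2, max_neg_fraction = 0.05) {
  stopifnot(inherits(em, "enrichment_matrix"))
  for (g in c(pos_groups, neg_groups)) {
    if (!g %in% rownames(em$f)) {
      stop("control group missing from enrichment matrix: ", g)
    }
  }
  mean_pos <- colMeans(em$f[pos_groups, , drop = FALSE])
  mean_neg <- colMeans(em$f[neg_groups, , drop = FALSE])
  flags <- mean_neg <= max_neg_fraction & mean_pos > 0 &
    mean_pos >= min_ratio * mean_neg
  em$cic_flags <- flags
  em$cic_clusters <- em$clusters[flags]
  em
}

#' Per-variant CIC enrichment
#'
#' The fraction of each variant's cells that fall into CAR-induced
#' clusters — the screen's measure of CAR activity.
#'
#' @param em An `enrichment_matrix`.
#' @param cic_set Cluster ids to treat as CICs; defaults to the flags set by
#'   [detect_cics()].
#' @return Named numeric vector in `[0, 1]`, one entry per variant row.
#' @export
cic_enrichment <- function(em, cic_set = NULL) {
  stopifnot(inherits(em, "enrichment_matrix"))
  cic_set <- cic_set %||% em$cic_clusters
  if (is.null(cic_set)) stop("no CIC set: run detect_cics() or pass cic_set")
  if (!all(cic_set %in% em$clusters)) {
    stop("cic_set contains unknown cluster ids")
  }
  cols <- match(cic_set, em$clusters)
  rowSums(em$f[, cols, drop = FALSE])
}

#' @method print enrichment_matrix
#' @export
print.enrichment_matrix <- function(x, ...) {
  cat("enrichment_matrix: ", nrow(x$f), " variants x ", ncol(x$f),
      " clusters", sep = "")
  if (!is.null(x$cic_flags)) {
    cat("; CICs: ", paste(x$clusters[x$cic_flags], collapse = ", "),
        sep = "")
  }
  cat("\n")
  invisible(x)
}
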