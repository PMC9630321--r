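# Negative-binomial single-cell count simulator with planted cluster
# structure, variant-to-cluster propensities and benchmark/negative control
# groups. This emulates the data structure of a pooled CAR T-cell screen
# after co-culture: transcriptional clusters, of which a subset are
# CAR-induced (enriched in stimulated benchmark CARs, depleted in
# TCR-negative and unstimulated controls).

#' Configuration for the expression simulator
#'
#' The default propensity design plants `n_cic` CAR-induced clusters (the
#' first `n_cic` cluster ids): benchmark positive controls (`pos_28z`,
#' `pos_BBz`) place 90% of their cells there, negative controls
#' (`neg_TCRminus`, `neg_unstim`) only 5%, and library variants span a
#' graded range of CIC propensities — the planted ground truth against which
#' CIC detection and per-variant enrichment are benchmarked.
#'
#' @param n_genes Number of genes (including `n_mito` mitochondrial genes).
#' @param n_clusters Number of planted clusters.
#' @param n_variants Number of library CAR variants.
#' @param cells_per_variant,cells_per_control Cells simulated per library
#'   variant and per control group.
#' @param variant_propensity Optional `(n_variants + 4) x n_clusters`
#'   stochastic matrix (library variants first, then the four control
#'   groups); rows must sum to 1. `NULL` builds the default design.
#' @param cic_clusters_truth Planted CAR-induced cluster ids (1-based).
#' @param nb_mean,nb_dispersion Negative-binomial baseline mean per gene and
#'   dispersion (`size = 1/dispersion`).
#' @param marker_genes_per_cluster Marker genes planted per cluster.
#' @param marker_lfc Marker log2 fold change (default 2, i.e. 4x).
#' @param mt_fraction_range Range of per-cell mitochondrial count fractions.
#' @param n_mito Number of mitochondrial genes (named `MT-*`).
#' @param variant_labels Optional labels for the library variants.
#' @param seed Integer seed.
#' @return Object of class `expr_sim_config`.
#' @export
expr_sim_config <- function(n_genes = 1000L, n_clusters = 8L,
                            n_variants = 20L, cells_per_variant = 100L,
                            cells_per_control = 250L,
                            variant_propensity = NULL,
                            cic_clusters_truth = 1:5,
                            nb_mean = 2, nb_dispersion = 0.5,
                            marker_genes_per_cluster = 25L,
                            marker_lfc = 2, mt_fraction_range = c(0.01, 0.10),
                            n_mito = 10L, variant_labels = NULL,
                            seed = 1L) {
  stopifnot(n_genes > n_mito + n_clusters * marker_genes_per_cluster,
            n_clusters >= 1L, n_variants >= 1L,
            all(cic_clusters_truth %in% seq_len(n_clusters)),
            nb_mean > 0, nb_dispersion > 0,
            length(mt_fraction_range) == 2L,
            mt_fraction_range[1] >= 0, mt_fraction_range[2] < 1)
  groups <- c("pos_28z", "pos_BBz", "neg_TCRminus", "neg_unstim")
  labels <- variant_labels %||% sprintf("V%02d", seq_len(n_variants))
  stopifnot(length(labels) == n_variants)
  if (is.null(variant_propensity)) {
    variant_propensity <- default_propensity(n_variants, n_clusters,
                                             cic_clusters_truth)
  }
  if (!all(dim(variant_propensity) == c(n_variants + 4L, n_clusters)) ||
      any(abs(rowSums(variant_propensity) - 1) > 1e-8) ||
      any(variant_propensity < 0)) {
    stop("variant_propensity must be a (n_variants + 4) x n_clusters ",
         "stochastic matrix")
  }
  rownames(variant_propensity) <- c(labels, groups)
  # planted rule must hold by construction (ratio >= 2, negatives <= 5%)
  cic <- cic_clusters_truth
  mp <- colMeans(variant_propensity[c("pos_28z", "pos_BBz"), , drop = FALSE])
  mn <- colMeans(variant_propensity[c("neg_TCRminus", "neg_unstim"), ,
                                    drop = FALSE])
  planted <- which(mn <= 0.05 & mp > 0 & mp >= 2 * mn)
  if (!setequal(planted, cic)) {
    stop("propensity rows do not plant the declared CIC set")
  }
  structure(list(n_genes = as.integer(n_genes),
                 n_clusters = as.integer(n_clusters),
                 n_variants = as.integer(n_variants),
                 cells_per_variant = as.integer(cells_per_variant),
                 cells_per_control = as.integer(cells_per_control),
                 variant_propensity = variant_propensity,
                 cic_clusters_truth = as.integer(cic_clusters_truth),
                 nb_mean = nb_mean, nb_dispersion = nb_dispersion,
                 marker_genes_per_cluster = as.integer(marker_genes_per_cluster),
                 marker_lfc = marker_lfc,
                 mt_fraction_range = mt_fraction_range,
                 n_mito = as.integer(n_mito),
                 variant_labels = labels, control_groups = groups,
                 seed = as.integer(seed)),
            class = "expr_sim_config")
}

# Default propensity design: graded CIC enrichment across library variants,
# strong enrichment for positives, depletion for negatives.
default_propensity <- function(n_variants, n_clusters, cic) {
  n_cic <- length(cic)
  non_cic <- setdiff(seq_len(n_clusters), cic)
  mk_row <- function(p_cic) {
    if (n_cic == 0L) return(rep(1 / n_clusters, n_clusters))
    row <- numeric(n_clusters)
    row[cic] <- p_cic / n_cic
    row[non_cic] <- (1 - p_cic) / max(1L, length(non_cic))
    row
  }
  p_var <- seq(0.05, 0.95, length.out = n_variants)
  m <- matrix(0, nrow = n_variants + 4L, ncol = n_clusters)
  for (i in seq_len(n_variants)) m[i, ] <- mk_row(p_var[i])
  m[n_variants + 1L, ] <- mk_row(0.90)   # pos_28z
  m[n_variants + 2L, ] <- mk_row(0.90)   # pos_BBz
  m[n_variants + 3L, ] <- mk_row(0.045)  # neg_TCRminus
  m[n_variants + 4L, ] <- mk_row(0.045)  # neg_unstim
  m
}

#' Simulate a single-cell count matrix with planted structure
#'
#' Draws each cell's cluster from its variant's propensity row, then its
#' counts from a negative binomial with cluster-specific marker up-shifts
#' and a per-cell mitochondrial fraction drawn from `mt_fraction_range`.
#'
#' @param cfg An [expr_sim_config()].
#' @param assignments Optional demultiplexing result (`cells` data.frame from
#'   [demux_cells()] with `status == "single"`): its barcodes and variant
#'   labels replace the generated library cells (the first
#'   `cfg$n_variants` distinct labels are used).
#' @param mtx_dir Optional directory: when given the counts are also written
#'   as an MTX triplet via [write_mtx()].
#' @return `list(counts, truth)`: `counts` a [car_counts()] whose metadata
#'   carries `variant`, `group` and `donor`; `truth` one row per cell with
#'   the planted cluster.
#' @export
simulate_expression <- function(cfg, assignments = NULL, mtx_dir = NULL) {
  stopifnot(inherits(cfg, "expr_sim_config"))
  with_seed(cfg$seed, {
    if (is.null(assignments)) {
      variant <- rep(cfg$variant_labels, each = cfg$cells_per_variant)
      group <- rep("variant", length(variant))
    } else {
      sub <- assignments[assignments$status == "single", , drop = FALSE]
      keep_labels <- head(unique(sub$variant), cfg$n_variants)
      sub <- sub[sub$variant %in% keep_labels, , drop = FALSE]
      variant <- sub$variant
      group <- rep("variant", length(variant))
    }
    for (g in cfg$control_groups) {
      variant <- c(variant, rep(g, cfg$cells_per_control))
      group <- c(group, rep(g, cfg$cells_per_control))
    }
    n_cells <- length(variant)
    barcodes <- if (!is.null(assignments)) {
      c(sub$barcode, random_barcodes(4L * cfg$cells_per_control, 16L))
    } else {
      random_barcodes(n_cells, 16L)
    }
    prop <- cfg$variant_propensity
    row_of <- match(variant, rownames(prop))
    if (anyNA(row_of)) {
      # variants beyond the configured rows: uniform propensity
      prop <- rbind(prop, uniform = rep(1 / cfg$n_clusters, cfg$n_clusters))
      row_of[is.na(row_of)] <- nrow(prop)
    }
    cluster <- vapply(row_of, function(r)
      sample.int(cfg$n_clusters, 1L, prob = prop[r, ]), 0L)
    if (any(tabulate(cluster, cfg$n_clusters) == 0L)) {
      warning("degenerate cluster with zero simulated cells")
    }
    # gene model
    n_mito <- cfg$n_mito
    genes <- c(sprintf("MT-%d", seq_len(n_mito)),
               sprintf("GENE%04d", seq_len(cfg$n_genes - n_mito)))
    base_mu <- rlnorm(cfg$n_genes, meanlog = log(cfg$nb_mean), sdlog = 0.5)
    base_mu[seq_len(n_mito)] <- 0  # mito means set per cell below
    marker_pool <- sample((n_mito + 1L):cfg$n_genes)
    markers <- split(marker_pool[seq_len(cfg$n_clusters *
                                           cfg$marker_genes_per_cluster)],
                     rep(seq_len(cfg$n_clusters),
                         each = cfg$marker_genes_per_cluster))
    depth <- rlnorm(n_cells, 0, 0.1)
    mt_target <- runif(n_cells, cfg$mt_fraction_range[1],
                       cfg$mt_fraction_range[2])
    size <- 1 / cfg$nb_dispersion
    counts <- matrix(0L, nrow = cfg$n_genes, ncol = n_cells)
    up <- 2^cfg$marker_lfc
    for (k in seq_len(cfg$n_clusters)) {
      cells_k <- which(cluster == k)
      if (length(cells_k) == 0L) next
      mu_g <- base_mu
      mu_g[markers[[k]]] <- mu_g[markers[[k]]] * up
      nonmito_total <- sum(mu_g)
      for (j in cells_k) {
        mu_j <- mu_g * depth[j]
        mt_mu <- mt_target[j] / (1 - mt_target[j]) * nonmito_total *
          depth[j] / n_mito
        mu_j[seq_len(n_mito)] <- mt_mu
        counts[, j] <- rnbinom(cfg$n_genes, mu = mu_j, size = size)
      }
    }
    rownames(counts) <- genes
    colnames(counts) <- barcodes
    meta <- data.frame(barcode = barcodes, variant = variant, group = group,
                       donor = "D1")
    cc <- car_counts(counts, genes, barcodes, meta)
    truth <- data.frame(barcode = barcodes, variant = variant, group = group,
                        cluster = cluster)
    if (!is.null(mtx_dir)) write_mtx(cc, mtx_dir)
    list(counts = cc, truth = truth)
  })
}
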