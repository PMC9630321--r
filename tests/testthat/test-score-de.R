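# Pseudo-bulk, PCA, gene-set scoring, rank-sum differential expression.

test_that("pseudobulk is the per-group arithmetic mean", {
  m <- matrix(c(1, 2, 3,
                3, 4, 5,
                5, 6, 10), nrow = 3, byrow = TRUE,
              dimnames = list(paste0("g", 1:3), paste0("c", 1:3)))
  pb <- pseudobulk(m, c("x", "x", "y"))
  expect_equal(pb["x", ], c(g1 = 1.5, g2 = 3.5, g3 = 5.5))
  expect_equal(pb["y", ], c(g1 = 3, g2 = 5, g3 = 10))
  # single-cell group is its own vector; identical cells give the same one
  pb2 <- pseudobulk(m[, c(1, 1, 3)], c("a", "a", "b"))
  expect_equal(pb2["a", ], m[, 1])
})

test_that("pca_embed: duplicated samples, rank-1 gradient, orthogonality", {
  set.seed(3)
  base <- matrix(rnorm(5 * 30), nrow = 5)
  m <- rbind(base, base[2, , drop = FALSE])  # duplicate of sample 2
  p <- pca_embed(m, 4)
  expect_equal(p$scores[2, ], p$scores[6, ])
  expect_true(all(diff(p$var_explained) <= 1e-12))
  expect_lte(sum(p$var_explained), 1 + 1e-12)
  # score columns are orthogonal
  cross <- crossprod(p$scores)
  expect_lt(max(abs(cross[upper.tri(cross)])), 1e-8)
  # planted 1-D gradient: PC1 captures essentially all variance
  grad <- outer(seq(-2, 2, length.out = 8), rnorm(30))
  pg <- pca_embed(grad + rnorm(240, sd = 1e-4), 3)
  expect_gte(pg$var_explained[1], 0.99)
  expect_error(pca_embed(m[1, , drop = FALSE]), "at least 2")
})

test_that("geneset_score equals a naive full-ranking oracle on dense toys", {
  set.seed(19)
  for (rep in 1:5) {
    m <- matrix(rexp(50 * 6), nrow = 50,
                dimnames = list(paste0("g", 1:50), paste0("c", 1:6)))
    m[sample(length(m), 60)] <- 0  # ties at zero
    sets <- list(s1 = paste0("g", sample(50, 3)),
                 s2 = paste0("g", sample(50, 10)))
    r_max <- 30
    sc <- geneset_score(m, sets, r_max = r_max)
    for (j in 1:6) {
      r <- pmin(rank(-m[, j], ties.method = "average"), r_max + 1)
      for (s in names(sets)) {
        idx <- match(sets[[s]], rownames(m))
        n <- length(idx)
        u <- sum(r[idx]) - n * (n + 1) / 2
        expect_lt(abs(sc[j, s] - min(1, max(0, 1 - u / (n * r_max)))),
                  1e-12)
      }
    }
  }
})

test_that("geneset_score boundary values at the analytic extremes", {
  m <- matrix(seq(100, 1, length.out = 100), ncol = 1,
              dimnames = list(paste0("g", 1:100), "c1"))
  # signature = the n top-expressed genes -> U' = 0 -> score exactly 1
  expect_equal(geneset_score(m, list(top = paste0("g", 1:5)),
                             r_max = 50)[1, 1], 1)
  # single signature gene beyond the rank cap -> U' = r_max -> score exactly 0
  expect_equal(geneset_score(m, list(bottom = "g100"), r_max = 50)[1, 1], 0)
  expect_warning(geneset_score(m, list(none = c("zz1", "zz2"))), "no gene")
})

test_that("geneset_summary fold change of the benchmark against itself is 1", {
  sc <- matrix(c(0.2, 0.4, 0.8, 0.6), ncol = 1,
               dimnames = list(NULL, "sig"))
  gs <- geneset_summary(sc, c("V1", "V1", "28z", "28z"), benchmark = "28z")
  expect_equal(gs$fold_change[gs$group == "28z"], 1)
  expect_equal(gs$mean_score[gs$group == "V1"], 0.3)
  expect_equal(gs$fold_change[gs$group == "V1"], 0.3 / 0.7)
})

test_that("rank_sum_de matches wilcox.test and flags extreme separation", {
  set.seed(23)
  m <- matrix(rpois(200 * 40, 2), nrow = 200,
              dimnames = list(sprintf("g%03d", 1:200),
                              sprintf("c%02d", 1:40)))
  m["g001", 1:20] <- m["g001", 1:20] + 30   # group-A-only expression
  norm <- lognormalize(m)
  de <- rank_sum_de(norm, colnames(m)[1:20], colnames(m)[21:40],
                    min_pct = 0, logfc_threshold = 0)
  expect_equal(de$gene[1], "g001")  # minimal p among tested genes
  a <- as.matrix(norm[, 1:20]); b <- as.matrix(norm[, 21:40])
  for (g in c("g001", "g010", "g100")) {
    w <- stats::wilcox.test(a[g, ], b[g, ], exact = FALSE,
                            correct = FALSE)$p.value
    expect_equal(de$p_val[de$gene == g], w, tolerance = 1e-12)
  }
  # BH adjustment is monotone and bounded by 1
  expect_true(all(de$p_adj >= de$p_val - 1e-15))
  expect_true(all(de$p_adj <= 1))
  # guards
  expect_error(rank_sum_de(norm, colnames(m)[1:5], colnames(m)[5:10]),
               "overlap")
  expect_error(rank_sum_de(norm, colnames(m)[1:2], colnames(m)[3:40]),
               "at least 3")
})

test_that("expression-fraction and fold-change prefilters restrict testing", {
  m <- matrix(0L, 4, 20, dimnames = list(c("off", "flat", "de", "fill"),
                                         paste0("c", 1:20)))
  m["flat", ] <- 5L
  m["de", 1:10] <- 12L; m["de", 11:20] <- 1L
  m["fill", 11:20] <- 11L   # balances column totals so "flat" stays flat
  norm <- lognormalize(m)
  de <- rank_sum_de(norm, paste0("c", 1:10), paste0("c", 11:20),
                    min_pct = 0.1, logfc_threshold = 0.25)
  # "off" fails min_pct, "flat" fails the fold-change threshold
  expect_setequal(de$gene, c("de", "fill"))
})
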