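test_that("variability ranking matches a direct sort for every statistic", {
  set.seed(10)
  v <- matrix(rnorm(20 * 8, sd = 2), 20, 8,
              dimnames = list(sprintf("g%02d", 1:20), sprintf("s%d", 1:8)))
  v["g05", ] <- 3                       # constant gene
  v["g09", ] <- c(0, 1, 2, 3, 4, 5, 2, 3)  # range exactly 5
  e <- as_expr(v)
  for (m in c("range", "var", "iqr")) {
    r <- rank_gene_variability(e, m)
    oracle <- switch(m,
                     range = apply(v, 1, function(x) max(x) - min(x)),
                     var = apply(v, 1, var),
                     iqr = apply(v, 1, IQR))
    expect_identical(r$gene, names(sort(oracle, decreasing = TRUE)))
    expect_equal(r$statistic, unname(sort(oracle, decreasing = TRUE)))
  }
  r <- rank_gene_variability(e, "range")
  expect_identical(r$gene[20], "g05")
  expect_equal(r$statistic[r$gene == "g09"], 5)
  expect_error(rank_gene_variability(e, "mad"), "arg")
})

test_that("gene selection applies the range threshold per stage with union", {
  v <- rbind(g1 = c(0, 5, 1, 1),    # range 5 at stage A only
             g2 = c(0, 1, 0, 7),    # range 7 at stage B only
             g3 = c(0, 1, 1, 2))    # never
  colnames(v) <- paste0("s", 1:4)
  e <- as_expr(v, stage = c("A", "A", "B", "B"))
  sel <- select_genes(e, threshold = 5)
  expect_identical(sel$per_stage$A, "g1")
  expect_identical(sel$per_stage$B, "g2")
  expect_setequal(sel$union, c("g1", "g2"))
  expect_length(select_genes(e, threshold = Inf)$union, 0)
  # monotone: lowering the threshold never removes a selected gene
  sel2 <- select_genes(e, threshold = 3)
  expect_true(all(sel$union %in% sel2$union))
})

test_that("selection on the synthetic atlas recovers the signature genes", {
  at <- small_atlas()
  sel <- select_genes(at$expr, threshold = 5)
  memb <- at$truth$signature_membership
  sig <- intersect(names(memb)[!is.na(memb)], rownames(at$expr$values))
  expect_gte(mean(sig %in% sel$union), 0.99)
})

test_that("silhouette separates real regions and dies under label shuffles", {
  at <- small_atlas()
  e <- at$expr
  dis <- e$samples[!e$samples$whole_embryo, ]
  ed <- e
  ed$values <- e$values[, dis$sample]
  ed$samples <- dis
  sel <- select_genes(e, threshold = 5)
  n_sig <- length(sel$union)
  curve <- silhouette_curve(ed, dis$region,
                            gene_counts = round(seq(n_sig, nrow(e$values),
                                                    length.out = 5)))
  expect_gt(curve$silhouette[1], 0.5)
  # adding genes without regional signal degrades the clustering quality
  expect_gt(curve$silhouette[1], curve$silhouette[5])

  # permuted labels: mean silhouette near or below zero
  set.seed(4)
  shuffled <- vapply(1:20, function(i) {
    silhouette_curve(ed, sample(dis$region),
                     gene_counts = n_sig)$silhouette
  }, numeric(1))
  expect_lt(mean(shuffled), 0.05)
  expect_warning(silhouette_curve(ed, dis$region, gene_counts = 1e6),
                 "truncated")
})

test_that("pca_with_null reproduces its definitions and conserves variance", {
  at <- small_atlas()
  sel <- select_genes(at$expr, threshold = 5)
  p <- pca_with_null(at$expr, genes = sel$union, n_permutations = 200,
                     seed = 3)
  # scores equal standardized data times loadings
  z <- t((at$expr$values[rownames(p$loadings),
                         rownames(p$scores)] - p$center) / p$scale)
  expect_equal(unname(p$scores), unname(z %*% p$loadings), tolerance = 1e-8)
  # total variance equals the number of standardized genes
  expect_equal(sum(p$eigenvalues), nrow(p$loadings), tolerance = 1e-8)
  expect_equal(sum(p$percent_variance), 100, tolerance = 1e-6)
  expect_true(all(diff(p$eigenvalues) <= 1e-12))
  expect_warning(pca_with_null(at$expr, genes = sel$union[1:20],
                               n_permutations = 50, seed = 1), "unstable")
})

test_that("a planted gradient is detected and its genes flagged", {
  set.seed(21)
  n <- 30
  grad <- seq(-1, 1, length.out = n)
  v <- matrix(rnorm(80 * n, sd = 1), 80, n,
              dimnames = list(sprintf("g%02d", 1:80), sprintf("s%02d", 1:n)))
  planted <- 1:8
  v[planted, ] <- v[planted, ] * 0.2 + rep(grad * 4, each = 8)
  e <- as_expr(v)
  p <- pca_with_null(e, n_permutations = 500, seed = 6)
  expect_lte(p$eig_pvalue[1], 0.01)
  expect_gte(p$n_significant, 1)
  expect_gte(mean(p$loading_significant[planted, 1]), 0.9)
})

test_that("pure-noise data rarely shows a significant component", {
  # dataset-level type-I calibration of the permutation null at alpha = 1%
  n_data <- 60
  flags <- 0
  for (i in seq_len(n_data)) {
    set.seed(3000 + i)
    v <- matrix(rnorm(40 * 10), 40, 10,
                dimnames = list(sprintf("g%02d", 1:40),
                                sprintf("s%02d", 1:10)))
    p <- pca_with_null(as_expr(v), n_permutations = 250, alpha = 0.01,
                       seed = i)
    flags <- flags + (p$n_significant >= 1)
  }
  expect_lte(flags / n_data, 0.01 + 3 * sqrt(0.01 * 0.99 / n_data))
})

test_that("gene-component correlation identifies aligned genes", {
  at <- small_atlas()
  sel <- select_genes(at$expr, threshold = 5)
  p <- pca_with_null(at$expr, genes = sel$union, n_permutations = 100,
                     seed = 3)
  e2 <- at$expr
  e2$values <- rbind(e2$values,
                     pc_clone = stats::setNames(rep(0, ncol(e2$values)),
                                                colnames(e2$values)))
  e2$values["pc_clone", rownames(p$scores)] <- p$scores[, 1]
  cc <- correlate_genes_to_component(e2, p, component = 1, top_n = 5)
  expect_equal(unname(cc$correlation["pc_clone"]), 1, tolerance = 1e-10)
  e2$values["pc_clone", rownames(p$scores)] <- -p$scores[, 1]
  cc2 <- correlate_genes_to_component(e2, p, component = 1)
  expect_equal(unname(cc2$correlation["pc_clone"]), -1, tolerance = 1e-10)
  # zero-variance genes are excluded with a note
  e2$values["pc_clone", ] <- 1
  expect_message(correlate_genes_to_component(e2, p), "zero-variance")
})

test_that("projection is exact for training samples and linear in mixtures", {
  at <- small_atlas()
  sel <- select_genes(at$expr, threshold = 5)
  p <- pca_with_null(at$expr, genes = sel$union, n_permutations = 100,
                     seed = 3)
  tr <- rownames(p$scores)[1]
  coords <- project_samples(p, at$expr$values[rownames(p$loadings), tr])
  expect_equal(unname(coords[1, ]), unname(p$scores[tr, ]),
               tolerance = 1e-8)
  # the training mean profile projects to the origin
  coords0 <- project_samples(p, p$center)
  expect_equal(unname(coords0[1, ]), rep(0, ncol(p$scores)),
               tolerance = 1e-8)
  # a 50:50 mixture of two samples projects to the score midpoint
  s2 <- rownames(p$scores)[2]
  mix <- (at$expr$values[rownames(p$loadings), tr] +
            at$expr$values[rownames(p$loadings), s2]) / 2
  cm <- project_samples(p, mix)
  expect_equal(unname(cm[1, ]),
               unname((p$scores[tr, ] + p$scores[s2, ]) / 2),
               tolerance = 1e-8)
  expect_error(project_samples(p, mix[-(1:3)]), "missing genes")
})

test_that("region layout assigns samples to nearest barycenters", {
  at <- small_atlas()
  sel <- select_genes(at$expr, threshold = 5)
  p <- pca_with_null(at$expr, genes = sel$union, n_permutations = 100,
                     seed = 3)
  labels <- at$expr$samples$region[match(rownames(p$scores),
                                         at$expr$samples$sample)]
  lay <- region_layout(p$scores, labels)
  # a point exactly at a barycenter belongs to that cell
  bcr <- rownames(lay$barycenters)[1]
  sc2 <- rbind(p$scores[, 1:2], at_bc = lay$barycenters[1, ])
  lay2 <- region_layout(sc2, c(labels, bcr))
  expect_identical(unname(lay2$assignment[nrow(sc2)]), bcr)
  # real labels beat shuffled labels
  set.seed(5)
  sh <- mean(replicate(20,
    mean(region_layout(p$scores, sample(labels))$in_own_cell)))
  expect_gt(mean(lay$in_own_cell), sh)
  # two barycenters: the boundary is the perpendicular bisector
  pts <- rbind(a1 = c(0, 0), a2 = c(0.4, 0), b1 = c(2, 0), b2 = c(1.6, 0),
               probe = c(0.9, 3))   # left of x = 1 -> region A
  expect_warning(region_layout(pts, c("A", "A", "B", "B", "A")),
                 "degenerate")
  expect_identical(unname(suppressWarnings(
    region_layout(pts, c("A", "A", "B", "B", "A"))$assignment[5])), "A")
})

test_that("embeddings have the right shape and fixed-seed determinism", {
  at <- small_atlas()
  sel <- select_genes(at$expr, threshold = 5)
  m <- embed_tsne(at$expr, genes = sel$union, method = "mds")
  expect_identical(dim(m), c(ncol(at$expr$values), 2L))
  expect_identical(m, embed_tsne(at$expr, genes = sel$union, method = "mds"))
  ts <- embed_tsne(at$expr, genes = sel$union, perplexity = 5, seed = 11,
                   method = "tsne")
  expect_identical(dim(ts), c(ncol(at$expr$values), 2L))
  ts2 <- embed_tsne(at$expr, genes = sel$union, perplexity = 5, seed = 11,
                    method = "tsne")
  expect_equal(ts, ts2, tolerance = 1e-6)
})
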