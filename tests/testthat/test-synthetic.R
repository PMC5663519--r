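test_that("generation is deterministic and conserves design quantities", {
  cfg <- atlas_config(n_genes = 300, replicates_per_region = 2,
                      stages = "st12", seed = 11)
  a1 <- generate_atlas(cfg)
  a2 <- generate_atlas(cfg)
  expect_identical(a1$counts$counts, a2$counts$counts)
  expect_identical(a1$truth$prototype, a2$truth$prototype)

  # mixing rows sum to one; prototypes non-negative
  expect_equal(unname(rowSums(a1$truth$mixing)),
               rep(1, nrow(a1$truth$mixing)), tolerance = 1e-9)
  expect_true(all(a1$truth$prototype >= 0))

  # drawn library sizes respect the configured range; realized totals are
  # within sampling noise of them
  lib <- a1$truth$library_sizes
  expect_true(all(lib >= cfg$library_size_range[1] &
                    lib <= cfg$library_size_range[2]))
  dis <- a1$counts$samples$sample[!a1$counts$samples$whole_embryo]
  E <- (a1$truth$prototype %*% t(a1$truth$mixing))[, dis]
  mu <- sweep(E, 2, a1$truth$sample_scale[dis], "*")
  sd_tot <- sqrt(colSums(mu + cfg$nb_dispersion * mu^2))
  expect_true(all(abs(colSums(a1$counts$counts[, dis]) - lib[dis]) <
                    5 * sd_tot))

  # each signature gene belongs to exactly one tissue
  memb <- a1$truth$signature_membership
  expect_true(all(memb[!is.na(memb)] %in% cfg$tissues))
})

test_that("config validation rejects malformed designs", {
  expect_error(atlas_config(contamination = 0.6), "contamination")
  expect_error(atlas_config(n_genes = -5), "positive integer")
  expect_error(atlas_config(n_genes = 10.5), "positive integer")
  expect_error(atlas_config(library_size_range = c(2e6, 1e6)), "increasing")
  expect_error(atlas_config(homeolog_fractions = c(asym_l_down = 0.9,
                                                   asym_s_down = 0.9,
                                                   subfunctionalized = 0,
                                                   similar = 0)), "sum")
})

test_that("noiseless limit reproduces prototype proportions per region", {
  cfg <- atlas_config(n_genes = 200, replicates_per_region = 1,
                      stages = "st12", contamination = 0,
                      nb_dispersion = 0, signature_fraction = 0.3,
                      library_size_range = c(5e6, 5e6), seed = 3)
  a <- generate_atlas(cfg)
  cm <- a$counts$counts
  sm <- a$counts$samples
  for (r in cfg$regions) {
    s <- sm$sample[sm$region == r & !sm$whole_embryo]
    proto <- a$truth$prototype[, cfg$region_tissue[[r]]]
    expected <- proto / sum(proto) * sum(cm[, s])
    # Poisson noise only: relative error on well-expressed genes is tiny
    hi <- expected > 500
    expect_true(mean(abs(cm[hi, s] - expected[hi]) / expected[hi]) < 0.05)
    expect_gt(cor(cm[, s], proto), 0.999)
  }
})

test_that("counts have the stated negative-binomial mean", {
  # 2,000 genes, 5 tissues, 16 dissected samples; over 200 replicate draws
  # the empirical mean at each checked (gene, sample) cell stays within 3
  # standard errors of the analytic mean mu (Var = mu + phi mu^2)
  n_draws <- 200
  probe_g <- seq(1, 2000, by = 97)   # 21 genes
  probe_s <- c(1, 6, 11, 16)
  dev <- 0; se <- 0
  sum_dev <- matrix(0, length(probe_g), length(probe_s))
  sum_var <- matrix(0, length(probe_g), length(probe_s))
  for (d in seq_len(n_draws)) {
    cfg <- atlas_config(n_genes = 2000, regions = c("ANF", "NPa", "NPp",
                                                    "NBa", "NBp", "PPE",
                                                    "NNE", "EXT"),
                        replicates_per_region = 2, stages = "st12",
                        n_we_stages = 1, seed = 20000 + d)
    a <- generate_atlas(cfg)
    sm <- a$counts$samples
    dis <- sm$sample[!sm$whole_embryo]
    expect_length(dis, 16)
    E <- a$truth$prototype %*% t(a$truth$mixing)
    mu <- sweep(E, 2, a$truth$sample_scale, "*")
    m <- mu[probe_g, dis[probe_s]]
    x <- a$counts$counts[probe_g, dis[probe_s]]
    sum_dev <- sum_dev + (x - m)
    sum_var <- sum_var + m + cfg$nb_dispersion * m^2
  }
  z <- abs(sum_dev) / sqrt(sum_var)
  # per-cell |mean - analytic mean| within 3 SE (allow 1 of 84 cells out,
  # the expected multiplicity at the 3-sigma level)
  expect_lte(sum(z > 3), 1)
})

test_that("homeolog injection realizes the configured classes", {
  cfg <- atlas_config(n_genes = 400, replicates_per_region = 2,
                      stages = "st12", seed = 5, n_homeolog_pairs = 20,
                      homeolog_fractions = c(asym_l_down = 0.15,
                                             asym_s_down = 0.35,
                                             subfunctionalized = 0.10,
                                             similar = 0.40),
                      length_fail_fraction = 0.1)
  a <- generate_atlas(cfg)
  b <- inject_homeolog_pairs(a$counts, a$truth, cfg)
  hom <- b$truth$homeologs

  # class bookkeeping is exact when fractions times n are integral
  expect_equal(as.vector(table(factor(hom$class,
                                      c("asym_l_down", "asym_s_down",
                                        "subfunctionalized", "similar")))),
               c(3, 7, 2, 8))
  expect_equal(sum(!hom$length_pass), 2)

  # asymmetric pairs: prototype L:S ratio equals the factor in every tissue
  proto <- b$truth$prototype
  for (i in which(hom$class == "asym_s_down")) {
    expect_equal(unname(proto[hom$gene_l[i], ] / proto[hom$gene_s[i], ]),
                 rep(cfg$homeolog_factor, ncol(proto)))
  }
  # similar pairs: copies equal in expectation
  for (i in which(hom$class == "similar")) {
    expect_equal(proto[hom$gene_l[i], ], proto[hom$gene_s[i], ],
                 ignore_attr = TRUE)
  }
  # subfunctionalized pairs swap dominance in at least one tissue each way
  for (i in which(hom$class == "subfunctionalized")) {
    d <- proto[hom$gene_l[i], cfg$tissues] - proto[hom$gene_s[i], cfg$tissues]
    expect_true(any(d > 0) && any(d < 0))
  }
  # determinism and the pairing metadata contract
  b2 <- inject_homeolog_pairs(a$counts, a$truth, cfg)
  expect_identical(b$counts$counts, b2$counts$counts)
  expect_error(inject_homeolog_pairs(a$counts, a$truth,
    atlas_config(n_genes = 400, n_homeolog_pairs = 300, seed = 5)),
    "n_genes")
})

test_that("similar homeolog copies have equal counts in the noiseless limit", {
  cfg <- atlas_config(n_genes = 200, replicates_per_region = 2,
                      stages = "st12", nb_dispersion = 0, contamination = 0,
                      library_size_range = c(5e6, 5e6),
                      n_homeolog_pairs = 10,
                      homeolog_fractions = c(asym_l_down = 0,
                                             asym_s_down = 0.5,
                                             subfunctionalized = 0,
                                             similar = 0.5),
                      seed = 9)
  a <- generate_atlas(cfg)
  b <- inject_homeolog_pairs(a$counts, a$truth, cfg)
  hom <- b$truth$homeologs
  cm <- b$counts$counts
  sim <- hom[hom$class == "similar", ]
  ratio <- rowSums(cm[sim$gene_l, ]) / rowSums(cm[sim$gene_s, ])
  expect_equal(unname(ratio), rep(1, nrow(sim)), tolerance = 0.05)
  # asymmetric-S-down: region-level L:S count ratio ~ the factor
  asym <- hom[hom$class == "asym_s_down", ]
  ratio_a <- rowSums(cm[asym$gene_l, ]) / pmax(rowSums(cm[asym$gene_s, ]), 1)
  expect_equal(unname(ratio_a), rep(4, nrow(asym)), tolerance = 0.1)
})

test_that("annotation generator plants enrichment and a universal term", {
  cfg <- atlas_config(n_genes = 500, replicates_per_region = 2,
                      stages = "st12", seed = 5)
  a <- generate_atlas(cfg)
  ann <- generate_annotation(cfg, a$truth)
  expect_setequal(ann$gene[ann$term == "ALL"], rownames(a$truth$prototype))

  # a term identical to one tissue's signature set must come out enriched
  memb <- a$truth$signature_membership
  sig1 <- names(memb)[!is.na(memb) & memb == "t1"]
  ann2 <- rbind(ann, data.frame(term = "EXACT", gene = sig1))
  asg <- stats::setNames(ifelse(!is.na(memb) & memb == "t1", 1L, 0L),
                         names(memb))
  er <- enrichment_test(asg, ann2)
  expect_true(er$significant[er$term == "EXACT"])
  expect_equal(min(er$p), er$p[er$term == "EXACT"])
  # the universal term can never be enriched
  expect_false(any(er$significant[er$term == "ALL"]))
})

test_that("odds-ratio-1 annotation yields null-calibrated enrichment", {
  # with no planted enrichment the Fisher test flags about alpha of terms
  cfg <- atlas_config(n_genes = 400, replicates_per_region = 2,
                      stages = "st12", seed = 13, enrichment_odds = 1,
                      n_terms = 40)
  a <- generate_atlas(cfg)
  ann <- generate_annotation(cfg, a$truth)
  set.seed(1)
  asg <- stats::setNames(sample(rep(1:8, length.out = 400)),
                         rownames(a$truth$prototype))
  er <- enrichment_test(asg, ann, p_cutoff = 1, q_cutoff = 1)
  # raw one-sided p <= 0.05 at roughly the nominal rate (conservative
  # because of discreteness); Bonferroni-level calls are absent
  expect_lte(mean(er$p <= 0.05), 0.10)
  expect_false(any(er$p_bonferroni <= 0.05 & er$q_value <= 0.05))
})

test_that("count containers round-trip through plain-text files", {
  cfg <- atlas_config(n_genes = 50, replicates_per_region = 1,
                      stages = "st12", n_we_stages = 2, seed = 2)
  a <- generate_atlas(cfg)
  dir <- withr::local_tempdir()
  write_counts(a$counts, dir)
  back <- read_counts(dir)
  expect_equal(back$counts, a$counts$counts)
  expect_equal(back$samples$region, a$counts$samples$region)
  write_truth(a$truth, dir)
  expect_true(file.exists(file.path(dir, "prototype.tsv")))
})
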