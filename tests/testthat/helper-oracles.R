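# Independent brute-force oracles and fixture builders shared by the suite.
# Each oracle is a direct transcription of the defining formula, kept free
# of any package internals so it can disagree with them.

# population Gini by the raw double sum over all pairs
gini_bruteforce <- function(x) {
  K <- length(x)
  sum(abs(outer(x, x, "-"))) / (2 * K^2 * mean(x))
}

# signed TOM by direct evaluation of the formula, element by element
tom_bruteforce <- function(a) {
  n <- nrow(a)
  ad <- a
  diag(ad) <- 0
  k <- colSums(ad)
  out <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) { out[i, j] <- 1; next }
      num <- sum(ad[i, -c(i, j)] * ad[-c(i, j), j]) + ad[i, j]
      out[i, j] <- num / (min(k[i], k[j]) + 1 - ad[i, j])
    }
  }
  out
}

# biweight midcorrelation of two vectors from the defining weights
bicor_bruteforce <- function(x, y) {
  tr <- function(v) {
    med <- median(v)
    m <- median(abs(v - med))
    if (m == 0) return(v - mean(v))
    u <- (v - med) / (9 * m)
    (v - med) * ((1 - u^2)^2 * (abs(u) < 1))
  }
  a <- tr(x); b <- tr(y)
  sum(a * b) / (sqrt(sum(a^2)) * sqrt(sum(b^2)))
}

# one-sided (enrichment) Fisher p by direct hypergeometric tail summation:
# a successes drawn, group size a+b, term size a+c, universe N
hyper_tail_bruteforce <- function(a, b, c, d) {
  N <- a + b + c + d
  m <- a + c          # term genes
  k <- a + b          # group size
  hi <- min(m, k)
  s <- 0
  for (x in a:hi) s <- s + choose(m, x) * choose(N - m, k - x) / choose(N, k)
  s
}

# two-sided exact binomial p by direct summation of the mass function
binom_two_sided_bruteforce <- function(x, n, p = 0.5) {
  dx <- dbinom(x, n, p)
  sum(dbinom(0:n, n, p)[dbinom(0:n, n, p) <= dx * (1 + 1e-7)])
}

# full TMM: trimmed (30% M, 5% A) precision-weighted mean of log ratios
# against a reference column, factors rescaled to geometric mean 1
tmm_bruteforce <- function(counts, ref = NULL) {
  lib <- colSums(counts)
  if (is.null(ref)) {
    uq <- apply(sweep(counts, 2, lib, "/"), 2, quantile, 0.75)
    ref <- which.min(abs(uq - mean(uq)))
  }
  f <- sapply(seq_len(ncol(counts)), function(j) {
    o <- counts[, ref]; x <- counts[, j]
    keep <- o > 0 & x > 0
    o <- o[keep]; x <- x[keep]
    M <- log2((x / lib[j]) / (o / lib[ref]))
    A <- 0.5 * log2((x / lib[j]) * (o / lib[ref]))
    w <- (lib[j] - x) / (lib[j] * x) + (lib[ref] - o) / (lib[ref] * o)
    finite <- is.finite(M) & is.finite(A) & abs(M) < 1e10
    M <- M[finite]; A <- A[finite]; w <- w[finite]
    if (max(abs(M)) < 1e-6) return(1)
    # rank-based double trimming: drop 30% of M and 5% of A per tail
    n <- length(M)
    loM <- floor(n * 0.30) + 1; hiM <- n + 1 - loM
    loA <- floor(n * 0.05) + 1; hiA <- n + 1 - loA
    keep2 <- rank(M) >= loM & rank(M) <= hiM &
      rank(A) >= loA & rank(A) <= hiA
    if (!any(keep2)) return(1)
    2^(sum(M[keep2] / w[keep2]) / sum(1 / w[keep2]))
  })
  f / exp(mean(log(f)))
}

# expression matrix with planted correlated blocks plus pure-noise rows
make_planted_blocks <- function(sizes, n_noise, n_samples, noise_sd = 0.3,
                                seed = 42) {
  set.seed(seed)
  rows <- list(); labs <- integer(0)
  for (b in seq_along(sizes)) {
    lat <- rnorm(n_samples)
    for (i in seq_len(sizes[b]))
      rows[[length(rows) + 1L]] <- lat + rnorm(n_samples, 0, noise_sd)
    labs <- c(labs, rep(b, sizes[b]))
  }
  for (i in seq_len(n_noise)) {
    rows[[length(rows) + 1L]] <- rnorm(n_samples)
    labs <- c(labs, 0L)
  }
  m <- do.call(rbind, rows)
  rownames(m) <- sprintf("tx%04d", seq_len(nrow(m)))
  colnames(m) <- sprintf("s%02d", seq_len(ncol(m)))
  list(x = m, truth = labs)
}

# wrap a bare matrix as an ea_expr with minimal metadata
as_expr <- function(values, region = "r", stage = "a",
                    whole_embryo = FALSE) {
  n <- ncol(values)
  samples <- data.frame(sample = colnames(values),
                        stage = rep_len(stage, n),
                        region = rep_len(region, n),
                        replicate = seq_len(n),
                        whole_embryo = rep_len(whole_embryo, n))
  structure(list(values = values, factors = rep(1, n), prior_count = 0.5,
                 samples = samples,
                 genes = data.frame(gene = rownames(values))),
            class = "ea_expr")
}

# small normalized atlas ready for NMF / signature tests (cached per session)
small_atlas <- local({
  cache <- NULL
  function(seed = 7, n_genes = 600, n_homeolog_pairs = 0,
           replicates = 3) {
    key <- paste(seed, n_genes, n_homeolog_pairs, replicates)
    if (!is.null(cache) && identical(cache$key, key)) return(cache$value)
    cfg <- atlas_config(n_genes = n_genes, replicates_per_region = replicates,
                        stages = "st12", seed = seed,
                        n_homeolog_pairs = n_homeolog_pairs)
    a <- generate_atlas(cfg)
    if (n_homeolog_pairs > 0)
      a <- inject_homeolog_pairs(a$counts, a$truth, cfg)
    fc <- filter_low_counts(a$counts)
    e <- to_log2_cpm(fc)
    out <- list(cfg = cfg, counts = a$counts, truth = a$truth,
                filtered = fc, expr = e)
    cache <<- list(key = key, value = out)
    out
  }
})
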