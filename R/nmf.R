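#' Max-1 normalization of linear expression
#'
#' Converts log2 expression back to the linear scale and rescales each gene
#' so its maximum over samples is 1 (the input representation for NMF
#' deconvolution). All-zero genes are left all-zero and flagged.
#'
#' @param expr an `ea_expr` object, or a numeric matrix already on the
#'   linear scale (`linear = TRUE`).
#' @param genes optional gene subset.
#' @param samples optional sample subset.
#' @param linear set TRUE when `expr` is a plain linear-scale matrix.
#' @return matrix in `[0, 1]` with attribute `"zero_genes"` listing all-zero
#'   rows.
#' @export
normalize_max1 <- function(expr, genes = NULL, samples = NULL,
                           linear = FALSE) {
  if (inherits(expr, "ea_expr")) {
    v <- expr$values
    if (!is.null(genes)) v <- v[genes, , drop = FALSE]
    if (!is.null(samples)) v <- v[, samples, drop = FALSE]
    lin <- 2^v
  } else {
    lin <- as.matrix(expr)
    if (!is.null(genes)) lin <- lin[genes, , drop = FALSE]
    if (!is.null(samples)) lin <- lin[, samples, drop = FALSE]
    if (!linear) lin <- 2^lin
  }
  if (nrow(lin) == 0) stop("no genes to normalize")
  mx <- apply(lin, 1, max)
  zero <- mx == 0
  mx[zero] <- 1
  out <- lin / mx
  attr(out, "zero_genes") <- rownames(lin)[zero]
  out
}

# one NMF run: Frobenius loss, multiplicative updates (Lee-Seung),
# random nonnegative init; components rescaled so each W column maxes at 1
nmf_run <- function(x, rank, tol = 1e-6, maxit = 2000) {
  n <- nrow(x); m <- ncol(x)
  eps <- 1e-10
  W <- matrix(stats::runif(n * rank), n, rank)
  H <- matrix(stats::runif(rank * m), rank, m)
  err_old <- Inf
  it <- 0L
  nx <- sqrt(sum(x^2))
  repeat {
    it <- it + 1L
    H <- H * (crossprod(W, x) / (crossprod(W) %*% H + eps))
    W <- W * ((x %*% t(H)) / (W %*% tcrossprod(H) + eps))
    if (it %% 10L == 0L || it >= maxit) {
      err <- sqrt(sum((x - W %*% H)^2)) / nx
      if (abs(err_old - err) < tol * max(err_old, 1e-12) || it >= maxit) break
      err_old <- err
    }
  }
  sc <- apply(W, 2, max)
  sc[sc == 0] <- 1
  W <- sweep(W, 2, sc, "/")
  H <- sweep(H, 1, sc, "*")
  dimnames(W) <- list(rownames(x), paste0("nmf", seq_len(rank)))
  dimnames(H) <- list(paste0("nmf", seq_len(rank)), colnames(x))
  list(W = W, H = H, error = err, iterations = it)
}

#' Scan NMF ranks for run-to-run stability
#'
#' For each candidate rank, fits `n_init` NMF runs from random nonnegative
#' initializations, pools all mixing-matrix rows and clusters them
#' (average-linkage on 1 - Pearson correlation, cut at the rank). A rank is
#' robust when exactly `rank` tight clusters emerge, each containing
#' exactly one row from every run, with within-cluster mean pairwise
#' correlation at least `tight_cor`. Ranks above the number of real
#' prototypical tissues fail this: the algorithm no longer converges to a
#' single solution.
#'
#' @param x non-negative matrix from [normalize_max1()].
#' @param ranks integer vector of candidate ranks (each >= 2).
#' @param n_init runs per rank (default 20).
#' @param seed integer seed.
#' @param tight_cor tightness threshold (default 0.95).
#' @param tol,maxit NMF convergence controls.
#' @return object of class `ea_rank_scan`: data.frame with `rank`,
#'   `n_tight_clusters`, `tightness` (minimum within-cluster mean
#'   correlation), `one_per_run`, `robust`.
#' @export
nmf_rank_scan <- function(x, ranks, n_init = 20, seed = 1L,
                          tight_cor = 0.95, tol = 1e-6, maxit = 2000) {
  if (any(ranks < 2)) stop("ranks must be >= 2")
  if (any(ranks > min(dim(x)))) stop("rank exceeds matrix dimensions")
  set.seed(seed)
  rows <- lapply(ranks, function(K) {
    runs <- lapply(seq_len(n_init), function(i)
      nmf_run(x, K, tol = tol, maxit = maxit))
    Hrows <- do.call(rbind, lapply(runs, `[[`, "H"))
    run_id <- rep(seq_len(n_init), each = K)
    keep <- apply(Hrows, 1, stats::sd) > 0
    cc <- suppressWarnings(stats::cor(t(Hrows[keep, , drop = FALSE])))
    cc[is.na(cc)] <- 0
    hc <- stats::hclust(stats::as.dist(1 - cc), method = "average")
    cl <- stats::cutree(hc, k = K)
    tight <- vapply(seq_len(K), function(k) {
      idx <- which(cl == k)
      if (length(idx) < 2) return(1)
      sub <- cc[idx, idx]
      mean(sub[upper.tri(sub)])
    }, numeric(1))
    one_per_run <- all(table(factor(run_id[keep], levels = seq_len(n_init)),
                             cl) == 1)
    n_tight <- sum(tight >= tight_cor)
    data.frame(rank = K, n_tight_clusters = n_tight,
               tightness = min(tight), one_per_run = one_per_run,
               robust = n_tight == K && one_per_run && all(keep))
  })
  structure(do.call(rbind, rows), class = c("ea_rank_scan", "data.frame"))
}

#' @export
print.ea_rank_scan <- function(x, ...) {
  cat("NMF rank-stability scan:\n")
  print.data.frame(x)
  invisible(x)
}

# match the components of `run` to those of `ref` by Pearson correlation of
# H rows: exhaustive best permutation for K <= 8, greedy beyond
match_components <- function(H_ref, H_run, min_cor = 0.5) {
  K <- nrow(H_ref)
  cc <- suppressWarnings(stats::cor(t(H_ref), t(H_run)))
  cc[is.na(cc)] <- 0
  if (K <= 8) {
    perms <- all_permutations(K)
    scores <- apply(perms, 1, function(p) sum(cc[cbind(seq_len(K), p)]))
    best <- perms[which.max(scores), ]
  } else {
    best <- integer(K)
    taken <- rep(FALSE, K)
    for (k in order(apply(cc, 1, max), decreasing = TRUE)) {
      j <- order(cc[k, ], decreasing = TRUE)
      j <- j[!taken[j]][1]
      best[k] <- j
      taken[j] <- TRUE
    }
  }
  matched_cor <- cc[cbind(seq_len(K), best)]
  if (any(matched_cor < min_cor))
    stop("runs could not be aligned unambiguously (matched correlation ",
         sprintf("%.2f", min(matched_cor)),
         "); the chosen rank is likely not robust - re-run nmf_rank_scan")
  best
}

all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    cbind(i, sub + (sub >= i))
  }))
}

#' Fit NMF as the aligned median of many random-initialization runs
#'
#' Runs the NMF algorithm `n_runs` times from random starts at the chosen
#' rank, aligns the components of every run to the best (lowest-error) run
#' by maximal-correlation matching of mixing-matrix rows, and returns the
#' elementwise median of the aligned component and mixing matrices.
#'
#' @param x non-negative matrix from [normalize_max1()].
#' @param rank the chosen (robust) rank.
#' @param n_runs random initializations (default 100).
#' @param seed integer seed.
#' @param tol,maxit NMF convergence controls.
#' @return object of class `ea_nmf`: `W` (genes x rank), `H` (rank x
#'   samples), `rank`, `n_runs`, `seed`, `errors`, `iterations`.
#' @export
nmf_fit_median <- function(x, rank, n_runs = 100, seed = 1L,
                           tol = 1e-6, maxit = 2000) {
  if (rank < 2 || rank > min(dim(x))) stop("invalid rank")
  set.seed(seed)
  runs <- lapply(seq_len(n_runs), function(i)
    nmf_run(x, rank, tol = tol, maxit = maxit))
  ref <- runs[[which.min(vapply(runs, `[[`, numeric(1), "error"))]]
  Ws <- array(NA_real_, c(nrow(x), rank, n_runs))
  Hs <- array(NA_real_, c(rank, ncol(x), n_runs))
  for (i in seq_along(runs)) {
    p <- match_components(ref$H, runs[[i]]$H)
    Ws[, , i] <- runs[[i]]$W[, p, drop = FALSE]
    Hs[, , i] <- runs[[i]]$H[p, , drop = FALSE]
  }
  W <- apply(Ws, c(1, 2), stats::median)
  H <- apply(Hs, c(1, 2), stats::median)
  dimnames(W) <- dimnames(ref$W)
  dimnames(H) <- dimnames(ref$H)
  structure(list(W = W, H = H, rank = rank, n_runs = n_runs, seed = seed,
                 errors = vapply(runs, `[[`, numeric(1), "error"),
                 iterations = vapply(runs, `[[`, numeric(1), "iterations")),
            class = "ea_nmf")
}

#' @export
print.ea_nmf <- function(x, ...) {
  cat(sprintf("ea_nmf: rank %d, median of %d runs; relative error %.4f (median run)\n",
              x$rank, x$n_runs, stats::median(x$errors)))
  invisible(x)
}

#' Extend NMF-tissue expression to all genes
#'
#' With the mixing matrix H fixed, solves the linear system W x H = X by
#' per-gene least squares on the full (all-gene) expression matrix and
#' clips negative entries to 0. For the genes used in fitting, the
#' recovered rows deviate from the fitted component matrix by at most about
#' 10 percent of each gene's highest expression.
#'
#' @param x_full non-negative matrix (all genes x the same samples),
#'   max-1 normalized like the fitting matrix.
#' @param H mixing matrix from [nmf_fit_median()] (or an `ea_nmf`).
#' @return `W_full` matrix (all genes x rank), non-negative.
#' @export
extend_components <- function(x_full, H) {
  if (inherits(H, "ea_nmf")) H <- H$H
  if (ncol(x_full) != ncol(H)) stop("sample mismatch between x_full and H")
  HHt <- tcrossprod(H)
  if (rcond(HHt) < 1e-12) stop("mixing matrix is rank-deficient")
  W <- x_full %*% t(H) %*% solve(HHt)
  W[W < 0] <- 0
  dimnames(W) <- list(rownames(x_full), rownames(H))
  W
}

#' Percent-of-max expression pattern of one gene across NMF-tissues
#'
#' @param W_full matrix from [extend_components()] (or fitted `W`).
#' @param gene gene id.
#' @return named numeric, maximum 100 (all-zero genes give all 0).
#' @export
nmf_pattern <- function(W_full, gene) {
  if (!gene %in% rownames(W_full)) stop("unknown gene: ", gene)
  percent_of_max(W_full[gene, ])
}

#' Percent-of-max average pattern across dissected regions
#'
#' Linear-scale mean expression of a gene per dissected region, rescaled so
#' the highest region is 100.
#'
#' @param expr an `ea_expr` object.
#' @param gene gene id.
#' @param stage optional stage restriction.
#' @return named numeric per region, maximum 100.
#' @export
average_pattern <- function(expr, gene, stage = NULL) {
  if (!gene %in% rownames(expr$values)) stop("unknown gene: ", gene)
  sm <- expr$samples
  use <- !sm$whole_embryo
  if (!is.null(stage)) use <- use & sm$stage == stage
  lin <- 2^expr$values[gene, sm$sample[use]]
  means <- tapply(lin, sm$region[use], mean)
  percent_of_max(means)
}

#' Linear-scale mean expression per dissected region
#'
#' @inheritParams average_pattern
#' @return named numeric per region (linear CPM-scale units).
#' @export
region_means <- function(expr, gene, stage = NULL) {
  sm <- expr$samples
  use <- !sm$whole_embryo
  if (!is.null(stage)) use <- use & sm$stage == stage
  lin <- 2^expr$values[gene, sm$sample[use]]
  tapply(lin, sm$region[use], mean)
}

percent_of_max <- function(x) {
  m <- max(x)
  if (m <= 0) return(stats::setNames(rep(0, length(x)), names(x)))
  100 * x / m
}
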