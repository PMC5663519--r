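#' Rank genes by expression variability
#'
#' Orders genes by a variability statistic of their log2 expression across
#' the given samples: total range (`"range"`), variance (`"var"`) or
#' interquartile range (`"iqr"`).
#'
#' @param expr an `ea_expr` object.
#' @param method one of `"range"`, `"var"`, `"iqr"`.
#' @param samples optional sample ids to restrict to.
#' @return data.frame (`gene`, `statistic`) sorted decreasing.
#' @export
rank_gene_variability <- function(expr, method = c("range", "var", "iqr"),
                                  samples = NULL) {
  method <- match.arg(method)
  v <- expr$values
  if (!is.null(samples)) v <- v[, samples, drop = FALSE]
  if (ncol(v) < 2) stop("need at least 2 samples")
  stat <- switch(method,
                 range = apply(v, 1, function(x) diff(range(x))),
                 var   = apply(v, 1, stats::var),
                 iqr   = apply(v, 1, stats::IQR))
  o <- order(stat, decreasing = TRUE)
  data.frame(gene = rownames(v)[o], statistic = stat[o],
             row.names = NULL)
}

# internal: standardize genes (rows to mean 0, sd 1) and return the
# samples x genes matrix plus centering info; constant genes dropped
standardize_expr <- function(values, warn = TRUE) {
  mu <- rowMeans(values)
  sdv <- apply(values, 1, stats::sd)
  keep <- sdv > 0
  if (!all(keep) && warn)
    warning(sum(!keep), " constant gene(s) dropped before standardization")
  z <- (values[keep, , drop = FALSE] - mu[keep]) / sdv[keep]
  list(z = t(z), center = mu[keep], scale = sdv[keep])
}

#' Silhouette quality of region clustering versus gene-list size
#'
#' For each candidate number of top-variability genes, computes PCA on the
#' standardized expression of those genes and the mean silhouette width of
#' the dissected-region labels in the space of the first 3 component scores
#' (Euclidean distance). Used to decide how many genes to select: the curve
#' drops sharply once genes without real regional differences are included.
#'
#' @param expr an `ea_expr` object.
#' @param labels region label per sample (same order as columns).
#' @param gene_counts integer vector of candidate gene-list sizes.
#' @param method variability statistic passed to [rank_gene_variability()].
#' @return data.frame (`n_genes`, `silhouette`).
#' @export
silhouette_curve <- function(expr, labels, gene_counts,
                             method = "range") {
  labels <- as.character(labels)
  tab <- table(labels)
  if (length(tab) < 2 || any(tab < 2))
    stop("need >= 2 label classes with >= 2 samples each")
  ranking <- rank_gene_variability(expr, method)
  avail <- nrow(ranking)
  if (any(gene_counts > avail)) {
    warning("gene counts above ", avail, " truncated")
    gene_counts <- pmin(gene_counts, avail)
  }
  cl <- as.integer(factor(labels))
  sil <- vapply(gene_counts, function(k) {
    gsel <- ranking$gene[seq_len(k)]
    st <- standardize_expr(expr$values[gsel, , drop = FALSE], warn = FALSE)
    sc <- svd_scores(st$z, ncomp = 3)
    sw <- cluster::silhouette(cl, stats::dist(sc))
    mean(sw[, "sil_width"])
  }, numeric(1))
  data.frame(n_genes = gene_counts, silhouette = sil)
}

svd_scores <- function(z, ncomp) {
  s <- svd(z, nu = min(ncomp, nrow(z) - 1L), nv = 0)
  k <- min(ncomp, length(s$d), ncol(s$u))
  s$u[, seq_len(k), drop = FALSE] %*% diag(s$d[seq_len(k)], k, k)
}

#' Select high-variation genes per stage
#'
#' Within each stage's dissected samples, genes whose log2-expression range
#' meets the threshold (default 5) are selected; the union across stages is
#' the working gene list for axis decoding and deconvolution.
#'
#' @param expr an `ea_expr` object (stage labels in `expr$samples`).
#' @param threshold minimum log2-expression range.
#' @param dissected_only if TRUE (default) whole-embryo samples are ignored.
#' @return object of class `ea_selection`: `per_stage` (named list of gene
#'   vectors), `union`, `threshold`, `method`.
#' @export
select_genes <- function(expr, threshold = 5, dissected_only = TRUE) {
  sm <- expr$samples
  use <- if (dissected_only) !sm$whole_embryo else rep(TRUE, nrow(sm))
  stages <- unique(sm$stage[use])
  per_stage <- lapply(stages, function(st) {
    ids <- sm$sample[use & sm$stage == st]
    rng <- apply(expr$values[, ids, drop = FALSE], 1,
                 function(x) diff(range(x)))
    rownames(expr$values)[rng >= threshold]
  })
  names(per_stage) <- stages
  sel <- structure(list(per_stage = per_stage,
                        union = Reduce(union, per_stage, character(0)),
                        threshold = threshold, method = "range"),
                   class = "ea_selection")
  sel
}

#' @export
print.ea_selection <- function(x, ...) {
  cat(sprintf("ea_selection: range >= %g; %s; union %d genes\n", x$threshold,
              paste(sprintf("%s: %d", names(x$per_stage),
                            lengths(x$per_stage)), collapse = ", "),
              length(x$union)))
  invisible(x)
}

#' PCA with a permutation-calibrated null
#'
#' Standardizes each gene (mean 0, sd 1 across the chosen samples), computes
#' PCA of the samples, and calibrates eigenvalue and loading significance
#' against a null built by independently permuting each gene's values across
#' samples (which destroys gene-sample structure while preserving every
#' gene's marginal distribution). The p-value of the rank-r eigenvalue is
#' the fraction of permuted datasets whose rank-r eigenvalue is at least the
#' observed one, with the standard (1 + exceedances) / (n_perm + 1)
#' correction. A gene's loading on a component is flagged significant when
#' its magnitude falls outside the two-sided permutation null at `alpha`.
#' The number of significant components is the leading run of component
#' p-values at or below `alpha`.
#'
#' @param expr an `ea_expr` object.
#' @param genes gene ids to use (e.g. `select_genes(expr)$union`).
#' @param samples optional sample ids (default: dissected samples only).
#' @param n_permutations permutations for the null (10,000 by default).
#' @param alpha significance level (default 0.01).
#' @param seed integer seed fixing the permutation stream.
#' @return object of class `ea_pca`: `scores` (samples x comps), `loadings`
#'   (genes x comps), `eigenvalues`, `percent_variance`, `eig_pvalue`,
#'   `n_significant`, `loading_significant` (logical genes x comps),
#'   `center`, `scale`, `n_permutations`, `alpha`.
#' @export
pca_with_null <- function(expr, genes = NULL, samples = NULL,
                          n_permutations = 10000, alpha = 0.01,
                          seed = 1L) {
  v <- expr$values
  if (!is.null(genes)) {
    miss <- setdiff(genes, rownames(v))
    if (length(miss) > 0) stop("unknown genes: ",
                               paste(utils::head(miss, 5), collapse = ", "))
    v <- v[genes, , drop = FALSE]
  }
  if (is.null(samples)) samples <- expr$samples$sample[!expr$samples$whole_embryo]
  v <- v[, samples, drop = FALSE]
  if (ncol(v) < 3) stop("need at least 3 samples")
  if (n_permutations < 100)
    warning("fewer than 100 permutations gives unstable p-values")
  st <- standardize_expr(v)
  z <- st$z                                   # samples x genes
  n <- nrow(z); g <- ncol(z)
  r <- min(n - 1L, g)
  sv <- svd(z, nu = r, nv = r)
  eig <- sv$d[seq_len(r)]^2 / (n - 1)
  loadings <- sv$v
  scores <- z %*% loadings
  dimnames(scores) <- list(rownames(z), paste0("PC", seq_len(r)))
  dimnames(loadings) <- list(colnames(z), paste0("PC", seq_len(r)))

  set.seed(seed)
  colidx <- rep(seq_len(g), each = n)
  eig_exceed <- numeric(r)
  load_exceed <- matrix(0, g, r)
  abs_load <- abs(loadings)
  for (p in seq_len(n_permutations)) {
    ord <- order(colidx, stats::runif(n * g))
    zp <- matrix(z[ord], n, g)
    ep <- eigen(tcrossprod(zp), symmetric = TRUE, only.values = FALSE)
    lam <- pmax(ep$values[seq_len(r)], 0) / (n - 1)
    eig_exceed <- eig_exceed + (lam >= eig)
    d <- sqrt(pmax(ep$values[seq_len(r)], 1e-12) )
    vp <- crossprod(zp, ep$vectors[, seq_len(r), drop = FALSE]) %*%
      diag(1 / d, r, r)
    load_exceed <- load_exceed + (abs(vp) >= abs_load)
  }
  eig_p <- (1 + eig_exceed) / (n_permutations + 1)
  load_p <- (1 + load_exceed) / (n_permutations + 1)
  n_sig <- 0L
  for (k in seq_len(r)) {
    if (eig_p[k] <= alpha) n_sig <- n_sig + 1L else break
  }
  structure(list(scores = scores, loadings = loadings, eigenvalues = eig,
                 percent_variance = 100 * eig / g,
                 eig_pvalue = eig_p, n_significant = n_sig,
                 loading_significant = load_p <= alpha,
                 loading_pvalue = load_p,
                 center = st$center, scale = st$scale,
                 n_permutations = n_permutations, alpha = alpha,
                 seed = seed),
            class = "ea_pca")
}

#' @export
print.ea_pca <- function(x, ...) {
  cat(sprintf("ea_pca: %d samples x %d genes; %d significant component(s) at alpha = %g (%d permutations)\n",
              nrow(x$scores), nrow(x$loadings), x$n_significant, x$alpha,
              x$n_permutations))
  k <- min(4, length(x$eigenvalues))
  cat(sprintf("  PC%d: %.1f%% (p = %.3g)\n", seq_len(k),
              x$percent_variance[seq_len(k)], x$eig_pvalue[seq_len(k)]),
      sep = "")
  invisible(x)
}

#' Correlate genes to a principal component
#'
#' Pearson correlation of each gene's (unstandardized) expression with the
#' score of one component, with the most positively and most negatively
#' correlated genes extracted (default top 60 per direction). Zero-variance
#' genes are excluded with a message.
#'
#' @param expr an `ea_expr` object.
#' @param pca an `ea_pca` from [pca_with_null()].
#' @param component component number.
#' @param top_n genes to report per direction.
#' @return list: `correlation` (named, sorted decreasing), `top_positive`,
#'   `top_negative`.
#' @export
correlate_genes_to_component <- function(expr, pca, component = 1,
                                         top_n = 60) {
  sc <- pca$scores[, component]
  v <- expr$values[, rownames(pca$scores), drop = FALSE]
  sdv <- apply(v, 1, stats::sd)
  if (any(sdv == 0))
    message(sum(sdv == 0), " zero-variance gene(s) excluded from correlation")
  v <- v[sdv > 0, , drop = FALSE]
  r <- as.vector(stats::cor(t(v), sc))
  names(r) <- rownames(v)
  r <- sort(r, decreasing = TRUE)
  list(correlation = r,
       top_positive = names(r)[seq_len(min(top_n, length(r)))],
       top_negative = rev(names(r))[seq_len(min(top_n, length(r)))])
}

#' Project new samples onto fitted components
#'
#' Standardizes the new profiles with the training means and standard
#' deviations, then multiplies by the loadings; a training sample projects
#' onto its stored scores and the mean profile projects to the origin.
#'
#' @param pca an `ea_pca` object.
#' @param new_expr numeric matrix (genes x new samples) or vector covering
#'   the genes the PCA was fitted on.
#' @return matrix of component coordinates (samples x components).
#' @export
project_samples <- function(pca, new_expr) {
  if (is.vector(new_expr)) new_expr <- matrix(new_expr,
                                              dimnames = list(names(new_expr),
                                                              "sample"))
  need <- rownames(pca$loadings)
  miss <- setdiff(need, rownames(new_expr))
  if (length(miss) > 0)
    stop("missing genes: ", paste(utils::head(miss, 10), collapse = ", "),
         if (length(miss) > 10) sprintf(" (+%d more)", length(miss) - 10))
  z <- (new_expr[need, , drop = FALSE] - pca$center) / pca$scale
  t(z) %*% pca$loadings
}

#' Region barycenters and Voronoi assignment in component space
#'
#' Computes the barycenter of each region's samples in a 2-D component
#' plane and assigns every sample to the Voronoi cell of its nearest
#' barycenter (the tessellation is exactly the nearest-barycenter
#' partition of the plane).
#'
#' @param scores samples x components matrix (e.g. `pca$scores`).
#' @param labels region label per sample.
#' @param dims the two component columns to use.
#' @return object of class `ea_layout`: `barycenters` (region x 2),
#'   `assignment` (nearest-barycenter region per sample), `in_own_cell`
#'   (logical), `degenerate` (TRUE when barycenters are collinear).
#' @export
region_layout <- function(scores, labels, dims = c(1, 2)) {
  labels <- as.character(labels)
  xy <- scores[, dims, drop = FALSE]
  bc <- do.call(rbind, lapply(split(seq_along(labels), labels),
                              function(i) colMeans(xy[i, , drop = FALSE])))
  degenerate <- FALSE
  if (nrow(bc) >= 3) {
    ctr <- sweep(bc, 2, colMeans(bc))
    if (qr(ctr)$rank < 2) degenerate <- TRUE
  } else degenerate <- TRUE
  if (degenerate) warning("barycenters are collinear/degenerate; tessellation is not 2-D")
  d2 <- outer(rowSums(xy^2), rep(1, nrow(bc))) -
    2 * xy %*% t(bc) + outer(rep(1, nrow(xy)), rowSums(bc^2))
  assignment <- rownames(bc)[apply(d2, 1, which.min)]
  structure(list(barycenters = bc, assignment = assignment,
                 labels = labels, in_own_cell = assignment == labels,
                 degenerate = degenerate),
            class = "ea_layout")
}

#' @export
print.ea_layout <- function(x, ...) {
  cat(sprintf("ea_layout: %d barycenters; %.0f%% of samples in their own region's cell\n",
              nrow(x$barycenters), 100 * mean(x$in_own_cell)))
  invisible(x)
}

#' Low-dimensional embedding of samples (tSNE or classical MDS)
#'
#' `method = "tsne"` delegates to the scikit-learn TSNE implementation
#' through the `python` interpreter on the PATH (no tSNE internals live in
#' this package); `method = "mds"` uses [stats::cmdscale()] on Euclidean
#' distances. Both operate on samples x genes standardized expression.
#'
#' @param expr an `ea_expr` object.
#' @param genes optional gene subset.
#' @param perplexity tSNE perplexity (7 or 9 are sensible for small designs).
#' @param seed random seed for tSNE.
#' @param method `"tsne"` or `"mds"`.
#' @return samples x 2 coordinate matrix.
#' @export
embed_tsne <- function(expr, genes = NULL, perplexity = 7, seed = 1L,
                       method = c("tsne", "mds")) {
  method <- match.arg(method)
  v <- expr$values
  if (!is.null(genes)) v <- v[genes, , drop = FALSE]
  st <- standardize_expr(v, warn = FALSE)
  if (method == "mds") {
    out <- stats::cmdscale(stats::dist(st$z), k = 2)
    colnames(out) <- c("dim1", "dim2")
    return(out)
  }
  if (Sys.which("python") == "")
    stop("method = 'tsne' needs a python interpreter with scikit-learn on the PATH")
  fin <- tempfile(fileext = ".tsv"); fout <- tempfile(fileext = ".tsv")
  on.exit(unlink(c(fin, fout)), add = TRUE)
  utils::write.table(st$z, fin, sep = "\t", row.names = FALSE,
                     col.names = FALSE)
  code <- sprintf(paste0(
    "import numpy as np\nfrom sklearn.manifold import TSNE\n",
    "x = np.loadtxt(%s, delimiter='\\t')\n",
    "e = TSNE(n_components=2, perplexity=%g, random_state=%d,\n",
    "         init='pca').fit_transform(x)\n",
    "np.savetxt(%s, e, delimiter='\\t')\n"),
    deparse(fin), perplexity, as.integer(seed), deparse(fout))
  res <- system2("python", c("-c", shQuote(code)), stdout = TRUE,
                 stderr = TRUE)
  if (!file.exists(fout))
    stop("tSNE backend failed: ", paste(res, collapse = "\n"))
  out <- as.matrix(utils::read.table(fout, sep = "\t"))
  dimnames(out) <- list(rownames(st$z), c("dim1", "dim2"))
  out
}
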