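#' Filter genes with too few counts
#'
#' Retains exactly the genes with at least `min_count` counts in at least
#' `min_samples` samples (defaults: 10 counts in 2 samples). Gene order is
#' preserved; the operation is idempotent.
#'
#' @param counts an [ea_counts()] object.
#' @param min_count minimum count per sample.
#' @param min_samples minimum number of samples reaching `min_count`.
#' @return the filtered `ea_counts`.
#' @export
filter_low_counts <- function(counts, min_count = 10, min_samples = 2) {
  stopifnot(inherits(counts, "ea_counts"))
  keep <- rowSums(counts$counts >= min_count) >= min_samples
  if (!any(keep)) warning("no genes pass the low-count filter")
  counts[keep, ]
}

#' TMM scaling factors
#'
#' Per-sample normalization factors from the trimmed mean of M-values:
#' log-ratios (M) against a reference sample are trimmed (30 percent of
#' M-values and 5 percent of A-values per tail) and averaged with
#' precision weights; factors are rescaled to geometric mean 1. Computed
#' with edgeR, the standard implementation of the method.
#'
#' @param counts an [ea_counts()] object (already low-count filtered).
#' @param reference sample id to normalize against, or `NULL` for the
#'   automatic choice (sample whose upper quartile is closest to the mean).
#' @return named numeric vector of factors, one per sample.
#' @export
tmm_factors <- function(counts, reference = NULL) {
  stopifnot(inherits(counts, "ea_counts"))
  tot <- colSums(counts$counts)
  if (any(tot == 0))
    stop("sample(s) with all-zero counts: ",
         paste(colnames(counts$counts)[tot == 0], collapse = ", "))
  ref <- NULL
  if (!is.null(reference)) {
    ref <- match(reference, colnames(counts$counts))
    if (is.na(ref)) stop("unknown reference sample: ", reference)
  }
  f <- edgeR::calcNormFactors(counts$counts, method = "TMM",
                              refColumn = ref,
                              logratioTrim = 0.3, sumTrim = 0.05)
  f <- f / exp(mean(log(f)))   # geometric mean exactly 1
  stats::setNames(f, colnames(counts$counts))
}

#' Normalize counts to log2-CPM
#'
#' `log2((count + prior) / (library size x TMM factor) * 1e6)`. The prior
#' count keeps zeros finite; values are monotone in the count.
#'
#' @param counts an [ea_counts()] object.
#' @param factors per-sample factors from [tmm_factors()]; defaults to
#'   computing them.
#' @param prior_count pseudo-count added to every count (default 0.5).
#' @return an `ea_expr` object: `values` (log2-CPM matrix), `factors`,
#'   `prior_count`, plus the sample and gene metadata carried over.
#' @export
to_log2_cpm <- function(counts, factors = NULL, prior_count = 0.5) {
  stopifnot(inherits(counts, "ea_counts"))
  if (is.null(factors)) factors <- tmm_factors(counts)
  eff <- colSums(counts$counts) * factors[colnames(counts$counts)]
  if (any(!is.finite(eff)) || any(eff <= 0))
    stop("non-positive effective library size")
  values <- log2(sweep(counts$counts + prior_count, 2, eff, "/") * 1e6)
  structure(list(values = values, factors = factors,
                 prior_count = prior_count,
                 samples = counts$samples, genes = counts$genes),
            class = "ea_expr")
}

#' @export
print.ea_expr <- function(x, ...) {
  cat(sprintf("ea_expr: log2-CPM, %d genes x %d samples (prior %.2g)\n",
              nrow(x$values), ncol(x$values), x$prior_count))
  invisible(x)
}

#' Linear-scale CPM
#'
#' Counts per million after TMM correction, without log transform or prior.
#'
#' @inheritParams to_log2_cpm
#' @return numeric matrix of CPM values.
#' @export
cpm_matrix <- function(counts, factors = NULL) {
  stopifnot(inherits(counts, "ea_counts"))
  if (is.null(factors)) factors <- tmm_factors(counts)
  eff <- colSums(counts$counts) * factors[colnames(counts$counts)]
  sweep(counts$counts, 2, eff, "/") * 1e6
}

#' Mean-variance precision weights
#'
#' Optional per-observation weights for the moderated homeolog test: a
#' lowess fit of sqrt standard deviation against mean log2 count, evaluated
#' at each observation's fitted log-count, inverted to a precision
#' (voom-style). All other pipeline stages use unweighted log2-CPM.
#'
#' @param counts an [ea_counts()] object.
#' @param expr the matching `ea_expr`.
#' @return numeric matrix of weights, same shape as `expr$values`.
#' @export
precision_weights <- function(counts, expr) {
  stopifnot(inherits(counts, "ea_counts"), inherits(expr, "ea_expr"))
  mean_lc <- rowMeans(expr$values)
  sd_g <- apply(expr$values, 1, stats::sd)
  lo <- stats::lowess(mean_lc, sqrt(sd_g), f = 0.5)
  fun <- stats::approxfun(lo$x, pmax(lo$y, 1e-4), rule = 2)
  w <- matrix(1 / fun(as.vector(expr$values))^4, nrow(expr$values),
              ncol(expr$values))
  dimnames(w) <- dimnames(expr$values)
  w
}

#' Write an expression matrix to TSV
#'
#' @param expr an `ea_expr` object.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_expr <- function(expr, path) {
  utils::write.table(data.frame(gene = rownames(expr$values), expr$values,
                                check.names = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
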