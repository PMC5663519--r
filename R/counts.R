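#' Build a count-matrix container
#'
#' Bundles an integer gene-by-sample count matrix with its sample and gene
#' metadata. This is the entry object of the pipeline: the synthetic-atlas
#' generator returns one, and all normalization starts from one.
#'
#' @param counts integer matrix, genes in rows, samples in columns. Dimnames
#'   are required and must match the metadata tables.
#' @param samples data.frame with one row per sample: columns `sample`,
#'   `stage`, `region`, `replicate`, `whole_embryo` (logical).
#' @param genes data.frame with one row per gene: columns `gene`,
#'   `ortholog`, `suffix` (`"l"`, `"s"` or `NA`), `length` (nt),
#'   `arm` (`"L"`, `"S"` or `NA`).
#' @return An object of class `ea_counts`.
#' @export
ea_counts <- function(counts, samples, genes) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) && nrow(counts) > 0)
    stop("`counts` must have row (gene) names")
  if (is.null(colnames(counts)))
    stop("`counts` must have column (sample) names")
  if (anyDuplicated(rownames(counts))) stop("gene ids must be unique")
  if (anyDuplicated(colnames(counts))) stop("sample ids must be unique")
  if (any(counts < 0)) stop("counts must be non-negative")
  if (any(counts != round(counts))) stop("counts must be integers")
  samples <- as.data.frame(samples)
  genes <- as.data.frame(genes)
  if (!identical(samples$sample, colnames(counts)))
    stop("sample metadata does not match count matrix columns")
  rn <- rownames(counts)
  if (is.null(rn)) rn <- character(0)
  if (!identical(as.character(genes$gene), rn))
    stop("gene metadata does not match count matrix rows")
  structure(list(counts = counts, samples = samples, genes = genes),
            class = "ea_counts")
}

#' @export
print.ea_counts <- function(x, ...) {
  cat(sprintf("ea_counts: %d genes x %d samples\n",
              nrow(x$counts), ncol(x$counts)))
  nwe <- sum(x$samples$whole_embryo)
  cat(sprintf("  dissected samples: %d (%d regions), whole-embryo: %d\n",
              ncol(x$counts) - nwe,
              length(unique(x$samples$region[!x$samples$whole_embryo])), nwe))
  invisible(x)
}

#' @export
dim.ea_counts <- function(x) dim(x$counts)

#' Subset a count container by gene and/or sample
#'
#' @param x an `ea_counts` object.
#' @param i gene selector (names, indices or logical).
#' @param j sample selector.
#' @param ... ignored.
#' @return an `ea_counts` restricted to the selection, order preserved.
#' @export
`[.ea_counts` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$counts))
  if (missing(j)) j <- seq_len(ncol(x$counts))
  ea_counts(x$counts[i, j, drop = FALSE],
            x$samples[match(colnames(x$counts[, j, drop = FALSE]),
                            x$samples$sample), , drop = FALSE],
            x$genes[match(rownames(x$counts[i, , drop = FALSE]),
                          x$genes$gene), , drop = FALSE])
}

#' Write a count container to plain-text files
#'
#' Writes `counts.tsv` (genes x samples), `samples.tsv` and `genes.tsv`
#' into `dir`.
#'
#' @param x an `ea_counts` object.
#' @param dir output directory, created if absent.
#' @return `dir`, invisibly.
#' @export
write_counts <- function(x, dir) {
  stopifnot(inherits(x, "ea_counts"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  df <- data.frame(gene = rownames(x$counts), x$counts, check.names = FALSE)
  utils::write.table(df, file.path(dir, "counts.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(x$samples, file.path(dir, "samples.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(x$genes, file.path(dir, "genes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Read a count container written by [write_counts()]
#'
#' @param dir directory holding `counts.tsv`, `samples.tsv`, `genes.tsv`.
#' @return an `ea_counts` object.
#' @export
read_counts <- function(dir) {
  df <- utils::read.table(file.path(dir, "counts.tsv"), sep = "\t",
                          header = TRUE, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$gene
  samples <- utils::read.table(file.path(dir, "samples.tsv"), sep = "\t",
                               header = TRUE)
  genes <- utils::read.table(file.path(dir, "genes.tsv"), sep = "\t",
                             header = TRUE)
  ea_counts(m, samples, genes)
}
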