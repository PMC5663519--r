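#' Filter transcripts for co-expression analysis
#'
#' Keeps transcripts whose normalized CPM exceeds 50 in at least one sample,
#' or whose summed CPM across all samples exceeds 40. (The second disjunct
#' is strictly weaker than the first whenever a single sample passes 50; it
#' only adds transcripts expressed at low level in many samples.)
#'
#' @param cpm numeric matrix of linear CPM values (transcripts x samples),
#'   e.g. from [cpm_matrix()] over all samples.
#' @param max_cpm single-sample threshold (default 50).
#' @param sum_cpm summed threshold (default 40).
#' @return character vector of retained transcript ids.
#' @export
wgcna_filter <- function(cpm, max_cpm = 50, sum_cpm = 40) {
  keep <- apply(cpm, 1, max) > max_cpm | rowSums(abs(cpm)) > sum_cpm
  rownames(cpm)[keep]
}

#' Biweight midcorrelation matrix
#'
#' Robust correlation based on the median and the median absolute
#' deviation: observations are weighted by `(1 - u^2)^2` with
#' `u = (x - median) / (9 mad)` and zero weight beyond `|u| >= 1`.
#' Transcripts with zero MAD fall back to the Pearson transform
#' (standard practice when the median absolute deviation degenerates).
#'
#' @param x numeric matrix, variables in columns.
#' @param y optional second matrix; default correlates `x` with itself.
#' @return correlation matrix in `[-1, 1]`.
#' @export
bicor_matrix <- function(x, y = NULL) {
  bw <- function(m) {
    apply(m, 2, function(col) {
      med <- stats::median(col)
      mad0 <- stats::median(abs(col - med))
      if (mad0 == 0) {
        a <- col - mean(col)
      } else {
        u <- (col - med) / (9 * mad0)
        w <- (1 - u^2)^2 * (abs(u) < 1)
        a <- (col - med) * w
      }
      nrm <- sqrt(sum(a^2))
      if (nrm == 0) rep(0, length(col)) else a / nrm
    })
  }
  ax <- bw(x)
  ay <- if (is.null(y)) ax else bw(y)
  out <- crossprod(ax, ay)
  pmin(pmax(out, -1), 1)
}

#' Signed adjacency from soft-thresholded biweight midcorrelation
#'
#' `a_ij = ((1 + bicor(x_i, x_j)) / 2) ^ power`; anticorrelated transcripts
#' get adjacency near 0, so the network sign structure is preserved.
#'
#' @param expr an `ea_expr` object or numeric matrix (transcripts x
#'   samples).
#' @param power soft-threshold power (default 22).
#' @param transcripts optional subset of transcript ids.
#' @return symmetric adjacency matrix in `[0, 1]` with unit diagonal.
#' @export
signed_adjacency <- function(expr, power = 22, transcripts = NULL) {
  v <- if (inherits(expr, "ea_expr")) expr$values else as.matrix(expr)
  if (!is.null(transcripts)) v <- v[transcripts, , drop = FALSE]
  b <- bicor_matrix(t(v))
  a <- ((1 + b) / 2)^power
  diag(a) <- 1
  a
}

#' Unsigned adjacency from soft-thresholded biweight midcorrelation
#'
#' `a_ij = |bicor(x_i, x_j)| ^ power`; strong negative associations get
#' adjacency near 1, which is what the seed-gene network construction needs
#' to retrieve anticorrelated partners.
#'
#' @inheritParams signed_adjacency
#' @return symmetric adjacency matrix in `[0, 1]` with unit diagonal.
#' @export
unsigned_adjacency <- function(expr, power = 22, transcripts = NULL) {
  v <- if (inherits(expr, "ea_expr")) expr$values else as.matrix(expr)
  if (!is.null(transcripts)) v <- v[transcripts, , drop = FALSE]
  b <- bicor_matrix(t(v))
  a <- abs(b)^power
  diag(a) <- 1
  a
}

#' Scale-free topology fit across candidate soft powers
#'
#' For each power: builds the (signed by default) adjacency, computes each
#' node's connectivity `k`, bins `k` into equal-width bins and regresses
#' `log10 p(k)` on `log10 k` over occupied bins; reports the fit R-squared
#' and the mean connectivity. Mean connectivity is non-increasing in power.
#'
#' @param expr an `ea_expr` object or matrix (transcripts x samples).
#' @param powers integer vector of candidate powers.
#' @param type `"signed"` or `"unsigned"`.
#' @param n_bins connectivity histogram bins (default 10).
#' @return data.frame (`power`, `r_squared`, `slope`, `mean_connectivity`).
#' @export
scale_free_fit <- function(expr, powers = c(1, 2, 4, 6, 8, 10, 14, 18, 22,
                                            26, 30),
                           type = c("signed", "unsigned"), n_bins = 10) {
  type <- match.arg(type)
  v <- if (inherits(expr, "ea_expr")) expr$values else as.matrix(expr)
  if (nrow(v) < 20) stop("need at least 20 transcripts")
  if (any(apply(v, 1, stats::sd) == 0)) stop("constant transcript(s) present")
  b <- bicor_matrix(t(v))
  base <- if (type == "signed") (1 + b) / 2 else abs(b)
  diag(base) <- 0
  rows <- lapply(powers, function(p) {
    a <- base^p
    k <- colSums(a)
    fit <- scale_free_r2(k, n_bins)
    data.frame(power = p, r_squared = fit$r2, slope = fit$slope,
               mean_connectivity = mean(k))
  })
  do.call(rbind, rows)
}

scale_free_r2 <- function(k, n_bins = 10) {
  k <- k[k > 0]
  if (length(k) < n_bins) n_bins <- max(2L, length(k) %/% 2L)
  if (diff(range(k)) < 1e-12)   # all-equal connectivity: no law to fit
    return(list(r2 = NA_real_, slope = NA_real_))
  br <- seq(min(k), max(k), length.out = n_bins + 1)
  bin <- cut(k, br, include.lowest = TRUE)
  dk <- tapply(k, bin, mean)
  pk <- tapply(k, bin, length) / length(k)
  ok <- !is.na(dk) & pk > 0
  if (sum(ok) < 3) return(list(r2 = NA_real_, slope = NA_real_))
  fit <- stats::lm(log10(pk[ok]) ~ log10(dk[ok]))
  list(r2 = summary(fit)$r.squared, slope = unname(stats::coef(fit)[2]))
}

#' Signed topological overlap matrix
#'
#' `TOM_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij)` with
#' unit diagonal; the dissimilarity `1 - TOM` feeds the clustering tree.
#' Two transcripts overlap strongly when they are adjacent and share
#' neighbours.
#'
#' @param adjacency symmetric matrix in `[0, 1]` from
#'   [signed_adjacency()].
#' @return list `tom` and `dissimilarity` (both symmetric, `tom` diag 1).
#' @export
topological_overlap <- function(adjacency) {
  if (!isSymmetric(unname(adjacency), tol = 1e-8))
    stop("adjacency must be symmetric")
  a <- adjacency
  diag(a) <- 0
  k <- colSums(a)
  num <- a %*% a + a
  denom <- outer(k, k, pmin) + 1 - a
  tom <- num / denom
  diag(tom) <- 1
  dimnames(tom) <- dimnames(adjacency)
  list(tom = tom, dissimilarity = 1 - tom)
}

#' Cluster transcripts into co-expression groups
#'
#' Average-linkage hierarchical clustering of the TOM dissimilarity,
#' followed by a simplified dynamic cut: the tree is cut at a height
#' determined by the deep-split level (deeper split = lower cut = more,
#' smaller clusters), clusters below `min_size` are dissolved into group 0
#' (unassigned), and - mirroring a cut that does not respect the dendrogram
#' for borderline members - unassigned transcripts are reassigned to the
#' nearest retained cluster when their average dissimilarity to it is below
#' the cut height. Groups are relabeled by decreasing size: group 1 is
#' always the largest; 0 stays unassigned.
#'
#' @param dissimilarity square matrix from [topological_overlap()].
#' @param min_size minimal transcripts per group (default 15).
#' @param deep_split integer 0-4 (default 4).
#' @param reassign reassign unlabeled transcripts to a close cluster
#'   (default TRUE).
#' @return object of class `ea_groups`: `assignment` (named integer, 0 =
#'   unassigned), `tree` (hclust), `cut_height`, `min_size`, `deep_split`,
#'   `sizes` (per non-zero group, decreasing).
#' @export
cluster_groups <- function(dissimilarity, min_size = 15, deep_split = 4,
                           reassign = TRUE) {
  if (nrow(dissimilarity) != ncol(dissimilarity))
    stop("dissimilarity must be square")
  if (!deep_split %in% 0:4) stop("deep_split must be 0..4")
  n <- nrow(dissimilarity)
  ids <- rownames(dissimilarity)
  if (is.null(ids)) ids <- paste0("tx", seq_len(n))
  if (n < min_size) {
    warning("fewer transcripts than min_size: all unassigned")
    return(structure(list(assignment = stats::setNames(integer(n), ids),
                          tree = NULL, cut_height = NA_real_,
                          min_size = min_size, deep_split = deep_split,
                          sizes = integer(0)),
                     class = "ea_groups"))
  }
  tree <- stats::hclust(stats::as.dist(dissimilarity), method = "average")
  h <- tree$height
  h5 <- stats::quantile(h, 0.05)
  frac <- c(0.95, 0.90, 0.85, 0.80, 0.75)[deep_split + 1]
  cut_height <- h5 + frac * (max(h) - h5)
  raw <- stats::cutree(tree, h = cut_height)
  keep_ids <- names(which(table(raw) >= min_size))
  lab <- ifelse(raw %in% as.integer(keep_ids), raw, 0L)
  if (reassign && any(lab == 0L) && length(keep_ids) > 0) {
    for (i in which(lab == 0L)) {
      avg <- vapply(as.integer(keep_ids), function(cid)
        mean(dissimilarity[i, lab == cid]), numeric(1))
      j <- which.min(avg)
      if (avg[j] < cut_height) lab[i] <- as.integer(keep_ids)[j]
    }
    # reassignment cannot create an undersized group, only grow kept ones
  }
  sizes <- sort(table(lab[lab != 0L]), decreasing = TRUE)
  relabel <- stats::setNames(seq_along(sizes), names(sizes))
  assignment <- ifelse(lab == 0L, 0L, relabel[as.character(lab)])
  names(assignment) <- ids
  structure(list(assignment = assignment, tree = tree,
                 cut_height = unname(cut_height), min_size = min_size,
                 deep_split = deep_split,
                 sizes = as.integer(sizes)),
            class = "ea_groups")
}

#' @export
print.ea_groups <- function(x, ...) {
  cat(sprintf("ea_groups: %d groups (largest %s, smallest %s), %d unassigned of %d transcripts\n",
              length(x$sizes),
              if (length(x$sizes)) x$sizes[1] else NA,
              if (length(x$sizes)) x$sizes[length(x$sizes)] else NA,
              sum(x$assignment == 0), length(x$assignment)))
  invisible(x)
}

#' Functional-term enrichment of co-expression groups
#'
#' One-sided Fisher's exact test of each (group, term) 2x2 table against
#' the background, with Bonferroni adjustment over all tests and
#' Benjamini-Hochberg q-values; a pair is significant when both the
#' adjusted p and the q-value are at or below the cutoffs (default 5
#' percent each).
#'
#' @param groups an `ea_groups` object or named integer vector.
#' @param annotation data.frame with columns `term`, `gene`.
#' @param background gene universe (default: all transcripts in `groups`).
#' @param p_cutoff Bonferroni-adjusted p cutoff.
#' @param q_cutoff BH q-value cutoff.
#' @return data.frame per (group, term): overlap counts, odds ratio, raw
#'   `p`, `p_bonferroni`, `q_value`, `significant`.
#' @export
enrichment_test <- function(groups, annotation, background = NULL,
                            p_cutoff = 0.05, q_cutoff = 0.05) {
  asg <- if (inherits(groups, "ea_groups")) groups$assignment else groups
  if (is.null(background)) background <- names(asg)
  if (length(background) == 0) stop("empty background")
  asg <- asg[names(asg) %in% background]
  terms <- split(annotation$gene, annotation$term)
  terms <- lapply(terms, intersect, background)
  N <- length(background)
  gids <- sort(unique(asg[asg > 0]))
  rows <- list()
  for (gid in gids) {
    members <- names(asg)[asg == gid]
    for (tn in names(terms)) {
      tg <- terms[[tn]]
      a <- length(intersect(members, tg))
      b <- length(members) - a
      cc <- length(tg) - a
      d <- N - a - b - cc
      ft <- stats::fisher.test(matrix(c(a, b, cc, d), 2, 2),
                               alternative = "greater")
      rows[[length(rows) + 1L]] <- data.frame(
        group = gid, term = tn, in_group_in_term = a, in_group = a + b,
        in_term = a + cc, background = N,
        odds_ratio = unname(ft$estimate), p = ft$p.value)
    }
  }
  out <- do.call(rbind, rows)
  out$p_bonferroni <- pmin(1, out$p * nrow(out))
  out$q_value <- stats::p.adjust(out$p, method = "BH")
  out$significant <- out$p_bonferroni <= p_cutoff & out$q_value <= q_cutoff
  out
}

#' Size-preserving randomized group assignments
#'
#' Control datasets for the enrichment comparison: each control permutes
#' the transcript-to-group labels while keeping every group's size, so any
#' enrichment seen in controls reflects chance overlap only.
#'
#' @param groups an `ea_groups` object or named integer vector.
#' @param n_datasets number of shuffled controls (default 5).
#' @param seed integer seed.
#' @return list of named integer vectors, same sizes as the input.
#' @export
randomized_control <- function(groups, n_datasets = 5, seed = 1L) {
  asg <- if (inherits(groups, "ea_groups")) groups$assignment else groups
  set.seed(seed)
  lapply(seq_len(n_datasets), function(i)
    stats::setNames(sample(asg), names(asg)))
}

#' Write group assignments to TSV
#'
#' @param groups an `ea_groups` object.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_groups <- function(groups, path) {
  utils::write.table(data.frame(transcript = names(groups$assignment),
                                group = unname(groups$assignment)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
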