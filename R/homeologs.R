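#' Pair homeologous gene copies
#'
#' Forms L/S homeolog pairs from gene metadata: an ortholog name yields a
#' pair only when it maps to exactly one `.l`-suffixed and one
#' `.s`-suffixed gene. Ambiguous names (three or more annotations, or two
#' copies on the same subgenome) are skipped and counted.
#'
#' @param gene_meta data.frame with columns `gene`, `ortholog`, `suffix`,
#'   `length` (as in `ea_counts$genes`).
#' @return data.frame (`ortholog`, `gene_l`, `gene_s`, `length_l`,
#'   `length_s`) with attribute `"n_skipped"`.
#' @export
pair_homeologs <- function(gene_meta) {
  gm <- gene_meta[!is.na(gene_meta$suffix) &
                    gene_meta$suffix %in% c("l", "s"), , drop = FALSE]
  skipped <- 0L
  rows <- list()
  for (o in unique(gm$ortholog)) {
    sub <- gm[gm$ortholog == o, ]
    if (nrow(sub) == 2 && setequal(sub$suffix, c("l", "s"))) {
      l <- sub[sub$suffix == "l", ]
      s <- sub[sub$suffix == "s", ]
      rows[[length(rows) + 1L]] <- data.frame(
        ortholog = o, gene_l = l$gene, gene_s = s$gene,
        length_l = l$length, length_s = s$length)
    } else skipped <- skipped + 1L
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(ortholog = character(0), gene_l = character(0),
               gene_s = character(0), length_l = numeric(0),
               length_s = numeric(0))
  if (skipped > 0) message(skipped, " ambiguous ortholog name(s) skipped")
  attr(out, "n_skipped") <- skipped
  out
}

#' Filter homeolog pairs to the testable set
#'
#' Keeps pairs whose transcript lengths differ by strictly less than 20
#' percent (`|l1 - l2| / max(l1, l2) < 0.2`, so counts are comparable
#' without length correction), drops pairs with zero counts in both copies,
#' and requires at least `min_count` total counts in at least one copy.
#' Pairs with a missing length are untestable and logged.
#'
#' @param pairs data.frame from [pair_homeologs()].
#' @param counts an [ea_counts()] object.
#' @param max_length_diff relative length-difference bound (default 0.2).
#' @param min_count minimum total counts in the better-covered copy.
#' @return the filtered pair data.frame.
#' @export
pair_filters <- function(pairs, counts, max_length_diff = 0.2,
                         min_count = 10) {
  cm <- counts$counts
  ok <- logical(nrow(pairs))
  n_nolen <- 0L
  for (i in seq_len(nrow(pairs))) {
    l1 <- pairs$length_l[i]; l2 <- pairs$length_s[i]
    if (is.na(l1) || is.na(l2)) { n_nolen <- n_nolen + 1L; next }
    if (abs(l1 - l2) / max(l1, l2) >= max_length_diff) next
    tl <- sum(cm[pairs$gene_l[i], ]); ts <- sum(cm[pairs$gene_s[i], ])
    if (tl == 0 && ts == 0) next
    if (max(tl, ts) < min_count) next
    ok[i] <- TRUE
  }
  if (n_nolen > 0) message(n_nolen, " pair(s) without length are untestable")
  pairs[ok, , drop = FALSE]
}

#' Moderated per-region differential test between homeolog copies
#'
#' For each dissected region with at least 2 replicates, tests whether the
#' L copy differs from the S copy: the per-sample difference of log2-CPM
#' (L minus S) is fitted with an intercept-only linear model across that
#' region's replicates and moderated with empirical-Bayes variance
#' shrinkage (limma). P-values are Benjamini-Hochberg adjusted across all
#' (pair, region) tests jointly ("bonferroni" is available as an option).
#'
#' @param pairs filtered pair data.frame from [pair_filters()].
#' @param expr an `ea_expr` object.
#' @param stage optional dissected stage restriction.
#' @param weights optional observation weights from [precision_weights()].
#' @param alpha adjusted-p significance threshold (default 0.05).
#' @param adjust `"BH"` (default) or `"bonferroni"`.
#' @return data.frame per (pair, region): `log_fc` (L minus S), `t`, `p`,
#'   `adj_p`, `significant`, `direction` (`"L>S"` / `"S>L"`).
#' @export
differential_by_region <- function(pairs, expr, stage = NULL,
                                   weights = NULL, alpha = 0.05,
                                   adjust = c("BH", "bonferroni")) {
  adjust <- match.arg(adjust)
  if (nrow(pairs) == 0) stop("no pairs to test")
  sm <- expr$samples
  use <- !sm$whole_embryo
  if (!is.null(stage)) use <- use & sm$stage == stage
  regions <- unique(sm$region[use])
  res <- list()
  for (r in regions) {
    ids <- sm$sample[use & sm$region == r]
    if (length(ids) < 2) {
      message("region ", r, " has a single replicate; skipped")
      next
    }
    D <- expr$values[pairs$gene_l, ids, drop = FALSE] -
      expr$values[pairs$gene_s, ids, drop = FALSE]
    rownames(D) <- pairs$ortholog
    w <- NULL
    if (!is.null(weights)) {
      # combine the two copies' precisions for the difference
      wl <- weights[pairs$gene_l, ids, drop = FALSE]
      ws <- weights[pairs$gene_s, ids, drop = FALSE]
      w <- 1 / (1 / wl + 1 / ws)
    }
    fit <- limma::lmFit(D, design = matrix(1, length(ids), 1), weights = w)
    fit <- limma::eBayes(fit)
    res[[r]] <- data.frame(ortholog = pairs$ortholog, region = r,
                           log_fc = fit$coefficients[, 1],
                           t = fit$t[, 1], p = fit$p.value[, 1],
                           row.names = NULL)
  }
  out <- do.call(rbind, res)
  out$adj_p <- stats::p.adjust(out$p, method = adjust)
  out$significant <- out$adj_p <= alpha
  out$direction <- ifelse(out$log_fc > 0, "L>S", "S>L")
  rownames(out) <- NULL
  out
}

#' Classify homeolog pairs from per-region test results
#'
#' `asymmetric`: one copy significantly higher in at least 2 regions and
#' never significantly lower (the decreased copy is recorded);
#' `subfunctionalized`: each copy significantly dominant in at least 1
#' region; `one_region`: exactly one significant region (fits neither
#' definition and is excluded from the chromosome-bias denominator);
#' `similar`: no significant region; `untestable`: no tested region.
#'
#' @param results data.frame from [differential_by_region()].
#' @return data.frame per pair: `ortholog`, `class`, `decreased`
#'   (`"L"`/`"S"`/`NA`), `n_up` (regions with L>S significant), `n_down`.
#' @export
classify_pairs <- function(results) {
  sp <- split(results, results$ortholog)
  rows <- lapply(names(sp), function(o) {
    rr <- sp[[o]]
    n_up <- sum(rr$significant & rr$direction == "L>S")
    n_down <- sum(rr$significant & rr$direction == "S>L")
    if (nrow(rr) == 0) {
      cls <- "untestable"; dec <- NA_character_
    } else if (n_up >= 1 && n_down >= 1) {
      cls <- "subfunctionalized"; dec <- NA_character_
    } else if (n_up >= 2) {
      cls <- "asymmetric"; dec <- "S"
    } else if (n_down >= 2) {
      cls <- "asymmetric"; dec <- "L"
    } else if (n_up + n_down == 1) {
      cls <- "one_region"; dec <- if (n_up == 1) "S" else "L"
    } else {
      cls <- "similar"; dec <- NA_character_
    }
    data.frame(ortholog = o, class = cls, decreased = dec,
               n_up = n_up, n_down = n_down)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Chromosome bias of asymmetric homeolog decrease
#'
#' Two-sided exact binomial test of whether the decreased copy of
#' asymmetric pairs falls on the S subgenome more often than chance (0.5).
#'
#' @param classification data.frame from [classify_pairs()], or a pair of
#'   counts via `s_down` and `n`.
#' @param s_down,n optional direct counts (S-decreased pairs out of n
#'   asymmetric pairs), bypassing `classification`.
#' @return `htest` from [stats::binom.test()].
#' @export
chromosome_bias <- function(classification = NULL, s_down = NULL, n = NULL) {
  if (is.null(s_down)) {
    asym <- classification[classification$class == "asymmetric", ]
    if (nrow(asym) == 0) stop("no asymmetric pairs")
    s_down <- sum(asym$decreased == "S")
    n <- nrow(asym)
  }
  stats::binom.test(s_down, n, p = 0.5, alternative = "two.sided")
}

#' Fraction of homeolog pairs co-clustering in the same co-expression group
#'
#' A pair counts as co-clustered when both copies carry the same non-zero
#' group id; the denominator is the pairs whose two copies are both present
#' in the clustered transcript set.
#'
#' @param pairs data.frame from [pair_homeologs()] (filtered or not).
#' @param groups an `ea_groups` object or named integer vector.
#' @return list: `fraction`, `n_same`, `n_evaluable`.
#' @export
co_cluster_rate <- function(pairs, groups) {
  asg <- if (inherits(groups, "ea_groups")) groups$assignment else groups
  inset <- pairs$gene_l %in% names(asg) & pairs$gene_s %in% names(asg)
  gl <- asg[pairs$gene_l[inset]]
  gs <- asg[pairs$gene_s[inset]]
  same <- gl == gs & gl > 0
  list(fraction = if (any(inset)) mean(same) else NA_real_,
       n_same = sum(same), n_evaluable = sum(inset))
}
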