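#' Build a seed-gene co-expression network
#'
#' For each seed transcript, retrieves its `top_k` most adjacent
#' transcripts in the unsigned adjacency (so strong negative partners are
#' retrieved too), computes the Pearson correlation and its p-value
#' (t-transform of r with n-2 degrees of freedom) between the seed and
#' each neighbour, and keeps the edges with `p <= p_cutoff`. Edge sign is
#' the sign of the correlation (negative edges are conventionally drawn
#' thick, positive thin). Node colours follow the co-expression group ids
#' when provided. Construction is deterministic given its inputs;
#' lowering `p_cutoff` never adds edges.
#'
#' @param seeds character vector of seed transcript ids.
#' @param adjacency matrix from [unsigned_adjacency()].
#' @param expr an `ea_expr` object (for correlations; columns restricted to
#'   the samples the adjacency was built on are the caller's concern).
#' @param groups optional `ea_groups` (node group ids / colours).
#' @param p_cutoff correlation p-value cutoff (default 1e-10; the
#'   less stringent 1e-9 used for large seed lists is a documented
#'   alternative).
#' @param top_k neighbours retrieved per seed (default 50).
#' @return object of class `ea_network`: `nodes` (id, is_seed, group,
#'   color), `edges` (from, to, correlation, p, sign), `p_cutoff`, `top_k`.
#' @export
seed_network <- function(seeds, adjacency, expr, groups = NULL,
                         p_cutoff = 1e-10, top_k = 50) {
  unknown <- setdiff(seeds, rownames(adjacency))
  if (length(unknown) > 0)
    stop("unknown seed gene(s): ", paste(unknown, collapse = ", "))
  v <- expr$values[rownames(adjacency), , drop = FALSE]
  n <- ncol(v)
  edges <- list()
  for (s in seeds) {
    arow <- adjacency[s, ]
    arow[s] <- -Inf
    nb <- names(sort(arow, decreasing = TRUE))[seq_len(min(top_k,
                                                           length(arow) - 1L))]
    r <- as.vector(stats::cor(v[s, ], t(v[nb, , drop = FALSE])))
    p <- cor_pvalue(r, n)
    keep <- p <= p_cutoff
    if (any(keep))
      edges[[s]] <- data.frame(from = s, to = nb[keep],
                               correlation = r[keep], p = p[keep],
                               sign = ifelse(r[keep] >= 0, "positive",
                                             "negative"))
  }
  edges <- if (length(edges)) do.call(rbind, edges) else
    data.frame(from = character(0), to = character(0),
               correlation = numeric(0), p = numeric(0),
               sign = character(0))
  # collapse duplicate seed-seed edges (kept once, order-normalized)
  if (nrow(edges) > 0) {
    key <- ifelse(edges$from < edges$to,
                  paste(edges$from, edges$to), paste(edges$to, edges$from))
    edges <- edges[!duplicated(key), , drop = FALSE]
  }
  ids <- union(seeds, unique(c(edges$from, edges$to)))
  grp <- rep(NA_integer_, length(ids))
  if (!is.null(groups)) {
    asg <- if (inherits(groups, "ea_groups")) groups$assignment else groups
    grp <- unname(asg[ids])
  }
  pal <- grDevices::hcl.colors(max(c(grp, 1), na.rm = TRUE) + 1, "Spectral")
  color <- ifelse(is.na(grp) | grp == 0, "#BBBBBB", pal[pmax(grp, 1)])
  nodes <- data.frame(id = ids, is_seed = ids %in% seeds, group = grp,
                      color = color)
  rownames(nodes) <- rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges, p_cutoff = p_cutoff,
                 top_k = top_k),
            class = "ea_network")
}

cor_pvalue <- function(r, n) {
  r <- pmin(pmax(r, -1 + 1e-15), 1 - 1e-15)
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  2 * stats::pt(-abs(tstat), df = n - 2)
}

#' @export
print.ea_network <- function(x, ...) {
  cat(sprintf("ea_network: %d nodes (%d seeds), %d edges (p <= %g, top %d neighbours per seed)\n",
              nrow(x$nodes), sum(x$nodes$is_seed), nrow(x$edges),
              x$p_cutoff, x$top_k))
  invisible(x)
}

#' Export a network to GraphML and JSON
#'
#' Writes `<stem>.graphml` (via igraph) and `<stem>.json` (node and edge
#' tables plus parameters). [read_network()] on the JSON returns an
#' identical network.
#'
#' @param network an `ea_network` object.
#' @param stem output path without extension.
#' @return character vector of the two file paths, invisibly.
#' @export
export_network <- function(network, stem) {
  g <- igraph::graph_from_data_frame(
    d = network$edges[, c("from", "to", "correlation", "p", "sign"),
                      drop = FALSE],
    directed = FALSE, vertices = network$nodes)
  gml <- paste0(stem, ".graphml")
  jsn <- paste0(stem, ".json")
  igraph::write_graph(g, gml, format = "graphml")
  jsonlite::write_json(list(nodes = network$nodes, edges = network$edges,
                            p_cutoff = network$p_cutoff,
                            top_k = network$top_k),
                       jsn, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(c(graphml = gml, json = jsn))
}

#' Read a network written by [export_network()]
#'
#' @param path path to the `.json` export.
#' @return an `ea_network` object identical to the exported one.
#' @export
read_network <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  nodes <- as.data.frame(x$nodes)
  edges <- as.data.frame(x$edges)
  if (nrow(edges) == 0)
    edges <- data.frame(from = character(0), to = character(0),
                        correlation = numeric(0), p = numeric(0),
                        sign = character(0))
  if (nrow(nodes) > 0) nodes$group <- as.integer(nodes$group)
  structure(list(nodes = nodes, edges = edges, p_cutoff = x$p_cutoff,
                 top_k = x$top_k),
            class = "ea_network")
}

#' Assemble a per-gene report card
#'
#' Gathers, for one gene, every layer of the atlas: the NMF-predicted
#' percent-of-max pattern across prototypical tissues, the average
#' percent-of-max pattern across dissected regions, linear mean expression
#' per region with the ectoderm-enrichment score (conventionally rendered
#' orange at 0 to green at 100), the whole-embryo stage series, the
#' co-expression group, and the top co-expressed genes. Layers whose
#' upstream artifact lacks the gene are omitted with a note.
#'
#' @param gene gene id.
#' @param expr an `ea_expr` object.
#' @param W_full optional extended component matrix.
#' @param enrichment optional result of [ectoderm_enrichment()].
#' @param groups optional `ea_groups`.
#' @param top_coexpressed number of co-expressed genes to list (Pearson on
#'   log2-CPM; default 10).
#' @return object of class `ea_report` (a list of layers with `notes`).
#' @export
report_gene <- function(gene, expr, W_full = NULL, enrichment = NULL,
                        groups = NULL, top_coexpressed = 10) {
  notes <- character(0)
  out <- list(gene = gene)
  if (!gene %in% rownames(expr$values))
    stop("unknown gene: ", gene)
  if (!is.null(W_full)) {
    if (gene %in% rownames(W_full)) out$nmf_pattern <- nmf_pattern(W_full,
                                                                   gene)
    else notes <- c(notes, "gene absent from the component matrix")
  }
  out$average_pattern <- average_pattern(expr, gene)
  out$region_means <- region_means(expr, gene)
  if (!is.null(enrichment)) {
    if (gene %in% rownames(enrichment$score))
      out$enrichment_score <- enrichment$score[gene, ]
    else notes <- c(notes, "gene absent from the enrichment table")
  }
  sm <- expr$samples
  we <- sm[sm$whole_embryo, ]
  if (nrow(we) > 0)
    out$we_series <- stats::setNames(2^expr$values[gene, we$sample],
                                     we$stage)
  if (!is.null(groups)) {
    asg <- if (inherits(groups, "ea_groups")) groups$assignment else groups
    if (gene %in% names(asg)) out$group <- unname(asg[gene])
    else notes <- c(notes, "gene not in the clustered transcript set")
  }
  if (top_coexpressed > 0) {
    if (stats::sd(expr$values[gene, ]) == 0) {
      notes <- c(notes, "constant gene: co-expression undefined")
    } else {
      r <- suppressWarnings(
        as.vector(stats::cor(expr$values[gene, ], t(expr$values))))
      names(r) <- rownames(expr$values)
      r <- r[names(r) != gene & !is.na(r)]
      out$top_coexpressed <- utils::head(sort(r, decreasing = TRUE),
                                         top_coexpressed)
    }
  }
  out$notes <- notes
  structure(out, class = "ea_report")
}

#' @export
print.ea_report <- function(x, ...) {
  cat("Gene report:", x$gene, "\n")
  if (!is.null(x$nmf_pattern)) {
    cat("  NMF pattern (% of max): ",
        paste(sprintf("%s=%.0f", names(x$nmf_pattern), x$nmf_pattern),
              collapse = " "), "\n")
  }
  cat("  average pattern (% of max): ",
      paste(sprintf("%s=%.0f", names(x$average_pattern), x$average_pattern),
            collapse = " "), "\n")
  if (!is.null(x$enrichment_score))
    cat("  ectoderm enrichment score: ",
        paste(sprintf("%s=%.0f", names(x$enrichment_score),
                      x$enrichment_score), collapse = " "), "\n")
  if (!is.null(x$group)) cat("  co-expression group:", x$group, "\n")
  if (length(x$notes)) cat("  notes:", paste(x$notes, collapse = "; "), "\n")
  invisible(x)
}
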