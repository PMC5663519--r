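#' Configuration for the synthetic ectoderm atlas generator
#'
#' Describes the study design the generator emulates: a set of microdissected
#' ectoderm regions (with an adjacency graph for cross-contamination between
#' neighbouring dissections), a smaller set of underlying prototypical
#' tissues, replicate dissections per region at one or more stages, and a
#' whole-embryo (WE) developmental series that also carries a non-ectoderm
#' component. Counts are negative-binomial with `Var = mu + phi * mu^2`.
#'
#' The defaults mirror the dissection design of a neurula-stage frog embryo:
#' seven regions (anterior neural fold ANF, anterior/posterior neural plate
#' NPa/NPp, anterior/posterior neural border NBa/NBp, preplacodal ectoderm
#' PPE, non-neural ectoderm NNE) resolving to five prototypical tissues, three
#' replicates per region, and a seven-stage WE series.
#'
#' @param n_genes number of genes.
#' @param n_tissues number of ground-truth prototypical ectoderm tissues.
#' @param regions character vector of dissected-region labels.
#' @param adjacency named list: for each region, the labels of its
#'   neighbouring regions (contamination donors).
#' @param region_tissue named character vector mapping each region to its
#'   dominant prototypical tissue (tissue labels `t1..tK` by default).
#' @param replicates_per_region replicates dissected per region and stage.
#' @param stages labels of the dissected stages.
#' @param n_we_stages number of whole-embryo stages (one sample each).
#' @param signature_fraction fraction of genes that are tissue-specific
#'   signature genes.
#' @param signature_fold fold-change of a signature gene in its tissue over
#'   the other tissues (default 64 = 2^6, comfortably above a log2-range-5
#'   selection threshold after mixing noise).
#' @param mesoderm_fraction fraction of genes expressed mainly in the WE
#'   non-ectoderm component (mesoderm/endoderm contaminant emulation).
#' @param contamination fraction of a dissected sample's expression drawn
#'   from the tissues of adjacent regions (must be < 0.5).
#' @param nb_dispersion negative-binomial dispersion phi; values below 1e-8
#'   are treated as Poisson (the phi -> 0 limit).
#' @param library_size_range length-2 numeric, total-count bounds; library
#'   sizes are drawn log-uniformly within the range.
#' @param we_nonecto_weight mixing weight of the non-ectoderm component in
#'   whole-embryo samples.
#' @param n_homeolog_pairs homeologous pairs to inject (see
#'   [inject_homeolog_pairs()]).
#' @param homeolog_fractions named numeric: fractions of pairs of class
#'   `asym_l_down`, `asym_s_down`, `subfunctionalized`, `similar`
#'   (must sum to <= 1; the remainder is assigned to `similar`).
#' @param homeolog_factor fold-change applied to the decreased copy.
#' @param length_fail_fraction fraction of pairs whose transcript lengths are
#'   assigned to fail the <20 percent length-difference filter.
#' @param n_terms number of uniform background annotation terms.
#' @param term_size expected genes per annotation term.
#' @param enrichment_odds odds ratio of signature-gene membership for the
#'   planted (one-per-tissue) annotation terms; 1 means no enrichment.
#' @param seed integer seed; the same config yields bit-identical output.
#' @return a validated `ea_config` list.
#' @export
atlas_config <- function(n_genes = 2000,
                         n_tissues = 5,
                         regions = c("ANF", "NPa", "NPp", "NBa", "NBp",
                                     "PPE", "NNE"),
                         adjacency = NULL,
                         region_tissue = NULL,
                         replicates_per_region = 3,
                         stages = c("st12", "st14"),
                         n_we_stages = 7,
                         signature_fraction = 0.15,
                         signature_fold = 64,
                         mesoderm_fraction = 0.05,
                         contamination = 0.1,
                         nb_dispersion = 0.05,
                         library_size_range = c(8e5, 1.2e6),
                         we_nonecto_weight = 0.5,
                         n_homeolog_pairs = 0,
                         homeolog_fractions = c(asym_l_down = 0.15,
                                                asym_s_down = 0.35,
                                                subfunctionalized = 0.10,
                                                similar = 0.40),
                         homeolog_factor = 4,
                         length_fail_fraction = 0.1,
                         n_terms = 30,
                         term_size = 40,
                         enrichment_odds = 20,
                         seed = 1L) {
  if (is.null(adjacency)) {
    adjacency <- list(ANF = c("NPa", "NBa"),
                      NPa = c("ANF", "NPp", "NBa"),
                      NPp = c("NPa", "NBp"),
                      NBa = c("ANF", "NPa", "NBp", "PPE"),
                      NBp = c("NPp", "NBa", "NNE"),
                      PPE = c("NBa", "NNE"),
                      NNE = c("PPE", "NBp"))
    adjacency <- adjacency[intersect(names(adjacency), regions)]
    adjacency <- lapply(adjacency, intersect, regions)
  }
  tissues <- paste0("t", seq_len(n_tissues))
  if (is.null(region_tissue)) {
    if (identical(sort(regions), sort(c("ANF", "NPa", "NPp", "NBa", "NBp",
                                        "PPE", "NNE"))) && n_tissues == 5) {
      # mirrors the published merge: ANF+PPE and NPp+NBp share a tissue
      region_tissue <- c(ANF = "t1", PPE = "t1", NPa = "t2", NPp = "t3",
                         NBp = "t3", NBa = "t4", NNE = "t5")[regions]
      names(region_tissue) <- regions
    } else {
      region_tissue <- stats::setNames(
        tissues[(seq_along(regions) - 1L) %% n_tissues + 1L], regions)
    }
  }
  for (v in list(n_genes = n_genes, n_tissues = n_tissues,
                 replicates_per_region = replicates_per_region,
                 n_we_stages = n_we_stages,
                 n_homeolog_pairs = n_homeolog_pairs)) {
    if (length(v) != 1 || is.na(v) || v != round(v) || v < 0)
      stop("count-valued config fields must be positive integers")
  }
  cfg <- list(n_genes = as.integer(n_genes),
              n_tissues = as.integer(n_tissues),
              tissues = tissues, regions = regions, adjacency = adjacency,
              region_tissue = region_tissue,
              replicates_per_region = as.integer(replicates_per_region),
              stages = stages, n_we_stages = as.integer(n_we_stages),
              signature_fraction = signature_fraction,
              signature_fold = signature_fold,
              mesoderm_fraction = mesoderm_fraction,
              contamination = contamination,
              nb_dispersion = nb_dispersion,
              library_size_range = as.numeric(library_size_range),
              we_nonecto_weight = we_nonecto_weight,
              n_homeolog_pairs = as.integer(n_homeolog_pairs),
              homeolog_fractions = homeolog_fractions,
              homeolog_factor = homeolog_factor,
              length_fail_fraction = length_fail_fraction,
              n_terms = as.integer(n_terms), term_size = term_size,
              enrichment_odds = enrichment_odds,
              seed = as.integer(seed))
  validate_config(cfg)
  structure(cfg, class = "ea_config")
}

validate_config <- function(cfg) {
  cnt <- c("n_genes", "n_tissues", "replicates_per_region", "n_we_stages")
  for (f in cnt) {
    v <- cfg[[f]]
    if (length(v) != 1 || is.na(v) || v < 1 || v != round(v))
      stop("config field `", f, "` must be a positive integer")
  }
  props <- c("signature_fraction", "mesoderm_fraction", "contamination",
             "we_nonecto_weight", "length_fail_fraction")
  for (f in props) {
    v <- cfg[[f]]
    if (v < 0 || v > 1) stop("config field `", f, "` must be in [0, 1]")
  }
  if (cfg$contamination >= 0.5) stop("contamination must be < 0.5")
  if (cfg$nb_dispersion < 0) stop("nb_dispersion must be >= 0")
  if (length(cfg$library_size_range) != 2 ||
      any(cfg$library_size_range <= 0) ||
      diff(cfg$library_size_range) < 0)
    stop("library_size_range must be an increasing positive pair")
  if (any(cfg$homeolog_fractions < 0) || sum(cfg$homeolog_fractions) > 1 + 1e-9)
    stop("homeolog class fractions must be non-negative and sum to <= 1")
  if (!all(names(cfg$region_tissue) == cfg$regions))
    stop("region_tissue must be named by the regions")
  if (!all(cfg$region_tissue %in% cfg$tissues))
    stop("region_tissue values must be tissue labels")
  if (!all(unlist(cfg$adjacency) %in% cfg$regions))
    stop("adjacency mentions unknown regions")
  invisible(cfg)
}

# per-gene expected expression (arbitrary units) for every sample, given the
# prototype matrix (genes x tissues+nonecto), the mixing matrix and the
# per-gene temporal modulation of the non-ectoderm component in WE samples
expected_expression <- function(prototype, mixing, samples, slope) {
  K1 <- ncol(prototype)
  E <- prototype %*% t(mixing)            # genes x samples, no temporal term
  we <- which(samples$whole_embryo)
  if (length(we) > 0) {
    m <- length(we)
    z <- if (m == 1) 0 else (seq_len(m) - (m + 1) / 2) / ((m - 1) / 2)
    for (i in seq_along(we)) {
      s <- we[i]
      extra <- prototype[, K1] * mixing[s, K1] * (exp(slope * z[i]) - 1)
      E[, s] <- E[, s] + extra
    }
  }
  E
}

draw_counts <- function(mu, dispersion) {
  n <- length(mu)
  if (dispersion < 1e-8) {
    matrix(stats::rpois(n, lambda = mu), nrow = nrow(mu),
           dimnames = dimnames(mu))
  } else {
    matrix(stats::rnbinom(n, mu = mu, size = 1 / dispersion), nrow = nrow(mu),
           dimnames = dimnames(mu))
  }
}

#' Generate a synthetic dissected-ectoderm atlas with recorded ground truth
#'
#' Draws a gene-by-sample count matrix with the structure the downstream
#' analysis assumes: dissected samples are negative-binomial draws around a
#' mixture of their region's dominant prototypical tissue and (at rate
#' `contamination`) the tissues of adjacent regions; whole-embryo samples mix
#' all ectoderm tissues with a non-ectoderm component whose per-gene level
#' follows a log-linear temporal trend across the WE series. Everything the
#' generator decided - the prototype matrix, the sample mixing proportions,
#' signature memberships, temporal slopes - is returned as ground truth.
#'
#' @param config an [atlas_config()] object.
#' @return a list with elements `counts` (an [ea_counts()] object) and
#'   `truth` (class `ea_truth`: `prototype` genes x (tissues + "nonecto"),
#'   `mixing` samples x (tissues + "nonecto") with rows summing to 1,
#'   `signature_membership` named character (NA = not a signature gene),
#'   `temporal_profile`, `sample_scale`, `library_sizes`, `homeologs`
#'   (NULL until [inject_homeolog_pairs()]), `seed`, `config`).
#' @export
generate_atlas <- function(config) {
  validate_config(config)
  set.seed(config$seed)
  n <- config$n_genes
  K <- config$n_tissues
  tissues <- config$tissues
  cols <- c(tissues, "nonecto")
  genes <- sprintf("g%05d", seq_len(n))

  base <- stats::rlnorm(n, meanlog = log(50), sdlog = 1.25)
  prototype <- base * exp(matrix(stats::rnorm(n * (K + 1), 0, 0.1),
                                 n, K + 1))
  dimnames(prototype) <- list(genes, cols)

  n_sig <- round(config$signature_fraction * n)
  n_meso <- round(config$mesoderm_fraction * n)
  membership <- stats::setNames(rep(NA_character_, n), genes)
  if (n_sig > 0) {
    sig <- seq_len(n_sig)
    tis <- tissues[(sig - 1L) %% K + 1L]
    membership[sig] <- tis
    for (i in sig) {
      prototype[i, ] <- base[i]
      prototype[i, membership[i]] <- base[i] * config$signature_fold
      prototype[i, "nonecto"] <- base[i] * 0.1
    }
  }
  if (n_meso > 0) {
    meso <- n_sig + seq_len(n_meso)
    prototype[meso, tissues] <- base[meso] * 0.25
    prototype[meso, "nonecto"] <- base[meso] * config$signature_fold
  }
  slope <- stats::rnorm(n, 0, 0.3)

  # sample table: dissected regions x stages x replicates, then WE series
  dis <- expand.grid(replicate = seq_len(config$replicates_per_region),
                     region = config$regions, stage = config$stages,
                     stringsAsFactors = FALSE)
  dis <- dis[, c("stage", "region", "replicate")]
  dis$sample <- sprintf("%s_%s_r%d", dis$region, dis$stage, dis$replicate)
  dis$whole_embryo <- FALSE
  we <- data.frame(stage = paste0("we", seq_len(config$n_we_stages)),
                   region = "WE", replicate = 1L,
                   sample = paste0("WE_we", seq_len(config$n_we_stages)),
                   whole_embryo = TRUE)
  samples <- rbind(dis, we)[, c("sample", "stage", "region", "replicate",
                                "whole_embryo")]
  ns <- nrow(samples)

  mixing <- matrix(0, ns, K + 1, dimnames = list(samples$sample, cols))
  for (s in seq_len(ns)) {
    if (samples$whole_embryo[s]) {
      mixing[s, "nonecto"] <- config$we_nonecto_weight
      mixing[s, tissues] <- (1 - config$we_nonecto_weight) / K
    } else {
      r <- samples$region[s]
      own <- config$region_tissue[[r]]
      mixing[s, own] <- mixing[s, own] + (1 - config$contamination)
      nb <- config$adjacency[[r]]
      if (config$contamination > 0 && length(nb) > 0) {
        for (q in nb) {
          t_q <- config$region_tissue[[q]]
          mixing[s, t_q] <- mixing[s, t_q] + config$contamination / length(nb)
        }
      } else {
        mixing[s, own] <- mixing[s, own] + config$contamination
      }
    }
  }

  lib <- exp(stats::runif(ns, log(config$library_size_range[1]),
                          log(config$library_size_range[2])))
  E <- expected_expression(prototype, mixing, samples, slope)
  scale <- lib / colSums(E)
  mu <- sweep(E, 2, scale, "*")
  counts <- draw_counts(mu, config$nb_dispersion)
  dimnames(counts) <- list(genes, samples$sample)

  gmeta <- data.frame(gene = genes, ortholog = genes,
                      suffix = NA_character_,
                      length = round(stats::runif(n, 500, 5000)),
                      arm = NA_character_)
  truth <- structure(list(prototype = prototype, mixing = mixing,
                          signature_membership = membership,
                          temporal_profile = stats::setNames(slope, genes),
                          sample_scale = stats::setNames(scale,
                                                         samples$sample),
                          library_sizes = stats::setNames(lib,
                                                          samples$sample),
                          homeologs = NULL, seed = config$seed,
                          config = config),
                     class = "ea_truth")
  list(counts = ea_counts(counts, samples, gmeta), truth = truth)
}

#' @export
print.ea_truth <- function(x, ...) {
  cat(sprintf("ea_truth: %d genes, %d tissues (+ nonecto), %d samples\n",
              nrow(x$prototype), ncol(x$prototype) - 1, nrow(x$mixing)))
  cat(sprintf("  signature genes: %d; homeolog pairs: %d; seed: %d\n",
              sum(!is.na(x$signature_membership)),
              if (is.null(x$homeologs)) 0L else nrow(x$homeologs), x$seed))
  invisible(x)
}

# largest-remainder apportionment of n pairs into the configured classes;
# the remainder goes to "similar"
apportion_classes <- function(fractions, n) {
  fr <- fractions[c("asym_l_down", "asym_s_down", "subfunctionalized",
                    "similar")]
  fr["similar"] <- fr["similar"] + (1 - sum(fr))
  exact <- fr * n
  k <- floor(exact)
  rem <- n - sum(k)
  if (rem > 0) {
    extra <- order(exact - k, decreasing = TRUE)[seq_len(rem)]
    k[extra] <- k[extra] + 1L
  }
  k
}

#' Inject homeologous gene pairs into a synthetic atlas
#'
#' Turns designated genes into homeologous pairs sharing an ortholog name
#' with `.l` / `.s` suffixed copies, reflecting the duplicated L and S
#' subgenomes of an allotetraploid. Classes: `similar` (copies equal in
#' expectation everywhere), `asym_l_down` / `asym_s_down` (one copy scaled
#' down by `homeolog_factor` uniformly across all tissues, hence all
#' regions), and `subfunctionalized` (dominance swaps between tissues: the S
#' copy is reduced in odd-indexed tissues, the L copy in even-indexed ones).
#' Counts of the affected genes are re-drawn from the modified prototypes
#' using the per-sample scale recorded at generation. Transcript lengths are
#' assigned so that `length_fail_fraction` of pairs fail the <20 percent
#' length-difference filter.
#'
#' @param counts,truth output of [generate_atlas()].
#' @param config the same [atlas_config()] (with `n_homeolog_pairs` > 0).
#' @return list(counts, truth) with renamed genes, updated metadata and a
#'   `truth$homeologs` table (ortholog, gene_l, gene_s, class, decreased,
#'   length_pass).
#' @export
inject_homeolog_pairs <- function(counts, truth, config) {
  np <- config$n_homeolog_pairs
  if (np == 0) return(list(counts = counts, truth = truth))
  if (2L * np > config$n_genes)
    stop("n_homeolog_pairs exceeds n_genes / 2")
  set.seed(config$seed + 1L)
  genes <- rownames(counts$counts)
  candidates <- genes[is.na(truth$signature_membership)]
  if (length(candidates) < 2L * np)
    stop("not enough non-signature genes to form the requested pairs")
  picked <- sample(candidates, 2L * np)
  gl <- picked[seq_len(np)]
  gs <- picked[np + seq_len(np)]

  nk <- apportion_classes(config$homeolog_fractions, np)
  classes <- rep(names(nk), times = nk)
  f <- config$homeolog_factor
  K <- config$n_tissues
  tissues <- config$tissues

  proto <- truth$prototype
  decreased <- character(np)
  for (p in seq_len(np)) {
    anc <- proto[gl[p], ]                  # ancestral profile
    pl <- anc; ps <- anc
    cl <- classes[p]
    if (cl == "asym_s_down") { ps <- anc / f; decreased[p] <- "S" }
    else if (cl == "asym_l_down") { pl <- anc / f; decreased[p] <- "L" }
    else if (cl == "subfunctionalized") {
      odd <- tissues[seq(1, K, by = 2)]
      even <- tissues[seq(2, K, by = 2)]
      ps[odd] <- anc[odd] / f
      pl[even] <- anc[even] / f
      decreased[p] <- "both"
    } else decreased[p] <- "none"
    proto[gl[p], ] <- pl
    proto[gs[p], ] <- ps
  }

  # redraw counts for affected genes from the modified prototypes
  aff <- c(gl, gs)
  E <- expected_expression(proto[aff, , drop = FALSE], truth$mixing,
                           counts$samples, truth$temporal_profile[aff])
  mu <- sweep(E, 2, truth$sample_scale, "*")
  newc <- draw_counts(mu, config$nb_dispersion)
  cm <- counts$counts
  cm[aff, ] <- newc

  # rename: pair p becomes homNNN.l / homNNN.s
  ortho <- sprintf("hom%04d", seq_len(np))
  map <- stats::setNames(c(paste0(ortho, ".l"), paste0(ortho, ".s")),
                         c(gl, gs))
  idx <- match(genes, names(map))
  new_ids <- ifelse(is.na(idx), genes, map[idx])
  rownames(cm) <- new_ids
  rownames(proto) <- new_ids
  names(truth$signature_membership) <- new_ids
  names(truth$temporal_profile) <- new_ids

  gm <- counts$genes
  gm$gene <- new_ids
  li <- match(gl, genes); si <- match(gs, genes)
  gm$ortholog[li] <- ortho; gm$ortholog[si] <- ortho
  gm$suffix[li] <- "l"; gm$suffix[si] <- "s"
  gm$arm[li] <- "L"; gm$arm[si] <- "S"
  n_fail <- round(config$length_fail_fraction * np)
  pass <- rep(TRUE, np)
  if (n_fail > 0) pass[np - seq_len(n_fail) + 1L] <- FALSE
  base_len <- gm$length[li]
  gm$length[si] <- ifelse(pass,
                          round(base_len * stats::runif(np, 0.90, 1.10)),
                          round(base_len * 1.35))

  truth$prototype <- proto
  truth$homeologs <- data.frame(ortholog = ortho,
                                gene_l = paste0(ortho, ".l"),
                                gene_s = paste0(ortho, ".s"),
                                class = classes, decreased = decreased,
                                length_pass = pass)
  list(counts = ea_counts(cm, counts$samples, gm), truth = truth)
}

#' Generate a synthetic functional-annotation table
#'
#' Builds a term-to-gene table for enrichment testing: one planted term per
#' prototypical tissue whose membership is enriched in that tissue's
#' ground-truth signature set at odds ratio `enrichment_odds`, `n_terms`
#' uniform background terms, and a universal term (`ALL`) annotating every
#' gene (which can therefore never be enriched).
#'
#' @param config an [atlas_config()] object.
#' @param truth the `ea_truth` from [generate_atlas()].
#' @return data.frame with columns `term`, `gene`.
#' @export
generate_annotation <- function(config, truth) {
  set.seed(config$seed + 2L)
  genes <- rownames(truth$prototype)
  n <- length(genes)
  p0 <- min(config$term_size / n, 0.9)
  or <- config$enrichment_odds
  p1 <- or * p0 / (1 - p0 + or * p0)
  out <- list()
  for (t in config$tissues) {
    sig <- names(truth$signature_membership)[
      !is.na(truth$signature_membership) & truth$signature_membership == t]
    if (length(sig) == 0) next
    pr <- ifelse(genes %in% sig, p1, p0)
    inset <- genes[stats::runif(n) < pr]
    if (length(inset) > 0)
      out[[length(out) + 1L]] <- data.frame(term = paste0("T_", t),
                                            gene = inset)
  }
  for (b in seq_len(config$n_terms)) {
    sz <- max(2L, round(stats::rnorm(1, config$term_size,
                                     config$term_size / 5)))
    out[[length(out) + 1L]] <- data.frame(
      term = sprintf("BG_%02d", b), gene = sample(genes, min(sz, n)))
  }
  out[[length(out) + 1L]] <- data.frame(term = "ALL", gene = genes)
  do.call(rbind, out)
}

#' Write the ground truth of a synthetic atlas to plain-text files
#'
#' @param truth an `ea_truth` object.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_truth <- function(truth, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  wt <- function(m, f) utils::write.table(
    data.frame(id = rownames(m), m, check.names = FALSE),
    file.path(dir, f), sep = "\t", quote = FALSE, row.names = FALSE)
  wt(truth$prototype, "prototype.tsv")
  wt(truth$mixing, "mixing.tsv")
  utils::write.table(
    data.frame(gene = names(truth$signature_membership),
               tissue = truth$signature_membership,
               temporal_slope = truth$temporal_profile),
    file.path(dir, "genes_truth.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  if (!is.null(truth$homeologs))
    utils::write.table(truth$homeologs, file.path(dir, "homeologs.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(seed = truth$seed,
                            library_sizes = as.list(truth$library_sizes)),
                       file.path(dir, "truth.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}
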