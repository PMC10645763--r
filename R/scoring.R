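#' Single-sample gene-set enrichment (ssGSEA)
#'
#' Per sample, genes are ranked by expression (average ranks for ties; the
#' top-expressed gene has rank N). Walking the list from the highest
#' expressed gene down, the in-set cumulative distribution accumulates
#' rank^tau (normalized by the set total) and the out-of-set distribution
#' accumulates 1 / (N - |S|); the enrichment score is the sum of their
#' running difference over all positions. With `normalize = TRUE` all
#' scores are divided by the range (max - min) across every sample and
#' set, the usual cross-sample normalization.
#'
#' @param expr Genes x samples matrix.
#' @param gene_sets Named list of gene-id vectors; sets are trimmed to the
#'   matrix with a message.
#' @param tau Rank-weighting exponent (default 0.25).
#' @param normalize Apply range normalization across all scores.
#' @return Samples x sets matrix of enrichment scores.
#' @export
ssgsea <- function(expr, gene_sets, tau = 0.25, normalize = TRUE) {
  stopifnot(is.matrix(expr), is.list(gene_sets), !is.null(names(gene_sets)))
  N <- nrow(expr)
  genes <- rownames(expr)
  sets <- lapply(gene_sets, intersect, x = genes)
  trimmed <- sum(lengths(gene_sets) - lengths(sets))
  if (trimmed > 0) {
    message("ssgsea: trimmed ", trimmed, " gene(s) absent from the matrix")
  }
  if (any(lengths(sets) == 0L)) {
    stop("gene set(s) with no overlap: ",
         paste(names(sets)[lengths(sets) == 0L], collapse = ", "))
  }
  if (any(lengths(sets) == N)) stop("a gene set covers all genes")
  ES <- matrix(NA_real_, ncol(expr), length(sets),
               dimnames = list(colnames(expr), names(sets)))
  set_idx <- lapply(sets, match, table = genes)
  for (s in seq_len(ncol(expr))) {
    x <- expr[, s]
    z <- rank(x, ties.method = "average")   # top gene gets rank N
    ord <- order(x, decreasing = TRUE)
    zo <- z[ord]
    for (k in seq_along(set_idx)) {
      inset <- ord %in% set_idx[[k]]
      wt <- zo^tau
      p_in <- cumsum(ifelse(inset, wt, 0)) / sum(wt[inset])
      p_out <- cumsum(!inset) / (N - sum(inset))
      ES[s, k] <- sum(p_in - p_out)
    }
  }
  if (normalize) {
    rng <- max(ES) - min(ES)
    if (rng > 0) ES <- ES / rng
  }
  ES
}

#' Bin-matched cell-level module score
#'
#' The AddModuleScore-style single-cell score: genes are binned into `nbin`
#' equal-count bins by their mean expression across cells; for each set
#' gene, `nctrl` control genes are sampled from its bin (without
#' replacement when the bin is large enough, with replacement otherwise);
#' the score of a cell is the mean expression of the set genes minus the
#' mean expression of the pooled control genes.
#'
#' @param expr Cells x genes log-normalized matrix.
#' @param gene_set Character vector of set genes; absent genes are dropped
#'   with a message.
#' @param nbin Number of expression bins (default 24).
#' @param nctrl Control genes sampled per set gene (default 100).
#' @param seed Integer seed for the control draw.
#' @return Named numeric score per cell.
#' @export
cell_module_score <- function(expr, gene_set, nbin = 24L, nctrl = 100L,
                              seed = 1L) {
  stopifnot(is.matrix(expr))
  genes <- colnames(expr)
  set_genes <- intersect(gene_set, genes)
  if (length(set_genes) < length(gene_set)) {
    message("cell_module_score: dropped ",
            length(gene_set) - length(set_genes), " absent set gene(s)")
  }
  if (!length(set_genes)) stop("no set genes present in the matrix")
  avg <- colMeans(expr)
  nbin <- min(nbin, length(genes))
  bin <- cut(rank(avg, ties.method = "first"), breaks = nbin, labels = FALSE)
  names(bin) <- genes
  set.seed(seed)
  ctrl <- unlist(lapply(set_genes, function(g) {
    pool <- genes[bin == bin[[g]]]
    sample(pool, nctrl, replace = length(pool) < nctrl)
  }))
  score <- rowMeans(expr[, set_genes, drop = FALSE]) -
    rowMeans(expr[, ctrl, drop = FALSE])
  stats::setNames(score, rownames(expr))
}

#' Nonparametric comparison of score distributions between groups
#'
#' Two groups: two-sided Wilcoxon rank-sum test (normal approximation with
#' tie correction). More than two: Kruskal-Wallis over all groups followed
#' by pairwise two-sided Wilcoxon tests of each group against a designated
#' reference group, with Benjamini-Hochberg correction across the pairwise
#' tests.
#'
#' @param scores Numeric vector of per-sample (or per-cell, per-gene)
#'   scores.
#' @param labels Group label per score.
#' @param reference Reference group for pairwise tests (default: largest
#'   group).
#' @param min_group Smallest allowed group size (default 2; connectivity
#'   comparisons relax this and flag small groups instead).
#' @return List with `global` (one-row data.frame: test, statistic, df, p)
#'   and, when more than two groups, `pairwise` (group vs reference, with
#'   W, p, q).
#' @export
compare_score_groups <- function(scores, labels, reference = NULL,
                                 min_group = 2L) {
  labels <- as.character(labels)
  stopifnot(length(scores) == length(labels))
  groups <- unique(labels)
  if (length(groups) < 2L) stop("need at least 2 groups")
  n_by <- table(labels)
  if (any(n_by < min_group)) {
    stop("group(s) with fewer than ", min_group, " observations: ",
         paste(names(n_by)[n_by < min_group], collapse = ", "))
  }
  if (length(groups) == 2L) {
    wt <- stats::wilcox.test(scores[labels == groups[1L]],
                             scores[labels == groups[2L]],
                             exact = FALSE, correct = TRUE)
    return(list(global = data.frame(test = "wilcoxon",
                                    statistic = unname(wt$statistic),
                                    df = NA_real_, p = wt$p.value)))
  }
  kw <- stats::kruskal.test(scores, factor(labels))
  if (is.null(reference)) reference <- names(which.max(n_by))
  if (!reference %in% groups) stop("reference group absent from labels")
  others <- setdiff(groups, reference)
  pw <- do.call(rbind, lapply(others, function(g) {
    wt <- stats::wilcox.test(scores[labels == g],
                             scores[labels == reference],
                             exact = FALSE, correct = TRUE)
    data.frame(group = g, reference = reference,
               W = unname(wt$statistic), p = wt$p.value,
               stringsAsFactors = FALSE)
  }))
  pw$q <- stats::p.adjust(pw$p, method = "BH")
  list(global = data.frame(test = "kruskal-wallis",
                           statistic = unname(kw$statistic),
                           df = unname(kw$parameter), p = kw$p.value),
       pairwise = pw)
}
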