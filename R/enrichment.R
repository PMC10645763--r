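#' Fisher's exact gene-set overlap test
#'
#' Builds the 2x2 in/out-of-A by in/out-of-B table over a gene universe and
#' reports the one-sided (greater) hypergeometric p-value — enrichment of B
#' members among A members — with the sample odds ratio (Haldane 0.5
#' correction when a cell is empty). Use [overlap_test_batch()] for BH
#' correction across several lists.
#'
#' @param setA,setB Character vectors of gene ids; must lie in `universe`.
#' @param universe Character vector, the expressed-gene background.
#' @return One-row data.frame: overlap, size_a, size_b, universe,
#'   odds_ratio, p.
#' @export
overlap_test <- function(setA, setB, universe) {
  if (!length(universe)) stop("empty universe")
  universe <- unique(universe)
  setA <- unique(setA); setB <- unique(setB)
  if (!all(setA %in% universe) || !all(setB %in% universe)) {
    stop("sets must be subsets of the universe")
  }
  k <- length(intersect(setA, setB))
  a <- length(setA); b <- length(setB); n <- length(universe)
  # hypergeometric tail: P(overlap >= k) drawing |B| from |A| successes
  p <- stats::phyper(k - 1L, a, n - a, b, lower.tail = FALSE)
  tab <- c(k, a - k, b - k, n - a - b + k)
  if (any(tab == 0)) tab <- tab + 0.5
  or <- (tab[1L] * tab[4L]) / (tab[2L] * tab[3L])
  data.frame(overlap = k, size_a = a, size_b = b, universe = n,
             odds_ratio = or, p = min(p, 1))
}

#' Batch overlap tests with BH correction
#'
#' Tests one gene set (e.g. a module) against each of several lists and
#' adjusts the one-sided p-values with Benjamini-Hochberg.
#'
#' @param setA Character vector (the module).
#' @param lists Named list of gene-id vectors.
#' @param universe Background gene universe.
#' @return Data.frame, one row per list, with a `q` column.
#' @export
overlap_test_batch <- function(setA, lists, universe) {
  stopifnot(is.list(lists), !is.null(names(lists)))
  res <- do.call(rbind, lapply(names(lists), function(nm) {
    row <- overlap_test(setA, lists[[nm]], universe)
    cbind(data.frame(list = nm, stringsAsFactors = FALSE), row)
  }))
  res$q <- stats::p.adjust(res$p, method = "BH")
  res
}

# equal-frequency discretization into n_bins levels
discretize_ef <- function(x, n_bins) {
  br <- unique(stats::quantile(x, probs = seq(0, 1, length.out = n_bins + 1L)))
  if (length(br) < 2L) return(NULL)  # constant vector
  cut(x, breaks = br, include.lowest = TRUE, labels = FALSE)
}

# plug-in mutual information (nats) between two discretized vectors
mi_discrete <- function(dx, dy) {
  tab <- table(dx, dy) / length(dx)
  px <- rowSums(tab); py <- colSums(tab)
  nz <- tab > 0
  sum(tab[nz] * log(tab[nz] / outer(px, py)[nz]))
}

#' ARACNE-style mutual-information network
#'
#' Pairwise mutual information from equal-frequency discretization
#' (`n_bins` levels, plug-in estimator in nats). The significance
#' threshold is the (1 - alpha) quantile of MI between `n_perm` randomly
#' chosen gene pairs with one member's samples permuted (seeded). Edges
#' below the threshold are removed; the data processing inequality then
#' prunes, in every triangle of surviving edges, the edge (i, j) whose MI
#' falls below min(MI_ik, MI_kj) * (1 - dpi_eps) — indirect associations
#' lose to the two stronger edges. Connectivity is the degree in the
#' retained unweighted graph.
#'
#' @param expr Genes x samples matrix (a module submatrix, typically).
#' @param n_bins Equal-frequency bins (default 5).
#' @param n_perm Permutation pairs for the null MI (default 100).
#' @param alpha Significance level for the MI threshold (default 0.05).
#' @param dpi_eps DPI tolerance (default 0: strict inequality).
#' @param seed Integer seed for the permutations.
#' @return List of class `fetomod_mi_network`: `mi` (symmetric matrix),
#'   `adjacency` (logical retained edges), `degree` (named), `threshold`,
#'   `dropped_genes`.
#' @export
aracne_network <- function(expr, n_bins = 5L, n_perm = 100L, alpha = 0.05,
                           dpi_eps = 0, seed = 1L) {
  stopifnot(is.matrix(expr), nrow(expr) >= 3L)
  if (ncol(expr) < 20L) warning("fewer than 20 samples: MI estimates are noisy")
  disc <- lapply(seq_len(nrow(expr)), function(i) discretize_ef(expr[i, ], n_bins))
  dropped <- rownames(expr)[vapply(disc, is.null, logical(1L))]
  if (length(dropped)) {
    message("aracne_network: dropped ", length(dropped), " constant gene(s)")
  }
  keep <- !vapply(disc, is.null, logical(1L))
  expr <- expr[keep, , drop = FALSE]
  disc <- disc[keep]
  g <- nrow(expr)
  ids <- rownames(expr)
  mi <- matrix(0, g, g, dimnames = list(ids, ids))
  for (i in seq_len(g - 1L)) {
    for (j in (i + 1L):g) {
      mi[i, j] <- mi[j, i] <- mi_discrete(disc[[i]], disc[[j]])
    }
  }
  diag(mi) <- vapply(disc, function(d) mi_discrete(d, d), numeric(1L))
  # permutation null: MI of random pairs with one side shuffled
  set.seed(seed)
  null_mi <- vapply(seq_len(n_perm), function(b) {
    ij <- sample(g, 2L)
    mi_discrete(disc[[ij[1L]]], sample(disc[[ij[2L]]]))
  }, numeric(1L))
  threshold <- stats::quantile(null_mi, 1 - alpha, names = FALSE)
  adj <- mi > threshold
  diag(adj) <- FALSE
  # data processing inequality over triangles of surviving edges
  if (g >= 3L) {
    remove <- matrix(FALSE, g, g)
    for (i in seq_len(g - 1L)) {
      for (j in (i + 1L):g) {
        if (!adj[i, j]) next
        ks <- which(adj[i, ] & adj[j, ])
        ks <- ks[ks != i & ks != j]
        if (any(mi[i, j] < pmin(mi[i, ks], mi[j, ks]) * (1 - dpi_eps))) {
          remove[i, j] <- remove[j, i] <- TRUE
        }
      }
    }
    adj <- adj & !remove
  }
  degree <- stats::setNames(rowSums(adj), ids)
  structure(list(mi = mi, adjacency = adj, degree = degree,
                 threshold = threshold, dropped_genes = dropped,
                 alpha = alpha, n_bins = n_bins, seed = seed),
            class = "fetomod_mi_network")
}

#' Compare hub connectivity between gene groups
#'
#' Kruskal-Wallis test over the degree distributions of the groups,
#' followed by pairwise two-sided Wilcoxon tests of each group against the
#' reference group (the full module, typically) with BH correction.
#'
#' @param network A [aracne_network()] result.
#' @param gene_groups Named list of gene-id vectors (subsets of the
#'   network's nodes).
#' @param reference_group Name of the reference entry in `gene_groups`.
#' @return As [compare_score_groups()]: `global` and `pairwise` tables.
#'   Groups with fewer than 3 nodes are flagged in a `small_groups`
#'   element but still tested.
#' @export
compare_connectivity <- function(network, gene_groups, reference_group) {
  stopifnot(inherits(network, "fetomod_mi_network"),
            reference_group %in% names(gene_groups))
  nodes <- names(network$degree)
  gene_groups <- lapply(gene_groups, intersect, x = nodes)
  small <- names(gene_groups)[lengths(gene_groups) < 3L]
  if (length(small)) {
    warning("group(s) with < 3 network nodes: ", paste(small, collapse = ", "))
  }
  gene_groups <- gene_groups[lengths(gene_groups) > 0L]
  scores <- unlist(lapply(gene_groups, function(g) network$degree[g]),
                   use.names = FALSE)
  labels <- rep(names(gene_groups), lengths(gene_groups))
  out <- compare_score_groups(scores, labels, reference = reference_group,
                              min_group = 1L)
  out$small_groups <- small
  out
}
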