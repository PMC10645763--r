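#' Filter lowly expressed and invariant genes
#'
#' Keeps genes with a positive value in strictly more than
#' `expressed_fraction` of samples (default 90%, the study's filter) and
#' drops zero-variance genes, the good-genes check hierarchical clustering
#' and correlation networks require.
#'
#' @param expr Genes x samples non-negative matrix.
#' @param expressed_fraction Required fraction of samples with value > 0.
#' @return The filtered matrix; errors if nothing survives.
#' @export
filter_genes <- function(expr, expressed_fraction = 0.9) {
  stopifnot(is.matrix(expr))
  if (any(expr < 0)) stop("expression must be non-negative")
  frac <- rowMeans(expr > 0)
  keep <- frac > expressed_fraction
  v <- apply(expr, 1L, stats::var)
  keep <- keep & v > 0
  if (!any(keep)) stop("no genes pass the expression filter")
  n_drop <- sum(!keep)
  if (n_drop > 0) message("filter_genes: dropped ", n_drop, " gene(s)")
  expr[keep, , drop = FALSE]
}

#' Flag outlier samples by hierarchical clustering
#'
#' Average-linkage clustering on Euclidean sample distances; a sample is
#' flagged when the height at which it first joins the tree exceeds
#' mean + `cut_sd` standard deviations of all merge heights. This mirrors
#' the visual dendrogram check used to drop aberrant tissue samples (e.g.
#' blood-clot contamination) before network construction.
#'
#' @param expr Genes x samples matrix.
#' @param cut_sd Multiple of the merge-height SD above the mean (default 2.5).
#' @return Character vector of flagged sample ids (possibly empty).
#' @export
detect_sample_outliers <- function(expr, cut_sd = 2.5) {
  stopifnot(is.matrix(expr))
  n <- ncol(expr)
  if (n < 4L) stop("need at least 4 samples to call outliers")
  hc <- stats::hclust(stats::dist(t(expr)), method = "average")
  cut <- mean(hc$height) + cut_sd * stats::sd(hc$height)
  # height at which each leaf is absorbed into the tree
  join_height <- vapply(seq_len(n), function(i) {
    hc$height[which(hc$merge == -i, arr.ind = TRUE)[1L, "row"]]
  }, numeric(1L))
  colnames(expr)[join_height > cut]
}

# biweight-midcorrelation transform of one vector: median-centered,
# Tukey-biweight weighted; MAD = 0 falls back to the Pearson transform
bicor_transform <- function(x) {
  med <- stats::median(x)
  mad0 <- stats::mad(x, constant = 1)
  if (mad0 == 0) return(x - mean(x))
  u <- (x - med) / (9 * mad0)
  w <- (1 - u^2)^2 * (abs(u) < 1)
  (x - med) * w
}

#' Biweight midcorrelation
#'
#' Robust correlation: observations are median-centered and down-weighted by
#' the Tukey biweight of their distance from the median (in units of
#' 9 * MAD), then correlated. Vectors with MAD = 0 fall back to Pearson.
#'
#' @param x,y Equal-length numeric vectors, n >= 3.
#' @return Correlation in \[-1, 1\].
#' @export
bicor <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3L)
  # MAD = 0 for either vector: the pair falls back to plain Pearson
  if (stats::mad(x, constant = 1) == 0 || stats::mad(y, constant = 1) == 0) {
    xt <- x - mean(x)
    yt <- y - mean(y)
  } else {
    xt <- bicor_transform(x)
    yt <- bicor_transform(y)
  }
  nx <- sqrt(sum(xt^2))
  ny <- sqrt(sum(yt^2))
  if (nx == 0 || ny == 0) stop("bicor undefined: zero weighted norm")
  sum(xt * yt) / (nx * ny)
}

#' All pairwise biweight midcorrelations between the rows of a matrix
#'
#' @param expr Genes x samples matrix (correlations across samples).
#' @return Symmetric genes x genes correlation matrix.
#' @export
bicor_matrix <- function(expr) {
  stopifnot(is.matrix(expr), ncol(expr) >= 3L)
  unit_rows <- function(m) {
    nrm <- sqrt(rowSums(m^2))
    if (any(nrm == 0)) stop("bicor undefined for gene(s): ",
                            paste(rownames(expr)[nrm == 0], collapse = ", "))
    m / nrm
  }
  deg <- apply(expr, 1L, function(v) stats::mad(v, constant = 1) == 0)
  B <- unit_rows(t(apply(expr, 1L, bicor_transform)))
  r <- tcrossprod(B)
  if (any(deg)) {
    # pairs involving a MAD = 0 gene fall back to full Pearson
    P <- unit_rows(expr - rowMeans(expr))
    rp <- tcrossprod(P[deg, , drop = FALSE], P)
    r[deg, ] <- rp
    r[, deg] <- t(rp)
  }
  r[r > 1] <- 1
  r[r < -1] <- -1
  diag(r) <- 1
  r
}

#' Signed (or unsigned) soft-thresholded adjacency
#'
#' Signed network: a_ij = ((1 + cor_ij) / 2)^beta, so strong negative
#' correlations get near-zero adjacency; unsigned uses |cor|^beta.
#'
#' @param expr Genes x samples matrix, or a precomputed correlation matrix
#'   passed via `cor_mat`.
#' @param power Soft-thresholding exponent beta (study default 14).
#' @param signed Use the signed transform (default TRUE).
#' @param cor_mat Optional precomputed correlation matrix (skips bicor).
#' @return Genes x genes adjacency in \[0, 1\], unit diagonal.
#' @export
adjacency <- function(expr = NULL, power = 14, signed = TRUE, cor_mat = NULL) {
  if (is.null(cor_mat)) cor_mat <- bicor_matrix(expr)
  a <- if (signed) ((1 + cor_mat) / 2)^power else abs(cor_mat)^power
  diag(a) <- 1
  a
}

#' Topological overlap matrix
#'
#' TOM_ij = (L_ij + a_ij) / (min(k_i, k_j) + 1 - a_ij) with
#' L_ij = sum over shared neighbors u of a_iu a_uj and k_i the connectivity
#' excluding the diagonal; TOM_ii = 1. 1 - TOM is the clustering
#' dissimilarity used for module detection.
#'
#' @param a Symmetric adjacency in \[0, 1\] with unit diagonal.
#' @return Symmetric TOM in \[0, 1\].
#' @export
tom <- function(a) {
  stopifnot(is.matrix(a), nrow(a) == ncol(a))
  n <- nrow(a)
  k <- rowSums(a) - diag(a)
  aa <- a %*% a
  # strip the u = i and u = j terms from the shared-neighbor path count
  L <- aa - a * matrix(diag(a), n, n) - a * matrix(diag(a), n, n, byrow = TRUE)
  num <- L + a
  den <- outer(k, k, pmin) + 1 - a
  tm <- num / den
  diag(tm) <- 1
  tm[tm > 1] <- 1
  tm[tm < 0] <- 0
  (tm + t(tm)) / 2
}

#' Choose the soft-thresholding power by scale-free topology fit
#'
#' For each candidate power the connectivity distribution is binned into 10
#' equal-count bins and log10(frequency) regressed on log10(mean
#' connectivity); the signed fit index is R^2 times the negative sign of the
#' slope (scale-free topology implies a negative slope). Returns the
#' smallest power reaching `target_r2`, else the power with the best signed
#' fit.
#'
#' @param expr Genes x samples matrix (>= 50 genes).
#' @param powers Candidate powers.
#' @param target_r2 Signed R^2 considered an adequate fit (default 0.8).
#' @param signed Signed network transform (default TRUE).
#' @return List with `power` (chosen) and `fit` (per-power table of signed
#'   R^2, slope and mean connectivity).
#' @export
pick_soft_threshold <- function(expr, powers = c(1:10, 12, 14, 16, 18, 20),
                                target_r2 = 0.8, signed = TRUE) {
  stopifnot(nrow(expr) >= 50L)
  cm <- bicor_matrix(expr)
  fit <- do.call(rbind, lapply(powers, function(b) {
    a <- adjacency(power = b, signed = signed, cor_mat = cm)
    k <- rowSums(a) - 1
    sf <- scale_free_fit(k)
    data.frame(power = b, signed_r2 = sf$signed_r2, slope = sf$slope,
               mean_k = mean(k))
  }))
  ok <- which(fit$signed_r2 >= target_r2)
  chosen <- if (length(ok)) fit$power[ok[1L]] else
    fit$power[which.max(fit$signed_r2)]
  list(power = chosen, fit = fit)
}

scale_free_fit <- function(k, n_bins = 10L) {
  br <- unique(stats::quantile(k, probs = seq(0, 1, length.out = n_bins + 1L)))
  if (length(br) < 3L) return(list(signed_r2 = 0, slope = 0))
  cut_k <- cut(k, breaks = br, include.lowest = TRUE)
  freq <- tabulate(cut_k, nbins = nlevels(cut_k)) / length(k)
  mk <- tapply(k, cut_k, mean)
  keep <- freq > 0 & mk > 0
  if (sum(keep) < 3L) return(list(signed_r2 = 0, slope = 0))
  fit <- suppressWarnings(stats::lm(log10(freq[keep]) ~ log10(mk[keep])))
  r2 <- suppressWarnings(summary(fit)$r.squared)
  slope <- stats::coef(fit)[[2L]]
  list(signed_r2 = -sign(slope) * r2, slope = slope)
}

# WGCNA-style color names assigned to modules in decreasing size order
module_palette <- c(
  "turquoise", "blue", "brown", "yellow", "green", "red", "black", "pink",
  "magenta", "purple", "greenyellow", "tan", "salmon", "cyan",
  "midnightblue", "lightcyan", "grey60", "lightgreen", "lightyellow",
  "royalblue", "darkred", "darkgreen", "darkturquoise", "darkgrey",
  "orange", "darkorange", "white", "skyblue", "saddlebrown", "steelblue",
  "paleturquoise", "violet", "darkolivegreen", "darkmagenta"
)

#' Cut the TOM dendrogram into modules
#'
#' Average-linkage clustering on 1 - TOM, then a top-down coarse cut. The
#' default `"gap"` cut places the height threshold at the midpoint of the
#' largest gap in the sorted merge heights: tight module branches merge in
#' a low band well separated from the background joins, while featureless
#' (noise) trees have their largest gap at the very bottom, so nothing
#' clusters and everything stays grey. The `"static"` variant cuts at
#' `cut_height_frac` times the maximum merge height instead; at high soft
#' powers TOM dissimilarities compress toward 1 and the static rule can
#' fall below every informative merge, which is why it is not the default.
#' Coarse clusters of at least `min_module_size` genes become modules; one
#' refinement pass re-cuts any module whose internal merge-height profile
#' shows a gap larger than `gap_frac` of its height range, keeping
#' sub-clusters of at least `min_module_size`. Unassigned genes receive
#' the reserved "grey" label. Modules are named by decreasing size with
#' conventional network colors.
#'
#' @param tom_mat TOM matrix from [tom()].
#' @param min_module_size Smallest allowed module (default 30).
#' @param cut_method `"gap"` (largest height gap, default) or `"static"`.
#' @param cut_height_frac Static cut as a fraction of the maximum merge
#'   height (used by `cut_method = "static"`).
#' @param gap_frac Relative height-gap that triggers a refinement split
#'   (default 0.25).
#' @return Named character vector gene -> module label ("grey" = none).
#' @export
cut_modules <- function(tom_mat, min_module_size = 30L,
                        cut_method = c("gap", "static"),
                        cut_height_frac = 0.99, gap_frac = 0.25) {
  stopifnot(nrow(tom_mat) >= min_module_size)
  cut_method <- match.arg(cut_method)
  genes <- rownames(tom_mat)
  if (is.null(genes)) genes <- paste0("g", seq_len(nrow(tom_mat)))
  d <- stats::as.dist(1 - tom_mat)
  hc <- stats::hclust(d, method = "average")
  if (cut_method == "gap") {
    sh <- sort(hc$height)
    if (length(sh) < 2L) return(stats::setNames(rep("grey", length(genes)),
                                                genes))
    # a cut below the (min_module_size - 1)-th merge cannot contain any
    # module, so gaps in that bottom tail (tight outlier pairs) are ignored
    lo <- min(min_module_size - 1L, length(sh) - 1L)
    g <- diff(sh)
    i <- (lo:length(g))[which.max(g[lo:length(g)])]
    h0 <- (sh[i] + sh[i + 1L]) / 2
  } else {
    h0 <- cut_height_frac * max(hc$height)
  }
  coarse <- stats::cutree(hc, h = h0)
  labels <- rep("grey", length(genes))
  names(labels) <- genes
  clusters <- split(seq_along(genes), coarse)
  clusters <- clusters[lengths(clusters) >= min_module_size]
  members <- list()
  for (cl in clusters) {
    members <- c(members, refine_cluster(tom_mat, cl, min_module_size,
                                         gap_frac))
  }
  if (length(members)) {
    members <- members[order(-lengths(members))]
    nms <- c(module_palette, paste0("module", seq_along(members)))
    for (i in seq_along(members)) labels[members[[i]]] <- nms[i]
  }
  labels
}

# one-pass top-down refinement: split a cluster at its largest internal
# height gap when that gap dominates the height range
refine_cluster <- function(tom_mat, idx, min_module_size, gap_frac) {
  if (length(idx) < 2L * min_module_size) return(list(idx))
  sub <- tom_mat[idx, idx]
  hc <- stats::hclust(stats::as.dist(1 - sub), method = "average")
  h <- sort(hc$height)
  rng <- max(h) - min(h)
  if (rng <= 0) return(list(idx))
  gaps <- diff(h)
  gi <- which.max(gaps)
  if (gaps[gi] <= gap_frac * rng) return(list(idx))
  cut_h <- (h[gi] + h[gi + 1L]) / 2
  sub_cl <- stats::cutree(hc, h = cut_h)
  parts <- split(idx, sub_cl)
  parts <- parts[lengths(parts) >= min_module_size]
  if (length(parts) < 2L) return(list(idx))  # degenerate split: keep intact
  unname(parts)
}

#' Module eigengenes
#'
#' The eigengene is the first principal component of the standardized module
#' submatrix across samples, scaled to unit variance and oriented so it
#' correlates positively with the module's mean expression profile. The
#' proportion of module variance it explains is reported per module.
#'
#' @param expr Genes x samples matrix.
#' @param labels Named gene -> module vector; "grey" is skipped.
#' @return List with `eigengenes` (samples x modules matrix) and
#'   `var_explained` (named numeric).
#' @export
module_eigengenes <- function(expr, labels) {
  mods <- sort(setdiff(unique(labels), "grey"))
  if (!length(mods)) stop("no modules to summarize")
  E <- matrix(NA_real_, ncol(expr), length(mods),
              dimnames = list(colnames(expr), mods))
  ve <- stats::setNames(numeric(length(mods)), mods)
  for (m in mods) {
    genes <- names(labels)[labels == m]
    if (length(genes) < 2L) stop("module ", m, " has fewer than 2 genes")
    sub <- expr[genes, , drop = FALSE]
    z <- t(scale(t(sub)))
    z[!is.finite(z)] <- 0
    sv <- svd(z, nu = 0L, nv = 1L)
    e <- sv$v[, 1L]
    if (stats::cor(e, colMeans(sub)) < 0) e <- -e
    E[, m] <- e / stats::sd(e)
    ve[m] <- sv$d[1L]^2 / sum(sv$d^2)
  }
  list(eigengenes = E, var_explained = ve)
}

#' Merge modules with highly correlated eigengenes
#'
#' Iteratively merges the pair of modules whose eigengene correlation is
#' highest while it exceeds `threshold` (study default r > 0.85),
#' recomputing eigengenes after every merge. The merged module keeps the
#' larger member's name (lexicographic tie-break).
#'
#' @param expr Genes x samples matrix.
#' @param labels Named gene -> module vector.
#' @param threshold Eigengene correlation above which modules merge.
#' @return Updated label vector.
#' @export
merge_modules <- function(expr, labels, threshold = 0.85) {
  repeat {
    mods <- sort(setdiff(unique(labels), "grey"))
    if (length(mods) < 2L) return(labels)
    me <- module_eigengenes(expr, labels)$eigengenes
    cc <- stats::cor(me)
    diag(cc) <- -Inf
    top <- which(cc == max(cc), arr.ind = TRUE)
    # deterministic choice among ties: lexicographic pair
    top <- top[order(rownames(cc)[top[, 1L]], colnames(cc)[top[, 2L]]), ,
               drop = FALSE]
    if (cc[top[1L, 1L], top[1L, 2L]] <= threshold) return(labels)
    a <- rownames(cc)[top[1L, 1L]]
    b <- colnames(cc)[top[1L, 2L]]
    na <- sum(labels == a); nb <- sum(labels == b)
    keep <- if (na > nb) a else if (nb > na) b else min(a, b)
    drop_ <- setdiff(c(a, b), keep)
    labels[labels == drop_] <- keep
  }
}

#' Full signed co-expression network construction
#'
#' Convenience wrapper running the whole module-detection chain: gene
#' filtering, sample-outlier removal, soft-threshold selection (unless a
#' power is fixed in the config), signed adjacency, TOM, tree cutting,
#' eigengene computation and eigengene merging.
#'
#' @param expr Genes x samples non-negative matrix.
#' @param config An [analysis_config()]; `soft_power = NULL` triggers
#'   scale-free selection.
#' @param filter Apply the expressed-fraction gene filter (disable for
#'   already-clean or simulated input).
#' @return List of class `fetomod_network`: `labels`, `eigengenes`,
#'   `var_explained`, `power`, `removed_samples`, `tom` and `expr` (the
#'   filtered matrix).
#' @export
build_network <- function(expr, config = analysis_config(), filter = TRUE) {
  if (filter) expr <- filter_genes(expr, config$expressed_fraction)
  removed <- character(0)
  if (ncol(expr) >= 4L) {
    removed <- detect_sample_outliers(expr, config$outlier_cut_sd)
    if (length(removed)) {
      message("build_network: removed ", length(removed), " outlier sample(s)")
      expr <- expr[, setdiff(colnames(expr), removed), drop = FALSE]
    }
  }
  power <- config$soft_power
  fit <- NULL
  if (is.null(power)) {
    st <- pick_soft_threshold(expr, target_r2 = config$scale_free_target_r2,
                              signed = config$signed)
    power <- st$power
    fit <- st$fit
  }
  a <- adjacency(expr, power = power, signed = config$signed)
  tm <- tom(a)
  labels <- cut_modules(tm, config$min_module_size, config$cut_method,
                        config$cut_height_frac, config$gap_frac)
  if (any(labels != "grey")) {
    labels <- merge_modules(expr, labels, config$merge_cor_threshold)
    eig <- module_eigengenes(expr, labels)
  } else {
    eig <- list(eigengenes = NULL, var_explained = NULL)
  }
  structure(list(labels = labels, eigengenes = eig$eigengenes,
                 var_explained = eig$var_explained, power = power,
                 soft_threshold_fit = fit, removed_samples = removed,
                 tom = tm, expr = expr),
            class = "fetomod_network")
}

#' @export
print.fetomod_network <- function(x, ...) {
  tab <- sort(table(x$labels), decreasing = TRUE)
  cat("fetomod network: ", length(x$labels), " genes, power ", x$power,
      "\n", sep = "")
  cat("modules (", sum(names(tab) != "grey"), "):\n", sep = "")
  print(tab)
  invisible(x)
}
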