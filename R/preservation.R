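#' Permutation Zsummary module preservation
#'
#' Tests whether modules defined in a reference expression dataset keep
#' their density and connectivity structure in an independent test dataset.
#' Six component statistics are computed per module on the test data:
#' density — meanAdj (mean off-diagonal signed adjacency among module
#' genes), propVarExplained (by the test-data eigengene), meanSignedKME
#' (mean correlation of module genes with that eigengene); connectivity —
#' cor.kIM (correlation of intramodular connectivity vectors, reference vs
#' test), cor.kME and cor.cor (correlation of the vectorized off-diagonal
#' gene-gene correlations). Each statistic is standardized against
#' `n_perm` label permutations: module labels are reassigned uniformly at
#' random in the test data (sizes preserved) while the reference side keeps
#' the real module, so the cross-dataset correlation statistics have a null
#' centered near zero; Z = (obs - mean_perm) / sd_perm. Zdensity and
#' Zconnectivity are the medians of their three Zs and
#' Zsummary = (Zdensity + Zconnectivity) / 2. Classification follows the
#' conventional thresholds: < 2 none, 2-10 weak-moderate, > 10 strong.
#'
#' @param ref_expr Reference genes x samples matrix (where modules were
#'   defined).
#' @param labels Named gene -> module vector from the reference network.
#' @param test_expr Test genes x samples matrix; genes absent from it are
#'   dropped from modules with a message.
#' @param n_perm Number of label permutations (study default 100; >= 20).
#' @param power Soft power reused for the test-data adjacency (reference
#'   network default 14).
#' @param seed Integer seed for the permutations.
#' @return A data.frame of class `fetomod_preservation`, one row per module:
#'   Zdensity, Zconnectivity, Zsummary, class, module size used, plus the
#'   six component Zs.
#' @export
module_preservation <- function(ref_expr, labels, test_expr, n_perm = 100L,
                                power = 14, seed = 1L) {
  stopifnot(n_perm >= 20L)
  common <- intersect(rownames(ref_expr), rownames(test_expr))
  dropped <- sum(!names(labels) %in% common)
  labels <- labels[names(labels) %in% common]
  mods <- sort(setdiff(unique(labels), "grey"))
  if (!length(mods)) stop("no non-grey modules overlap the test dataset")
  if (dropped) message("module_preservation: dropped ", dropped,
                       " gene(s) absent from the test data")
  universe <- names(labels)
  ref <- ref_expr[universe, , drop = FALSE]
  test <- test_expr[universe, , drop = FALSE]
  # correlations over the whole label universe, computed once
  cor_ref <- stats::cor(t(ref))
  cor_test <- stats::cor(t(test))
  adj_test <- ((1 + cor_test) / 2)^power

  stat_names <- c("meanAdj", "propVarExplained", "meanSignedKME",
                  "cor.kIM", "cor.kME", "cor.cor")
  eigengene_of <- function(mat, gene_idx) {
    z <- t(scale(t(mat[gene_idx, , drop = FALSE])))
    z[!is.finite(z)] <- 0
    sv <- svd(z, nu = 0L, nv = 1L)
    e <- sv$v[, 1L]
    if (stats::cor(e, colMeans(mat[gene_idx, , drop = FALSE])) < 0) e <- -e
    list(e = e, pve = sv$d[1L]^2 / sum(sv$d^2))
  }
  # reference-side module vectors: computed once, for the REAL module genes;
  # permutations reassign labels in the test data only (paired by position)
  ref_side <- function(gene_idx) {
    cr <- cor_ref[gene_idx, gene_idx]
    er <- eigengene_of(ref, gene_idx)$e
    list(kim = rowSums(((1 + cr) / 2)^power) - 1,
         kme = stats::cor(t(ref[gene_idx, , drop = FALSE]), er)[, 1L],
         corvec = cr[upper.tri(cr)])
  }
  test_side_stats <- function(gene_idx, refv) {
    ct <- cor_test[gene_idx, gene_idx]
    at <- adj_test[gene_idx, gene_idx]
    off <- upper.tri(ct)
    eg <- eigengene_of(test, gene_idx)
    kme_test <- stats::cor(t(test[gene_idx, , drop = FALSE]), eg$e)[, 1L]
    kim_test <- rowSums(at) - 1
    c(meanAdj = mean(at[off]),
      propVarExplained = eg$pve,
      meanSignedKME = mean(kme_test),
      cor.kIM = stats::cor(refv$kim, kim_test),
      cor.kME = stats::cor(refv$kme, kme_test),
      cor.cor = stats::cor(refv$corvec, ct[off]))
  }

  sizes <- table(labels)[mods]
  refv <- lapply(mods, function(m) ref_side(which(labels == m)))
  names(refv) <- mods
  obs <- t(vapply(mods, function(m)
    test_side_stats(which(labels == m), refv[[m]]),
    numeric(length(stat_names))))
  set.seed(seed)
  perm <- array(NA_real_, c(n_perm, length(mods), length(stat_names)),
                dimnames = list(NULL, mods, stat_names))
  for (b in seq_len(n_perm)) {
    shuffled <- sample(labels)  # test-data labels: sizes preserved
    for (mi in seq_along(mods)) {
      perm[b, mi, ] <- test_side_stats(which(shuffled == mods[mi]),
                                       refv[[mods[mi]]])
    }
  }
  res <- do.call(rbind, lapply(seq_along(mods), function(mi) {
    mu <- apply(perm[, mi, , drop = FALSE], 3L, mean, na.rm = TRUE)
    sd_ <- apply(perm[, mi, , drop = FALSE], 3L, stats::sd, na.rm = TRUE)
    z <- (obs[mi, ] - mu) / sd_
    degenerate <- sd_ == 0
    z[degenerate & obs[mi, ] > mu] <- Inf
    z[degenerate & obs[mi, ] <= mu] <- 0
    zd <- stats::median(z[1:3])
    zc <- stats::median(z[4:6])
    zs <- (zd + zc) / 2
    cls <- if (zs < 2) "none" else if (zs <= 10) "weak-moderate" else "strong"
    out <- data.frame(module = mods[mi], size = as.integer(sizes[mi]),
                      Zdensity = zd, Zconnectivity = zc, Zsummary = zs,
                      class = cls, degenerate = any(degenerate),
                      stringsAsFactors = FALSE)
    for (s in stat_names) out[[paste0("Z.", s)]] <- z[[s]]
    out
  }))
  attr(res, "n_perm") <- n_perm
  attr(res, "seed") <- seed
  class(res) <- c("fetomod_preservation", "data.frame")
  res
}
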