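#' Map SNPs to genes by position
#'
#' A SNP is assigned to a gene when its position falls inside the gene body
#' extended by `window_kb` kilobases on each side (default 0: gene body
#' only). Coordinates are 1-based inclusive. A SNP overlapping several
#' genes yields one pair per gene.
#'
#' @param variants Data.frame with `snp`, `chrom`, `pos`.
#' @param gene_annotations Data.frame with `gene`, `chrom`, `start`, `end`
#'   (1-based inclusive).
#' @param genes Optional character vector restricting the annotation to a
#'   gene list (e.g. a module); genes missing from the annotation are
#'   skipped with a message.
#' @param window_kb Flanking window in kb added to both gene ends.
#' @return Data.frame of (snp, gene) pairs.
#' @export
map_snps_to_genes <- function(variants, gene_annotations, genes = NULL,
                              window_kb = 0) {
  stopifnot(all(c("snp", "chrom", "pos") %in% colnames(variants)),
            all(c("gene", "chrom", "start", "end") %in%
                  colnames(gene_annotations)))
  ann <- gene_annotations
  if (!is.null(genes)) {
    missing_ann <- setdiff(genes, ann$gene)
    if (length(missing_ann)) {
      message("map_snps_to_genes: no annotation for ", length(missing_ann),
              " gene(s); skipped")
    }
    ann <- ann[ann$gene %in% genes, , drop = FALSE]
  }
  w <- window_kb * 1000
  out <- lapply(seq_len(nrow(ann)), function(i) {
    hit <- variants$chrom == ann$chrom[i] &
      variants$pos >= ann$start[i] - w &
      variants$pos <= ann$end[i] + w
    if (!any(hit)) return(NULL)
    data.frame(snp = variants$snp[hit], gene = ann$gene[i],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) out <- data.frame(snp = character(0), gene = character(0),
                                      stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Greedy LD clumping of eQTL records
#'
#' Sorts records by p-value ascending, accepts the top SNP as an index, and
#' removes every remaining SNP within `window_kb` of it whose squared
#' Pearson dosage correlation with the index is at least `r2_threshold`
#' (study rule: retain only pairs with r^2 < 0.2), then repeats. SNPs
#' missing from the reference genotypes pass through with a warning.
#'
#' @param eqtls Data.frame of eQTL records (needs `snp`, `p`).
#' @param reference_genotypes A genotype list (`dosages`, `variants`) used
#'   as the LD reference panel.
#' @param r2_threshold Squared-correlation threshold (default 0.2).
#' @param window_kb Clumping window in kb (default 250).
#' @return The retained subset of `eqtls`, index SNPs first (by p).
#' @export
ld_clump <- function(eqtls, reference_genotypes, r2_threshold = 0.2,
                     window_kb = 250) {
  stopifnot(all(c("snp", "p") %in% colnames(eqtls)))
  if (!nrow(eqtls)) return(eqtls)
  dos <- reference_genotypes$dosages
  vi <- reference_genotypes$variants
  absent <- setdiff(eqtls$snp, colnames(dos))
  if (length(absent)) {
    warning("ld_clump: ", length(absent),
            " SNP(s) absent from the LD reference; passed through")
  }
  ord <- order(eqtls$p, eqtls$snp)  # snp id breaks p ties deterministically
  pending <- eqtls$snp[ord]
  keep <- character(0)
  w <- window_kb * 1000
  info <- vi[match(pending, vi$snp), c("chrom", "pos")]
  rownames(info) <- pending
  while (length(pending)) {
    idx <- pending[1L]
    keep <- c(keep, idx)
    pending <- pending[-1L]
    if (!length(pending) || !idx %in% colnames(dos)) next
    near <- pending[pending %in% colnames(dos) &
                      !is.na(info[pending, "chrom"]) &
                      info[pending, "chrom"] == info[idx, "chrom"] &
                      abs(info[pending, "pos"] - info[idx, "pos"]) <= w]
    if (length(near)) {
      r2 <- suppressWarnings(
        stats::cor(dos[, idx], dos[, near, drop = FALSE])^2)
      drop_ <- near[!is.na(r2) & r2 >= r2_threshold]
      pending <- setdiff(pending, drop_)
    }
  }
  out <- eqtls[match(keep, eqtls$snp), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Assemble PGS weights from clumped eQTL records
#'
#' One weight per SNP: a SNP that is an eQTL for several module genes
#' contributes once, with the smallest-p record's effect size.
#'
#' @param eqtls Clumped eQTL records (`snp`, `effect_allele`,
#'   `other_allele`, `beta`, `p`, optionally `gene`).
#' @param tag Provenance label (module name or control type).
#' @return Data.frame of class `fetomod_pgs_weights`.
#' @export
pgs_weights <- function(eqtls, tag = "module") {
  stopifnot(all(c("snp", "effect_allele", "other_allele", "beta") %in%
                  colnames(eqtls)))
  ord <- if ("p" %in% colnames(eqtls)) order(eqtls$p, eqtls$snp)
  else seq_len(nrow(eqtls))
  e <- eqtls[ord, , drop = FALSE]
  dup <- duplicated(e$snp)
  if (any(dup)) {
    message("pgs_weights: ", sum(dup),
            " SNP(s) mapped to several genes; smallest-p record kept")
    e <- e[!dup, , drop = FALSE]
  }
  out <- data.frame(snp = e$snp, effect_allele = e$effect_allele,
                    other_allele = e$other_allele, weight = e$beta,
                    gene = if ("gene" %in% colnames(e)) e$gene else NA_character_,
                    stringsAsFactors = FALSE)
  attr(out, "tag") <- tag
  class(out) <- c("fetomod_pgs_weights", "data.frame")
  rownames(out) <- NULL
  out
}

#' Compute a per-sample expression polygenic score
#'
#' score_s = sum_j weight_j * dosage_sj after orienting each weight to the
#' cohort's allele coding: if the weight's effect/other alleles are swapped
#' relative to the genotype file, the weight's sign is flipped (so a record
#' re-expressed on the opposite allele yields the identical score); if
#' neither orientation matches, the SNP is dropped with a message. Missing
#' dosages are imputed per `missing_policy`: "mean" (2 x in-cohort effect
#' allele frequency, the default), "zero", or "drop" (sample-wise pairwise
#' deletion of that SNP).
#'
#' @param genotypes Genotype list (`dosages`, `variants`).
#' @param weights A [pgs_weights()] table.
#' @param missing_policy One of "mean", "zero", "drop".
#' @return Named numeric vector of scores (one per sample).
#' @export
build_pgs <- function(genotypes, weights,
                      missing_policy = c("mean", "zero", "drop")) {
  missing_policy <- match.arg(missing_policy)
  stopifnot(nrow(weights) > 0)
  dos <- genotypes$dosages
  vi <- genotypes$variants
  m <- match(weights$snp, vi$snp)
  usable <- !is.na(m)
  if (any(!usable)) {
    message("build_pgs: ", sum(!usable), " weight SNP(s) not genotyped; dropped")
  }
  w <- weights[usable, , drop = FALSE]
  gvi <- vi[m[usable], , drop = FALSE]
  direct <- w$effect_allele == gvi$effect_allele &
    w$other_allele == gvi$other_allele
  swapped <- w$effect_allele == gvi$other_allele &
    w$other_allele == gvi$effect_allele
  mismatch <- !direct & !swapped
  if (any(mismatch)) {
    message("build_pgs: ", sum(mismatch),
            " SNP(s) with unresolvable allele mismatch; dropped")
  }
  w <- w[!mismatch, , drop = FALSE]
  direct <- direct[!mismatch]
  if (!nrow(w)) stop("no usable SNPs left for the PGS")
  D <- dos[, w$snp, drop = FALSE]
  w$weight[!direct] <- -w$weight[!direct]
  if (anyNA(D)) {
    if (missing_policy == "mean") {
      eaf2 <- colMeans(D, na.rm = TRUE)  # = 2 x effect allele frequency
      for (j in which(colSums(is.na(D)) > 0)) D[is.na(D[, j]), j] <- eaf2[j]
    } else if (missing_policy == "zero") {
      D[is.na(D)] <- 0
    }  # "drop": NAs excluded per sample below
  }
  W <- matrix(w$weight, nrow(D), ncol(D), byrow = TRUE)
  score <- rowSums(D * W, na.rm = missing_policy == "drop")
  stats::setNames(score, rownames(dos))
}

#' Negative-control PGS gene sets and weights
#'
#' Three specificity controls mirror the study design: `size_matched_module`
#' uses another detected module of similar size; `random_genes` draws a
#' size-matched random gene list from the expressed-gene universe;
#' `alternative_tissue_weights` keeps the target module's genes but swaps
#' in a second tissue's eQTL effect sizes.
#'
#' @param mode One of "size_matched_module", "random_genes",
#'   "alternative_tissue_weights".
#' @param size Target gene-list size (for `random_genes`).
#' @param universe Expressed-gene universe to draw from.
#' @param module_genes Target module's genes (for
#'   `alternative_tissue_weights`; also the default size reference).
#' @param alt_modules Named list of other modules' gene sets (for
#'   `size_matched_module`; the closest in size is chosen).
#' @param seed Integer seed for the random draw.
#' @return Character vector of control genes, or for
#'   `alternative_tissue_weights` simply `module_genes` (the caller then
#'   supplies the alternative eQTL table to [pgs_weights()]).
#' @export
negative_control_genes <- function(mode = c("size_matched_module",
                                            "random_genes",
                                            "alternative_tissue_weights"),
                                   size = NULL, universe = NULL,
                                   module_genes = NULL, alt_modules = NULL,
                                   seed = 1L) {
  mode <- match.arg(mode)
  if (is.null(size) && !is.null(module_genes)) size <- length(module_genes)
  switch(mode,
    random_genes = {
      stopifnot(!is.null(universe), !is.null(size))
      if (length(universe) < size) stop("gene universe smaller than requested size")
      set.seed(seed)
      sample(universe, size)
    },
    size_matched_module = {
      stopifnot(!is.null(alt_modules), length(alt_modules) > 0,
                !is.null(size))
      gap <- abs(lengths(alt_modules) - size)
      alt_modules[[which.min(gap)]]
    },
    alternative_tissue_weights = {
      stopifnot(!is.null(module_genes))
      module_genes
    }
  )
}

#' Regress module expression scores on a PGS
#'
#' Ordinary least squares of a per-sample module score (e.g. its ssGSEA
#' enrichment) on the PGS plus covariates, the validation used to show the
#' expression PGS tracks module expression. A condition-number guard
#' rejects collinear covariate matrices.
#'
#' @param pgs Named numeric PGS vector.
#' @param module_scores Named numeric score vector over the same samples.
#' @param covariates Optional data.frame of covariates (rows = samples).
#' @return One-row data.frame: beta, se, p (two-sided), n.
#' @export
validate_pgs <- function(pgs, module_scores, covariates = NULL) {
  samples <- intersect(names(pgs), names(module_scores))
  if (!is.null(covariates)) samples <- intersect(samples, rownames(covariates))
  if (length(samples) < 3L) stop("fewer than 3 aligned samples")
  df <- data.frame(score = module_scores[samples], pgs = pgs[samples])
  if (!is.null(covariates)) df <- cbind(df, covariates[samples, , drop = FALSE])
  X <- stats::model.matrix(score ~ ., data = df)
  if (kappa(crossprod(X)) > 1e12) stop("collinear covariates in validate_pgs")
  fit <- stats::lm(score ~ ., data = df)
  cf <- summary(fit)$coefficients
  data.frame(beta = cf["pgs", 1L], se = cf["pgs", 2L], p = cf["pgs", 4L],
             n = length(samples))
}
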