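#' Parameters for the synthetic genotype-expression-phenotype generator
#'
#' The generator plants a known causal chain: LD-blocked biallelic genotypes,
#' cis-eQTL effects on module genes, latent-factor co-expression modules, and
#' an adult phenotype downstream of the genetic component of one module's
#' activity, measured in an independent (two-sample) cohort. Defaults give a
#' desk-scale system that a full simulate-analyze cycle traverses in well
#' under two minutes.
#'
#' @param n_exposure_samples,n_outcome_samples Cohort sizes (disjoint draws).
#' @param n_genes Total genes; genes beyond the planted modules are noise.
#' @param module_sizes Integer vector of planted module sizes.
#' @param n_snps Number of biallelic SNPs.
#' @param ld_block_size SNPs per LD block (each block on its own chromosome).
#' @param ld_rho Within-block latent haplotype correlation in \[0, 1).
#' @param maf_range Per-SNP minor allele frequency drawn uniformly here.
#' @param eqtl_frac Fraction of each module's genes given one cis-eQTL.
#' @param eqtl_beta_sd SD of eQTL effect sizes (per effect-allele copy).
#' @param eqtl_positive_frac If non-NULL, this fraction of eQTL betas is
#'   forced positive; default NULL leaves signs random.
#' @param loading_range Uniform interval for module-gene factor loadings.
#' @param noise_sd Residual SD of expression noise.
#' @param gamma Causal effect of target-module genetic activity on outcome.
#' @param target_module Index of the module carrying the causal effect.
#' @param pleiotropy_frac Fraction of eQTL SNPs with direct outcome effects.
#' @param pleiotropy_sd SD of direct (pleiotropic) SNP-outcome effects.
#' @param binary_outcome Threshold the liability into a case/control trait?
#' @param prevalence Case fraction when `binary_outcome` is TRUE.
#' @param seed Integer seed; all randomness derives from it.
#' @return A validated list of class `fetomod_sim_params`.
#' @export
sim_params <- function(n_exposure_samples = 1000L,
                       n_outcome_samples = 1000L,
                       n_genes = 2000L,
                       module_sizes = c(100L, 100L, 80L, 60L, 50L),
                       n_snps = 1000L,
                       ld_block_size = 10L,
                       ld_rho = 0.3,
                       maf_range = c(0.1, 0.5),
                       eqtl_frac = 0.3,
                       eqtl_beta_sd = 0.3,
                       eqtl_positive_frac = NULL,
                       loading_range = c(0.6, 0.9),
                       noise_sd = 1,
                       gamma = 0.5,
                       target_module = 1L,
                       pleiotropy_frac = 0,
                       pleiotropy_sd = 0.1,
                       binary_outcome = FALSE,
                       prevalence = 0.1,
                       seed = 1L) {
  p <- as.list(environment())
  stopifnot(
    p$n_exposure_samples >= 2, p$n_outcome_samples >= 2,
    p$n_genes >= 1, all(p$module_sizes >= 1),
    sum(p$module_sizes) <= p$n_genes,
    p$n_snps >= 1, p$ld_block_size >= 1,
    p$ld_rho >= 0, p$ld_rho < 1,
    length(p$maf_range) == 2L, p$maf_range[1] > 0, p$maf_range[2] <= 0.5,
    p$maf_range[1] <= p$maf_range[2],
    p$eqtl_frac >= 0, p$eqtl_frac <= 1,
    p$eqtl_beta_sd >= 0,
    is.null(p$eqtl_positive_frac) ||
      (p$eqtl_positive_frac >= 0 && p$eqtl_positive_frac <= 1),
    length(p$loading_range) == 2L, p$loading_range[1] <= p$loading_range[2],
    p$noise_sd >= 0,
    p$target_module >= 1, p$target_module <= length(p$module_sizes),
    p$pleiotropy_frac >= 0, p$pleiotropy_frac <= 1,
    p$pleiotropy_sd >= 0,
    is.logical(p$binary_outcome),
    p$prevalence > 0, p$prevalence < 1
  )
  n_eqtl <- sum(round(p$eqtl_frac * p$module_sizes))
  if (n_eqtl > p$n_snps) stop("not enough SNPs for the requested eQTL count")
  class(p) <- "fetomod_sim_params"
  p
}

#' Simulate LD-blocked biallelic genotype dosages
#'
#' Haplotypes arise from equicorrelated Gaussian blocks: within a block each
#' haplotype's latent vector shares a common factor with weight sqrt(rho).
#' A latent value above the (1 - MAF) normal quantile carries the effect
#' allele; the dosage is the sum of two independent haplotypes, so it lies in
#' \{0, 1, 2\}. Each block sits on its own chromosome with consecutive
#' 1-based positions spaced 1 kb apart.
#'
#' @param n Number of samples.
#' @param n_snps Number of SNPs.
#' @param block_size SNPs per LD block.
#' @param rho Within-block latent correlation in \[0, 1).
#' @param maf_range Uniform range for per-SNP minor allele frequency.
#' @param seed Integer seed.
#' @return A list with `dosages` (n x n_snps matrix, samples in rows) and
#'   `variants` (data.frame: snp, chrom, pos, effect_allele, other_allele).
#' @export
simulate_genotypes <- function(n, n_snps, block_size = 10L, rho = 0.3,
                               maf_range = c(0.1, 0.5), seed = 1L) {
  if (rho < 0 || rho >= 1) stop("rho must lie in [0, 1)")
  stopifnot(n >= 1, n_snps >= 1, block_size >= 1)
  set.seed(seed)
  maf <- stats::runif(n_snps, maf_range[1], maf_range[2])
  thresh <- stats::qnorm(1 - maf)
  n_blocks <- ceiling(n_snps / block_size)
  block <- rep(seq_len(n_blocks), each = block_size)[seq_len(n_snps)]
  hap <- function() {
    z <- matrix(0, n, n_snps)
    for (b in seq_len(n_blocks)) {
      idx <- which(block == b)
      shared <- stats::rnorm(n)
      z[, idx] <- sqrt(rho) * shared +
        sqrt(1 - rho) * matrix(stats::rnorm(n * length(idx)), n)
    }
    z
  }
  dos <- (hap() > rep(thresh, each = n)) + (hap() > rep(thresh, each = n))
  storage.mode(dos) <- "double"
  ids <- sprintf("rs%05d", seq_len(n_snps))
  pos_in_block <- stats::ave(seq_len(n_snps), block, FUN = seq_along)
  alleles <- c("A", "C", "G", "T")
  ea <- sample(alleles, n_snps, replace = TRUE)
  # avoid palindromic pairs so harmonization keeps every simulated SNP
  oa <- vapply(ea, function(a) {
    sample(setdiff(alleles, c(a, chartr("ACGT", "TGCA", a))), 1L)
  }, character(1L))
  vi <- data.frame(
    snp = ids,
    chrom = paste0("chr", block),
    pos = as.integer(pos_in_block * 1000L),
    effect_allele = ea,
    other_allele = oa,
    maf = maf,
    stringsAsFactors = FALSE
  )
  rownames(dos) <- sprintf("S%04d", seq_len(n))
  colnames(dos) <- ids
  list(dosages = dos, variants = vi)
}

#' Simulate an expression cohort with planted co-expression modules
#'
#' Expression follows a linear latent-factor model,
#' X\[g, s\] = sum_j beta_gj dosage\[s, j\] + lambda_g F\[m(g), s\] + eps,
#' with one standard-normal factor per module and per sample, loadings drawn
#' uniformly from `loading_range` for module genes (0 otherwise), Gaussian
#' noise with SD `noise_sd`, and one cis-eQTL for a random `eqtl_frac` of
#' each module's genes with effect beta ~ N(0, eqtl_beta_sd^2).
#'
#' @param params A [sim_params()] object.
#' @param cohort `"exposure"` or `"outcome"`; selects the cohort size and an
#'   independent genotype draw (two-sample structure).
#' @return A list with `genotypes` (as [simulate_genotypes()]), `expression`
#'   (genes x samples matrix), and `truth` (module labels, eQTL map, factor
#'   scores, loadings, gamma, pleiotropy flags).
#' @export
simulate_cohort <- function(params, cohort = c("exposure", "outcome")) {
  stopifnot(inherits(params, "fetomod_sim_params"))
  cohort <- match.arg(cohort)
  n <- if (cohort == "exposure") params$n_exposure_samples else
    params$n_outcome_samples
  # disjoint substreams: exposure and outcome cohorts never share draws
  geno_seed <- params$seed * 2L + (cohort == "outcome")
  geno <- simulate_genotypes(n, params$n_snps, params$ld_block_size,
                             params$ld_rho, params$maf_range, seed = geno_seed)
  set.seed(params$seed + 7L)  # truth assignment: identical for both cohorts
  n_modules <- length(params$module_sizes)
  module_names <- paste0("M", seq_len(n_modules))
  labels <- rep("grey", params$n_genes)
  gene_ids <- sprintf("G%05d", seq_len(params$n_genes))
  start <- 1L
  for (m in seq_len(n_modules)) {
    labels[start:(start + params$module_sizes[m] - 1L)] <- module_names[m]
    start <- start + params$module_sizes[m]
  }
  loadings <- numeric(params$n_genes)
  in_module <- labels != "grey"
  loadings[in_module] <- stats::runif(sum(in_module), params$loading_range[1],
                                      params$loading_range[2])
  # one cis-eQTL for a fraction of each module's genes, distinct SNPs
  eqtl_gene <- integer(0)
  for (m in seq_len(n_modules)) {
    genes_m <- which(labels == module_names[m])
    k <- round(params$eqtl_frac * length(genes_m))
    if (k > 0) eqtl_gene <- c(eqtl_gene, sample(genes_m, k))
  }
  eqtl_snp <- if (length(eqtl_gene)) sample(params$n_snps, length(eqtl_gene))
  else integer(0)
  eqtl_beta <- stats::rnorm(length(eqtl_gene), 0, params$eqtl_beta_sd)
  if (!is.null(params$eqtl_positive_frac) && length(eqtl_beta)) {
    force_pos <- stats::runif(length(eqtl_beta)) < params$eqtl_positive_frac
    eqtl_beta[force_pos] <- abs(eqtl_beta[force_pos])
  }
  pleio <- rep(FALSE, params$n_snps)
  if (params$pleiotropy_frac > 0 && length(eqtl_snp)) {
    k <- round(params$pleiotropy_frac * length(eqtl_snp))
    if (k > 0) pleio[sample(eqtl_snp, k)] <- TRUE
  }
  pleio_delta <- numeric(params$n_snps)
  pleio_delta[pleio] <- stats::rnorm(sum(pleio), 0, params$pleiotropy_sd)

  # cohort-specific draws
  set.seed(geno_seed + 104729L)
  FF <- matrix(stats::rnorm(n_modules * n), n_modules, n,
               dimnames = list(module_names, rownames(geno$dosages)))
  X <- matrix(0, params$n_genes, n,
              dimnames = list(gene_ids, rownames(geno$dosages)))
  for (m in seq_len(n_modules)) {
    idx <- which(labels == module_names[m])
    X[idx, ] <- outer(loadings[idx], FF[m, ])
  }
  if (length(eqtl_gene)) {
    X[eqtl_gene, ] <- X[eqtl_gene, ] +
      eqtl_beta * t(geno$dosages[, eqtl_snp, drop = FALSE])
  }
  X <- X + matrix(stats::rnorm(params$n_genes * n, 0, params$noise_sd),
                  params$n_genes, n)
  truth <- list(
    module_labels = stats::setNames(labels, gene_ids),
    module_names = module_names,
    eqtl_map = data.frame(
      snp = geno$variants$snp[eqtl_snp],
      gene = gene_ids[eqtl_gene],
      beta = eqtl_beta,
      module = labels[eqtl_gene],
      stringsAsFactors = FALSE
    ),
    loadings = stats::setNames(loadings, gene_ids),
    factor_scores = FF,
    gamma = params$gamma,
    target_module = module_names[params$target_module],
    pleiotropy = stats::setNames(pleio, geno$variants$snp),
    pleiotropy_delta = stats::setNames(pleio_delta, geno$variants$snp)
  )
  list(genotypes = geno, expression = X, truth = truth)
}

#' Genetic activity of the target module implied by genotypes
#'
#' The genetic component of the module summary, projected through the
#' population first principal direction of the true module covariance
#' (lambda lambda' plus the diagonal of per-gene cis and noise variances) —
#' the direction the sample PC1 of module expression estimates. Each module
#' eQTL contributes beta_j * dosage_j weighted by its gene's coordinate in
#' that direction. Used as the causal exposure in [simulate_outcome()].
#' @noRd
genetic_module_activity <- function(truth, genotypes, module, noise_sd = 1) {
  em <- truth$eqtl_map[truth$eqtl_map$module == module, , drop = FALSE]
  if (!nrow(em)) return(stats::setNames(rep(0, nrow(genotypes$dosages)),
                                        rownames(genotypes$dosages)))
  genes <- names(truth$module_labels)[truth$module_labels == module]
  lam <- truth$loadings[genes]
  cis_var <- stats::setNames(numeric(length(genes)), genes)
  vi <- genotypes$variants
  maf <- vi$maf[match(em$snp, vi$snp)]
  if (is.null(maf) || anyNA(maf)) {
    maf <- colMeans(genotypes$dosages[, em$snp, drop = FALSE],
                    na.rm = TRUE) / 2
  }
  cis_var[em$gene] <- em$beta^2 * 2 * maf * (1 - maf)
  sigma <- outer(lam, lam) + diag(cis_var + noise_sd^2, length(genes))
  v <- eigen(sigma, symmetric = TRUE)$vectors[, 1L]
  if (sum(v * lam) < 0) v <- -v
  names(v) <- genes
  drop(genotypes$dosages[, em$snp, drop = FALSE] %*% (v[em$gene] * em$beta))
}

#' Simulate the downstream phenotype of a cohort
#'
#' Liability L = gamma * M + sum over pleiotropic SNPs of delta_j * dosage_j
#' + e, with e standard normal and M the target module's genetically
#' determined activity reconstructed from this cohort's genotypes through the
#' true eQTL path. A binary outcome thresholds L at the prevalence quantile.
#'
#' @param truth Truth component of a [simulate_cohort()] result.
#' @param genotypes Genotypes of the cohort being phenotyped.
#' @param params The [sim_params()] used throughout.
#' @param module Module label carrying the causal effect (default: target).
#' @return Named numeric (or 0/1) phenotype vector over samples.
#' @export
simulate_outcome <- function(truth, genotypes, params,
                             module = truth$target_module) {
  stopifnot(inherits(params, "fetomod_sim_params"))
  if (!module %in% truth$module_names) stop("unknown module label: ", module)
  M <- genetic_module_activity(truth, genotypes, module, params$noise_sd)
  L <- params$gamma * M
  if (any(truth$pleiotropy)) {
    snps <- names(truth$pleiotropy)[truth$pleiotropy]
    L <- L + drop(genotypes$dosages[, snps, drop = FALSE] %*%
                    truth$pleiotropy_delta[snps])
  }
  set.seed(params$seed + 313L + nrow(genotypes$dosages))
  L <- L + stats::rnorm(length(L))
  if (params$binary_outcome) {
    y <- as.numeric(L > stats::quantile(L, 1 - params$prevalence))
  } else {
    y <- L
  }
  stats::setNames(y, rownames(genotypes$dosages))
}

# vectorized per-SNP simple OLS: returns beta, se, p for y ~ each column of X
ols_per_snp <- function(y, X) {
  n <- length(y)
  xc <- scale(X, center = TRUE, scale = FALSE)
  yc <- y - mean(y)
  sxx <- colSums(xc^2)
  keep <- sxx > 0
  beta <- rep(NA_real_, ncol(X))
  se <- rep(NA_real_, ncol(X))
  beta[keep] <- colSums(xc[, keep, drop = FALSE] * yc) / sxx[keep]
  rss <- sum(yc^2) - beta[keep]^2 * sxx[keep]
  rss <- pmax(rss, 0)
  se[keep] <- sqrt(rss / (n - 2) / sxx[keep])
  p <- 2 * stats::pt(-abs(beta / se), df = n - 2)
  data.frame(beta = beta, se = se, p = p, monomorphic = !keep)
}

#' Two-sample summary statistics from disjoint simulated cohorts
#'
#' Exposure effects are per-SNP OLS slopes of the target module's measured
#' activity — the first principal component of its genes' expression, sign
#' oriented to the module mean profile — on dosage in the exposure cohort.
#' Outcome effects are per-SNP OLS (or logistic for a binary trait) of the
#' phenotype on dosage in the independent outcome cohort. Monomorphic SNPs
#' are skipped with a message.
#'
#' @param exposure,outcome Results of [simulate_cohort()] for the two roles.
#' @param phenotype Phenotype vector over the outcome cohort's samples.
#' @param snps SNP ids to compute statistics for (default: the exposure
#'   cohort's eQTL SNPs of the target module).
#' @param module Module whose activity defines the exposure.
#' @param binary Treat the phenotype as binary (logistic outcome model)?
#' @return List of two data.frames, `exposure` and `outcome`, each in
#'   [read_summary_stats()] layout (snp, effect_allele, other_allele, beta,
#'   se, p).
#' @export
make_two_sample_stats <- function(exposure, outcome, phenotype, snps = NULL,
                                  module = exposure$truth$target_module,
                                  binary = FALSE) {
  truth <- exposure$truth
  if (is.null(snps)) {
    snps <- truth$eqtl_map$snp[truth$eqtl_map$module == module]
  }
  if (!length(snps)) stop("no SNPs to analyze")
  genes <- names(truth$module_labels)[truth$module_labels == module]
  sub <- exposure$expression[genes, , drop = FALSE]
  pc <- stats::prcomp(t(sub), center = TRUE, scale. = FALSE)
  act <- pc$x[, 1L]
  if (stats::cor(act, colMeans(sub)) < 0) act <- -act

  vi <- exposure$genotypes$variants
  vi <- vi[match(snps, vi$snp), , drop = FALSE]

  exp_fit <- ols_per_snp(act, exposure$genotypes$dosages[, snps, drop = FALSE])
  y <- phenotype[rownames(outcome$genotypes$dosages)]
  Xo <- outcome$genotypes$dosages[, snps, drop = FALSE]
  if (binary) {
    out_fit <- do.call(rbind, lapply(seq_along(snps), function(j) {
      x <- Xo[, j]
      if (stats::var(x) == 0) {
        return(data.frame(beta = NA_real_, se = NA_real_, p = NA_real_,
                          monomorphic = TRUE))
      }
      fit <- stats::glm(y ~ x, family = stats::binomial())
      cf <- summary(fit)$coefficients
      data.frame(beta = cf["x", 1], se = cf["x", 2], p = cf["x", 4],
                 monomorphic = FALSE)
    }))
  } else {
    out_fit <- ols_per_snp(y, Xo)
  }
  drop_mono <- exp_fit$monomorphic | out_fit$monomorphic
  if (any(drop_mono)) {
    message("make_two_sample_stats: skipped ", sum(drop_mono),
            " monomorphic SNP(s)")
  }
  keep <- !drop_mono
  shape <- function(fit) data.frame(
    snp = vi$snp[keep],
    effect_allele = vi$effect_allele[keep],
    other_allele = vi$other_allele[keep],
    beta = fit$beta[keep], se = fit$se[keep], p = fit$p[keep],
    stringsAsFactors = FALSE
  )
  list(exposure = shape(exp_fit), outcome = shape(out_fit))
}
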