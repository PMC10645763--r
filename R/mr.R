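is_palindromic <- function(a1, a2) {
  comp <- chartr("ACGT", "TGCA", a1)
  comp == a2
}

#' Harmonize exposure and outcome summary statistics
#'
#' Intersects the two record sets on SNP id and aligns both to the
#' exposure's effect allele: when the outcome's alleles are swapped the
#' outcome beta is negated; when neither orientation matches the SNP is
#' dropped. Palindromic (A/T, C/G) SNPs are removed unconditionally —
#' their strand cannot be resolved from alleles alone — matching the
#' "ambiguous SNPs removed" rule. Idempotent.
#'
#' @param exposure,outcome Data.frames in [read_summary_stats()] layout.
#' @return Data.frame of class `fetomod_harmonized`: snp, effect_allele,
#'   other_allele, beta_exp, se_exp, p_exp, beta_out, se_out, p_out, plus
#'   logical flags `flipped`; dropped SNPs are recorded in the
#'   `dropped` attribute with a reason.
#' @export
harmonize <- function(exposure, outcome) {
  common <- intersect(exposure$snp, outcome$snp)
  if (!length(common)) stop("no SNPs shared between exposure and outcome")
  e <- exposure[match(common, exposure$snp), , drop = FALSE]
  o <- outcome[match(common, outcome$snp), , drop = FALSE]
  palin <- is_palindromic(e$effect_allele, e$other_allele) |
    is_palindromic(o$effect_allele, o$other_allele)
  direct <- e$effect_allele == o$effect_allele &
    e$other_allele == o$other_allele
  swapped <- e$effect_allele == o$other_allele &
    e$other_allele == o$effect_allele
  unmatched <- !direct & !swapped
  keep <- !palin & !unmatched
  dropped <- data.frame(
    snp = common[!keep],
    reason = ifelse(palin[!keep], "palindromic", "allele_mismatch"),
    stringsAsFactors = FALSE
  )
  if (nrow(dropped)) {
    message("harmonize: dropped ", sum(dropped$reason == "palindromic"),
            " palindromic and ", sum(dropped$reason == "allele_mismatch"),
            " mismatched SNP(s)")
  }
  e <- e[keep, , drop = FALSE]
  o <- o[keep, , drop = FALSE]
  flip <- swapped[keep]
  h <- data.frame(
    snp = e$snp, effect_allele = e$effect_allele,
    other_allele = e$other_allele,
    beta_exp = e$beta, se_exp = e$se, p_exp = e$p,
    beta_out = ifelse(flip, -o$beta, o$beta),
    se_out = o$se, p_out = o$p,
    flipped = flip, stringsAsFactors = FALSE
  )
  if (!nrow(h)) stop("no SNPs left after harmonization")
  stopifnot(all(h$se_exp > 0), all(h$se_out > 0))
  rownames(h) <- NULL
  attr(h, "dropped") <- dropped
  class(h) <- c("fetomod_harmonized", "data.frame")
  h
}

mr_estimate <- function(method, estimate, se, p, n_snps) {
  data.frame(method = method, estimate = estimate, se = se, p = p,
             n_snps = n_snps, stringsAsFactors = FALSE)
}

#' Inverse-variance-weighted MR estimate
#'
#' Fixed-effects meta-analysis of the per-SNP Wald ratios, equivalent to
#' regressing outcome betas on exposure betas through the origin with
#' weights 1/se_out^2: estimate = sum(w bx by) / sum(w bx^2),
#' se = 1 / sqrt(sum(w bx^2)), two-sided normal p. With a single SNP the
#' Wald ratio is reported instead, flagged.
#'
#' @param h A [harmonize()] result.
#' @return One-row data.frame: method, estimate, se, p, n_snps.
#' @export
mr_ivw <- function(h) {
  n <- nrow(h)
  if (n < 2L) {
    warning("mr_ivw: fewer than 2 SNPs; reporting the Wald ratio")
    return(mr_wald(h))
  }
  w <- 1 / h$se_out^2
  est <- sum(w * h$beta_exp * h$beta_out) / sum(w * h$beta_exp^2)
  se <- 1 / sqrt(sum(w * h$beta_exp^2))
  p <- 2 * stats::pnorm(-abs(est / se))
  mr_estimate("ivw", est, se, p, n)
}

#' Single-SNP Wald ratio estimate
#'
#' First-order ratio estimate beta_out / beta_exp with
#' se = se_out / |beta_exp| (exposure uncertainty ignored, the common
#' default).
#'
#' @param h A one-or-more-row [harmonize()] result; with several SNPs one
#'   row per SNP is returned.
#' @return Data.frame of Wald estimates (method "wald").
#' @export
mr_wald <- function(h) {
  est <- h$beta_out / h$beta_exp
  se <- h$se_out / abs(h$beta_exp)
  p <- 2 * stats::pnorm(-abs(est / se))
  out <- mr_estimate("wald", est, se, p, 1L)
  out$snp <- h$snp
  out
}

#' Weighted-median MR estimate
#'
#' Orders the per-SNP Wald ratios and takes the value where the normalized
#' cumulative weight, offset by half of each SNP's weight, crosses 0.5
#' (linear interpolation), with weights (beta_exp / se_out)^2 — the
#' inverse-variance weight of each ratio. Consistent when at least half of
#' the total instrument weight comes from valid instruments. The standard
#' error comes from a seeded parametric bootstrap resampling both betas
#' from normals at their reported SEs.
#'
#' @param h A [harmonize()] result with >= 3 SNPs.
#' @param n_boot Bootstrap replicates (default 1000).
#' @param seed Integer seed for the bootstrap.
#' @return One-row data.frame: method, estimate, se, p, n_snps.
#' @export
mr_weighted_median <- function(h, n_boot = 1000L, seed = 1L) {
  zero <- h$beta_exp == 0
  if (any(zero)) {
    message("mr_weighted_median: dropped ", sum(zero),
            " SNP(s) with zero exposure beta")
    h <- h[!zero, , drop = FALSE]
  }
  if (nrow(h) < 3L) stop("weighted median needs >= 3 SNPs")
  wm <- function(bx, by, w) {
    r <- by / bx
    ord <- order(r)
    r <- r[ord]; w <- w[ord] / sum(w)
    cw <- cumsum(w) - w / 2
    stats::approx(cw, r, xout = 0.5, rule = 2L)$y
  }
  w <- (h$beta_exp / h$se_out)^2
  est <- wm(h$beta_exp, h$beta_out, w)
  set.seed(seed)
  boot <- vapply(seq_len(n_boot), function(b) {
    bx <- stats::rnorm(nrow(h), h$beta_exp, h$se_exp)
    by <- stats::rnorm(nrow(h), h$beta_out, h$se_out)
    wm(bx, by, (bx / h$se_out)^2)
  }, numeric(1L))
  se <- stats::sd(boot)
  p <- 2 * stats::pnorm(-abs(est / se))
  mr_estimate("weighted_median", est, se, p, nrow(h))
}

#' MR-Egger regression
#'
#' Weighted least squares of outcome betas on exposure betas with an
#' intercept, weights 1/se_out^2, after orienting every exposure beta
#' non-negative (flipping the outcome beta in step). The slope is the
#' pleiotropy-adjusted causal estimate; the intercept estimates directional
#' pleiotropy, its t-test (df = n - 2) being the Egger intercept test.
#'
#' @param h A [harmonize()] result with >= 3 SNPs.
#' @return Two-row data.frame: methods "egger_slope" and "egger_intercept".
#' @export
mr_egger <- function(h) {
  if (nrow(h) < 3L) stop("MR-Egger needs >= 3 SNPs")
  flip <- h$beta_exp < 0
  bx <- abs(h$beta_exp)
  by <- ifelse(flip, -h$beta_out, h$beta_out)
  w <- 1 / h$se_out^2
  fit <- stats::lm(by ~ bx, weights = w)
  cf <- suppressWarnings(summary(fit))$coefficients  # exact fits are fine
  df <- nrow(h) - 2L
  rows <- rbind(
    mr_estimate("egger_slope", cf["bx", 1L], cf["bx", 2L],
                2 * stats::pt(-abs(cf["bx", 3L]), df), nrow(h)),
    mr_estimate("egger_intercept", cf["(Intercept)", 1L],
                cf["(Intercept)", 2L],
                2 * stats::pt(-abs(cf["(Intercept)", 3L]), df), nrow(h))
  )
  rows
}

#' MR sensitivity analyses
#'
#' Cochran's Q for instrument heterogeneity around the IVW estimate
#' (Q = sum w_i beta_exp_i^2 (r_i - beta_ivw)^2 in the weighted-regression
#' parameterization, chi-square with n - 1 df), leave-one-out IVW
#' estimates, per-SNP Wald ratios, and the Egger intercept test.
#'
#' @param h A [harmonize()] result with >= 2 SNPs.
#' @return List of class `fetomod_mr_sensitivity`: `Q` (statistic, df, p),
#'   `leave_one_out` (snp_removed, estimate, se, p), `single_snp` (Wald
#'   table), `egger_intercept` (or NULL below 3 SNPs).
#' @export
mr_sensitivity <- function(h) {
  if (nrow(h) < 2L) stop("sensitivity analyses need >= 2 SNPs")
  ivw <- mr_ivw(h)
  w <- 1 / h$se_out^2
  r <- h$beta_out / h$beta_exp
  Q <- sum(w * h$beta_exp^2 * (r - ivw$estimate)^2)
  df <- nrow(h) - 1L
  loo <- do.call(rbind, lapply(seq_len(nrow(h)), function(i) {
    sub <- h[-i, , drop = FALSE]
    est <- if (nrow(sub) >= 2L) mr_ivw(sub) else mr_wald(sub)[, 1:5]
    data.frame(snp_removed = h$snp[i], estimate = est$estimate,
               se = est$se, p = est$p, stringsAsFactors = FALSE)
  }))
  egger <- if (nrow(h) >= 3L) {
    eg <- mr_egger(h)
    eg[eg$method == "egger_intercept", , drop = FALSE]
  } else NULL
  structure(list(
    Q = data.frame(Q = Q, df = df, p = stats::pchisq(Q, df, lower.tail = FALSE)),
    leave_one_out = loo,
    single_snp = mr_wald(h),
    egger_intercept = egger,
    ivw = ivw
  ), class = "fetomod_mr_sensitivity")
}

#' Run all MR estimators on a harmonized instrument set
#'
#' @param h A [harmonize()] result.
#' @param n_boot Bootstrap replicates for the weighted median.
#' @param seed Seed for the bootstrap.
#' @return Data.frame stacking IVW, weighted-median and Egger rows.
#' @export
mr_all <- function(h, n_boot = 1000L, seed = 1L) {
  out <- mr_ivw(h)
  if (nrow(h) >= 3L) {
    out <- rbind(out, mr_weighted_median(h, n_boot, seed), mr_egger(h))
  }
  out
}
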