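test_that("genotype simulator: LD structure, MAF thresholding, determinism", {
  # rho = 0: empirical pairwise r^2 near zero
  g0 <- simulate_genotypes(2000L, 30L, block_size = 5L, rho = 0, seed = 2L)
  r2 <- cor(g0$dosages)^2
  expect_lt(mean(r2[upper.tri(r2)]), 0.01)

  # rho = 0.9: within-block correlation dominates between-block
  g9 <- simulate_genotypes(2000L, 30L, block_size = 5L, rho = 0.9,
                           maf_range = c(0.3, 0.3), seed = 2L)
  cc <- abs(cor(g9$dosages))
  blk <- rep(seq_len(6L), each = 5L)
  same <- outer(blk, blk, "==") & upper.tri(cc)
  diff_ <- outer(blk, blk, "!=") & upper.tri(cc)
  expect_gt(mean(cc[same]), 5 * mean(cc[diff_]))

  # determinism and dosage range
  g9b <- simulate_genotypes(2000L, 30L, block_size = 5L, rho = 0.9,
                            maf_range = c(0.3, 0.3), seed = 2L)
  expect_identical(g9$dosages, g9b$dosages)
  expect_true(all(g9$dosages %in% c(0, 1, 2)))
  expect_error(simulate_genotypes(10L, 5L, rho = 1), "rho")

  # block membership recorded in variant metadata: one chrom per block
  expect_identical(unique(g9$variants$chrom[1:5]), "chr1")
  expect_identical(unique(g9$variants$chrom[6:10]), "chr2")
  # realized allele frequency tracks the requested MAF
  expect_equal(mean(g9$dosages) / 2, 0.3, tolerance = 0.05)
})

test_that("cohort simulator plants the stated co-expression structure", {
  # no loadings, no eQTLs: pure noise
  p0 <- small_world(seed = 3L, eqtl_frac = 0, loading_range = c(0, 0),
                    n_exposure_samples = 400L)
  ex0 <- simulate_cohort(p0, "exposure")
  cc <- cor(t(ex0$expression[1:80, ]))
  expect_lt(mean(abs(cc[upper.tri(cc)])), 0.06)

  # within-module correlation matches the closed-form factor-model value
  p <- small_world(seed = 3L, eqtl_frac = 0, n_exposure_samples = 2000L)
  ex <- simulate_cohort(p, "exposure")
  lab <- ex$truth$module_labels
  lam <- ex$truth$loadings
  m1 <- names(lab)[lab == "M1"]
  emp <- cor(t(ex$expression[m1, ]))
  v <- p$noise_sd^2
  theo <- outer(lam[m1], lam[m1]) /
    sqrt(outer(lam[m1]^2 + v, lam[m1]^2 + v))
  off <- upper.tri(emp)
  expect_equal(mean(emp[off]), mean(theo[off]), tolerance = 0.03)
  expect_lt(max(abs(emp[off] - theo[off])), 0.15)

  # an eQTL gene regressed on its SNP recovers beta within 2 SE
  p1 <- small_world(seed = 5L, n_exposure_samples = 1000L)
  ex1 <- simulate_cohort(p1, "exposure")
  em <- ex1$truth$eqtl_map
  hit <- em[which.max(abs(em$beta)), ]
  fit <- summary(lm(ex1$expression[hit$gene, ] ~
                      ex1$genotypes$dosages[, hit$snp]))$coefficients
  expect_lt(abs(fit[2L, 1L] - hit$beta), 2 * fit[2L, 2L])

  # determinism
  ex1b <- simulate_cohort(p1, "exposure")
  expect_identical(ex1$expression, ex1b$expression)
  # two-sample structure: disjoint genotype draws
  ou <- simulate_cohort(p1, "outcome")
  expect_false(identical(ou$genotypes$dosages, ex1$genotypes$dosages))
  expect_identical(ou$truth$eqtl_map, ex1$truth$eqtl_map)
})

test_that("outcome simulator: null calibration, proportionality, determinism", {
  # gamma = 0, no pleiotropy: per-SNP associations are null at alpha = 0.05
  p0 <- small_world(seed = 7L, gamma = 0, n_outcome_samples = 500L)
  ex <- simulate_cohort(p0, "exposure")
  ou <- simulate_cohort(p0, "outcome")
  y <- simulate_outcome(ex$truth, ou$genotypes, p0)
  ps <- apply(ou$genotypes$dosages, 2L, function(x) {
    if (var(x) == 0) return(NA_real_)
    summary(lm(y ~ x))$coefficients[2L, 4L]
  })
  expect_lt(abs(mean(ps < 0.05, na.rm = TRUE) - 0.05), 0.04)

  # gamma = 0.5: outcome betas proportional to exposure betas with slope
  # gamma after the measurement-error attenuation the generating equations
  # imply (exposure betas are estimates: raw slope shrinks by
  # Var(true)/Var(observed) = 1 - mean(se^2)/Var(observed))
  p5 <- mr_world(seed = 7L, gamma = 0.5, eqtl_beta_sd = 1)
  ex5 <- simulate_cohort(p5, "exposure")
  ou5 <- simulate_cohort(p5, "outcome")
  y5 <- simulate_outcome(ex5$truth, ou5$genotypes, p5)
  st <- suppressMessages(make_two_sample_stats(ex5, ou5, y5))
  slope <- coef(lm(st$outcome$beta ~ 0 + st$exposure$beta))[[1L]]
  atten <- 1 - mean(st$exposure$se^2) / mean(st$exposure$beta^2)
  expect_equal(slope / atten, 0.5, tolerance = 0.3)

  # same seed, same phenotypes; unknown module errors
  y5b <- simulate_outcome(ex5$truth, ou5$genotypes, p5)
  expect_identical(y5, y5b)
  expect_error(simulate_outcome(ex5$truth, ou5$genotypes, p5,
                                module = "M99"), "unknown module")
})

test_that("two-sample summary statistics behave like a real eQTL/GWAS pair", {
  p <- mr_world(seed = 11L, gamma = 0, eqtl_beta_sd = 1)
  ex <- simulate_cohort(p, "exposure")
  ou <- simulate_cohort(p, "outcome")
  y <- simulate_outcome(ex$truth, ou$genotypes, p)
  # exposure p-values at non-eQTL SNPs are approximately uniform
  non_eqtl <- setdiff(ex$genotypes$variants$snp, ex$truth$eqtl_map$snp)
  st_all <- suppressMessages(
    make_two_sample_stats(ex, ou, y, snps = non_eqtl))
  expect_gt(ks.test(st_all$exposure$p, "punif")$p.value, 0.01)

  # planted eQTL SNPs: estimated exposure sign matches the planted
  # loading-weighted sign for well-measured instruments
  st <- suppressMessages(make_two_sample_stats(ex, ou, y))
  em <- ex$truth$eqtl_map[ex$truth$eqtl_map$module == "M1", ]
  em <- em[match(st$exposure$snp, em$snp), ]
  strong <- abs(st$exposure$beta) > 2 * st$exposure$se
  if (sum(strong) >= 3L) {
    agree <- sign(st$exposure$beta[strong]) == sign(em$beta[strong])
    expect_gt(mean(agree), 0.9)
  }

  # reversed roles with gamma = 0: no reverse-causation signal
  st_rev <- suppressMessages(make_two_sample_stats(
    ou, ex, simulate_outcome(ou$truth, ex$genotypes, p)))
  h <- suppressMessages(harmonize(st_rev$exposure, st_rev$outcome))
  ivw <- mr_ivw(h)
  expect_gt(ivw$p, 0.01)
})

test_that("Wald ratios of strong instruments concentrate around gamma", {
  # the concentration property requires instruments that are actually
  # strong on the module-activity scale: small module, large cis effects
  p <- sim_params(n_exposure_samples = 2000L, n_outcome_samples = 2000L,
                  n_genes = 40L, module_sizes = c(20L), n_snps = 60L,
                  eqtl_frac = 0.75, eqtl_beta_sd = 2,
                  maf_range = c(0.3, 0.5), gamma = 0.5, seed = 13L)
  ex <- simulate_cohort(p, "exposure")
  ou <- simulate_cohort(p, "outcome")
  y <- simulate_outcome(ex$truth, ou$genotypes, p)
  st <- suppressMessages(make_two_sample_stats(ex, ou, y))
  strong <- abs(st$exposure$beta) > 2 * st$exposure$se
  expect_gt(sum(strong), 5L)
  wald <- st$outcome$beta[strong] / st$exposure$beta[strong]
  expect_lt(abs(median(wald) - p$gamma), 0.1)
})
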