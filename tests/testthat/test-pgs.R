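fake_geno <- function(dosages, chrom = "chr1", pos = NULL) {
  n_snp <- ncol(dosages)
  if (is.null(pos)) pos <- seq_len(n_snp) * 1000L
  list(dosages = dosages,
       variants = data.frame(snp = colnames(dosages),
                             chrom = rep(chrom, length.out = n_snp),
                             pos = pos,
                             effect_allele = rep("A", n_snp),
                             other_allele = rep("G", n_snp),
                             stringsAsFactors = FALSE))
}

test_that("SNP-to-gene mapping is 1-based inclusive with optional window", {
  variants <- data.frame(snp = c("rs1", "rs2", "rs3"), chrom = "chr1",
                         pos = c(100L, 201L, 150L))
  ann <- data.frame(gene = c("GA", "GB"), chrom = "chr1",
                    start = c(100L, 120L), end = c(200L, 180L))
  pairs <- map_snps_to_genes(variants, ann)
  # SNP at gene start included; 1 bp past end excluded at w = 0
  expect_true(any(pairs$snp == "rs1" & pairs$gene == "GA"))
  expect_false(any(pairs$snp == "rs2"))
  # SNP overlapping two genes emits two pairs
  expect_identical(sort(pairs$gene[pairs$snp == "rs3"]), c("GA", "GB"))
  # 1 kb window rescues the just-outside SNP
  pairs_w <- map_snps_to_genes(variants, ann, window_kb = 1)
  expect_true(any(pairs_w$snp == "rs2" & pairs_w$gene == "GA"))
  # missing annotation logged and skipped
  expect_message(map_snps_to_genes(variants, ann, genes = c("GA", "GZ")),
                 "no annotation")
})

test_that("greedy LD clumping retains index SNPs by p-value", {
  set.seed(11)
  n <- 500L
  base <- rbinom(n, 2L, 0.4)
  # rs2 in strong LD with rs1; rs3 nearly independent
  flip <- function(x, k) { i <- sample(n, k); x[i] <- 2 - x[i]; x }
  dos <- cbind(rs1 = base, rs2 = flip(base, 60L), rs3 = rbinom(n, 2L, 0.4))
  geno <- fake_geno(dos)
  r2_12 <- cor(dos[, 1L], dos[, 2L])^2
  expect_gt(r2_12, 0.2)
  eq <- data.frame(snp = c("rs1", "rs2", "rs3"), p = c(1e-8, 1e-4, 1e-3),
                   stringsAsFactors = FALSE)
  kept <- ld_clump(eq, geno, r2_threshold = 0.2, window_kb = 250)
  expect_identical(kept$snp, c("rs1", "rs3"))

  # r^2 below the threshold: both retained
  dos2 <- cbind(rs1 = base, rs2 = rbinom(n, 2L, 0.4))
  expect_lt(cor(dos2[, 1L], dos2[, 2L])^2, 0.2)
  kept2 <- ld_clump(eq[1:2, ], fake_geno(dos2), 0.2, 250)
  expect_identical(sort(kept2$snp), c("rs1", "rs2"))

  # input order does not matter given distinct p-values
  kept_r <- ld_clump(eq[c(3, 1, 2), ], geno, 0.2, 250)
  expect_identical(sort(kept_r$snp), sort(kept$snp))

  # clump property on a random configuration: output subset of input and
  # every removed SNP is in LD with a retained, smaller-p SNP
  set.seed(3)
  m <- 12L
  dosr <- sapply(seq_len(m), function(j) rbinom(300L, 2L, 0.5))
  dosr[, 7:9] <- dosr[, 1:3]  # perfect proxies
  colnames(dosr) <- paste0("rs", seq_len(m))
  genor <- fake_geno(dosr)
  eqr <- data.frame(snp = colnames(dosr), p = runif(m))
  keptr <- ld_clump(eqr, genor, 0.2, 250)
  expect_true(all(keptr$snp %in% eqr$snp))
  removed <- setdiff(eqr$snp, keptr$snp)
  for (s in removed) {
    r2 <- cor(dosr[, s], dosr[, keptr$snp, drop = FALSE])^2
    partners <- keptr$snp[r2[1L, ] >= 0.2]
    expect_true(any(eqr$p[match(partners, eqr$snp)] <
                      eqr$p[eqr$snp == s]))
  }

  # SNPs missing from the panel pass through with a warning
  expect_warning(ld_clump(data.frame(snp = "zz9", p = 0.1), geno, 0.2, 250),
                 "absent")
})

test_that("PGS summation handles orientation, duplicates, missingness, linearity", {
  dos <- matrix(c(0, 1, 2,
                  2, 1, 0), nrow = 2L, byrow = TRUE,
                dimnames = list(c("S1", "S2"), c("rs1", "rs2", "rs3")))
  geno <- fake_geno(dos)

  # one SNP, weight 1: score equals dosage
  w1 <- pgs_weights(data.frame(snp = "rs1", effect_allele = "A",
                               other_allele = "G", beta = 1, p = 1e-5))
  expect_equal(unname(build_pgs(geno, w1)), dos[, "rs1"], ignore_attr = TRUE)

  # hand-computed 3-SNP weighted sum
  w3 <- pgs_weights(data.frame(snp = c("rs1", "rs2", "rs3"),
                               effect_allele = "A", other_allele = "G",
                               beta = c(0.5, -0.2, 0.1), p = c(1, 2, 3) * 1e-6))
  expect_equal(unname(build_pgs(geno, w3)),
               c(0 * 0.5 + 1 * -0.2 + 2 * 0.1,
                 2 * 0.5 + 1 * -0.2 + 0 * 0.1),
               tolerance = 1e-12)

  # strand bookkeeping: swapping alleles and negating beta changes nothing
  wf <- w3
  wf$effect_allele[2L] <- "G"; wf$other_allele[2L] <- "A"
  wf$weight[2L] <- -wf$weight[2L]
  expect_equal(build_pgs(geno, wf), build_pgs(geno, w3), tolerance = 1e-12)

  # linearity over weight tables on the same SNP set
  wa <- w3; wa$weight <- c(0.1, 0.2, 0.3)
  wb <- w3; wb$weight <- c(-0.2, 0.05, 0)
  wab <- w3; wab$weight <- wa$weight + wb$weight
  expect_equal(build_pgs(geno, wab),
               build_pgs(geno, wa) + build_pgs(geno, wb), tolerance = 1e-12)

  # duplicate SNP (eQTL for two genes) contributes once, smallest p wins
  dupe <- data.frame(snp = c("rs1", "rs1"), effect_allele = "A",
                     other_allele = "G", beta = c(1, 100), p = c(1e-8, 1e-2),
                     gene = c("g1", "g2"))
  wd <- suppressMessages(pgs_weights(dupe))
  expect_identical(nrow(wd), 1L)
  expect_equal(wd$weight, 1)

  # unresolvable allele mismatch dropped with a message
  wmis <- w3
  wmis$effect_allele[3L] <- "T"; wmis$other_allele[3L] <- "C"
  expect_message(build_pgs(geno, wmis), "mismatch")

  # missing dosage: mean imputation equals 2 x in-cohort EAF
  dos_na <- dos; dos_na["S1", "rs1"] <- NA
  gna <- fake_geno(dos_na)
  expect_equal(unname(build_pgs(gna, w1)["S1"]), mean(dos_na[, "rs1"],
                                                      na.rm = TRUE))
  expect_equal(unname(build_pgs(gna, w1, missing_policy = "zero")["S1"]), 0)
})

test_that("negative controls: seeded draws, size guard, zero-weight constancy", {
  universe <- paste0("G", 1:100)
  g1 <- negative_control_genes("random_genes", size = 10L,
                               universe = universe, seed = 5L)
  g2 <- negative_control_genes("random_genes", size = 10L,
                               universe = universe, seed = 5L)
  expect_identical(g1, g2)
  expect_identical(length(unique(g1)), 10L)
  expect_error(negative_control_genes("random_genes", size = 200L,
                                      universe = universe), "smaller")

  # size-matched module picks the closest-size alternative
  alt <- list(a = paste0("G", 1:8), b = paste0("G", 1:11), c = paste0("G", 1:30))
  expect_identical(negative_control_genes("size_matched_module", size = 10L,
                                          alt_modules = alt), alt$b)

  # all-zero alternative weights give a constant PGS
  dos <- matrix(rbinom(20L, 2L, 0.5), 5L, 4L,
                dimnames = list(paste0("S", 1:5), paste0("rs", 1:4)))
  geno <- fake_geno(dos)
  wz <- pgs_weights(data.frame(snp = colnames(dos), effect_allele = "A",
                               other_allele = "G", beta = 0, p = 1e-5))
  expect_equal(unname(build_pgs(geno, wz)), rep(0, 5))
})

test_that("PGS validation regression: invariances and collinearity guard", {
  set.seed(2)
  n <- 120L
  pgs <- setNames(rnorm(n), paste0("S", 1:n))
  score <- setNames(0.4 * pgs + rnorm(n), names(pgs))
  fit <- validate_pgs(pgs, score)
  expect_lt(fit$p, 0.01)
  expect_gt(fit$beta, 0)
  expect_identical(fit$n, n)

  # location shift of the PGS leaves inference unchanged
  fit_shift <- validate_pgs(pgs + 100, score)
  expect_equal(fit_shift$p, fit$p, tolerance = 1e-9)
  expect_equal(fit_shift$beta, fit$beta, tolerance = 1e-9)

  # permuted PGS is null on average (single-draw sanity: p not tiny)
  fit_perm <- validate_pgs(setNames(sample(pgs), names(pgs)), score)
  expect_gt(fit_perm$p, 1e-4)

  # collinear covariates rejected
  covs <- data.frame(x1 = rnorm(n), row.names = names(pgs))
  covs$x2 <- 2 * covs$x1
  expect_error(validate_pgs(pgs, score, covs), "collinear")
})
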