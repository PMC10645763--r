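test_that("gene filter applies the >90%-of-samples rule and drops constants", {
  set.seed(1)
  expr <- matrix(abs(rnorm(42 * 4)) + 0.1, 4, 42,
                 dimnames = list(paste0("G", 1:4), paste0("S", 1:42)))
  expr[1L, 1:5] <- 0          # expressed in 37/42 = 88% -> dropped at 0.9
  expr[2L, ] <- 3             # constant non-zero -> dropped (zero variance)
  kept <- suppressMessages(filter_genes(expr, 0.9))
  expect_identical(rownames(kept), c("G3", "G4"))
  # all pass -> identity
  expect_identical(filter_genes(expr[3:4, ], 0.9), expr[3:4, ])
  expect_error(filter_genes(expr[1, , drop = FALSE], 0.999), "no genes")
})

test_that("sample outlier detection flags shifted samples, not nulls", {
  # null: homogeneous Gaussian samples rarely flagged
  flags <- vapply(1:40, function(s) {
    set.seed(s)
    e <- matrix(rnorm(50 * 20), 50, 20,
                dimnames = list(NULL, paste0("S", 1:20)))
    length(detect_sample_outliers(e))
  }, numeric(1L))
  expect_lte(mean(flags > 0), 0.05 + 2 * sqrt(0.05 * 0.95 / 40))

  # one sample shifted by 10 sd on all genes is flagged
  set.seed(9)
  e <- matrix(rnorm(50 * 20), 50, 20,
              dimnames = list(NULL, paste0("S", 1:20)))
  e[, 7L] <- e[, 7L] + 10
  expect_identical(detect_sample_outliers(e), "S7")

  expect_error(detect_sample_outliers(e[, 1:3]), "4 samples")
})

test_that("bicor matches its defining formula and resists outliers", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(bicor(x, x), 1)
  expect_equal(bicor(x, rev(x)), -1)

  # brute-force evaluation of the biweight formula, independent of bicor()
  bicor_oracle <- function(x, y) {
    tr <- function(v) {
      u <- (v - median(v)) / (9 * median(abs(v - median(v))))
      w <- (1 - u^2)^2 * (abs(u) < 1)
      (v - median(v)) * w
    }
    xt <- tr(x); yt <- tr(y)
    sum(xt * yt) / sqrt(sum(xt^2) * sum(yt^2))
  }
  xo <- c(1, 2, 3, 4, 100)
  yo <- c(1, 2, 3, 4, 5)
  expect_equal(bicor(xo, yo), bicor_oracle(xo, yo), tolerance = 1e-12)
  # outlier damps bicor less than it distorts Pearson
  expect_gt(bicor(xo, yo), cor(xo, yo))

  # MAD = 0 falls back to Pearson
  const_mad <- c(1, 1, 1, 1, 9)   # median 1, MAD 0
  expect_equal(bicor(const_mad, yo), cor(const_mad, yo))
  # matrix path agrees with the scalar path
  m <- rbind(a = xo, b = yo, c = rev(yo))
  bm <- bicor_matrix(m)
  expect_equal(bm["a", "b"], bicor(xo, yo), tolerance = 1e-12)
  expect_equal(bm, t(bm))
})

test_that("signed adjacency endpoints and closed-form values", {
  cm <- matrix(c(1, 1, 0, -1,
                 1, 1, 0, 0,
                 0, 0, 1, 0,
                 -1, 0, 0, 1), 4, 4)
  a <- adjacency(cor_mat = cm, power = 14)
  expect_equal(a[1L, 2L], 1)            # cor  1 -> 1
  expect_equal(a[1L, 4L], 0)            # cor -1 -> 0
  expect_equal(a[1L, 3L], 0.5^14)       # cor  0 -> 0.5^14
  expect_equal(a, t(a), tolerance = 1e-12)
  expect_true(all(a >= 0 & a <= 1))
})

test_that("TOM matches hand-computed values and stays in range", {
  a <- matrix(0.5, 3, 3); diag(a) <- 1
  tm <- tom(a)
  # L = 0.25, k = 1: (0.25 + 0.5) / (1 + 1 - 0.5) = 0.5
  expect_equal(tm[1L, 2L], 0.5, tolerance = 1e-12)
  expect_equal(diag(tm), rep(1, 3))

  # isolated gene: TOM row approximately its adjacency row
  a2 <- matrix(c(1, .6, 1e-6,
                 .6, 1, 1e-6,
                 1e-6, 1e-6, 1), 3, 3)
  tm2 <- tom(a2)
  expect_equal(tm2[3L, 1L], a2[3L, 1L], tolerance = 1e-3)

  set.seed(4)
  cm <- cor(matrix(rnorm(200), 20, 10))
  tr <- tom(adjacency(cor_mat = cm, power = 6))
  expect_true(all(tr >= 0 & tr <= 1))
  expect_equal(tr, t(tr), tolerance = 1e-12)
})

test_that("soft-threshold selection: noise fails scale-freeness, order-invariant", {
  set.seed(2)
  noise <- matrix(rnorm(80 * 30), 80, 30,
                  dimnames = list(paste0("G", 1:80), NULL))
  st <- pick_soft_threshold(noise, powers = c(1, 6), target_r2 = 0.8)
  expect_lt(st$fit$signed_r2[st$fit$power == 1], 0.8)

  perm <- sample(nrow(noise))
  st2 <- pick_soft_threshold(noise[perm, ], powers = c(1, 6),
                             target_r2 = 0.8)
  expect_identical(st$power, st2$power)
  expect_error(pick_soft_threshold(noise[1:30, ]), ">= 50")
})

test_that("tree cut recovers separated blocks and leaves noise grey", {
  # two planted blocks with zero cross-block correlation
  p <- sim_params(n_genes = 80L, module_sizes = c(40L, 40L), n_snps = 10L,
                  eqtl_frac = 0, n_exposure_samples = 400L,
                  noise_sd = 0.3, seed = 21L)
  ex <- simulate_cohort(p, "exposure")
  tm <- tom(adjacency(ex$expression, power = 14))
  lab <- cut_modules(tm, min_module_size = 30L)
  expect_identical(length(setdiff(unique(lab), "grey")), 2L)
  expect_identical(sum(lab == "grey"), 0L)
  expect_equal(adjusted_rand_index(lab, ex$truth$module_labels), 1)

  # pure noise: most genes grey across seeds
  grey_frac <- vapply(1:10, function(s) {
    set.seed(s)
    e <- matrix(rnorm(200 * 60), 200, 60,
                dimnames = list(paste0("G", 1:200), NULL))
    lb <- cut_modules(tom(adjacency(e, power = 14)), min_module_size = 30L)
    mean(lb == "grey")
  }, numeric(1L))
  expect_gte(mean(grey_frac >= 0.8), 0.8)

  # gene-order invariance up to renaming
  perm <- sample(nrow(tm))
  lab_p <- cut_modules(tm[perm, perm], min_module_size = 30L)
  expect_equal(adjusted_rand_index(lab_p, lab[perm]), 1)
})

test_that("eigengenes equal the SVD oracle, oriented to the mean profile", {
  # module of two identical genes: eigengene tracks the shared profile
  prof <- c(1, 3, 2, 5, 4, 6)
  expr <- rbind(G1 = prof, G2 = prof, G3 = rnorm(6), G4 = rnorm(6))
  colnames(expr) <- paste0("S", 1:6)
  lab <- c(G1 = "m1", G2 = "m1", G3 = "m2", G4 = "m2")
  eg <- module_eigengenes(expr, lab)
  expect_equal(eg$var_explained[["m1"]], 1)
  expect_equal(abs(cor(eg$eigengenes[, "m1"], prof)), 1)
  expect_gte(cor(eg$eigengenes[, "m1"], prof), 0)  # orientation

  # SVD oracle on a random module
  set.seed(8)
  e2 <- matrix(rnorm(5 * 12), 5, 12,
               dimnames = list(paste0("G", 1:5), paste0("S", 1:12)))
  lab2 <- setNames(rep("mod", 5), rownames(e2))
  eg2 <- module_eigengenes(e2, lab2)$eigengenes[, "mod"]
  oracle <- svd(t(scale(t(e2))))$v[, 1L]
  expect_equal(abs(cor(eg2, oracle)), 1, tolerance = 1e-10)
  expect_equal(sd(eg2), 1)
  expect_error(module_eigengenes(e2, setNames(c("a", rep("b", 4)),
                                              rownames(e2))), "fewer than 2")
})

test_that("eigengene merging joins split factors, respects threshold, idempotent", {
  # one planted factor artificially split in two
  p <- sim_params(n_genes = 60L, module_sizes = c(60L), n_snps = 10L,
                  eqtl_frac = 0, n_exposure_samples = 300L, seed = 31L)
  ex <- simulate_cohort(p, "exposure")
  lab <- setNames(rep(c("a", "b"), each = 30L), rownames(ex$expression))
  merged <- merge_modules(ex$expression, lab, threshold = 0.85)
  expect_identical(length(unique(merged)), 1L)

  # threshold 1: nothing merges
  expect_identical(merge_modules(ex$expression, lab, threshold = 1), lab)

  # idempotence
  expect_identical(merge_modules(ex$expression, merged, threshold = 0.85),
                   merged)
})
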