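# small simulated worlds shared across tests (kept tiny for speed)

small_world <- function(seed = 1L, ...) {
  args <- list(n_exposure_samples = 300L, n_outcome_samples = 300L,
               n_genes = 300L, module_sizes = c(60L, 50L, 40L),
               n_snps = 200L, seed = seed)
  override <- list(...)
  args[names(override)] <- override
  do.call(sim_params, args)
}

# two-sample MR calibration world: 15 instruments on a 50-gene module,
# cohorts of 2000, causal effect on the scale the study reports
mr_world <- function(seed = 1L, ...) {
  args <- list(n_exposure_samples = 2000L, n_outcome_samples = 2000L,
               n_genes = 100L, module_sizes = c(50L), n_snps = 100L,
               eqtl_frac = 0.3, gamma = -0.009, seed = seed)
  override <- list(...)
  args[names(override)] <- override
  do.call(sim_params, args)
}

# toy expression matrix with dimnames
toy_expr <- function(n_genes = 10L, n_samples = 6L, seed = 1L) {
  set.seed(seed)
  m <- matrix(abs(rnorm(n_genes * n_samples)), n_genes, n_samples,
              dimnames = list(paste0("G", seq_len(n_genes)),
                              paste0("S", seq_len(n_samples))))
  m
}

# harmonized-instrument table built directly at summary level
summary_instruments <- function(n = 15L, gamma = 0.1, se_exp = 0.02,
                                se_out = 0.05, pleio = rep(0, n),
                                positive = FALSE, seed = 1L) {
  set.seed(seed)
  sgn <- if (positive) rep(1, n) else sample(c(-1, 1), n, replace = TRUE)
  bx_true <- runif(n, 0.1, 0.3) * sgn
  bx <- rnorm(n, bx_true, se_exp)
  by <- rnorm(n, gamma * bx_true + pleio, se_out)
  structure(data.frame(
    snp = sprintf("rs%03d", seq_len(n)),
    effect_allele = "A", other_allele = "G",
    beta_exp = bx, se_exp = se_exp, p_exp = 1e-8,
    beta_out = by, se_out = se_out, p_out = 0.5,
    flipped = FALSE, stringsAsFactors = FALSE
  ), class = c("fetomod_harmonized", "data.frame"))
}
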