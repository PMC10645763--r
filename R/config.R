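#' Analysis configuration with study defaults
#'
#' Collects every tunable parameter of the pipeline in one validated list.
#' Defaults are the values used in the placental co-expression study this
#' package reimplements: signed network at soft power 14, eigengene merge at
#' r > 0.85, 90% expressed-sample gene filter, 100 preservation permutations
#' with Zsummary thresholds 2 and 10, LD clumping at r^2 < 0.2, BH FDR at
#' 0.05.
#'
#' @param ... Named overrides of any default listed below.
#' @return A list of class `fetomod_config`.
#' @examples
#' cfg <- analysis_config(soft_power = 6)
#' cfg$merge_cor_threshold
#' @export
analysis_config <- function(...) {
  cfg <- list(
    # network
    soft_power = 14L,
    signed = TRUE,
    min_module_size = 30L,
    merge_cor_threshold = 0.85,
    scale_free_target_r2 = 0.8,
    expressed_fraction = 0.9,
    outlier_cut_sd = 2.5,
    cut_method = "gap",
    cut_height_frac = 0.99,
    gap_frac = 0.25,
    # preservation
    n_perm = 100L,
    z_weak = 2,
    z_strong = 10,
    # PGS
    clump_r2 = 0.2,
    clump_window_kb = 250,
    gene_window_kb = 0,
    missing_policy = "mean",
    # scoring
    ssgsea_tau = 0.25,
    ssgsea_normalize = TRUE,
    nbin = 24L,
    nctrl = 100L,
    # MR
    wm_boot = 1000L,
    # multiplicity
    fdr_level = 0.05,
    seed = 1L
  )
  override <- list(...)
  unknown <- setdiff(names(override), names(cfg))
  if (length(unknown)) {
    stop("unknown config parameter(s): ", paste(unknown, collapse = ", "))
  }
  cfg[names(override)] <- override
  validate_config(cfg)
  class(cfg) <- "fetomod_config"
  cfg
}

validate_config <- function(cfg) {
  stopifnot(
    cfg$soft_power >= 1,
    is.logical(cfg$signed),
    cfg$min_module_size >= 2,
    cfg$merge_cor_threshold > 0, cfg$merge_cor_threshold <= 1,
    cfg$scale_free_target_r2 > 0, cfg$scale_free_target_r2 < 1,
    cfg$expressed_fraction > 0, cfg$expressed_fraction < 1,
    cfg$outlier_cut_sd > 0,
    cfg$cut_method %in% c("gap", "static"),
    cfg$cut_height_frac > 0, cfg$cut_height_frac <= 1,
    cfg$gap_frac > 0, cfg$gap_frac < 1,
    cfg$n_perm >= 20,
    cfg$z_weak < cfg$z_strong,
    cfg$clump_r2 > 0, cfg$clump_r2 <= 1,
    cfg$clump_window_kb > 0,
    cfg$gene_window_kb >= 0,
    cfg$missing_policy %in% c("mean", "drop", "zero"),
    cfg$ssgsea_tau > 0,
    is.logical(cfg$ssgsea_normalize),
    cfg$nbin >= 2, cfg$nctrl >= 1,
    cfg$wm_boot >= 100,
    cfg$fdr_level > 0, cfg$fdr_level < 1
  )
  invisible(cfg)
}

#' @export
print.fetomod_config <- function(x, ...) {
  cat("fetomod analysis configuration\n")
  for (nm in names(x)) cat(sprintf("  %-22s %s\n", nm, format(x[[nm]])))
  invisible(x)
}
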