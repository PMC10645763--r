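stage_seed <- function(seed, stage) {
  # per-stage substream: offset the global seed by a fixed stage index
  offsets <- c(simulate = 0L, network = 11L, preserve = 23L, pgs = 37L,
               score = 53L, phewas = 71L, mr = 89L, enrich = 107L,
               connectivity = 127L)
  if (!stage %in% names(offsets)) stop("unknown stage: ", stage)
  (seed + offsets[[stage]] * 1009L) %% .Machine$integer.max
}

#' Run the full synthetic-data analysis pipeline
#'
#' Executes the study's inference chain end to end on generated data:
#' simulate (two cohorts plus phenotype) -> network (module detection)
#' -> preserve (modules re-tested in the outcome cohort's expression)
#' -> pgs (eQTL-weighted score with clumping, plus a random-gene negative
#' control) -> score (ssGSEA validation of the PGS) -> phewas (PGS against
#' the phenotype and null outcomes) -> mr (two-sample estimates with
#' sensitivity analyses) -> enrich / connectivity (overlap of the detected
#' vs planted module; ARACNE degree comparison). Each stage writes TSV
#' artifacts under `out_dir` and appends to a JSON run manifest recording
#' config, seeds, file hashes and wall-clock time. Stages consume prior
#' artifacts; requesting a stage without its upstream dependency errors.
#'
#' @param out_dir Output directory (created if absent).
#' @param sim A [sim_params()] object (the generator's stated world).
#' @param config An [analysis_config()].
#' @param stages Character vector of stages to run, in pipeline order.
#' @return The run manifest (list), invisibly; artifacts land in `out_dir`.
#' @export
run_pipeline <- function(out_dir,
                         sim = sim_params(),
                         config = analysis_config(),
                         stages = c("simulate", "network", "preserve", "pgs",
                                    "score", "phewas", "mr", "enrich",
                                    "connectivity")) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  order_all <- c("simulate", "network", "preserve", "pgs", "score", "phewas",
                 "mr", "enrich", "connectivity")
  stages <- order_all[order_all %in% stages]
  deps <- list(network = "simulate", preserve = c("simulate", "network"),
               pgs = "simulate", score = c("simulate", "network", "pgs"),
               phewas = c("simulate", "pgs"), mr = "simulate",
               enrich = c("simulate", "network"),
               connectivity = c("simulate", "network"))
  for (s in stages) {
    missing_dep <- setdiff(deps[[s]], stages)
    if (length(missing_dep)) {
      stop("stage '", s, "' requires stage(s): ",
           paste(missing_dep, collapse = ", "))
    }
  }
  manifest <- list(config = unclass(config), sim = unclass(sim),
                   seed = config$seed, stages = list())
  env <- new.env()
  art <- function(name) file.path(out_dir, name)
  record <- function(stage, files, t0) {
    manifest$stages[[stage]] <<- list(
      files = as.list(tools::md5sum(files[file.exists(files)])),
      seconds = round(as.numeric(Sys.time()) - t0, 2))
    jsonlite::write_json(manifest, art("manifest.json"), auto_unbox = TRUE,
                         digits = NA, null = "null")
  }

  for (s in stages) {
    t0 <- as.numeric(Sys.time())
    message("pipeline: stage ", s)
    files <- switch(s,
      simulate = {
        sim$seed <- stage_seed(config$seed, "simulate")
        env$exposure <- simulate_cohort(sim, "exposure")
        env$outcome <- simulate_cohort(sim, "outcome")
        env$phenotype <- simulate_outcome(env$exposure$truth,
                                          env$outcome$genotypes, sim)
        env$sim <- sim
        write_expression(env$exposure$expression, art("expression.tsv"))
        write_dosages(env$exposure$genotypes, art("dosages_exposure.tsv"),
                      art("variants_exposure.tsv"))
        truth_sets <- split(names(env$exposure$truth$module_labels),
                            env$exposure$truth$module_labels)
        truth_sets <- truth_sets[names(truth_sets) != "grey"]
        write_gmt(truth_sets, art("planted_modules.gmt"))
        jsonlite::write_json(
          list(gamma = sim$gamma,
               target_module = env$exposure$truth$target_module,
               eqtl_map = env$exposure$truth$eqtl_map),
          art("truth.json"), auto_unbox = TRUE, digits = NA)
        st <- make_two_sample_stats(env$exposure, env$outcome, env$phenotype)
        env$stats <- st
        write_results(st$exposure, art("exposure_stats.tsv"),
                      seed = sim$seed)
        write_results(st$outcome, art("outcome_stats.tsv"), seed = sim$seed)
        art(c("expression.tsv", "dosages_exposure.tsv",
              "variants_exposure.tsv", "planted_modules.gmt", "truth.json",
              "exposure_stats.tsv", "outcome_stats.tsv"))
      },
      network = {
        env$network <- build_network(env$exposure$expression, config,
                                     filter = FALSE)
        part <- data.frame(gene = names(env$network$labels),
                           module = unname(env$network$labels))
        write_results(part, art("partition.tsv"), seed = config$seed)
        mods <- split(part$gene, part$module)
        mods <- mods[names(mods) != "grey"]
        write_gmt(mods, art("modules.gmt"))
        if (!is.null(env$network$eigengenes)) {
          eig <- data.frame(sample_id = rownames(env$network$eigengenes),
                            env$network$eigengenes, check.names = FALSE)
          write_results(eig, art("eigengenes.tsv"))
        }
        art(c("partition.tsv", "modules.gmt", "eigengenes.tsv"))
      },
      preserve = {
        seed <- stage_seed(config$seed, "preserve")
        pres <- module_preservation(env$exposure$expression,
                                    env$network$labels,
                                    env$outcome$expression,
                                    n_perm = config$n_perm,
                                    power = config$soft_power %||% env$network$power,
                                    seed = seed)
        env$preservation <- pres
        write_results(as.data.frame(pres), art("preservation.tsv"),
                      seed = seed)
        art("preservation.tsv")
      },
      pgs = {
        seed <- stage_seed(config$seed, "pgs")
        truth <- env$exposure$truth
        target <- truth$target_module
        em <- truth$eqtl_map[truth$eqtl_map$module == target, , drop = FALSE]
        vi <- env$exposure$genotypes$variants
        eqtl <- data.frame(
          snp = em$snp, gene = em$gene, beta = em$beta,
          effect_allele = vi$effect_allele[match(em$snp, vi$snp)],
          other_allele = vi$other_allele[match(em$snp, vi$snp)],
          se = 0.05, p = 1e-4, stringsAsFactors = FALSE)
        clumped <- ld_clump(eqtl, env$exposure$genotypes,
                            config$clump_r2, config$clump_window_kb)
        env$weights <- pgs_weights(clumped, tag = target)
        env$pgs <- build_pgs(env$exposure$genotypes, env$weights,
                             config$missing_policy)
        # random-gene negative control: same size, genes without eQTLs
        ctrl_genes <- negative_control_genes(
          "random_genes", size = sum(truth$module_labels == target),
          universe = rownames(env$exposure$expression), seed = seed)
        env$control_genes <- ctrl_genes
        ctrl_em <- truth$eqtl_map[truth$eqtl_map$gene %in% ctrl_genes, ,
                                  drop = FALSE]
        ctrl_eqtl <- data.frame(
          snp = ctrl_em$snp, gene = ctrl_em$gene, beta = ctrl_em$beta,
          effect_allele = vi$effect_allele[match(ctrl_em$snp, vi$snp)],
          other_allele = vi$other_allele[match(ctrl_em$snp, vi$snp)],
          se = 0.05, p = 1e-4, stringsAsFactors = FALSE)
        env$control_pgs <- if (nrow(ctrl_eqtl) >= 1L) {
          build_pgs(env$exposure$genotypes,
                    pgs_weights(ctrl_eqtl, tag = "random_genes"),
                    config$missing_policy)
        } else NULL
        write_results(as.data.frame(env$weights), art("pgs_weights.tsv"),
                      seed = seed)
        write_results(data.frame(sample_id = names(env$pgs),
                                 pgs = unname(env$pgs)),
                      art("pgs_scores.tsv"), seed = seed)
        art(c("pgs_weights.tsv", "pgs_scores.tsv"))
      },
      score = {
        target <- env$exposure$truth$target_module
        detected <- split(names(env$network$labels), env$network$labels)
        detected <- detected[names(detected) != "grey"]
        # score the planted target set alongside detected modules
        sets <- c(detected, list(planted_target = names(
          env$exposure$truth$module_labels)[
            env$exposure$truth$module_labels == target]))
        shifted <- env$exposure$expression -
          min(env$exposure$expression)  # ssGSEA ranks: shift is harmless
        env$scores <- ssgsea(shifted, sets, tau = config$ssgsea_tau,
                             normalize = config$ssgsea_normalize)
        env$validation <- validate_pgs(env$pgs,
                                       env$scores[, "planted_target"])
        sc <- data.frame(sample_id = rownames(env$scores), env$scores,
                         check.names = FALSE)
        write_results(sc, art("ssgsea_scores.tsv"))
        write_results(env$validation, art("pgs_validation.tsv"))
        art(c("ssgsea_scores.tsv", "pgs_validation.tsv"))
      },
      phewas = {
        seed <- stage_seed(config$seed, "phewas")
        set.seed(seed)
        # outcome cohort: the planted phenotype plus null outcomes
        out_geno <- env$outcome$genotypes
        pgs_out <- build_pgs(out_geno, env$weights, config$missing_policy)
        n <- length(pgs_out)
        outcomes <- data.frame(planted = unname(env$phenotype[names(pgs_out)]))
        for (k in 1:20) outcomes[[paste0("null_", k)]] <- stats::rnorm(n)
        rownames(outcomes) <- names(pgs_out)
        env$phewas <- run_phewas(pgs_out, outcomes,
                                 fdr_level = config$fdr_level)
        write_results(as.data.frame(env$phewas), art("phewas.tsv"),
                      seed = seed)
        art("phewas.tsv")
      },
      mr = {
        seed <- stage_seed(config$seed, "mr")
        h <- harmonize(env$stats$exposure, env$stats$outcome)
        env$mr <- mr_all(h, n_boot = config$wm_boot, seed = seed)
        env$mr_sens <- mr_sensitivity(h)
        write_results(env$mr, art("mr_estimates.tsv"), seed = seed)
        write_results(env$mr_sens$single_snp, art("mr_single_snp.tsv"))
        write_results(env$mr_sens$leave_one_out, art("mr_leave_one_out.tsv"))
        write_results(env$mr_sens$Q, art("mr_heterogeneity.tsv"))
        art(c("mr_estimates.tsv", "mr_single_snp.tsv",
              "mr_leave_one_out.tsv", "mr_heterogeneity.tsv"))
      },
      enrich = {
        target <- env$exposure$truth$target_module
        planted <- names(env$exposure$truth$module_labels)[
          env$exposure$truth$module_labels == target]
        detected <- split(names(env$network$labels), env$network$labels)
        detected <- detected[names(detected) != "grey"]
        env$enrich <- overlap_test_batch(planted, detected,
                                         rownames(env$exposure$expression))
        write_results(env$enrich, art("enrichment.tsv"))
        art("enrichment.tsv")
      },
      connectivity = {
        seed <- stage_seed(config$seed, "connectivity")
        target <- env$exposure$truth$target_module
        genes <- names(env$exposure$truth$module_labels)[
          env$exposure$truth$module_labels == target]
        net <- aracne_network(env$exposure$expression[genes, , drop = FALSE],
                              seed = seed)
        env$mi_network <- net
        write_results(data.frame(gene = names(net$degree),
                                 degree = unname(net$degree)),
                      art("connectivity.tsv"), seed = seed)
        art("connectivity.tsv")
      }
    )
    record(s, files, t0)
  }
  manifest$results <- env
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
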