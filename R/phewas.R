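#' Classify an outcome vector for model selection
#'
#' Reduced PHESANT-style typing rule: two distinct values gives binary,
#' integer-valued with at most 20 distinct levels gives ordinal, anything
#' else continuous. Outcomes with fewer than `min_n` non-missing values or
#' a single distinct value are unusable.
#'
#' @param values Outcome vector (numeric; factors are converted).
#' @param min_n Minimum non-missing observations (default 50).
#' @param max_ordinal_levels Distinct-level bound for the ordinal class.
#' @return One of "binary", "ordinal", "continuous", or "skip" (with a
#'   `reason` attribute) when the outcome cannot be fitted.
#' @export
classify_outcome <- function(values, min_n = 50L, max_ordinal_levels = 20L) {
  if (is.factor(values)) values <- as.numeric(values)
  v <- values[!is.na(values)]
  if (length(v) < min_n) {
    return(structure("skip", reason = "too few non-missing values"))
  }
  u <- unique(v)
  if (length(u) < 2L) {
    return(structure("skip", reason = "single distinct value"))
  }
  if (length(u) == 2L) return("binary")
  if (all(v == round(v)) && length(u) <= max_ordinal_levels) return("ordinal")
  "continuous"
}

# expand a covariate data.frame: categoricals one-hot with the most
# frequent level as reference
expand_covariates <- function(covariates) {
  if (is.null(covariates) || !ncol(covariates)) return(NULL)
  out <- covariates
  for (nm in colnames(covariates)) {
    col <- covariates[[nm]]
    if (is.character(col) || is.factor(col)) {
      col <- factor(col)
      ref <- names(which.max(table(col)))
      out[[nm]] <- stats::relevel(col, ref = ref)
    }
  }
  out
}

#' Phenome-wide association scan of a PGS
#'
#' Each outcome column is typed with [classify_outcome()] and fitted
#' complete-case against the PGS plus covariates: continuous by OLS, binary
#' (recoded 0/1) by logistic regression, ordinal by proportional-odds
#' maximum likelihood. Categorical covariates are one-hot expanded with the
#' most frequent level as reference. Benjamini-Hochberg FDR is applied
#' across all successfully fitted outcomes; non-converged or separated fits
#' are flagged and excluded from the FDR with a warning.
#'
#' @param pgs Named numeric PGS vector.
#' @param outcomes Data.frame of outcome columns (rownames = sample ids).
#' @param covariates Optional covariate data.frame (rownames = sample ids).
#' @param fdr_level BH FDR level defining the significant set (default 0.05).
#' @param categories Optional named vector outcome -> category label (for
#'   plotting).
#' @return Data.frame of class `fetomod_phewas`: outcome, family, beta
#'   (log-OR for binary/ordinal), se, p, q, n, signed_logp, significant,
#'   flag.
#' @export
run_phewas <- function(pgs, outcomes, covariates = NULL, fdr_level = 0.05,
                       categories = NULL) {
  stopifnot(is.data.frame(outcomes), !is.null(rownames(outcomes)))
  samples <- intersect(names(pgs), rownames(outcomes))
  if (!is.null(covariates)) samples <- intersect(samples, rownames(covariates))
  if (length(samples) < 10L) stop("too few aligned samples")
  cov_exp <- expand_covariates(
    if (is.null(covariates)) NULL else covariates[samples, , drop = FALSE])
  base <- data.frame(pgs = pgs[samples])
  if (!is.null(cov_exp)) base <- cbind(base, cov_exp)
  rows <- lapply(colnames(outcomes), function(oc) {
    y <- outcomes[samples, oc]
    type <- classify_outcome(y)
    row <- data.frame(outcome = oc, family = as.character(type),
                      beta = NA_real_, se = NA_real_, p = NA_real_,
                      n = sum(!is.na(y)), flag = "", stringsAsFactors = FALSE)
    if (type == "skip") {
      row$flag <- attr(type, "reason")
      return(row)
    }
    df <- cbind(base, .y = y)
    df <- df[stats::complete.cases(df), , drop = FALSE]
    row$n <- nrow(df)
    fit <- tryCatch(switch(
      as.character(type),
      continuous = {
        f <- stats::lm(.y ~ ., data = df)
        summary(f)$coefficients["pgs", c(1L, 2L, 4L)]
      },
      binary = {
        df$.y <- as.numeric(df$.y == max(df$.y))
        f <- suppressWarnings(stats::glm(.y ~ ., data = df,
                                         family = stats::binomial()))
        if (!f$converged) stop("non-convergence")
        cf <- summary(f)$coefficients["pgs", ]
        if (cf[2L] > 100) stop("separation")  # absurd SE flags separation
        cf[c(1L, 2L, 4L)]
      },
      ordinal = {
        df$.y <- factor(df$.y, ordered = TRUE)
        f <- suppressWarnings(MASS::polr(.y ~ ., data = df, Hess = TRUE))
        cf <- summary(f)$coefficients["pgs", ]
        z <- cf[1L] / cf[2L]
        c(cf[1L], cf[2L], 2 * stats::pnorm(-abs(z)))
      }), error = function(e) conditionMessage(e))
    if (is.character(fit)) {
      row$flag <- fit
      warning("run_phewas: outcome ", oc, " excluded (", fit, ")")
    } else {
      row$beta <- fit[[1L]]; row$se <- fit[[2L]]; row$p <- fit[[3L]]
    }
    row
  })
  res <- do.call(rbind, rows)
  fitted <- !is.na(res$p)
  res$q <- NA_real_
  res$q[fitted] <- stats::p.adjust(res$p[fitted], method = "BH")
  res$signed_logp <- sign(res$beta) * -log10(res$p)
  res$significant <- !is.na(res$q) & res$q < fdr_level
  res$category <- if (is.null(categories)) "all" else
    unname(categories[res$outcome])
  attr(res, "fdr_level") <- fdr_level
  class(res) <- c("fetomod_phewas", "data.frame")
  res
}

#' Plot-ready Miami table from a pheWAS result
#'
#' Signed -log10 p per outcome plus the FDR threshold line: the largest raw
#' p among outcomes passing BH at the scan's level (absent when nothing
#' passes).
#'
#' @param result A [run_phewas()] result.
#' @return List with `table` (outcome, category, signed_logp, significant)
#'   and `threshold` (-log10 of the threshold p, or NA with
#'   `has_threshold = FALSE`).
#' @export
miami_table <- function(result) {
  stopifnot(inherits(result, "fetomod_phewas"))
  tab <- result[!is.na(result$p),
                c("outcome", "category", "signed_logp", "significant")]
  sig_p <- result$p[result$significant & !is.na(result$p)]
  has <- length(sig_p) > 0
  list(table = tab,
       threshold = if (has) -log10(max(sig_p)) else NA_real_,
       has_threshold = has)
}
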