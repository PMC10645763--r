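#' Read a gene-by-sample expression matrix from TSV
#'
#' Expects a tab-separated file whose header names the samples and whose first
#' column holds gene identifiers. Values must be finite, non-negative
#' abundances (RPKM-like). Duplicate gene or sample identifiers are rejected.
#'
#' @param path Path to a TSV file.
#' @return A numeric matrix with genes as rows (rownames = gene ids) and
#'   samples as columns (colnames = sample ids).
#' @export
read_expression <- function(path) {
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(raw) < 2L) stop("expression file needs a gene column plus >=1 sample")
  gene_ids <- as.character(raw[[1L]])
  dup <- gene_ids[duplicated(gene_ids)]
  if (length(dup)) {
    stop("duplicate gene id(s): ", paste(unique(dup), collapse = ", "))
  }
  sample_ids <- colnames(raw)[-1L]
  if (anyDuplicated(sample_ids)) {
    stop("duplicate sample id(s): ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  }
  vals <- as.matrix(raw[, -1L, drop = FALSE])
  if (!is.numeric(vals)) stop("non-numeric expression values in ", path)
  if (any(!is.finite(vals))) stop("non-finite expression values in ", path)
  rownames(vals) <- gene_ids
  colnames(vals) <- sample_ids
  vals
}

#' Write an expression matrix to TSV
#'
#' Inverse of [read_expression()]; first column is named `gene_id`.
#'
#' @param expr Numeric matrix, genes x samples, with dimnames.
#' @param path Output path.
#' @export
write_expression <- function(expr, path) {
  stopifnot(is.matrix(expr), !is.null(rownames(expr)), !is.null(colnames(expr)))
  df <- data.frame(gene_id = rownames(expr), expr, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene sets from a GMT file
#'
#' Standard GMT: one set per line, fields are name, description, then member
#' genes, all tab-separated. The description is retained as an attribute but
#' otherwise unused.
#'
#' @param path Path to a GMT file.
#' @return Named list of character vectors of gene ids, with a
#'   `descriptions` attribute.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  sets <- vector("list", length(lines))
  nms <- character(length(lines))
  desc <- character(length(lines))
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    if (length(fields) < 3L) {
      stop("GMT line ", i, " has fewer than 3 fields (empty member list?)")
    }
    nms[[i]] <- fields[[1L]]
    desc[[i]] <- fields[[2L]]
    sets[[i]] <- unique(fields[-(1:2)])
  }
  if (anyDuplicated(nms)) {
    stop("duplicate gene-set name(s): ",
         paste(unique(nms[duplicated(nms)]), collapse = ", "))
  }
  names(sets) <- nms
  attr(sets, "descriptions") <- stats::setNames(desc, nms)
  sets
}

#' Write gene sets to a GMT file
#'
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @param descriptions Optional character vector of per-set descriptions.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  stopifnot(is.list(sets), !is.null(names(sets)))
  if (is.null(descriptions)) {
    descriptions <- attr(sets, "descriptions")
    if (is.null(descriptions)) descriptions <- rep("na", length(sets))
  }
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[[i]], descriptions[[i]], sets[[i]]), collapse = "\t")
  }, character(1L))
  writeLines(lines, path)
  invisible(path)
}

#' Read GWAS or eQTL summary statistics from a delimited table
#'
#' `column_map` names the file columns that carry each field; mandatory
#' entries are `snp`, `effect_allele`, `other_allele`, `beta`, `se`, `p`.
#' Optional entries: `gene` (for eQTL tables), `eaf`, `n`, `chrom`, `pos`.
#' Alleles are upper-cased. Rows with missing beta or se are dropped with a
#' message; rows with se <= 0 are an error.
#'
#' @param path Path to a delimited text file with a header.
#' @param column_map Named character vector/list mapping field -> column name.
#' @param sep Field separator (default tab).
#' @return A data.frame with standardized column names (`snp`,
#'   `effect_allele`, `other_allele`, `beta`, `se`, `p`, plus any optional
#'   fields supplied).
#' @export
read_summary_stats <- function(path, column_map, sep = "\t") {
  column_map <- as.list(column_map)
  need <- c("snp", "effect_allele", "other_allele", "beta", "se", "p")
  missing_need <- setdiff(need, names(column_map))
  if (length(missing_need)) {
    stop("column_map lacks mandatory field(s): ",
         paste(missing_need, collapse = ", "))
  }
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           check.names = FALSE, stringsAsFactors = FALSE)
  absent <- setdiff(unlist(column_map), colnames(raw))
  if (length(absent)) {
    stop("mapped column(s) absent from file: ", paste(absent, collapse = ", "))
  }
  out <- data.frame(
    snp = as.character(raw[[column_map$snp]]),
    effect_allele = toupper(as.character(raw[[column_map$effect_allele]])),
    other_allele = toupper(as.character(raw[[column_map$other_allele]])),
    beta = as.numeric(raw[[column_map$beta]]),
    se = as.numeric(raw[[column_map$se]]),
    p = as.numeric(raw[[column_map$p]]),
    stringsAsFactors = FALSE
  )
  for (opt in c("gene", "eaf", "n", "chrom", "pos")) {
    if (!is.null(column_map[[opt]])) {
      col <- raw[[column_map[[opt]]]]
      out[[opt]] <- if (opt %in% c("gene", "chrom")) as.character(col) else as.numeric(col)
    }
  }
  bad <- !is.finite(out$beta) | !is.finite(out$se)
  if (any(bad)) {
    message("read_summary_stats: dropped ", sum(bad),
            " row(s) with missing beta or se")
    out <- out[!bad, , drop = FALSE]
  }
  if (any(out$se <= 0)) stop("se <= 0 in summary statistics")
  rownames(out) <- NULL
  out
}

#' Read a sample-by-SNP dosage table plus variant metadata
#'
#' The dosage TSV has a header of SNP ids and a first column of sample ids;
#' entries are expected effect-allele counts in \[0, 2\] (NA allowed). The
#' variant table supplies per-SNP metadata (`snp`, `chrom`, `pos`,
#' `effect_allele`, `other_allele`).
#'
#' @param dosage_path Path to the dosage TSV.
#' @param variant_path Path to the variant metadata TSV.
#' @return A list with components `dosages` (samples x SNPs numeric matrix)
#'   and `variants` (data.frame aligned to the dosage columns).
#' @export
read_dosages <- function(dosage_path, variant_path) {
  raw <- utils::read.delim(dosage_path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE)
  sample_ids <- as.character(raw[[1L]])
  dosages <- as.matrix(raw[, -1L, drop = FALSE])
  storage.mode(dosages) <- "double"
  rownames(dosages) <- sample_ids
  vi <- utils::read.delim(variant_path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  validate_variants(vi)
  if (anyDuplicated(colnames(dosages))) stop("duplicate SNP ids in dosage file")
  if (!setequal(colnames(dosages), vi$snp)) {
    stop("dosage columns and variant table disagree on SNP ids")
  }
  vi <- vi[match(colnames(dosages), vi$snp), , drop = FALSE]
  rownames(vi) <- NULL
  ok <- is.na(dosages) | (dosages >= 0 & dosages <= 2)
  if (!all(ok)) stop("dosage outside [0,2]")
  list(dosages = dosages, variants = vi)
}

#' Write dosages and variant metadata
#'
#' @param geno A list as returned by [read_dosages()] or
#'   [simulate_genotypes()].
#' @param dosage_path,variant_path Output paths.
#' @export
write_dosages <- function(geno, dosage_path, variant_path) {
  df <- data.frame(sample_id = rownames(geno$dosages), geno$dosages,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, dosage_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(geno$variants, variant_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(dosage_path)
}

validate_variants <- function(vi) {
  need <- c("snp", "chrom", "pos", "effect_allele", "other_allele")
  missing_need <- setdiff(need, colnames(vi))
  if (length(missing_need)) {
    stop("variant table lacks column(s): ", paste(missing_need, collapse = ", "))
  }
  if (anyDuplicated(vi$snp)) stop("duplicate variant ids")
  if (any(vi$pos < 1)) stop("positions are 1-based; pos < 1 found")
  if (any(vi$effect_allele == vi$other_allele)) {
    stop("effect and other allele identical for some variant")
  }
  invisible(vi)
}

#' Read dosages from a minimal VCF
#'
#' Uses the VariantAnnotation package. Dosage is taken from the DS FORMAT
#' field when present, otherwise computed as the count of ALT alleles in GT.
#' Multi-allelic records are skipped with a warning. Effect allele = ALT.
#'
#' @param path Path to a VCF file.
#' @return A list with `dosages` (samples x SNPs) and `variants` metadata,
#'   as in [read_dosages()].
#' @export
read_vcf_dosages <- function(path) {
  if (!requireNamespace("VariantAnnotation", quietly = TRUE)) {
    stop("read_vcf_dosages requires the VariantAnnotation package")
  }
  vcf <- VariantAnnotation::readVcf(path)
  alt <- VariantAnnotation::alt(vcf)
  n_alt <- S4Vectors::elementNROWS(alt)
  keep <- n_alt == 1L
  if (any(!keep)) {
    warning(sum(!keep), " multi-allelic record(s) skipped")
    vcf <- vcf[keep, ]
  }
  gr <- SummarizedExperiment::rowRanges(vcf)
  geno <- VariantAnnotation::geno(vcf)
  if ("DS" %in% names(geno)) {
    dos <- t(geno$DS)
  } else if ("GT" %in% names(geno)) {
    gt <- geno$GT
    cnt <- function(g) {
      if (is.na(g) || g %in% c(".", "./.", ".|.")) return(NA_real_)
      sum(as.integer(strsplit(g, "[/|]")[[1L]]) > 0L)
    }
    dos <- t(apply(gt, c(1L, 2L), cnt))
  } else {
    stop("VCF has neither DS nor GT FORMAT fields")
  }
  storage.mode(dos) <- "double"
  ids <- names(gr)
  colnames(dos) <- ids
  vi <- data.frame(
    snp = ids,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    pos = GenomicRanges::start(gr),
    effect_allele = as.character(unlist(VariantAnnotation::alt(vcf))),
    other_allele = as.character(VariantAnnotation::ref(vcf)),
    stringsAsFactors = FALSE
  )
  validate_variants(vi)
  list(dosages = dos, variants = vi)
}

#' Write a results table as TSV with a JSON provenance sidecar
#'
#' Floats are written at 6 significant digits. The sidecar (same path with
#' `.json` appended) records the configuration list and seed used.
#'
#' @param df A data.frame.
#' @param path Output TSV path.
#' @param config Optional list recorded in the sidecar.
#' @param seed Optional seed recorded in the sidecar.
#' @export
write_results <- function(df, path, config = NULL, seed = NULL) {
  fmt <- df
  num <- vapply(fmt, is.double, logical(1L))
  fmt[num] <- lapply(fmt[num], signif, digits = 6L)
  utils::write.table(fmt, path, sep = "\t", quote = FALSE, row.names = FALSE)
  sidecar <- list(written = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                  config = config, seed = seed)
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       null = "null", digits = NA)
  invisible(path)
}
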