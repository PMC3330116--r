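# On-disk formats. All tabular files are TSV with a header row; genomic
# positions in TSV/VCF are 1-based, BED intervals are 0-based half-open
# (conversion handled by rtracklayer on import). Missing numeric values are
# written as the literal token NA.

fread_tsv <- function(path) {
  if (!file.exists(path)) stop_twinewas("file not found: ", path)
  data.table::fread(path, sep = "\t", na.strings = "NA", data.table = TRUE)
}

fwrite_tsv <- function(dt, path) {
  data.table::fwrite(dt, path, sep = "\t", na = "NA", quote = FALSE)
}

matrix_to_dt <- function(m, id_col) {
  dt <- data.table::as.data.table(m, keep.rownames = id_col)
  dt
}

dt_to_matrix <- function(dt, id_col) {
  ids <- dt[[id_col]]
  if (anyDuplicated(ids)) stop_twinewas("duplicate ", id_col, " in ", id_col, " table")
  m <- as.matrix(dt[, !id_col, with = FALSE])
  rownames(m) <- ids
  m
}

#' Write a simulated or assembled dataset bundle to a directory
#'
#' Writes `methylation.tsv`, `annotation.tsv`, `samples.tsv`,
#' `phenotypes.tsv`, `genotypes.tsv`, `snp_map.tsv` and, when present,
#' `truth.tsv`, `wbc.tsv` and `expression.tsv`.
#'
#' @param bundle list as returned by [read_dataset()] or [simulate_dataset()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fwrite_tsv(matrix_to_dt(bundle$meth$betas, "probe_id"),
             file.path(dir, "methylation.tsv"))
  fwrite_tsv(bundle$meth$annotation, file.path(dir, "annotation.tsv"))
  fwrite_tsv(as.data.table(bundle$cohort), file.path(dir, "samples.tsv"))
  if (!is.null(bundle$phenos))
    fwrite_tsv(matrix_to_dt(bundle$phenos$values, "trait"),
               file.path(dir, "phenotypes.tsv"))
  if (!is.null(bundle$genos)) {
    fwrite_tsv(matrix_to_dt(bundle$genos$dosages, "snp_id"),
               file.path(dir, "genotypes.tsv"))
    fwrite_tsv(bundle$genos$map, file.path(dir, "snp_map.tsv"))
  }
  if (!is.null(bundle$truth)) fwrite_tsv(bundle$truth, file.path(dir, "truth.tsv"))
  if (!is.null(bundle$wbc))
    fwrite_tsv(matrix_to_dt(bundle$wbc, "cell_type"), file.path(dir, "wbc.tsv"))
  if (!is.null(bundle$expression))
    fwrite_tsv(matrix_to_dt(bundle$expression, "gene"),
               file.path(dir, "expression.tsv"))
  invisible(dir)
}

#' Read a dataset bundle and align samples across tables
#'
#' Reads the TSV file set written by [write_dataset()] (genotypes may instead
#' be a VCF). Samples present in the methylation matrix but absent from the
#' genotype or phenotype tables are retained (those tables simply lack them);
#' samples absent from the sample sheet are dropped with a message. All
#' matrices are re-ordered to the sample-sheet order restricted to available
#' columns.
#'
#' @param dir directory containing the bundle, or a named list of paths with
#'   elements `methylation`, `annotation`, `samples` and optionally
#'   `phenotypes`, `genotypes`, `snp_map`, `vcf`, `truth`, `wbc`, `expression`.
#' @param maf_min minor-allele-frequency filter for genotypes (default 0.05).
#' @return list with elements `meth` (`meth_set`), `cohort` (`twin_cohort`),
#'   `genos` (`geno_set` or `NULL`), `phenos` (`pheno_table` or `NULL`),
#'   `truth`, `wbc`, `expression` (or `NULL`) and `log` (dropped-sample
#'   counts).
#' @export
read_dataset <- function(dir, maf_min = 0.05) {
  if (is.character(dir) && length(dir) == 1L && dir.exists(dir)) {
    p <- function(f) file.path(dir, f)
    paths <- list(methylation = p("methylation.tsv"),
                  annotation = p("annotation.tsv"),
                  samples = p("samples.tsv"))
    for (f in c("phenotypes", "genotypes", "snp_map", "truth", "wbc",
                "expression")) {
      fp <- p(paste0(f, ".tsv"))
      if (file.exists(fp)) paths[[f]] <- fp
    }
  } else {
    paths <- dir
  }
  cohort <- twin_cohort(fread_tsv(paths$samples))
  betas <- dt_to_matrix(fread_tsv(paths$methylation), "probe_id")
  meth <- methylation_matrix(betas, fread_tsv(paths$annotation))

  log <- list()
  keep <- intersect(cohort$individual_id, colnames(meth$betas))
  log$n_meth_not_in_sheet <- ncol(meth$betas) - length(keep)
  log$n_sheet_not_in_meth <- nrow(cohort) - length(keep)
  if (log$n_meth_not_in_sheet > 0 || log$n_sheet_not_in_meth > 0)
    message("read_dataset: dropped ", log$n_meth_not_in_sheet,
            " methylation column(s) and ", log$n_sheet_not_in_meth,
            " sample-sheet row(s) without a cross-table match")
  cohort <- twin_cohort(cohort[cohort$individual_id %in% keep])
  meth$betas <- meth$betas[, cohort$individual_id, drop = FALSE]

  genos <- NULL
  if (!is.null(paths$vcf)) {
    genos <- read_genotypes_vcf(paths$vcf, maf_min = maf_min)
  } else if (!is.null(paths$genotypes)) {
    genos <- genotype_matrix(dt_to_matrix(fread_tsv(paths$genotypes), "snp_id"),
                             fread_tsv(paths$snp_map), maf_min = maf_min)
  }
  if (!is.null(genos)) {
    common <- intersect(cohort$individual_id, colnames(genos$dosages))
    miss <- setdiff(cohort$individual_id, colnames(genos$dosages))
    if (length(miss)) {
      log$n_no_genotypes <- length(miss)
      warning(length(miss), " sample(s) lack genotypes; retained for EWAS, ",
              "excluded from meQTL/GWAS scans", call. = FALSE)
    }
    genos$dosages <- genos$dosages[, common, drop = FALSE]
  }

  phenos <- NULL
  if (!is.null(paths$phenotypes)) {
    pv <- dt_to_matrix(fread_tsv(paths$phenotypes), "trait")
    common <- intersect(cohort$individual_id, colnames(pv))
    phenos <- phenotype_table(pv[, common, drop = FALSE])
  }
  truth <- if (!is.null(paths$truth)) fread_tsv(paths$truth) else NULL
  wbc <- if (!is.null(paths$wbc)) dt_to_matrix(fread_tsv(paths$wbc), "cell_type") else NULL
  expression <- if (!is.null(paths$expression))
    dt_to_matrix(fread_tsv(paths$expression), "gene") else NULL

  list(meth = meth, cohort = cohort, genos = genos, phenos = phenos,
       truth = truth, wbc = wbc, expression = expression, log = log)
}

#' Read genotype dosages from a VCF
#'
#' Dosages are taken from the `DS` FORMAT field when present, otherwise
#' computed as the alternate-allele count of the `GT` field.
#'
#' @param path VCF file (plain or bgzipped).
#' @param maf_min minor-allele-frequency filter (default 0.05).
#' @return a `geno_set`.
#' @export
read_genotypes_vcf <- function(path, maf_min = 0.05) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  has_ds <- any(grepl("\\bDS\\b", v@gt[, 1]))
  if (has_ds) {
    d <- vcfR::extract.gt(v, element = "DS", as.numeric = TRUE)
  } else {
    gt <- vcfR::extract.gt(v, element = "GT")
    d <- apply(gt, 2, function(col) {
      vapply(strsplit(col, "[/|]"), function(a) sum(a == "1"), numeric(1))
    })
    d <- matrix(d, nrow = nrow(gt), dimnames = dimnames(gt))
  }
  ids <- fix[, "ID"]
  ids[is.na(ids) | ids == "."] <-
    paste0(fix[, "CHROM"], ":", fix[, "POS"])[is.na(ids) | ids == "."]
  rownames(d) <- ids
  map <- data.table::data.table(snp_id = ids, chrom = fix[, "CHROM"],
                                pos = as.integer(fix[, "POS"]))
  genotype_matrix(d, map, maf_min = maf_min)
}

#' Read a BED interval track as genomic ranges
#'
#' @param path BED file (0-based half-open intervals).
#' @return a `GRanges` with 1-based closed coordinates.
#' @export
read_bed <- function(path) {
  rtracklayer::import(path, format = "BED")
}

#' Read a YAML run configuration
#'
#' @param path YAML file of key-value pairs.
#' @return named list.
#' @export
read_config <- function(path) {
  yaml::read_yaml(path)
}

#' Write a JSON run summary
#'
#' @param x named list of scalar summaries.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_run_summary <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
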