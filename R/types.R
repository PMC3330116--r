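# Lightweight S3 containers. Samples are always columns of the numeric
# matrices; alignment between tables is by sample id, never by order.

#' Construct a methylation matrix with probe annotation
#'
#' @param betas numeric matrix of methylation fractions (beta values) in
#'   `[0,1]`, probes in rows, individuals in columns. Row names are probe ids,
#'   column names sample ids. Missing values are `NA`.
#' @param annotation data.frame with one row per probe: `probe_id`, `chrom`,
#'   `pos` (1-based CpG coordinate), `nearest_gene`, `tss_distance` (bp),
#'   `cpg_island` (0/1), `unique_mapping` (0/1). `autosomal` is derived from
#'   `chrom` if absent.
#' @return object of class `meth_set`.
#' @export
methylation_matrix <- function(betas, annotation) {
  betas <- as.matrix(betas)
  annotation <- as.data.table(annotation)
  need <- c("probe_id", "chrom", "pos", "nearest_gene", "tss_distance",
            "cpg_island", "unique_mapping")
  miss <- setdiff(need, names(annotation))
  if (length(miss))
    stop_twinewas("annotation is missing mandatory column(s): ",
                  paste(miss, collapse = ", "))
  if (!"autosomal" %in% names(annotation))
    annotation[, autosomal := !chrom %in% c("chrX", "X", "chrY", "Y")]
  if (nrow(annotation) != nrow(betas))
    stop_twinewas("annotation has ", nrow(annotation), " rows but betas has ",
                  nrow(betas), " probes")
  if (is.null(rownames(betas))) rownames(betas) <- annotation$probe_id
  if (anyDuplicated(annotation$probe_id))
    stop_twinewas("duplicate probe_id in annotation")
  if (!identical(rownames(betas), as.character(annotation$probe_id)))
    stop_twinewas("betas row names do not match annotation probe_id order")
  if (is.null(colnames(betas)))
    stop_twinewas("betas must carry sample ids as column names")
  if (anyDuplicated(colnames(betas)))
    stop_twinewas("duplicate sample id in methylation matrix")
  bad <- which(!is.na(betas) & (betas < 0 | betas > 1), arr.ind = TRUE)
  if (nrow(bad)) {
    stop_twinewas("beta value outside [0,1] at probe ",
                  rownames(betas)[bad[1, 1]], ", sample ",
                  colnames(betas)[bad[1, 2]])
  }
  structure(list(betas = betas, annotation = annotation), class = "meth_set")
}

#' @export
print.meth_set <- function(x, ...) {
  cat("meth_set:", nrow(x$betas), "probes x", ncol(x$betas), "samples;",
      sum(x$annotation$autosomal), "autosomal probes\n")
  invisible(x)
}

#' Construct a twin cohort sample sheet
#'
#' @param df data.frame with columns `individual_id`, `family_id`, `zygosity`
#'   (`MZ`, `DZ` or `singleton`), `age` (years), `sex`, `chip_id`,
#'   `chip_position` (ordinal slot on the chip), `batch_id`.
#' @return a validated `twin_cohort` data.table.
#' @export
twin_cohort <- function(df) {
  df <- as.data.table(df)
  need <- c("individual_id", "family_id", "zygosity", "age", "sex",
            "chip_id", "chip_position", "batch_id")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop_twinewas("sample sheet is missing mandatory column(s): ",
                  paste(miss, collapse = ", "))
  if (anyDuplicated(df$individual_id))
    stop_twinewas("duplicate individual_id in sample sheet")
  if (!all(df$zygosity %in% c("MZ", "DZ", "singleton")))
    stop_twinewas("zygosity must be MZ, DZ or singleton")
  if (any(df$age <= 0)) stop_twinewas("ages must be positive")
  fam <- df[zygosity != "singleton",
            .(n = .N, nzyg = uniqueN(zygosity)), by = family_id]
  if (nrow(fam) && any(fam$n != 2L))
    stop_twinewas("each non-singleton family must have exactly 2 members")
  if (nrow(fam) && any(fam$nzyg != 1L))
    stop_twinewas("co-twins must share zygosity")
  cls <- class(df)
  class(df) <- unique(c("twin_cohort", cls))
  df[]
}

#' Construct a genotype dosage matrix
#'
#' @param dosages numeric matrix of allele dosages in `[0,2]`, SNPs in rows,
#'   individuals in columns; row names are SNP ids.
#' @param map data.frame with `snp_id`, `chrom`, `pos` (1-based bp).
#' @param maf_min minimum minor allele frequency; SNPs below it are dropped
#'   (default 0.05).
#' @return object of class `geno_set` with fields `dosages`, `map` (including
#'   empirical `maf`), and `n_dropped_maf`.
#' @export
genotype_matrix <- function(dosages, map, maf_min = 0.05) {
  dosages <- as.matrix(dosages)
  map <- as.data.table(map)
  need <- c("snp_id", "chrom", "pos")
  miss <- setdiff(need, names(map))
  if (length(miss))
    stop_twinewas("SNP map is missing mandatory column(s): ",
                  paste(miss, collapse = ", "))
  if (nrow(map) != nrow(dosages))
    stop_twinewas("SNP map rows do not match dosage rows")
  if (is.null(rownames(dosages))) rownames(dosages) <- map$snp_id
  if (is.null(colnames(dosages)))
    stop_twinewas("dosages must carry sample ids as column names")
  if (anyDuplicated(colnames(dosages)))
    stop_twinewas("duplicate sample id in genotype matrix")
  rng <- range(dosages, na.rm = TRUE)
  if (rng[1] < 0 || rng[2] > 2)
    stop_twinewas("dosages must lie in [0,2]")
  p <- rowMeans(dosages, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  keep <- maf >= maf_min
  map[, maf := maf]
  structure(list(dosages = dosages[keep, , drop = FALSE],
                 map = map[keep],
                 n_dropped_maf = sum(!keep)),
            class = "geno_set")
}

#' @export
print.geno_set <- function(x, ...) {
  cat("geno_set:", nrow(x$dosages), "SNPs x", ncol(x$dosages), "samples (",
      x$n_dropped_maf, "dropped at MAF filter)\n")
  invisible(x)
}

#' The sixteen age-related phenotypes and their cohort-level parameters
#'
#' One row per trait: the linear age slope (trait units per year), its
#' reported standard error, the fraction of individuals with data, a typical
#' residual standard deviation and intercept used by the synthetic generator,
#' and flags for which analyses the trait enters (genome-wide association
#' scans exclude the four parental longevity/reproduction traits). Lung
#' function is carried as two traits (FEV1, FVC) sharing one parameter row.
#'
#' @return data.table with columns `trait`, `age_slope`, `age_slope_se`,
#'   `data_pct`, `resid_sd`, `intercept`, `gwas`, `mz_dmr`.
#' @export
phenotype_parameters <- function() {
  dt <- data.table::data.table(
    trait = c("Telomere", "SBP", "DBP", "FEV1", "FVC", "Grip", "BMD",
              "DHEAS", "Cholesterol", "HDL", "LDL", "Albumin", "Creatinine",
              "MLONG", "PLONG", "MREPROD", "PREPROD"),
    age_slope = c(-0.030, 0.663, -0.019, -0.028, -0.028, -0.451, -0.005,
                  -0.023, 0.052, 0.016, 0.018, -0.102, 0.120,
                  2.3e-6, 4.1e-6, 6.3e-6, 6.2e-6),
    age_slope_se = c(0.009, 0.146, 0.098, 0.006, 0.006, 0.081, 0.001,
                     0.007, 0.012, 0.012, 0.011, 0.030, 0.102,
                     2.8e-4, 1.7e-4, 5.3e-4, 4.5e-4),
    data_pct = c(62.2, 100, 100, 97.7, 97.7, 64.0, 86.7, 99.4, 97.1, 97.1,
                 94.8, 91.9, 86.0, 73.8, 73.3, 80.8, 82.0),
    resid_sd = c(0.65, 14, 9, 0.45, 0.55, 6, 0.11, 1.6, 1.0, 0.38, 0.92,
                 2.8, 11, 9, 9, 4.5, 5),
    intercept = c(8.5, 85, 80, 3.7, 4.6, 55, 1.2, 6.5, 2.7, 0.8, 2.2, 50, 63,
                  78, 74, 27, 30),
    gwas = c(TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE,
             TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE),
    mz_dmr = c(FALSE, TRUE, TRUE, TRUE, TRUE, FALSE, TRUE, TRUE, TRUE, TRUE,
               TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE)
  )
  dt
}

#' Construct a phenotype table
#'
#' @param values numeric matrix, traits in rows, individuals in columns;
#'   row names are trait names, `NA` marks missing measurements.
#' @return object of class `pheno_table` with fields `values` and `traits`.
#' @export
phenotype_table <- function(values) {
  values <- as.matrix(values)
  if (is.null(rownames(values))) stop_twinewas("trait names required as row names")
  if (is.null(colnames(values)))
    stop_twinewas("phenotype values must carry sample ids as column names")
  if (anyDuplicated(colnames(values)))
    stop_twinewas("duplicate sample id in phenotype table")
  structure(list(values = values, traits = rownames(values)),
            class = "pheno_table")
}

#' @export
print.pheno_table <- function(x, ...) {
  cat("pheno_table:", nrow(x$values), "traits x", ncol(x$values), "samples\n")
  invisible(x)
}
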