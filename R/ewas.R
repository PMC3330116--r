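# Epigenome-wide association scans for chronological age (a-DMRs) and
# age-related phenotypes (ap-DMRs), with a twin-structure-preserving
# permutation FDR, and blood-cell-count checks at discovered DMRs.

#' Epigenome-wide association scan
#'
#' Per probe, fits the twin LMM of methylation on the trait (chronological
#' age or a phenotype) with chip and chip-position fixed effects and
#' family/zygosity random intercepts, and reports the likelihood-ratio
#' p-value against the trait-free null. Raw beta values are the default
#' response scale; `raw_scale = FALSE` applies the per-probe inverse-normal
#' transform instead.
#'
#' @param m a `meth_set`.
#' @param cohort a `twin_cohort`.
#' @param trait `"age"` or a row name of `phenos`.
#' @param phenos a `pheno_table` (required unless `trait == "age"`).
#' @param adjust_age include age as a fixed covariate in both full and null
#'   models (ap-DMR age correction; ignored for `trait == "age"`).
#' @param raw_scale regress raw betas (default `TRUE`).
#' @param covariates fixed-effect cohort columns (default chip, position).
#' @return data.table with `probe_id`, `trait`, `beta`, `se`, `p`,
#'   `direction` (`hyper`/`hypo`), `age_adjusted`, `converged`; attribute
#'   `n_used`.
#' @export
scan_dmrs <- function(m, cohort, trait, phenos = NULL, adjust_age = FALSE,
                      raw_scale = TRUE,
                      covariates = c("chip_id", "chip_position")) {
  stopifnot(inherits(m, "meth_set"))
  ids <- intersect(cohort$individual_id, colnames(m$betas))
  co <- as.data.table(cohort)
  if (identical(trait, "age")) {
    tv <- co$age[match(ids, co$individual_id)]
    adjust_age <- FALSE
  } else {
    if (is.null(phenos)) stop_twinewas("phenotype table required for trait ", trait)
    if (!trait %in% rownames(phenos$values))
      stop_twinewas("unknown trait: ", trait)
    tv <- phenos$values[trait, ids]
  }
  keep <- !is.na(tv)
  ids <- ids[keep]
  tv <- tv[keep]
  if (length(unique(tv)) < 2L)
    stop_twinewas("trait '", trait, "' is constant in the analysis sample")
  Y <- m$betas[, ids, drop = FALSE]
  if (!raw_scale) {
    Y <- t(apply(Y, 1, inverse_normal_transform))
    colnames(Y) <- ids
  }
  G <- matrix(tv, ncol = 1, dimnames = list(ids, trait))
  extra <- if (adjust_age)
    list(age = co$age[match(ids, co$individual_id)]) else NULL
  tests <- data.table::data.table(iy = seq_len(nrow(Y)), ig = 1L)
  res <- twin_assoc_scan(Y, cohort, ids, G, tests, covariates = covariates,
                         extra = extra)
  out <- data.table::data.table(
    probe_id = rownames(m$betas)[res$iy],
    trait = trait,
    beta = res$beta, se = res$se, p = res$p,
    direction = ifelse(res$beta >= 0, "hyper", "hypo"),
    age_adjusted = adjust_age,
    converged = res$converged)
  data.table::setattr(out, "n_used", length(ids))
  out[]
}

#' Twin-structure-preserving permutation FDR for EWAS scans
#'
#' Per replicate, methylation profiles are permuted as family blocks:
#' co-twins' columns move together and are reassigned among families of the
#' same size and zygosity (size-1 units pool into one stratum), so twin
#' covariance and co-methylation are preserved while the methylation-trait
#' pairing is broken. Traits, covariates and missingness stay with the
#' individuals.
#'
#' @param observed result of [scan_dmrs()].
#' @param m,cohort,trait,phenos,... as for [scan_dmrs()].
#' @param n_perm permutation replicates (default 100).
#' @param seed RNG seed.
#' @param alpha nominal FDR (default 0.05).
#' @return list as from [permutation_fdr()] plus `observed` with
#'   `fdr_significant` flags and a `summary` list.
#' @export
permutation_fdr_ewas <- function(observed, m, cohort, trait, phenos = NULL,
                                 n_perm = 100L, seed = 1L, alpha = 0.05, ...) {
  if (n_perm < 1L) stop_twinewas("n_perm must be at least 1")
  ids0 <- intersect(cohort$individual_id, colnames(m$betas))
  perm_p <- with_seed(seed, lapply(seq_len(n_perm), function(r) {
    perm <- family_permutation(cohort, ids0)
    mp <- m
    mp$betas <- m$betas[, ids0[perm], drop = FALSE]
    colnames(mp$betas) <- ids0
    scan_dmrs(mp, cohort, trait, phenos, ...)$p
  }))
  fdr <- permutation_fdr(observed$p, perm_p, alpha = alpha)
  observed <- data.table::copy(observed)
  thr <- fdr$threshold
  observed[, fdr_significant := !is.na(thr) & p <= thr]
  fdr$observed <- observed[]
  fdr$summary <- list(
    trait = observed$trait[1],
    n_probes = nrow(observed),
    n_significant = observed[, sum(fdr_significant)],
    threshold = as.numeric(thr),
    n_perm = n_perm)
  fdr
}

#' Blood-cell-count associations at discovered DMRs
#'
#' For each DMR probe and each white-blood-cell subtype, fits the twin LMM
#' of methylation on the cell count. Significance is reported against a
#' Bonferroni-corrected level of 0.05 over the number of DMR probes tested
#' (the per-test nominal threshold, also printed to one significant figure).
#'
#' @param dmr_probes character vector of DMR probe ids.
#' @param m a `meth_set`.
#' @param cohort a `twin_cohort`.
#' @param wbc matrix of cell counts (cell types x individuals); expected rows
#'   `neutrophils`, `eosinophils`, `monocytes`, `lymphocytes` (missing types
#'   are skipped with a warning).
#' @param alpha family-wise level (default 0.05).
#' @return data.table with `probe_id`, `cell_type`, `beta`, `se`, `p`,
#'   `significant`; attributes `bonferroni_nominal_p` (exact) and
#'   `bonferroni_nominal_p_1sf` (one significant figure). Empty input gives
#'   an empty table.
#' @export
wbc_association <- function(dmr_probes, m, cohort, wbc, alpha = 0.05) {
  expected <- c("neutrophils", "eosinophils", "monocytes", "lymphocytes")
  have <- intersect(expected, rownames(wbc))
  if (length(have) < length(expected))
    warning("missing cell type(s): ",
            paste(setdiff(expected, have), collapse = ", "), call. = FALSE)
  dmr_probes <- intersect(dmr_probes, rownames(m$betas))
  nominal <- bonferroni_nominal(length(dmr_probes), alpha)
  if (!length(dmr_probes) || !length(have)) {
    out <- data.table::data.table(probe_id = character(), cell_type = character(),
                                  beta = numeric(), se = numeric(), p = numeric(),
                                  significant = logical())
    data.table::setattr(out, "bonferroni_nominal_p", nominal)
    return(out)
  }
  ids <- Reduce(intersect, list(cohort$individual_id, colnames(m$betas),
                                colnames(wbc)))
  Y <- m$betas[dmr_probes, ids, drop = FALSE]
  res <- data.table::rbindlist(lapply(have, function(ct) {
    G <- matrix(wbc[ct, ids], ncol = 1, dimnames = list(ids, ct))
    tests <- data.table::data.table(iy = seq_along(dmr_probes), ig = 1L)
    r <- twin_assoc_scan(Y, cohort, ids, G, tests)
    data.table::data.table(probe_id = dmr_probes[r$iy], cell_type = ct,
                           beta = r$beta, se = r$se, p = r$p)
  }))
  res[, significant := p <= nominal]
  data.table::setattr(res, "bonferroni_nominal_p", nominal)
  data.table::setattr(res, "bonferroni_nominal_p_1sf", signif(nominal, 1))
  res[]
}

#' Bonferroni nominal p-value threshold
#'
#' @param n_tests number of probes tested.
#' @param alpha family-wise level (default 0.05).
#' @return `alpha / n_tests` (NA for zero tests).
#' @export
bonferroni_nominal <- function(n_tests, alpha = 0.05) {
  if (n_tests < 1L) return(NA_real_)
  alpha / n_tests
}
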