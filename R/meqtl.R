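# Cis methylation-QTL mapping with permutation FDR.

#' Enumerate cis probe-SNP pairs
#'
#' All (probe, SNP) pairs on the same chromosome with
#' `|pos_SNP - pos_CpG| <= window` (1-based point coordinates, boundary
#' inclusive).
#'
#' @param annotation probe annotation table (`probe_id`, `chrom`, `pos`).
#' @param genos a `geno_set`.
#' @param window cis window in bp (default 100000; 50000 is a common
#'   alternative preset).
#' @return data.table with `probe_id`, `snp_id`, `distance` (SNP - CpG, bp);
#'   attribute `n_probes_no_cis` counts probes without any cis SNP.
#' @export
cis_pairs <- function(annotation, genos, window = 100000) {
  if (window <= 0) stop_twinewas("cis window must be positive")
  ann <- as.data.table(annotation)[, .(probe_id, chrom, cpg_pos = pos)]
  snp <- as.data.table(genos$map)[, .(snp_id, chrom, snp_pos = pos)]
  setkey(snp, chrom)
  pairs <- snp[ann, on = "chrom", allow.cartesian = TRUE]
  pairs <- pairs[!is.na(snp_id) & abs(snp_pos - cpg_pos) <= window]
  out <- pairs[, .(probe_id, snp_id, distance = snp_pos - cpg_pos)]
  data.table::setattr(out, "n_probes_no_cis",
                      sum(!ann$probe_id %in% out$probe_id))
  out[]
}

#' Cis-meQTL association scan
#'
#' Per pair, regresses inverse-normal-transformed methylation on additive
#' SNP dosage with chip and chip-position fixed effects and family/zygosity
#' random intercepts; p-values from the likelihood-ratio test against the
#' genotype-free null. The best SNP per probe (smallest p, ties broken by
#' smallest |distance| then lexicographic SNP id) is flagged.
#'
#' @param pairs result of [cis_pairs()].
#' @param m a `meth_set` (raw betas; the scan applies the inverse-normal
#'   transform per probe).
#' @param genos a `geno_set`.
#' @param cohort a `twin_cohort`.
#' @param covariates fixed-effect cohort columns (default chip, position).
#' @param normalize apply [inverse_normal_transform()] per probe (default
#'   `TRUE`).
#' @return data.table with `probe_id`, `snp_id`, `distance`, `beta`, `se`,
#'   `p`, `is_best_per_probe`, `converged`; attributes `n_skipped_monomorphic`
#'   and `n_used`.
#' @export
scan_meqtls <- function(pairs, m, genos, cohort,
                        covariates = c("chip_id", "chip_position"),
                        normalize = TRUE) {
  ids <- Reduce(intersect, list(cohort$individual_id, colnames(m$betas),
                                colnames(genos$dosages)))
  if (length(ids) < 10L) stop_twinewas("too few samples with both data types")
  probes <- unique(pairs$probe_id)
  snps <- unique(pairs$snp_id)
  Y <- m$betas[probes, ids, drop = FALSE]
  if (normalize) {
    Y <- t(apply(Y, 1, inverse_normal_transform))
    degen <- rowSums(!is.na(Y)) == 0L
    if (any(degen)) {
      message(sum(degen), " constant probe(s) skipped by the normal transform")
      probes <- probes[!degen]
      Y <- Y[!degen, , drop = FALSE]
    }
  }
  colnames(Y) <- ids
  G <- t(genos$dosages[snps, ids, drop = FALSE])

  mono <- apply(G, 2, function(x) var(x) == 0)
  n_skip <- sum(mono)
  keep_snps <- colnames(G)[!mono]
  tests <- as.data.table(pairs)[snp_id %in% keep_snps & probe_id %in% probes]
  tests[, iy := match(probe_id, probes)]
  tests[, ig := match(snp_id, keep_snps)]
  G <- G[, keep_snps, drop = FALSE]

  res <- twin_assoc_scan(Y, cohort, ids, G, tests[, .(iy, ig)],
                         covariates = covariates)
  out <- data.table::data.table(
    probe_id = probes[res$iy],
    snp_id = keep_snps[res$ig],
    beta = res$beta, se = res$se, p = res$p, converged = res$converged)
  out <- merge(out, as.data.table(pairs), by = c("probe_id", "snp_id"),
               sort = FALSE)
  out[, adist := abs(distance)]
  data.table::setorder(out, probe_id, p, adist, snp_id)
  out[, is_best_per_probe := seq_len(.N) == 1L, by = probe_id]
  out[, adist := NULL]
  data.table::setattr(out, "n_skipped_monomorphic", n_skip)
  data.table::setattr(out, "n_used", length(ids))
  out[]
}

#' Permutation FDR for the cis-meQTL scan
#'
#' Per replicate, whole methylation columns are shuffled against the
#' genotype columns (one sample-label permutation per replicate, preserving
#' co-methylation across probes; genotype-methylation pairing is what is
#' broken, so twin structure is not preserved for this null), the scan is
#' re-run on the same pair list, and the best SNP per probe is collected.
#'
#' @param observed result of [scan_meqtls()].
#' @param pairs,m,genos,cohort as for [scan_meqtls()].
#' @param n_perm number of replicates (default 10).
#' @param seed RNG seed.
#' @param alpha nominal FDR (default 0.05).
#' @param ... passed to [scan_meqtls()].
#' @return list as from [permutation_fdr()] plus `observed` with an added
#'   `fdr_significant` flag (best-SNP rows at or below the threshold) and
#'   `summary` (n probes tested / significant, threshold).
#' @export
permutation_fdr_meqtl <- function(observed, pairs, m, genos, cohort,
                                  n_perm = 10L, seed = 1L, alpha = 0.05, ...) {
  if (n_perm < 1L) stop_twinewas("n_perm must be at least 1")
  ids <- Reduce(intersect, list(cohort$individual_id, colnames(m$betas),
                                colnames(genos$dosages)))
  perm_best <- with_seed(seed, lapply(seq_len(n_perm), function(r) {
    mp <- m
    shuffled <- sample(ids)
    mp$betas <- m$betas[, shuffled, drop = FALSE]
    colnames(mp$betas) <- ids
    sc <- scan_meqtls(pairs, mp, genos, cohort, ...)
    sc[is_best_per_probe == TRUE, p]
  }))
  obs_best <- observed[is_best_per_probe == TRUE, p]
  fdr <- permutation_fdr(obs_best, perm_best, alpha = alpha)
  observed <- data.table::copy(observed)
  thr <- fdr$threshold
  observed[, fdr_significant := is_best_per_probe & !is.na(thr) & p <= thr]
  sig_probes <- observed[fdr_significant == TRUE, unique(probe_id)]
  fdr$observed <- observed[]
  fdr$summary <- list(
    n_probes_tested = length(unique(observed$probe_id)),
    n_probes_significant = length(sig_probes),
    percent_significant = 100 * length(sig_probes) /
      length(unique(observed$probe_id)),
    threshold = as.numeric(thr),
    n_perm = n_perm)
  fdr
}

#' Percentage of tested probes with cis-meQTLs
#'
#' The headline summary of a cis-meQTL scan: `100 * n_significant /
#' n_tested`.
#'
#' @param n_significant probes with a significant cis-meQTL.
#' @param n_tested probes tested.
#' @return percentage (numeric scalar).
#' @export
meqtl_probe_percent <- function(n_significant, n_tested) {
  100 * n_significant / n_tested
}
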