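# Genotype-methylation-phenotype mediation overlap: phenotype GWAS under the
# twin LMM, three-way intersection of cis-meQTL SNPs, GWAS-suggestive SNPs
# and ap-DMR-suggestive probes per phenotype, and a methylation-permutation
# null for the overlap rate.

#' Genome-wide association scan for a phenotype
#'
#' Per SNP, the twin LMM of the trait on additive dosage with chip and
#' chip-position fixed effects and family/zygosity random intercepts;
#' likelihood-ratio p-values. Only the quantitative GWAS-eligible traits are
#' accepted (parental longevity and age-at-reproduction traits are excluded).
#'
#' @param phenos a `pheno_table`.
#' @param genos a `geno_set`.
#' @param cohort a `twin_cohort`.
#' @param trait trait name.
#' @param p_suggestive suggestive threshold recorded in the output flag
#'   (default 0.001).
#' @return data.table with `snp_id`, `trait`, `beta`, `se`, `p`,
#'   `suggestive`; attribute `n_skipped_monomorphic`.
#' @export
gwas_scan <- function(phenos, genos, cohort, trait, p_suggestive = 0.001) {
  if (!trait %in% rownames(phenos$values))
    stop_twinewas("unknown trait: ", trait)
  if (trait %in% phenotype_parameters()[gwas == FALSE, trait]) {
    warning("trait '", trait, "' is not GWAS-eligible (excluded trait class)",
            call. = FALSE)
    return(data.table::data.table(snp_id = character(), trait = character(),
                                  beta = numeric(), se = numeric(),
                                  p = numeric(), suggestive = logical()))
  }
  ids <- Reduce(intersect, list(cohort$individual_id, colnames(phenos$values),
                                colnames(genos$dosages)))
  tv <- phenos$values[trait, ids]
  ids <- ids[!is.na(tv)]
  tv <- tv[!is.na(tv)]
  G <- t(genos$dosages[, ids, drop = FALSE])
  mono <- apply(G, 2, function(x) var(x) == 0)
  G <- G[, !mono, drop = FALSE]
  Y <- matrix(tv, nrow = 1, dimnames = list(trait, ids))
  tests <- data.table::data.table(iy = 1L, ig = seq_len(ncol(G)))
  res <- twin_assoc_scan(Y, cohort, ids, G, tests)
  out <- data.table::data.table(
    snp_id = colnames(G)[res$ig], trait = trait,
    beta = res$beta, se = res$se, p = res$p)
  out[, suggestive := p <= p_suggestive]
  data.table::setattr(out, "n_skipped_monomorphic", sum(mono))
  out[]
}

#' Three-way genotype-methylation-phenotype overlap
#'
#' Given the significant cis-meQTL pair list, per-trait GWAS tables, and
#' per-trait ap-DMR scans, a probe is a three-way hit when one of its
#' cis-meQTL SNPs is GWAS-suggestive for a trait for which the probe is also
#' ap-DMR-suggestive. Counts shrink monotonically through the stages.
#'
#' @param meqtl_pairs data.table of significant meQTL pairs (`probe_id`,
#'   `snp_id`).
#' @param gwas named list (by trait) of GWAS tables (`snp_id`, `p`).
#' @param apdmr named list (by trait) of ap-DMR tables (`probe_id`, `p`).
#' @param p_gwas suggestive GWAS threshold (default 0.001).
#' @param p_apdmr suggestive ap-DMR threshold (default 0.01).
#' @return `overlap_report` list: stage counts, per-trait breakdown,
#'   `percent_threeway`, and the three-way probe/SNP tables.
#' @export
threeway_overlap <- function(meqtl_pairs, gwas, apdmr,
                             p_gwas = 0.001, p_apdmr = 0.01) {
  traits <- names(gwas)
  if (!setequal(traits, names(apdmr)))
    stop_twinewas("trait names differ between GWAS and ap-DMR tables")
  mq <- as.data.table(meqtl_pairs)[, .(probe_id, snp_id)]
  n_meqtl_probes <- uniqueN(mq$probe_id)
  n_meqtl_snps <- uniqueN(mq$snp_id)

  sugg_snps <- data.table::rbindlist(lapply(traits, function(tr) {
    g <- as.data.table(gwas[[tr]])
    g[p <= p_gwas, .(snp_id, trait = tr)]
  }))
  stage2 <- merge(mq, sugg_snps, by = "snp_id", allow.cartesian = TRUE)
  n_snps_also_gwas <- uniqueN(stage2$snp_id)
  n_probes_of_those <- uniqueN(stage2$probe_id)

  sugg_probes <- data.table::rbindlist(lapply(traits, function(tr) {
    a <- as.data.table(apdmr[[tr]])
    a[p <= p_apdmr, .(probe_id, trait = tr)]
  }))
  stage3 <- merge(stage2, sugg_probes, by = c("probe_id", "trait"))
  per_trait <- stage3[, .(n_probes = uniqueN(probe_id),
                          n_snps = uniqueN(snp_id)), by = trait]
  rep <- overlap_report(
    n_meqtl_probes = n_meqtl_probes, n_meqtl_snps = n_meqtl_snps,
    n_snps_also_gwas = n_snps_also_gwas,
    n_probes_of_those = n_probes_of_those,
    n_probes_threeway = uniqueN(stage3$probe_id),
    n_snps_threeway = uniqueN(stage3$snp_id))
  rep$per_trait <- per_trait[]
  rep$threeway <- unique(stage3[, .(probe_id, snp_id, trait)])
  rep
}

#' Assemble an overlap report from stage counts
#'
#' Computes the headline overlap percentage
#' `100 * n_probes_threeway / n_meqtl_probes` and validates the monotone
#' shrinkage of the stages.
#'
#' @param n_meqtl_probes,n_meqtl_snps probes/SNPs in the significant
#'   cis-meQTL set.
#' @param n_snps_also_gwas meQTL SNPs that are also GWAS-suggestive.
#' @param n_probes_of_those probes owning such SNPs.
#' @param n_probes_threeway,n_snps_threeway full three-way hits.
#' @return `overlap_report` list including `percent_threeway`.
#' @export
overlap_report <- function(n_meqtl_probes, n_meqtl_snps, n_snps_also_gwas,
                           n_probes_of_those, n_probes_threeway,
                           n_snps_threeway) {
  if (n_probes_threeway > n_probes_of_those ||
      n_probes_of_those > n_meqtl_probes)
    stop_twinewas("overlap stage counts must shrink monotonically")
  structure(list(
    n_meqtl_probes = n_meqtl_probes, n_meqtl_snps = n_meqtl_snps,
    n_snps_also_gwas = n_snps_also_gwas,
    n_probes_of_those = n_probes_of_those,
    n_probes_threeway = n_probes_threeway,
    n_snps_threeway = n_snps_threeway,
    percent_threeway = 100 * n_probes_threeway / n_meqtl_probes),
    class = "overlap_report")
}

#' @export
print.overlap_report <- function(x, ...) {
  cat("meQTL probes:", x$n_meqtl_probes, "with", x$n_meqtl_snps, "SNPs\n")
  cat("SNPs also GWAS-suggestive:", x$n_snps_also_gwas, "(probes:",
      x$n_probes_of_those, ")\n")
  cat("three-way probes:", x$n_probes_threeway, "(SNPs:", x$n_snps_threeway,
      ") =", format(x$percent_threeway, digits = 3), "%\n")
  invisible(x)
}

#' Permutation null for the three-way overlap
#'
#' Per replicate, only the methylation data are permuted (family-preserving
#' block permutation, keeping twin structure and co-methylation), the cis
#' scan is re-run, the top `n_top` probes by best cis p-value are selected
#' (ties broken by probe id), their meQTL SNPs are taken at the observed
#' significance threshold (falling back to the best cis SNP), ap-DMR scans
#' are re-run on the permuted methylation, and the three-way overlap is
#' recomputed against the observed GWAS tables.
#'
#' @param m a `meth_set`.
#' @param genos a `geno_set`.
#' @param phenos a `pheno_table`.
#' @param cohort a `twin_cohort`.
#' @param pairs cis pair list from [cis_pairs()].
#' @param gwas named list of observed GWAS tables.
#' @param n_top number of top probes to carry (the observed significant
#'   meQTL probe count).
#' @param meqtl_threshold observed meQTL significance threshold (p-value).
#' @param n_perm replicates (default 2).
#' @param seed RNG seed.
#' @param p_gwas,p_apdmr suggestive thresholds.
#' @param apdmr_adjust_age age-correct the permuted ap-DMR scans.
#' @return list with `mean_probes`, `mean_percent`, `per_replicate`
#'   (data.table).
#' @export
permuted_overlap_null <- function(m, genos, phenos, cohort, pairs, gwas,
                                  n_top, meqtl_threshold, n_perm = 2L,
                                  seed = 1L, p_gwas = 0.001, p_apdmr = 0.01,
                                  apdmr_adjust_age = FALSE) {
  if (n_perm < 1L) stop_twinewas("n_perm must be at least 1")
  traits <- names(gwas)
  ids0 <- intersect(cohort$individual_id, colnames(m$betas))
  reps <- with_seed(seed, lapply(seq_len(n_perm), function(r) {
    perm <- family_permutation(cohort, ids0)
    mp <- m
    mp$betas <- m$betas[, ids0[perm], drop = FALSE]
    colnames(mp$betas) <- ids0
    sc <- scan_meqtls(pairs, mp, genos, cohort)
    best <- sc[is_best_per_probe == TRUE][order(p, probe_id)]
    top <- head(best$probe_id, n_top)
    topsnps <- sc[probe_id %in% top & p <= meqtl_threshold,
                  .(probe_id, snp_id)]
    fallback <- sc[is_best_per_probe == TRUE & probe_id %in%
                     setdiff(top, topsnps$probe_id), .(probe_id, snp_id)]
    mq <- rbind(topsnps, fallback)
    apdmr <- lapply(traits, function(tr)
      scan_dmrs(mp, cohort, tr, phenos, adjust_age = apdmr_adjust_age))
    names(apdmr) <- traits
    ov <- threeway_overlap(mq, gwas, apdmr, p_gwas = p_gwas,
                           p_apdmr = p_apdmr)
    data.table::data.table(replicate = r,
                           n_probes_threeway = ov$n_probes_threeway,
                           percent = 100 * ov$n_probes_threeway /
                             max(length(top), 1L))
  }))
  per_rep <- data.table::rbindlist(reps)
  list(mean_probes = mean(per_rep$n_probes_threeway),
       mean_percent = mean(per_rep$percent),
       per_replicate = per_rep[])
}
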