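test_that("co-methylation: identical probes correlate fully; block noise decays", {
  bun <- default_bundle()
  m <- bun$meth
  # plant a duplicated probe pair 10 bp apart on an otherwise empty contig
  b <- rbind(m$betas, dupA = m$betas[1, ], dupB = m$betas[1, ])
  ann <- rbind(m$annotation,
               data.table::data.table(
                 probe_id = c("dupA", "dupB"), chrom = "chr99",
                 pos = c(100L, 110L), nearest_gene = "dupgene",
                 tss_distance = 0L, cpg_island = 0L, unique_mapping = 1L,
                 autosomal = TRUE))
  rownames(b) <- ann$probe_id
  m2 <- methylation_matrix(b, ann)
  prof <- comethylation_profile(m2, probe_subset = c("dupA", "dupB"),
                                max_dist = 400)
  expect_equal(prof[bin_low == 0, n_pairs], 1L)
  expect_equal(prof[bin_low == 0, mean_rho], 1.0)

  full <- comethylation_profile(m)
  first3 <- full[bin_high <= 2000, mean_rho]
  expect_true(all(diff(first3) < 0))
  expect_false(any(is.nan(full$mean_rho)))
  expect_true(all(full[n_pairs == 0, is.na(mean_rho)]))
})

test_that("independent probes show near-zero co-methylation everywhere", {
  cfg <- sim_config(n_probes = 300, frac_heritable = 0, frac_meqtl = 0,
                    frac_age = 0, n_mediated = 0, n_wbc_probes = 0,
                    cometh_frac = 0, fam_env = 0, chip_sd = 0, seed = 61)
  co <- simulate_cohort(cfg)
  m <- simulate_methylation(cfg, co)
  prof <- comethylation_profile(m)
  expect_lt(max(abs(prof[n_pairs > 0, mean_rho])), 0.12)
})

test_that("unrelated-only co-methylation stays close to the all-individual profile", {
  bun <- default_bundle()
  all_prof <- comethylation_profile(bun$meth)
  unrel <- comethylation_profile(bun$meth, cohort = bun$cohort,
                                 unrelated_only = TRUE)
  both <- merge(all_prof, unrel, by = c("bin_low", "bin_high"))
  both <- both[n_pairs.x > 10]
  expect_lt(max(abs(both$mean_rho.x - both$mean_rho.y)), 0.05)
})

test_that("enrichment: identity on self, exact arithmetic, planted island bias", {
  bun <- default_bundle()
  ann <- bun$meth$annotation
  isl <- ann[cpg_island == 1]
  track <- GenomicRanges::reduce(GenomicRanges::GRanges(
    isl$chrom, IRanges::IRanges(isl$pos - 25L, isl$pos + 25L)))
  tracks <- list(islands = track)

  self <- enrichment_bootstrap(ann$probe_id, ann$probe_id, ann, tracks,
                               n_boot = 100, seed = 1)
  expect_equal(self$enrichment, 1.0, tolerance = 1e-12)
  expect_true(self$ci_low <= 1 && 1 <= self$ci_high)

  # array-style arithmetic: background proportion 11299/26690, 300/490 in DMRs
  expect_equal((300 / 490) / (11299 / 26690), 1.44635, tolerance = 1e-4)

  age_probes <- bun$truth[class == "age", probe_id]
  en <- enrichment_bootstrap(age_probes, ann$probe_id, ann, tracks,
                             n_boot = 400, seed = 2)
  expect_gt(en$ci_low, 1)           # planted island-biased class

  # empty background category flags undefined, no NaN
  far <- GenomicRanges::GRanges("chrY", IRanges::IRanges(1, 10))
  en0 <- enrichment_bootstrap(age_probes, ann$probe_id, ann,
                              list(off = far), n_boot = 10, seed = 3)
  expect_true(en0$undefined)
  expect_true(is.na(en0$enrichment))
})

test_that("methylation-expression correlation: exact inverse and independence", {
  bun <- default_bundle()
  ann <- bun$meth$annotation
  elig <- ann[abs(tss_distance) <= 2000]
  genes <- unique(elig$nearest_gene)
  mm <- t(vapply(genes, function(g)
    colMeans(bun$meth$betas[elig[nearest_gene == g, probe_id], , drop = FALSE]),
    numeric(ncol(bun$meth$betas))))
  expr_inv <- -mm
  rownames(expr_inv) <- genes
  mec <- methylation_expression_correlation(bun$meth, expr_inv)
  expect_true(all(abs(mec$rho + 1) < 1e-12))
  expect_lt(attr(mec, "wilcoxon_p"), 1e-10)

  set.seed(62)
  expr_ind <- matrix(rnorm(length(genes) * ncol(mm)), length(genes),
                     dimnames = list(genes, colnames(mm)))
  mec0 <- methylation_expression_correlation(bun$meth, expr_ind)
  expect_lt(abs(attr(mec0, "mean_rho")), 0.05)
})

test_that("replication: self-copy fully replicates; sign-randomized truth ~50%", {
  bun <- default_bundle()
  dmr <- scan_dmrs(bun$meth, bun$cohort, "age")
  disc <- dmr[p < 1e-3, .(probe_id, direction)]
  rep_self <- replication_check(disc, bun$meth, bun$cohort, mode = "lmm")
  expect_equal(rep_self$summary$frac_same_direction, 1.0)

  expect_equal(replication_percent(184, 490), 100 * 184 / 490)
  expect_equal(round(replication_percent(184, 490)), 38)

  set.seed(63)
  flipped <- data.table::copy(disc)
  flipped$direction <- sample(c("hyper", "hypo"), nrow(disc), TRUE)
  rep_flip <- replication_check(flipped, bun$meth, bun$cohort, mode = "lmm")
  expect_lt(abs(rep_flip$summary$frac_same_direction - 0.5), 0.25)

  # probes absent from the replication panel stay in the denominator
  m2 <- bun$meth
  keep <- setdiff(rownames(m2$betas), disc$probe_id[1])
  m2$betas <- m2$betas[keep, ]
  m2$annotation <- m2$annotation[probe_id %in% keep]
  rep_miss <- replication_check(disc, m2, bun$cohort, mode = "lmm")
  expect_equal(rep_miss$summary$n_discovery, nrow(disc))
  expect_equal(rep_miss$summary$n_tested, nrow(disc) - 1L)
})

test_that("replication in an independent younger cohort preserves direction", {
  cfg <- sim_config(n_probes = 300, seed = 64)
  bun <- simulate_dataset(cfg, expression = FALSE)
  dmr <- scan_dmrs(bun$meth, bun$cohort, "age")
  tru_age <- bun$truth[class == "age", probe_id]
  disc <- dmr[probe_id %in% tru_age & p < 1e-3, .(probe_id, direction)]
  skip_if(nrow(disc) < 10)

  # second cohort: same probe truth, fresh individuals, ages 20-61, mixed sex
  cfg2 <- sim_config(n_probes = 300, n_mz_pairs = 22, n_dz_pairs = 0,
                     n_singletons = 0, n_mz_split = 0, n_dz_split = 0,
                     frac_meqtl = 0, n_mediated = 0,
                     age_range = c(20, 61), seed = 65)
  co2 <- simulate_cohort(cfg2)
  probes <- simulate_probes(cfg)            # discovery truth
  m2 <- simulate_methylation(cfg2, co2, probes = probes)
  co2$sex <- rep_len(c("F", "M"), nrow(co2))
  rep_lmm <- replication_check(disc, m2, twin_cohort(co2), mode = "lmm")
  expect_gte(rep_lmm$summary$frac_same_direction, 0.75)
  rep_sp <- replication_check(disc, m2, twin_cohort(co2),
                              mode = "unrelated_spearman")
  expect_gte(rep_sp$summary$frac_same_direction, 0.6)
})
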