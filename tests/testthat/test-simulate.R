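test_that("cohort generator reproduces the study design and is deterministic", {
  cfg <- sim_config(seed = 1)
  co <- simulate_cohort(cfg)
  expect_equal(nrow(co), 172)
  fam <- data.table::as.data.table(co)[, .N, by = family_id]
  expect_equal(sum(fam$N == 2), 76)
  expect_equal(sum(fam$N == 1), 20)
  expect_true(all(co$age >= 32 & co$age <= 80))
  # co-twins share age and family
  dt <- data.table::as.data.table(co)[zygosity != "singleton"]
  expect_true(all(dt[, data.table::uniqueN(age) == 1L, by = family_id]$V1))
  # same-batch intact pairs follow the split settings
  same_batch <- dt[, .(intact = data.table::uniqueN(batch_id) == 1L),
                   by = .(family_id, zygosity)]
  expect_equal(same_batch[zygosity == "MZ", sum(intact)], 33 - 12)
  expect_equal(same_batch[zygosity == "DZ", sum(intact)], 43 - 12)

  co2 <- simulate_cohort(cfg)
  expect_identical(co, co2)

  tiny <- simulate_cohort(sim_config(n_mz_pairs = 1, n_dz_pairs = 0,
                                     n_singletons = 0, n_mz_split = 0,
                                     n_dz_split = 0, seed = 2))
  expect_equal(nrow(tiny), 2)
  expect_equal(unique(tiny$zygosity), "MZ")
  expect_equal(data.table::uniqueN(tiny$family_id), 1)
  expect_error(sim_config(n_mz_pairs = 0, n_dz_pairs = 0, n_singletons = 0),
               "at least one individual")
})

test_that("genotypes respect twin sharing and Hardy-Weinberg expectations", {
  cfg <- sim_config(n_mz_pairs = 5, n_dz_pairs = 2000, n_singletons = 200,
                    n_snps = 30, n_probes = 50, frac_meqtl = 0,
                    n_mediated = 0, maf_range = c(0.5, 0.5), seed = 3)
  co <- simulate_cohort(cfg)
  g <- simulate_genotypes(cfg, co)
  dt <- data.table::as.data.table(co)
  # MZ co-twins: identical dosage columns
  for (f in unique(dt[zygosity == "MZ", family_id])) {
    ids <- dt[family_id == f, individual_id]
    expect_identical(g$dosages[, ids[1]], g$dosages[, ids[2]])
  }
  # DZ co-twins: dosage correlation near 1/2 (law of sibling sharing)
  dz <- dt[zygosity == "DZ"][order(family_id, individual_id)]
  id1 <- dz[seq(1, .N, by = 2), individual_id]
  id2 <- dz[seq(2, .N, by = 2), individual_id]
  rr <- vapply(seq_len(nrow(g$dosages)), function(s)
    cor(g$dosages[s, id1], g$dosages[s, id2]), numeric(1))
  expect_lt(abs(mean(rr) - 0.5), 0.02)
  # HWE at maf 0.5: founder dosage mean near 1
  singles <- dt[zygosity == "singleton", individual_id]
  expect_lt(abs(mean(g$dosages[, singles]) - 1), 0.05)
})

test_that("methylation generator is seed-deterministic with labelled truth", {
  cfg <- sim_config(n_probes = 100, seed = 4)
  b1 <- simulate_dataset(cfg, expression = FALSE)
  b2 <- simulate_dataset(cfg, expression = FALSE)
  expect_identical(b1$meth$betas, b2$meth$betas)
  expect_identical(b1$truth, b2$truth)
  expect_true(all(b1$meth$betas >= 0 & b1$meth$betas <= 1))
  expect_setequal(unique(b1$truth$class), c("heritable", "meqtl", "age", "null"))
  # every meQTL-class probe has at least one cis SNP (generator contract)
  cp <- cis_pairs(b1$meth$annotation, b1$genos)
  expect_true(all(b1$truth[class == "meqtl", probe_id] %in% cp$probe_id))
})

test_that("null generator leaves MZ and DZ ICC distributions indistinguishable", {
  cfg <- sim_config(n_probes = 300, frac_heritable = 0, frac_meqtl = 0,
                    frac_age = 0, n_mediated = 0, n_wbc_probes = 0,
                    fam_env = 0, chip_sd = 0, order_effect_sd = 0,
                    cometh_frac = 0, seed = 5)
  co <- simulate_cohort(cfg)
  m <- simulate_methylation(cfg, co)
  icc <- twin_icc_scan(m, co)
  ks <- ks.test(icc$icc_mz, icc$icc_dz)
  expect_gt(ks$p.value, 0.01)
})

test_that("phenotype generator recovers the planted age slope and missingness", {
  cfg <- sim_config(n_mz_pairs = 0, n_dz_pairs = 0, n_singletons = 5000,
                    n_probes = 10, frac_meqtl = 0, n_mediated = 0, seed = 6)
  co <- simulate_cohort(cfg)
  ph <- simulate_phenotypes(cfg, co)
  sbp <- ph$values["SBP", co$individual_id]
  ok <- !is.na(sbp)
  slope <- coef(lm(sbp[ok] ~ co$age[ok]))[2]
  expect_lt(abs(slope - 0.663), 0.05)
  # telomere length observed fraction matches 62.2% data availability
  expect_lt(abs(mean(!is.na(ph$values["Telomere", ])) - 0.622), 0.03)

  # zero noise, zero slope: constant trait
  cfg0 <- sim_config(n_singletons = 50, n_probes = 10, frac_meqtl = 0,
                     n_mediated = 0, seed = 7)
  cfg0$pheno$age_slope <- 0
  cfg0$pheno$resid_sd <- 0
  ph0 <- simulate_phenotypes(cfg0, simulate_cohort(cfg0))
  v <- ph0$values["SBP", ]
  expect_equal(var(v[!is.na(v)]), 0)
})

test_that("expression coupling shifts per-gene correlations negative", {
  cfg <- sim_config(n_probes = 150, seed = 8, expression_coupling = 0.5)
  bun <- simulate_dataset(cfg)
  mec <- methylation_expression_correlation(bun$meth, bun$expression)
  expect_lt(attr(mec, "mean_rho"), -0.1)

  cfg0 <- sim_config(n_probes = 150, seed = 8, expression_coupling = 0)
  bun0 <- simulate_dataset(cfg0)
  mec0 <- methylation_expression_correlation(bun0$meth, bun0$expression)
  expect_lt(abs(attr(mec0, "mean_rho")), 0.05)

  e1 <- simulate_expression(cfg, bun$meth)
  e2 <- simulate_expression(cfg, bun$meth)
  expect_identical(e1, e2)
})

test_that("age-class probes are predominantly hyper-methylated as configured", {
  bun <- default_bundle()
  dmr <- scan_dmrs(bun$meth, bun$cohort, "age")
  m <- merge(dmr, bun$truth, by = "probe_id")
  sig <- m[class == "age" & p < 1e-3]
  expect_gt(nrow(sig), 10)
  expect_lt(abs(mean(sig$direction == "hyper") - 0.98), 0.07)
  # declared direction matches the planted slope sign
  expect_true(all(sig[age_slope > 0, direction] == "hyper"))
})
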