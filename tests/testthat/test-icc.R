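# brute-force one-way ANOVA ICC oracle via aov()
icc_oracle <- function(values) {
  df <- data.frame(y = c(t(values)),
                   pair = factor(rep(seq_len(nrow(values)), each = 2)))
  tab <- summary(aov(y ~ pair, data = df))[[1]]
  msb <- tab["pair", "Mean Sq"]
  msw <- tab["Residuals", "Mean Sq"]
  (msb - msw) / (msb + msw)
}

test_that("probe ICC matches hand-worked pair ANOVA examples", {
  expect_equal(probe_icc(rbind(c(0.2, 0.2), c(0.4, 0.4))), 1.0)
  # pairs (0,1),(1,0): MSB = 0, MSW = 0.5 -> ICC = -1
  expect_equal(probe_icc(rbind(c(0, 1), c(1, 0))), -1.0)
  # 4 pairs (1,2)...(7,8): pair means 1.5,3.5,5.5,7.5; MSW = 0.5
  v <- rbind(c(1, 2), c(3, 4), c(5, 6), c(7, 8))
  msb <- 2 * var(c(1.5, 3.5, 5.5, 7.5))
  expect_equal(probe_icc(v), (msb - 0.5) / (msb + 0.5))
  expect_equal(probe_icc(v), icc_oracle(v), tolerance = 1e-12)
})

test_that("probe ICC equals the brute-force ANOVA oracle on all small instances", {
  set.seed(55)
  for (n_pairs in 2:6) {
    for (r in 1:25) {
      v <- matrix(rnorm(2 * n_pairs), ncol = 2)
      expect_equal(probe_icc(v), icc_oracle(v), tolerance = 1e-10)
    }
  }
})

test_that("ICC handles missing pairs and degenerate input", {
  v <- rbind(c(0.2, 0.3), c(NA, 0.5), c(0.4, 0.1))
  expect_equal(probe_icc(v), probe_icc(v[c(1, 3), ]))
  one <- probe_icc(rbind(c(1, 2)))
  expect_true(is.na(one))
  expect_true(attr(one, "undefined"))
  const <- probe_icc(rbind(c(1, 1), c(1, 1)))
  expect_true(is.na(const))
})

test_that("Falconer heritability follows the twin-ICC arithmetic", {
  # batch-1 style means: 2 x (0.257 - 0.168) = 0.178
  expect_equal(2 * (0.257 - 0.168), 0.178)
  icc <- data.table::data.table(
    probe_id = c("a", "b"), batch_id = "all",
    icc_mz = c(0.30, 0.214), icc_dz = c(0.20, 0.136),
    n_mz_pairs = 30L, n_dz_pairs = 40L)
  icc[, heritability := 2 * (icc_mz - icc_dz)]
  s <- heritability_summary(icc, n_boot = 50, seed = 1)
  expect_equal(s$mean_h2, mean(c(0.2, 0.156)), tolerance = 1e-12)
  # identical distributions give zero heritability
  icc2 <- data.table::copy(icc)[, icc_dz := icc_mz][, heritability := 0]
  s2 <- heritability_summary(icc2, n_boot = 50, seed = 1)
  expect_equal(s2$mean_h2, 0)
})

test_that("per-batch heritability never pools pairs across batches", {
  bun <- default_bundle()
  icc <- twin_icc_scan(bun$meth, bun$cohort, per_batch = TRUE)
  expect_setequal(unique(icc$batch_id), c("batch1", "batch2"))
  co <- data.table::as.data.table(bun$cohort)
  n_mz_b1 <- co[zygosity == "MZ", sum(table(family_id[batch_id == "batch1"]) == 2)]
  expect_equal(unique(icc[batch_id == "batch1", n_mz_pairs]), n_mz_b1)
  # pooled scan uses all complete pairs regardless of batch
  pooled <- twin_icc_scan(bun$meth, bun$cohort)
  expect_equal(unique(pooled$n_mz_pairs), 33L)
})

test_that("profile correlations: duplicated columns correlate exactly and groups order correctly", {
  bun <- default_bundle()
  m <- bun$meth
  co <- data.table::as.data.table(bun$cohort)
  # duplicate one individual as a fake MZ pair
  fake <- data.table::copy(co[1:2])
  fake$individual_id <- c("dupA", "dupB")
  fake$family_id <- "dupF"
  fake$zygosity <- "MZ"
  fake$batch_id <- co$batch_id[1]
  co2 <- twin_cohort(rbind(co, fake))
  b2 <- cbind(m$betas, dupA = m$betas[, 1], dupB = m$betas[, 1])
  m2 <- methylation_matrix(b2, m$annotation)
  pc <- pairwise_profile_correlations(m2, co2, max_unrelated = 50)
  expect_equal(pc[id1 == "dupA" & id2 == "dupB", r], 1.0)

  pc_full <- pairwise_profile_correlations(m, bun$cohort, max_unrelated = 800)
  s <- attr(pc_full, "summary")
  expect_gt(s[group == "MZ", mean_r], s[group == "DZ", mean_r])
  expect_gt(s[group == "DZ", mean_r], s[group == "unrelated", mean_r])
  w1 <- wilcox.test(pc_full[group == "MZ", r], pc_full[group == "DZ", r],
                    alternative = "greater")$p.value
  w2 <- wilcox.test(pc_full[group == "DZ", r], pc_full[group == "unrelated", r],
                    alternative = "greater")$p.value
  expect_lt(w1, 0.01)
  expect_lt(w2, 0.01)
})

test_that("independent noise profiles show no group separation", {
  set.seed(77)
  co <- simulate_cohort(sim_config(seed = 9))
  b <- matrix(runif(200 * nrow(co)), 200,
              dimnames = list(sprintf("p%03d", 1:200), co$individual_id))
  ann <- data.frame(probe_id = rownames(b), chrom = "chr1", pos = 1:200,
                    nearest_gene = "g", tss_distance = 0L, cpg_island = 0L,
                    unique_mapping = 1L)
  m <- methylation_matrix(b, ann)
  s <- attr(pairwise_profile_correlations(m, co, max_unrelated = 300), "summary")
  expect_lt(max(abs(s$mean_r)), 0.15)
  expect_lt(diff(range(s$mean_r)), 0.1)
})
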