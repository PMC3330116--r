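test_that("cis pair enumeration respects the window boundary exactly", {
  ann <- data.frame(probe_id = "cg1", chrom = "chr1", pos = 1000000L)
  map <- data.frame(snp_id = c("rsA", "rsB", "rsC"), chrom = "chr1",
                    pos = c(950000L, 1100000L, 1100001L))
  dos <- matrix(c(0, 1, 2, 1, 0, 1, 2, 2, 0), 3,
                dimnames = list(map$snp_id, c("s1", "s2", "s3")))
  g <- genotype_matrix(dos, map, maf_min = 0)
  cp <- cis_pairs(ann, g, window = 100000)
  expect_setequal(cp$snp_id, c("rsA", "rsB"))     # rsC is window+1 bp away
  expect_equal(cp[snp_id == "rsA", distance], -50000L)

  ann2 <- rbind(ann, data.frame(probe_id = "cg2", chrom = "chr2",
                                pos = 1000000L))
  cp2 <- cis_pairs(ann2, g, window = 100000)
  expect_equal(attr(cp2, "n_probes_no_cis"), 1L)
  expect_error(cis_pairs(ann, g, window = 0), "positive")
})

test_that("planted cis-effect detection matches the analytic power oracle", {
  # independent oracle: the LRT behaves like a noncentral chi-square(1) with
  # ncp = n * b^2 * 2*maf*(1-maf) / s2e; the Monte-Carlo detection rate must
  # track it, and a strong effect (0.8 SD/allele) must exceed 80% power
  cfg <- sim_config(n_mz_pairs = 30, n_dz_pairs = 35, n_singletons = 20,
                    seed = 30)
  co <- simulate_cohort(cfg)
  n <- nrow(co)
  maf <- 0.3
  alpha <- 1e-5
  set.seed(31)
  for (b in c(0.5, 0.8)) {
    hits <- logical(60)
    for (r in seq_len(60)) {
      dos <- rbinom(n, 1, maf) + rbinom(n, 1, maf)
      y <- rnorm(n) + b * dos
      names(y) <- co$individual_id
      Y <- matrix(inverse_normal_transform(y), nrow = 1,
                  dimnames = list("p", co$individual_id))
      G <- matrix(dos, ncol = 1, dimnames = list(co$individual_id, "g"))
      res <- twinewas:::twin_assoc_scan(Y, co, co$individual_id, G,
        data.table::data.table(iy = 1L, ig = 1L))
      hits[r] <- res$p < alpha
    }
    vtot <- 1 + b^2 * 2 * maf * (1 - maf)   # INT rescales to unit variance
    ncp <- n * b^2 * 2 * maf * (1 - maf) / vtot
    pow <- pchisq(qchisq(alpha, 1, lower.tail = FALSE), 1, ncp = ncp,
                  lower.tail = FALSE)
    expect_lt(abs(mean(hits) - pow), 0.17)
    if (b == 0.8) expect_gte(mean(hits), 0.8)
  }
})

test_that("twin structure is corrected: null type-I error is nominal", {
  # genotypes carry family structure, methylation carries family covariance,
  # but the two are independent; the family/zygosity random effects must
  # keep the test calibrated
  cfg <- sim_config(n_probes = 800, frac_heritable = 0.5, frac_meqtl = 0,
                    frac_age = 0, n_mediated = 0, n_wbc_probes = 0,
                    cometh_frac = 0, seed = 32)
  bun <- simulate_dataset(cfg, expression = FALSE)
  cp <- cis_pairs(bun$meth$annotation, bun$genos)
  cp <- cp[!duplicated(probe_id)]          # one SNP per probe
  mq <- scan_meqtls(cp, bun$meth, bun$genos, bun$cohort)
  a <- mean(mq$p < 0.01)
  expect_gte(a, 0.004)
  expect_lte(a, 0.02)
})

test_that("monomorphic SNPs are skipped and counted", {
  bun <- default_bundle()
  g <- bun$genos
  g$dosages[1, ] <- 2                     # force monomorphic
  cp <- cis_pairs(bun$meth$annotation, g)
  keep <- cp[snp_id == rownames(g$dosages)[1]]
  skip_if(nrow(keep) == 0)
  mq <- scan_meqtls(cp, bun$meth, g, bun$cohort)
  expect_equal(attr(mq, "n_skipped_monomorphic"), 1L)
  expect_false(rownames(g$dosages)[1] %in% mq$snp_id)
})

test_that("permutation FDR reports ~1 under a pure null and preserves probe multisets", {
  cfg <- sim_config(n_probes = 120, frac_heritable = 0, frac_meqtl = 0,
                    frac_age = 0, n_mediated = 0, n_wbc_probes = 0,
                    seed = 33)
  bun <- simulate_dataset(cfg, expression = FALSE)
  cp <- cis_pairs(bun$meth$annotation, bun$genos)
  mq <- scan_meqtls(cp, bun$meth, bun$genos, bun$cohort)
  f <- permutation_fdr_meqtl(mq, cp, bun$meth, bun$genos, bun$cohort,
                             n_perm = 4, seed = 2)
  # null data: estimated FDR near 1 across the curve (clipped at small counts)
  expect_gt(median(f$curve$fdr), 0.5)
  expect_equal(f$summary$n_probes_significant, 0)

  # label permutation preserves each probe's multiset of beta values
  ids <- colnames(bun$meth$betas)
  perm <- sample(ids)
  expect_equal(sort(bun$meth$betas[5, perm]), sort(bun$meth$betas[5, ids]))
})

test_that("best-SNP flags break p ties by |distance| then SNP id", {
  co <- simulate_cohort(sim_config(n_mz_pairs = 10, n_dz_pairs = 10,
                                   n_singletons = 10, n_mz_split = 2,
                                   n_dz_split = 2, seed = 34))
  n <- nrow(co)
  set.seed(35)
  dos <- rbinom(n, 1, 0.4) + rbinom(n, 1, 0.4)
  # two SNPs with identical dosages (identical p), different distances
  g <- genotype_matrix(
    matrix(rep(dos, 2), 2, byrow = TRUE,
           dimnames = list(c("rsFar", "rsNear"), co$individual_id)),
    data.frame(snp_id = c("rsFar", "rsNear"), chrom = "chr1",
               pos = c(1000000L + 5000L, 1000000L + 200L)), maf_min = 0)
  b <- matrix(plogis(rnorm(n, 0, 0.3)), 1,
              dimnames = list("cg1", co$individual_id))
  ann <- data.frame(probe_id = "cg1", chrom = "chr1", pos = 1000000L,
                    nearest_gene = "g", tss_distance = 0L, cpg_island = 0L,
                    unique_mapping = 1L)
  m <- methylation_matrix(b, ann)
  mq <- scan_meqtls(cis_pairs(ann, g), m, g, co)
  expect_equal(mq[is_best_per_probe == TRUE, snp_id], "rsNear")
})
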