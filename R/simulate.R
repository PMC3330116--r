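# Synthetic twin-cohort generator. Every generator is a pure function of
# (config, seed): the RNG state is seeded from cfg$seed plus a fixed offset
# per stage and restored afterwards.
#
# Methylation is generated as a Gaussian liability per probe -- additive
# genetic term (shared fully by MZ co-twins, correlation 1/2 in DZ), family
# environment, cis-SNP dosage effect, linear age trend, chip and chip-order
# artefacts, distance-decaying co-methylation noise, and iid noise -- mapped
# to [0,1] by the inverse logit. The liability keeps the additive covariance
# structure the twin models assume; the inverse logit bounds beta values.

#' Simulation configuration
#'
#' Defaults describe a two-batch cohort of 33 MZ pairs, 43 DZ pairs and 20
#' singletons (172 women aged 32-80), assayed on 12-sample chips, with a
#' probe-class mixture of heritable, cis-meQTL-driven, age-drifting and null
#' probes. Variance fractions are relative to the total per-probe liability
#' variance `liability_sd^2`.
#'
#' @param n_mz_pairs,n_dz_pairs,n_singletons cohort composition.
#' @param n_probes,n_snps array and genotype panel sizes.
#' @param seed integer seed; same config implies an identical dataset.
#' @param frac_heritable,frac_meqtl,frac_age probe class fractions (the
#'   remainder is null); must sum to at most 1.
#' @param h2_target liability-scale heritability of heritable-class probes.
#' @param fam_env shared family-environment variance fraction.
#' @param meqtl_effect cis-SNP effect, in liability SDs per allele.
#' @param n_mediated number of meQTL probes whose methylation also drives a
#'   phenotype (planted SNP -> CpG -> trait chains); `mediated_effect` is
#'   their per-allele effect, `mediation_coupling` the methylation -> trait
#'   coefficient in trait residual SDs per liability SD, and
#'   `mediated_maf_min` the minor-allele-frequency floor for their cis SNPs
#'   (chains sit on common variants so every link is well powered).
#' @param n_env_coupled null-class probes coupled to `env_trait` at
#'   `env_coupling` (environmentally driven discordance architecture).
#' @param age_effect age slope magnitude, logit units per year;
#'   `hyper_fraction` of age-class probes gain methylation with age.
#' @param age_range uniform age range in years.
#' @param liability_sd total per-probe liability SD (logit units).
#' @param cometh_frac,cometh_block,cometh_decay co-methylation share of the
#'   liability variance, block span (bp) and exponential decay scale (bp).
#' @param chip_sd,order_effect_sd,chip_capacity chip random shift SD (logit),
#'   per-position drift SD (logit per slot), samples per chip.
#' @param n_mz_split,n_dz_split twin pairs whose members land in different
#'   batches (default leaves 21 MZ and 31 DZ same-batch pairs).
#' @param batch1_frac target fraction of individuals in batch 1.
#' @param maf_range,cis_snps_per_probe,cis_max_dist genotype panel layout.
#' @param n_wbc_probes,wbc_effect probes coupled to lymphocyte counts and
#'   their effect in liability SDs; `wbc_alpha` Dirichlet parameters for cell
#'   proportions, `wbc_total_mean`/`wbc_total_sd` total count (10^3 cells/ml).
#' @param expression_coupling,expression_noise expression model: expression =
#'   baseline - coupling x standardized gene methylation + N(0, noise).
#' @param pheno per-trait parameters, see [phenotype_parameters()].
#' @return object of class `sim_config`.
#' @export
sim_config <- function(n_mz_pairs = 33L, n_dz_pairs = 43L, n_singletons = 20L,
                       n_probes = 2000L, n_snps = 600L, seed = 1L,
                       frac_heritable = 0.25, frac_meqtl = 0.10,
                       frac_age = 0.10,
                       h2_target = 0.4, fam_env = 0.08,
                       meqtl_effect = 0.5,
                       n_mediated = 5L, mediated_effect = 1.0,
                       mediation_coupling = 1.5, mediated_maf_min = 0.25,
                       n_env_coupled = 0L, env_trait = "LDL",
                       env_coupling = 0.8,
                       age_effect = 0.015, hyper_fraction = 0.98,
                       age_range = c(32, 80),
                       liability_sd = 0.35,
                       cometh_frac = 0.2, cometh_block = 2000,
                       cometh_decay = 1000,
                       chip_sd = 0.1, order_effect_sd = 0.004,
                       chip_capacity = 12L,
                       n_mz_split = 12L, n_dz_split = 12L,
                       batch1_frac = 93 / 172,
                       maf_range = c(0.1, 0.5),
                       cis_snps_per_probe = 2L, cis_max_dist = 20000L,
                       n_wbc_probes = 5L, wbc_effect = 0.5,
                       wbc_alpha = c(neutrophils = 11.5, lymphocytes = 6,
                                     monocytes = 1.5, eosinophils = 1),
                       wbc_total_mean = 7, wbc_total_sd = 1.7,
                       expression_coupling = 0.5, expression_noise = 1,
                       pheno = phenotype_parameters()) {
  cfg <- as.list(environment())
  if (frac_heritable + frac_meqtl + frac_age > 1 + 1e-12)
    stop_twinewas("probe class fractions must sum to at most 1")
  if (any(c(liability_sd, chip_sd, order_effect_sd, cometh_frac) < 0))
    stop_twinewas("variance parameters must be non-negative")
  if (cometh_block <= 0) stop_twinewas("cometh_block must be positive")
  if (maf_range[1] <= 0 || maf_range[2] > 0.5)
    stop_twinewas("MAF range must lie in (0, 0.5]")
  if (n_mz_pairs + n_dz_pairs + n_singletons <= 0)
    stop_twinewas("cohort must contain at least one individual")
  structure(cfg, class = "sim_config")
}

#' Simulate a twin cohort sample sheet
#'
#' Co-twins share family id and age; a configurable number of pairs is split
#' across the two assay batches, and chips of `chip_capacity` samples are
#' filled within batch with families kept adjacent.
#'
#' @param cfg a [sim_config()].
#' @return a `twin_cohort`.
#' @export
simulate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(child_seed(cfg$seed, 1L), {
    n_fam <- cfg$n_mz_pairs + cfg$n_dz_pairs + cfg$n_singletons
    fam_zyg <- c(rep("MZ", cfg$n_mz_pairs), rep("DZ", cfg$n_dz_pairs),
                 rep("singleton", cfg$n_singletons))
    fam_age <- runif(n_fam, cfg$age_range[1], cfg$age_range[2])
    fam_id <- sprintf("F%03d", seq_len(n_fam))
    rows <- lapply(seq_len(n_fam), function(f) {
      k <- if (fam_zyg[f] == "singleton") 1L else 2L
      data.table::data.table(
        individual_id = paste0(fam_id[f], letters[seq_len(k)]),
        family_id = fam_id[f], zygosity = fam_zyg[f],
        age = fam_age[f], sex = "F")
    })
    co <- data.table::rbindlist(rows)

    # batch assignment: split pairs contribute one member to each batch;
    # intact pairs alternate; singletons fill towards batch1_frac
    split_pair <- logical(n_fam)
    mz_idx <- which(fam_zyg == "MZ")
    dz_idx <- which(fam_zyg == "DZ")
    if (cfg$n_mz_split > 0) split_pair[sample(mz_idx, min(cfg$n_mz_split, length(mz_idx)))] <- TRUE
    if (cfg$n_dz_split > 0) split_pair[sample(dz_idx, min(cfg$n_dz_split, length(dz_idx)))] <- TRUE
    co[, batch_id := NA_character_]
    tick <- 0L
    for (f in seq_len(n_fam)) {
      members <- which(co$family_id == fam_id[f])
      if (fam_zyg[f] == "singleton") next
      if (split_pair[f]) {
        co$batch_id[members] <- c("batch1", "batch2")
      } else {
        co$batch_id[members] <- if (tick %% 2L == 0L) "batch1" else "batch2"
        tick <- tick + 1L
      }
    }
    n_total <- nrow(co)
    for (i in which(is.na(co$batch_id))) {
      n1 <- sum(co$batch_id == "batch1", na.rm = TRUE)
      co$batch_id[i] <- if (n1 < cfg$batch1_frac * n_total) "batch1" else "batch2"
    }

    co <- co[order(batch_id, family_id, individual_id)]
    co[, chip_id := paste0(batch_id, "_chip",
                           ceiling(seq_len(.N) / cfg$chip_capacity)),
       by = batch_id]
    co[, chip_position := seq_len(.N), by = chip_id]
    twin_cohort(co)
  })
}

#' Simulate probe annotation with ground-truth class labels
#'
#' Probes are laid out in promoter clusters (1-3 probes within ~2 kb of a
#' gene TSS) across 22 autosomes. Classes `heritable`, `meqtl`, `age`, `wbc`
#' and `null` are assigned at the configured fractions; age-class probes are
#' preferentially placed in CpG islands (membership probability 0.7 against a
#' background of 0.4234).
#'
#' @param cfg a [sim_config()].
#' @return list with `annotation` (data.table) and `truth` (data.table with
#'   `probe_id`, `class`, `h2_true`, `age_slope`, `mediated`, `env_coupled`,
#'   `wbc_probe`).
#' @export
simulate_probes <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(child_seed(cfg$seed, 2L), {
    P <- cfg$n_probes
    ann <- data.table::data.table(probe_id = sprintf("cg%06d", seq_len(P)))
    # gene clusters
    n_per_gene <- integer(0)
    while (sum(n_per_gene) < P)
      n_per_gene <- c(n_per_gene, sample(1:3, 64, TRUE, prob = c(.45, .4, .15)))
    cum <- cumsum(n_per_gene)
    n_genes <- which(cum >= P)[1]
    n_per_gene <- n_per_gene[seq_len(n_genes)]
    n_per_gene[n_genes] <- n_per_gene[n_genes] - (sum(n_per_gene) - P)
    gene_chrom <- paste0("chr", rep_len(1:22, n_genes))
    gene_rank <- stats::ave(seq_len(n_genes), gene_chrom, FUN = seq_along)
    gene_tss <- 1e6 + (gene_rank - 1) * 40000
    gene_id <- sprintf("GENE%04d", seq_len(n_genes))
    g_of_probe <- rep(seq_len(n_genes), times = n_per_gene)
    offset <- round(runif(P, -1500, 500))
    ann[, chrom := gene_chrom[g_of_probe]]
    ann[, pos := as.integer(gene_tss[g_of_probe] + offset)]
    ann[, nearest_gene := gene_id[g_of_probe]]
    ann[, tss_distance := as.integer(offset)]
    ann[, unique_mapping := 1L]

    cls <- rep("null", P)
    n_her <- round(cfg$frac_heritable * P)
    n_meq <- round(cfg$frac_meqtl * P)
    n_age <- round(cfg$frac_age * P)
    idx <- sample.int(P)
    cls[idx[seq_len(n_her)]] <- "heritable"
    cls[idx[n_her + seq_len(n_meq)]] <- "meqtl"
    cls[idx[n_her + n_meq + seq_len(n_age)]] <- "age"
    null_idx <- which(cls == "null")
    wbc_idx <- head(null_idx, cfg$n_wbc_probes)
    env_idx <- if (cfg$n_env_coupled > 0)
      utils::tail(null_idx, cfg$n_env_coupled) else integer(0)

    ann[, cpg_island := rbinom(P, 1L, ifelse(cls == "age", 0.7, 0.4234))]
    ann[, autosomal := TRUE]

    hyper <- rbinom(P, 1L, cfg$hyper_fraction) * 2L - 1L
    truth <- data.table::data.table(
      probe_id = ann$probe_id,
      class = cls,
      h2_true = ifelse(cls == "heritable", cfg$h2_target, 0),
      age_slope = ifelse(cls == "age", hyper * cfg$age_effect, 0),
      mediated = FALSE,
      env_coupled = seq_len(P) %in% env_idx,
      wbc_probe = seq_len(P) %in% wbc_idx)
    meq_idx <- which(cls == "meqtl")
    truth[head(meq_idx, cfg$n_mediated), mediated := TRUE]
    list(annotation = ann[], truth = truth[])
  })
}

#' Simulate a genotype dosage panel
#'
#' Founder genotypes are Hardy-Weinberg draws at per-SNP MAFs; MZ co-twins
#' share genotypes exactly and DZ co-twins inherit each parental allele
#' independently with probability 1/2 (expected dosage correlation 0.5).
#' When probe annotation is supplied, `cis_snps_per_probe` SNPs are placed
#' within `cis_max_dist` of every meQTL-class probe; remaining SNPs land near
#' random probes.
#'
#' @param cfg a [sim_config()].
#' @param cohort a `twin_cohort`.
#' @param probes optional result of [simulate_probes()].
#' @return a `geno_set`; attribute `causal_snp` maps meQTL-class probes to
#'   their causal SNP id.
#' @export
simulate_genotypes <- function(cfg, cohort, probes = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(child_seed(cfg$seed, 3L), {
    causal <- NULL
    if (!is.null(probes)) {
      ann <- probes$annotation
      meq <- which(probes$truth$class == "meqtl")
      cis <- data.table::rbindlist(lapply(meq, function(i) {
        k <- cfg$cis_snps_per_probe
        d <- sample(c(-1, 1), k, TRUE) * round(runif(k, 500, cfg$cis_max_dist))
        data.table::data.table(chrom = ann$chrom[i],
                               pos = as.integer(ann$pos[i] + d),
                               probe = i)
      }))
      n_bg <- max(cfg$n_snps - nrow(cis), 0L)
      bg_probe <- sample.int(nrow(ann), n_bg, replace = TRUE)
      bg <- data.table::data.table(
        chrom = ann$chrom[bg_probe],
        pos = as.integer(ann$pos[bg_probe] +
                         sample(c(-1, 1), n_bg, TRUE) *
                         round(runif(n_bg, 500, 90000))),
        probe = NA_integer_)
      map <- rbind(cis, bg)
    } else {
      map <- data.table::data.table(
        chrom = paste0("chr", sample(1:22, cfg$n_snps, TRUE)),
        pos = as.integer(round(runif(cfg$n_snps, 1e6, 5e7))),
        probe = NA_integer_)
    }
    S <- nrow(map)
    map[, snp_id := sprintf("rs%06d", seq_len(S))]
    maf <- runif(S, cfg$maf_range[1], cfg$maf_range[2])
    if (!is.null(probes)) {
      # planted mediation chains sit on common variants
      med_probe <- which(probes$truth$mediated)
      is_med_cis <- !is.na(map$probe) & map$probe %in% med_probe
      if (any(is_med_cis))
        maf[is_med_cis] <- runif(sum(is_med_cis),
                                 max(cfg$mediated_maf_min, cfg$maf_range[1]),
                                 cfg$maf_range[2])
    }

    co <- as.data.table(cohort)
    N <- nrow(co)
    dos <- matrix(NA_real_, S, N, dimnames = list(map$snp_id, co$individual_id))
    fam <- split(seq_len(N), co$family_id)
    for (members in fam) {
      zyg <- co$zygosity[members[1]]
      if (zyg == "MZ") {
        g <- rbinom(S, 1L, maf) + rbinom(S, 1L, maf)
        dos[, members] <- g
      } else if (zyg == "DZ") {
        f1 <- rbinom(S, 1L, maf); f2 <- rbinom(S, 1L, maf)
        m1 <- rbinom(S, 1L, maf); m2 <- rbinom(S, 1L, maf)
        for (tw in members) {
          cf <- rbinom(S, 1L, 0.5); cm <- rbinom(S, 1L, 0.5)
          dos[, tw] <- (cf * f1 + (1 - cf) * f2) + (cm * m1 + (1 - cm) * m2)
        }
      } else {
        dos[, members] <- rbinom(S, 1L, maf) + rbinom(S, 1L, maf)
      }
    }
    if (!is.null(probes)) {
      causal <- map[!is.na(probe),
                    .(probe_id = probes$annotation$probe_id[probe],
                      snp_id = snp_id)]
      causal <- causal[!duplicated(probe_id)]   # first cis SNP is causal
    }
    g <- genotype_matrix(dos, map[, .(snp_id, chrom, pos)], maf_min = 0)
    attr(g, "causal_snp") <- causal
    g
  })
}

#' Simulate white-blood-cell subtype counts
#'
#' Dirichlet cell-type proportions multiplied by a normal total count.
#'
#' @param cfg a [sim_config()].
#' @param cohort a `twin_cohort`.
#' @return matrix, cell types x individuals (10^3 cells/ml).
#' @export
simulate_wbc <- function(cfg, cohort) {
  with_seed(child_seed(cfg$seed, 4L), {
    co <- as.data.table(cohort)
    N <- nrow(co)
    a <- cfg$wbc_alpha
    g <- matrix(rgamma(length(a) * N, shape = rep(a, N)), nrow = length(a))
    prop <- sweep(g, 2, colSums(g), "/")
    total <- pmax(rnorm(N, cfg$wbc_total_mean, cfg$wbc_total_sd), 1.5)
    counts <- sweep(prop, 2, total, "*")
    dimnames(counts) <- list(names(a), co$individual_id)
    counts
  })
}

#' Simulate beta-value methylation with twin covariance structure
#'
#' See the package vignette for the liability model. Variance components are
#' calibrated so that `h2_target` is the heritable-class fraction of the
#' total liability variance (including chip and chip-order artefacts), which
#' makes the Falconer estimator unbiased on the liability scale.
#'
#' @param cfg a [sim_config()].
#' @param cohort a `twin_cohort`.
#' @param genos a `geno_set` from [simulate_genotypes()] (required when the
#'   meQTL class fraction is positive).
#' @param probes result of [simulate_probes()]; generated if `NULL`.
#' @param wbc optional cell-count matrix from [simulate_wbc()].
#' @return a `meth_set` with attributes `truth` (ground-truth table) and
#'   `liabilities` (the latent Gaussian matrix, for phenotype coupling).
#' @export
simulate_methylation <- function(cfg, cohort, genos = NULL, probes = NULL,
                                 wbc = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  if (is.null(probes)) probes <- simulate_probes(cfg)
  ann <- probes$annotation
  truth <- data.table::copy(probes$truth)
  if (cfg$frac_meqtl > 0 && is.null(genos))
    stop_twinewas("genotypes required when the meQTL class fraction is > 0")
  with_seed(child_seed(cfg$seed, 5L), {
    co <- as.data.table(cohort)
    N <- nrow(co)
    P <- nrow(ann)
    Tv <- cfg$liability_sd^2
    v_chip <- cfg$chip_sd^2
    pos_c <- co$chip_position - mean(co$chip_position)
    v_order <- cfg$order_effect_sd^2 * mean(pos_c^2)
    c2 <- cfg$fam_env * Tv
    b2 <- cfg$cometh_frac * Tv
    g2 <- truth$h2_true * Tv
    e2 <- Tv - g2 - c2 - b2 - v_chip - v_order
    if (any(e2 <= 0))
      stop_twinewas("variance budget exceeded: lower h2_target, fam_env, ",
                    "cometh_frac or chip/order SDs relative to liability_sd")

    comp <- sample(1:3, P, TRUE, prob = c(.60, .25, .15))
    mu <- rnorm(P, c(-1.6, 1.3, 0)[comp], c(0.6, 0.5, 0.6)[comp])

    L <- matrix(rnorm(P * N), P, N) * sqrt(e2)      # iid noise
    L <- L + mu

    # additive genetic values, var 1, MZ share fully, DZ correlation 1/2
    fams <- split(seq_len(N), co$family_id)
    gmat <- matrix(0, P, N)
    for (members in fams) {
      zyg <- co$zygosity[members[1]]
      if (zyg == "MZ") {
        gmat[, members] <- rnorm(P)
      } else if (zyg == "DZ") {
        shared <- rnorm(P)
        for (tw in members)
          gmat[, tw] <- sqrt(0.5) * shared + sqrt(0.5) * rnorm(P)
      } else {
        gmat[, members] <- rnorm(P)
      }
    }
    L <- L + gmat * sqrt(g2)

    fenv <- matrix(0, P, N)
    for (members in fams) fenv[, members] <- rnorm(P)
    L <- L + fenv * sqrt(c2)

    # co-methylation: exponential-kernel Gaussian process within blocks
    if (b2 > 0) {
      o <- order(ann$chrom, ann$pos)
      block <- integer(P)
      bid <- 0L
      start_pos <- -Inf; cur_chr <- ""
      for (i in o) {
        if (ann$chrom[i] != cur_chr || ann$pos[i] - start_pos > cfg$cometh_block) {
          bid <- bid + 1L
          cur_chr <- ann$chrom[i]
          start_pos <- ann$pos[i]
        }
        block[i] <- bid
      }
      for (bidx in split(seq_len(P), block)) {
        k <- length(bidx)
        if (k == 1L) {
          L[bidx, ] <- L[bidx, ] + sqrt(b2) * rnorm(N)
        } else {
          D <- abs(outer(ann$pos[bidx], ann$pos[bidx], "-"))
          K <- exp(-D / cfg$cometh_decay)
          Lc <- t(chol(K + diag(1e-10, k)))
          L[bidx, ] <- L[bidx, ] + sqrt(b2) * (Lc %*% matrix(rnorm(k * N), k, N))
        }
      }
    }

    # cis-meQTL dosage effects
    truth[, meqtl_snp := NA_character_]
    truth[, meqtl_beta := 0]
    if (!is.null(genos)) {
      causal <- attr(genos, "causal_snp")
      if (!is.null(causal)) {
        causal <- causal[snp_id %in% rownames(genos$dosages)]
        pi_map <- match(causal$probe_id, ann$probe_id)
        for (j in seq_len(nrow(causal))) {
          i <- pi_map[j]
          eff <- (if (truth$mediated[i]) cfg$mediated_effect else
                    cfg$meqtl_effect) * cfg$liability_sd
          d <- genos$dosages[causal$snp_id[j], co$individual_id]
          L[i, ] <- L[i, ] + eff * (d - mean(d))
          truth[i, `:=`(meqtl_snp = causal$snp_id[j], meqtl_beta = eff)]
        }
      }
    }

    age_c <- co$age - mean(range(cfg$age_range))
    L <- L + truth$age_slope %o% age_c

    chips <- unique(co$chip_id)
    delta <- matrix(rnorm(P * length(chips), 0, cfg$chip_sd), P,
                    dimnames = list(NULL, chips))
    L <- L + delta[, co$chip_id]
    oslope <- rnorm(P, 0, cfg$order_effect_sd)
    L <- L + oslope %o% pos_c

    if (!is.null(wbc) && any(truth$wbc_probe)) {
      z <- as.numeric(scale(wbc["lymphocytes", co$individual_id]))
      for (i in which(truth$wbc_probe))
        L[i, ] <- L[i, ] + cfg$wbc_effect * cfg$liability_sd * z
    }

    dimnames(L) <- list(ann$probe_id, co$individual_id)
    betas <- plogis(L)
    m <- methylation_matrix(betas, ann)
    attr(m, "truth") <- truth[]
    attr(m, "liabilities") <- L
    m
  })
}

#' Simulate age-related phenotypes
#'
#' Each trait is `intercept + age_slope * age + family effect + noise` with
#' the Table-style age slopes and completely-at-random missingness at the
#' configured per-trait rates. Probes flagged `mediated` or `env_coupled` in
#' the ground truth additionally contribute their (standardized) liability to
#' the designated trait, creating SNP -> CpG -> trait and environment ->
#' CpG -> trait architectures.
#'
#' @param cfg a [sim_config()].
#' @param cohort a `twin_cohort`.
#' @param meth optional `meth_set` from [simulate_methylation()] (needed for
#'   coupled traits).
#' @return a `pheno_table`; attribute `mediated_traits` records which trait
#'   each mediated probe drives.
#' @export
simulate_phenotypes <- function(cfg, cohort, meth = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(child_seed(cfg$seed, 6L), {
    co <- as.data.table(cohort)
    N <- nrow(co)
    ph <- cfg$pheno
    vals <- matrix(NA_real_, nrow(ph), N,
                   dimnames = list(ph$trait, co$individual_id))
    fams <- split(seq_len(N), co$family_id)
    for (t in seq_len(nrow(ph))) {
      fam_re <- numeric(N)
      for (members in fams) fam_re[members] <- rnorm(1, 0, 0.3 * ph$resid_sd[t])
      vals[t, ] <- ph$intercept[t] + ph$age_slope[t] * co$age + fam_re +
        rnorm(N, 0, ph$resid_sd[t])
    }

    med_tab <- NULL
    if (!is.null(meth)) {
      truth <- attr(meth, "truth")
      liab <- attr(meth, "liabilities")
      # couple chains to near-complete GWAS traits so the chain's sample
      # size is the full cohort
      gwas_traits <- ph$trait[ph$gwas & ph$data_pct >= 90]
      med_idx <- which(truth$mediated)
      if (length(med_idx)) {
        tr <- rep_len(gwas_traits, length(med_idx))
        med_tab <- data.table::data.table(probe_id = truth$probe_id[med_idx],
                                          trait = tr)
        for (j in seq_along(med_idx)) {
          z <- as.numeric(scale(liab[med_idx[j], co$individual_id]))
          k <- match(tr[j], ph$trait)
          vals[tr[j], ] <- vals[tr[j], ] +
            cfg$mediation_coupling * ph$resid_sd[k] * z
        }
      }
      env_idx <- which(truth$env_coupled)
      for (j in env_idx) {
        z <- as.numeric(scale(liab[j, co$individual_id]))
        k <- match(cfg$env_trait, ph$trait)
        vals[cfg$env_trait, ] <- vals[cfg$env_trait, ] +
          cfg$env_coupling * ph$resid_sd[k] * z
      }
    }

    miss_rate <- (100 - ph$data_pct) / 100
    for (t in seq_len(nrow(ph)))
      vals[t, runif(N) < miss_rate[t]] <- NA_real_
    out <- phenotype_table(vals)
    attr(out, "mediated_traits") <- med_tab
    out
  })
}

#' Simulate gene expression negatively coupled to promoter methylation
#'
#' `expression = baseline - coupling * z(gene mean methylation) + noise`.
#'
#' @param cfg a [sim_config()].
#' @param m a `meth_set`.
#' @return matrix, genes x individuals.
#' @export
simulate_expression <- function(cfg, m) {
  stopifnot(inherits(cfg, "sim_config"), inherits(m, "meth_set"))
  with_seed(child_seed(cfg$seed, 7L), {
    ann <- m$annotation
    genes <- unique(ann$nearest_gene)
    N <- ncol(m$betas)
    expr <- matrix(NA_real_, length(genes), N,
                   dimnames = list(genes, colnames(m$betas)))
    for (g in seq_along(genes)) {
      idx <- which(ann$nearest_gene == genes[g])
      mm <- colMeans(m$betas[idx, , drop = FALSE])
      z <- if (sd(mm) > 0) as.numeric(scale(mm)) else numeric(N)
      expr[g, ] <- 8 - cfg$expression_coupling * z +
        rnorm(N, 0, cfg$expression_noise)
    }
    expr
  })
}

#' Simulate a complete dataset bundle
#'
#' Wires [simulate_cohort()], [simulate_probes()], [simulate_genotypes()],
#' [simulate_wbc()], [simulate_methylation()], [simulate_phenotypes()] and
#' [simulate_expression()] into the bundle shape used by [read_dataset()] /
#' [write_dataset()].
#'
#' @param cfg a [sim_config()].
#' @param expression also simulate the expression matrix (default `TRUE`).
#' @return bundle list with `meth`, `cohort`, `genos`, `phenos`, `wbc`,
#'   `expression`, `truth`.
#' @export
simulate_dataset <- function(cfg, expression = TRUE) {
  cohort <- simulate_cohort(cfg)
  probes <- simulate_probes(cfg)
  genos <- simulate_genotypes(cfg, cohort, probes)
  wbc <- simulate_wbc(cfg, cohort)
  meth <- simulate_methylation(cfg, cohort, genos, probes, wbc)
  phenos <- simulate_phenotypes(cfg, cohort, meth)
  expr <- if (expression) simulate_expression(cfg, meth) else NULL
  truth <- attr(meth, "truth")
  med <- attr(phenos, "mediated_traits")
  if (!is.null(med)) {
    truth <- merge(truth, med[, .(probe_id, mediated_trait = trait)],
                   by = "probe_id", all.x = TRUE, sort = FALSE)
  }
  list(meth = meth, cohort = cohort, genos = genos, phenos = phenos,
       wbc = wbc, expression = expr, truth = truth)
}
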