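# Twin similarity statistics: whole-profile correlations, per-probe one-way
# random-effects intraclass correlations, and the Falconer-style heritability
# 2(ICC_MZ - ICC_DZ).

#' One-way random-effects intraclass correlation for twin pairs
#'
#' ICC(1,1) from the pair-level one-way ANOVA:
#' `(MSB - MSW) / (MSB + MSW)` for pairs of size two, where MSB is the
#' between-pair and MSW the within-pair mean square. Ranges over `[-1, 1]`.
#'
#' @param values numeric matrix with two columns (twin 1, twin 2) and one row
#'   per pair, or a length-2k vector paired consecutively.
#' @return the ICC, or `NA` with attribute `undefined = TRUE` when fewer than
#'   2 complete pairs are available or the data are constant.
#' @examples
#' probe_icc(rbind(c(0.2, 0.2), c(0.4, 0.4)))   # 1
#' @export
probe_icc <- function(values) {
  if (is.null(dim(values))) values <- matrix(values, ncol = 2, byrow = TRUE)
  values <- values[complete.cases(values), , drop = FALSE]
  n <- nrow(values)
  if (n < 2L) {
    out <- NA_real_
    attr(out, "undefined") <- TRUE
    return(out)
  }
  pm <- rowMeans(values)
  gm <- mean(values)
  msb <- 2 * sum((pm - gm)^2) / (n - 1)
  msw <- sum((values - pm)^2) / n
  if (msb + msw == 0) {
    out <- NA_real_
    attr(out, "undefined") <- TRUE
    return(out)
  }
  (msb - msw) / (msb + msw)
}

# pairs of complete co-twins of a given zygosity, optionally same-batch only
.twin_pairs <- function(cohort, ids, zyg, same_batch = FALSE) {
  co <- as.data.table(cohort)[individual_id %in% ids & zygosity == zyg]
  co <- co[order(family_id, individual_id)]
  fam <- co[, .N, by = family_id][N == 2L, family_id]
  co <- co[family_id %in% fam]
  if (same_batch) {
    ok <- co[, uniqueN(batch_id) == 1L, by = family_id][V1 == TRUE, family_id]
    co <- co[family_id %in% ok]
  }
  if (!nrow(co)) return(data.table::data.table(id1 = character(), id2 = character(),
                                               family_id = character()))
  co[, .(id1 = individual_id[1], id2 = individual_id[2]), by = family_id]
}

#' Per-probe twin ICCs and Falconer heritability
#'
#' Computes ICC(1,1) across MZ pairs and DZ pairs at every probe and the
#' heritability estimate `2 * (ICC_MZ - ICC_DZ)`, unbounded by construction
#' and reported raw. When `per_batch = TRUE`, pairs are never pooled across
#' batches: each batch contributes its own ICC/heritability rows, and only
#' same-batch pairs are used.
#'
#' @param m a `meth_set`.
#' @param cohort a `twin_cohort`.
#' @param per_batch compute within each assay batch separately (default
#'   `FALSE`).
#' @return data.table with `probe_id`, `batch_id`, `icc_mz`, `icc_dz`,
#'   `n_mz_pairs`, `n_dz_pairs`, `heritability`.
#' @export
twin_icc_scan <- function(m, cohort, per_batch = FALSE) {
  stopifnot(inherits(m, "meth_set"))
  ids <- intersect(cohort$individual_id, colnames(m$betas))
  batches <- if (per_batch) unique(as.data.table(cohort)$batch_id) else "all"
  res <- lapply(batches, function(b) {
    sub_ids <- if (identical(b, "all")) ids else
      intersect(ids, cohort$individual_id[cohort$batch_id == b])
    mzp <- .twin_pairs(cohort, sub_ids, "MZ", same_batch = per_batch)
    dzp <- .twin_pairs(cohort, sub_ids, "DZ", same_batch = per_batch)
    icc_grp <- function(pairs) {
      if (nrow(pairs) < 2L) return(rep(NA_real_, nrow(m$betas)))
      v1 <- m$betas[, pairs$id1, drop = FALSE]
      v2 <- m$betas[, pairs$id2, drop = FALSE]
      vapply(seq_len(nrow(v1)), function(i)
        as.numeric(probe_icc(cbind(v1[i, ], v2[i, ]))), numeric(1))
    }
    data.table::data.table(
      probe_id = m$annotation$probe_id,
      batch_id = b,
      icc_mz = icc_grp(mzp),
      icc_dz = icc_grp(dzp),
      n_mz_pairs = nrow(mzp),
      n_dz_pairs = nrow(dzp))
  })
  out <- data.table::rbindlist(res)
  out[, heritability := 2 * (icc_mz - icc_dz)]
  out[]
}

#' Genome-wide heritability summary
#'
#' Mean Falconer heritability with a probe-resampling bootstrap 95 percent
#' CI, and a paired Wilcoxon signed-rank test of the ICC_MZ versus ICC_DZ
#' distributions, per batch when the ICC table carries several batches.
#'
#' @param iccs result of [twin_icc_scan()].
#' @param n_boot bootstrap resamples (default 1000).
#' @param seed RNG seed for the bootstrap.
#' @return data.table with one row per batch: `batch_id`, `mean_icc_mz`,
#'   `mean_icc_dz`, `mean_h2`, `ci_low`, `ci_high`, `p_mz_gt_dz`, `n_probes`.
#' @export
heritability_summary <- function(iccs, n_boot = 1000L, seed = 1L) {
  if (!nrow(iccs)) stop_twinewas("empty ICC table")
  with_seed(seed, {
    out <- iccs[!is.na(heritability),
      {
        h <- heritability
        bm <- vapply(seq_len(n_boot), function(b)
          mean(h[sample.int(length(h), replace = TRUE)]), numeric(1))
        ci <- quantile(bm, c(0.025, 0.975), names = FALSE)
        wp <- suppressWarnings(wilcox.test(icc_mz, icc_dz, paired = TRUE,
                                           alternative = "greater"))$p.value
        .(mean_icc_mz = mean(icc_mz), mean_icc_dz = mean(icc_dz),
          mean_h2 = mean(h), ci_low = ci[1], ci_high = ci[2],
          p_mz_gt_dz = wp, n_probes = .N)
      },
      by = batch_id]
    out[]
  })
}

#' Whole-profile pairwise correlations by relatedness group
#'
#' Pearson correlation of whole-profile beta vectors for every MZ pair, DZ
#' pair, and cross-family (unrelated) pair. By default pairs are restricted
#' to individuals assayed in the same batch, and the unrelated enumeration
#' uses all cross-family pairs within batch, optionally capped by seeded
#' subsampling.
#'
#' @param m a `meth_set`.
#' @param cohort a `twin_cohort`.
#' @param same_batch restrict pairs to a common batch (default `TRUE`).
#' @param max_unrelated cap on unrelated pairs (default `Inf`); subsampling
#'   is seeded by `seed`.
#' @param seed RNG seed for subsampling.
#' @return data.table with `group` (`MZ`, `DZ`, `unrelated`), `id1`, `id2`,
#'   `r`; attribute `summary` holds per-group mean/median/count.
#' @export
pairwise_profile_correlations <- function(m, cohort, same_batch = TRUE,
                                          max_unrelated = Inf, seed = 1L) {
  stopifnot(inherits(m, "meth_set"))
  if (!nrow(m$betas)) stop_twinewas("methylation matrix has zero probes")
  ids <- intersect(cohort$individual_id, colnames(m$betas))
  co <- as.data.table(cohort)[individual_id %in% ids]
  mzp <- .twin_pairs(cohort, ids, "MZ", same_batch = same_batch)
  dzp <- .twin_pairs(cohort, ids, "DZ", same_batch = same_batch)

  cmb <- utils::combn(co$individual_id, 2)
  fam <- co$family_id[match(cmb[1, ], co$individual_id)] !=
    co$family_id[match(cmb[2, ], co$individual_id)]
  bok <- if (same_batch)
    co$batch_id[match(cmb[1, ], co$individual_id)] ==
      co$batch_id[match(cmb[2, ], co$individual_id)] else TRUE
  un <- data.table::data.table(id1 = cmb[1, ], id2 = cmb[2, ])[fam & bok]
  if (nrow(un) > max_unrelated) {
    un <- with_seed(seed, un[sample.int(.N, max_unrelated)])
  }

  corr_of <- function(pairs, group) {
    if (!nrow(pairs)) return(data.table::data.table(
      group = character(), id1 = character(), id2 = character(), r = numeric()))
    r <- vapply(seq_len(nrow(pairs)), function(i)
      cor(m$betas[, pairs$id1[i]], m$betas[, pairs$id2[i]],
          use = "complete.obs"), numeric(1))
    data.table::data.table(group = group, id1 = pairs$id1, id2 = pairs$id2, r = r)
  }
  out <- rbind(corr_of(mzp, "MZ"), corr_of(dzp, "DZ"), corr_of(un, "unrelated"))
  smry <- out[, .(mean_r = mean(r), median_r = median(r), n_pairs = .N),
              by = group]
  data.table::setattr(out, "summary", smry)
  out[]
}
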