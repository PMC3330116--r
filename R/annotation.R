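# Functional characterization of DMRs: co-methylation decay with genomic
# distance, annotation-track enrichment with bootstrap CIs,
# methylation-expression correlation, and replication of discovery DMRs in a
# second cohort.

#' Co-methylation decay profile
#'
#' Spearman correlation between all same-chromosome probe pairs within
#' `max_dist`, binned by pairwise bp distance. Optionally restricted to a
#' probe subset (e.g. a-DMRs: correlations of subset probes against all
#' neighbours) and/or to one individual per family (unrelated columns).
#'
#' @param m a `meth_set`.
#' @param max_dist maximum pair distance in bp (default 50000).
#' @param bins distance bin edges (default
#'   `c(0, 500, 1000, 2000, 5000, 10000, 50000)`).
#' @param probe_subset optional probe ids; pairs must include at least one.
#' @param cohort optional `twin_cohort`; with `unrelated_only = TRUE` keeps
#'   the first individual per family.
#' @param unrelated_only see above (default `FALSE`).
#' @return data.table with `bin_low`, `bin_high`, `mean_rho`, `n_pairs`
#'   (empty bins report `n_pairs = 0` and `NA` mean, never NaN).
#' @export
comethylation_profile <- function(m, max_dist = 50000,
                                  bins = c(0, 500, 1000, 2000, 5000, 10000,
                                           50000),
                                  probe_subset = NULL, cohort = NULL,
                                  unrelated_only = FALSE) {
  stopifnot(inherits(m, "meth_set"))
  ids <- colnames(m$betas)
  if (unrelated_only) {
    if (is.null(cohort)) stop_twinewas("cohort required for unrelated_only")
    co <- as.data.table(cohort)[individual_id %in% ids]
    ids <- co[order(family_id, individual_id),
              .(id = individual_id[1]), by = family_id]$id
  }
  ann <- m$annotation
  b <- m$betas[, ids, drop = FALSE]
  pairs_list <- list()
  for (chr in unique(ann$chrom)) {
    idx <- which(ann$chrom == chr)
    if (length(idx) < 2L) next
    idx <- idx[order(ann$pos[idx])]
    ps <- ann$pos[idx]
    for (a in seq_along(idx)[-length(idx)]) {
      bmax <- which(ps - ps[a] > max_dist)
      hi <- if (length(bmax)) bmax[1] - 1L else length(idx)
      if (hi > a)
        pairs_list[[length(pairs_list) + 1L]] <- data.table::data.table(
          i = idx[a], j = idx[(a + 1L):hi], d = ps[(a + 1L):hi] - ps[a])
    }
  }
  pr <- data.table::rbindlist(pairs_list)
  if (!is.null(probe_subset)) {
    sel <- match(probe_subset, ann$probe_id)
    pr <- pr[i %in% sel | j %in% sel]
  }
  if (nrow(pr)) {
    pr[, rho := vapply(seq_len(.N), function(k)
      cor(b[i[k], ], b[j[k], ], method = "spearman",
          use = "complete.obs"), numeric(1))]
  } else {
    pr <- data.table::data.table(i = integer(), j = integer(), d = numeric(),
                                 rho = numeric())
  }
  out <- data.table::data.table(bin_low = head(bins, -1), bin_high = bins[-1])
  out[, c("mean_rho", "n_pairs") := {
    sub <- pr[d >= bin_low & d < bin_high]
    .(if (nrow(sub)) mean(sub$rho) else NA_real_, nrow(sub))
  }, by = seq_len(nrow(out))]
  out[]
}

#' Annotation-track enrichment with bootstrap confidence intervals
#'
#' Enrichment of a DMR probe set in an interval track: the proportion of DMR
#' probes whose CpG coordinate falls inside a track interval over the same
#' proportion in the background probe set, with a 95 percent percentile CI
#' from resampling the DMR set with replacement.
#'
#' @param dmr_probes character vector of DMR probe ids.
#' @param background character vector of background probe ids (the full
#'   array).
#' @param annotation probe annotation (`probe_id`, `chrom`, `pos`).
#' @param tracks named list of `GRanges` (e.g. from [read_bed()]).
#' @param n_boot bootstrap resamples (default 1000).
#' @param seed RNG seed.
#' @return data.table with `category`, `prop_dmr`, `prop_background`,
#'   `enrichment`, `ci_low`, `ci_high`, `n_dmr`, `n_background`. Empty
#'   background membership gives `NA` enrichment with an `undefined` flag.
#' @export
enrichment_bootstrap <- function(dmr_probes, background, annotation, tracks,
                                 n_boot = 1000L, seed = 1L) {
  ann <- as.data.table(annotation)
  bg <- ann[probe_id %in% background]
  dmr <- ann[probe_id %in% dmr_probes]
  gr_of <- function(tab) GenomicRanges::GRanges(
    tab$chrom, IRanges::IRanges(start = tab$pos, width = 1L))
  bg_gr <- gr_of(bg)
  dmr_gr <- gr_of(dmr)
  with_seed(seed, data.table::rbindlist(lapply(names(tracks), function(nm) {
    tr <- tracks[[nm]]
    in_bg <- suppressWarnings(IRanges::overlapsAny(bg_gr, tr))
    in_dmr <- suppressWarnings(IRanges::overlapsAny(dmr_gr, tr))
    p_bg <- mean(in_bg)
    p_dmr <- mean(in_dmr)
    if (p_bg == 0) {
      return(data.table::data.table(
        category = nm, prop_dmr = p_dmr, prop_background = 0,
        enrichment = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
        n_dmr = nrow(dmr), n_background = nrow(bg), undefined = TRUE))
    }
    enr <- p_dmr / p_bg
    bs <- vapply(seq_len(n_boot), function(b)
      mean(in_dmr[sample.int(length(in_dmr), replace = TRUE)]) / p_bg,
      numeric(1))
    ci <- quantile(bs, c(0.025, 0.975), names = FALSE)
    data.table::data.table(
      category = nm, prop_dmr = p_dmr, prop_background = p_bg,
      enrichment = enr, ci_low = min(ci[1], enr), ci_high = max(ci[2], enr),
      n_dmr = nrow(dmr), n_background = nrow(bg), undefined = FALSE)
  })))
}

#' Per-gene methylation-expression correlation
#'
#' Restricts probes to those within `tss_window` bp of the transcription
#' start site, averages methylation per gene over shared individuals, and
#' reports the per-gene Spearman correlation with expression plus a Wilcoxon
#' signed-rank test of the correlation distribution against zero.
#'
#' @param m a `meth_set`.
#' @param expr expression matrix (genes x individuals).
#' @param tss_window TSS distance cutoff in bp (default 2000).
#' @param gene_subset optional gene names to restrict to (e.g. a-DMR genes).
#' @return data.table with `gene`, `rho`, `n`; attributes `wilcoxon_p`,
#'   `mean_rho`, `n_genes_excluded`.
#' @export
methylation_expression_correlation <- function(m, expr, tss_window = 2000,
                                               gene_subset = NULL) {
  ann <- m$annotation
  ids <- intersect(colnames(m$betas), colnames(expr))
  if (!length(ids)) stop_twinewas("no shared individuals between matrices")
  elig <- ann[abs(tss_distance) <= tss_window]
  genes <- intersect(unique(elig$nearest_gene), rownames(expr))
  if (!is.null(gene_subset)) genes <- intersect(genes, gene_subset)
  n_excluded <- length(unique(ann$nearest_gene)) - length(genes)
  res <- data.table::rbindlist(lapply(genes, function(g) {
    probes <- elig[nearest_gene == g, probe_id]
    mm <- colMeans(m$betas[probes, ids, drop = FALSE], na.rm = TRUE)
    data.table::data.table(
      gene = g,
      rho = suppressWarnings(cor(mm, expr[g, ids], method = "spearman",
                                 use = "complete.obs")),
      n = length(ids))
  }))
  wp <- if (nrow(res) >= 3L)
    suppressWarnings(wilcox.test(res$rho, mu = 0)$p.value) else NA_real_
  data.table::setattr(res, "wilcoxon_p", wp)
  data.table::setattr(res, "mean_rho", mean(res$rho, na.rm = TRUE))
  data.table::setattr(res, "n_genes_excluded", n_excluded)
  res[]
}

#' Replication of discovery DMRs in a second cohort
#'
#' Two modes. `"lmm"`: per discovery probe, the twin LMM of normalized
#' betas on age with chip, chip position and sex fixed effects and a family
#' random intercept in the replication cohort. `"unrelated_spearman"`:
#' Spearman correlation of raw betas against age in unrelated individuals.
#' Summary fractions use all discovery DMRs as the denominator; probes
#' absent from the replication panel stay in the denominator, flagged
#' untested.
#'
#' @param discovery_dmrs data.table of discovery a-DMRs (`probe_id`,
#'   `direction`).
#' @param m2 replication `meth_set`.
#' @param cohort2 replication `twin_cohort`.
#' @param mode `"lmm"` or `"unrelated_spearman"`.
#' @param p_nominal nominal replication significance (default 0.05).
#' @return list with `table` (probe_id, tested, beta/rho, p, direction2,
#'   same_direction, replicated) and `summary` (fractions and percentages
#'   over all discovery DMRs).
#' @export
replication_check <- function(discovery_dmrs, m2, cohort2,
                              mode = c("lmm", "unrelated_spearman"),
                              p_nominal = 0.05) {
  mode <- match.arg(mode)
  dd <- as.data.table(discovery_dmrs)
  present <- dd$probe_id %in% rownames(m2$betas)
  probes <- dd$probe_id[present]
  co <- as.data.table(cohort2)
  if (mode == "lmm") {
    if (!"sex" %in% names(co)) stop_twinewas("replication cohort needs sex")
    ids <- intersect(co$individual_id, colnames(m2$betas))
    Y <- m2$betas[probes, ids, drop = FALSE]
    Y <- t(apply(Y, 1, inverse_normal_transform))
    colnames(Y) <- ids
    age <- co$age[match(ids, co$individual_id)]
    G <- matrix(age, ncol = 1, dimnames = list(ids, "age"))
    covs <- intersect(c("chip_id", "chip_position", "sex"), names(co))
    covs <- covs[vapply(covs, function(cv)
      length(unique(co[[cv]][match(ids, co$individual_id)])) > 1L, logical(1))]
    tests <- data.table::data.table(iy = seq_along(probes), ig = 1L)
    r <- twin_assoc_scan(Y, cohort2, ids, G, tests, covariates = covs)
    tab <- data.table::data.table(probe_id = probes[r$iy], effect = r$beta,
                                  p = r$p)
  } else {
    ids <- intersect(co$individual_id, colnames(m2$betas))
    co_sub <- co[individual_id %in% ids][order(family_id, individual_id)]
    ids <- co_sub[, .(id = individual_id[1]), by = family_id]$id
    age <- co$age[match(ids, co$individual_id)]
    tab <- data.table::rbindlist(lapply(probes, function(pb) {
      ct <- suppressWarnings(cor.test(m2$betas[pb, ids], age,
                                      method = "spearman"))
      data.table::data.table(probe_id = pb, effect = unname(ct$estimate),
                             p = ct$p.value)
    }))
  }
  tab[, direction2 := ifelse(effect >= 0, "hyper", "hypo")]
  out <- merge(dd[, .(probe_id, direction)], tab, by = "probe_id",
               all.x = TRUE, sort = FALSE)
  out[, tested := !is.na(effect)]
  out[, same_direction := tested & direction == direction2]
  out[, replicated := same_direction & p <= p_nominal]
  n_all <- nrow(dd)
  summary <- list(
    n_discovery = n_all,
    n_tested = sum(out$tested),
    n_same_direction = sum(out$same_direction),
    n_replicated = sum(out$replicated),
    frac_same_direction = sum(out$same_direction) / n_all,
    frac_replicated = sum(out$replicated) / n_all,
    percent_same_direction = 100 * sum(out$same_direction) / n_all,
    percent_replicated = 100 * sum(out$replicated) / n_all)
  list(table = out[], summary = summary)
}

#' Replication percentage from counts
#'
#' `100 * n_replicated / n_discovery`, the convention that keeps every
#' discovery DMR in the denominator.
#'
#' @param n_replicated replicated probes.
#' @param n_discovery all discovery probes.
#' @return percentage.
#' @export
replication_percent <- function(n_replicated, n_discovery) {
  100 * n_replicated / n_discovery
}
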