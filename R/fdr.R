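# Permutation-based FDR. FDR(t) = (mean count of permuted p-values <= t
# across replicates) / (count of observed p-values <= t), evaluated on the
# observed p grid, then made monotone non-decreasing in t (step-up
# monotonization: FDR*(t) = min over t' >= t of FDR(t')). The reported 5%
# threshold is the largest observed t with FDR*(t) <= alpha.

#' Permutation FDR curve and threshold
#'
#' @param obs_p observed p-values (one per tested unit).
#' @param perm_p list of permuted p-value vectors, one per replicate (each
#'   from the same selection rule as `obs_p`, e.g. best SNP per probe).
#' @param alpha nominal FDR level (default 0.05).
#' @return list with `curve` (data.table: `p_threshold`, `n_obs`,
#'   `mean_n_perm`, `fdr_raw`, `fdr`), `threshold` (largest p with
#'   FDR <= alpha; `NA` with attribute `undefined` if no threshold attains
#'   it), `n_significant`.
#' @export
permutation_fdr <- function(obs_p, perm_p, alpha = 0.05) {
  if (!length(perm_p)) stop_twinewas("need at least one permutation replicate")
  obs_p <- obs_p[!is.na(obs_p)]
  grid <- sort(unique(obs_p))
  n_obs <- findInterval(grid, sort(obs_p))
  perm_sorted <- lapply(perm_p, function(p) sort(p[!is.na(p)]))
  mean_perm <- rowMeans(vapply(perm_sorted, function(sp)
    findInterval(grid, sp), numeric(length(grid))))
  fdr_raw <- mean_perm / pmax(n_obs, 1L)
  fdr <- rev(cummin(rev(fdr_raw)))
  curve <- data.table::data.table(p_threshold = grid, n_obs = n_obs,
                                  mean_n_perm = mean_perm,
                                  fdr_raw = fdr_raw, fdr = fdr)
  ok <- which(fdr <= alpha)
  if (length(ok)) {
    threshold <- grid[max(ok)]
    n_sig <- n_obs[max(ok)]
  } else {
    threshold <- NA_real_
    attr(threshold, "undefined") <- TRUE
    n_sig <- 0L
  }
  list(curve = curve, threshold = threshold, n_significant = n_sig)
}

# Family-preserving permutation of methylation columns: family blocks are
# reassigned among families of the same size (and, for complete pairs, the
# same zygosity), co-twins moving together; everything attached to the
# individual (trait, covariates, missingness) stays in place. Size-1 units
# (singletons and lone co-twins) form a single stratum. Returns a
# permutation of `ids`: sample i receives the methylation column of
# ids[perm[i]].
family_permutation <- function(cohort, ids) {
  co <- as.data.table(cohort)[match(ids, individual_id)]
  pos <- seq_along(ids)
  fam <- split(pos, co$family_id)
  size <- vapply(fam, length, integer(1))
  zyg <- vapply(fam, function(m) co$zygosity[m[1]], character(1))
  stratum <- ifelse(size == 1L, "size1", paste0("pair_", zyg))
  perm <- integer(length(ids))
  for (s in unique(stratum)) {
    units <- fam[stratum == s]
    if (length(units) < 3L)
      stop_twinewas("permutation stratum '", s, "' has fewer than 3 families; ",
                    "the permutation space is degenerate")
    shuffled <- sample(length(units))
    for (k in seq_along(units)) {
      src <- units[[shuffled[k]]]
      dst <- units[[k]]
      # deterministic member order within family (by individual id)
      src <- src[order(co$individual_id[src])]
      dst <- dst[order(co$individual_id[dst])]
      perm[dst] <- src
    }
  }
  perm
}
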