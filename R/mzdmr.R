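# Monozygotic-twin discordance analysis: within-pair methylation differences
# regressed on within-pair phenotype differences. MZ co-twins share genotype
# and family environment, so an association of differences points to
# environmentally mediated effects.

#' Within-pair differences for MZ twins
#'
#' Signed twin differences (lower individual id minus higher, fixed once per
#' pair and shared across probes and traits) restricted to MZ pairs whose
#' two members were assayed in the same batch. Traits observed in fewer than
#' `min_pairs` complete pairs are excluded and logged.
#'
#' @param m a `meth_set`.
#' @param phenos a `pheno_table`.
#' @param cohort a `twin_cohort`.
#' @param min_pairs minimum complete pairs per trait (default 12).
#' @return list with `d_meth` (probes x pairs), `d_pheno` (traits x pairs),
#'   `pairs` (data.table: pair_id, id1, id2, age), `excluded_traits`.
#' @export
pair_differences <- function(m, phenos, cohort, min_pairs = 12L) {
  ids <- intersect(cohort$individual_id, colnames(m$betas))
  mzp <- .twin_pairs(cohort, ids, "MZ", same_batch = TRUE)
  if (!nrow(mzp)) stop_twinewas("no same-batch MZ pairs available")
  co <- as.data.table(cohort)
  d_meth <- m$betas[, mzp$id1, drop = FALSE] - m$betas[, mzp$id2, drop = FALSE]
  colnames(d_meth) <- mzp$family_id
  d_pheno <- NULL
  excluded <- character(0)
  if (!is.null(phenos)) {
    pv <- phenos$values
    d_pheno <- matrix(NA_real_, nrow(pv), nrow(mzp),
                      dimnames = list(rownames(pv), mzp$family_id))
    for (k in seq_len(nrow(mzp))) {
      if (mzp$id1[k] %in% colnames(pv) && mzp$id2[k] %in% colnames(pv))
        d_pheno[, k] <- pv[, mzp$id1[k]] - pv[, mzp$id2[k]]
    }
    n_complete <- rowSums(!is.na(d_pheno))
    excluded <- rownames(d_pheno)[n_complete < min_pairs]
    if (length(excluded))
      message("excluding trait(s) with < ", min_pairs, " complete pairs: ",
              paste(excluded, collapse = ", "))
    d_pheno <- d_pheno[n_complete >= min_pairs, , drop = FALSE]
  }
  pairs <- data.table::data.table(
    pair_id = mzp$family_id, id1 = mzp$id1, id2 = mzp$id2,
    age = co$age[match(mzp$id1, co$individual_id)])
  list(d_meth = d_meth, d_pheno = d_pheno, pairs = pairs,
       excluded_traits = excluded)
}

# F-test p for d_meth ~ d_pheno (+ age), via the partial F against the
# model without d_pheno. For the uncorrected analysis this equals the
# overall-regression F-test.
.mz_ftest <- function(dm, dp, age = NULL, intercept = TRUE) {
  ok <- !is.na(dm) & !is.na(dp)
  if (!is.null(age)) ok <- ok & !is.na(age)
  dm <- dm[ok]; dp <- dp[ok]
  n <- length(dm)
  X0 <- if (intercept) matrix(1, n, 1) else matrix(numeric(0), n, 0)
  if (!is.null(age)) X0 <- cbind(X0, age[ok])
  X1 <- cbind(X0, dp)
  rss <- function(X) {
    if (!ncol(X)) return(sum(dm^2))
    sum(lm.fit(X, dm)$residuals^2)
  }
  r0 <- rss(X0); r1 <- rss(X1)
  df2 <- n - ncol(X1)
  if (df2 <= 0) return(c(beta = NA_real_, se = NA_real_, p = NA_real_))
  f <- lm.fit(X1, dm)
  beta <- f$coefficients["dp"]
  sigma2 <- r1 / df2
  XtXinv <- chol2inv(chol(crossprod(X1)))
  se <- sqrt(sigma2 * XtXinv[ncol(X1), ncol(X1)])
  fstat <- (r0 - r1) / 1 / sigma2
  p <- pf(fstat, 1, df2, lower.tail = FALSE)
  if (p == 0) p <- .Machine$double.xmin   # perfect fit underflow, flagged min
  c(beta = unname(beta), se = se, p = p)
}

#' MZ-discordance DMR scan
#'
#' Per probe, ordinary linear regression of methylation within-pair
#' differences on phenotype within-pair differences, with the p-value from
#' the F statistic (the partial F of the phenotype-difference term, which
#' for the uncorrected model equals the overall regression F). The
#' age-corrected variant includes the shared pair age as a covariate in both
#' models. Permutation FDR shuffles the pairing of phenotype differences
#' against methylation differences.
#'
#' @param diffs result of [pair_differences()].
#' @param trait trait name (row of `diffs$d_pheno`).
#' @param adjust_age include pair age as covariate (default `FALSE`).
#' @param n_perm permutation replicates for the FDR (default 100; 0 skips).
#' @param seed RNG seed.
#' @param alpha nominal FDR (default 0.05).
#' @param intercept include an intercept (default `TRUE`).
#' @return list with `result` (data.table: probe_id, trait, beta, se, p,
#'   direction, fdr_significant), `fdr` (curve/threshold or `NULL`),
#'   `n_pairs`.
#' @export
mz_dmr_scan <- function(diffs, trait, adjust_age = FALSE, n_perm = 100L,
                        seed = 1L, alpha = 0.05, intercept = TRUE) {
  if (is.null(diffs$d_pheno) || !trait %in% rownames(diffs$d_pheno))
    stop_twinewas("trait '", trait, "' not available in the pair differences")
  dp <- diffs$d_pheno[trait, ]
  if (sum(!is.na(dp)) < 12L)
    stop_twinewas("fewer than 12 complete pairs for trait ", trait)
  if (var(dp, na.rm = TRUE) == 0)
    stop_twinewas("phenotype differences for '", trait, "' have zero variance")
  age <- if (adjust_age) diffs$pairs$age else NULL
  scan_once <- function(dp_vec) {
    t(apply(diffs$d_meth, 1, .mz_ftest, dp = dp_vec, age = age,
            intercept = intercept))
  }
  obs <- scan_once(dp)
  res <- data.table::data.table(
    probe_id = rownames(diffs$d_meth), trait = trait,
    beta = obs[, "beta"], se = obs[, "se"], p = obs[, "p"])
  res[, direction := ifelse(beta >= 0, "hyper", "hypo")]

  fdr <- NULL
  if (n_perm >= 1L) {
    ok <- which(!is.na(dp))
    perm_p <- with_seed(seed, lapply(seq_len(n_perm), function(r) {
      dpp <- dp
      dpp[ok] <- dp[ok][sample(length(ok))]
      scan_once(dpp)[, "p"]
    }))
    fdr <- permutation_fdr(res$p, perm_p, alpha = alpha)
    thr <- fdr$threshold
    res[, fdr_significant := !is.na(thr) & p <= thr]
  }
  list(result = res[], fdr = fdr, n_pairs = sum(!is.na(dp)))
}

#' Monte-Carlo power of the MZ-discordance test
#'
#' Draws `n_sim` sets of `n_pairs` bivariate-normal difference pairs at
#' correlation `r`, applies the same regression F-test as [mz_dmr_scan()],
#' and reports the fraction of p-values below `alpha` with an exact binomial
#' 95 percent CI. An analytic Fisher-z approximation is reported alongside.
#'
#' @param r true correlation (|r| < 1).
#' @param n_pairs number of MZ pairs (>= 3).
#' @param alpha significance level in (0,1).
#' @param n_sim Monte-Carlo replicates (default 10000).
#' @param seed RNG seed.
#' @return list with `power`, `ci_low`, `ci_high`, `power_fisher_z`,
#'   `n_sim`.
#' @export
mz_power_estimate <- function(r, n_pairs, alpha, n_sim = 10000L, seed = 1L) {
  if (abs(r) >= 1) stop_twinewas("|r| must be below 1")
  if (n_pairs < 3L) stop_twinewas("need at least 3 pairs")
  if (alpha <= 0 || alpha >= 1) stop_twinewas("alpha must be in (0,1)")
  hits <- with_seed(seed, {
    sum(vapply(seq_len(n_sim), function(s) {
      x <- rnorm(n_pairs)
      y <- r * x + sqrt(1 - r^2) * rnorm(n_pairs)
      .mz_ftest(y, x)["p"] < alpha
    }, logical(1)))
  })
  ci <- binom.test(hits, n_sim)$conf.int
  z <- atanh(r) * sqrt(n_pairs - 3)
  zcrit <- qnorm(1 - alpha / 2)
  pow_z <- pnorm(-zcrit - z) + pnorm(z - zcrit)
  list(power = hits / n_sim, ci_low = ci[1], ci_high = ci[2],
       power_fisher_z = pow_z, n_sim = n_sim)
}
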