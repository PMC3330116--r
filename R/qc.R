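#' Probe quality control
#'
#' Drops probes that do not map uniquely and/or probes with any missing beta
#' value, and reports the autosomal / X-chromosome split of the retained set.
#'
#' @param m a `meth_set`.
#' @param require_unique drop probes whose `unique_mapping` flag is 0
#'   (default `TRUE`).
#' @param drop_missing drop probes with any missing beta (default `TRUE`).
#' @return the filtered `meth_set`, with attribute `qc_report`: a list with
#'   counts `n_in`, `n_dropped_nonunique`, `n_dropped_missing`, `n_out`,
#'   `n_autosomal`, `n_x`.
#' @export
probe_qc <- function(m, require_unique = TRUE, drop_missing = TRUE) {
  stopifnot(inherits(m, "meth_set"))
  ann <- m$annotation
  n_in <- nrow(ann)
  keep <- rep(TRUE, n_in)
  n_nonuniq <- 0L
  if (require_unique) {
    bad <- ann$unique_mapping == 0
    n_nonuniq <- sum(bad)
    keep <- keep & !bad
  }
  n_missing <- 0L
  if (drop_missing) {
    has_na <- rowSums(is.na(m$betas)) > 0
    n_missing <- sum(has_na & keep)
    keep <- keep & !has_na
  }
  if (!any(keep)) stop_twinewas("probe_qc removed every probe")
  out <- methylation_matrix(m$betas[keep, , drop = FALSE], ann[keep])
  attr(out, "qc_report") <- list(
    n_in = n_in,
    n_dropped_nonunique = n_nonuniq,
    n_dropped_missing = n_missing,
    n_out = sum(keep),
    n_autosomal = sum(out$annotation$autosomal),
    n_x = sum(!out$annotation$autosomal))
  out
}

#' PCA covariate screen
#'
#' Standardizes each probe to zero mean and unit variance, extracts the first
#' `n_pcs` principal components over samples, and tests each component against
#' each covariate (age, chip, chip position by default) with a one-way linear
#' model F-test. Covariates associated with PC1 or PC2 at `alpha` are flagged
#' as confounders to include as fixed effects downstream.
#'
#' @param m a `meth_set` (probes with missing or constant values are skipped).
#' @param cohort a `twin_cohort` covering the methylation samples.
#' @param n_pcs number of leading components to test (default 5).
#' @param covariates named list mapping covariate name to the cohort column;
#'   default `age`, `chip_id` (categorical), `chip_position`.
#' @param alpha flagging level for PC1/PC2 association (default 0.05).
#' @return data.table with columns `pc`, `covariate`, `p`, `degenerate`,
#'   `flagged`; attribute `var_explained` gives the PC variance fractions.
#' @export
pca_covariate_screen <- function(m, cohort, n_pcs = 5L,
                                 covariates = c("age", "chip_id", "chip_position"),
                                 alpha = 0.05) {
  stopifnot(inherits(m, "meth_set"))
  ids <- intersect(cohort$individual_id, colnames(m$betas))
  if (n_pcs >= length(ids))
    stop_twinewas("n_pcs (", n_pcs, ") must be below the sample count (",
                  length(ids), ")")
  b <- m$betas[, ids, drop = FALSE]
  b <- b[rowSums(is.na(b)) == 0, , drop = FALSE]
  sds <- apply(b, 1, sd)
  b <- b[sds > 0, , drop = FALSE]
  z <- t(scale(t(b)))                    # probe-wise N(0,1) standardization
  pc <- prcomp(t(z), center = TRUE, scale. = FALSE)
  scores <- pc$x[, seq_len(n_pcs), drop = FALSE]
  co <- as.data.table(cohort)[match(ids, individual_id)]

  res <- data.table::rbindlist(lapply(seq_len(n_pcs), function(k) {
    data.table::rbindlist(lapply(covariates, function(cv) {
      x <- co[[cv]]
      degen <- length(unique(x[!is.na(x)])) < 2L
      p <- NA_real_
      if (!degen) {
        xx <- if (is.character(x) || is.logical(x)) factor(x) else x
        fit <- lm(scores[, k] ~ xx)
        a <- anova(fit)
        p <- a[["Pr(>F)"]][1]
      }
      data.table::data.table(pc = k, covariate = cv, p = p, degenerate = degen)
    }))
  }))
  res[, flagged := !degenerate & pc <= 2L & !is.na(p) & p < alpha]
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  data.table::setattr(res, "var_explained", ve[seq_len(n_pcs)])
  res[]
}
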