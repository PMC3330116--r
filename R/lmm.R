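# R interface to the twin variance-components engine (src/twin_lmm.cpp).
# The model has fixed effects plus two random intercepts: family (variance
# s2f, shared by all co-twins) and MZ pair (variance s2z, shared only within
# MZ pairs), so cov(co-twins) = s2f + s2z * 1[MZ]. Estimation is ML (for
# likelihood-ratio tests) or REML (for reporting); fits are deterministic
# (method-of-moments start, Nelder-Mead, tolerance 1e-8, <= 200 iterations).

# Orthogonal pair rotation for a set of analysis samples. Returns the output
# row classes and the index/coefficient scheme used to rotate both the
# response matrix (samples in columns) and the design matrix (samples in
# rows).
build_twin_transform <- function(cohort, ids) {
  co <- as.data.table(cohort)[match(ids, individual_id)]
  if (anyNA(co$individual_id))
    stop_twinewas("analysis ids missing from the sample sheet")
  pos <- seq_along(ids)
  fam <- split(pos, co$family_id)
  i1 <- integer(0); i2 <- integer(0); type <- integer(0)
  for (members in fam) {
    members <- members[order(co$individual_id[members])]
    zyg <- co$zygosity[members[1]]
    if (length(members) == 2L) {
      st <- if (zyg == "MZ") 4L else 3L
      i1 <- c(i1, members[1], members[1])
      i2 <- c(i2, members[2], members[2])
      type <- c(type, st, 2L)            # sum row then diff row
    } else {
      i1 <- c(i1, members[1]); i2 <- c(i2, NA_integer_)
      type <- c(type, if (zyg == "MZ") 1L else 0L)
    }
  }
  est_fam <- any(type %in% c(3L, 4L))
  est_mz <- any(type == 4L) && any(type %in% c(0L, 3L))
  list(ids = ids, i1 = i1, i2 = i2, type = type,
       est_fam = est_fam, est_mz = est_mz,
       n = length(type))
}

# rotate matrix with samples in columns (probes x samples)
rotate_cols <- function(M, tr) {
  out <- matrix(NA_real_, nrow(M), tr$n)
  s <- 1 / sqrt(2)
  pair <- !is.na(tr$i2)
  sumrow <- pair & tr$type %in% c(3L, 4L)
  diffrow <- pair & tr$type == 2L
  out[, !pair] <- M[, tr$i1[!pair], drop = FALSE]
  out[, sumrow] <- s * (M[, tr$i1[sumrow], drop = FALSE] +
                        M[, tr$i2[sumrow], drop = FALSE])
  out[, diffrow] <- s * (M[, tr$i1[diffrow], drop = FALSE] -
                         M[, tr$i2[diffrow], drop = FALSE])
  out
}

# rotate design matrix with samples in rows (samples x p)
rotate_rows <- function(X, tr) t(rotate_cols(t(X), tr))

# Fixed-effect design from cohort columns + extras; drops aliased columns.
build_design <- function(cohort, ids, covariates = c("chip_id", "chip_position"),
                         extra = NULL) {
  co <- as.data.table(cohort)[match(ids, individual_id)]
  df <- data.frame(row.names = ids)
  for (cv in covariates) {
    x <- co[[cv]]
    df[[cv]] <- if (is.character(x) || is.logical(x)) factor(x) else x
  }
  if (!is.null(extra)) for (nm in names(extra)) df[[nm]] <- extra[[nm]]
  X <- model.matrix(~., df)
  qrX <- qr(X)
  aliased <- character(0)
  if (qrX$rank < ncol(X)) {
    drop <- qrX$pivot[-seq_len(qrX$rank)]
    aliased <- colnames(X)[drop]
    warning("dropping aliased fixed-effect column(s): ",
            paste(aliased, collapse = ", "), call. = FALSE)
    X <- X[, -drop, drop = FALSE]
  }
  attr(X, "aliased") <- aliased
  X
}

#' Fit the twin linear mixed model
#'
#' Fits `response ~ fixed effects` with family and MZ-pair random intercepts
#' by profiled ML or REML on orthogonally rotated twin blocks. Complete-case
#' analysis: rows with a missing response or covariate are dropped. When the
#' design makes a component unidentifiable (e.g. only MZ pairs, where the
#' family and pair variances are aliased), the aliased component is fixed at
#' zero and flagged.
#'
#' @param response named numeric vector (names are individual ids).
#' @param cohort a `twin_cohort`.
#' @param covariates cohort columns used as fixed effects (default chip and
#'   chip position).
#' @param extra named list of additional fixed-effect vectors aligned with
#'   `response` (e.g. `list(age = ...)`).
#' @param mode `"ML"` (default, required for [lrt_compare()]) or `"REML"`.
#' @return object of class `twin_lmm_fit`: list with `coefficients`
#'   (data.table: term, estimate, se, z, p_wald), `varcomp` (`s2f`, `s2z`,
#'   `s2e`), `logLik`, `n_used`, `converged`, `aliased_terms`,
#'   `varcomp_aliased`, `mode`, `ids`.
#' @export
fit_lmm <- function(response, cohort, covariates = c("chip_id", "chip_position"),
                    extra = NULL, mode = c("ML", "REML")) {
  mode <- match.arg(mode)
  ids <- names(response)
  if (is.null(ids)) stop_twinewas("response must be named by individual id")
  keep <- !is.na(response)
  if (!is.null(extra))
    for (e in extra) keep <- keep & !is.na(e)
  ids <- ids[keep]
  y <- response[keep]
  extra <- if (!is.null(extra)) lapply(extra, function(e) e[keep])
  co <- as.data.table(cohort)
  if (!length(intersect(ids, co$individual_id)))
    stop_twinewas("no analysis samples present in the cohort (0 families)")
  X <- build_design(cohort, ids, covariates, extra)
  if (length(y) < ncol(X) + 3L)
    stop_twinewas("need at least ", ncol(X) + 3L, " complete cases, got ",
                  length(y))
  tr <- build_twin_transform(cohort, ids)
  Xt <- rotate_rows(X, tr)
  yt <- as.numeric(rotate_cols(matrix(y, nrow = 1), tr))
  fit <- cpp_twin_fit(Xt, yt, tr$type, reml = (mode == "REML"),
                      est_fam = tr$est_fam, est_mz = tr$est_mz)
  coefs <- data.table::data.table(
    term = colnames(X),
    estimate = as.numeric(fit$beta),
    se = as.numeric(fit$se))
  coefs[, z := estimate / se]
  coefs[, p_wald := 2 * pnorm(-abs(z))]
  structure(list(
    coefficients = coefs,
    varcomp = c(s2f = fit$s2f, s2z = fit$s2z, s2e = fit$s2e),
    logLik = fit$loglik,
    n_used = length(y),
    converged = as.logical(fit$converged),
    aliased_terms = attr(X, "aliased"),
    varcomp_aliased = c(fam = !tr$est_fam, mz = !tr$est_mz),
    mode = mode, ids = ids), class = "twin_lmm_fit")
}

#' @export
print.twin_lmm_fit <- function(x, ...) {
  cat("twin LMM (", x$mode, "), n =", x$n_used, ", logLik =",
      format(x$logLik, digits = 6), "\n")
  print(x$coefficients)
  cat("variance components:", paste(names(x$varcomp),
      format(x$varcomp, digits = 4), sep = "=", collapse = "  "), "\n")
  invisible(x)
}

#' Likelihood-ratio test of nested twin LMM fits
#'
#' `2 * (logLik_full - logLik_null)` (floored at zero) against the upper tail
#' of a chi-square with degrees of freedom equal to the difference in fixed
#' parameter count. Both fits must be ML on the same rows.
#'
#' @param full,null `twin_lmm_fit` objects from [fit_lmm()] with `mode="ML"`.
#' @return list with `statistic`, `df`, `p`.
#' @export
lrt_compare <- function(full, null) {
  stopifnot(inherits(full, "twin_lmm_fit"), inherits(null, "twin_lmm_fit"))
  if (full$mode != "ML" || null$mode != "ML")
    stop_twinewas("LRT requires ML fits")
  if (full$n_used != null$n_used || !identical(sort(full$ids), sort(null$ids)))
    stop_twinewas("full and null fits use different rows")
  df <- nrow(full$coefficients) - nrow(null$coefficients)
  if (df <= 0 ||
      !all(null$coefficients$term %in% full$coefficients$term))
    stop_twinewas("null model is not nested in the full model")
  stat <- max(0, 2 * (full$logLik - null$logLik))
  list(statistic = stat, df = df, p = pchisq(stat, df, lower.tail = FALSE))
}

# Internal batch association driver shared by the EWAS, meQTL and GWAS scans.
#
# Y: responses, units x samples (rows = probes or a single trait)
# g: matrix of tested predictors, samples x K
# tests: data.table(iy, ig) 1-based, grouped by iy
# Returns data.table(iy, ig, beta, se, p, ll_full, ll_null, converged).
twin_assoc_scan <- function(Y, cohort, ids, g, tests,
                            covariates = c("chip_id", "chip_position"),
                            extra = NULL) {
  X0 <- build_design(cohort, ids, covariates, extra)
  tr <- build_twin_transform(cohort, ids)
  Yt <- rotate_cols(Y[, ids, drop = FALSE], tr)
  X0t <- rotate_rows(X0, tr)
  Gt <- rotate_rows(g[ids, , drop = FALSE], tr)
  o <- order(tests$iy)
  tests <- tests[o]
  res <- cpp_twin_assoc(t(Yt), X0t, Gt,
                        as.integer(tests$iy - 1L), as.integer(tests$ig - 1L),
                        tr$type, est_fam = tr$est_fam, est_mz = tr$est_mz)
  # Bartlett-type small-sample factor: the ML likelihood-ratio statistic for
  # one added fixed term behaves like (n/(n-p)) * F at modest n, so the raw
  # chi-square reference is anticonservative when the chip design is wide.
  n <- tr$n
  p_full <- ncol(X0t) + 1L
  stat <- pmax(0, 2 * (res$ll_full - res$ll_null)) * (n - p_full) / n
  out <- data.table::data.table(
    iy = tests$iy, ig = tests$ig,
    beta = as.numeric(res$beta), se = as.numeric(res$se),
    p = pchisq(stat, df = 1, lower.tail = FALSE),
    ll_full = as.numeric(res$ll_full), ll_null = as.numeric(res$ll_null),
    s2f = as.numeric(res$s2f), s2z = as.numeric(res$s2z),
    s2e = as.numeric(res$s2e),
    converged = as.logical(res$converged))
  out
}
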