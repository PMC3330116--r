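#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run an expression with a temporary RNG seed
#'
#' Restores the caller's RNG state on exit so generators are pure functions of
#' (config, seed).
#' @noRd
with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  expr
}

#' Derive a child seed, kept within 32-bit integer range
#' @noRd
child_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 1103L + k * 12347L) %% 2147483629)
}

stop_twinewas <- function(...) stop(..., call. = FALSE)

#' Rank-based inverse-normal transform
#'
#' Maps values to normal scores via the Blom offset `(r - 3/8)/(n + 1/4)`,
#' where `r` is the (average, for ties) rank and `n` the number of non-missing
#' values. Missing values stay missing; the transform is invariant to any
#' strictly monotone transform of the input.
#'
#' @param x numeric vector (may contain `NA`).
#' @return numeric vector of normal scores, same length as `x`. If all
#'   non-missing values are identical the result is all-`NA` with attribute
#'   `degenerate = TRUE`.
#' @examples
#' inverse_normal_transform(c(1, 2, 3))
#' @export
inverse_normal_transform <- function(x) {
  ok <- !is.na(x)
  n <- sum(ok)
  if (n < 3L) stop_twinewas("inverse_normal_transform() needs >= 3 non-missing values")
  out <- rep(NA_real_, length(x))
  if (length(unique(x[ok])) == 1L) {
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  r <- rank(x[ok], ties.method = "average")
  out[ok] <- qnorm((r - 3 / 8) / (n + 1 / 4))
  out
}
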