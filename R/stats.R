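#' Statistical primitives with an UNDEFINED-safe contract
#'
#' Thin wrappers around the standard tests used throughout the pipeline.
#' Instead of throwing on degenerate input (too few observations,
#' zero-variance groups, constant rank vectors) they return a result
#' flagged `undefined`, so a single pathological patient never kills a
#' cohort run. Two-sided p-values throughout; no multiple-testing
#' correction by default (a Bonferroni divisor can be applied by the
#' caller via `alpha`).
#'
#' @param a,b numeric vectors (group ON/OFF values, or paired vectors).
#' @param alpha significance level (default 0.05).
#' @param var_equal use the pooled-variance Student variant instead of
#'   Welch (default `FALSE`).
#' @return list of class `swa_test` with fields `statistic`, `p_value`,
#'   `n1`, `n2`, `alpha`, `significant` (`p < alpha`), `undefined`,
#'   `reason`, `method`.
#' @name swa_stats
NULL

new_swa_test <- function(statistic = NA_real_, p_value = NA_real_,
                         n1 = NA_integer_, n2 = NA_integer_, alpha = 0.05,
                         undefined = FALSE, reason = NA_character_,
                         method = "welch") {
  structure(list(statistic = statistic, p_value = p_value,
                 n1 = as.integer(n1), n2 = as.integer(n2), alpha = alpha,
                 significant = isTRUE(!undefined & p_value < alpha),
                 undefined = undefined, reason = reason, method = method),
            class = "swa_test")
}

undefined_test <- function(reason, method, n1 = NA, n2 = NA, alpha = 0.05) {
  new_swa_test(undefined = TRUE, reason = reason, method = method,
               n1 = n1, n2 = n2, alpha = alpha)
}

#' @export
print.swa_test <- function(x, ...) {
  if (x$undefined) {
    cat(sprintf("<swa_test %s> UNDEFINED: %s\n", x$method, x$reason))
  } else {
    cat(sprintf("<swa_test %s> statistic = %.4g, p = %.4g (n1 = %d, n2 = %d)%s\n",
                x$method, x$statistic, x$p_value, x$n1, x$n2,
                if (x$significant) " *" else ""))
  }
  invisible(x)
}

#' @rdname swa_stats
#' @export
welch_test <- function(a, b, alpha = 0.05, var_equal = FALSE) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  method <- if (var_equal) "student" else "welch"
  if (length(a) < 2 || length(b) < 2)
    return(undefined_test("fewer than 2 observations in a group", method,
                          length(a), length(b), alpha))
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    if (a[1] == b[1])
      return(new_swa_test(0, 1, length(a), length(b), alpha, method = method))
    return(undefined_test("both groups constant with different values",
                          method, length(a), length(b), alpha))
  }
  tt <- stats::t.test(a, b, var.equal = var_equal)
  new_swa_test(unname(tt$statistic), tt$p.value, length(a), length(b), alpha,
               method = method)
}

#' @rdname swa_stats
#' @export
paired_test <- function(a, b, alpha = 0.05) {
  assert_that(length(a) == length(b),
              "paired_test: lengths differ (%d vs %d)", length(a), length(b))
  keep <- !is.na(a) & !is.na(b)
  d <- a[keep] - b[keep]
  n <- length(d)
  if (n < 2)
    return(undefined_test("fewer than 2 complete pairs", "paired", n, n, alpha))
  if (stats::var(d) == 0) {
    if (d[1] == 0)
      return(new_swa_test(0, 1, n, n, alpha, method = "paired"))
    return(undefined_test("zero-variance non-zero differences", "paired",
                          n, n, alpha))
  }
  tt <- stats::t.test(d)
  new_swa_test(unname(tt$statistic), tt$p.value, n, n, alpha,
               method = "paired")
}

#' @rdname swa_stats
#' @param x,y numeric vectors for the rank correlation.
#' @export
spearman_rho <- function(x, y, alpha = 0.05) {
  assert_that(length(x) == length(y),
              "spearman_rho: lengths differ (%d vs %d)", length(x), length(y))
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3)
    return(undefined_test("fewer than 3 complete pairs", "spearman", n, n,
                          alpha))
  if (stats::var(x) == 0 || stats::var(y) == 0)
    return(undefined_test("constant vector", "spearman", n, n, alpha))
  rho <- stats::cor(x, y, method = "spearman")
  p <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                        exact = FALSE)$p.value)
  new_swa_test(rho, p, n, n, alpha, method = "spearman")
}
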