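#' Two-sided Mann-Whitney U test with Bonferroni adjustment
#'
#' Compares two independent samples with the Mann-Whitney U (Wilcoxon
#' rank-sum) test. The exact null distribution is used when
#' `n1 + n2 <= 16` and there are no ties; otherwise the normal
#' approximation with tie correction and continuity correction is used. The
#' two-sided p-value doubles the smaller tail and is capped at 1. The
#' Bonferroni-adjusted p-value is `min(1, family_size * p)`.
#'
#' @param x,y numeric vectors (both non-empty).
#' @param family_size number of comparisons in the Bonferroni family
#'   (integer >= 1).
#' @return A list of class `mwu_result`: `U` (rank-sum statistic for `x`),
#'   `p`, `p_adj`, `n1`, `n2`, `median_x`, `median_y`, `exact`.
#' @export
mann_whitney <- function(x, y, family_size = 1L) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) == 0L || length(y) == 0L) {
    stop("both groups must be non-empty", call. = FALSE)
  }
  if (anyNA(x) || anyNA(y)) stop("missing values in input", call. = FALSE)
  check_number(family_size, "family_size", lower = 1)
  n1 <- length(x); n2 <- length(y)
  ties <- anyDuplicated(c(x, y)) > 0L
  exact <- (n1 + n2) <= 16L && !ties
  res <- suppressWarnings(
    wilcox.test(x, y, alternative = "two.sided", exact = exact,
                correct = TRUE)
  )
  U <- unname(res$statistic)
  stopifnot(U >= 0, U <= n1 * n2)
  p <- min(1, res$p.value)
  structure(
    list(U = U, p = p, p_adj = min(1, family_size * p),
         n1 = n1, n2 = n2,
         median_x = median(x), median_y = median(y), exact = exact),
    class = "mwu_result"
  )
}

#' @export
print.mwu_result <- function(x, ...) {
  cat(sprintf(
    "Mann-Whitney U = %g, n1 = %d, n2 = %d, medians %.4g / %.4g\n  %s p = %.4g (Bonferroni-adjusted %.4g)\n",
    x$U, x$n1, x$n2, x$median_x, x$median_y,
    if (x$exact) "exact" else "normal-approximation", x$p, x$p_adj))
  invisible(x)
}

#' Fisher's exact test, with Monte-Carlo p for larger tables
#'
#' For a 2x2 table the exact two-sided p-value is computed by hypergeometric
#' enumeration of margin-fixed tables. For larger tables the p-value is
#' simulated: tables are sampled uniformly over all tables with the observed
#' margins, extremeness is measured by null table probability less than or
#' equal to the observed one, and the estimate is
#' `(1 + n_extreme) / (1 + n_sim)`.
#'
#' @param table non-negative integer matrix (r x c) with no zero row or
#'   column margin.
#' @param n_sim number of simulated tables for r x c tables (default 1e5).
#' @param seed optional integer seed for the Monte-Carlo branch; the global
#'   RNG state is restored afterwards.
#' @param force_monte_carlo simulate the p-value even for a 2x2 table
#'   (mainly for checking Monte-Carlo convergence against the exact
#'   branch).
#' @return A list of class `contingency_result`: `table`, `p`,
#'   `method` (`"exact2x2"` or `"monte_carlo"`), and for the Monte-Carlo
#'   branch `n_sim` and `seed`.
#' @export
fisher_exact <- function(table, n_sim = 1e5, seed = NULL,
                         force_monte_carlo = FALSE) {
  table <- as.matrix(table)
  if (!is.numeric(table) || any(is.na(table)) || any(table < 0) ||
      any(table != round(table))) {
    stop("`table` must contain non-negative integer counts", call. = FALSE)
  }
  if (nrow(table) < 2L || ncol(table) < 2L) {
    stop("`table` must be at least 2 x 2", call. = FALSE)
  }
  storage.mode(table) <- "integer"
  if (any(rowSums(table) == 0L) || any(colSums(table) == 0L)) {
    stop("test undefined: zero row or column margin", call. = FALSE)
  }
  if (nrow(table) == 2L && ncol(table) == 2L && !force_monte_carlo) {
    p <- fisher.test(table)$p.value
    out <- list(table = table, p = min(1, p), method = "exact2x2",
                n_sim = NULL, seed = NULL)
  } else {
    check_number(n_sim, "n_sim", lower = 1)
    p <- with_seed(
      seed,
      fisher.test(table, simulate.p.value = TRUE, B = as.integer(n_sim))$p.value
    )
    out <- list(table = table, p = min(1, p), method = "monte_carlo",
                n_sim = as.integer(n_sim), seed = seed)
  }
  stopifnot(out$p > 0, out$p <= 1)
  structure(out, class = "contingency_result")
}

#' @export
print.contingency_result <- function(x, ...) {
  cat(sprintf("Fisher's exact test (%s): p = %.4g\n",
              if (x$method == "exact2x2") "exact 2x2"
              else sprintf("Monte Carlo, %d simulated tables", x$n_sim),
              x$p))
  print(x$table)
  invisible(x)
}
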