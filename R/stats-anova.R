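#' Unbalanced two-way ANOVA with Type III sums of squares
#'
#' Fits `values ~ A * B` with sum-to-zero contrasts and computes Type III
#' sums of squares: each effect is tested by comparing the full model to the
#' model with that effect's columns removed, in the presence of all other
#' effects. Appropriate for unbalanced designs such as a sex x tissue
#' expression panel; on balanced designs Type III equals sequential SS.
#'
#' @param values numeric response vector.
#' @param factor_a,factor_b factors (or coercible) with at least two levels
#'   each; every crossed cell must contain at least one observation.
#' @param names_ab length-2 character vector naming the effects in the
#'   output (default `c("A", "B")`).
#' @return A list of class `anova_type3` with a data.frame `table`
#'   (rows `A`, `B`, `A:B`, `Residuals`; columns `sum_sq`, `df`, `F`, `p`)
#'   and a `degenerate` flag set when the residual sum of squares is zero.
#' @export
two_way_anova_type3 <- function(values, factor_a, factor_b,
                                names_ab = c("A", "B")) {
  values <- as.numeric(values)
  fa <- droplevels(as.factor(factor_a))
  fb <- droplevels(as.factor(factor_b))
  if (length(values) != length(fa) || length(values) != length(fb)) {
    stop("`values` and the factors must have equal length", call. = FALSE)
  }
  if (anyNA(values) || anyNA(fa) || anyNA(fb)) {
    stop("missing values in input", call. = FALSE)
  }
  if (nlevels(fa) < 2L) stop("factor A has a single level", call. = FALSE)
  if (nlevels(fb) < 2L) stop("factor B has a single level", call. = FALSE)
  cell_n <- table(fa, fb)
  if (any(cell_n == 0L)) {
    empty <- which(cell_n == 0L, arr.ind = TRUE)
    cells <- apply(empty, 1L, function(i) {
      paste0(levels(fa)[i[1L]], ":", levels(fb)[i[2L]])
    })
    stop("empty cell(s) in the two-way design: ",
         paste(cells, collapse = ", "),
         "; pre-filter or rebalance the data", call. = FALSE)
  }

  dat <- data.frame(.y = values, .a = fa, .b = fb)
  fit <- lm(.y ~ .a * .b, data = dat,
            contrasts = list(.a = "contr.sum", .b = "contr.sum"))
  rss_full <- sum(residuals(fit)^2)
  degenerate <- rss_full <= max(.Machine$double.eps * sum(values^2),
                                .Machine$double.eps)
  effect_names <- c(names_ab[1L], names_ab[2L],
                    paste0(names_ab[1L], ":", names_ab[2L]), "Residuals")
  if (!degenerate) {
    a3 <- car::Anova(fit, type = "III")
    idx <- match(c(".a", ".b", ".a:.b", "Residuals"), rownames(a3))
    tab <- data.frame(
      effect = effect_names,
      sum_sq = a3[idx, "Sum Sq"],
      df = a3[idx, "Df"],
      F = a3[idx, "F value"],
      p = a3[idx, "Pr(>F)"],
      row.names = NULL
    )
  } else {
    # zero residual variance: car::Anova refuses, but the model-comparison
    # SS are still defined; F and p are not
    X <- model.matrix(fit)
    asgn <- attr(X, "assign")
    rss_without <- function(k) {
      M <- X[, asgn != k, drop = FALSE]
      sum(qr.resid(qr(M), values)^2)
    }
    ss <- vapply(1:3, rss_without, numeric(1)) - rss_full
    df_eff <- vapply(1:3, function(k) sum(asgn == k), numeric(1))
    tab <- data.frame(
      effect = effect_names,
      sum_sq = c(ss, rss_full),
      df = c(df_eff, length(values) - ncol(X)),
      F = NA_real_,
      p = NA_real_,
      row.names = NULL
    )
  }
  stopifnot(all(tab$sum_sq >= -1e-8))
  tab$sum_sq <- pmax(tab$sum_sq, 0)
  structure(list(table = tab, fit = fit, degenerate = degenerate),
            class = "anova_type3")
}

#' @export
print.anova_type3 <- function(x, ...) {
  cat("Two-way type III ANOVA",
      if (x$degenerate) " (degenerate: zero residual variance)", "\n",
      sep = "")
  print(x$table, digits = 4)
  invisible(x)
}

#' Tukey HSD all-pairs comparisons
#'
#' One-way all-pairs comparisons via the studentized-range distribution with
#' the pooled within-group variance; unbalanced group sizes are handled with
#' the Tukey-Kramer adjustment.
#'
#' @param values numeric response vector.
#' @param groups grouping factor with >= 2 non-empty levels and pooled
#'   residual df >= 1.
#' @return A data.frame of class `tukey_pairs` with columns `group1`,
#'   `group2`, `diff` (mean of `group1` minus mean of `group2`), `p_adj`.
#' @export
tukey_hsd <- function(values, groups) {
  values <- as.numeric(values)
  g <- as.factor(groups)
  if (any(table(g) == 0L)) {
    stop("group(s) with zero observations: ",
         paste(names(which(table(g) == 0L)), collapse = ", "),
         call. = FALSE)
  }
  g <- droplevels(g)
  if (nlevels(g) < 2L) stop("need at least two groups", call. = FALSE)
  if (length(values) - nlevels(g) < 1L) {
    stop("pooled residual degrees of freedom must be >= 1", call. = FALSE)
  }
  fit <- aov(values ~ g)
  th <- TukeyHSD(fit)$g
  pair_names <- strsplit(rownames(th), "-", fixed = TRUE)
  out <- data.frame(
    group1 = vapply(pair_names, `[[`, "", 1L),
    group2 = vapply(pair_names, `[[`, "", 2L),
    diff = th[, "diff"],
    p_adj = th[, "p adj"],
    row.names = NULL
  )
  class(out) <- c("tukey_pairs", "data.frame")
  out
}

# Symmetric logical significance matrix (TRUE = significantly different)
# from tukey_hsd output, at level alpha.
pairwise_significance <- function(pairs, groups, alpha = 0.05) {
  groups <- as.character(groups)
  sig <- matrix(FALSE, length(groups), length(groups),
                dimnames = list(groups, groups))
  for (i in seq_len(nrow(pairs))) {
    s <- pairs$p_adj[i] < alpha
    sig[pairs$group1[i], pairs$group2[i]] <- s
    sig[pairs$group2[i], pairs$group1[i]] <- s
  }
  sig
}
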