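# Independent oracles used to check the statistical machinery. Each is a
# deliberately naive implementation (enumeration, projection, simulation)
# kept separate from the package code paths it validates.

# Exact two-sided Mann-Whitney p by enumerating all assignments of the
# pooled values to the first group (no ties assumed). Two-sided p doubles
# the smaller tail (including the observed point), capped at 1.
oracle_mwu <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  pooled <- c(x, y)
  u_stat <- function(a, b) sum(outer(a, b, ">"))
  u_obs <- u_stat(x, y)
  sets <- combn(n1 + n2, n1)
  us <- apply(sets, 2L, function(idx) u_stat(pooled[idx], pooled[-idx]))
  p_low <- mean(us <= u_obs)
  p_high <- mean(us >= u_obs)
  list(U = u_obs, p = min(1, 2 * min(p_low, p_high)))
}

# All r x c tables with the given margins, with their null probabilities
# P(T) = prod(row!) prod(col!) / (N! prod(cells!)).
enumerate_margin_tables <- function(row_sums, col_sums) {
  r <- length(row_sums); cc <- length(col_sums)
  tables <- list()
  fill_row <- function(tab, i, remaining_cols) {
    if (i > r) {
      if (all(remaining_cols == 0L)) tables[[length(tables) + 1L]] <<- tab
      return(invisible())
    }
    # enumerate compositions of row_sums[i] bounded by remaining_cols
    comp <- function(prefix, j, left) {
      if (j == cc) {
        if (left <= remaining_cols[cc]) {
          row <- c(prefix, left)
          tab[i, ] <- row
          fill_row(tab, i + 1L, remaining_cols - row)
        }
        return(invisible())
      }
      for (v in 0:min(left, remaining_cols[j])) comp(c(prefix, v), j + 1L, left - v)
    }
    comp(integer(), 1L, row_sums[i])
  }
  fill_row(matrix(0L, r, cc), 1L, as.integer(col_sums))
  tables
}

table_log_prob <- function(tab) {
  sum(lgamma(rowSums(tab) + 1)) + sum(lgamma(colSums(tab) + 1)) -
    lgamma(sum(tab) + 1) - sum(lgamma(tab + 1))
}

# Exact two-sided Fisher p: total probability of margin-fixed tables no
# more probable than the observed one.
oracle_fisher <- function(tab) {
  tabs <- enumerate_margin_tables(rowSums(tab), colSums(tab))
  lp <- vapply(tabs, table_log_prob, numeric(1))
  lp_obs <- table_log_prob(tab)
  sum(exp(lp[lp <= lp_obs + 1e-7]))
}

# Type III sums of squares by explicit least-squares projections: for each
# effect, the increase in residual sum of squares when that effect's
# model-matrix columns (sum-to-zero coding) are removed from the full
# two-way interaction model.
oracle_type3 <- function(values, fa, fb) {
  fa <- factor(fa); fb <- factor(fb)
  old <- options(contrasts = c("contr.sum", "contr.poly"))
  on.exit(options(old))
  X <- model.matrix(~ fa * fb)
  asgn <- attr(X, "assign")   # 0 intercept, 1 fa, 2 fb, 3 fa:fb
  rss <- function(M) {
    fit <- qr(M)
    res <- values - M %*% qr.coef(fit, values)
    sum(res^2)
  }
  rss_full <- rss(X)
  ss <- vapply(1:3, function(k) rss(X[, asgn != k, drop = FALSE]) - rss_full,
               numeric(1))
  names(ss) <- c("A", "B", "A:B")
  c(ss, Residuals = rss_full)
}

# Monte-Carlo oracle for the Tukey studentized-range adjusted p-value of
# one pair in a balanced one-way layout: simulate the distribution of
# q = range(k standard normals) / sqrt(chisq_df / df).
oracle_tukey_p <- function(q_obs, k, df, n_draws = 1e6, seed = 42) {
  withr::with_seed(seed, {
    z <- matrix(rnorm(n_draws * k), ncol = k)
    rng <- apply(z, 1L, max) - apply(z, 1L, min)
    s <- sqrt(rchisq(n_draws, df) / df)
    mean(rng / s >= q_obs)
  })
}

# Closed-form average-power oracle for the simulator in the Poisson /
# large-mean limit: per-gene two-sample t test on log2 counts with
# delta-method variance, BH threshold found as the fixed point of
# alpha = q * (pi0 * alpha + pi1 * power(alpha)).
oracle_power_poisson <- function(n_per_group, mu, fc, prop_de, fdr_q) {
  df <- 2 * n_per_group - 2
  sigma2 <- 1 / (mu * log(2)^2)          # Var log2(X), X ~ Poisson(mu)
  delta <- log2(fc)
  ncp <- delta / sqrt(2 * sigma2 / n_per_group)
  pow <- function(alpha) {
    crit <- qt(1 - alpha / 2, df)
    pt(-crit, df, ncp) + 1 - pt(crit, df, ncp)
  }
  alpha <- fdr_q * prop_de
  for (i in 1:200) {
    r <- (1 - prop_de) * alpha + prop_de * pow(alpha)
    alpha_new <- fdr_q * r
    if (abs(alpha_new - alpha) < 1e-12) break
    alpha <- alpha_new
  }
  pow(alpha)
}
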