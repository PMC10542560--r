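#' Define an RNA-seq power-simulation scenario
#'
#' Parameters of a two-group negative-binomial RNA-seq design used by
#' [simulate_power()] and [required_sample_size()]: the number of genes,
#' the fraction of truly differentially expressed (DE) genes, their fold
#' change, the control-group mean count, the negative-binomial dispersion
#' (0 gives Poisson counts), the target FDR for Benjamini-Hochberg
#' rejection, the power target for the sample-size search, the number of
#' simulation replicates, and a seed.
#'
#' @param n_genes total number of genes (>= 10).
#' @param prop_de fraction of DE genes in (0, 1).
#' @param fc fold change applied to DE genes (> 1; half of the DE genes are
#'   shifted up by `fc`, half down by `1/fc`, unless `all_up`).
#' @param mu control-group mean count (> 0).
#' @param dispersion negative-binomial dispersion (>= 0); may also be a
#'   per-gene vector of length `n_genes` for tagwise realism.
#' @param fdr_q Benjamini-Hochberg FDR threshold (default 0.1).
#' @param target_power power target for [required_sample_size()]
#'   (default 0.8).
#' @param n_reps simulation replicates per sample size (default 25).
#' @param seed integer seed.
#' @param all_up if `TRUE`, all DE genes are shifted up (sensitivity
#'   analysis; default splits directions evenly).
#' @return A list of class `power_scenario`.
#' @export
power_scenario <- function(n_genes = 10000, prop_de = 0.1, fc = 2,
                           mu = 100, dispersion = 0.015, fdr_q = 0.1,
                           target_power = 0.8, n_reps = 25, seed = 1,
                           all_up = FALSE) {
  check_number(n_genes, "n_genes", 10)
  check_number(prop_de, "prop_de", 0, 1)
  check_number(fc, "fc", 0)
  check_number(mu, "mu", 1e-12)
  if (!is.numeric(dispersion) ||
      !(length(dispersion) %in% c(1L, n_genes)) ||
      any(dispersion < 0)) {
    stop("`dispersion` must be a non-negative scalar or a length-n_genes ",
         "vector", call. = FALSE)
  }
  check_number(fdr_q, "fdr_q", 0, 1)
  check_number(target_power, "target_power", 0, 1)
  check_number(n_reps, "n_reps", 1)
  check_number(seed, "seed")
  check_flag(all_up, "all_up")
  if (prop_de > 0 && fc == 1) {
    stop("fc = 1 with prop_de > 0 leaves the power target undefined",
         call. = FALSE)
  }
  if (fc < 1) stop("`fc` must be > 1 (direction is handled internally)",
                   call. = FALSE)
  structure(
    list(n_genes = as.integer(n_genes), prop_de = prop_de, fc = fc,
         mu = mu, dispersion = dispersion, fdr_q = fdr_q,
         target_power = target_power, n_reps = as.integer(n_reps),
         seed = as.integer(seed), all_up = all_up),
    class = "power_scenario"
  )
}

# Draw a genes x samples count matrix; `means` is per-gene expected count.
draw_counts <- function(means, n_samples, dispersion) {
  n_genes <- length(means)
  total <- n_genes * n_samples
  mu_mat <- rep(means, times = n_samples)
  if (length(dispersion) == 1L && dispersion == 0) {
    counts <- rpois(total, lambda = mu_mat)
  } else {
    # zero entries in a tagwise vector would give size = Inf, which
    # rnbinom rejects; clamp to an effectively-Poisson dispersion
    size <- 1 / pmax(dispersion, 1e-8)
    counts <- rnbinom(total, size = rep(size, length.out = n_genes),
                      mu = mu_mat)
  }
  matrix(counts, nrow = n_genes, ncol = n_samples)
}

# Vectorized per-gene two-sample t-test (pooled variance) on rows of two
# matrices. Group sizes are always equal here and null genes have equal
# variances, so the pooled test is exact under the null while keeping the
# full 2n - 2 residual df (a Welch df can collapse to ~2 at small counts).
t_test_rows <- function(x1, x2) {
  n1 <- ncol(x1); n2 <- ncol(x2)
  m1 <- rowMeans(x1); m2 <- rowMeans(x2)
  v1 <- rowSums((x1 - m1)^2) / (n1 - 1)
  v2 <- rowSums((x2 - m2)^2) / (n2 - 1)
  df <- n1 + n2 - 2
  vp <- ((n1 - 1) * v1 + (n2 - 1) * v2) / df
  se2 <- vp * (1 / n1 + 1 / n2)
  tt <- (m1 - m2) / sqrt(se2)
  p <- 2 * pt(-abs(tt), df)
  # zero-variance rows: identical values give p = 1, separated ones p = 0
  flat <- se2 == 0
  if (any(flat)) p[flat] <- ifelse(m1[flat] == m2[flat], 1, 0)
  p
}

simulate_power_once <- function(scenario, n_per_group) {
  n_genes <- scenario$n_genes
  n_de <- round(scenario$prop_de * n_genes)
  de_idx <- seq_len(n_de)
  mu1 <- rep(scenario$mu, n_genes)
  mu2 <- mu1
  if (n_de > 0L) {
    if (scenario$all_up) {
      mu2[de_idx] <- scenario$mu * scenario$fc
    } else {
      n_up <- ceiling(n_de / 2)
      mu2[de_idx[seq_len(n_up)]] <- scenario$mu * scenario$fc
      if (n_de > n_up) {
        mu2[de_idx[(n_up + 1L):n_de]] <- scenario$mu / scenario$fc
      }
    }
  }
  c1 <- draw_counts(mu1, n_per_group, scenario$dispersion)
  c2 <- draw_counts(mu2, n_per_group, scenario$dispersion)

  # median-of-ratios size factors: total-count scaling would fold the
  # composition bias of asymmetric up/down DE into the null genes and
  # inflate the realized FDR
  counts <- cbind(c1, c2)
  ref <- apply(counts, 1L, median)
  pos <- ref > 0
  sf <- apply(counts[pos, , drop = FALSE] / ref[pos], 2L, median)
  sf[sf <= 0] <- 1
  sf <- sf / exp(mean(log(sf)))
  norm <- sweep(counts, 2L, sf, `/`)
  logx <- log2(norm + 0.5)
  p <- t_test_rows(logx[, seq_len(n_per_group), drop = FALSE],
                   logx[, n_per_group + seq_len(n_per_group), drop = FALSE])
  padj <- p.adjust(p, method = "BH")
  rejected <- padj < scenario$fdr_q
  list(
    power = if (n_de > 0L) mean(rejected[de_idx]) else NA_real_,
    n_rejected = sum(rejected),
    n_false = sum(rejected[-de_idx])
  )
}

#' Monte-Carlo average power of a two-group RNA-seq design
#'
#' Simulates `n_reps` replicates of the scenario at a given per-group
#' sample size. Each replicate draws negative-binomial counts for all
#' genes (DE genes shifted by the fold change, half up and half down),
#' normalizes samples with median-of-ratios size factors, tests each gene
#' with a pooled-variance two-sample t-test on
#' `log2(normalized count + 0.5)`, applies Benjamini-Hochberg at the
#' scenario's FDR threshold, and records the fraction of truly DE genes
#' rejected. Average power is the mean over replicates.
#'
#' @param scenario a [power_scenario()].
#' @param n_per_group samples per group (>= 2).
#' @param rep_seeds optional integer vector of per-replicate seeds
#'   (length `n_reps`); defaults to seeds derived from the scenario seed.
#'   Sharing `rep_seeds` across sample sizes pairs the simulations.
#' @return A list of class `power_estimate`: `power`, `se` (Monte-Carlo
#'   standard error over replicates), `per_rep` (per-replicate power),
#'   `fdr` (mean realized false-discovery proportion), `n_per_group`.
#' @export
simulate_power <- function(scenario, n_per_group, rep_seeds = NULL) {
  stopifnot(inherits(scenario, "power_scenario"))
  check_number(n_per_group, "n_per_group", 2)
  if (is.null(rep_seeds)) {
    rep_seeds <- scenario$seed + seq_len(scenario$n_reps) * 1000L
  }
  stopifnot(length(rep_seeds) == scenario$n_reps)
  reps <- lapply(rep_seeds, function(s) {
    with_seed(s %% .Machine$integer.max,
              simulate_power_once(scenario, as.integer(n_per_group)))
  })
  pw <- vapply(reps, `[[`, numeric(1), "power")
  n_rej <- vapply(reps, `[[`, numeric(1), "n_rejected")
  n_false <- vapply(reps, `[[`, numeric(1), "n_false")
  fdp <- ifelse(n_rej > 0, n_false / n_rej, 0)
  structure(
    list(power = mean(pw),
         se = if (length(pw) > 1L) sd(pw) / sqrt(length(pw)) else NA_real_,
         per_rep = pw, fdr = mean(fdp), n_per_group = as.integer(n_per_group)),
    class = "power_estimate"
  )
}

#' @export
print.power_estimate <- function(x, ...) {
  cat(sprintf("estimated average power %.3f (MC se %.3g) at n = %d/group\n",
              x$power, x$se, x$n_per_group))
  invisible(x)
}

#' Smallest per-group sample size reaching the power target
#'
#' Linear search over n = 2 ... `n_max`, reusing the same per-replicate
#' seeds at every n so the power curve is paired across sample sizes.
#' Returns the first n whose estimated average power reaches the
#' scenario's `target_power`, together with the full power curve; `n` is
#' `NA` when the target is not reached by `n_max`.
#'
#' @param scenario a [power_scenario()].
#' @param n_max largest sample size tried (default 30).
#' @param stop_at_target if `TRUE` (default) the search stops at the first
#'   n reaching the target; set `FALSE` to trace the whole curve.
#' @return A list of class `sample_size_estimate`: `n` (integer or `NA`),
#'   `reached` (logical), `curve` (data.frame with `n`, `power`, `se`).
#' @export
required_sample_size <- function(scenario, n_max = 30, stop_at_target = TRUE) {
  stopifnot(inherits(scenario, "power_scenario"))
  check_number(n_max, "n_max", 2)
  rep_seeds <- scenario$seed + seq_len(scenario$n_reps) * 1000L
  ns <- 2:as.integer(n_max)
  curve <- data.frame(n = integer(), power = numeric(), se = numeric())
  n_found <- NA_integer_
  for (n in ns) {
    est <- simulate_power(scenario, n, rep_seeds = rep_seeds)
    curve <- rbind(curve, data.frame(n = n, power = est$power, se = est$se))
    if (is.na(n_found) && est$power >= scenario$target_power) {
      n_found <- n
      if (stop_at_target) break
    }
  }
  structure(
    list(n = n_found, reached = !is.na(n_found), curve = curve,
         target_power = scenario$target_power),
    class = "sample_size_estimate"
  )
}

#' @export
print.sample_size_estimate <- function(x, ...) {
  if (x$reached) {
    cat(sprintf("smallest n per group with power >= %.2f: %d\n",
                x$target_power, x$n))
  } else {
    cat(sprintf("power %.2f not reached by n = %d per group\n",
                x$target_power, max(x$curve$n)))
  }
  print(x$curve, digits = 3)
  invisible(x)
}
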