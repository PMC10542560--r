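#' Assemble per-gene priority records
#'
#' Full-joins conservation profiles (see [conservation_profiles()]) and
#' brain-expression profiles (see [brain_expression_profiles()]) by human
#' gene ID into one record per gene, the row layout written by
#' [write_priority_table()]. Genes present in only one source keep `NA` for
#' the other source's metrics; no gene is dropped. Duplicate IDs within a
#' source with conflicting values are an error.
#'
#' @param conservation data.frame from [conservation_profiles()], or `NULL`.
#' @param brain data.frame from [brain_expression_profiles()], or `NULL`.
#' @return A data.frame of priority records.
#' @export
build_priority_records <- function(conservation = NULL, brain = NULL) {
  if (is.null(conservation) && is.null(brain)) {
    stop("at least one of `conservation` and `brain` is required",
         call. = FALSE)
  }
  check_dups <- function(df, what) {
    if (is.null(df)) return(invisible())
    dup_ids <- unique(df$human_id[duplicated(df$human_id)])
    for (id in dup_ids) {
      rows <- df[df$human_id == id, , drop = FALSE]
      if (nrow(unique(rows)) > 1L) {
        stop("conflicting duplicate records for gene ", id, " in ", what,
             call. = FALSE)
      }
    }
    invisible()
  }
  check_dups(conservation, "conservation profiles")
  check_dups(brain, "brain-expression profiles")
  if (!is.null(conservation)) {
    conservation <- conservation[!duplicated(conservation$human_id), ,
                                 drop = FALSE]
  }
  if (!is.null(brain)) brain <- brain[!duplicated(brain$human_id), ,
                                      drop = FALSE]

  ids <- sort(unique(c(conservation$human_id, brain$human_id)))
  out <- data.frame(human_id = ids, stringsAsFactors = FALSE)

  pull <- function(df, col, default = NA) {
    if (is.null(df) || !col %in% names(df)) return(rep(default, length(ids)))
    df[[col]][match(ids, df$human_id)]
  }
  for (col in c("sim_mouse_cat", "sim_rat_cat", "dnds_mouse_cat",
                "dnds_rat_cat", "devel_cat", "devel_class")) {
    out[[col]] <- pull(conservation, col, NA_character_)
  }
  for (col in c("sim_mouse_pct", "sim_rat_pct", "dnds_mouse", "dnds_rat")) {
    out[[col]] <- pull(conservation, col, NA_real_)
  }
  out$spec_enrich_cat <- pull(brain, "spec_enrich_cat", NA_character_)
  out$mean_cns_cat <- pull(brain, "mean_cns_cat", NA_character_)
  out$specificity <- pull(brain, "specificity", NA_real_)
  out$enriched_tissues <- pull(brain, "enriched_tissues", NA_character_)
  out$mean_cns_tpm <- pull(brain, "mean_cns_tpm", NA_real_)
  out$sex_main <- pull(brain, "sex_main", NA)
  out$male_higher <- pull(brain, "male_higher", NA)
  out$sex_tissue_interaction <- pull(brain, "sex_tissue_interaction", NA)
  out[order(out$human_id), , drop = FALSE]
}

# category columns usable as distribution-comparison metrics
PRIORITY_METRICS <- c("sim_mouse_cat", "sim_rat_cat", "dnds_mouse_cat",
                      "dnds_rat_cat", "devel_cat", "spec_enrich_cat",
                      "mean_cns_cat")

#' High/Medium/Low counts for one metric
#'
#' @param records a priority-record data.frame.
#' @param metric one of `"sim_mouse_cat"`, `"sim_rat_cat"`,
#'   `"dnds_mouse_cat"`, `"dnds_rat_cat"`, `"devel_cat"`,
#'   `"spec_enrich_cat"`, `"mean_cns_cat"`.
#' @return Named integer vector of counts over High, Medium, Low
#'   (`NA`-categorized genes excluded).
#' @export
priority_distribution <- function(records, metric) {
  metric <- match.arg(metric, PRIORITY_METRICS)
  x <- records[[metric]]
  as.integer(table(factor(x[!is.na(x)], levels = PRIORITY_LEVELS))) |>
    setNames(PRIORITY_LEVELS)
}

#' Compare priority distributions across datasets
#'
#' Tests whether the High/Medium/Low composition of a metric differs across
#' two or more datasets: an omnibus Monte-Carlo Fisher's exact test on the
#' k x 3 count table, followed — only when the omnibus p is below `alpha`
#' — by pairwise 2 x 3 tests. Pairwise p-values are unadjusted by default.
#' Datasets with no categorized gene for the metric are excluded with a
#' warning.
#'
#' @param distributions named list of High/Medium/Low count vectors (as
#'   from [priority_distribution()]), one per dataset; at least two.
#' @param alpha significance gate for running the pairwise follow-ups.
#' @param n_sim,seed Monte-Carlo settings, see [fisher_exact()].
#' @param adjust if `TRUE`, Bonferroni-adjust the pairwise p-values over
#'   the number of pairs tested.
#' @return A list of class `priority_comparison`: `table` (k x 3 counts),
#'   `omnibus` (a `contingency_result`), `pairwise` (data.frame with
#'   `dataset1`, `dataset2`, `p`, `significant`, or `NULL` when the omnibus
#'   gate fails).
#' @export
compare_priority_distributions <- function(distributions, alpha = 0.05,
                                           n_sim = 1e5, seed = NULL,
                                           adjust = FALSE) {
  if (!is.list(distributions) || length(distributions) < 2L) {
    stop("need at least two datasets", call. = FALSE)
  }
  if (is.null(names(distributions)) || any(!nzchar(names(distributions)))) {
    names(distributions) <- paste0("dataset", seq_along(distributions))
  }
  tab <- do.call(rbind, lapply(distributions, function(d) {
    if (!all(PRIORITY_LEVELS %in% names(d))) {
      stop("each distribution needs High/Medium/Low counts", call. = FALSE)
    }
    as.integer(d[PRIORITY_LEVELS])
  }))
  colnames(tab) <- PRIORITY_LEVELS
  empty <- rowSums(tab) == 0L
  if (any(empty)) {
    warning("excluding dataset(s) with no categorized gene: ",
            paste(rownames(tab)[empty], collapse = ", "), call. = FALSE)
    tab <- tab[!empty, , drop = FALSE]
  }
  if (nrow(tab) < 2L) stop("fewer than two non-empty datasets", call. = FALSE)
  # canonical orientation: datasets sorted by name so the p-value does not
  # depend on input order for a fixed seed
  tab <- tab[order(rownames(tab)), , drop = FALSE]
  zero_cols <- colSums(tab) == 0L
  test_tab <- tab[, !zero_cols, drop = FALSE]

  omnibus <- fisher_exact(test_tab, n_sim = n_sim, seed = seed)
  pairwise <- NULL
  if (omnibus$p < alpha) {
    combos <- combn(rownames(tab), 2L)
    p <- apply(combos, 2L, function(pair) {
      sub <- tab[pair, , drop = FALSE]
      sub <- sub[, colSums(sub) > 0L, drop = FALSE]
      fisher_exact(sub, n_sim = n_sim,
                   seed = if (is.null(seed)) NULL else seed + 1L)$p
    })
    if (adjust) p <- pmin(1, p * ncol(combos))
    pairwise <- data.frame(dataset1 = combos[1L, ], dataset2 = combos[2L, ],
                           p = p, significant = p < alpha,
                           row.names = NULL)
  }
  structure(list(table = tab, omnibus = omnibus, pairwise = pairwise,
                 alpha = alpha),
            class = "priority_comparison")
}

#' @export
print.priority_comparison <- function(x, ...) {
  cat("Priority-distribution comparison\n")
  print(x$table)
  cat(sprintf("omnibus Monte-Carlo Fisher p = %.4g\n", x$omnibus$p))
  if (!is.null(x$pairwise)) {
    cat("pairwise follow-ups:\n")
    print(x$pairwise, digits = 4)
  } else {
    cat("omnibus p >= ", x$alpha, "; no pairwise follow-ups\n", sep = "")
  }
  invisible(x)
}

#' Overlap and direction concordance of two DEG lists
#'
#' Counts genes shared by two differentially-expressed-gene lists and how
#' many shared genes are regulated in the same direction.
#'
#' @param list1,list2 data.frames with columns `gene` and `direction`
#'   (`"up"`/`"down"`), as produced by [generate_deg_lists()].
#' @return A list: `shared` (count), `concordant` (count),
#'   `shared_genes` (character).
#' @export
deg_overlap <- function(list1, list2) {
  for (l in list(list1, list2)) {
    if (!all(c("gene", "direction") %in% names(l))) {
      stop("DEG lists need `gene` and `direction` columns", call. = FALSE)
    }
  }
  shared <- intersect(list1$gene, list2$gene)
  d1 <- list1$direction[match(shared, list1$gene)]
  d2 <- list2$direction[match(shared, list2$gene)]
  list(shared = length(shared), concordant = sum(d1 == d2),
       shared_genes = shared)
}

#' Summary arithmetic for a nominal-p DEG threshold
#'
#' For a dataset with `n_tested` genes and `n_degs` genes passing an
#' uncorrected p-value threshold `alpha`: the percentage of tested genes
#' called differentially expressed, and the number of false positives
#' expected under the global null (`alpha * n_tested`).
#'
#' @param n_degs number of genes passing the threshold.
#' @param n_tested number of genes tested.
#' @param alpha the nominal p-value threshold (default 0.05).
#' @return A list: `pct_degs` (percentage), `expected_false_positives`.
#' @export
deg_threshold_summary <- function(n_degs, n_tested, alpha = 0.05) {
  check_number(n_degs, "n_degs", 0)
  check_number(n_tested, "n_tested", 1)
  check_number(alpha, "alpha", 0, 1)
  if (n_degs > n_tested) stop("n_degs cannot exceed n_tested", call. = FALSE)
  list(pct_degs = 100 * n_degs / n_tested,
       expected_false_positives = alpha * n_tested)
}
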