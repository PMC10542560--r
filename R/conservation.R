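#' Quartile summary with outlier fences
#'
#' Median, quartiles (linear interpolation between order statistics,
#' `quantile()` type 7), interquartile range, and the usual 1.5 x IQR
#' outlier fences.
#'
#' @param x numeric vector; missing values are dropped.
#' @return A list of class `quartile_summary`: `median`, `q1`, `q3`, `iqr`,
#'   `lower_fence`, `upper_fence`, `n`.
#' @export
quartile_summary <- function(x) {
  x <- as.numeric(x)
  x <- x[!is.na(x)]
  if (length(x) == 0L) stop("no non-missing values", call. = FALSE)
  q <- unname(quantile(x, c(0.25, 0.5, 0.75), type = 7))
  iqr <- q[3L] - q[1L]
  structure(
    list(median = q[2L], q1 = q[1L], q3 = q[3L], iqr = iqr,
         lower_fence = q[1L] - 1.5 * iqr, upper_fence = q[3L] + 1.5 * iqr,
         n = length(x)),
    class = "quartile_summary"
  )
}

#' Categorize protein sequence similarity
#'
#' Bins percent protein sequence similarity between a rodent gene and its
#' human ortholog: similarity >= 90 is High, 80 <= similarity < 90 is
#' Medium, and similarity < 80 is Low. Vectorized; `NA` passes through.
#'
#' @param pct_similarity numeric vector of percentages in `[0, 100]`.
#' @param high,low category thresholds (defaults 90 and 80).
#' @return Character vector over `{"High", "Medium", "Low", NA}`.
#' @export
categorize_similarity <- function(pct_similarity, high = 90, low = 80) {
  x <- as.numeric(pct_similarity)
  if (any(x < 0 | x > 100, na.rm = TRUE)) {
    stop("pct_similarity must be within [0, 100]", call. = FALSE)
  }
  out <- ifelse(x >= high, "High", ifelse(x >= low, "Medium", "Low"))
  out[is.na(x)] <- NA_character_
  out
}

#' Categorize dN/dS ratios within a candidate set
#'
#' Categories are relative to the candidate genes of one dataset and one
#' species pair: values strictly below the candidate median are High;
#' outliers beyond the quartile fences (below Q1 - 1.5 IQR or above
#' Q3 + 1.5 IQR) are Low; every other value is Medium. A ratio that is
#' missing because dS is undefined at 100% sequence similarity is High; any
#' other missing ratio is not categorized (`NA`). Because the median is
#' dataset-relative, categories are not comparable across datasets.
#'
#' @param ratios numeric vector of dN/dS values (>= 0, `NA` allowed).
#' @param missing_reason character vector parallel to `ratios`; for missing
#'   entries, `"similarity_100"` marks ratios undefined due to 100%
#'   sequence similarity (categorized High). Any other value (or `NA`)
#'   leaves the gene uncategorized.
#' @return A list of class `dnds_categories`: `category` (character vector),
#'   `summary` (the [quartile_summary()] of the non-missing ratios), and
#'   `low_tail_outliers` (count of Low calls below the lower fence; such
#'   genes are strongly conserved yet land in Low under the fence rule).
#' @export
categorize_dnds <- function(ratios, missing_reason = NULL) {
  x <- as.numeric(ratios)
  if (all(is.na(x))) stop("all dN/dS values are missing", call. = FALSE)
  if (any(x < 0, na.rm = TRUE)) stop("dN/dS must be >= 0", call. = FALSE)
  if (is.null(missing_reason)) missing_reason <- rep(NA_character_, length(x))
  if (length(missing_reason) != length(x)) {
    stop("`missing_reason` must be parallel to `ratios`", call. = FALSE)
  }
  qs <- quartile_summary(x)
  category <- character(length(x))
  obs <- !is.na(x)
  outlier <- obs & (x < qs$lower_fence | x > qs$upper_fence)
  category[obs] <- ifelse(outlier[obs], "Low",
                          ifelse(x[obs] < qs$median, "High", "Medium"))
  category[!obs] <- ifelse(missing_reason[!obs] %in% "similarity_100",
                           "High", NA_character_)
  structure(
    list(category = category, summary = qs,
         low_tail_outliers = sum(obs & x < qs$lower_fence)),
    class = "dnds_categories"
  )
}

#' Categorize developmental-expression conservation
#'
#' Maps forebrain developmental-conservation classes to priorities: `HMR`
#' (shared temporal expression in human, mouse, and rat) is High; `HM` or
#' `HR` (shared with one rodent, including the case where only that rodent
#' was testable) is Medium; `H` (shared with neither tested rodent) is Low;
#' missing class (no data for either rodent comparison) is `NA`.
#'
#' @param class character vector over `{"HMR", "HM", "HR", "H", NA}`.
#' @return Character vector over `{"High", "Medium", "Low", NA}`.
#' @export
categorize_devel <- function(class) {
  class <- as.character(class)
  bad <- !is.na(class) & !class %in% c("HMR", "HM", "HR", "H")
  if (any(bad)) {
    stop("invalid developmental class: ",
         paste(unique(class[bad]), collapse = ", "), call. = FALSE)
  }
  unname(c(HMR = "High", HM = "Medium", HR = "Medium", H = "Low")[class])
}

#' Per-gene conservation profiles for a candidate set
#'
#' Assembles, for each candidate human gene, the sequence-similarity
#' category and dN/dS category per species pair plus the developmental
#' category. All candidates with data are categorized (including non-1:1
#' orthologs); dN/dS ratios are `dn / ds`, undefined when `ds == 0` —
#' treated as High when similarity is 100% and left uncategorized
#' otherwise.
#'
#' @param candidates character vector of candidate human gene IDs.
#' @param mouse_pairs an `ortholog_table` for mouse (see
#'   [read_ortholog_table()]).
#' @param rat_pairs optional `ortholog_table` for rat.
#' @param devel optional `devel_table` (see [read_devel_table()]).
#' @return A data.frame with one row per candidate: `human_id`,
#'   `sim_mouse_pct`, `sim_mouse_cat`, `dnds_mouse`, `dnds_mouse_cat`,
#'   `sim_rat_pct`, `sim_rat_cat`, `dnds_rat`, `dnds_rat_cat`,
#'   `devel_class`, `devel_cat`. Attributes `dnds_summary_mouse` /
#'   `dnds_summary_rat` carry the [quartile_summary()] objects.
#' @export
conservation_profiles <- function(candidates, mouse_pairs, rat_pairs = NULL,
                                  devel = NULL) {
  candidates <- unique(as.character(candidates))
  out <- data.frame(human_id = candidates, stringsAsFactors = FALSE)

  add_species <- function(out, pairs, prefix) {
    sim <- setNames(rep(NA_real_, length(candidates)), candidates)
    dn <- ds <- sim
    hit <- pairs$human_id %in% candidates
    sub <- pairs[hit, , drop = FALSE]
    # a human gene can pair with several rodent genes; prefer the canonical
    # one-to-one pair, then the most similar of the rest
    sub <- sub[order(-sub$one_to_one, -sub$pct_similarity), , drop = FALSE]
    sub <- sub[!duplicated(sub$human_id), , drop = FALSE]
    sim[sub$human_id] <- sub$pct_similarity
    dn[sub$human_id] <- sub$dn
    ds[sub$human_id] <- sub$ds

    ratio <- ifelse(!is.na(ds) & ds > 0, dn / ds, NA_real_)
    reason <- ifelse(is.na(ratio) & !is.na(sim) & sim == 100,
                     "similarity_100", NA_character_)
    out[[paste0("sim_", prefix, "_pct")]] <- unname(sim)
    out[[paste0("sim_", prefix, "_cat")]] <- categorize_similarity(sim)
    out[[paste0("dnds_", prefix)]] <- unname(ratio)
    if (all(is.na(ratio) & is.na(reason))) {
      out[[paste0("dnds_", prefix, "_cat")]] <- NA_character_
      attr(out, paste0("dnds_summary_", prefix)) <- NULL
    } else {
      cats <- categorize_dnds(ratio, reason)
      out[[paste0("dnds_", prefix, "_cat")]] <- cats$category
      attr(out, paste0("dnds_summary_", prefix)) <- cats$summary
    }
    out
  }

  out <- add_species(out, mouse_pairs, "mouse")
  if (!is.null(rat_pairs)) {
    out <- add_species(out, rat_pairs, "rat")
  } else {
    out$sim_rat_pct <- NA_real_; out$sim_rat_cat <- NA_character_
    out$dnds_rat <- NA_real_; out$dnds_rat_cat <- NA_character_
  }

  if (!is.null(devel)) {
    idx <- match(candidates, devel$human_id)
    out$devel_class <- devel$class[idx]
  } else {
    out$devel_class <- NA_character_
  }
  out$devel_cat <- categorize_devel(out$devel_class)
  out
}

#' Candidate-vs-background comparison of a conservation metric
#'
#' Two-sided Mann-Whitney U comparison of candidate genes against the
#' genome background for a numeric conservation metric (percent similarity,
#' dN/dS, or brain specificity), with Bonferroni adjustment over the
#' comparison family. The background must exclude the candidates; when IDs
#' are supplied this is verified.
#'
#' @param candidate_values,background_values numeric vectors.
#' @param family_size Bonferroni family size (default 1).
#' @param candidate_ids,background_ids optional gene IDs used to verify the
#'   two sets are disjoint.
#' @return An `mwu_result` (see [mann_whitney()]).
#' @export
conservation_vs_background <- function(candidate_values, background_values,
                                       family_size = 1L,
                                       candidate_ids = NULL,
                                       background_ids = NULL) {
  if (!is.null(candidate_ids) && !is.null(background_ids)) {
    overlap <- intersect(candidate_ids, background_ids)
    if (length(overlap)) {
      stop("candidate and background sets overlap: ",
           paste(head(overlap, 5L), collapse = ", "),
           if (length(overlap) > 5L) ", ...", call. = FALSE)
    }
  }
  mann_whitney(candidate_values[!is.na(candidate_values)],
               background_values[!is.na(background_values)],
               family_size = family_size)
}

#' Candidate-vs-background comparison of developmental classes
#'
#' Tabulates candidate and background developmental-conservation classes
#' over `{HMR, HM, HR, H}` and tests the 2 x 4 table with a Monte-Carlo
#' Fisher's exact test. Genes with partial or missing data (class `NA`, or
#' data for only one rodent species) must be excluded by the caller, as in
#' the genome-wide comparison. Classes observed in neither set are dropped
#' with a message.
#'
#' @param candidate_classes,background_classes character vectors of classes.
#' @param n_sim,seed Monte-Carlo settings, see [fisher_exact()].
#' @return A `contingency_result`.
#' @export
devel_vs_background <- function(candidate_classes, background_classes,
                                n_sim = 1e5, seed = NULL) {
  lv <- c("HMR", "HM", "HR", "H")
  cand <- table(factor(candidate_classes, levels = lv))
  bg <- table(factor(background_classes, levels = lv))
  if (sum(cand) == 0L || sum(bg) == 0L) {
    stop("empty class row: both sets need at least one categorized gene",
         call. = FALSE)
  }
  tab <- rbind(candidate = as.integer(cand), background = as.integer(bg))
  colnames(tab) <- lv
  zero <- colSums(tab) == 0L
  if (any(zero)) {
    message("dropping class(es) observed in neither set: ",
            paste(lv[zero], collapse = ", "))
    tab <- tab[, !zero, drop = FALSE]
  }
  fisher_exact(tab, n_sim = n_sim, seed = seed)
}
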