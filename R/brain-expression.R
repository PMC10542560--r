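# Brain specificity, tissue enrichment, mean CNS expression, and sex
# effects computed from an expression panel.

# per-tissue mean TPM across individuals for one gene (all samples; the
# age filter applies only to the sex/tissue ANOVA)
tissue_means <- function(panel, gene) {
  v <- panel_gene_values(panel, gene)
  tapply(v, panel$samples$tissue, mean)
}

panel_gene_values <- function(panel, gene) {
  stopifnot(inherits(panel, "expression_panel"))
  if (!gene %in% colnames(panel$tpm)) {
    stop("gene not in panel: ", gene, call. = FALSE)
  }
  panel$tpm[, gene]
}

#' Brain specificity score
#'
#' The log2 fold change of total CNS expression over total expression in
#' other tissues: per-tissue mean TPM is computed across individuals, the
#' means are summed over the CNS tissue set and over the non-CNS tissues,
#' and the score is `log2(sum_CNS / sum_nonCNS)`. A score of 3 means
#' 8-fold higher expression in the brain relative to the rest of the body.
#' Genes expressed exclusively in the CNS or exclusively outside it have no
#' finite score and are excluded (`NA` with an `excluded_reason`
#' attribute).
#'
#' @param panel an [expression_panel()].
#' @param gene gene identifier (must be in the panel).
#' @return A single number, or `NA` (with attribute `excluded_reason`
#'   `"cns_exclusive"` or `"body_exclusive"`) for excluded genes.
#' @export
specificity_score <- function(panel, gene) {
  tm <- tissue_means(panel, gene)
  cns <- intersect(names(tm), panel$tissue_sets$cns)
  noncns <- setdiff(names(tm), panel$tissue_sets$cns)
  sum_cns <- sum(tm[cns])
  sum_noncns <- sum(tm[noncns])
  if (sum_noncns == 0) {
    return(structure(NA_real_, excluded_reason = "cns_exclusive"))
  }
  if (sum_cns == 0) {
    return(structure(NA_real_, excluded_reason = "body_exclusive"))
  }
  log2(sum_cns / sum_noncns)
}

#' Mean CNS expression and its category
#'
#' Computes, for one gene, the mean TPM in each CNS tissue across all
#' individuals regardless of age, then the unweighted grand mean over the
#' CNS tissues. The grand mean is categorized High when >= `tpm_high`
#' (default 20 TPM), Medium in `[tpm_low, tpm_high)`, Low below `tpm_low`
#' (default 10 TPM).
#'
#' @param panel an [expression_panel()].
#' @param gene gene identifier.
#' @param tpm_high,tpm_low category thresholds in TPM.
#' @return A list: `mean_cns_tpm`, `category`, `tissue_means` (named per
#'   CNS tissue).
#' @export
mean_cns_expression <- function(panel, gene, tpm_high = 20, tpm_low = 10) {
  tm <- tissue_means(panel, gene)
  cns <- panel$tissue_sets$cns
  missing_tissues <- setdiff(cns, names(tm))
  if (length(missing_tissues)) {
    stop("CNS tissue(s) with zero samples in the panel: ",
         paste(missing_tissues, collapse = ", "), call. = FALSE)
  }
  grand <- mean(tm[cns])
  category <- if (grand >= tpm_high) "High"
              else if (grand >= tpm_low) "Medium" else "Low"
  list(mean_cns_tpm = unname(grand), category = category,
       tissue_means = tm[cns])
}

# CNS samples passing the age cutoff, with occupied-cell validation
cns_age_subset <- function(panel, age_cutoff) {
  keep <- panel$samples$tissue %in% panel$tissue_sets$cns &
    panel$samples$age >= age_cutoff
  sub <- panel$samples[keep, , drop = FALSE]
  if (nrow(sub) == 0L) {
    stop("no CNS samples at age >= ", age_cutoff,
         "; lower the cutoff or regenerate the panel", call. = FALSE)
  }
  cells <- table(sub$sex, sub$tissue)
  if (any(cells == 0L) || ncol(cells) < length(panel$tissue_sets$cns)) {
    stop("empty sex x tissue cell(s) after the age >= ", age_cutoff,
         " filter; lower the cutoff or use a balanced synthetic panel",
         call. = FALSE)
  }
  keep
}

#' Brain-tissue enrichment of one gene
#'
#' Restricts the panel to CNS tissues and donors at or above the age
#' cutoff, fits a two-way type III ANOVA (Sex, Tissue, Sex:Tissue), and —
#' when the Tissue effect is significant at `alpha` — runs Tukey HSD across
#' tissues and builds a compact letter display ordered by descending tissue
#' mean. Tissues whose letters include `"a"` are called enriched. When the
#' Tissue effect is not significant the gene is not enriched in any
#' specific region.
#'
#' @param panel an [expression_panel()].
#' @param gene gene identifier.
#' @param alpha significance level (default 0.05).
#' @param age_cutoff minimum donor age in years (default 55).
#' @return A list of class `tissue_enrichment`: `anova` (an
#'   `anova_type3`), `tissue_significant`, `cld` (a [compact_letter_display()]
#'   result or `NULL`), `enriched_tissues` (character, possibly empty).
#' @export
tissue_enrichment <- function(panel, gene, alpha = 0.05, age_cutoff = 55) {
  check_number(alpha, "alpha", 0, 1)
  keep <- cns_age_subset(panel, age_cutoff)
  v <- panel_gene_values(panel, gene)[keep]
  meta <- panel$samples[keep, , drop = FALSE]

  anova <- two_way_anova_type3(v, meta$sex, meta$tissue,
                               names_ab = c("Sex", "Tissue"))
  p_tissue <- anova$table$p[anova$table$effect == "Tissue"]
  tissue_significant <- isTRUE(p_tissue < alpha)
  cld <- NULL
  enriched <- character()
  if (tissue_significant) {
    pairs <- tukey_hsd(v, meta$tissue)
    tiss <- sort(unique(meta$tissue))
    sig <- pairwise_significance(pairs, tiss, alpha = alpha)
    means <- tapply(v, meta$tissue, mean)[tiss]
    cld <- compact_letter_display(sig, means)
    enriched <- names(x = cld$letters)[grepl("a", cld$letters, fixed = TRUE)]
  }
  structure(
    list(gene = gene, anova = anova,
         tissue_significant = tissue_significant,
         cld = cld, enriched_tissues = enriched,
         alpha = alpha, age_cutoff = age_cutoff),
    class = "tissue_enrichment"
  )
}

#' @export
print.tissue_enrichment <- function(x, ...) {
  cat("Tissue enrichment for ", x$gene, " (alpha = ", x$alpha,
      ", age >= ", x$age_cutoff, ")\n", sep = "")
  print(x$anova)
  if (x$tissue_significant) {
    cat("enriched tissue(s): ",
        if (length(x$enriched_tissues))
          paste(x$enriched_tissues, collapse = ", ") else "none", "\n",
        sep = "")
  } else {
    cat("Tissue effect not significant; not enriched in any region\n")
  }
  invisible(x)
}

#' Combined brain specificity / region enrichment category
#'
#' Applies the priority rules for the combined specificity + enrichment
#' metric: High when the specificity score is > 0 and expression is
#' enriched in reward regions but not cerebellum or spinal cord; Medium
#' when specificity > 0 with enrichment only in non-reward CNS regions,
#' enrichment in no specific region, or mixed reward/non-reward enrichment
#' — or when specificity <= 0 but reward regions are enriched; Low when
#' specificity <= 0 with enrichment confined to cerebellum and/or spinal
#' cord or with no enrichment at all.
#'
#' @param specificity specificity score (finite; excluded genes cannot be
#'   categorized).
#' @param enriched_tissues character vector of enriched tissues (possibly
#'   empty).
#' @param tissue_sets a [tissue_sets()] configuration.
#' @return `"High"`, `"Medium"`, or `"Low"`.
#' @export
spec_enrich_category <- function(specificity, enriched_tissues, tissue_sets) {
  if (is.na(specificity)) {
    stop("specificity is missing (excluded gene); cannot categorize",
         call. = FALSE)
  }
  unknown <- setdiff(enriched_tissues, tissue_sets$cns)
  if (length(unknown)) {
    stop("enriched tissue(s) outside the CNS set: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  reward <- any(enriched_tissues %in% tissue_sets$reward)
  nonreward <- any(enriched_tissues %in% tissue_sets$nonreward_cns)
  if (specificity > 0) {
    if (reward && !nonreward) "High" else "Medium"
  } else {
    if (reward) "Medium" else "Low"
  }
}

#' Sex effects on CNS expression of one gene
#'
#' From the same age-filtered CNS two-way ANOVA as [tissue_enrichment()]:
#' whether Sex has a significant main effect, which sex is higher (by the
#' unweighted grand mean of per-tissue means, `NA` when the main effect is
#' absent), and whether the Sex:Tissue interaction is significant.
#'
#' @inheritParams tissue_enrichment
#' @return A list: `sex_main`, `male_higher` (logical or `NA`),
#'   `sex_tissue_interaction`, `male_grand_mean`, `female_grand_mean`.
#' @export
sex_effects <- function(panel, gene, alpha = 0.05, age_cutoff = 55) {
  keep <- cns_age_subset(panel, age_cutoff)
  v <- panel_gene_values(panel, gene)[keep]
  meta <- panel$samples[keep, , drop = FALSE]
  anova <- two_way_anova_type3(v, meta$sex, meta$tissue,
                               names_ab = c("Sex", "Tissue"))
  p_sex <- anova$table$p[anova$table$effect == "Sex"]
  p_int <- anova$table$p[anova$table$effect == "Sex:Tissue"]
  cell_means <- tapply(v, list(meta$sex, meta$tissue), mean)
  grand <- rowMeans(cell_means)
  sex_main <- isTRUE(p_sex < alpha)
  list(
    sex_main = sex_main,
    male_higher = if (sex_main) unname(grand["male"] > grand["female"]) else NA,
    sex_tissue_interaction = isTRUE(p_int < alpha),
    male_grand_mean = unname(grand["male"]),
    female_grand_mean = unname(grand["female"])
  )
}

#' Brain-expression profiles for a set of genes
#'
#' Runs [specificity_score()], [mean_cns_expression()],
#' [tissue_enrichment()], [spec_enrich_category()] and [sex_effects()] for
#' each gene and collects one row per gene. Genes excluded from the
#' specificity score (CNS- or body-exclusive) get `NA` specificity and no
#' combined category.
#'
#' @param panel an [expression_panel()].
#' @param genes gene identifiers (default: all panel genes).
#' @param alpha significance level for ANOVA/Tukey/CLD (default 0.05).
#' @param age_cutoff minimum donor age for the sex/tissue analyses.
#' @param tpm_high,tpm_low mean-CNS-expression category thresholds.
#' @return A data.frame with one row per gene: `human_id`, `specificity`,
#'   `excluded_reason`, `enriched_tissues` (comma-separated),
#'   `cld` (tissue=letters, comma-separated), `spec_enrich_cat`,
#'   `mean_cns_tpm`, `mean_cns_cat`, `sex_main`, `male_higher`,
#'   `sex_tissue_interaction`.
#' @export
brain_expression_profiles <- function(panel, genes = panel_genes(panel),
                                      alpha = 0.05, age_cutoff = 55,
                                      tpm_high = 20, tpm_low = 10) {
  rows <- lapply(genes, function(g) {
    spec <- specificity_score(panel, g)
    mc <- mean_cns_expression(panel, g, tpm_high = tpm_high,
                              tpm_low = tpm_low)
    enr <- tissue_enrichment(panel, g, alpha = alpha,
                             age_cutoff = age_cutoff)
    sx <- sex_effects(panel, g, alpha = alpha, age_cutoff = age_cutoff)
    excluded <- attr(spec, "excluded_reason")
    data.frame(
      human_id = g,
      specificity = as.numeric(spec),
      excluded_reason = excluded %||% NA_character_,
      enriched_tissues = paste(enr$enriched_tissues, collapse = ","),
      cld = if (is.null(enr$cld)) NA_character_ else
        paste(names(enr$cld$letters), enr$cld$letters,
              sep = "=", collapse = ","),
      spec_enrich_cat = if (is.na(spec)) NA_character_ else
        spec_enrich_category(as.numeric(spec), enr$enriched_tissues,
                             panel$tissue_sets),
      mean_cns_tpm = mc$mean_cns_tpm,
      mean_cns_cat = mc$category,
      sex_main = sx$sex_main,
      male_higher = sx$male_higher,
      sex_tissue_interaction = sx$sex_tissue_interaction,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}
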