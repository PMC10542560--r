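# Synthetic fixture generators. Each generator plants effects with explicit
# separation margins beyond the category thresholds, records the intended
# truth per gene, and (optionally) writes schema-valid TSV files accepted by
# the package readers.

#' Generate a synthetic ortholog table with planted similarity classes
#'
#' Similarities are drawn from distributions separated from the 90/80%
#' category thresholds: planted-High genes in `[high_min, 99.5]` (default
#' margin 92), planted-Medium in `[81, 88]`, planted-Low in
#' `[50, low_max]` (default 75). A configurable fraction of the High genes
#' get exactly 100% similarity with missing dN/dS (the dS-undefined case).
#' dN/dS ratios for non-outlier genes are uniform on `[0.05, 0.25]`;
#' planted outliers are uniform on `[1, 3]`, far above the bulk's upper
#' quartile fence. A fraction of extra rows are one2many pairs.
#'
#' @param n_genes number of one-to-one genes.
#' @param frac_high_sim,frac_low_sim fractions of genes planted High / Low
#'   on similarity (the rest are Medium).
#' @param frac_outlier_dnds fraction of genes planted as dN/dS outliers.
#' @param frac_sim100 fraction of planted-High genes given exactly 100%
#'   similarity and missing dN/dS.
#' @param frac_one2many fraction of additional one2many rows.
#' @param species `"mouse"` or `"rat"` (controls gene-ID prefixes).
#' @param high_min,low_max separation margins for the High and Low classes.
#' @param seed integer seed; generation is deterministic given the seed.
#' @param path optional path; when given, the table is written as TSV.
#' @return A list: `pairs` (`ortholog_table`-shaped data.frame), `truth`
#'   (per one-to-one gene: `rodent_id`, `human_id`, `sim_class`,
#'   `dnds_outlier`, `sim100`), `path` (or `NULL`).
#' @export
generate_ortholog_table <- function(n_genes = 1000, frac_high_sim = 0.5,
                                    frac_low_sim = 0.2,
                                    frac_outlier_dnds = 0.05,
                                    frac_sim100 = 0.02,
                                    frac_one2many = 0.05,
                                    species = c("mouse", "rat"),
                                    high_min = 92, low_max = 75,
                                    seed = 1, path = NULL) {
  species <- match.arg(species)
  check_number(n_genes, "n_genes", 1)
  for (f in c(frac_high_sim, frac_low_sim, frac_outlier_dnds, frac_sim100,
              frac_one2many)) {
    check_number(f, "fraction", 0, 1)
  }
  if (frac_high_sim + frac_low_sim > 1) {
    stop("frac_high_sim + frac_low_sim must be <= 1", call. = FALSE)
  }
  with_seed(seed, {
    n_genes <- as.integer(n_genes)
    prefix <- if (species == "mouse") "mm_gene_" else "rn_gene_"
    rodent_id <- sprintf("%s%05d", prefix, seq_len(n_genes))
    human_id <- sprintf("hs_gene_%05d", seq_len(n_genes))

    n_high <- round(frac_high_sim * n_genes)
    n_low <- round(frac_low_sim * n_genes)
    n_med <- n_genes - n_high - n_low
    sim_class <- sample(rep(c("High", "Medium", "Low"),
                            c(n_high, n_med, n_low)))
    sim <- numeric(n_genes)
    sim[sim_class == "High"] <- runif(sum(sim_class == "High"), high_min, 99.5)
    sim[sim_class == "Medium"] <- runif(sum(sim_class == "Medium"), 81, 88)
    sim[sim_class == "Low"] <- runif(sum(sim_class == "Low"), 50, low_max)

    sim100 <- rep(FALSE, n_genes)
    high_idx <- which(sim_class == "High")
    n100 <- round(frac_sim100 * length(high_idx))
    if (n100 > 0L) {
      pick <- sample(high_idx, n100)
      sim100[pick] <- TRUE
      sim[pick] <- 100
    }

    outlier <- rep(FALSE, n_genes)
    n_out <- round(frac_outlier_dnds * n_genes)
    eligible <- which(!sim100)
    if (n_out > 0L) outlier[sample(eligible, min(n_out, length(eligible)))] <- TRUE

    ratio <- numeric(n_genes)
    ratio[!outlier] <- runif(sum(!outlier), 0.05, 0.25)
    ratio[outlier] <- runif(sum(outlier), 1, 3)
    ds <- runif(n_genes, 0.2, 0.8)
    dn <- ratio * ds
    dn[sim100] <- NA_real_
    ds[sim100] <- NA_real_

    pairs <- data.frame(
      rodent_id = rodent_id, human_id = human_id,
      homology_type = "one2one",
      pct_similarity = round(sim, 4), dn = round(dn, 6), ds = round(ds, 6),
      stringsAsFactors = FALSE
    )

    n_extra <- round(frac_one2many * n_genes)
    if (n_extra > 0L) {
      host <- sample(n_genes, n_extra, replace = TRUE)
      extra <- data.frame(
        rodent_id = sprintf("%s%05d", prefix, n_genes + seq_len(n_extra)),
        human_id = human_id[host],
        homology_type = "one2many",
        pct_similarity = round(runif(n_extra, 40, 95), 4),
        dn = round(runif(n_extra, 0.01, 0.5), 6),
        ds = round(runif(n_extra, 0.2, 0.8), 6),
        stringsAsFactors = FALSE
      )
      pairs <- rbind(pairs, extra)
    }
    pairs$one_to_one <- pairs$homology_type == "one2one"

    truth <- data.frame(
      rodent_id = rodent_id, human_id = human_id, sim_class = sim_class,
      dnds_outlier = outlier, sim100 = sim100, stringsAsFactors = FALSE
    )
    if (!is.null(path)) {
      write.table(pairs[c("rodent_id", "human_id", "homology_type",
                          "pct_similarity", "dn", "ds")],
                  path, sep = "\t", quote = FALSE, na = "",
                  row.names = FALSE)
    }
    attr(pairs, "species") <- species
    class(pairs) <- c("ortholog_table", "data.frame")
    list(pairs = pairs, truth = truth, path = path)
  })
}

#' Generate a synthetic developmental-conservation table
#'
#' Assigns each human gene a forebrain developmental class sampled from
#' `probs` (over HMR, HM, HR, H), plus fractions of genes with data for
#' only one rodent species or no data at all.
#'
#' @param human_ids character vector of human gene IDs.
#' @param probs class probabilities over `c(HMR, HM, HR, H)` for genes with
#'   complete data.
#' @param frac_partial fraction of genes with data for one rodent only.
#' @param frac_missing fraction of genes with no data (class `NA`).
#' @param seed integer seed.
#' @param path optional TSV output path.
#' @return A list: `table` (a `devel_table`-shaped data.frame), `path`.
#' @export
generate_devel_table <- function(human_ids,
                                 probs = c(HMR = 0.75, HM = 0.1,
                                           HR = 0.05, H = 0.1),
                                 frac_partial = 0.1, frac_missing = 0.05,
                                 seed = 1, path = NULL) {
  stopifnot(length(human_ids) >= 1L, abs(sum(probs) - 1) < 1e-8)
  with_seed(seed, {
    n <- length(human_ids)
    status <- sample(c("complete", "partial", "missing"), n, replace = TRUE,
                     prob = c(1 - frac_partial - frac_missing,
                              frac_partial, frac_missing))
    cls <- character(n)
    avail_m <- avail_r <- logical(n)
    comp <- status == "complete"
    cls[comp] <- sample(c("HMR", "HM", "HR", "H"), sum(comp),
                        replace = TRUE, prob = probs)
    avail_m[comp] <- TRUE; avail_r[comp] <- TRUE
    part <- which(status == "partial")
    for (i in part) {
      use_mouse <- runif(1) < 0.5
      conserved <- runif(1) < probs[["HMR"]] + probs[["HM"]]
      avail_m[i] <- use_mouse; avail_r[i] <- !use_mouse
      cls[i] <- if (conserved) {
        if (use_mouse) "HM" else "HR"
      } else "H"
    }
    cls[status == "missing"] <- NA_character_
    tab <- data.frame(human_id = human_ids, class = cls,
                      available_mouse = avail_m, available_rat = avail_r,
                      stringsAsFactors = FALSE)
    if (!is.null(path)) {
      write.table(tab, path, sep = "\t", quote = FALSE, na = "NA",
                  row.names = FALSE)
    }
    class(tab) <- c("devel_table", "data.frame")
    list(table = tab, path = path)
  })
}

#' Generate a GTEx-like expression panel with planted effects
#'
#' Builds a samples x genes TPM panel with log-normal noise around
#' tissue-specific means. Baseline genes share one mean across all
#' tissues (so their expected specificity score is
#' `log2(n_CNS / n_nonCNS)`, negative with the default 12 CNS vs 24
#' non-CNS tissues). Planted effects:
#' \describe{
#'   \item{brain_specific}{all CNS tissue means multiplied by `cns_fold`
#'     (default 16, i.e. expected specificity `log2(16 * 12/24) = 3`).}
#'   \item{reward_enriched}{one reward tissue (default nucleus accumbens)
#'     multiplied by `enrich_fold`.}
#'   \item{nonreward_enriched}{cerebellum and spinal cord multiplied by
#'     `enrich_fold`.}
#'   \item{sex_dimorphic}{male samples multiplied by `sex_fold` in every
#'     tissue.}
#'   \item{sex_interaction}{male samples multiplied by
#'     `interaction_fold` in the caudate only.}
#' }
#' Effects are multiplicative and may be combined; planting the same gene
#' both `reward_enriched` and `nonreward_enriched` is an error.
#'
#' @param n_genes number of genes.
#' @param tissue_sets a [tissue_sets()]; defaults to [gtex_tissue_sets()].
#' @param noncns_tissues labels for the non-CNS tissues (default 24 generic
#'   body tissues).
#' @param n_per_cell samples per sex x tissue cell (>= 2).
#' @param planted list with optional integer/character vectors
#'   `brain_specific`, `reward_enriched`, `nonreward_enriched`,
#'   `sex_dimorphic`, `sex_interaction` naming planted genes (indices or
#'   IDs).
#' @param cns_fold,enrich_fold,sex_fold,interaction_fold effect sizes
#'   (multiplicative; defaults 16, 4, 2.5, 6).
#' @param base_tpm_range range of baseline per-gene mean TPM (log-uniform;
#'   default 12-40 TPM).
#' @param sdlog log-normal noise sd on the log scale (default 0.3).
#' @param age_range donor ages, uniform (default 55-75 so the default
#'   age-55 cutoff keeps every sample).
#' @param seed integer seed.
#' @param tpm_path,meta_path optional TSV output paths (TPM written
#'   genes x samples).
#' @return A list: `panel` (an [expression_panel()]), `truth` (per gene:
#'   planted flags and the intended combined specificity/enrichment
#'   category), `tpm_path`, `meta_path`.
#' @export
generate_expression_panel <- function(n_genes = 30,
                                      tissue_sets = gtex_tissue_sets(),
                                      noncns_tissues = default_noncns_tissues(),
                                      n_per_cell = 4,
                                      planted = list(),
                                      cns_fold = 16, enrich_fold = 4,
                                      sex_fold = 2.5, interaction_fold = 6,
                                      base_tpm_range = c(12, 40),
                                      sdlog = 0.3,
                                      age_range = c(55, 75),
                                      seed = 1,
                                      tpm_path = NULL, meta_path = NULL) {
  check_number(n_genes, "n_genes", 1)
  check_number(n_per_cell, "n_per_cell", 2)
  stopifnot(inherits(tissue_sets, "tissue_sets"))
  with_seed(seed, {
    n_genes <- as.integer(n_genes)
    genes <- sprintf("hs_gene_%05d", seq_len(n_genes))

    as_ids <- function(x) {
      if (is.null(x)) return(character())
      if (is.numeric(x)) genes[x] else as.character(x)
    }
    plant <- lapply(
      setNames(nm = c("brain_specific", "reward_enriched",
                      "nonreward_enriched", "sex_dimorphic",
                      "sex_interaction")),
      function(nm) as_ids(planted[[nm]])
    )
    unknown <- setdiff(unlist(plant), genes)
    if (length(unknown)) {
      stop("planted gene(s) not in the panel: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    both <- intersect(plant$reward_enriched, plant$nonreward_enriched)
    if (length(both)) {
      stop("gene(s) planted contradictorily as both reward- and ",
           "non-reward-enriched: ", paste(both, collapse = ", "),
           call. = FALSE)
    }

    tissues <- c(tissue_sets$cns, noncns_tissues)
    meta <- expand.grid(tissue = tissues, sex = c("male", "female"),
                        rep = seq_len(as.integer(n_per_cell)),
                        stringsAsFactors = FALSE)
    meta$sample_id <- sprintf("S%04d", seq_len(nrow(meta)))
    meta$age <- round(runif(nrow(meta), age_range[1], age_range[2]), 0)

    base <- exp(runif(n_genes, log(base_tpm_range[1]), log(base_tpm_range[2])))
    # gene x tissue expected means
    mu <- matrix(base, nrow = n_genes, ncol = length(tissues),
                 dimnames = list(genes, tissues))
    cns <- tissue_sets$cns
    mu[plant$brain_specific, cns] <- mu[plant$brain_specific, cns] * cns_fold
    reward_target <- if ("nucleus_accumbens" %in% cns) "nucleus_accumbens"
                     else tissue_sets$reward[1]
    mu[plant$reward_enriched, reward_target] <-
      mu[plant$reward_enriched, reward_target] * enrich_fold
    mu[plant$nonreward_enriched, tissue_sets$nonreward_cns] <-
      mu[plant$nonreward_enriched, tissue_sets$nonreward_cns] * enrich_fold

    # sample x gene TPM
    tpm <- matrix(0, nrow = nrow(meta), ncol = n_genes,
                  dimnames = list(meta$sample_id, genes))
    for (i in seq_len(nrow(meta))) {
      m <- setNames(mu[, meta$tissue[i]], rownames(mu))
      if (meta$sex[i] == "male") {
        m[plant$sex_dimorphic] <- m[plant$sex_dimorphic] * sex_fold
        if (meta$tissue[i] == "caudate") {
          m[plant$sex_interaction] <- m[plant$sex_interaction] *
            interaction_fold
        }
      }
      tpm[i, ] <- rlnorm(n_genes, meanlog = log(m) - sdlog^2 / 2,
                         sdlog = sdlog)
    }

    baseline_spec <- log2(length(cns) / length(noncns_tissues))
    spec_pos <- genes %in% plant$brain_specific | baseline_spec > 0
    expected_cat <- ifelse(
      spec_pos,
      ifelse(genes %in% plant$reward_enriched, "High",
             ifelse(genes %in% plant$nonreward_enriched, "Medium", "Medium")),
      ifelse(genes %in% plant$reward_enriched, "Medium", "Low")
    )
    truth <- data.frame(
      gene = genes,
      brain_specific = genes %in% plant$brain_specific,
      reward_enriched = genes %in% plant$reward_enriched,
      nonreward_enriched = genes %in% plant$nonreward_enriched,
      sex_dimorphic = genes %in% plant$sex_dimorphic,
      sex_interaction = genes %in% plant$sex_interaction,
      expected_spec_enrich = expected_cat,
      stringsAsFactors = FALSE
    )

    panel <- expression_panel(tpm, meta[c("sample_id", "tissue", "sex",
                                          "age")], tissue_sets)
    if (!is.null(tpm_path)) {
      out <- data.frame(gene = genes, t(tpm), check.names = FALSE)
      write.table(out, tpm_path, sep = "\t", quote = FALSE,
                  row.names = FALSE)
    }
    if (!is.null(meta_path)) {
      write.table(meta[c("sample_id", "tissue", "sex", "age")], meta_path,
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
    list(panel = panel, truth = truth, tpm_path = tpm_path,
         meta_path = meta_path)
  })
}

#' Default non-CNS tissue labels for synthetic panels
#'
#' Twenty-four generic body tissues, so the baseline CNS:non-CNS ratio of a
#' uniformly expressed gene is 12/24 (specificity -1), mimicking the
#' negative genome-wide median specificity of a whole-body panel.
#' @return Character vector of 24 tissue labels.
#' @export
default_noncns_tissues <- function() {
  c("adipose", "adrenal_gland", "artery", "bladder", "breast", "colon",
    "esophagus", "heart", "kidney", "liver", "lung", "muscle", "nerve",
    "ovary", "pancreas", "prostate", "salivary_gland", "skin",
    "small_intestine", "spleen", "stomach", "testis", "thyroid",
    "whole_blood")
}

#' Generate two DEG lists with a controlled overlap structure
#'
#' Builds two differentially-expressed-gene lists sharing exactly
#' `n_shared` genes, of which `round(frac_concordant * n_shared)` are
#' regulated in the same direction in both lists.
#'
#' @param n_shared number of shared genes.
#' @param n_unique_each genes unique to each list (length-1 or length-2).
#' @param frac_concordant fraction of shared genes with the same direction.
#' @param seed integer seed.
#' @return A list: `list1`, `list2` (data.frames with `gene`,
#'   `direction`), `shared_genes`, `concordant_genes`.
#' @export
generate_deg_lists <- function(n_shared = 15, n_unique_each = c(618, 124),
                               frac_concordant = 10 / 15, seed = 1) {
  check_number(n_shared, "n_shared", 0)
  check_number(frac_concordant, "frac_concordant", 0, 1)
  if (length(n_unique_each) == 1L) n_unique_each <- rep(n_unique_each, 2L)
  stopifnot(length(n_unique_each) == 2L, all(n_unique_each >= 0))
  with_seed(seed, {
    n_shared <- as.integer(n_shared)
    n_conc <- round(frac_concordant * n_shared)
    shared <- sprintf("shared_%04d", seq_len(n_shared))
    u1 <- sprintf("only1_%04d", seq_len(n_unique_each[1]))
    u2 <- sprintf("only2_%04d", seq_len(n_unique_each[2]))
    dirs <- c("up", "down")
    d_shared1 <- sample(dirs, n_shared, replace = TRUE)
    d_shared2 <- d_shared1
    if (n_shared > n_conc) {
      flip <- seq_len(n_shared) > n_conc
      d_shared2[flip] <- ifelse(d_shared1[flip] == "up", "down", "up")
    }
    list1 <- data.frame(
      gene = c(shared, u1),
      direction = c(d_shared1, sample(dirs, length(u1), replace = TRUE)),
      stringsAsFactors = FALSE
    )
    list2 <- data.frame(
      gene = c(shared, u2),
      direction = c(d_shared2, sample(dirs, length(u2), replace = TRUE)),
      stringsAsFactors = FALSE
    )
    list(list1 = list1, list2 = list2, shared_genes = shared,
         concordant_genes = shared[seq_len(n_conc)])
  })
}
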