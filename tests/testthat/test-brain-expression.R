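# Brain specificity, mean CNS expression, tissue enrichment, sex effects.

test_that("specificity_score computes the log2 CNS/non-CNS ratio", {
  sets <- tissue_sets(cns = c("nucleus_accumbens", "cerebellum"),
                      reward = "nucleus_accumbens")
  tissues <- c("nucleus_accumbens", "cerebellum", "liver", "heart")
  mk <- function(na, cb, li, he) {
    m <- matrix(rep(c(na, cb, li, he), 2), 4, 2,
                dimnames = list(tissues, c("male", "female")))
    m
  }
  panel <- build_panel(list(
    balanced = mk(10, 10, 10, 10),     # sum CNS = sum nonCNS
    eightfold = mk(80, 80, 10, 10),    # 8x ratio -> 3
    cns_only = mk(5, 5, 0, 0),
    body_only = mk(0, 0, 5, 5)
  ), tissues, sets)
  expect_equal(specificity_score(panel, "balanced"), 0)
  expect_equal(specificity_score(panel, "eightfold"), 3)
  ex <- specificity_score(panel, "cns_only")
  expect_true(is.na(ex))
  expect_equal(attr(ex, "excluded_reason"), "cns_exclusive")
  ex2 <- specificity_score(panel, "body_only")
  expect_equal(attr(ex2, "excluded_reason"), "body_exclusive")
  expect_error(specificity_score(panel, "nope"), "not in panel")
})

test_that("specificity is antisymmetric under swapping CNS and non-CNS", {
  g <- generate_expression_panel(n_genes = 5, seed = 41,
                                 planted = list(brain_specific = 1))
  panel <- g$panel
  swapped <- panel
  noncns <- setdiff(unique(panel$samples$tissue), panel$tissue_sets$cns)
  swapped$tissue_sets <- tissue_sets(cns = noncns, reward = noncns[1])
  for (gene in panel_genes(panel)) {
    expect_equal(specificity_score(swapped, gene),
                 -specificity_score(panel, gene), tolerance = 1e-12)
  }
})

test_that("scaling TPM leaves specificity fixed and scales the CNS mean", {
  g <- generate_expression_panel(n_genes = 4, seed = 42)
  panel <- g$panel
  scaled <- panel
  scaled$tpm <- panel$tpm * 3.7
  for (gene in panel_genes(panel)) {
    expect_equal(specificity_score(scaled, gene),
                 specificity_score(panel, gene), tolerance = 1e-12)
    expect_equal(mean_cns_expression(scaled, gene)$mean_cns_tpm,
                 3.7 * mean_cns_expression(panel, gene)$mean_cns_tpm,
                 tolerance = 1e-12)
  }
})

test_that("mean CNS expression takes the unweighted grand mean of tissues", {
  sets <- tissue_sets(cns = c("tissue_a", "tissue_b"), reward = "tissue_a")
  # tissue_a samples 10,10,20,20 (mean 15); tissue_b all 40
  m <- matrix(c(15, 15, 40, 40), 2, 2,
              dimnames = list(c("tissue_a", "tissue_b"),
                              c("male", "female")))
  meta <- data.frame(
    sample_id = c("S1", "S2", "S3"),
    tissue = c("tissue_a", "tissue_a", "tissue_b"),
    sex = c("male", "female", "male"), age = 60
  )
  tpm <- matrix(c(10, 20, 40), 3, 1, dimnames = list(meta$sample_id, "g"))
  panel <- expression_panel(tpm, meta, sets)
  got <- mean_cns_expression(panel, "g")
  expect_equal(got$mean_cns_tpm, 27.5)   # (15 + 40)/2, not pooled 23.3
  expect_equal(got$category, "High")
})

test_that("mean CNS categories honor the 20/10 TPM boundaries", {
  sets <- tissue_sets(cns = "tissue_a", reward = "tissue_a")
  meta <- data.frame(sample_id = c("S1", "S2"), tissue = "tissue_a",
                     sex = c("male", "female"), age = 60)
  for (case in list(list(20, "High"), list(19.99, "Medium"),
                    list(10, "Medium"), list(1.10, "Low"))) {
    tpm <- matrix(case[[1]], 2, 1, dimnames = list(meta$sample_id, "g"))
    panel <- expression_panel(tpm, meta, sets)
    expect_equal(mean_cns_expression(panel, "g")$category, case[[2]])
  }
  # CNS tissue with zero samples is an error naming the tissue
  sets2 <- tissue_sets(cns = c("tissue_a", "ghost"), reward = "tissue_a")
  tpm <- matrix(5, 2, 1, dimnames = list(meta$sample_id, "g"))
  panel2 <- expression_panel(tpm, meta, sets2)
  expect_error(mean_cns_expression(panel2, "g"), "ghost")
})

test_that("tissue_enrichment finds planted patterns and the null case", {
  g <- generate_expression_panel(
    n_genes = 3, n_per_cell = 6, seed = 43,
    planted = list(reward_enriched = 1)
  )
  panel <- g$panel
  enr <- tissue_enrichment(panel, "hs_gene_00001")
  expect_true(enr$tissue_significant)
  expect_equal(enr$enriched_tissues, "nucleus_accumbens")
  # CLD of the top tissue must be exactly "a" for a well-separated gene
  expect_equal(unname(enr$cld$letters[1]), "a")

  # spinal cord highest with overlapping cerebellum: both carry an "a"
  sets <- gtex_tissue_sets()
  base <- setNames(rep(10, 12), sets$cns)
  shifted <- base; shifted["spinal_cord"] <- 30; shifted["cerebellum"] <- 27
  mk <- function(v) matrix(rep(v, 2), length(v), 2,
                           dimnames = list(names(v), c("male", "female")))
  withr::with_seed(44, {
    panel2 <- build_panel(list(dpysl2_like = mk(shifted)), sets$cns, sets,
                          n_per_cell = 4, jitter = 0.15)
  })
  enr2 <- tissue_enrichment(panel2, "dpysl2_like")
  expect_true(all(c("spinal_cord", "cerebellum") %in% enr2$enriched_tissues))
  expect_false("caudate" %in% enr2$enriched_tissues)
})

test_that("exchangeable tissues are declared enriched at rate <= alpha", {
  hits <- 0L
  n_runs <- 40L
  for (s in seq_len(n_runs)) {
    g <- generate_expression_panel(n_genes = 1, n_per_cell = 3,
                                   seed = 500 + s)
    enr <- tissue_enrichment(g$panel, "hs_gene_00001", alpha = 0.05)
    if (enr$tissue_significant) hits <- hits + 1L
  }
  # Binomial(40, 0.05): P(X > 7) < 1e-3
  expect_lte(hits, 7L)
})

test_that("spec_enrich_category implements the full rule table", {
  sets <- gtex_tissue_sets()
  cases <- list(
    list(1.2, "nucleus_accumbens", "High"),
    list(1.2, c("nucleus_accumbens", "caudate"), "High"),
    list(0.5, "cerebellum", "Medium"),            # nonreward only
    list(0.5, character(), "Medium"),             # no enrichment
    list(0.5, c("nucleus_accumbens", "spinal_cord"), "Medium"),  # mixed
    list(-2.0, "nucleus_accumbens", "Medium"),    # reward despite spec < 0
    list(-2.0, "spinal_cord", "Low"),
    list(-2.0, c("cerebellum", "spinal_cord"), "Low"),
    list(-2.0, character(), "Low"),               # uncovered case -> Low
    list(0, "nucleus_accumbens", "Medium"),       # boundary: not > 0
    list(0, character(), "Low")
  )
  for (cs in cases) {
    expect_equal(spec_enrich_category(cs[[1]], cs[[2]], sets), cs[[3]],
                 info = paste(cs[[1]], paste(cs[[2]], collapse = "+")))
  }
  expect_error(spec_enrich_category(NA, character(), sets), "excluded")
  expect_error(spec_enrich_category(1, "liver", sets), "outside the CNS")
})

test_that("sex effects distinguish main effects from interactions", {
  # pure main effect: males shifted in every tissue
  g <- generate_expression_panel(n_genes = 3, n_per_cell = 5, seed = 45,
                                 planted = list(sex_dimorphic = 1,
                                                sex_interaction = 2))
  panel <- g$panel
  main <- sex_effects(panel, "hs_gene_00001")
  expect_true(main$sex_main)
  expect_true(main$male_higher)

  inter <- sex_effects(panel, "hs_gene_00002")
  expect_true(inter$sex_tissue_interaction)

  null <- sex_effects(panel, "hs_gene_00003", alpha = 1e-4)
  expect_false(null$sex_main)
  expect_true(is.na(null$male_higher))
})

test_that("identical sexes give no sex effect and NA direction", {
  sets <- toy_tissue_sets()
  tissues <- sets$cns
  m <- matrix(c(10, 20, 10, 20), 2, 2,
              dimnames = list(tissues, c("male", "female")))
  withr::with_seed(46, {
    panel <- build_panel(list(g = m), tissues, sets, n_per_cell = 4,
                         jitter = 0.05)
  })
  sx <- sex_effects(panel, "g", alpha = 0.01)
  expect_false(sx$sex_main)
  expect_true(is.na(sx$male_higher))
})

test_that("age filtering errors usefully when cells empty out", {
  g <- generate_expression_panel(n_genes = 1, seed = 47,
                                 age_range = c(30, 40))
  expect_error(tissue_enrichment(g$panel, "hs_gene_00001", age_cutoff = 55),
               "age >= 55")
})

test_that("brain_expression_profiles collects consistent per-gene rows", {
  g <- generate_expression_panel(
    n_genes = 6, n_per_cell = 4, seed = 48,
    planted = list(brain_specific = c(1, 2), reward_enriched = 1,
                   nonreward_enriched = 2)
  )
  prof <- brain_expression_profiles(g$panel)
  expect_equal(nrow(prof), 6)
  expect_equal(prof$spec_enrich_cat[1], "High")
  expect_equal(prof$spec_enrich_cat[2], "Medium")
  expect_true(all(prof$spec_enrich_cat[3:6] %in% c("Medium", "Low")))
  # categories recompute from the stored numbers
  for (i in seq_len(nrow(prof))) {
    enriched <- strsplit(prof$enriched_tissues[i], ",")[[1]]
    expect_equal(
      spec_enrich_category(prof$specificity[i], enriched,
                           g$panel$tissue_sets),
      prof$spec_enrich_cat[i]
    )
  }
})
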