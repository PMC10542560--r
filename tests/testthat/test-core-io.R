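# Readers, writers, configuration, and the panel container.

make_ortholog_file <- function(path, rows) {
  header <- "rodent_id\thuman_id\thomology_type\tpct_similarity\tdn\tds"
  writeLines(c(header, rows), path)
  path
}

test_that("read_ortholog_table parses, flags one2one, and keeps missing dN/dS", {
  f <- withr::local_tempfile(fileext = ".tsv")
  make_ortholog_file(f, c(
    "mm1\ths1\tone2one\t95.2\t0.01\t0.2",
    "mm2\ths2\tone2one\t100\t\t",
    "mm3\ths3\tortholog_one2one\t85\t0.05\t0.3",
    "mm4\ths4\tone2many\t70\t0.2\t0.5"
  ))
  tab <- read_ortholog_table(f, "mouse")
  expect_equal(nrow(tab), 4)
  expect_equal(sum(tab$one_to_one), 3)       # prefix form normalized too
  expect_true(is.na(tab$dn[2]) && is.na(tab$ds[2]))   # retained, ratio missing
  expect_equal(attr(tab, "species"), "mouse")
})

test_that("read_ortholog_table rejects malformed input with located errors", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("rodent_id\thuman_id\tpct_similarity", "mm1\ths1\t90"), f)
  expect_error(read_ortholog_table(f), "homology_type")

  make_ortholog_file(f, "mm1\ths1\tone2one\t101\t0.1\t0.2")
  expect_error(read_ortholog_table(f), "out of \\[0, 100\\] on line 2")

  make_ortholog_file(f, "mm1\ths1\tone2one\tabc\t0.1\t0.2")
  expect_error(read_ortholog_table(f), "non-numeric.*line 2")

  make_ortholog_file(f, c("mm1\ths1\tone2one\t90\t0.1\t0.2",
                          "mm1\ths1\tone2one\t91\t0.1\t0.2"))
  expect_error(read_ortholog_table(f), "duplicate")
})

test_that("read_devel_table validates class/availability consistency", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("human_id\tclass\tavailable_mouse\tavailable_rat",
               "hs1\tHMR\tTRUE\tTRUE",
               "hs2\tHM\tTRUE\tFALSE",
               "hs3\tNA\tFALSE\tFALSE"), f)
  tab <- read_devel_table(f)
  expect_equal(tab$class, c("HMR", "HM", NA))

  writeLines(c("human_id\tclass\tavailable_mouse\tavailable_rat",
               "hs1\tHM\tFALSE\tTRUE"), f)
  expect_error(read_devel_table(f), "inconsistent.*line 2")
})

test_that("read_expression_panel filters excluded tissues and maps sex aliases", {
  sets <- tissue_sets(cns = c("nucleus_accumbens", "cerebellum"),
                      reward = "nucleus_accumbens",
                      excluded = "cells_cultured")
  tpm <- withr::local_tempfile(fileext = ".tsv")
  meta <- withr::local_tempfile(fileext = ".tsv")
  # genes x samples TSV, 6 samples, one in an excluded tissue
  writeLines(c("gene\tS1\tS2\tS3\tS4\tS5\tS6",
               "g1\t1\t2\t3\t4\t5\t6",
               "g2\t6\t5\t4\t3\t2\t1"), tpm)
  writeLines(c("sample_id\ttissue\tsex\tage",
               "S1\tnucleus_accumbens\tM\t60",
               "S2\tnucleus_accumbens\tF\t61",
               "S3\tcerebellum\tMale\t62",
               "S4\tcerebellum\tfemale\t63",
               "S5\tliver\tF\t64",
               "S6\tcells_cultured\tM\t65"), meta)
  expect_message(panel <- read_expression_panel(tpm, meta, sets),
                 "dropping 1 sample")
  expect_equal(nrow(panel$tpm), 5)
  expect_setdiff_empty <- setdiff(panel$samples$sex, c("male", "female"))
  expect_length(expect_setdiff_empty, 0)
  expect_equal(panel$tpm["S1", "g1"], 1)

  # sample missing from metadata
  writeLines(c("sample_id\ttissue\tsex\tage",
               "S1\tnucleus_accumbens\tM\t60"), meta)
  expect_error(read_expression_panel(tpm, meta, sets), "S2")
})

test_that("bracketed ages are rejected unless coercion is requested", {
  sets <- toy_tissue_sets()
  tpm <- withr::local_tempfile(fileext = ".tsv")
  meta <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene\tS1\tS2", "g1\t1\t2"), tpm)
  writeLines(c("sample_id\ttissue\tsex\tage",
               "S1\tnucleus_accumbens\tM\t50-59",
               "S2\tcerebellum\tF\t60-69"), meta)
  expect_error(read_expression_panel(tpm, meta, sets), "bracket")
  panel <- read_expression_panel(tpm, meta, sets,
                                 age_bracket_lower_bound = TRUE)
  expect_equal(panel$samples$age, c(50, 60))
})

test_that("unknown tissues error only when a non-CNS list is declared", {
  tpm <- withr::local_tempfile(fileext = ".tsv")
  meta <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene\tS1\tS2", "g1\t1\t2"), tpm)
  writeLines(c("sample_id\ttissue\tsex\tage",
               "S1\tnucleus_accumbens\tM\t60",
               "S2\tmystery_tissue\tF\t61"), meta)
  open_sets <- tissue_sets(cns = "nucleus_accumbens",
                           reward = "nucleus_accumbens")
  expect_s3_class(read_expression_panel(tpm, meta, open_sets),
                  "expression_panel")
  closed_sets <- tissue_sets(cns = "nucleus_accumbens",
                             reward = "nucleus_accumbens",
                             noncns = "liver")
  expect_error(read_expression_panel(tpm, meta, closed_sets),
               "mystery_tissue")
})

test_that("GCT 1.2 round-trips and header mismatches are format errors", {
  gct <- withr::local_tempfile(fileext = ".gct")
  meta <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("#1.2", "2\t3",
               "Name\tDescription\tS1\tS2\tS3",
               "g1\tna\t1\t2\t3",
               "g2\tna\t4\t5\t6"), gct)
  writeLines(c("sample_id\ttissue\tsex\tage",
               "S1\tnucleus_accumbens\tM\t60",
               "S2\tcerebellum\tF\t61",
               "S3\tliver\tF\t62"), meta)
  panel <- read_expression_panel(gct, meta, toy_tissue_sets())
  expect_equal(dim(panel$tpm), c(3L, 2L))
  expect_equal(panel$tpm["S3", "g2"], 6)

  writeLines(c("#1.2", "10\t3",
               "Name\tDescription\tS1\tS2\tS3",
               "g1\tna\t1\t2\t3"), gct)
  expect_error(read_expression_panel(gct, meta, toy_tissue_sets()),
               "declares 10 genes but has 1")
})

test_that("tissue_sets enforces the reward/CNS/excluded relations", {
  expect_error(tissue_sets(cns = "a", reward = "b"), "subset")
  expect_error(tissue_sets(cns = "a", reward = "a", excluded = "a"),
               "overlap")
  gtex <- gtex_tissue_sets()
  expect_length(gtex$cns, 12)
  expect_length(gtex$reward, 10)
  expect_setequal(gtex$nonreward_cns, c("cerebellum", "spinal_cord"))
})

test_that("priority table writing round-trips exactly and rejects empties", {
  rec <- data.frame(
    human_id = c("hs1", "hs2"),
    sim_mouse_cat = c("High", "Low"), sim_rat_cat = c("High", NA),
    dnds_mouse_cat = c("High", "Medium"), dnds_rat_cat = c("High", "Low"),
    devel_cat = c("High", NA), spec_enrich_cat = c("High", "Medium"),
    mean_cns_cat = c("High", "Low"),
    sim_mouse_pct = c(99.5, 45.2), sim_rat_pct = c(98.1, NA),
    dnds_mouse = c(0.01, 0.5), dnds_rat = c(0.02, 0.9),
    devel_class = c("HMR", NA), specificity = c(3.2, -1.5),
    enriched_tissues = c("nucleus_accumbens", ""),
    mean_cns_tpm = c(55.2, 2.1),
    sex_main = c(TRUE, FALSE), male_higher = c(TRUE, NA),
    sex_tissue_interaction = c(FALSE, FALSE),
    stringsAsFactors = FALSE
  )
  f <- withr::local_tempfile(fileext = ".tsv")
  write_priority_table(rec, f)
  # devel NA is the literal string NA, not an empty cell
  lines <- readLines(f)
  expect_true(grepl("\tNA\t", lines[3]))
  back <- read_priority_table(f)
  for (col in setdiff(names(rec), "enriched_tissues")) {
    expect_equal(back[[col]], rec[[col]], info = col)
  }
  expect_error(write_priority_table(rec[0, ], f), "non-empty")
})

test_that("read_config merges YAML over defaults and validates keys", {
  cfg <- read_config()
  expect_equal(cfg$alpha, 0.05)
  expect_equal(cfg$age_cutoff, 55)
  expect_equal(cfg$thresholds$similarity_high, 90)

  f <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("alpha: 0.01",
               "thresholds:",
               "  tpm_high: 30",
               "tissue_sets:",
               "  cns: [nucleus_accumbens, cerebellum]",
               "  reward: [nucleus_accumbens]"), f)
  cfg2 <- read_config(f)
  expect_equal(cfg2$alpha, 0.01)
  expect_equal(cfg2$thresholds$tpm_high, 30)
  expect_equal(cfg2$thresholds$tpm_low, 10)       # default survives
  expect_equal(cfg2$tissue_sets$cns, c("nucleus_accumbens", "cerebellum"))

  writeLines("bogus_key: 1", f)
  expect_error(read_config(f), "unknown config keys")
})
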