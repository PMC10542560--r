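#' Tissue-set configuration for an expression panel
#'
#' Defines which tissues of a panel count as central nervous system (CNS),
#' which CNS tissues are reward-related, which samples are dropped outright
#' (e.g. duplicated brain collections, cultured cell lines), and optionally
#' the complete list of accepted non-CNS tissues.
#'
#' @param cns character vector of CNS tissue labels.
#' @param reward character vector of reward-related tissues; must be a subset
#'   of `cns`.
#' @param excluded tissue labels whose samples are removed when a panel is
#'   read; must be disjoint from `cns`.
#' @param noncns optional character vector naming every accepted non-CNS
#'   tissue. When `NULL` (default) any tissue not listed in `cns` or
#'   `excluded` is treated as non-CNS; when given, an unlisted tissue in the
#'   sample metadata is an error.
#'
#' @return A list of class `tissue_sets` with components `cns`, `reward`,
#'   `nonreward_cns`, `excluded`, `noncns`.
#' @seealso [gtex_tissue_sets()] for the default 12-tissue CNS configuration.
#' @export
tissue_sets <- function(cns, reward, excluded = character(), noncns = NULL) {
  cns <- as.character(cns); reward <- as.character(reward)
  excluded <- as.character(excluded)
  if (anyDuplicated(cns)) stop("duplicate CNS tissue labels", call. = FALSE)
  if (!all(reward %in% cns)) {
    stop("reward tissues must be a subset of the CNS set: ",
         paste(setdiff(reward, cns), collapse = ", "), call. = FALSE)
  }
  if (length(intersect(excluded, cns))) {
    stop("excluded tissues overlap the CNS set: ",
         paste(intersect(excluded, cns), collapse = ", "), call. = FALSE)
  }
  if (!is.null(noncns)) {
    noncns <- as.character(noncns)
    if (length(intersect(noncns, c(cns, excluded)))) {
      stop("non-CNS tissue list overlaps the CNS or excluded sets",
           call. = FALSE)
    }
  }
  structure(
    list(cns = cns, reward = reward,
         nonreward_cns = setdiff(cns, reward),
         excluded = excluded, noncns = noncns),
    class = "tissue_sets"
  )
}

#' Default CNS / reward tissue sets
#'
#' The default configuration mirrors the 12 CNS tissues of the GTEx human
#' panel: 10 reward-related tissues (amygdala, anterior cingulate cortex,
#' caudate, frontal cortex, hippocampus, hypothalamus, nucleus accumbens,
#' pituitary, putamen, substantia nigra) plus two primarily motor-related
#' tissues (cerebellum, spinal cord). Duplicate cortical/cerebellar
#' collections and cultured cell lines are excluded.
#'
#' @return A `tissue_sets` object.
#' @export
gtex_tissue_sets <- function() {
  reward <- c("amygdala", "anterior_cingulate_cortex", "caudate",
              "frontal_cortex", "hippocampus", "hypothalamus",
              "nucleus_accumbens", "pituitary", "putamen",
              "substantia_nigra")
  tissue_sets(
    cns = c(reward, "cerebellum", "spinal_cord"),
    reward = reward,
    excluded = c("cortex_replicate", "cerebellum_replicate",
                 "cells_cultured_fibroblasts", "cells_ebv_lymphocytes")
  )
}

#' @export
print.tissue_sets <- function(x, ...) {
  cat("Tissue sets:\n")
  cat("  CNS (", length(x$cns), "): ", paste(x$cns, collapse = ", "),
      "\n", sep = "")
  cat("  reward (", length(x$reward), "): ",
      paste(x$reward, collapse = ", "), "\n", sep = "")
  cat("  non-reward CNS: ", paste(x$nonreward_cns, collapse = ", "),
      "\n", sep = "")
  if (length(x$excluded)) {
    cat("  excluded: ", paste(x$excluded, collapse = ", "), "\n", sep = "")
  }
  if (!is.null(x$noncns)) {
    cat("  non-CNS (", length(x$noncns), " declared)\n", sep = "")
  }
  invisible(x)
}
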