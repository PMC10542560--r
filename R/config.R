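#' Pipeline configuration
#'
#' Reads a YAML configuration file and merges it over the package defaults.
#' Recognized keys: `alpha` (significance level for ANOVA/Tukey/CLD and the
#' distribution comparisons), `age_cutoff` (minimum donor age in years for the
#' sex/tissue analyses), `n_sim` (Monte-Carlo replicates for simulated Fisher
#' p-values), `bonferroni_family` (override for the Mann-Whitney family
#' size), `thresholds` (`similarity_high`, `similarity_low`, `tpm_high`,
#' `tpm_low`) and `tissue_sets` (`cns`, `reward`, `excluded`, `noncns`).
#'
#' @param path path to a YAML file, or `NULL` for pure defaults.
#' @return A list of class `brainprior_config`.
#' @export
read_config <- function(path = NULL) {
  cfg <- default_config()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
    user <- yaml::read_yaml(path)
    if (!is.null(user$tissue_sets)) {
      ts <- user$tissue_sets
      base <- cfg$tissue_sets
      cfg$tissue_sets <- tissue_sets(
        cns = ts$cns %||% base$cns,
        reward = ts$reward %||% base$reward,
        excluded = ts$excluded %||% base$excluded,
        noncns = ts$noncns %||% base$noncns
      )
      user$tissue_sets <- NULL
    }
    if (!is.null(user$thresholds)) {
      cfg$thresholds[names(user$thresholds)] <- user$thresholds
      user$thresholds <- NULL
    }
    unknown <- setdiff(names(user), names(cfg))
    if (length(unknown)) {
      stop("unknown config keys: ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
    cfg[names(user)] <- user
  }
  check_number(cfg$alpha, "alpha", 0, 1)
  check_number(cfg$age_cutoff, "age_cutoff", 0)
  check_number(cfg$n_sim, "n_sim", 1)
  structure(cfg, class = "brainprior_config")
}

default_config <- function() {
  list(
    alpha = 0.05,
    age_cutoff = 55,
    n_sim = 1e5,
    bonferroni_family = NULL,
    thresholds = list(similarity_high = 90, similarity_low = 80,
                      tpm_high = 20, tpm_low = 10),
    tissue_sets = gtex_tissue_sets()
  )
}
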