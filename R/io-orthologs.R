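#' Read an ortholog annotation table
#'
#' Reads a tab-separated table of rodent-human ortholog pairs as exported
#' from Ensembl/biomaRt. Required columns: `rodent_id`, `human_id`,
#' `homology_type` (`one2one`, `one2many`, `many2many`; an
#' `ortholog_` prefix is stripped), `pct_similarity` (percentage of the
#' matched protein sequence, rodent perspective, 0-100). Optional columns
#' `dn` and `ds` (also accepted as `dN`/`dS`) carry nonsynonymous and
#' synonymous divergence; blanks are missing values. All rows are returned;
#' downstream statistics filter on the derived `one_to_one` flag.
#'
#' @param path path to the TSV file.
#' @param species `"mouse"` or `"rat"`; recorded as an attribute.
#' @return A `data.frame` of class `ortholog_table` with columns
#'   `rodent_id`, `human_id`, `homology_type`, `pct_similarity`, `dn`, `ds`,
#'   `one_to_one`.
#' @export
read_ortholog_table <- function(path, species = c("mouse", "rat")) {
  species <- match.arg(species)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                    colClasses = "character", na.strings = c("NA", ""))
  required <- c("rodent_id", "human_id", "homology_type", "pct_similarity")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols)) {
    stop("ortholog table is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  names(raw)[names(raw) == "dN"] <- "dn"
  names(raw)[names(raw) == "dS"] <- "ds"
  if (!"dn" %in% names(raw)) raw$dn <- NA_character_
  if (!"ds" %in% names(raw)) raw$ds <- NA_character_

  out <- raw[c("rodent_id", "human_id", "homology_type", "pct_similarity",
               "dn", "ds")]
  # header line is line 1, so data row i sits on file line i + 1
  for (col in c("pct_similarity", "dn", "ds")) {
    vals <- suppressWarnings(as.numeric(out[[col]]))
    bad <- which(!is.na(out[[col]]) & is.na(vals))
    if (length(bad)) {
      stop(sprintf("non-numeric `%s` value %s on line %d of %s",
                   col, dQuote(out[[col]][bad[1]]), bad[1] + 1L, path),
           call. = FALSE)
    }
    out[[col]] <- vals
  }
  if (anyNA(out$rodent_id) || !all(nzchar(out$rodent_id))) {
    stop("empty rodent_id in ortholog table", call. = FALSE)
  }
  oor <- which(!is.na(out$pct_similarity) &
                 (out$pct_similarity < 0 | out$pct_similarity > 100))
  if (length(oor)) {
    stop(sprintf("pct_similarity out of [0, 100] on line %d (value %s)",
                 oor[1] + 1L, format(out$pct_similarity[oor[1]])),
         call. = FALSE)
  }
  neg <- which((!is.na(out$dn) & out$dn < 0) | (!is.na(out$ds) & out$ds < 0))
  if (length(neg)) {
    stop(sprintf("negative dN or dS on line %d", neg[1] + 1L), call. = FALSE)
  }
  out$homology_type <- sub("^ortholog_", "", out$homology_type)
  valid_types <- c("one2one", "one2many", "many2many")
  if (!all(out$homology_type %in% valid_types)) {
    bad <- setdiff(unique(out$homology_type), valid_types)
    stop("unknown homology_type value(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  dup <- duplicated(out[c("rodent_id", "human_id")])
  if (any(dup)) {
    stop("duplicate (rodent_id, human_id) pair(s): ",
         paste(unique(paste(out$rodent_id[dup], out$human_id[dup], sep = "/")),
               collapse = ", "), call. = FALSE)
  }
  out$one_to_one <- out$homology_type == "one2one"
  attr(out, "species") <- species
  class(out) <- c("ortholog_table", "data.frame")
  out
}

#' Read a developmental-conservation table
#'
#' Reads a tab-separated table assigning each human gene a forebrain
#' developmental-conservation class: `HMR` (temporal expression conserved in
#' human, mouse and rat), `HM` (human and mouse only), `HR` (human and rat
#' only), or `H` (conserved with neither rodent). Columns `available_mouse`
#' and `available_rat` flag whether data for the species comparison exists;
#' `class` may be missing when neither comparison has data.
#'
#' @param path path to the TSV file with columns `human_id`, `class`,
#'   `available_mouse`, `available_rat`.
#' @return A `data.frame` of class `devel_table`.
#' @export
read_devel_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                    colClasses = "character", na.strings = c("NA", ""))
  required <- c("human_id", "class", "available_mouse", "available_rat")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols)) {
    stop("developmental table is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  out <- raw[required]
  for (col in c("available_mouse", "available_rat")) {
    v <- toupper(out[[col]])
    flag <- v %in% c("TRUE", "T", "1")
    bad <- !v %in% c("TRUE", "T", "1", "FALSE", "F", "0")
    if (any(bad)) {
      stop(sprintf("non-logical `%s` value on line %d", col,
                   which(bad)[1] + 1L), call. = FALSE)
    }
    out[[col]] <- flag
  }
  ok_class <- is.na(out$class) | out$class %in% c("HMR", "HM", "HR", "H")
  if (!all(ok_class)) {
    stop("invalid developmental class on line ",
         which(!ok_class)[1] + 1L, " (allowed: HMR, HM, HR, H)",
         call. = FALSE)
  }
  # class must be consistent with availability
  inconsistent <-
    (!is.na(out$class) & out$class %in% c("HMR", "HM") & !out$available_mouse) |
    (!is.na(out$class) & out$class %in% c("HMR", "HR") & !out$available_rat) |
    (is.na(out$class) & (out$available_mouse | out$available_rat)) |
    (!is.na(out$class) & !out$available_mouse & !out$available_rat)
  if (any(inconsistent)) {
    stop("developmental class inconsistent with species availability on line ",
         which(inconsistent)[1] + 1L, call. = FALSE)
  }
  if (anyDuplicated(out$human_id)) {
    stop("duplicate human_id in developmental table", call. = FALSE)
  }
  class(out) <- c("devel_table", "data.frame")
  out
}
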