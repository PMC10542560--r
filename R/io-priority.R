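# Priority-table serialization. Column order is fixed so tables from
# different runs line up; categorical NA is written as the literal "NA".

PRIORITY_COLUMNS <- c(
  "human_id",
  "sim_mouse_cat", "sim_rat_cat", "dnds_mouse_cat", "dnds_rat_cat",
  "devel_cat", "spec_enrich_cat", "mean_cns_cat",
  "sim_mouse_pct", "sim_rat_pct", "dnds_mouse", "dnds_rat",
  "devel_class", "specificity", "enriched_tissues", "mean_cns_tpm",
  "sex_main", "male_higher", "sex_tissue_interaction"
)

#' Write a priority table
#'
#' Serializes per-gene priority records to a TSV with a stable column order:
#' the gene identifier, the eight High/Medium/Low category columns (sequence
#' similarity and dN/dS for each rodent species, developmental conservation,
#' brain specificity + enrichment, mean CNS expression), the supporting
#' numeric columns, and the sex-effect flags. Missing categories are written
#' as the literal string `NA`.
#'
#' @param records a data.frame of priority records, as produced by
#'   [build_priority_records()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_priority_table <- function(records, path) {
  if (!is.data.frame(records) || nrow(records) == 0L) {
    stop("`records` must be a non-empty data.frame of priority records",
         call. = FALSE)
  }
  for (col in setdiff(PRIORITY_COLUMNS, names(records))) {
    records[[col]] <- NA
  }
  records <- records[PRIORITY_COLUMNS]
  write.table(records, path, sep = "\t", quote = FALSE, na = "NA",
              row.names = FALSE)
  invisible(path)
}

#' Read a priority table written by [write_priority_table()]
#'
#' @param path path to the TSV file.
#' @return A data.frame with the standard priority columns and types.
#' @export
read_priority_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tab <- read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                    colClasses = "character", na.strings = "NA")
  missing_cols <- setdiff(PRIORITY_COLUMNS, names(tab))
  if (length(missing_cols)) {
    stop("priority table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  numeric_cols <- c("sim_mouse_pct", "sim_rat_pct", "dnds_mouse", "dnds_rat",
                    "specificity", "mean_cns_tpm")
  logical_cols <- c("sex_main", "male_higher", "sex_tissue_interaction")
  cat_cols <- c("sim_mouse_cat", "sim_rat_cat", "dnds_mouse_cat",
                "dnds_rat_cat", "devel_cat", "spec_enrich_cat",
                "mean_cns_cat")
  for (col in numeric_cols) tab[[col]] <- as.numeric(tab[[col]])
  for (col in logical_cols) tab[[col]] <- as.logical(tab[[col]])
  for (col in cat_cols) {
    bad <- !is.na(tab[[col]]) & !tab[[col]] %in% PRIORITY_LEVELS
    if (any(bad)) {
      stop("invalid category value in column ", col, ": ",
           paste(unique(tab[[col]][bad]), collapse = ", "), call. = FALSE)
    }
  }
  tab
}
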