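#' Construct an expression panel
#'
#' An expression panel bundles a samples x genes TPM matrix with per-sample
#' metadata (tissue, sex, age in years) and a tissue-set configuration.
#' Normally built by [read_expression_panel()] or
#' [generate_expression_panel()].
#'
#' @param tpm numeric matrix, samples in rows, genes in columns, TPM units.
#' @param sample_meta data.frame with columns `sample_id`, `tissue`, `sex`
#'   (`"male"`/`"female"`), `age` (numeric years); one row per TPM row.
#' @param tissue_sets a [tissue_sets()] configuration.
#' @return An object of class `expression_panel`.
#' @export
expression_panel <- function(tpm, sample_meta, tissue_sets = gtex_tissue_sets()) {
  stopifnot(is.matrix(tpm), is.numeric(tpm), is.data.frame(sample_meta))
  required <- c("sample_id", "tissue", "sex", "age")
  missing_cols <- setdiff(required, names(sample_meta))
  if (length(missing_cols)) {
    stop("sample metadata is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (nrow(tpm) != nrow(sample_meta)) {
    stop("TPM matrix and sample metadata disagree on the number of samples",
         call. = FALSE)
  }
  if (is.null(rownames(tpm))) rownames(tpm) <- sample_meta$sample_id
  if (!identical(rownames(tpm), as.character(sample_meta$sample_id))) {
    stop("TPM row names do not match sample metadata sample_id order",
         call. = FALSE)
  }
  if (is.null(colnames(tpm))) stop("TPM matrix must have gene names",
                                   call. = FALSE)
  if (any(tpm < 0, na.rm = TRUE)) stop("negative TPM values", call. = FALSE)
  if (anyNA(tpm)) stop("missing TPM values", call. = FALSE)
  if (!all(sample_meta$sex %in% c("male", "female"))) {
    stop("sample sex must be 'male' or 'female'", call. = FALSE)
  }
  if (!is.numeric(sample_meta$age) || anyNA(sample_meta$age)) {
    stop("sample age must be numeric years", call. = FALSE)
  }
  if (!inherits(tissue_sets, "tissue_sets")) {
    stop("`tissue_sets` must be built with tissue_sets()", call. = FALSE)
  }
  if (length(intersect(sample_meta$tissue, tissue_sets$excluded))) {
    stop("panel still contains samples from excluded tissues", call. = FALSE)
  }
  if (!is.null(tissue_sets$noncns)) {
    known <- c(tissue_sets$cns, tissue_sets$noncns)
    unknown <- setdiff(unique(sample_meta$tissue), known)
    if (length(unknown)) {
      stop("tissue(s) not in any configured set: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
  }
  structure(
    list(tpm = tpm,
         samples = data.frame(sample_id = as.character(sample_meta$sample_id),
                              tissue = as.character(sample_meta$tissue),
                              sex = as.character(sample_meta$sex),
                              age = as.numeric(sample_meta$age),
                              stringsAsFactors = FALSE),
         tissue_sets = tissue_sets),
    class = "expression_panel"
  )
}

#' @export
print.expression_panel <- function(x, ...) {
  tis <- unique(x$samples$tissue)
  cat("Expression panel: ", nrow(x$tpm), " samples x ", ncol(x$tpm),
      " genes\n", sep = "")
  cat("  tissues: ", length(tis), " (", sum(tis %in% x$tissue_sets$cns),
      " CNS)\n", sep = "")
  cat("  sex: ", sum(x$samples$sex == "male"), " male / ",
      sum(x$samples$sex == "female"), " female; age ",
      min(x$samples$age), "-", max(x$samples$age), " years\n", sep = "")
  invisible(x)
}

#' Genes of an expression panel
#' @param panel an `expression_panel`.
#' @return Character vector of gene identifiers.
#' @export
panel_genes <- function(panel) {
  stopifnot(inherits(panel, "expression_panel"))
  colnames(panel$tpm)
}

# sex label dialects accepted by the reader
SEX_ALIASES <- c(male = "male", m = "male", males = "male",
                 female = "female", f = "female", females = "female")

#' Read an expression panel from disk
#'
#' Reads a TPM matrix (plain TSV, or GCT 1.2 when the file starts with
#' `#1.2`) together with a sample-attribute TSV (`sample_id`, `tissue`,
#' `sex`, `age`). Sex labels are normalized via a documented alias map
#' (`M`/`F`, any case, optional plural). Samples from tissues listed in
#' `tissue_sets$excluded` are dropped with a message. Samples present in the
#' matrix but absent from the metadata are an error, as are (when the
#' configuration declares a non-CNS list) tissues not in any set.
#'
#' @param tpm_path path to the expression matrix. A plain TSV has gene or
#'   sample identifiers in the first column, per `genes_in_rows`.
#' @param meta_path path to the sample-attribute TSV.
#' @param tissue_sets a [tissue_sets()] configuration.
#' @param genes_in_rows orientation of a plain-TSV matrix: `TRUE` (default)
#'   means rows are genes and columns samples (as in GCT). Ignored for GCT.
#' @param age_bracket_lower_bound if `TRUE`, bracketed ages such as
#'   `"50-59"` are coerced to their lower bound; by default they are
#'   rejected because an exact age cutoff cannot be applied to brackets.
#' @return An [expression_panel()].
#' @export
read_expression_panel <- function(tpm_path, meta_path,
                                  tissue_sets = gtex_tissue_sets(),
                                  genes_in_rows = TRUE,
                                  age_bracket_lower_bound = FALSE) {
  if (!file.exists(tpm_path)) stop("file not found: ", tpm_path, call. = FALSE)
  if (!file.exists(meta_path)) stop("file not found: ", meta_path, call. = FALSE)

  first <- readLines(tpm_path, n = 1L)
  if (startsWith(first, "#1.2")) {
    mat <- read_gct(tpm_path)            # genes x samples
    tpm <- t(mat)
  } else {
    tab <- read.delim(tpm_path, sep = "\t", header = TRUE,
                      check.names = FALSE, row.names = 1L)
    mat <- as.matrix(tab)
    if (!is.numeric(mat)) stop("non-numeric expression values in ", tpm_path,
                               call. = FALSE)
    tpm <- if (genes_in_rows) t(mat) else mat
  }

  meta <- read.delim(meta_path, sep = "\t", header = TRUE,
                     check.names = FALSE, colClasses = "character",
                     na.strings = c("NA", ""))
  required <- c("sample_id", "tissue", "sex", "age")
  missing_cols <- setdiff(required, names(meta))
  if (length(missing_cols)) {
    stop("sample metadata is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  absent <- setdiff(rownames(tpm), meta$sample_id)
  if (length(absent)) {
    stop("sample(s) in expression matrix but not in metadata: ",
         paste(absent, collapse = ", "), call. = FALSE)
  }
  meta <- meta[match(rownames(tpm), meta$sample_id), , drop = FALSE]

  sex_norm <- unname(SEX_ALIASES[tolower(meta$sex)])
  if (anyNA(sex_norm)) {
    stop("unrecognized sex label(s): ",
         paste(unique(meta$sex[is.na(sex_norm)]), collapse = ", "),
         call. = FALSE)
  }
  meta$sex <- sex_norm

  age_num <- suppressWarnings(as.numeric(meta$age))
  bracket <- grepl("^\\s*\\d+\\s*-\\s*\\d+\\s*$", meta$age)
  if (any(is.na(age_num))) {
    if (all(bracket[is.na(age_num)]) && age_bracket_lower_bound) {
      lower <- as.numeric(sub("-.*$", "", meta$age))
      age_num[is.na(age_num)] <- lower[is.na(age_num)]
    } else if (any(bracket)) {
      stop("bracketed ages (e.g. \"50-59\") cannot be used with an exact ",
           "age cutoff; rerun with age_bracket_lower_bound = TRUE to ",
           "coerce to the bracket lower bound", call. = FALSE)
    } else {
      stop("non-numeric age value(s): ",
           paste(unique(meta$age[is.na(age_num)]), collapse = ", "),
           call. = FALSE)
    }
  }
  meta$age <- age_num

  drop <- meta$tissue %in% tissue_sets$excluded
  if (any(drop)) {
    message("dropping ", sum(drop), " sample(s) from excluded tissue(s): ",
            paste(unique(meta$tissue[drop]), collapse = ", "))
    tpm <- tpm[!drop, , drop = FALSE]
    meta <- meta[!drop, , drop = FALSE]
  }
  expression_panel(tpm, meta, tissue_sets)
}

# GCT 1.2: line 1 "#1.2"; line 2 "<n_genes>\t<n_samples>"; line 3 header
# (Name, Description, sample ids); then one row per gene.
read_gct <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 3L) stop("truncated GCT file: ", path, call. = FALSE)
  dims <- strsplit(trimws(lines[2L]), "\t| +")[[1]]
  dims <- suppressWarnings(as.integer(dims))
  if (length(dims) < 2L || anyNA(dims[1:2])) {
    stop("malformed GCT dimension line in ", path, call. = FALSE)
  }
  n_genes <- dims[1L]; n_samples <- dims[2L]
  body <- read.delim(text = lines[-(1:2)], sep = "\t", header = TRUE,
                     check.names = FALSE)
  if (!all(c("Name", "Description") %in% names(body)[1:2])) {
    stop("GCT header must start with Name and Description columns",
         call. = FALSE)
  }
  if (nrow(body) != n_genes) {
    stop(sprintf("GCT declares %d genes but has %d data rows",
                 n_genes, nrow(body)), call. = FALSE)
  }
  if (ncol(body) - 2L != n_samples) {
    stop(sprintf("GCT declares %d samples but has %d data columns",
                 n_samples, ncol(body) - 2L), call. = FALSE)
  }
  mat <- as.matrix(body[, -(1:2), drop = FALSE])
  if (!is.numeric(mat)) stop("non-numeric expression values in GCT body",
                             call. = FALSE)
  rownames(mat) <- body$Name
  mat
}
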