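#' Compact letter display from pairwise significance
#'
#' Summarizes an all-pairs comparison as letter codes using the
#' insert-and-absorb algorithm: starting from a single letter covering all
#' groups, every significantly different pair splits the letters containing
#' both members, and letters whose group set is contained in another are
#' absorbed. Two groups share at least one letter if and only if their
#' comparison is non-significant; this invariant is asserted on every call.
#' Letters are ranked by group mean so the cluster containing the
#' highest-mean group is labeled `"a"`.
#'
#' @param pairwise_sig symmetric logical matrix with group dimnames;
#'   `TRUE` marks a significantly different pair. The diagonal is ignored.
#' @param means named numeric vector of group means (same groups).
#' @return A list of class `cld`: `letters` (named character vector of
#'   letter strings, ordered by descending mean), `means`, `clusters`
#'   (list of group sets per letter).
#' @export
compact_letter_display <- function(pairwise_sig, means) {
  if (!is.matrix(pairwise_sig) || !is.logical(pairwise_sig)) {
    stop("`pairwise_sig` must be a logical matrix", call. = FALSE)
  }
  groups <- rownames(pairwise_sig)
  if (is.null(groups) || !identical(groups, colnames(pairwise_sig))) {
    stop("`pairwise_sig` must have matching row and column group names",
         call. = FALSE)
  }
  diag(pairwise_sig) <- FALSE
  if (anyNA(pairwise_sig)) {
    stop("`pairwise_sig` must be complete (no NA off-diagonal entries)",
         call. = FALSE)
  }
  if (!isTRUE(all.equal(pairwise_sig, t(pairwise_sig)))) {
    stop("inconsistent `pairwise_sig`: a pair is marked both significant ",
         "and not (matrix is asymmetric)", call. = FALSE)
  }
  if (is.null(names(means)) || !setequal(names(means), groups)) {
    stop("`means` must be named with the same groups as `pairwise_sig`",
         call. = FALSE)
  }
  means <- means[groups]

  # insert-and-absorb
  clusters <- list(groups)
  for (i in seq_along(groups)[-1L]) {
    for (j in seq_len(i - 1L)) {
      if (!pairwise_sig[i, j]) next
      gi <- groups[i]; gj <- groups[j]
      hit <- vapply(clusters, function(s) gi %in% s && gj %in% s, logical(1))
      if (!any(hit)) next
      new_clusters <- clusters[!hit]
      for (s in clusters[hit]) {
        new_clusters <- c(new_clusters, list(setdiff(s, gi)),
                          list(setdiff(s, gj)))
      }
      # absorb: drop clusters contained in another
      keep <- rep(TRUE, length(new_clusters))
      for (a in seq_along(new_clusters)) {
        for (b in seq_along(new_clusters)) {
          if (a != b && keep[b] &&
              all(new_clusters[[a]] %in% new_clusters[[b]]) &&
              !(all(new_clusters[[b]] %in% new_clusters[[a]]) && a < b)) {
            keep[a] <- FALSE
            break
          }
        }
      }
      clusters <- new_clusters[keep]
    }
  }
  clusters <- clusters[lengths(clusters) > 0L]

  # order letters so "a" goes to the cluster holding the highest mean
  top_mean <- vapply(clusters, function(s) max(means[s]), numeric(1))
  clusters <- clusters[order(-top_mean)]
  letter_symbols <- make_letters(length(clusters))
  names(clusters) <- letter_symbols

  codes <- vapply(groups, function(g) {
    paste0(letter_symbols[vapply(clusters, function(s) g %in% s, logical(1))],
           collapse = "")
  }, character(1))

  # CLD invariant: share a letter <=> not significantly different
  for (i in seq_along(groups)[-1L]) {
    for (j in seq_len(i - 1L)) {
      share <- any(strsplit(codes[i], "")[[1]] %in% strsplit(codes[j], "")[[1]])
      if (share == pairwise_sig[i, j]) {
        stop("internal error: compact letter display violates the ",
             "share-letter/non-significance invariant for pair ",
             groups[i], "/", groups[j], call. = FALSE)
      }
    }
  }

  ord <- order(-means)
  structure(list(letters = codes[ord], means = means[ord],
                 clusters = clusters),
            class = "cld")
}

# a, b, ..., z, aa, ab, ... for many clusters
make_letters <- function(n) {
  if (n <= 26L) return(letters[seq_len(n)])
  c(letters, as.vector(outer(letters, letters, paste0)))[seq_len(n)]
}

#' @export
print.cld <- function(x, ...) {
  print(data.frame(group = names(x$letters), mean = unname(x$means),
                   letters = unname(x$letters)), digits = 4)
  invisible(x)
}
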