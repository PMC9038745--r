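# TSV / Newick / JSON interchange: readers validate, writers round-trip.

#' Read a feature table from TSV
#'
#' Expects a header row of feature ids with the first column named
#' `sample_id`; all remaining cells must be numeric.
#'
#' @param path Path to a TSV file.
#' @return A validated feature table tibble.
#' @export
read_feature_table <- function(path) {
  if (!file.exists(path) || file.size(path) == 0) {
    abort_phylosym(sprintf("Empty or missing file: %s", path),
                   "phylosym_parse_error")
  }
  tab <- utils::read.delim(path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (anyDuplicated(names(tab))) {
    abort_phylosym(
      sprintf("Duplicated column name(s): %s",
              paste(unique(names(tab)[duplicated(names(tab))]),
                    collapse = ", ")),
      "phylosym_validation_error"
    )
  }
  if (!ncol(tab) || names(tab)[1] != "sample_id") {
    abort_phylosym("First column must be `sample_id`.",
                   "phylosym_parse_error")
  }
  feats <- setdiff(names(tab), "sample_id")
  for (f in feats) {
    v <- suppressWarnings(as.numeric(tab[[f]]))
    if (anyNA(v) && !anyNA(tab[[f]])) {
      bad <- which(is.na(v))[1]
      abort_phylosym(
        sprintf("Non-numeric cell at row %d, column '%s'.", bad, f),
        "phylosym_parse_error"
      )
    }
    tab[[f]] <- v
  }
  out <- tibble::as_tibble(tab)
  check_feature_table(out)
  out
}

#' Write a feature table to TSV
#'
#' @param table Feature table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(table, path) {
  check_feature_table(table)
  readr::write_tsv(table, path)
  invisible(path)
}

#' Read a study design from TSV
#'
#' @param path Path to a TSV with at least `sample_id` and `species`.
#' @return A validated design tibble.
#' @export
read_design <- function(path) {
  tab <- tibble::as_tibble(utils::read.delim(path, check.names = FALSE,
                                             stringsAsFactors = FALSE))
  need <- c("sample_id", "species")
  if (!all(need %in% names(tab))) {
    abort_phylosym("Design must contain `sample_id` and `species`.",
                   "phylosym_parse_error")
  }
  if (anyDuplicated(tab$sample_id)) {
    abort_phylosym("Duplicated sample ids in design.",
                   "phylosym_validation_error")
  }
  tab
}

#' Write a study design to TSV
#'
#' @param design Design tibble.
#' @param path Output path.
#' @export
write_design <- function(design, path) {
  readr::write_tsv(design, path)
  invisible(path)
}

#' Read a Newick tree
#'
#' @param path Path to a Newick file with branch lengths.
#' @return An `ape::phylo`.
#' @export
read_newick <- function(path) {
  tree <- tryCatch(ape::read.tree(path), error = function(e) NULL)
  if (is.null(tree)) {
    abort_phylosym(sprintf("Malformed Newick in %s", path),
                   "phylosym_parse_error")
  }
  tree
}

#' Write a tree to Newick
#'
#' @param tree An `ape::phylo`.
#' @param path Output path.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}
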