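# Feature-table preprocessing: internal-standard normalization with a noise
# floor and log transform, balance-score / background filtering, per-group
# median representatives, exact rarefaction, and SCFA molar ratios.

#' Internal-standard normalization, noise floor, and log transform
#'
#' Divides each sample's abundances by that sample's internal-standard
#' abundance, zeroes normalized values below `noise_floor`, applies
#' `log(1 + x)`, and drops the internal-standard feature. Refuses to run on a
#' table already in logged state (no silent double transform).
#'
#' @param table Feature table (first column `sample_id`), raw or normalized.
#' @param internal_standard_id Feature id of the internal standard; must be
#'   strictly positive in every sample.
#' @param noise_floor Normalized abundance below which values are set to 0.
#'   Use 0 to disable the floor (e.g. for LC data where only the
#'   normalization and log are wanted).
#' @return The transformed feature table, transform state `"log"`.
#' @export
normalize_and_log <- function(table, internal_standard_id, noise_floor = 0.01) {
  check_feature_table(table)
  if (ft_transform(table) == "log") {
    abort_phylosym("Table is already log-transformed.",
                   "phylosym_invalid_argument")
  }
  if (noise_floor < 0) {
    abort_phylosym("`noise_floor` must be >= 0.", "phylosym_invalid_argument")
  }
  if (!internal_standard_id %in% names(table)) {
    abort_phylosym(
      sprintf("Internal standard '%s' not found.", internal_standard_id),
      "phylosym_normalization_error"
    )
  }
  is_vals <- table[[internal_standard_id]]
  bad <- table$sample_id[!(is.finite(is_vals) & is_vals > 0)]
  if (length(bad)) {
    abort_phylosym(
      paste("Internal standard missing or non-positive in samples:",
            paste(bad, collapse = ", ")),
      "phylosym_normalization_error"
    )
  }
  m <- ft_matrix(table)
  m <- m[, setdiff(colnames(m), internal_standard_id), drop = FALSE]
  m <- m / is_vals
  m[m < noise_floor] <- 0
  ft_tibble(log1p(m), transform = "log")
}

#' Balance-score and background feature filters
#'
#' Drops features with a balance score below `balance_threshold` (when a
#' score is available), and features whose mean abundance across background
#' samples (blanks and/or digested diet samples) is at least
#' `background_rule_ratio` times their mean abundance across study samples.
#' With `keep_dietary = TRUE`, features triggering only the background rule
#' are flagged in the report but retained (shared food/fecal features, as
#' appropriate for polar metabolite panels whose dietary nutrients are
#' absorbed upstream of the colon).
#'
#' @param table Feature table.
#' @param feature_meta Optional tibble with `feature_id` and `balance_score`
#'   in [0, 1].
#' @param balance_threshold Balance score below which features are dropped.
#' @param background_table Optional feature table of background samples
#'   sharing feature ids with `table`.
#' @param background_rule_ratio Ratio of background mean to study mean at or
#'   above which a feature is treated as background.
#' @param keep_dietary If TRUE, background-rule features are flagged, not
#'   removed.
#' @return List with `table` (filtered) and `report` (tibble: `feature_id`,
#'   `rule`, `statistic`, `removed`).
#' @export
feature_filters <- function(table, feature_meta = NULL, balance_threshold = 0.5,
                            background_table = NULL,
                            background_rule_ratio = 0.5,
                            keep_dietary = FALSE) {
  check_feature_table(table)
  if (balance_threshold < 0 || balance_threshold > 1) {
    abort_phylosym("`balance_threshold` must be in [0, 1].",
                   "phylosym_invalid_argument")
  }
  feats <- setdiff(names(table), "sample_id")
  report <- tibble::tibble(feature_id = character(), rule = character(),
                           statistic = double(), removed = logical())

  if (!is.null(feature_meta) && "balance_score" %in% names(feature_meta)) {
    scores <- feature_meta$balance_score[match(feats, feature_meta$feature_id)]
    low <- !is.na(scores) & scores < balance_threshold
    report <- dplyr::bind_rows(report, tibble::tibble(
      feature_id = feats[low], rule = "balance_score",
      statistic = scores[low], removed = TRUE
    ))
  }

  if (!is.null(background_table)) {
    check_feature_table(background_table, "background_table")
    shared <- intersect(feats, setdiff(names(background_table), "sample_id"))
    if (length(shared)) {
      bg_mean <- colMeans(ft_matrix(background_table)[, shared, drop = FALSE])
      st_mean <- colMeans(ft_matrix(table)[, shared, drop = FALSE])
      hit <- bg_mean > 0 & bg_mean >= background_rule_ratio * st_mean
      report <- dplyr::bind_rows(report, tibble::tibble(
        feature_id = shared[hit], rule = "background",
        statistic = (bg_mean / pmax(st_mean, .Machine$double.eps))[hit],
        removed = !keep_dietary
      ))
    }
  }

  drop <- unique(report$feature_id[report$removed])
  out <- table[c("sample_id", setdiff(feats, drop))]
  attr(out, "transform") <- ft_transform(table)
  list(table = out, report = report)
}

#' Per-group median representative profiles
#'
#' Collapses samples to one representative row per group (typically per host
#' species) using the per-feature median; even sample counts use the
#' midpoint of the two central values.
#'
#' @param table Feature table.
#' @param design Design tibble mapping `sample_id` to grouping factors.
#' @param group_factor Name of the grouping column in `design`.
#' @return A feature table with one row per group; `sample_id` holds the
#'   group labels.
#' @export
median_representative <- function(table, design, group_factor = "species") {
  check_feature_table(table)
  if (!group_factor %in% names(design)) {
    abort_phylosym(sprintf("`%s` not found in design.", group_factor),
                   "phylosym_invalid_argument")
  }
  m <- ft_matrix(table)
  groups <- design[[group_factor]][match(rownames(m), design$sample_id)]
  if (anyNA(groups)) {
    abort_phylosym("Some samples are missing from the design.",
                   "phylosym_validation_error")
  }
  med <- apply(m, 2, function(x) tapply(x, groups, stats::median))
  if (is.null(dim(med))) med <- matrix(med, nrow = 1,
                                       dimnames = list(unique(groups),
                                                       colnames(m)))
  ft_tibble(med, transform = ft_transform(table))
}

#' Exact expected rarefaction curves
#'
#' For each sample and each depth `d`, the exact hypergeometric expectation
#' of the number of features observed in a subsample of size `d` without
#' replacement: `E[S_d] = sum_i (1 - choose(N - N_i, d) / choose(N, d))`.
#'
#' @param count_table Integer count feature table.
#' @param depths Integer vector of subsampling depths.
#' @return Tibble with columns `sample_id`, `depth`, `expected_richness`.
#' @export
rarefaction_curve <- function(count_table, depths) {
  check_feature_table(count_table)
  m <- ft_matrix(count_table)
  if (any(m != round(m))) {
    abort_phylosym("Counts must be integers.", "phylosym_invalid_argument")
  }
  purrr::map_dfr(seq_len(nrow(m)), function(i) {
    x <- m[i, ]
    N <- sum(x)
    bad <- depths > N
    if (any(bad)) {
      abort_phylosym(
        sprintf("Depth(s) %s exceed total count %d of sample '%s'.",
                paste(depths[bad], collapse = ", "), N, rownames(m)[i]),
        "phylosym_invalid_argument"
      )
    }
    x <- x[x > 0]
    es <- vapply(depths, function(d) {
      # log-scale binomial ratios for numerical stability
      sum(1 - exp(lchoose(N - x, d) - lchoose(N, d)))
    }, numeric(1))
    tibble::tibble(sample_id = rownames(m)[i], depth = depths,
                   expected_richness = es)
  })
}

#' Acetate : propionate : butyrate molar ratios
#'
#' Rescales each sample's acetate, propionate and butyrate molar
#' concentrations to percentages summing to 100, and summarizes groups both
#' as the ratio of group means (primary) and the mean of per-sample ratios.
#'
#' @param scfa_table Feature table with columns `acetate`, `propionate`,
#'   `butyrate` in molar units.
#' @param design Optional design tibble for the group summary.
#' @param group_factor Grouping column in `design`.
#' @return List with `per_sample` (tibble incl. `flagged` for all-zero
#'   samples) and, when a design is given, `per_group` (ratio-of-means and
#'   mean-of-ratios percentages).
#' @export
scfa_molar_ratio <- function(scfa_table, design = NULL,
                             group_factor = "diet") {
  check_feature_table(scfa_table)
  need <- c("acetate", "propionate", "butyrate")
  if (!all(need %in% names(scfa_table))) {
    abort_phylosym("Table must contain acetate, propionate, butyrate.",
                   "phylosym_invalid_argument")
  }
  m <- as.matrix(scfa_table[need])
  tot <- rowSums(m)
  flagged <- tot == 0
  pct <- m / ifelse(tot == 0, NA_real_, tot) * 100
  per_sample <- tibble::tibble(
    sample_id = scfa_table$sample_id,
    acetate_pct = pct[, 1], propionate_pct = pct[, 2],
    butyrate_pct = pct[, 3], flagged = flagged
  )
  out <- list(per_sample = per_sample)
  if (!is.null(design)) {
    groups <- design[[group_factor]][match(scfa_table$sample_id,
                                           design$sample_id)]
    gm <- rowsum(m, groups) / as.vector(table(groups)[sort(unique(groups))])
    gm_pct <- gm / rowSums(gm) * 100
    mor <- rowsum(pct[!flagged, , drop = FALSE], groups[!flagged]) /
      as.vector(table(groups[!flagged])[sort(unique(groups[!flagged]))])
    out$per_group <- tibble::tibble(
      group = rownames(gm_pct),
      acetate_pct = unname(gm_pct[, 1]),
      propionate_pct = unname(gm_pct[, 2]),
      butyrate_pct = unname(gm_pct[, 3]),
      acetate_pct_mor = unname(mor[rownames(gm_pct), 1]),
      propionate_pct_mor = unname(mor[rownames(gm_pct), 2]),
      butyrate_pct_mor = unname(mor[rownames(gm_pct), 3])
    )
  }
  out
}
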