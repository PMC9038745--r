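# Differential-feature discovery: PCA-loading candidate extraction, IndVal
# indicator testing with a permutation null, and Bonferroni filtering, wired
# in the order candidates -> IndVal -> Bonferroni.

#' PCA of a (logged) feature table
#'
#' Column-centers features (no unit-variance scaling) and takes the singular
#' value decomposition. Each component is oriented so its largest-magnitude
#' loading is positive.
#'
#' @param table Feature table in logged state, >= 2 samples and features.
#' @return A `phylosym_pca`: list with `loadings` (tibble `feature_id` +
#'   `PC1 ...`), `scores` (tibble `sample_id` + `PC1 ...`), and
#'   `var_explained`.
#' @export
pca_loadings <- function(table) {
  m <- ft_matrix(table)
  if (nrow(m) < 2 || ncol(m) < 2) {
    abort_phylosym("Need >= 2 samples and >= 2 features.",
                   "phylosym_invalid_argument")
  }
  x <- scale(m, center = TRUE, scale = FALSE)
  if (all(abs(x) < 1e-12)) {
    abort_phylosym("Constant table: PCA is undefined.",
                   "phylosym_degenerate_input")
  }
  sv <- svd(x)
  k <- sum(sv$d > 1e-10 * sv$d[1])
  d <- sv$d[seq_len(k)]
  U <- sv$u[, seq_len(k), drop = FALSE]
  V <- sv$v[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    i <- which.max(abs(V[, j]))
    if (V[i, j] < 0) {
      V[, j] <- -V[, j]
      U[, j] <- -U[, j]
    }
  }
  pcs <- paste0("PC", seq_len(k))
  scores <- U %*% diag(d, k)
  dimnames(scores) <- list(rownames(m), pcs)
  dimnames(V) <- list(colnames(m), pcs)
  structure(list(
    loadings = tibble::as_tibble(V, rownames = "feature_id"),
    scores = tibble::as_tibble(scores, rownames = "sample_id"),
    var_explained = d^2 / sum(sv$d^2)
  ), class = "phylosym_pca")
}

#' Candidate features from the tails of PCA loadings
#'
#' For each listed component independently, keeps features whose loading is
#' at or above the `(100 - percentile)`-th percentile or at or below the
#' `percentile`-th percentile of that component's loadings, and returns the
#' union with per-feature provenance.
#'
#' @param pca A `phylosym_pca` (or its `loadings` tibble).
#' @param components Component names, e.g. `c("PC1", "PC2")`.
#' @param percentile Tail size in percent, strictly between 0 and 50.
#' @return Tibble: `feature_id`, `component`, `tail` (`"top"`/`"bottom"`),
#'   `loading`; one row per (feature, component, tail) hit. Warns when
#'   empty.
#' @export
candidate_by_loading_percentile <- function(pca, components = c("PC1", "PC2"),
                                            percentile = 1) {
  loadings <- if (inherits(pca, "phylosym_pca")) pca$loadings else pca
  if (percentile <= 0 || percentile >= 50) {
    abort_phylosym("`percentile` must be strictly between 0 and 50.",
                   "phylosym_invalid_argument")
  }
  miss <- setdiff(components, names(loadings))
  if (length(miss)) {
    abort_phylosym(paste("Components not available:",
                         paste(miss, collapse = ", ")),
                   "phylosym_invalid_argument")
  }
  out <- purrr::map_dfr(components, function(pc) {
    v <- loadings[[pc]]
    hi <- stats::quantile(v, 1 - percentile / 100, names = FALSE)
    lo <- stats::quantile(v, percentile / 100, names = FALSE)
    dplyr::bind_rows(
      tibble::tibble(feature_id = loadings$feature_id[v >= hi],
                     component = pc, tail = "top", loading = v[v >= hi]),
      tibble::tibble(feature_id = loadings$feature_id[v <= lo],
                     component = pc, tail = "bottom", loading = v[v <= lo])
    )
  })
  if (!nrow(out)) warning("No candidate features selected.")
  out
}

#' Indicator-value (IndVal) association test
#'
#' For feature f and group g, specificity `A = m_gf / sum_h m_hf` uses
#' group-equalized means (`m_gf` = mean abundance of f within g; the
#' "IndVal.g" correction for unequal group sizes) and fidelity `B` is the
#' fraction of g's samples in which f is detected (> 0). The statistic is
#' `sqrt(A * B)` maximized over groups; its p-value comes from permuting the
#' group labels, `p = (1 + #(max-stat* >= observed)) / (1 + n_perm)`.
#' `mode = "indval"` uses group sums instead of means (size-biased, as in
#' the classical definition).
#'
#' @param table Feature table (abundances; presence is `> 0`).
#' @param design Design tibble.
#' @param group_factor Factor column of `design` to test, >= 2 levels.
#' @param mode `"indval.g"` (default) or `"indval"`.
#' @param n_perm Number of permutations (>= 1).
#' @param seed Integer seed.
#' @param alpha Significance cutoff for the Bonferroni-adjusted flag.
#' @return An `indval_table`: tibble with `feature_id`, `factor`,
#'   `best_group`, `specificity`, `fidelity`, `stat`, `p_value`,
#'   `p_adjusted` (Bonferroni over the features tested), `significant`
#'   (at 0.05); attributes `n_perm`, `seed`, `m_tests`.
#' @export
indval_test <- function(table, design, group_factor, mode = c("indval.g",
                                                              "indval"),
                        n_perm = 999, seed = 1L, alpha = 0.05) {
  mode <- match.arg(mode)
  m <- ft_matrix(table)
  grp <- design[[group_factor]][match(rownames(m), design$sample_id)]
  if (anyNA(grp)) {
    abort_phylosym("Some samples are missing from the design.",
                   "phylosym_alignment_error")
  }
  grp <- factor(grp)
  if (nlevels(grp) < 2) {
    abort_phylosym("Factor must have >= 2 levels.",
                   "phylosym_invalid_argument")
  }
  stat_all <- .indval_stats(m, grp, mode)
  obs <- stat_all$max_stat
  exceed <- numeric(ncol(m))
  with_seed(seed, {
    for (b in seq_len(n_perm)) {
      sp <- .indval_stats(m, sample(grp), mode)$max_stat
      exceed <- exceed + (sp >= obs)
    }
  })
  p <- (1 + exceed) / (1 + n_perm)
  m_tests <- ncol(m)
  p_adj <- pmin(1, p * m_tests)
  out <- tibble::tibble(
    feature_id = colnames(m),
    factor = group_factor,
    best_group = stat_all$best_group,
    specificity = stat_all$A,
    fidelity = stat_all$B,
    stat = obs,
    p_value = p,
    p_adjusted = p_adj,
    significant = p_adj <= alpha
  )
  structure(out, class = c("indval_table", class(out)),
            n_perm = n_perm, seed = seed, m_tests = m_tests)
}

# Per-feature IndVal components; returns max-over-groups statistic, the best
# group, and that group's A and B.
.indval_stats <- function(m, grp, mode) {
  sizes <- as.vector(table(grp))
  levels_g <- levels(grp)
  sums <- rowsum(m, grp)          # groups x features
  means <- sums / sizes
  num <- if (mode == "indval.g") means else sums
  denom <- colSums(num)
  A <- sweep(num, 2, ifelse(denom == 0, 1, denom), "/")
  pres <- rowsum((m > 0) * 1, grp) / sizes
  stat <- sqrt(A * pres)
  best <- max.col(t(stat), ties.method = "first")
  idx <- cbind(best, seq_len(ncol(m)))
  list(max_stat = stat[idx], best_group = levels_g[best],
       A = A[idx], B = pres[idx])
}

#' Bonferroni adjustment and significance filter
#'
#' `adjusted = min(1, p * m)` with `m` the number of tests in the batch;
#' features with adjusted p at or below `alpha` are kept.
#'
#' @param pvals Numeric p-values in [0, 1].
#' @param alpha Significance cutoff.
#' @param m Number of tests; defaults to `length(pvals)`.
#' @return Tibble: `p_value`, `p_adjusted`, `kept`, plus attribute `m`.
#' @export
bonferroni_filter <- function(pvals, alpha = 0.05, m = length(pvals)) {
  if (!length(pvals)) {
    return(tibble::tibble(p_value = double(), p_adjusted = double(),
                          kept = logical()))
  }
  if (any(pvals < 0 | pvals > 1)) {
    abort_phylosym("p-values must be in [0, 1].", "phylosym_invalid_argument")
  }
  adj <- pmin(1, pvals * m)
  out <- tibble::tibble(p_value = pvals, p_adjusted = adj, kept = adj <= alpha)
  attr(out, "m") <- m
  out
}

#' Differential-feature discovery pipeline
#'
#' Runs the full procedure in order: PCA on the logged table, candidate
#' extraction from the loading tails of the chosen components, IndVal
#' testing of the candidates only against each factor, and Bonferroni
#' correction with `m` equal to the number of candidates tested per factor.
#' An optional manual exclusion list (suspected artifacts) is applied before
#' reporting.
#'
#' @param table Logged feature table.
#' @param design Design tibble.
#' @param factors Character vector of design factors to test.
#' @param components,percentile Candidate extraction parameters.
#' @param mode,n_perm,seed,alpha IndVal parameters.
#' @param exclude Character vector of feature ids to drop before reporting.
#' @return List with `candidates` (provenance tibble) and `results`
#'   (combined `indval_table` rows across factors, candidates only).
#' @export
differential_features <- function(table, design, factors,
                                  components = c("PC1", "PC2"),
                                  percentile = 1, mode = "indval.g",
                                  n_perm = 999, seed = 1L, alpha = 0.05,
                                  exclude = character()) {
  pca <- pca_loadings(table)
  cand <- candidate_by_loading_percentile(pca, components, percentile)
  keep_ids <- setdiff(unique(cand$feature_id), exclude)
  sub <- table[c("sample_id", keep_ids)]
  attr(sub, "transform") <- ft_transform(table)
  results <- purrr::map_dfr(seq_along(factors), function(i) {
    indval_test(sub, design, factors[i], mode = mode, n_perm = n_perm,
                seed = derive_seed(seed, i), alpha = alpha)
  })
  list(candidates = cand, results = results)
}
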