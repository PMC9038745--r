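# Permutation-based hypothesis tests on dissimilarity matrices: sequential
# (Type I) PERMANOVA, homogeneity of multivariate dispersions, Mantel tests,
# one-way ANOVA with Tukey HSD on dissimilarity vectors, and the
# subset-robustness resampling design.

# Orthonormal basis increments for a sequential model: returns a list with
# one n x df_k matrix per term (the new orthonormal directions the term adds
# beyond the preceding model, intercept included in the base).
.sequential_increments <- function(design, terms) {
  n <- nrow(design)
  Q <- matrix(1 / sqrt(n), n, 1)
  increments <- vector("list", length(terms))
  names(increments) <- terms
  for (k in seq_along(terms)) {
    v <- design[[terms[k]]]
    X <- if (is.numeric(v)) {
      matrix(as.double(v), n, 1)
    } else {
      stats::model.matrix(~ 0 + f, data.frame(f = factor(v)))
    }
    # residualize against the preceding model, then take an SVD basis of
    # what is left: the singular vectors above tolerance are the directions
    # the term adds, and their count is the rank it contributes
    R <- X - Q %*% crossprod(Q, X)
    sv <- svd(R)
    rank <- sum(sv$d > 1e-8 * max(sv$d, 1))
    if (rank > 0) {
      Qk <- sv$u[, seq_len(rank), drop = FALSE]
      Q <- cbind(Q, Qk)
      increments[[k]] <- Qk
    } else {
      increments[[k]] <- matrix(0, n, 0)
    }
  }
  increments
}

#' Sequential (Type I) PERMANOVA on a dissimilarity matrix
#'
#' Partitions the total sum of squared dissimilarities
#' (`sum_{i<j} d_ij^2 / n`) among model terms added in the stated order, in
#' the style of vegan's adonis. Term k's SS is `tr(H_k G)` where `G` is the
#' Gower-centered `-D^2/2` matrix and `H_k` projects onto the directions the
#' term adds beyond the preceding model; its df is the rank added. The
#' pseudo-F is `(SS_k / df_k) / (SS_res / df_res)`; significance comes from
#' permuting sample identities of `D` (free exchangeability) with all terms
#' recomputed, `p = (1 + #(F* >= F)) / (1 + n_perm)`.
#'
#' @param D Labeled symmetric dissimilarity matrix.
#' @param design Design tibble with `sample_id` and the term columns.
#' @param terms Character vector of design columns, in entry order.
#' @param n_perm Number of permutations.
#' @param seed Integer seed for the permutation stream.
#' @return A `permanova_table`: tibble with one row per term plus
#'   `Residuals` and `Total` (`term`, `df`, `sum_sq`, `mean_sq`, `pseudo_f`,
#'   `r_squared`, `p_value`), with `n_perm` and `seed` attributes. Aliased
#'   terms (rank 0) get df 0 and undefined F.
#' @export
permanova_sequential <- function(D, design, terms, n_perm = 999, seed = 1L) {
  check_distance_matrix(D)
  ids <- rownames(D)
  if (!all(ids %in% design$sample_id)) {
    abort_phylosym("Design does not cover all samples of D.",
                   "phylosym_alignment_error")
  }
  design <- design[match(ids, design$sample_id), ]
  missing_terms <- setdiff(terms, names(design))
  if (length(missing_terms)) {
    abort_phylosym(paste("Terms not in design:",
                         paste(missing_terms, collapse = ", ")),
                   "phylosym_invalid_argument")
  }
  n <- nrow(D)
  G <- .gower_center(D^2)
  ss_total <- sum(diag(G))
  inc <- .sequential_increments(design, terms)
  df <- vapply(inc, ncol, integer(1))
  Qall <- do.call(cbind, inc)
  term_index <- rep(seq_along(terms), df)

  ss_terms <- if (ncol(Qall)) {
    as.vector(rowsum(colSums(Qall * (G %*% Qall)), term_index))
  } else {
    numeric(0)
  }
  ss_by_term <- numeric(length(terms))
  ss_by_term[sort(unique(term_index))] <- ss_terms
  df_res <- n - 1 - sum(df)
  ss_res <- ss_total - sum(ss_by_term)
  ms <- ifelse(df > 0, ss_by_term / df, NA_real_)
  ms_res <- ss_res / df_res
  f_obs <- ms / ms_res

  p <- rep(NA_real_, length(terms))
  if (n_perm > 0 && ncol(Qall)) {
    exceed <- numeric(length(terms))
    f_seen <- !is.na(f_obs)
    with_seed(seed, {
      for (b in seq_len(n_perm)) {
        perm <- sample.int(n)
        Gp <- G[perm, perm]
        ssp <- numeric(length(terms))
        ssp[sort(unique(term_index))] <-
          as.vector(rowsum(colSums(Qall * (Gp %*% Qall)), term_index))
        fp <- (ssp / df) / ((ss_total - sum(ssp)) / df_res)
        exceed <- exceed + (f_seen & !is.na(fp) & fp >= f_obs)
      }
    })
    p[f_seen] <- (1 + exceed[f_seen]) / (1 + n_perm)
  }

  out <- tibble::tibble(
    term = c(terms, "Residuals", "Total"),
    df = unname(c(df, df_res, n - 1)),
    sum_sq = unname(c(ss_by_term, ss_res, ss_total)),
    mean_sq = unname(c(ms, ms_res, NA_real_)),
    pseudo_f = unname(c(f_obs, NA_real_, NA_real_)),
    r_squared = unname(c(ss_by_term, ss_res, ss_total) / ss_total),
    p_value = c(p, NA_real_, NA_real_)
  )
  new_permanova_table(out, n_perm = n_perm, seed = seed)
}

# Constructor: asserts SS and df additivity before stamping the class.
new_permanova_table <- function(tbl, n_perm, seed) {
  body <- tbl[!(tbl$term %in% c("Residuals", "Total")), ]
  res <- tbl[tbl$term == "Residuals", ]
  tot <- tbl[tbl$term == "Total", ]
  stopifnot(
    sum(body$df) + res$df == tot$df,
    abs(sum(body$sum_sq) + res$sum_sq - tot$sum_sq) <=
      1e-9 * max(1, abs(tot$sum_sq))
  )
  structure(tbl, class = c("permanova_table", class(tbl)),
            n_perm = n_perm, seed = seed)
}

#' Homogeneity of multivariate dispersions (PERMDISP)
#'
#' Embeds `D` by principal coordinates retaining negative axes, computes
#' each sample's distance to its group centroid as
#' `sqrt(max(0, real-axis squared distance - negative-axis squared
#' distance))`, and tests group equality of these distances with a one-way F
#' whose null distribution comes from permuting group labels.
#'
#' @inheritParams permanova_sequential
#' @param group_factor Grouping column in `design`; groups of size 1 are
#'   excluded with a warning.
#' @return A `permdisp_test`: list with `dispersions` (per-sample tibble),
#'   `group_means`, `f`, `p_value`, `n_perm`, `seed`.
#' @export
permdisp <- function(D, design, group_factor, n_perm = 999, seed = 1L) {
  check_distance_matrix(D)
  ids <- rownames(D)
  grp <- design[[group_factor]][match(ids, design$sample_id)]
  sizes <- table(grp)
  if (sum(sizes >= 2) < 2) {
    abort_phylosym("Need >= 2 groups with >= 2 samples.",
                   "phylosym_invalid_argument")
  }
  if (any(sizes < 2)) {
    warning(sprintf("Excluding size-1 group(s): %s",
                    paste(names(sizes)[sizes < 2], collapse = ", ")))
    keep <- grp %in% names(sizes)[sizes >= 2]
    D <- D[keep, keep]
    ids <- ids[keep]
    grp <- grp[keep]
  }
  eig <- eigen(.gower_center(D^2), symmetric = TRUE)
  pos <- eig$values > 1e-10
  neg <- eig$values < -1e-10
  Zr <- eig$vectors[, pos, drop = FALSE] %*%
    diag(sqrt(eig$values[pos]), sum(pos))
  Zi <- eig$vectors[, neg, drop = FALSE] %*%
    diag(sqrt(-eig$values[neg]), sum(neg))
  dist_to_centroid <- function(g) {
    g <- factor(g)
    ng <- tabulate(g)
    cr <- rowsum(Zr, g) / ng
    ci <- rowsum(Zi, g) / ng
    gi <- as.integer(g)
    d2 <- rowSums(Zr^2) - 2 * rowSums(Zr * cr[gi, , drop = FALSE]) +
      rowSums(cr^2)[gi] -
      (rowSums(Zi^2) - 2 * rowSums(Zi * ci[gi, , drop = FALSE]) +
         rowSums(ci^2)[gi])
    sqrt(pmax(0, d2))
  }
  d <- dist_to_centroid(grp)
  f_obs <- .oneway_f(d, grp)
  # permute sample identities and recompute centroids and distances, so the
  # null statistic carries the same centroid-estimation structure as the
  # observed one (keeps the test calibrated under exchangeability)
  null <- with_seed(seed, {
    vapply(seq_len(n_perm), function(b) {
      gp <- sample(grp)
      .oneway_f(dist_to_centroid(gp), gp)
    }, numeric(1))
  })
  structure(list(
    dispersions = tibble::tibble(sample_id = ids, group = grp, distance = d),
    group_means = tibble::tibble(
      group = names(tapply(d, grp, mean)),
      mean_dispersion = as.vector(tapply(d, grp, mean))
    ),
    f = f_obs,
    p_value = perm_pvalue(f_obs, null),
    n_perm = n_perm, seed = seed
  ), class = "permdisp_test")
}

.oneway_f <- function(x, g) {
  n <- length(x)
  k <- length(unique(g))
  gm <- tapply(x, g, mean)
  gn <- tapply(x, g, length)
  ssb <- sum(gn * (gm - mean(x))^2)
  ssw <- sum((x - gm[g])^2)
  if (ssw == 0) return(Inf)
  (ssb / (k - 1)) / (ssw / (n - k))
}

#' Mantel test between two dissimilarity matrices
#'
#' Correlates the strictly-lower-triangle vectors of two matrices over the
#' same samples (auto-aligned by id); significance is one-sided upper, by
#' permuting one matrix's sample labels.
#'
#' @param D1,D2 Labeled symmetric dissimilarity matrices over the same
#'   sample set.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @param n_perm Number of label permutations.
#' @param seed Integer seed.
#' @return A `mantel_test`: list with `r`, `p_value`, `n_perm`, `method`,
#'   `n`, `seed`.
#' @export
mantel_test <- function(D1, D2, method = c("pearson", "spearman"),
                        n_perm = 9999, seed = 1L) {
  method <- match.arg(method)
  check_distance_matrix(D1, "D1")
  check_distance_matrix(D2, "D2")
  ids <- rownames(D1)
  if (!setequal(ids, rownames(D2))) {
    abort_phylosym("D1 and D2 sample ids differ.", "phylosym_alignment_error")
  }
  if (length(ids) < 3) {
    abort_phylosym("Need >= 3 samples.", "phylosym_invalid_argument")
  }
  D2 <- D2[ids, ids]
  if (method == "spearman") {
    # pair values are only rearranged by label permutation, so pre-ranking
    # the triangles once makes every permuted statistic a Pearson cor of ranks
    D1 <- .rank_matrix(D1)
    D2 <- .rank_matrix(D2)
  }
  v1 <- D1[lower.tri(D1)]
  if (stats::sd(v1) == 0 || stats::sd(D2[lower.tri(D2)]) == 0) {
    abort_phylosym("Zero variance in a dissimilarity triangle.",
                   "phylosym_degenerate_input")
  }
  r_obs <- stats::cor(v1, D2[lower.tri(D2)])
  n <- length(ids)
  null <- with_seed(seed, {
    vapply(seq_len(n_perm), function(b) {
      p <- sample.int(n)
      Dp <- D2[p, p]
      stats::cor(v1, Dp[lower.tri(Dp)])
    }, numeric(1))
  })
  structure(list(r = r_obs, p_value = perm_pvalue(r_obs, null),
                 n_perm = n_perm, method = method, n = n, seed = seed),
            class = "mantel_test")
}

.rank_matrix <- function(D) {
  v <- rank(D[lower.tri(D)])
  R <- matrix(0, nrow(D), ncol(D), dimnames = dimnames(D))
  R[lower.tri(R)] <- v
  R + t(R)
}

#' @export
print.mantel_test <- function(x, ...) {
  cat(sprintf("Mantel test (%s): r = %.4f, p = %.4g (n = %d, %d permutations)\n",
              x$method, x$r, x$p_value, x$n, x$n_perm))
  invisible(x)
}

#' @export
print.permdisp_test <- function(x, ...) {
  cat(sprintf("Multivariate dispersion test: F = %.4f, p = %.4g (%d permutations)\n",
              x$f, x$p_value, x$n_perm))
  print(x$group_means)
  invisible(x)
}

#' One-way ANOVA with Tukey HSD post hoc
#'
#' Classical one-way F with its F-distribution p-value, followed by Tukey's
#' honest significant differences on all group pairs (studentized-range
#' adjusted p). With zero within-group variance everywhere the F is infinite
#' and reported with a p-to-zero flag.
#'
#' @param values Numeric response vector.
#' @param groups Grouping vector of the same length, >= 2 levels.
#' @return An `anova_tukey` list: `f`, `df_between`, `df_within`, `p_value`,
#'   `degenerate`, and `pairwise` (tibble: `pair`, `diff`, `lwr`, `upr`,
#'   `p_adjusted`).
#' @export
anova_tukey <- function(values, groups) {
  groups <- factor(groups)
  if (nlevels(groups) < 2) {
    abort_phylosym("Need >= 2 groups.", "phylosym_invalid_argument")
  }
  ssw <- sum(stats::ave(values, groups, FUN = function(x) x - mean(x))^2)
  if (ssw == 0) {
    return(structure(list(
      f = Inf, df_between = nlevels(groups) - 1,
      df_within = length(values) - nlevels(groups),
      p_value = 0, degenerate = TRUE,
      pairwise = tibble::tibble(pair = character(), diff = double(),
                                lwr = double(), upr = double(),
                                p_adjusted = double())
    ), class = "anova_tukey"))
  }
  fit <- stats::aov(values ~ groups, data = data.frame(values, groups))
  an <- summary(fit)[[1]]
  tk <- stats::TukeyHSD(fit)$groups
  structure(list(
    f = an[["F value"]][1],
    df_between = an[["Df"]][1],
    df_within = an[["Df"]][2],
    p_value = an[["Pr(>F)"]][1],
    degenerate = FALSE,
    pairwise = tibble::tibble(
      pair = rownames(tk), diff = tk[, "diff"], lwr = tk[, "lwr"],
      upr = tk[, "upr"], p_adjusted = tk[, "p adj"]
    )
  ), class = "anova_tukey")
}

#' @export
print.anova_tukey <- function(x, ...) {
  cat(sprintf("One-way ANOVA: F(%d, %d) = %.4g, p = %.4g\n",
              x$df_between, x$df_within, x$f, x$p_value))
  if (nrow(x$pairwise)) print(x$pairwise)
  invisible(x)
}

#' Subset-robustness resampling of distance-based analyses
#'
#' For each `n` in `1..n_max` and each repetition, randomly subsets the
#' samples so every species keeps at most `n` (species with fewer keep all),
#' shares the subset across all supplied matrices, reruns the requested
#' analyses, and tabulates their statistics — checking that conclusions are
#' not driven by heavily sampled species.
#'
#' @param D_list Named list of labeled dissimilarity matrices over a common
#'   sample set.
#' @param design Design tibble with `sample_id` and `species`.
#' @param n_max Largest per-species cap.
#' @param n_reps Repetitions per cap.
#' @param analyses Subset of `c("permanova", "mantel", "permdisp")`.
#' @param terms PERMANOVA term order (required when `"permanova"` is run).
#' @param group_factor Grouping for PERMDISP.
#' @param n_perm Permutations per test.
#' @param seed Integer seed; subsets and tests are deterministic given it.
#' @return Tidy tibble: `n_cap`, `rep`, `analysis`, `dataset`, `term`,
#'   `statistic`, `value`, `p_value`, `n_samples`.
#' @export
subset_robustness <- function(D_list, design, n_max = 5, n_reps = 5,
                              analyses = c("permanova", "mantel", "permdisp"),
                              terms = NULL, group_factor = "species",
                              n_perm = 199, seed = 1L) {
  analyses <- match.arg(analyses, several.ok = TRUE)
  if (is.null(names(D_list))) {
    names(D_list) <- paste0("dataset", seq_along(D_list))
  }
  common <- Reduce(intersect, lapply(D_list, rownames))
  common <- intersect(common, design$sample_id)
  if (!length(common)) {
    abort_phylosym("No common sample ids across matrices and design.",
                   "phylosym_alignment_error")
  }
  des <- design[match(common, design$sample_id), ]
  rows <- list()
  for (n_cap in seq_len(n_max)) {
    for (rep_i in seq_len(n_reps)) {
      sub_ids <- with_seed(derive_seed(seed, 1000L * n_cap + rep_i), {
        unlist(lapply(split(des$sample_id, des$species), function(ids) {
          if (length(ids) <= n_cap) ids else sample(ids, n_cap)
        }), use.names = FALSE)
      })
      sub_des <- des[match(sub_ids, des$sample_id), ]
      rec <- function(analysis, dataset, term, statistic, value, p_value) {
        tibble::tibble(n_cap = n_cap, rep = rep_i, analysis = analysis,
                       dataset = dataset, term = term, statistic = statistic,
                       value = value, p_value = p_value,
                       n_samples = length(sub_ids))
      }
      if ("permanova" %in% analyses) {
        if (is.null(terms)) {
          abort_phylosym("PERMANOVA requires `terms`.",
                         "phylosym_invalid_argument")
        }
        for (nm in names(D_list)) {
          Ds <- D_list[[nm]][sub_ids, sub_ids]
          pt <- permanova_sequential(Ds, sub_des, terms, n_perm = n_perm,
                                     seed = derive_seed(seed, 7L))
          body <- pt[!(pt$term %in% c("Residuals", "Total")), ]
          rows[[length(rows) + 1L]] <- rec(
            "permanova", nm, body$term, "r_squared", body$r_squared,
            body$p_value
          )
        }
      }
      if ("mantel" %in% analyses && length(D_list) >= 2) {
        cmb <- utils::combn(names(D_list), 2)
        for (j in seq_len(ncol(cmb))) {
          a <- cmb[1, j]; b <- cmb[2, j]
          mt <- mantel_test(D_list[[a]][sub_ids, sub_ids],
                            D_list[[b]][sub_ids, sub_ids],
                            n_perm = n_perm, seed = derive_seed(seed, 8L))
          rows[[length(rows) + 1L]] <- rec(
            "mantel", paste(a, b, sep = ":"), NA_character_, "r", mt$r,
            mt$p_value
          )
        }
      }
      if ("permdisp" %in% analyses && n_cap >= 2) {
        for (nm in names(D_list)) {
          pd <- tryCatch(
            suppressWarnings(
              permdisp(D_list[[nm]][sub_ids, sub_ids], sub_des, group_factor,
                       n_perm = n_perm, seed = derive_seed(seed, 9L))
            ),
            phylosym_error = function(e) NULL
          )
          if (!is.null(pd)) {
            rows[[length(rows) + 1L]] <- rec(
              "permdisp", nm, group_factor, "f", pd$f, pd$p_value
            )
          }
        }
      }
    }
  }
  dplyr::bind_rows(rows)
}
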