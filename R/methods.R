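# broom-style tidiers and ggplot2 autoplot methods for result objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a PERMANOVA table
#'
#' @param x A `permanova_table`.
#' @param ... Unused.
#' @return A plain tibble, one row per term plus residuals and total.
#' @export
tidy.permanova_table <- function(x, ...) {
  tibble::as_tibble(unclass(x)[c("term", "df", "sum_sq", "mean_sq",
                                 "pseudo_f", "r_squared", "p_value")])
}

#' @rdname tidy.permanova_table
#' @export
glance.permanova_table <- function(x, ...) {
  tot <- x[x$term == "Total", ]
  res <- x[x$term == "Residuals", ]
  tibble::tibble(
    n = tot$df + 1,
    total_ss = tot$sum_sq,
    residual_r_squared = res$r_squared,
    n_perm = attr(x, "n_perm"),
    seed = attr(x, "seed")
  )
}

#' Tidy a Mantel test result
#'
#' @param x A `mantel_test`.
#' @param ... Unused.
#' @export
tidy.mantel_test <- function(x, ...) {
  tibble::tibble(r = x$r, p_value = x$p_value, method = x$method,
                 n = x$n, n_perm = x$n_perm)
}

#' @rdname tidy.mantel_test
#' @export
glance.mantel_test <- tidy.mantel_test

#' Tidy a tree-congruence test
#'
#' @param x A `congruence_test`.
#' @param ... Unused.
#' @export
tidy.congruence_test <- function(x, ...) {
  tibble::tibble(
    statistic = x$statistic, observed = x$observed,
    bakers_gamma = x$bakers_gamma,
    cophenetic_pearson = x$cophenetic_pearson,
    null_mean = x$null_mean, null_sd = x$null_sd,
    p_value = x$p_value, n_shuffles = x$n_shuffles
  )
}

#' @rdname tidy.congruence_test
#' @export
glance.congruence_test <- tidy.congruence_test

#' Tidy a dispersion-homogeneity test
#'
#' @param x A `permdisp_test`.
#' @param ... Unused.
#' @return Per-group mean dispersions with the shared F and p.
#' @export
tidy.permdisp_test <- function(x, ...) {
  dplyr::mutate(x$group_means, f = x$f, p_value = x$p_value)
}

#' @rdname tidy.permdisp_test
#' @export
glance.permdisp_test <- function(x, ...) {
  tibble::tibble(f = x$f, p_value = x$p_value, n_groups = nrow(x$group_means),
                 n_perm = x$n_perm)
}

#' Tidy an ANOVA + Tukey result
#'
#' @param x An `anova_tukey`.
#' @param ... Unused.
#' @return The pairwise Tukey table.
#' @export
tidy.anova_tukey <- function(x, ...) x$pairwise

#' @rdname tidy.anova_tukey
#' @export
glance.anova_tukey <- function(x, ...) {
  tibble::tibble(f = x$f, df_between = x$df_between, df_within = x$df_within,
                 p_value = x$p_value, degenerate = x$degenerate)
}

#' Plot an ordination
#'
#' Scatter of the first two principal coordinates, optionally colored by a
#' design factor.
#'
#' @param object A `phylosym_pcoa`.
#' @param design Optional design tibble.
#' @param colour Design column to map to color.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.phylosym_pcoa <- function(object, design = NULL, colour = NULL, ...) {
  df <- object$coordinates
  pct <- round(100 * object$prop_explained[1:2], 1)
  if (!is.null(design) && !is.null(colour)) {
    df[[colour]] <- design[[colour]][match(df$sample_id, design$sample_id)]
  }
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$PC1, .data$PC2)) +
    ggplot2::labs(x = sprintf("PCo1 (%.1f%%)", pct[1]),
                  y = sprintf("PCo2 (%.1f%%)", pct[2]))
  if (!is.null(colour) && colour %in% names(df)) {
    p + ggplot2::geom_point(ggplot2::aes(colour = .data[[colour]])) +
      ggplot2::theme_minimal()
  } else {
    p + ggplot2::geom_point() + ggplot2::theme_minimal()
  }
}

#' Plot a dissimilarity distribution
#'
#' @param object A `dissim_dist`.
#' @param ... Unused.
#' @return A ggplot boxplot of the pairwise dissimilarities.
#' @export
autoplot.dissim_dist <- function(object, ...) {
  df <- tibble::tibble(dissimilarity = object$values,
                       scope = object$scope)
  ggplot2::ggplot(df, ggplot2::aes(.data$scope, .data$dissimilarity)) +
    ggplot2::geom_boxplot(outlier.shape = NA) +
    ggplot2::labs(x = NULL, y = sprintf("%s dissimilarity", object$metric)) +
    ggplot2::theme_minimal()
}

#' Compare dissimilarity distributions across datasets
#'
#' @param distributions Named list of `dissim_dist` objects (e.g. one per
#'   omic layer).
#' @return A ggplot boxplot panel mirroring the functional-redundancy
#'   contrast.
#' @export
plot_dissimilarity_contrast <- function(distributions) {
  df <- purrr::map_dfr(names(distributions), function(nm) {
    tibble::tibble(dataset = nm, dissimilarity = distributions[[nm]]$values)
  })
  ggplot2::ggplot(df, ggplot2::aes(.data$dataset, .data$dissimilarity)) +
    ggplot2::geom_boxplot(outlier.shape = NA) +
    ggplot2::labs(x = NULL, y = "Bray-Curtis dissimilarity") +
    ggplot2::theme_minimal()
}

#' Plot top indicator features
#'
#' @param object An `indval_table`.
#' @param top Number of features to show.
#' @param ... Unused.
#' @return A ggplot bar chart of the strongest indicators.
#' @export
autoplot.indval_table <- function(object, top = 20, ...) {
  df <- dplyr::slice_max(tibble::as_tibble(object), .data$stat, n = top)
  ggplot2::ggplot(df, ggplot2::aes(stats::reorder(.data$feature_id,
                                                  .data$stat),
                                   .data$stat, fill = .data$best_group)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "IndVal statistic") +
    ggplot2::theme_minimal()
}
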