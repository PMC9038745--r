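# Beta-diversity currency: pairwise dissimilarity matrices, principal
# coordinates (Gower centering, signed eigenvalues), and dissimilarity
# distribution summaries.

#' Bray-Curtis dissimilarity matrix
#'
#' `d(x, y) = sum_i |x_i - y_i| / sum_i (x_i + y_i)`. Double zeros contribute
#' nothing; a pair of all-zero samples is defined as distance 0 with a
#' warning, keeping the matrix valid.
#'
#' @param table Feature table with non-negative abundances, >= 2 samples.
#' @return Square symmetric matrix with sample ids as dimnames and a
#'   `"metric"` attribute.
#' @export
bray_curtis_matrix <- function(table) {
  m <- ft_matrix(table)
  if (nrow(m) < 2) {
    abort_phylosym("Need at least 2 samples.", "phylosym_invalid_argument")
  }
  if (any(m < 0)) {
    abort_phylosym("Negative abundances are not allowed.",
                   "phylosym_invalid_input")
  }
  num <- as.matrix(stats::dist(m, method = "manhattan"))
  rs <- rowSums(m)
  den <- outer(rs, rs, "+")
  if (any(den == 0 & upper.tri(den))) {
    warning("Pair(s) of all-zero samples; their distance is defined as 0.")
  }
  D <- ifelse(den == 0, 0, num / den)
  diag(D) <- 0
  dimnames(D) <- list(rownames(m), rownames(m))
  attr(D, "metric") <- "bray_curtis"
  D
}

#' Jaccard dissimilarity matrix on presence/absence
#'
#' `d(x, y) = 1 - |shared| / |either|` on detected (abundance > 0) features;
#' an all-zero pair is defined as 0 with a warning.
#'
#' @inheritParams bray_curtis_matrix
#' @return Square symmetric matrix with a `"metric"` attribute.
#' @export
jaccard_matrix <- function(table) {
  m <- ft_matrix(table) > 0
  storage.mode(m) <- "double"
  if (nrow(m) < 2) {
    abort_phylosym("Need at least 2 samples.", "phylosym_invalid_argument")
  }
  shared <- tcrossprod(m)
  ni <- diag(shared)
  union <- outer(ni, ni, "+") - shared
  if (any(union == 0 & upper.tri(union))) {
    warning("Pair(s) of all-zero samples; their distance is defined as 0.")
  }
  D <- ifelse(union == 0, 0, 1 - shared / union)
  diag(D) <- 0
  dimnames(D) <- list(rownames(m), rownames(m))
  attr(D, "metric") <- "jaccard"
  D
}

#' Dissimilarity matrix under a named metric
#'
#' @inheritParams bray_curtis_matrix
#' @param metric `"bray_curtis"` (default) or `"jaccard"`.
#' @export
dissimilarity_matrix <- function(table, metric = c("bray_curtis", "jaccard")) {
  metric <- match.arg(metric)
  switch(metric,
         bray_curtis = bray_curtis_matrix(table),
         jaccard = jaccard_matrix(table))
}

#' Principal coordinates analysis (classical MDS with signed eigenvalues)
#'
#' Gower-centers `-D^2 / 2` and eigendecomposes it. Coordinates are returned
#' only for eigenvalues above 1e-10; negative eigenvalues are retained in the
#' eigenvalue vector and reported, uncorrected, unless `correction =
#' "lingoes"` (which adds the smallest constant to off-diagonal squared
#' dissimilarities making the matrix embeddable). Each axis is oriented so
#' its largest-magnitude coordinate is positive.
#'
#' @param D Labeled symmetric dissimilarity matrix.
#' @param correction `"none"` (default) or `"lingoes"`.
#' @return An object of class `phylosym_pcoa`: list with `coordinates`
#'   (tibble, `sample_id` + `PC1 ...`), `eigenvalues` (descending, signed),
#'   `prop_explained` (per positive axis), `correction`.
#' @export
pcoa <- function(D, correction = c("none", "lingoes")) {
  correction <- match.arg(correction)
  check_distance_matrix(D)
  D2 <- D^2
  if (correction == "lingoes") {
    G0 <- .gower_center(D2)
    c_star <- -min(eigen(G0, symmetric = TRUE, only.values = TRUE)$values)
    if (c_star > 1e-12) {
      D2 <- D2 + 2 * c_star
      diag(D2) <- 0
    }
  }
  G <- .gower_center(D2)
  eig <- eigen(G, symmetric = TRUE)
  pos <- eig$values > 1e-10
  coords <- eig$vectors[, pos, drop = FALSE] %*%
    diag(sqrt(eig$values[pos]), sum(pos))
  # sign convention: largest-|coordinate| entry on each axis is positive
  for (k in seq_len(ncol(coords))) {
    j <- which.max(abs(coords[, k]))
    if (coords[j, k] < 0) coords[, k] <- -coords[, k]
  }
  colnames(coords) <- paste0("PC", seq_len(ncol(coords)))
  rownames(coords) <- rownames(D)
  structure(list(
    coordinates = tibble::as_tibble(coords, rownames = "sample_id"),
    eigenvalues = eig$values,
    prop_explained = eig$values[pos] / sum(eig$values[pos]),
    correction = correction
  ), class = "phylosym_pcoa")
}

.gower_center <- function(D2) {
  A <- -D2 / 2
  n <- nrow(A)
  J <- diag(n) - matrix(1 / n, n, n)
  J %*% A %*% J
}

#' @export
print.phylosym_pcoa <- function(x, ...) {
  npos <- sum(x$eigenvalues > 1e-10)
  cat("Principal coordinates analysis\n")
  cat(sprintf("  %d samples, %d positive axes (correction: %s)\n",
              nrow(x$coordinates), npos, x$correction))
  cat(sprintf("  first axes explain %s of positive-eigenvalue variance\n",
              paste(sprintf("%.1f%%", 100 * utils::head(x$prop_explained, 3)),
                    collapse = ", ")))
  invisible(x)
}

#' Distribution of pairwise dissimilarities
#'
#' Collects the unique off-diagonal dissimilarities in scope: all pairs,
#' only within-group pairs, or only between-group pairs. Groups with fewer
#' than two samples are excluded from the within-group scope with a warning.
#'
#' @param D Labeled symmetric dissimilarity matrix.
#' @param design Design tibble (required for group scopes).
#' @param scope `"all"`, `"within"`, or `"between"`.
#' @param group_factor Grouping column in `design`.
#' @return An object of class `dissim_dist`: list with `values`, `median`,
#'   `q1`, `q3`, `n_pairs`, `scope`, `metric`.
#' @export
dissimilarity_distribution <- function(D, design = NULL,
                                       scope = c("all", "within", "between"),
                                       group_factor = "species") {
  scope <- match.arg(scope)
  check_distance_matrix(D)
  ids <- rownames(D)
  pairs <- which(lower.tri(D), arr.ind = TRUE)
  vals <- D[lower.tri(D)]
  if (scope != "all") {
    if (is.null(design)) {
      abort_phylosym("Group scopes require a design.",
                     "phylosym_invalid_argument")
    }
    grp <- design[[group_factor]][match(ids, design$sample_id)]
    if (scope == "within") {
      small <- names(which(table(grp) < 2))
      if (length(small)) {
        warning(sprintf("Excluding group(s) with < 2 samples: %s",
                        paste(small, collapse = ", ")))
      }
      keep <- grp[pairs[, 1]] == grp[pairs[, 2]]
    } else {
      keep <- grp[pairs[, 1]] != grp[pairs[, 2]]
    }
    vals <- vals[keep]
  }
  structure(list(
    values = vals,
    median = stats::median(vals),
    q1 = unname(stats::quantile(vals, 0.25)),
    q3 = unname(stats::quantile(vals, 0.75)),
    n_pairs = length(vals),
    scope = scope,
    metric = attr(D, "metric") %||% "unknown"
  ), class = "dissim_dist")
}

#' @export
print.dissim_dist <- function(x, ...) {
  cat(sprintf(
    "Dissimilarity distribution (%s, scope %s): n = %d pairs\n  median %.3f [Q1 %.3f, Q3 %.3f]\n",
    x$metric, x$scope, x$n_pairs, x$median, x$q1, x$q3))
  invisible(x)
}
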