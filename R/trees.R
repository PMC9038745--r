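# Dendrogram / phylogeny handling and tree-congruence statistics: Ward
# clustering, cophenetic and patristic matrices, Baker's Gamma with a
# label-shuffle permutation null, and shared-clade extraction.

#' Ward hierarchical clustering of a dissimilarity matrix
#'
#' Agglomerative clustering via [stats::hclust()]. `"ward.D2"` (default)
#' minimizes the increase in within-cluster sum of squared dissimilarities
#' (distances treated as squared-Euclidean surrogates); `"ward.D"` is the
#' historical variant operating on the dissimilarities directly.
#'
#' @param D Labeled symmetric dissimilarity matrix, >= 2 samples.
#' @param variant `"ward.D2"` (default) or `"ward.D"`.
#' @return An `stats::hclust` object.
#' @export
ward_dendrogram <- function(D, variant = c("ward.D2", "ward.D")) {
  variant <- match.arg(variant)
  check_distance_matrix(D)
  if (nrow(D) < 2) {
    abort_phylosym("Need >= 2 samples.", "phylosym_invalid_argument")
  }
  stats::hclust(stats::as.dist(D), method = variant)
}

#' Cophenetic distance matrix of a dendrogram
#'
#' Entry (i, j) is the merge height at which leaves i and j first join. The
#' result is ultrametric by construction.
#'
#' @param dendrogram An `hclust` object.
#' @return Labeled symmetric matrix ordered by leaf label.
#' @export
cophenetic_matrix <- function(dendrogram) {
  m <- as.matrix(stats::cophenetic(dendrogram))
  ord <- order(rownames(m))
  m <- m[ord, ord]
  attr(m, "metric") <- "cophenetic"
  m
}

#' Patristic distance matrix of a phylogeny
#'
#' Entry (i, j) is the sum of branch lengths along the path between leaves
#' i and j.
#'
#' @param host_tree An `ape::phylo` with branch lengths.
#' @return Labeled symmetric matrix ordered by leaf label.
#' @export
patristic_matrix <- function(host_tree) {
  if (is.null(host_tree$edge.length)) {
    abort_phylosym("Tree has no branch lengths.", "phylosym_invalid_input")
  }
  m <- ape::cophenetic.phylo(host_tree)
  ord <- order(rownames(m))
  m <- m[ord, ord]
  attr(m, "metric") <- "patristic"
  m
}

# Pair "merge-stage" statistics: for every unordered leaf pair, the number of
# leaves in the smallest cluster (dendrogram) or clade (phylogeny) containing
# both. Returns a labeled symmetric matrix (diagonal 1).
.pair_cluster_sizes <- function(tree) {
  if (inherits(tree, "hclust")) {
    labels <- tree$labels
    n <- length(labels)
    M <- matrix(1, n, n, dimnames = list(labels, labels))
    members <- c(as.list(seq_len(n)), vector("list", n - 1))
    for (k in seq_len(nrow(tree$merge))) {
      ab <- tree$merge[k, ]
      left <- if (ab[1] < 0) -ab[1] else members[[n + ab[1]]]
      right <- if (ab[2] < 0) -ab[2] else members[[n + ab[2]]]
      size <- length(left) + length(right)
      M[left, right] <- size
      M[right, left] <- size
      members[[n + k]] <- c(left, right)
    }
    M
  } else if (inherits(tree, "phylo")) {
    labels <- tree$tip.label
    n <- length(labels)
    M <- matrix(1, n, n, dimnames = list(labels, labels))
    clades <- .clade_tip_sets(tree)
    # process larger clades first so smaller (nested) ones overwrite
    for (tips in clades[order(-lengths(clades))]) {
      M[tips, tips] <- length(tips)
    }
    diag(M) <- 1
    M
  } else {
    abort_phylosym("Expected an hclust or phylo object.",
                   "phylosym_invalid_argument")
  }
}

# Leaf-label sets of all internal nodes (clades), including the root.
.clade_tip_sets <- function(tree) {
  if (inherits(tree, "hclust")) {
    labels <- tree$labels
    n <- length(labels)
    members <- c(as.list(seq_len(n)), vector("list", n - 1))
    out <- vector("list", n - 1)
    for (k in seq_len(nrow(tree$merge))) {
      ab <- tree$merge[k, ]
      left <- if (ab[1] < 0) -ab[1] else members[[n + ab[1]]]
      right <- if (ab[2] < 0) -ab[2] else members[[n + ab[2]]]
      members[[n + k]] <- c(left, right)
      out[[k]] <- labels[members[[n + k]]]
    }
    out
  } else {
    n <- length(tree$tip.label)
    lapply(seq(n + 1, n + tree$Nnode), function(node) {
      tree$tip.label[.descendant_tips(tree, node)]
    })
  }
}

.descendant_tips <- function(tree, node) {
  n <- length(tree$tip.label)
  kids <- tree$edge[tree$edge[, 1] == node, 2]
  unlist(lapply(kids, function(k) {
    if (k <= n) k else .descendant_tips(tree, k)
  }))
}

.check_leaf_sets <- function(l1, l2) {
  if (!setequal(l1, l2)) {
    diff <- c(setdiff(l1, l2), setdiff(l2, l1))
    abort_phylosym(paste("Leaf sets differ:", paste(diff, collapse = ", ")),
                   "phylosym_alignment_error")
  }
}

tree_labels <- function(tree) {
  if (inherits(tree, "hclust")) tree$labels else tree$tip.label
}

#' Baker's Gamma index between two trees
#'
#' For every unordered leaf pair in each tree, the pair statistic is the
#' number of leaves in the smallest cluster containing both; Baker's Gamma
#' is the Spearman rank correlation (average ranks for ties) between the two
#' pair-statistic vectors. Depends only on topology (cluster sizes), so it
#' is invariant to monotone transformations of merge heights.
#'
#' @param tree1,tree2 `hclust` or `ape::phylo` objects over the same leaf
#'   labels.
#' @return Gamma in [-1, 1].
#' @export
bakers_gamma <- function(tree1, tree2) {
  .check_leaf_sets(tree_labels(tree1), tree_labels(tree2))
  ids <- sort(tree_labels(tree1))
  M1 <- .pair_cluster_sizes(tree1)[ids, ids]
  M2 <- .pair_cluster_sizes(tree2)[ids, ids]
  stats::cor(M1[lower.tri(M1)], M2[lower.tri(M2)], method = "spearman")
}

#' Cophenetic correlation between two trees
#'
#' Pearson (default) or Spearman correlation between the lower triangles of
#' the two trees' cophenetic matrices; a phylogeny contributes its patristic
#' matrix.
#'
#' @inheritParams bakers_gamma
#' @param method `"pearson"` or `"spearman"`.
#' @return Correlation coefficient.
#' @export
cophenetic_correlation <- function(tree1, tree2,
                                   method = c("pearson", "spearman")) {
  method <- match.arg(method)
  .check_leaf_sets(tree_labels(tree1), tree_labels(tree2))
  ids <- sort(tree_labels(tree1))
  M1 <- .tree_distance_matrix(tree1)[ids, ids]
  M2 <- .tree_distance_matrix(tree2)[ids, ids]
  v1 <- M1[lower.tri(M1)]
  v2 <- M2[lower.tri(M2)]
  if (stats::sd(v1) == 0 || stats::sd(v2) == 0) {
    abort_phylosym("Zero variance in a cophenetic triangle.",
                   "phylosym_degenerate_input")
  }
  stats::cor(v1, v2, method = method)
}

.tree_distance_matrix <- function(tree) {
  if (inherits(tree, "hclust")) cophenetic_matrix(tree)
  else patristic_matrix(tree)
}

#' Label-shuffle permutation null for tree congruence
#'
#' Shuffles `tree2`'s leaf labels uniformly `n_shuffles` times, recomputes
#' the congruence statistic, and reports a one-sided upper p-value
#' `(1 + #(stat* >= observed)) / (1 + n_shuffles)` — one-sided because
#' phylosymbiosis predicts positive congruence. Both Baker's Gamma and the
#' cophenetic Pearson correlation of the observed pair are always reported.
#'
#' @inheritParams bakers_gamma
#' @param statistic `"bakers_gamma"` (default) or `"cophenetic_correlation"`.
#' @param n_shuffles Number of label shuffles.
#' @param seed Integer seed.
#' @return A `congruence_test`: list with `statistic`, `observed`,
#'   `bakers_gamma`, `cophenetic_pearson`, `null_mean`, `null_sd`,
#'   `null_quantiles`, `p_value`, `n_shuffles`, `seed`.
#' @export
label_shuffle_null <- function(tree1, tree2,
                               statistic = c("bakers_gamma",
                                             "cophenetic_correlation"),
                               n_shuffles = 999, seed = 1L) {
  statistic <- match.arg(statistic)
  .check_leaf_sets(tree_labels(tree1), tree_labels(tree2))
  ids <- sort(tree_labels(tree1))
  n <- length(ids)
  if (statistic == "bakers_gamma") {
    M1 <- .pair_cluster_sizes(tree1)[ids, ids]
    M2 <- .pair_cluster_sizes(tree2)[ids, ids]
    stat_fun <- function(A, B) {
      stats::cor(A[lower.tri(A)], B[lower.tri(B)], method = "spearman")
    }
  } else {
    M1 <- .tree_distance_matrix(tree1)[ids, ids]
    M2 <- .tree_distance_matrix(tree2)[ids, ids]
    stat_fun <- function(A, B) {
      stats::cor(A[lower.tri(A)], B[lower.tri(B)])
    }
  }
  obs <- stat_fun(M1, M2)
  null <- with_seed(seed, {
    vapply(seq_len(n_shuffles), function(b) {
      p <- sample.int(n)
      stat_fun(M1, M2[p, p])
    }, numeric(1))
  })
  structure(list(
    statistic = statistic,
    observed = obs,
    bakers_gamma = bakers_gamma(tree1, tree2),
    cophenetic_pearson = tryCatch(cophenetic_correlation(tree1, tree2),
                                  phylosym_error = function(e) NA_real_),
    null_mean = mean(null),
    null_sd = stats::sd(null),
    null_quantiles = stats::quantile(null, c(0.025, 0.5, 0.975)),
    p_value = perm_pvalue(obs, null),
    n_shuffles = n_shuffles,
    seed = seed
  ), class = "congruence_test")
}

#' @export
print.congruence_test <- function(x, ...) {
  cat(sprintf(
    "Tree congruence vs label-shuffle null (%s)\n  observed = %.4f (Baker's Gamma %.4f, cophenetic Pearson %.4f)\n  null mean %.4f (sd %.4f); p = %.4g (%d shuffles)\n",
    x$statistic, x$observed, x$bakers_gamma, x$cophenetic_pearson,
    x$null_mean, x$null_sd, x$p_value, x$n_shuffles))
  invisible(x)
}

#' Non-trivial clades shared by two trees
#'
#' Returns every leaf set of size 2 to n-1 that forms a clade (the exact
#' leaf set of an internal node or merge cluster) in both trees.
#'
#' @inheritParams bakers_gamma
#' @return List of character vectors (sorted leaf labels), possibly empty.
#' @export
common_subtrees <- function(tree1, tree2) {
  l1 <- tree_labels(tree1)
  .check_leaf_sets(l1, tree_labels(tree2))
  n <- length(l1)
  canon <- function(tree) {
    sets <- .clade_tip_sets(tree)
    sets <- Filter(function(s) length(s) >= 2 && length(s) < n, sets)
    unique(vapply(sets, function(s) paste(sort(s), collapse = "\r"),
                  character(1)))
  }
  shared <- intersect(canon(tree1), canon(tree2))
  lapply(shared, function(s) strsplit(s, "\r", fixed = TRUE)[[1]])
}

#' Serialize a dendrogram to Newick with merge heights as branch lengths
#'
#' @param dendrogram An `hclust` object.
#' @return A Newick string (also usable via [ape::read.tree()]).
#' @export
dendrogram_newick <- function(dendrogram) {
  phy <- ape::as.phylo(dendrogram)
  ape::write.tree(phy)
}
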