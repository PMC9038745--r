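# Shared fixtures and independent oracles, all built in code.

# tiny labeled feature table
make_table <- function(m, ids = sprintf("s%02d", seq_len(nrow(m))),
                       feats = sprintf("f%03d", seq_len(ncol(m))),
                       transform = "raw") {
  dimnames(m) <- list(ids, feats)
  out <- tibble::as_tibble(m, rownames = "sample_id")
  attr(out, "transform") <- transform
  out
}

# random labeled Euclidean distance matrix from n points in k dims
random_euclidean_D <- function(n, k = 3, seed = 1) {
  set.seed(seed)
  x <- matrix(rnorm(n * k), n)
  D <- as.matrix(dist(x))
  dimnames(D) <- list(sprintf("s%02d", 1:n), sprintf("s%02d", 1:n))
  D
}

# independent Mantel oracle: plain correlation of lower triangles
oracle_mantel_r <- function(D1, D2, method = "pearson") {
  ids <- sort(rownames(D1))
  a <- D1[ids, ids]; b <- D2[ids, ids]
  cor(a[lower.tri(a)], b[lower.tri(b)], method = method)
}

# brute-force patristic oracle: walk every leaf pair's path via the root
oracle_patristic <- function(tree) {
  n <- length(tree$tip.label)
  parent <- integer(max(tree$edge)); elen <- numeric(max(tree$edge))
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  elen[tree$edge[, 2]] <- tree$edge.length
  root <- setdiff(tree$edge[, 1], tree$edge[, 2])
  path_to_root <- function(i) {
    nodes <- i
    while (i != root) { i <- parent[i]; nodes <- c(nodes, i) }
    nodes
  }
  M <- matrix(0, n, n, dimnames = list(tree$tip.label, tree$tip.label))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    pi <- path_to_root(i); pj <- path_to_root(j)
    shared <- intersect(pi, pj)
    d <- sum(elen[setdiff(pi, shared)]) + sum(elen[setdiff(pj, shared)])
    M[i, j] <- M[j, i] <- d
  }
  ord <- order(rownames(M))
  M[ord, ord]
}

# brute-force cophenetic oracle from the merge list
oracle_cophenetic <- function(hc) {
  n <- length(hc$labels)
  M <- matrix(0, n, n, dimnames = list(hc$labels, hc$labels))
  members <- c(as.list(seq_len(n)), vector("list", n - 1))
  for (k in seq_len(nrow(hc$merge))) {
    ab <- hc$merge[k, ]
    left <- if (ab[1] < 0) -ab[1] else members[[n + ab[1]]]
    right <- if (ab[2] < 0) -ab[2] else members[[n + ab[2]]]
    M[left, right] <- hc$height[k]
    M[right, left] <- hc$height[k]
    members[[n + k]] <- c(left, right)
  }
  ord <- order(rownames(M))
  M[ord, ord]
}

# small simulation used by several suites: a fast coupled study
small_study <- function(seed = 1, n_species = 10, per_species = 3,
                        sigma2_phy = 2, sigma2_ind = 0.2, ...) {
  cfg <- sim_config(seed = seed, n_species = n_species,
                    sigma2_phy = sigma2_phy, sigma2_ind = sigma2_ind,
                    n_microbe_features = 120, seq_depth = 2000,
                    lc_features = 300, lc_detect_fraction = 0.3,
                    gc_features = 80, gc_core_features = 40,
                    n_functions = 60, function_fan_in = 10, ...)
  tree <- simulate_host_tree(n_species, depth = 100, seed = seed)
  design <- simulate_design(tree, per_species, seed = seed)
  micro <- simulate_microbiome(tree, design, cfg)
  list(cfg = cfg, tree = tree, design = design, micro = micro)
}
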