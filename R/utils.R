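# Internal helpers: seed handling, validation, shared small utilities.

`%||%` <- rlang::`%||%`

#' Derive a stage-specific sub-seed from a global seed
#'
#' Every random draw in the package is reachable from one global seed through
#' this splitting rule: `sub-seed = (seed + 104729 * stage_index) mod (2^31 - 1)`.
#' 104729 is the 10,000th prime; the modulus keeps the result a valid 32-bit
#' integer seed.
#'
#' @param seed Integer global seed.
#' @param stage Integer stage index (>= 0).
#' @return An integer seed.
#' @export
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.numeric(stage))
  as.integer((as.double(seed) + 104729 * as.double(stage)) %% 2147483647)
}

# Evaluate `code` under a local RNG state seeded with `seed`; the caller's RNG
# stream is untouched. Deterministic per seed.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Abort with a classed condition so callers/tests can distinguish error kinds.
abort_phylosym <- function(message, class) {
  rlang::abort(message, class = c(class, "phylosym_error"))
}

# --- feature-table helpers ---------------------------------------------------

# A feature table is a tibble whose first column is `sample_id` (unique
# character) and whose remaining columns are non-negative numeric feature
# abundances. The transform state ("raw" | "normalized" | "log") rides along
# as the "transform" attribute (defaults to "raw" when absent).

check_feature_table <- function(table, arg = "table") {
  if (!is.data.frame(table) || !"sample_id" %in% names(table)) {
    abort_phylosym(
      sprintf("`%s` must be a data frame with a `sample_id` column.", arg),
      "phylosym_invalid_argument"
    )
  }
  if (anyDuplicated(table$sample_id)) {
    abort_phylosym(
      sprintf("`%s` has duplicated sample ids.", arg),
      "phylosym_validation_error"
    )
  }
  feats <- setdiff(names(table), "sample_id")
  if (anyDuplicated(feats)) {
    abort_phylosym(
      sprintf("`%s` has duplicated feature ids.", arg),
      "phylosym_validation_error"
    )
  }
  invisible(table)
}

# Numeric matrix (samples x features) with sample ids as rownames.
ft_matrix <- function(table) {
  check_feature_table(table)
  m <- as.matrix(table[setdiff(names(table), "sample_id")])
  storage.mode(m) <- "double"
  rownames(m) <- table$sample_id
  m
}

# Rebuild a feature-table tibble from a samples x features matrix.
ft_tibble <- function(m, transform = NULL) {
  out <- tibble::as_tibble(m, rownames = "sample_id")
  if (!is.null(transform)) attr(out, "transform") <- transform
  out
}

ft_transform <- function(table) attr(table, "transform") %||% "raw"

check_distance_matrix <- function(D, arg = "D") {
  if (!is.matrix(D) || nrow(D) != ncol(D)) {
    abort_phylosym(sprintf("`%s` must be a square matrix.", arg),
                   "phylosym_invalid_input")
  }
  if (is.null(rownames(D))) {
    abort_phylosym(sprintf("`%s` must carry sample ids as dimnames.", arg),
                   "phylosym_invalid_input")
  }
  if (max(abs(D - t(D))) > 1e-12) {
    abort_phylosym(sprintf("`%s` is not symmetric.", arg),
                   "phylosym_invalid_input")
  }
  invisible(D)
}

# Strict lower triangle of a labeled distance matrix, in a fixed id order.
lower_triangle <- function(D, ids = rownames(D)) {
  D <- D[ids, ids, drop = FALSE]
  D[lower.tri(D)]
}

# Permutation p-value including the observed statistic: never 0, floor
# 1 / (n_perm + 1).
perm_pvalue <- function(stat_obs, stat_null) {
  (1 + sum(stat_null >= stat_obs)) / (1 + length(stat_null))
}
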