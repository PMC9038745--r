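# End-to-end orchestration: synthetic (or user-supplied) multi-omic layers
# through preprocessing, dissimilarities, PERMANOVA/Mantel, tree congruence
# and differential features, with a reproducibility manifest.

#' Default pipeline configuration
#'
#' A nested list mirroring the analysis stages. `synthesis` carries a
#' [sim_config()]; alternatively `inputs` may name TSV/Newick paths for the
#' tables, design and tree (exactly one of the two is active). The global
#' `seed` fans out to every stage through [derive_seed()].
#'
#' @param seed Global integer seed.
#' @param out_dir Output directory (`NULL` for no file output).
#' @param ... Overrides merged over the defaults by name.
#' @return A `run_config` list.
#' @export
default_config <- function(seed = 1L, out_dir = NULL, ...) {
  cfg <- list(
    seed = seed,
    out_dir = out_dir,
    synthesis = sim_config(seed = seed),
    inputs = NULL,
    stages = list(preprocess = TRUE, dissim = TRUE, tests = TRUE,
                  trees = TRUE, difffeat = TRUE),
    metric = "bray_curtis",
    permanova_terms = c("diet", "gut_morphology", "order", "species",
                        "collection_time"),
    n_perm_permanova = 999,
    n_perm_mantel = 999,
    n_shuffles_congruence = 999,
    ward_variant = "ward.D2",
    congruence_statistic = "bakers_gamma",
    difffeat_factors = c("diet", "order", "gut_morphology"),
    difffeat_percentile = 1,
    difffeat_n_perm = 999,
    noise_floor = 0.01,
    balance_threshold = 0.5
  )
  dots <- list(...)
  cfg[names(dots)] <- dots
  structure(cfg, class = "run_config")
}

#' Read a pipeline configuration from YAML
#'
#' Values in the file override the defaults by name; `synthesis` entries
#' override the default simulation config.
#'
#' @param path Path to a YAML file.
#' @return A `run_config` list.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  seed <- raw$seed %||% 1L
  cfg <- default_config(seed = seed)
  syn <- raw$synthesis
  raw$synthesis <- NULL
  cfg[names(raw)] <- raw
  if (!is.null(syn)) {
    cfg$synthesis <- do.call(sim_config, c(list(seed = seed), syn))
  }
  structure(cfg, class = "run_config")
}

#' Run the full phylosymbiosis analysis pipeline
#'
#' Executes the enabled stages in order: data synthesis (or input loading),
#' preprocessing (internal-standard normalization + log for both metabolome
#' layers, balance-score filtering for the GC layer, species median
#' representatives), dissimilarity matrices, sequential PERMANOVA and Mantel
#' tests, dendrogram-phylogeny congruence, dissimilarity-distribution
#' contrasts, and differential-feature discovery. When `out_dir` is set,
#' result tables, trees, a JSON manifest (config hash, seed, package
#' version) and all feature tables are written there; identical configs
#' yield identical outputs.
#'
#' @param config A `run_config` from [default_config()] or [read_config()].
#' @return A named list bundle with elements `data`, `distances`,
#'   `permanova`, `mantel`, `congruence`, `dissim_contrast`, `difffeat`,
#'   `scfa`, and `manifest`.
#' @export
run_pipeline <- function(config = default_config()) {
  seed <- config$seed
  bundle <- list()

  # --- data layer ---
  if (is.null(config$inputs)) {
    syn <- config$synthesis
    preset <- table1_preset()
    design <- preset$design
    tree <- preset$tree
    micro <- simulate_microbiome(tree, design, syn)
    lc <- simulate_metabolome_lc(micro, tree, design, syn)
    gc <- simulate_metabolome_gc(micro, design, syn)
    fun <- simulate_function_profiles(micro, syn)
    scfa <- simulate_scfa(design, syn)
  } else {
    inp <- config$inputs
    design <- read_design(inp$design)
    tree <- read_newick(inp$tree)
    if (!all(unique(design$species) %in% tree$tip.label)) {
      abort_phylosym("Design species missing from tree.",
                     "phylosym_validation_error")
    }
    micro <- list(table = read_feature_table(inp$microbiome), truth = NULL)
    lc <- list(table = read_feature_table(inp$lc),
               background_table = if (!is.null(inp$lc_background)) {
                 read_feature_table(inp$lc_background)
               })
    gc <- list(table = read_feature_table(inp$gc),
               feature_meta = if (!is.null(inp$gc_meta)) {
                 tibble::as_tibble(utils::read.delim(inp$gc_meta))
               })
    fun <- if (!is.null(inp$functions)) read_feature_table(inp$functions)
    scfa <- if (!is.null(inp$scfa)) read_feature_table(inp$scfa)
  }
  bundle$data <- list(design = design, tree = tree, microbiome = micro,
                      lc = lc, gc = gc, functions = fun, scfa = scfa)

  # --- preprocess ---
  lc_is <- intersect(c("IS_ampicillin"), names(lc$table))
  lc_log <- if (length(lc_is)) {
    normalize_and_log(lc$table, lc_is, noise_floor = 0)
  } else {
    lc$table
  }
  gc_filtered <- feature_filters(gc$table, feature_meta = gc$feature_meta,
                                 balance_threshold = config$balance_threshold)
  gc_is <- intersect(c("IS_ribitol"), names(gc_filtered$table))
  gc_log <- if (length(gc_is)) {
    normalize_and_log(gc_filtered$table, gc_is,
                      noise_floor = config$noise_floor)
  } else {
    gc_filtered$table
  }
  tables <- list(microbiome = micro$table, lc = lc_log, gc = gc_log)
  if (!is.null(fun)) tables$functions <- fun

  # --- dissimilarities ---
  D <- lapply(tables, dissimilarity_matrix, metric = config$metric)
  bundle$distances <- D

  # --- hypothesis tests ---
  if (isTRUE(config$stages$tests)) {
    bundle$permanova <- lapply(names(D)[names(D) != "functions"], function(nm) {
      permanova_sequential(D[[nm]], design, config$permanova_terms,
                           n_perm = config$n_perm_permanova,
                           seed = derive_seed(seed, 11L))
    })
    names(bundle$permanova) <- names(D)[names(D) != "functions"]
    pairs <- utils::combn(c("microbiome", "lc", "gc"), 2)
    bundle$mantel <- lapply(seq_len(ncol(pairs)), function(j) {
      mantel_test(D[[pairs[1, j]]], D[[pairs[2, j]]],
                  n_perm = config$n_perm_mantel,
                  seed = derive_seed(seed, 12L))
    })
    names(bundle$mantel) <- apply(pairs, 2, paste, collapse = ":")
  }

  # --- tree congruence on species medians ---
  if (isTRUE(config$stages$trees)) {
    bundle$congruence <- lapply(names(tables)[names(tables) != "functions"],
                                function(nm) {
      med <- median_representative(tables[[nm]], design, "species")
      Dm <- dissimilarity_matrix(med, metric = config$metric)
      dend <- ward_dendrogram(Dm, variant = config$ward_variant)
      label_shuffle_null(tree, dend,
                         statistic = config$congruence_statistic,
                         n_shuffles = config$n_shuffles_congruence,
                         seed = derive_seed(seed, 13L))
    })
    names(bundle$congruence) <- names(tables)[names(tables) != "functions"]
  }

  # --- dissimilarity contrast (functional redundancy) ---
  bundle$dissim_contrast <- purrr::map_dfr(names(D), function(nm) {
    dd <- dissimilarity_distribution(D[[nm]])
    tibble::tibble(dataset = nm, median = dd$median, q1 = dd$q1, q3 = dd$q3,
                   n_pairs = dd$n_pairs)
  })

  # --- differential features ---
  if (isTRUE(config$stages$difffeat)) {
    bundle$difffeat <- differential_features(
      gc_log, design, config$difffeat_factors,
      percentile = config$difffeat_percentile,
      n_perm = config$difffeat_n_perm, seed = derive_seed(seed, 14L)
    )
  }

  # --- targeted SCFA panel ---
  if (!is.null(scfa)) {
    bundle$scfa <- scfa_molar_ratio(scfa, design, "diet")
  }

  hashable <- unclass(config)
  hashable$out_dir <- NULL
  bundle$manifest <- list(
    config_hash = rlang::hash(hashable),
    seed = seed,
    package_version = as.character(utils::packageVersion("phylosym")),
    stages_run = names(config$stages)[unlist(config$stages)]
  )

  if (!is.null(config$out_dir)) {
    .write_bundle(bundle, config)
  }
  bundle
}

.write_bundle <- function(bundle, config) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(config$out_dir, ...)
  write_design(bundle$data$design, p("design.tsv"))
  write_newick(bundle$data$tree, p("host_tree.nwk"))
  write_feature_table(bundle$data$microbiome$table, p("microbiome.tsv"))
  for (nm in names(bundle$permanova %||% list())) {
    readr::write_tsv(tidy(bundle$permanova[[nm]]),
                     p(sprintf("permanova_%s.tsv", nm)))
  }
  if (!is.null(bundle$mantel)) {
    jsonlite::write_json(lapply(bundle$mantel, unclass), p("mantel.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(bundle$congruence)) {
    jsonlite::write_json(lapply(bundle$congruence, function(x) {
      x$null_quantiles <- as.list(x$null_quantiles)
      unclass(x)
    }), p("congruence.json"), auto_unbox = TRUE, digits = NA)
  }
  readr::write_tsv(bundle$dissim_contrast, p("dissimilarity_medians.tsv"))
  if (!is.null(bundle$difffeat)) {
    readr::write_tsv(bundle$difffeat$results, p("indval.tsv"))
    readr::write_tsv(bundle$difffeat$candidates, p("candidates.tsv"))
  }
  jsonlite::write_json(bundle$manifest, p("manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(config$out_dir)
}
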