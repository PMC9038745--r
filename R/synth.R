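# Synthetic study generator: host phylogenies, study designs, and coupled
# microbiome / LC-like / GC-like metabolome / predicted-function tables with
# controllable phylosymbiotic signal. Every draw is deterministic given the
# config seed; sub-seeds per layer follow derive_seed().

# stage indices of the seed-splitting rule
.STAGE <- c(tree = 1L, design = 2L, microbiome = 3L, lc = 4L, gc = 5L,
            functions = 6L, scfa = 7L)

#' Simulation configuration
#'
#' Bundles every knob of the synthetic study generator. The defaults emulate
#' the sampling design and data envelope of a zoo-scale mammalian gut survey:
#' 25 host species and 101 samples with uneven per-species counts, amplicon
#' libraries of ~21,000 reads detecting a few hundred microbial features per
#' sample, a sparse and diverse LC-type metabolome (~10,000 features, ~11.5%
#' detected per sample), a small dense GC-type metabolome (~350 features with
#' a shared core of ~130 detected per sample), and redundancy-mapped
#' predicted-function profiles.
#'
#' @param seed Integer; fully determines all generated data.
#' @param n_species Number of host species (used by [simulate_design()]).
#' @param samples_per_species Integer vector (recycled) of per-species sample
#'   counts for [simulate_design()]; `NULL` means 4 each.
#' @param tree_depth Root-to-tip depth of simulated ultrametric trees
#'   (arbitrary time units).
#' @param sigma2_phy Brownian-motion variance of latent species traits per
#'   unit branch length. Controls the strength of phylosymbiosis.
#' @param sigma2_ind Variance of the per-sample (within-species) Gaussian
#'   noise added to latent traits.
#' @param n_microbe_features,seq_depth,microbe_detect_fraction Microbiome
#'   layer: number of features, multinomial sequencing depth, and the
#'   per-sample fraction of features that pass the latent detection quantile.
#' @param lc_features,lc_detect_fraction LC metabolome layer: total feature
#'   count and per-sample detection fraction.
#' @param lc_role_fractions Named numeric vector summing to 1 partitioning LC
#'   features into roles `microbiome`, `phylogeny`, `diet`, `background`,
#'   `noise`.
#' @param mixing_density Probability that a given microbial feature feeds a
#'   given microbiome-driven LC feature (sparse non-negative mixing).
#' @param lc_diet_effect Log-scale shift of diet-driven LC features inside
#'   their diet group.
#' @param gc_features,gc_core_features,gc_core_presence,gc_noise_presence GC
#'   layer: total features, size of the shared core, per-sample presence
#'   probability of core and of non-core features.
#' @param gc_enriched_features,gc_effect,gc_enriched_group Number of planted
#'   group-enriched GC features (lactate/succinate analogues), their
#'   log-scale effect, and the diet group they are planted in.
#' @param n_functions,function_fan_in Predicted-function layer: size of the
#'   shared function pool and the number of functions each microbial feature
#'   contributes to.
#' @param scfa_ratios Named list of planted acetate:propionate:butyrate molar
#'   ratios per diet group (each a length-3 numeric).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_species = 25L,
                       samples_per_species = NULL,
                       tree_depth = 100,
                       sigma2_phy = 0.05,
                       sigma2_ind = 0.5,
                       n_microbe_features = 1000L,
                       seq_depth = 21000L,
                       microbe_detect_fraction = 0.25,
                       lc_features = 10029L,
                       lc_detect_fraction = 0.115,
                       lc_role_fractions = c(microbiome = 0.45, phylogeny = 0.15,
                                             diet = 0.05, background = 0.05,
                                             noise = 0.30),
                       mixing_density = 0.05,
                       lc_diet_effect = 3,
                       gc_features = 347L,
                       gc_core_features = 130L,
                       gc_core_presence = 0.93,
                       gc_noise_presence = 0.05,
                       gc_enriched_features = 6L,
                       gc_effect = 3,
                       gc_enriched_group = "omnivore",
                       n_functions = 200L,
                       function_fan_in = 20L,
                       scfa_ratios = list(herbivore = c(75, 15, 10),
                                          carnivore = c(60, 25, 15),
                                          omnivore = c(73, 7, 21))) {
  cfg <- as.list(environment())
  if (cfg$sigma2_phy < 0 || cfg$sigma2_ind < 0) {
    abort_phylosym("Variances must be >= 0.", "phylosym_invalid_argument")
  }
  if (cfg$mixing_density <= 0 || cfg$mixing_density > 1) {
    abort_phylosym("`mixing_density` must be in (0, 1].",
                   "phylosym_invalid_argument")
  }
  counts <- c(cfg$n_species, cfg$n_microbe_features, cfg$seq_depth,
              cfg$lc_features, cfg$gc_features, cfg$n_functions,
              cfg$function_fan_in)
  if (any(counts < 1)) {
    abort_phylosym("Counts must be >= 1.", "phylosym_invalid_argument")
  }
  if (abs(sum(cfg$lc_role_fractions) - 1) > 1e-8) {
    abort_phylosym("`lc_role_fractions` must sum to 1.",
                   "phylosym_invalid_argument")
  }
  structure(cfg, class = "sim_config")
}

#' Simulate an ultrametric host phylogeny
#'
#' Pure-birth (Yule) topology with all root-to-tip path lengths rescaled to
#' exactly `depth`, standing in for a divergence-dated host tree.
#'
#' @param n_species Number of leaves (>= 2).
#' @param depth Root-to-tip depth in arbitrary time units.
#' @param seed Integer seed; the same seed always yields the same tree.
#' @return An ultrametric rooted `ape::phylo` with unique leaf labels
#'   `sp01 ...`.
#' @export
simulate_host_tree <- function(n_species, depth = 100, seed = 1L) {
  if (n_species < 2) {
    abort_phylosym("`n_species` must be >= 2.", "phylosym_invalid_argument")
  }
  if (depth <= 0) {
    abort_phylosym("`depth` must be > 0.", "phylosym_invalid_argument")
  }
  tree <- with_seed(derive_seed(seed, .STAGE[["tree"]]), {
    ape::rphylo(n_species, birth = 1, death = 0)
  })
  tree$tip.label <- sprintf("sp%02d", seq_len(n_species))
  cur <- max(ape::node.depth.edgelength(tree))
  tree$edge.length <- tree$edge.length * (depth / cur)
  tree
}

# Table-1-like animal roster: species, per-species sample count, order, diet
# group, gut morphology.
.table1_roster <- function() {
  tibble::tribble(
    ~species, ~n, ~order, ~diet, ~gut_morphology,
    "red_ruffed_lemur", 1L, "Primates", "omnivore", "simple",
    "black_white_ruffed_lemur", 1L, "Primates", "omnivore", "simple",
    "mandrill", 8L, "Primates", "omnivore", "simple",
    "chimpanzee", 10L, "Primates", "omnivore", "simple",
    "gibbon", 3L, "Primates", "omnivore", "simple",
    "capuchin", 1L, "Primates", "omnivore", "simple",
    "gorilla", 6L, "Primates", "herbivore", "simple",
    "sheep", 5L, "Artiodactyla", "herbivore", "foregut",
    "goat", 1L, "Artiodactyla", "herbivore", "foregut",
    "black_bear", 2L, "Carnivora", "omnivore", "simple",
    "brown_bear", 5L, "Carnivora", "omnivore", "simple",
    "coati", 7L, "Carnivora", "omnivore", "simple",
    "african_wild_dog", 1L, "Carnivora", "carnivore", "simple",
    "arabian_wolf", 1L, "Carnivora", "carnivore", "simple",
    "tiger", 2L, "Carnivora", "carnivore", "simple",
    "leopard", 2L, "Carnivora", "carnivore", "simple",
    "lion", 3L, "Carnivora", "carnivore", "simple",
    "jungle_cat", 2L, "Carnivora", "carnivore", "simple",
    "sand_cat", 1L, "Carnivora", "carnivore", "simple",
    "hyena", 1L, "Carnivora", "carnivore", "simple",
    "rhinoceros", 13L, "Perissodactyla", "herbivore", "hindgut",
    "zebra", 16L, "Perissodactyla", "herbivore", "hindgut",
    "donkey", 1L, "Perissodactyla", "herbivore", "hindgut",
    "african_elephant", 3L, "Proboscidea", "herbivore", "hindgut",
    "asian_elephant", 5L, "Proboscidea", "herbivore", "hindgut"
  )
}

# Fixed ultrametric stand-in phylogeny for the preset roster (depth 100,
# arbitrary time units; node depths honor the ordinal groupings, not real
# divergence dates).
.table1_newick <- function() {
  prim <- paste0(
    "((red_ruffed_lemur:10,black_white_ruffed_lemur:10):30,",
    "(capuchin:35,(mandrill:25,(gibbon:18,(gorilla:8,chimpanzee:8):10):7):10):5)"
  )
  carn <- paste0(
    "((hyena:35,((sand_cat:4,jungle_cat:4):16,",
    "(tiger:8,(leopard:4,lion:4):4):12):15):15,",
    "((african_wild_dog:8,arabian_wolf:8):37,",
    "(coati:40,(black_bear:5,brown_bear:5):35):5):5)"
  )
  art <- "(sheep:12,goat:12)"
  per <- "(rhinoceros:55,(zebra:8,donkey:8):47)"
  pro <- "(african_elephant:8,asian_elephant:8)"
  paste0("(", pro, ":92,(", prim, ":50,(", carn, ":30,(", art, ":63,",
         per, ":20):5):10):10);")
}

#' Preset 25-species, 101-sample study design
#'
#' Reconstructs a zoo-survey roster: 25 mammalian species across five orders
#' (Primates, Artiodactyla, Carnivora, Perissodactyla, Proboscidea), three
#' diet groups and three gut morphologies, with uneven per-species sample
#' counts totalling 101, plus a fixed ultrametric stand-in host phylogeny
#' consistent with the ordinal groupings. Collection times are fixed seeded
#' draws in [0, 14] hours, independent of all signals.
#'
#' @return A list with `design` (tibble: `sample_id`, `species`, `order`,
#'   `diet`, `gut_morphology`, `collection_time`, `sex`) and `tree`
#'   (`ape::phylo`).
#' @export
table1_preset <- function() {
  roster <- .table1_roster()
  design <- tidyr::uncount(roster, .data$n, .remove = TRUE, .id = "rep")
  design <- dplyr::mutate(
    design,
    sample_id = sprintf("%s_%02d", .data$species, .data$rep),
    .before = 1
  )
  design$rep <- NULL
  extras <- with_seed(20170301L, {
    list(time = round(stats::runif(nrow(design), 0, 14), 1),
         sex = sample(c("F", "M"), nrow(design), replace = TRUE))
  })
  design$collection_time <- extras$time
  design$sex <- extras$sex
  tree <- ape::read.tree(text = .table1_newick())
  list(design = tibble::as_tibble(design), tree = tree)
}

#' Simulate a generic study design for a given host tree
#'
#' Assigns species to orders by cutting the tree into clades, and to diet
#' groups and gut morphologies cyclically; per-species sample counts are
#' recycled from `samples_per_species`. Collection times are uniform in
#' [0, 14] h, independent of everything else.
#'
#' @param tree `ape::phylo` host tree.
#' @param samples_per_species Integer vector, recycled across species.
#' @param seed Integer seed.
#' @return A design tibble with the same columns as [table1_preset()].
#' @export
simulate_design <- function(tree, samples_per_species = 4L, seed = 1L) {
  species <- tree$tip.label
  ns <- length(species)
  n_per <- rep_len(as.integer(samples_per_species), ns)
  with_seed(derive_seed(seed, .STAGE[["design"]]), {
    design <- tibble::tibble(
      species = rep(species, n_per),
      order = rep(paste0("order", ((seq_len(ns) - 1L) %/% 5L) + 1L), n_per),
      diet = rep(c("herbivore", "omnivore", "carnivore")[
        ((seq_len(ns) - 1L) %% 3L) + 1L], n_per),
      gut_morphology = rep(c("simple", "foregut", "hindgut")[
        ((seq_len(ns) - 1L) %% 3L) + 1L], n_per)
    )
    design <- dplyr::mutate(
      dplyr::group_by(design, .data$species),
      sample_id = sprintf("%s_%02d", .data$species, dplyr::row_number()),
      .before = 1
    )
    design <- dplyr::ungroup(design)
    design$collection_time <- round(stats::runif(nrow(design), 0, 14), 1)
    design$sex <- sample(c("F", "M"), nrow(design), replace = TRUE)
    design
  })
}

# Latent species traits: Brownian motion on the tree. Returns a
# species x n_features matrix: root state N(0, 1) per feature plus a
# phylogenetically correlated deviation with variance sigma2_phy per unit
# branch length.
.bm_species_traits <- function(tree, species, n_features, sigma2_phy) {
  root <- matrix(stats::rnorm(n_features), nrow = 1)
  base <- root[rep(1, length(species)), , drop = FALSE]
  rownames(base) <- species
  if (sigma2_phy > 0) {
    C <- ape::vcv(tree)[species, species]
    L <- chol(C + diag(1e-10, nrow(C)))
    Z <- matrix(stats::rnorm(length(species) * n_features),
                nrow = length(species))
    base <- base + sqrt(sigma2_phy) * crossprod(L, Z)
  }
  base
}

# Per-sample latent matrix from species traits + individual noise, then
# quantile-threshold zero-inflation: per sample, only the top
# `detect_fraction` of latent values survive.
.latent_to_detected <- function(traits, design, sigma2_ind, detect_fraction) {
  lat <- traits[design$species, , drop = FALSE]
  if (sigma2_ind > 0) {
    lat <- lat + matrix(stats::rnorm(length(lat), sd = sqrt(sigma2_ind)),
                        nrow = nrow(lat))
  }
  rownames(lat) <- design$sample_id
  keep <- t(apply(lat, 1, function(x) {
    x >= stats::quantile(x, 1 - detect_fraction, names = FALSE)
  }))
  list(latent = lat, keep = keep)
}

#' Simulate a phylosymbiotic microbiome count table
#'
#' Latent per-species log-abundances evolve along the host tree by Brownian
#' motion (variance `sigma2_phy` per unit branch length); each sample adds
#' Gaussian individual noise (`sigma2_ind`), abundances below the per-sample
#' detection quantile are zeroed, survivors are softmax-transformed to
#' proportions, and counts are drawn multinomially at the configured
#' sequencing depth.
#'
#' @param tree Host phylogeny (`ape::phylo`) covering all design species.
#' @param design Study design tibble (see [table1_preset()]).
#' @param config A [sim_config()].
#' @return List with `table` (count feature table, first column `sample_id`)
#'   and `truth` (tibble: `feature_id`, `role`, `group`).
#' @export
simulate_microbiome <- function(tree, design, config = sim_config()) {
  species <- unique(design$species)
  if (!all(species %in% tree$tip.label)) {
    abort_phylosym(
      paste("Species missing from tree:",
            paste(setdiff(species, tree$tip.label), collapse = ", ")),
      "phylosym_mapping_error"
    )
  }
  nf <- config$n_microbe_features
  out <- with_seed(derive_seed(config$seed, .STAGE[["microbiome"]]), {
    traits <- .bm_species_traits(tree, species, nf, config$sigma2_phy)
    det <- .latent_to_detected(traits, design, config$sigma2_ind,
                               config$microbe_detect_fraction)
    prob <- exp(det$latent) * det$keep
    prob <- prob / rowSums(prob)
    counts <- t(apply(prob, 1, function(p) {
      stats::rmultinom(1, config$seq_depth, p)[, 1]
    }))
    counts
  })
  colnames(out) <- sprintf("asv%04d", seq_len(nf))
  truth <- tibble::tibble(feature_id = colnames(out), role = "phylogeny",
                          group = NA_character_)
  list(table = ft_tibble(out, transform = "raw"), truth = truth)
}

#' Simulate a sparse, diverse LC-type metabolome coupled to the microbiome
#'
#' Features are partitioned into generative roles: microbiome-driven (sparse
#' non-negative linear mixing of microbial log-abundances), phylogeny-driven
#' (Brownian motion on the host tree), diet-driven (shared shift within one
#' diet group), background (constant, also present in blank samples) and pure
#' noise. Per sample, only the top `lc_detect_fraction` of latent values are
#' detected; detected abundances are exponentiated peak areas scaled by a
#' per-sample instrument drift that also scales the appended internal
#' standard (`IS_ampicillin`).
#'
#' @inheritParams simulate_microbiome
#' @param microbiome Result of [simulate_microbiome()] (or its `$table`).
#' @return List with `table`, `truth` (feature roles, planted diet group and
#'   `planted` flag), and `background_table` (three blank samples for
#'   background filtering).
#' @export
simulate_metabolome_lc <- function(microbiome, tree, design,
                                   config = sim_config()) {
  micro <- if (is.data.frame(microbiome)) microbiome else microbiome$table
  if (!identical(sort(micro$sample_id), sort(design$sample_id))) {
    abort_phylosym("Microbiome and design sample ids differ.",
                   "phylosym_alignment_error")
  }
  micro <- micro[match(design$sample_id, micro$sample_id), ]
  M <- ft_matrix(micro)
  logM <- log1p(M / rowSums(M) * 1e4)
  nf <- config$lc_features
  n_role <- pmax(0L, round(config$lc_role_fractions * nf))
  names(n_role) <- names(config$lc_role_fractions)
  n_role[["noise"]] <- nf - sum(n_role[setdiff(names(n_role), "noise")])
  roles <- rep(names(n_role), n_role)
  species <- unique(design$species)
  diets <- sort(unique(design$diet))

  res <- with_seed(derive_seed(config$seed, .STAGE[["lc"]]), {
    lat <- matrix(0, nrow(design), nf)
    group <- rep(NA_character_, nf)
    idx <- split(seq_len(nf), roles)

    if (length(idx$microbiome)) {
      k <- length(idx$microbiome)
      W <- matrix(stats::rbinom(ncol(M) * k, 1, config$mixing_density) *
                    abs(stats::rnorm(ncol(M) * k)), ncol(M), k)
      mix <- logM %*% W
      sds <- apply(mix, 2, stats::sd)
      sds[sds == 0] <- 1
      lat[, idx$microbiome] <- scale(mix, scale = sds) +
        matrix(stats::rnorm(k), nrow(design), k, byrow = TRUE)
    }
    if (length(idx$phylogeny)) {
      traits <- .bm_species_traits(tree, species, length(idx$phylogeny),
                                   config$sigma2_phy)
      lat[, idx$phylogeny] <- traits[design$species, , drop = FALSE] +
        matrix(stats::rnorm(nrow(design) * length(idx$phylogeny),
                            sd = sqrt(max(config$sigma2_ind, 1e-12))),
               nrow(design))
    }
    if (length(idx$diet)) {
      gr <- sample(diets, length(idx$diet), replace = TRUE)
      group[idx$diet] <- gr
      eff <- outer(design$diet, gr, "==") * config$lc_diet_effect
      lat[, idx$diet] <- eff +
        matrix(stats::rnorm(length(eff)), nrow(design))
    }
    if (length(idx$background)) {
      base <- stats::rnorm(length(idx$background), mean = 2)
      lat[, idx$background] <- matrix(base, nrow(design),
                                      length(idx$background), byrow = TRUE) +
        matrix(stats::rnorm(nrow(design) * length(idx$background), sd = 0.1),
               nrow(design))
    }
    if (length(idx$noise)) {
      lat[, idx$noise] <- matrix(stats::rnorm(nrow(design) * length(idx$noise)),
                                 nrow(design))
    }

    thr <- apply(lat, 1, stats::quantile, probs = 1 - config$lc_detect_fraction,
                 names = FALSE)
    keep <- lat >= thr
    drift <- exp(stats::rnorm(nrow(design), sd = 0.2))
    abund <- exp(lat) * keep * drift
    blanks <- matrix(0, 3, nf)
    if (length(idx$background)) {
      base <- colMeans(lat[, idx$background, drop = FALSE])
      blanks[, idx$background] <-
        exp(matrix(base, 3, length(idx$background), byrow = TRUE) +
              matrix(stats::rnorm(3 * length(idx$background), sd = 0.1), 3))
    }
    list(abund = abund, blanks = blanks, group = group, drift = drift)
  })

  feat_ids <- sprintf("lc%05d", seq_len(nf))
  tab <- res$abund
  dimnames(tab) <- list(design$sample_id, feat_ids)
  tab <- cbind(tab, IS_ampicillin = 1000 * res$drift)
  blanks <- res$blanks
  dimnames(blanks) <- list(sprintf("blank_%d", 1:3), feat_ids)
  truth <- tibble::tibble(
    feature_id = c(feat_ids, "IS_ampicillin"),
    role = c(roles, "internal_standard"),
    group = c(res$group, NA),
    planted = c(roles == "diet", FALSE)
  )
  list(table = ft_tibble(tab, transform = "raw"), truth = truth,
       background_table = ft_tibble(blanks, transform = "raw"))
}

#' Simulate a dense, core-dominated GC-type metabolome
#'
#' A large shared core of features is present in most samples with
#' log-normally varying abundance; a few planted group-enriched features
#' (fermentation-product analogues such as lactate/succinate) are shifted up
#' in one diet group; the remainder are sporadic noise features. A
#' ribitol-like internal standard is appended, and per-feature balance
#' scores are emitted (high for core/enriched features, lower for noise).
#'
#' @inheritParams simulate_metabolome_lc
#' @return List with `table`, `truth`, and `feature_meta` (tibble:
#'   `feature_id`, `balance_score`, `role`).
#' @export
simulate_metabolome_gc <- function(microbiome, design, config = sim_config()) {
  micro <- if (is.data.frame(microbiome)) microbiome else microbiome$table
  if (!identical(sort(micro$sample_id), sort(design$sample_id))) {
    abort_phylosym("Microbiome and design sample ids differ.",
                   "phylosym_alignment_error")
  }
  nf <- config$gc_features
  n_core <- min(config$gc_core_features, nf)
  n_enr <- min(config$gc_enriched_features, nf - n_core)
  n_noise <- nf - n_core - n_enr
  roles <- c(rep("core", n_core), rep("diet", n_enr), rep("noise", n_noise))
  ns <- nrow(design)

  res <- with_seed(derive_seed(config$seed, .STAGE[["gc"]]), {
    base <- stats::rnorm(nf, mean = c(2, 2, 0)[match(roles, c("core", "diet",
                                                              "noise"))])
    lat <- matrix(base, ns, nf, byrow = TRUE) +
      matrix(stats::rnorm(ns * nf, sd = 0.7), ns)
    if (n_enr > 0) {
      in_grp <- design$diet == config$gc_enriched_group
      lat[, n_core + seq_len(n_enr)] <-
        lat[, n_core + seq_len(n_enr), drop = FALSE] +
        config$gc_effect * in_grp
    }
    pres_p <- c(core = config$gc_core_presence, diet = 0.95,
                noise = config$gc_noise_presence)[roles]
    pres <- matrix(stats::rbinom(ns * nf, 1, rep(pres_p, each = ns)), ns)
    drift <- exp(stats::rnorm(ns, sd = 0.2))
    abund <- exp(lat) * pres * drift
    balance <- numeric(nf)
    balance[roles != "noise"] <- stats::runif(sum(roles != "noise"), 0.7, 1)
    balance[roles == "noise"] <- stats::runif(sum(roles == "noise"), 0.1, 0.6)
    list(abund = abund, drift = drift, balance = balance)
  })

  feat_ids <- sprintf("gc%03d", seq_len(nf))
  tab <- res$abund
  dimnames(tab) <- list(design$sample_id, feat_ids)
  tab <- cbind(tab, IS_ribitol = 1000 * res$drift)
  truth <- tibble::tibble(
    feature_id = c(feat_ids, "IS_ribitol"),
    role = c(roles, "internal_standard"),
    group = c(ifelse(roles == "diet", config$gc_enriched_group, NA), NA),
    planted = c(roles == "diet", FALSE)
  )
  meta <- tibble::tibble(
    feature_id = c(feat_ids, "IS_ribitol"),
    balance_score = c(res$balance, 1),
    role = c(roles, "internal_standard")
  )
  list(table = ft_tibble(tab, transform = "raw"), truth = truth,
       feature_meta = meta)
}

#' Simulate redundancy-mapped predicted-function profiles
#'
#' Each microbial feature contributes its relative abundance to `fan_in`
#' functions drawn from a shared pool; a function's abundance is the sum of
#' its contributors. The many-to-one mapping collapses taxonomic turnover,
#' so between-sample dissimilarity of function profiles is lower than that
#' of the microbiome itself. `fan_in` equal to the pool size means complete
#' redundancy (identical profiles); `fan_in = 1` with a pool at least as
#' large as the number of microbes yields a unique relabeling.
#'
#' @inheritParams simulate_metabolome_lc
#' @return A feature table of function relative abundances.
#' @export
simulate_function_profiles <- function(microbiome, config = sim_config()) {
  micro <- if (is.data.frame(microbiome)) microbiome else microbiome$table
  fan_in <- config$function_fan_in
  n_fun <- config$n_functions
  if (fan_in < 1) {
    abort_phylosym("`function_fan_in` must be >= 1.",
                   "phylosym_invalid_argument")
  }
  if (fan_in > n_fun) {
    abort_phylosym("`function_fan_in` cannot exceed `n_functions`.",
                   "phylosym_invalid_argument")
  }
  M <- ft_matrix(micro)
  rel <- M / rowSums(M)
  nm <- ncol(rel)
  map <- with_seed(derive_seed(config$seed, .STAGE[["functions"]]), {
    mp <- matrix(0, nm, n_fun)
    if (fan_in == n_fun) {
      mp[] <- 1
    } else if (fan_in == 1 && n_fun >= nm) {
      mp[cbind(seq_len(nm), sample(n_fun, nm))] <- 1
    } else {
      for (i in seq_len(nm)) mp[i, sample(n_fun, fan_in)] <- 1
    }
    mp
  })
  fun <- rel %*% map
  colnames(fun) <- sprintf("fn%04d", seq_len(n_fun))
  rownames(fun) <- rownames(rel)
  ft_tibble(fun, transform = "raw")
}

#' Simulate a targeted short-chain fatty acid panel
#'
#' Draws per-sample molar concentrations of acetate, propionate and butyrate
#' around the planted per-diet-group molar ratios of the config, with
#' log-normal sample-level scatter.
#'
#' @inheritParams simulate_microbiome
#' @return A feature table with columns `acetate`, `propionate`, `butyrate`.
#' @export
simulate_scfa <- function(design, config = sim_config()) {
  ratios <- config$scfa_ratios
  out <- with_seed(derive_seed(config$seed, .STAGE[["scfa"]]), {
    t(vapply(design$diet, function(d) {
      r <- ratios[[d]] %||% c(60, 25, 15)
      total <- exp(stats::rnorm(1, log(100), 0.4))
      r / sum(r) * total * exp(stats::rnorm(3, 0, 0.1))
    }, numeric(3)))
  })
  colnames(out) <- c("acetate", "propionate", "butyrate")
  rownames(out) <- design$sample_id
  ft_tibble(out, transform = "raw")
}
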