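# Synthetic study generator: trees, preset design, coupled omic layers.

test_that("simulated host trees are ultrametric, rescaled, deterministic", {
  t2 <- simulate_host_tree(2, depth = 100, seed = 5)
  expect_equal(unname(ape::cophenetic.phylo(t2)[1, 2]), 200)

  t8 <- simulate_host_tree(8, depth = 50, seed = 7)
  depths <- ape::node.depth.edgelength(t8)[seq_len(8)]
  expect_lt(max(depths) - min(depths), 1e-9)
  expect_equal(max(depths), 50)

  a <- ape::write.tree(simulate_host_tree(25, 100, seed = 1))
  b <- ape::write.tree(simulate_host_tree(25, 100, seed = 1))
  expect_identical(a, b)
  expect_false(identical(
    a, ape::write.tree(simulate_host_tree(25, 100, seed = 2))
  ))

  expect_error(simulate_host_tree(1, 100), class = "phylosym_invalid_argument")
})

test_that("the preset design reproduces the published roster", {
  pre <- table1_preset()
  expect_equal(nrow(pre$design), 101L)
  expect_equal(length(unique(pre$design$species)), 25L)
  counts <- table(pre$design$species)
  expect_equal(unname(counts[["zebra"]]), 16L)
  expect_equal(unname(counts[["rhinoceros"]]), 13L)
  expect_equal(unname(counts[["chimpanzee"]]), 10L)
  expect_equal(unname(counts[["donkey"]]), 1L)
  # every species maps to exactly one order/diet/morphology
  per_sp <- dplyr::distinct(pre$design[c("species", "order", "diet",
                                         "gut_morphology")])
  expect_equal(nrow(per_sp), 25L)
  expect_setequal(unique(pre$design$order),
                  c("Primates", "Artiodactyla", "Carnivora",
                    "Perissodactyla", "Proboscidea"))
  # the stand-in phylogeny covers the design and is ultrametric
  expect_setequal(pre$tree$tip.label, unique(pre$design$species))
  expect_true(ape::is.ultrametric(pre$tree, tol = 1e-9))
  expect_true(all(pre$design$collection_time >= 0 &
                    pre$design$collection_time <= 14))
  # deterministic: two calls identical
  expect_identical(pre$design, table1_preset()$design)
})

test_that("microbiome counts honor depth, sparsity, and determinism", {
  st <- small_study(seed = 3)
  m <- as.matrix(st$micro$table[, -1])
  expect_true(all(rowSums(m) == st$cfg$seq_depth))
  # detection fraction: about detect_fraction of features nonzero per sample
  frac <- rowMeans(m > 0)
  expect_true(all(frac <= st$cfg$microbe_detect_fraction + 0.05))
  # determinism
  again <- simulate_microbiome(st$tree, st$design, st$cfg)
  expect_identical(st$micro$table, again$table)
  # unknown species is a mapping error
  bad <- st$design
  bad$species[1] <- "unknown_taxon"
  expect_error(simulate_microbiome(st$tree, bad, st$cfg),
               class = "phylosym_mapping_error")
})

test_that("with no signal, species share expected composition", {
  cfg <- sim_config(seed = 2, sigma2_phy = 0, sigma2_ind = 0,
                    n_microbe_features = 50, seq_depth = 5000,
                    microbe_detect_fraction = 1)
  tree <- simulate_host_tree(6, 100, seed = 2)
  design <- simulate_design(tree, 2, seed = 2)
  micro <- simulate_microbiome(tree, design, cfg)
  rel <- as.matrix(micro$table[, -1])
  rel <- rel / rowSums(rel)
  # all rows drawn from one shared multinomial law: per-feature spread is
  # binomial sampling noise only
  expect_lt(max(apply(rel, 2, sd)), 0.01)
})

test_that("strong phylogenetic signal yields phylosymbiotic distances", {
  cfg <- sim_config(seed = 11, sigma2_phy = 10 / 100, sigma2_ind = 0.01,
                    n_microbe_features = 150, seq_depth = 3000)
  tree <- simulate_host_tree(15, 100, seed = 11)
  design <- simulate_design(tree, 3, seed = 11)
  micro <- simulate_microbiome(tree, design, cfg)
  med <- median_representative(micro$table, design, "species")
  D <- bray_curtis_matrix(med)
  P <- patristic_matrix(tree)
  r <- oracle_mantel_r(D, P)
  expect_gt(r, 0.5)
  mt <- mantel_test(D, P, n_perm = 199, seed = 1)
  expect_equal(mt$r, r, tolerance = 1e-12)
})

test_that("LC metabolome has internal standard, sparsity target, blanks", {
  pre <- table1_preset()
  cfg <- sim_config(seed = 9, n_microbe_features = 150, seq_depth = 3000,
                    lc_features = 2000)
  micro <- simulate_microbiome(pre$tree, pre$design, cfg)
  lc <- simulate_metabolome_lc(micro, pre$tree, pre$design, cfg)
  m <- as.matrix(lc$table[, -1])
  expect_true(all(lc$table$IS_ampicillin > 0))
  detected <- rowSums(m[, colnames(m) != "IS_ampicillin"] > 0)
  target <- cfg$lc_features * cfg$lc_detect_fraction
  expect_lt(abs(median(detected) / target - 1), 0.2)
  # roles partition the features
  expect_setequal(unique(lc$truth$role),
                  c("microbiome", "phylogeny", "diet", "background", "noise",
                    "internal_standard"))
  expect_equal(nrow(lc$truth), ncol(m))
  # blanks carry the background features
  bg_ids <- lc$truth$feature_id[lc$truth$role == "background"]
  blank <- as.matrix(lc$background_table[, -1])
  expect_true(all(blank[, bg_ids] > 0))
  expect_true(all(blank[, setdiff(colnames(blank), bg_ids)] == 0))
})

test_that("GC metabolome is core-dominated with balance scores", {
  pre <- table1_preset()
  cfg <- sim_config(seed = 4, n_microbe_features = 100, seq_depth = 2000)
  micro <- simulate_microbiome(pre$tree, pre$design, cfg)
  gc <- simulate_metabolome_gc(micro, pre$design, cfg)
  m <- as.matrix(gc$table[, -1])
  detected <- rowSums(m[, colnames(m) != "IS_ribitol"] > 0)
  expect_lt(abs(median(detected) / 131 - 1), 0.25)
  # core features present in most samples, noise features sporadic
  core <- gc$truth$feature_id[gc$truth$role == "core"]
  noise <- gc$truth$feature_id[gc$truth$role == "noise"]
  expect_gt(mean(m[, core] > 0), 0.85)
  expect_lt(mean(m[, noise] > 0), 0.15)
  scores <- gc$feature_meta
  expect_true(all(scores$balance_score[scores$role != "noise"] >= 0.5))
  # full-core config: every feature everywhere
  cfg2 <- sim_config(seed = 4, n_microbe_features = 100, seq_depth = 2000,
                     gc_features = 30, gc_core_features = 30,
                     gc_enriched_features = 0, gc_core_presence = 1)
  gc2 <- simulate_metabolome_gc(micro, pre$design, cfg2)
  expect_true(all(as.matrix(gc2$table[, -1]) > 0))
  # same config, different seed: different tables, same envelope
  gc3 <- simulate_metabolome_gc(
    micro, pre$design,
    sim_config(seed = 5, n_microbe_features = 100, seq_depth = 2000)
  )
  expect_false(identical(gc$table, gc3$table))
  expect_equal(dim(gc$table), dim(gc3$table))
})

test_that("function profiles collapse taxonomic turnover", {
  st <- small_study(seed = 6)
  # complete redundancy: all microbes feed all functions -> identical profiles
  cfg_full <- st$cfg
  cfg_full$function_fan_in <- cfg_full$n_functions
  fun_full <- simulate_function_profiles(st$micro, cfg_full)
  Df <- suppressWarnings(bray_curtis_matrix(fun_full))
  expect_lt(max(Df), 1e-12)
  # identity map: function distances equal microbiome distances on proportions
  cfg_id <- st$cfg
  cfg_id$function_fan_in <- 1L
  cfg_id$n_functions <- cfg_id$n_microbe_features
  fun_id <- simulate_function_profiles(st$micro, cfg_id)
  rel <- as.matrix(st$micro$table[, -1])
  rel <- rel / rowSums(rel)
  Dm <- bray_curtis_matrix(make_table(rel, ids = st$micro$table$sample_id))
  Di <- bray_curtis_matrix(fun_id)
  expect_equal(unname(Di), unname(Dm), tolerance = 1e-12)
  # intermediate fan-in: functions more similar than microbiome
  fun_mid <- simulate_function_profiles(st$micro, st$cfg)
  Dmid <- bray_curtis_matrix(fun_mid)
  expect_lt(median(Dmid[lower.tri(Dmid)]), median(Dm[lower.tri(Dm)]))
  expect_error(
    simulate_function_profiles(st$micro,
                               sim_config(function_fan_in = 0)),
    class = "phylosym_invalid_argument"
  )
})

test_that("mantel signal is monotone in the phylo-to-noise variance ratio", {
  ratios <- c(0.001, 0.01, 0.1, 1, 10)
  med_r <- vapply(seq_along(ratios), function(i) {
    rs <- vapply(1:5, function(rep) {
      cfg <- sim_config(seed = 100 * i + rep, sigma2_phy = ratios[i] * 0.01,
                        sigma2_ind = 0.01, n_microbe_features = 80,
                        seq_depth = 1500)
      tree <- simulate_host_tree(10, 100, seed = 100 * i + rep)
      design <- simulate_design(tree, 2, seed = rep)
      micro <- simulate_microbiome(tree, design, cfg)
      med <- median_representative(micro$table, design, "species")
      oracle_mantel_r(bray_curtis_matrix(med), patristic_matrix(tree))
    }, numeric(1))
    median(rs)
  }, numeric(1))
  # non-decreasing in the ratio, up to replicate noise on the flat left end
  expect_true(all(diff(med_r) > -0.1))
  expect_gt(med_r[5], med_r[1])
})
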