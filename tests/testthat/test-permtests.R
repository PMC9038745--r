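# Sequential PERMANOVA, dispersion test, Mantel, ANOVA+Tukey, subset
# resampling.

test_that("sequential PERMANOVA reproduces the design's degrees of freedom", {
  pre <- table1_preset()
  D <- random_euclidean_D(101, 4, seed = 2)
  dimnames(D) <- list(pre$design$sample_id, pre$design$sample_id)
  pt <- permanova_sequential(
    D, pre$design,
    c("diet", "gut_morphology", "order", "species", "collection_time"),
    n_perm = 19, seed = 1
  )
  expect_equal(pt$df, c(2, 2, 2, 18, 1, 75, 100))
  expect_equal(sum(pt$r_squared[1:6]), 1, tolerance = 1e-12)
})

test_that("pseudo-F on Euclidean distances equals the classical one-way F", {
  set.seed(3)
  y <- rnorm(30)
  g <- rep(letters[1:3], 10)
  D <- as.matrix(dist(y))
  dimnames(D) <- list(paste0("s", 1:30), paste0("s", 1:30))
  des <- tibble::tibble(sample_id = paste0("s", 1:30), g = g)
  pt <- permanova_sequential(D, des, "g", n_perm = 0)
  cls <- summary(stats::aov(y ~ g))[[1]]
  expect_equal(pt$pseudo_f[1], cls$`F value`[1], tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_equal(pt$sum_sq[3], sum((y - mean(y))^2), tolerance = 1e-9)
})

test_that("PERMANOVA agrees with vegan's sequential adonis on random data", {
  set.seed(14)
  tab <- make_table(matrix(rpois(25 * 40, 6), nrow = 25))
  D <- bray_curtis_matrix(tab)
  des <- tibble::tibble(
    sample_id = rownames(D),
    a = sample(letters[1:3], 25, TRUE),
    b = sample(letters[1:2], 25, TRUE),
    z = rnorm(25)
  )
  pt <- permanova_sequential(D, des, c("a", "b", "z"), n_perm = 0)
  ad <- vegan::adonis2(stats::as.dist(D) ~ a + b + z,
                       data = as.data.frame(des), permutations = 2,
                       by = "terms")
  expect_equal(pt$sum_sq[1:3], unname(ad$SumOfSqs[1:3]), tolerance = 1e-9)
  expect_equal(pt$pseudo_f[1:3], unname(ad$F[1:3]), tolerance = 1e-9)
  expect_equal(pt$df[1:3], unname(ad$Df[1:3]))
})

test_that("sequential SS is order-dependent but sums invariantly", {
  set.seed(15)
  tab <- make_table(matrix(rpois(20 * 30, 5), nrow = 20))
  D <- bray_curtis_matrix(tab)
  des <- tibble::tibble(sample_id = rownames(D),
                        a = sample(letters[1:3], 20, TRUE),
                        b = sample(letters[1:4], 20, TRUE))
  p_ab <- permanova_sequential(D, des, c("a", "b"), n_perm = 0)
  p_ba <- permanova_sequential(D, des, c("b", "a"), n_perm = 0)
  expect_false(isTRUE(all.equal(p_ab$sum_sq[p_ab$term == "a"],
                                p_ba$sum_sq[p_ba$term == "a"])))
  expect_equal(sum(p_ab$sum_sq[1:2]), sum(p_ba$sum_sq[1:2]),
               tolerance = 1e-9)
  # aliased duplicate term adds rank 0 and an undefined F
  des$a2 <- des$a
  p_alias <- permanova_sequential(D, des, c("a", "a2"), n_perm = 0)
  expect_equal(p_alias$df[p_alias$term == "a2"], 0)
  expect_true(is.na(p_alias$pseudo_f[p_alias$term == "a2"]))
})

test_that("PERMANOVA permutation p-values are deterministic per seed", {
  set.seed(16)
  tab <- make_table(matrix(rpois(18 * 25, 5), nrow = 18))
  D <- bray_curtis_matrix(tab)
  des <- tibble::tibble(sample_id = rownames(D),
                        a = sample(letters[1:3], 18, TRUE))
  p1 <- permanova_sequential(D, des, "a", n_perm = 99, seed = 7)
  p2 <- permanova_sequential(D, des, "a", n_perm = 99, seed = 7)
  expect_identical(p1$p_value, p2$p_value)
  expect_gte(p1$p_value[1], 1 / 100)
})

test_that("dispersion test matches betadisper geometry and handles degenerates", {
  D <- random_euclidean_D(20, 3, seed = 5)
  grp <- rep(c("a", "b"), each = 10)
  des <- tibble::tibble(sample_id = rownames(D), g = grp)
  pd <- permdisp(D, des, "g", n_perm = 99, seed = 1)
  bd <- vegan::betadisper(stats::as.dist(D), grp, type = "centroid")
  expect_equal(pd$dispersions$distance, unname(bd$distances),
               tolerance = 1e-9)
  expect_equal(pd$f, unname(stats::anova(bd)$`F value`[1]), tolerance = 1e-9)
  # non-Euclidean matrix exercises the negative-axis correction
  set.seed(6)
  tab <- make_table(matrix(rpois(16 * 30, 4), nrow = 16))
  Db <- bray_curtis_matrix(tab)
  desb <- tibble::tibble(sample_id = rownames(Db),
                         g = rep(c("a", "b"), each = 8))
  pdb <- permdisp(Db, desb, "g", n_perm = 99, seed = 2)
  bdb <- vegan::betadisper(stats::as.dist(Db), desb$g, type = "centroid")
  expect_equal(pdb$dispersions$distance, unname(bdb$distances),
               tolerance = 1e-8)
  # duplicated points: zero dispersion within each group
  m <- rbind(c(1, 0), c(1, 0), c(0, 1), c(0, 1))
  Dd <- bray_curtis_matrix(make_table(m))
  desd <- tibble::tibble(sample_id = sprintf("s%02d", 1:4),
                         g = c("a", "a", "b", "b"))
  pdd <- permdisp(Dd, desd, "g", n_perm = 19, seed = 1)
  expect_equal(pdd$group_means$mean_dispersion, c(0, 0))
  # size-1 groups are excluded with a warning
  des1 <- tibble::tibble(sample_id = rownames(D),
                         g = c(rep(c("a", "b"), each = 9), "lone", "lone2"))
  expect_warning(permdisp(D, des1, "g", n_perm = 19, seed = 1), "lone")
})

test_that("Mantel statistics, bounds, and invariances hold", {
  D <- random_euclidean_D(15, 3, seed = 8)
  # self-comparison: r = 1 and the p floor is attained
  mt <- mantel_test(D, D, n_perm = 199, seed = 1)
  expect_equal(mt$r, 1)
  expect_equal(mt$p_value, 1 / 200)
  # r matches the lower-triangle oracle and vegan
  D2 <- random_euclidean_D(15, 3, seed = 9)
  m2 <- mantel_test(D, D2, n_perm = 99, seed = 1)
  expect_equal(m2$r, oracle_mantel_r(D, D2), tolerance = 1e-12)
  vg <- vegan::mantel(stats::as.dist(D), stats::as.dist(D2), permutations = 99)
  expect_equal(m2$r, unname(vg$statistic), tolerance = 1e-12)
  # consistent reordering of both matrices leaves r unchanged
  p <- sample(15)
  m3 <- mantel_test(D[p, p], D2[p, p], n_perm = 99, seed = 1)
  expect_equal(m3$r, m2$r, tolerance = 1e-12)
  # spearman variant equals the rank-based oracle
  ms <- mantel_test(D, D2, method = "spearman", n_perm = 99, seed = 1)
  expect_equal(ms$r, oracle_mantel_r(D, D2, "spearman"), tolerance = 1e-12)
  # constant matrix is degenerate
  Dc <- matrix(1, 15, 15, dimnames = dimnames(D))
  diag(Dc) <- 0
  Dc[] <- 0
  expect_error(mantel_test(D, Dc, n_perm = 9),
               class = "phylosym_degenerate_input")
  # disjoint sample sets are an alignment error
  Dx <- D2
  rownames(Dx) <- colnames(Dx) <- paste0("t", 1:15)
  expect_error(mantel_test(D, Dx, n_perm = 9),
               class = "phylosym_alignment_error")
})

test_that("one-way ANOVA + Tukey matches the t-test identity and flags ties", {
  set.seed(20)
  x <- c(rnorm(12), rnorm(12, 1))
  g <- rep(c("a", "b"), each = 12)
  at <- anova_tukey(x, g)
  tt <- stats::t.test(x ~ g, var.equal = TRUE)
  expect_equal(at$f, unname(tt$statistic)^2, tolerance = 1e-9)
  expect_equal(nrow(at$pairwise), 1)
  # identical groups: F near zero, Tukey p near one
  xid <- rep(c(1, 2, 3), 4)
  gid <- rep(c("a", "b"), each = 6)
  at2 <- anova_tukey(xid, gid)
  expect_lt(at2$f, 1e-20)
  expect_gt(at2$pairwise$p_adjusted[1], 0.999)
  # a strongly shifted third group is the only significant pair
  set.seed(21)
  x3 <- c(rnorm(50), rnorm(50), rnorm(50, 3))
  g3 <- rep(c("a", "b", "c"), each = 50)
  at3 <- anova_tukey(x3, g3)
  sig <- at3$pairwise$p_adjusted < 0.05
  expect_setequal(at3$pairwise$pair[sig], c("c-a", "c-b"))
  # zero within-group variance everywhere
  at4 <- anova_tukey(c(1, 1, 2, 2), c("a", "a", "b", "b"))
  expect_true(is.infinite(at4$f) && at4$degenerate)
})

test_that("subset resampling caps per-species counts and is reproducible", {
  pre <- table1_preset()
  cfg <- sim_config(seed = 30, n_microbe_features = 80, seq_depth = 1000)
  micro <- simulate_microbiome(pre$tree, pre$design, cfg)
  D <- bray_curtis_matrix(micro$table)
  res <- subset_robustness(list(micro = D), pre$design, n_max = 2,
                           n_reps = 2, analyses = "permanova",
                           terms = c("diet", "species"), n_perm = 19,
                           seed = 4)
  expect_equal(unique(res$n_samples[res$n_cap == 1]), 25)
  # n_cap 2: singleton species contribute their one sample
  n2 <- sum(pmin(2, table(pre$design$species)))
  expect_equal(unique(res$n_samples[res$n_cap == 2]), n2)
  res_again <- subset_robustness(list(micro = D), pre$design, n_max = 2,
                                 n_reps = 2, analyses = "permanova",
                                 terms = c("diet", "species"), n_perm = 19,
                                 seed = 4)
  expect_identical(res, res_again)
  # mantel across two matrices shares the subset
  tab2 <- micro$table
  res_m <- subset_robustness(list(a = D, b = bray_curtis_matrix(tab2)),
                             pre$design, n_max = 1, n_reps = 1,
                             analyses = "mantel", n_perm = 19, seed = 4)
  expect_equal(res_m$analysis, "mantel")
  expect_equal(res_m$value, 1)  # identical tables, identical matrices
})
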