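# Normalization, filtering, medians, rarefaction, SCFA ratios.

test_that("internal-standard normalization, noise floor, and log transform", {
  tab <- make_table(matrix(c(4, 8,     # feature a
                             0.015, 0.01, # feature b (below floor in s2 only
                                          # after normalization)
                             0, 0,     # all-zero feature
                             2, 1),    # internal standard
                           nrow = 2),
                    feats = c("a", "b", "zero", "IS"))
  out <- normalize_and_log(tab, "IS", noise_floor = 0.01)
  expect_equal(attr(out, "transform"), "log")
  expect_false("IS" %in% names(out))
  # sample 1: 4 / 2 = 2 -> log(3)
  expect_equal(out$a[1], log(3))
  expect_equal(out$a[2], log(1 + 8))
  # 0.015/2 = 0.0075 < floor -> 0; 0.01/1 = 0.01 >= floor survives
  expect_equal(out$b, c(0, log(1.01)))
  expect_equal(out$zero, c(0, 0))
  # double transform is refused
  expect_error(normalize_and_log(out, "a"),
               class = "phylosym_invalid_argument")
  # zero internal standard names the offending sample
  bad <- tab
  bad$IS[2] <- 0
  expect_error(normalize_and_log(bad, "IS"),
               regexp = "s02", class = "phylosym_normalization_error")
})

test_that("balance-score and background filters follow the stated rules", {
  tab <- make_table(matrix(c(5, 5, 10, 10, 3, 3, 7, 7), nrow = 2),
                    feats = c("lowscore", "clean", "bg", "absent_bg"))
  meta <- tibble::tibble(feature_id = c("lowscore", "clean", "bg",
                                        "absent_bg"),
                         balance_score = c(0.49, 0.95, 0.80, 0.90))
  bg <- make_table(matrix(c(0, 0, 0, 0, 10, 8, 0, 0), nrow = 2),
                   ids = c("blank1", "blank2"),
                   feats = c("lowscore", "clean", "bg", "absent_bg"))
  res <- feature_filters(tab, feature_meta = meta, balance_threshold = 0.5,
                         background_table = bg, background_rule_ratio = 0.5)
  # 0.49 < 0.50 discarded; bg mean 9 >= 0.5 * study mean 3 discarded;
  # features absent from all backgrounds retained regardless of ratio
  expect_setequal(setdiff(names(res$table), "sample_id"),
                  c("clean", "absent_bg"))
  expect_setequal(res$report$rule, c("balance_score", "background"))
  # keep-dietary switch flags but retains background-rule features
  res2 <- feature_filters(tab, feature_meta = meta, balance_threshold = 0.5,
                          background_table = bg, background_rule_ratio = 0.5,
                          keep_dietary = TRUE)
  expect_true("bg" %in% names(res2$table))
  expect_true("bg" %in% res2$report$feature_id)
  expect_false(res2$report$removed[res2$report$feature_id == "bg"])
  # a feature never triggering a rule is never removed
  expect_false("clean" %in% res$report$feature_id)
  expect_error(feature_filters(tab, balance_threshold = 1.5),
               class = "phylosym_invalid_argument")
})

test_that("median representatives use midpoint medians and commute with subsetting", {
  tab <- make_table(matrix(c(1, 3, 100,   # species x, feature f1
                             2, 4, 6), ncol = 2),
                    ids = c("x_1", "x_2", "x_3"), feats = c("f1", "f2"))
  des <- tibble::tibble(sample_id = c("x_1", "x_2", "x_3"),
                        species = c("x", "x", "x"))
  med <- median_representative(tab, des, "species")
  expect_equal(med$f1, 3)
  expect_equal(med$f2, 4)
  # even count -> midpoint
  tab2 <- make_table(matrix(c(2, 4), ncol = 1), ids = c("y_1", "y_2"),
                     feats = "f1")
  des2 <- tibble::tibble(sample_id = c("y_1", "y_2"), species = "y")
  expect_equal(median_representative(tab2, des2, "species")$f1, 3)
  # single-sample species passes through unchanged
  st <- small_study(seed = 8, per_species = 1)
  med1 <- median_representative(st$micro$table, st$design, "species")
  m <- as.matrix(st$micro$table[, -1])
  rownames(m) <- st$design$species[match(st$micro$table$sample_id,
                                         st$design$sample_id)]
  m1 <- as.matrix(med1[, -1])
  rownames(m1) <- med1$sample_id
  expect_equal(m1[med1$sample_id[1], ], m[med1$sample_id[1], ])
  # commutes with feature subsetting
  st2 <- small_study(seed = 9)
  feats <- names(st2$micro$table)[2:20]
  a <- median_representative(st2$micro$table[c("sample_id", feats)],
                             st2$design, "species")
  b <- median_representative(st2$micro$table, st2$design,
                             "species")[c("sample_id", feats)]
  expect_equal(as.data.frame(a), as.data.frame(b))
})

test_that("rarefaction expectations are exact, monotone, and concave", {
  # two features of 5 reads each: E[S_1] = 2 * (1 - C(5,1)/C(10,1)) = 1
  tab <- make_table(matrix(c(5, 5), nrow = 1), feats = c("f1", "f2"))
  expect_equal(rarefaction_curve(tab, 1)$expected_richness, 1)
  # full depth recovers observed richness exactly
  tab2 <- make_table(matrix(c(3, 7, 0, 1), nrow = 1),
                     feats = paste0("f", 1:4))
  expect_equal(rarefaction_curve(tab2, 11)$expected_richness, 3)
  # singleton features: every draw is a new feature
  tab3 <- make_table(matrix(rep(1, 6), nrow = 1), feats = paste0("f", 1:6))
  expect_equal(rarefaction_curve(tab3, c(1, 3, 6))$expected_richness,
               c(1, 3, 6))
  # non-decreasing and concave along a depth grid
  st <- small_study(seed = 2, n_species = 4, per_species = 1)
  rc <- rarefaction_curve(st$micro$table, seq(100, 2000, by = 100))
  for (s in unique(rc$sample_id)) {
    es <- rc$expected_richness[rc$sample_id == s]
    expect_true(all(diff(es) > -1e-9))
    expect_true(all(diff(diff(es)) < 1e-9))
  }
  # matches vegan's independent implementation
  m <- as.matrix(st$micro$table[, -1])
  expect_equal(
    rc$expected_richness[rc$sample_id == st$micro$table$sample_id[1]],
    suppressWarnings(
      unname(vegan::rarefy(m[1, , drop = FALSE], seq(100, 2000, by = 100))[1, ])
    ),
    tolerance = 1e-9
  )
  expect_error(rarefaction_curve(st$micro$table, 10^6),
               class = "phylosym_invalid_argument")
})

test_that("SCFA molar ratios rescale, flag degenerates, and recover planted groups", {
  tab <- make_table(matrix(c(75, 150, 0,
                             15, 30, 0,
                             10, 20, 0), nrow = 3),
                    feats = c("acetate", "propionate", "butyrate"))
  res <- scfa_molar_ratio(tab)
  expect_equal(res$per_sample$acetate_pct[1:2], c(75, 75))
  expect_equal(res$per_sample$propionate_pct[1:2], c(15, 15))
  expect_equal(res$per_sample$butyrate_pct[1:2], c(10, 10))
  expect_true(res$per_sample$flagged[3])
  # planted omnivore 73:7:21 profile recovered from the generator
  pre <- table1_preset()
  scfa <- simulate_scfa(pre$design, sim_config(seed = 21))
  grp <- scfa_molar_ratio(scfa, pre$design, "diet")$per_group
  omn <- grp[grp$group == "omnivore", ]
  expect_equal(
    c(omn$acetate_pct, omn$propionate_pct, omn$butyrate_pct),
    c(73, 7, 21) / sum(c(73, 7, 21)) * 100,
    tolerance = 0.05
  )
})
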