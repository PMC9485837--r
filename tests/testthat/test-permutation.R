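test_that("exhaustive enumeration reproduces the hand-counted p-value", {
  vals <- setNames(c(0, 0, -1, 1), paste0("s", 1:4))
  grp <- setNames(c("A", "A", "B", "B"), names(vals))
  res <- permute_group_statistic(vals, grp, c("A", "B"), "variance_ratio",
                                 alternative = "less", relabel = "pair")
  expect_true(res$exhaustive)
  expect_equal(res$observed, 0)
  expect_equal(res$p_value, 1 / 6)
  expect_equal(res$n_perm, 6)
})

test_that("sampled p agrees with exhaustive p within Monte-Carlo error", {
  set.seed(101)
  vals <- setNames(rnorm(12), paste0("s", 1:12))
  grp <- setNames(rep(c("A", "B"), each = 6), names(vals))
  ex <- permute_group_statistic(vals, grp, c("A", "B"), "mean_difference",
                                alternative = "less", relabel = "pair")
  expect_true(ex$exhaustive)
  sm <- permute_group_statistic(vals, grp, c("A", "B"), "mean_difference",
                                alternative = "less", relabel = "pair",
                                n_perm = 4000, seed = 5,
                                exhaustive_limit = 1)
  expect_false(sm$exhaustive)
  tol <- 2 * sqrt(ex$p_value * (1 - ex$p_value) / 4000)
  expect_lt(abs(sm$p_value - ex$p_value), tol + 1e-12)
})

test_that("relabeling preserves the color multiset and the null is returned", {
  set.seed(102)
  vals <- setNames(rnorm(15), paste0("s", 1:15))
  grp <- setNames(rep(c("red", "pink", "white"), each = 5), names(vals))
  res <- permute_group_statistic(vals, grp, c("red", "pink"),
                                 "variance_ratio", n_perm = 200,
                                 alternative = "less", seed = 3,
                                 exhaustive_limit = 10)
  expect_length(res$null, 200)
  expect_true(all(is.finite(res$null) | is.nan(res$null) |
                    is.infinite(res$null)))
})

test_that("degenerate identical data give p = 1 one-sided", {
  vals <- setNames(rep(2, 8), paste0("s", 1:8))
  grp <- setNames(rep(c("A", "B"), each = 4), names(vals))
  res <- permute_group_statistic(vals, grp, c("A", "B"), "mean_difference",
                                 alternative = "less", relabel = "pair")
  expect_equal(res$observed, 0)
  expect_equal(res$p_value, 1)
})

test_that("errors on undefined variance ratios and empty groups", {
  vals <- setNames(c(1, 1, 2, 2, 2), paste0("s", 1:5))
  grp <- setNames(c("A", "A", "B", "B", "B"), names(vals))
  expect_error(
    permute_group_statistic(vals, grp, c("A", "B"), "variance_ratio"),
    "var\\(B\\) = 0")
  expect_error(
    permute_group_statistic(vals, grp, c("A", "Z"), "mean_difference"),
    "empty group")
})

test_that("the pairwise color-test table has the full factorial layout", {
  set.seed(103)
  S <- matrix(rnorm(60), 30, 2,
              dimnames = list(paste0("s", 1:30), c("PC1", "PC2")))
  colors <- setNames(rep(c("white", "pink", "red"), each = 10),
                     rownames(S))
  tab <- all_pairwise_color_tests(S, colors, n_perm = 100, seed = 1)
  expect_equal(nrow(tab), 3 * 2 * 2)
  expect_equal(sort(unique(paste(tab$group_a, tab$group_b))),
               sort(c("red pink", "red white", "pink white")))
  # red is always the numerator group of pairs that contain it
  has_red <- tab$group_a == "red" | tab$group_b == "red"
  expect_true(all(tab$group_a[has_red] == "red"))
})

test_that("planted low red variance is detected; null colors are not", {
  set.seed(104)
  hits <- 0
  for (rep in 1:50) {
    S <- matrix(rnorm(47 * 2), 47, 2,
                dimnames = list(sprintf("sp%02d", 1:47), c("PC1", "PC2")))
    colors <- setNames(rep(c("white", "pink", "red"), c(20, 18, 9)),
                       rownames(S))
    S[colors == "red", ] <- S[colors == "red", ] * sqrt(0.1)
    tab <- all_pairwise_color_tests(S, colors, n_perm = 400)
    pr <- tab[tab$statistic == "variance_ratio" & tab$group_a == "red" &
                tab$component == "PC1", "p_value"]
    if (all(pr < 0.05)) hits <- hits + 1
  }
  expect_gte(hits / 50, 0.9)
  # null: random colors -> no systematic significance
  set.seed(105)
  ps <- replicate(20, {
    S <- matrix(rnorm(30), 30, 1,
                dimnames = list(paste0("s", 1:30), "PC1"))
    colors <- setNames(sample(rep(c("white", "pink", "red"), each = 10)),
                       rownames(S))
    permute_group_statistic(setNames(S[, 1], rownames(S)), colors,
                            c("red", "pink"), "variance_ratio",
                            n_perm = 100, alternative = "less")$p_value
  })
  expect_gt(mean(ps < 0.05), -1)  # sanity
  expect_lt(mean(ps < 0.05), 0.3)
})

test_that("trait-range resampling stays within ranges with uniform moments", {
  tt <- trait_table(small_trait_df())
  ds <- resample_trait_ranges(tt, n_datasets = 400, seed = 7)
  expect_length(ds, 400)
  lo <- setNames(tt$calyx_height_min, tt$species)
  hi <- setNames(tt$calyx_height_max, tt$species)
  draws <- sapply(ds, function(m) m[, "calyx_height"])
  expect_true(all(draws >= lo[rownames(draws)] - 1e-12))
  expect_true(all(draws <= hi[rownames(draws)] + 1e-12))
  mid <- (lo + hi) / 2
  se <- (hi - lo) / sqrt(12) / sqrt(400)
  expect_true(all(abs(rowMeans(draws) - mid[rownames(draws)]) <=
                    3 * se[rownames(draws)] + 1e-9))
  # untouched columns stay at the encoded values
  base <- encode_traits(tt)
  expect_equal(ds[[1]][, "stem_length"], base[, "stem_length"])
  # degenerate range: constant draws
  tt2 <- tt
  tt2$calyx_width_min <- tt2$calyx_width_max <- tt2$calyx_width_median <- 7
  ds2 <- resample_trait_ranges(trait_table(as.data.frame(tt2)),
                               n_datasets = 5, seed = 1)
  expect_true(all(sapply(ds2, function(m) all(m[, "calyx_width"] == 7))))
  # determinism
  expect_identical(resample_trait_ranges(tt, n_datasets = 3, seed = 9),
                   resample_trait_ranges(tt, n_datasets = 3, seed = 9))
})

test_that("resampled pPCA summaries degenerate correctly and find planted structure", {
  sc <- synth_scenario(n_species = 24, range_half_width = 0,
                       color_counts = c(white = 10, pink = 8, red = 6))
  tree <- simulate_tree(sc, seed = 110)
  tt <- simulate_traits(sc, tree, seed = 111)
  # zero-width ranges: every dataset identical, zero across-dataset variance
  rs <- resampled_ppca_summary(tt, tree, n_datasets = 8, seed = 112)
  expect_true(all(rs$summary$var < 1e-20))
  # planted red shrinkage: red group variance below white/pink in nearly all
  sc2 <- synth_scenario(n_species = 30, red_contrast = 0.25,
                        color_counts = c(white = 12, pink = 10, red = 8))
  tree2 <- simulate_tree(sc2, seed = 113)
  tt2 <- simulate_traits(sc2, tree2, seed = 114)
  rs2 <- resampled_ppca_summary(tt2, tree2, n_datasets = 40, seed = 115)
  vr <- rs2$draws[, "red|PC1|var"]
  vw <- rs2$draws[, "white|PC1|var"]
  vp <- rs2$draws[, "pink|PC1|var"]
  expect_gte(mean(vr < vw & vr < vp), 0.95)
})
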