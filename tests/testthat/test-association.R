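test_that("residuals obey the OLS identities", {
  age <- c(30, 40, 50, 60, 70)
  expect_equal(unname(prediction_residuals(age, age)$residuals), rep(0, 5))
  expect_equal(unname(prediction_residuals(age + 5, age)$residuals),
               rep(0, 5))
  expect_equal(unname(prediction_residuals(2 * age, age)$residuals),
               rep(0, 5))
  set.seed(3)
  pred <- age + rnorm(5, 0, 4)
  rr <- prediction_residuals(pred, age)
  expect_lt(abs(mean(rr$residuals)), 1e-8)
  expect_lt(abs(cor(rr$residuals, age)), 1e-8)
  expect_error(prediction_residuals(c(1, 2, 3), rep(50, 3)), "constant")
  expect_error(prediction_residuals(1:2, 1:2), "3")
})

test_that("index correlations handle exact, missing and tiny columns", {
  set.seed(4)
  v <- runif(30)
  idx <- data.frame(same = v,
                    inv = -v,
                    tiny = c(v[1:2], rep(NA, 28)))
  rep_out <- correlate_with_indices(v, idx)
  expect_equal(rep_out$rho[rep_out$index == "same"], 1)
  expect_equal(rep_out$rho[rep_out$index == "inv"], -1)
  expect_match(rep_out$note[rep_out$index == "tiny"], "skipped")
  expect_true(all(rep_out$q_value >= rep_out$p_value, na.rm = TRUE))
})

test_that("group comparison picks the right test and significance stars", {
  set.seed(5)
  two <- group_compare(c(rnorm(20), rnorm(20, 8)), rep(c("a", "b"), each = 20))
  expect_equal(two$test, "wilcoxon_rank_sum")
  expect_lte(two$p_value, 0.001)
  expect_equal(two$stars, "***")
  three <- group_compare(rnorm(60), rep(c("a", "b", "c"), 20))
  expect_equal(three$test, "kruskal_wallis")
  expect_warning(
    d <- group_compare(c(rnorm(20), 1), c(rep(c("a", "b"), 10), "lone")),
    "lone")
  expect_equal(d$n_groups, 2)
  expect_error(group_compare(rnorm(5), rep("one", 5)), "2 usable")
})

test_that("group-comparison p-values are calibrated under the null", {
  set.seed(6)
  pvals <- replicate(120, {
    group_compare(rnorm(40), rep(c("a", "b"), 20))$p_value
  })
  expect_gt(suppressWarnings(stats::ks.test(pvals, "punif"))$p.value, 0.01)
})

test_that("marker discriminators detect planted labels and nothing else", {
  set.seed(7)
  n <- 160
  x <- matrix(rnorm(n * 8), n, 8)
  labels <- as.integer(x[, 1] + x[, 2] + rnorm(n, 0, 0.3) > 0)
  res <- marker_discriminator(x, labels, folds = 4, seed = 1)
  expect_gte(res$auc, 0.9)
  expect_true(all(c("specificity", "sensitivity") %in% colnames(res$roc)))
  perm <- marker_discriminator(x, sample(labels), folds = 4, seed = 1)
  expect_lt(abs(perm$auc - 0.5), 0.1)
  expect_error(marker_discriminator(x, rep(1L, n)), "classes")
})

test_that("marker overlap is an exact partition", {
  expect_equal(marker_overlap(c("a", "b", "c"), c("b", "c", "d"))[1:3],
               list(only_a = 1L, shared = 2L, only_b = 1L))
  expect_equal(marker_overlap(c("a", "b"), c("x"))[1:3],
               list(only_a = 2L, shared = 0L, only_b = 1L))
  ms <- data.frame(view = "species", feature = c("a", "b"))
  expect_equal(marker_overlap(ms, ms)$shared, 2L)
})

test_that("marker-source comparison uses identical folds and honest tests", {
  set.seed(8)
  n <- 140
  x <- matrix(rnorm(n * 10), n, 10)
  colnames(x) <- paste0("f", 1:10)
  target <- x[, 1] + x[, 2] + rnorm(n, 0, 0.2)
  dup <- compare_marker_sources(x, target, features_a = 1:2,
                                features_b = 1:2, folds = 4, seed = 2)
  expect_equal(dup$p_value, 1)
  expect_match(dup$note, "identical")
  contrast <- compare_marker_sources(x, target, features_a = 1:2,
                                     features_b = 9:10, folds = 4, seed = 2)
  expect_gt(contrast$r2_a, contrast$r2_b)
  same_folds <- compare_marker_sources(x, target, features_a = 1:2,
                                       features_b = 9:10, folds = 4,
                                       seed = 2)
  expect_identical(contrast$fold_hash, same_folds$fold_hash)
  expect_error(compare_marker_sources(x, target, integer(0), 1:2),
               "non-empty")
})

test_that("disease counts sum the binary flags", {
  md <- data.frame(IBD = c(1, 0, 1), T2D = c(0, 0, 1), CRC = c(0, NA, 1))
  expect_equal(disease_count(md, c("IBD", "T2D", "CRC")), c(1L, 0L, 3L))
  expect_error(disease_count(md, "Gout"), "Gout")
})
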