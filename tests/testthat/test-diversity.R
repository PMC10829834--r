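test_that("alpha diversity matches hand-computed Shannon values", {
  x <- rbind(u = c(0.25, 0.25, 0.25, 0.25),
             p = c(1, 0, 0, 0),
             m = c(0.5, 0.3, 0.2, 0))
  a <- alpha_diversity(x)
  expect_equal(a$shannon[1], log(4), tolerance = 1e-12)
  expect_equal(a$richness[1], 4L)
  expect_equal(a$shannon[2], 0)
  expect_equal(a$richness[2], 1L)
  # -sum(p log p) = -(0.5 log 0.5 + 0.3 log 0.3 + 0.2 log 0.2)
  expect_equal(a$shannon[3], 1.0296530140645737, tolerance = 1e-9)
  expect_warning(z <- alpha_diversity(rbind(c(0, 0), c(1, 1))), "all-zero")
  expect_equal(z$richness[1], 0L)
  expect_equal(z$shannon[1], 0)
})

test_that("Shannon is maximal at uniformity and zero at a point mass", {
  set.seed(3)
  for (n in c(3, 7, 20)) {
    x <- matrix(rexp(n * 5), 5, n)
    x <- x / rowSums(x)
    a <- alpha_diversity(x)
    expect_true(all(a$shannon <= log(n) + 1e-12))
  }
})

test_that("Bray-Curtis matches hand values and is a proper distance", {
  d <- bray_curtis(rbind(a = c(1, 0), b = c(0, 1), c = c(0.6, 0.4),
                         d = c(0.4, 0.6)))
  expect_equal(d["a", "b"], 1)
  expect_equal(d["c", "d"], 0.2, tolerance = 1e-12)
  expect_equal(unname(diag(d)), rep(0, 4))
  set.seed(8)
  x <- matrix(rexp(40 * 12), 40, 12)
  dm <- bray_curtis(x / rowSums(x))
  expect_equal(dm, t(dm))
  expect_true(all(dm >= 0 & dm <= 1 + 1e-12))
  expect_warning(dz <- bray_curtis(rbind(c(0, 0), c(0, 0), c(1, 2))),
                 "all-zero")
  expect_equal(dz[1, 2], 0)
})

test_that("adjusted PERMANOVA guards its preconditions", {
  set.seed(5)
  x <- matrix(rexp(30 * 8), 30, 8)
  x <- x / rowSums(x)
  rownames(x) <- paste0("s", 1:30)
  d <- bray_curtis(x)
  md <- data.frame(grp = rep(c("a", "b"), 15),
                   batch = rep(c("x", "y"), each = 15),
                   sparse = c(rep("u", 5), rep(NA, 25)))
  res <- permanova_adjusted(d, md, confounders = "batch", variable = "grp",
                            n_permutations = 99, seed = 1)
  expect_equal(res$term[1:2], c("batch", "grp"))
  expect_true(all(res$R2[1:2] >= 0 & res$R2[1:2] <= 1))
  expect_lte(sum(res$R2[1:2]), 1)
  # covariates observed in under half the samples are dropped before fitting
  res2 <- permanova_adjusted(d, md, confounders = c("batch", "sparse"),
                             variable = "grp", n_permutations = 49, seed = 1)
  expect_true("sparse" %in% attr(res2, "dropped_covariates"))
  md$const <- "only"
  expect_error(permanova_adjusted(d, md, variable = "const",
                                  n_permutations = 49, seed = 1), "constant")
  expect_error(permanova_adjusted(d[1:2, 1:2], md[1:2, ], variable = "grp",
                                  n_permutations = 49, seed = 1), "3")
})

test_that("PERMANOVA detects a planted composition shift", {
  set.seed(11)
  x <- matrix(rexp(40 * 20), 40, 20)
  x[1:20, 1:5] <- x[1:20, 1:5] + 8
  x <- x / rowSums(x)
  rownames(x) <- paste0("s", 1:40)
  md <- data.frame(grp = rep(c("a", "b"), each = 20))
  res <- permanova_adjusted(bray_curtis(x), md, variable = "grp",
                            n_permutations = 999, seed = 1)
  expect_lte(res$p_value[1], 0.005)
})

test_that("feature-age correlations handle exact and degenerate features", {
  set.seed(2)
  age <- runif(40, 20, 90)
  x <- cbind(exact = age, noise = rnorm(40), const = rep(1, 40))
  fc <- feature_age_correlation(x, age)
  expect_equal(fc$rho[fc$feature == "exact"], 1)
  expect_true(is.na(fc$rho[fc$feature == "const"]))
  expect_match(fc$note[fc$feature == "const"], "constant")
  expect_true(all(fc$q_value >= fc$p_value, na.rm = TRUE))
  tr <- age_trend(age + rnorm(40, 0, 5), age)
  expect_gt(tr$rho, 0.8)
})
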