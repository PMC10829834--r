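test_that("ALE of a linear predictor matches the closed form", {
  set.seed(9)
  n <- 300
  X <- matrix(runif(n * 5), n, 5)
  colnames(X) <- paste0("f", 1:5)
  pf <- function(sp, pw) 2 * sp[, 2] + 0.5 * sp[, 4]
  a <- compute_ale(species = X, pathways = NULL, view = "species",
                   feature = 2, predict_fn = pf)
  interior <- 2:(length(a$grid) - 1)
  expected <- 2 * (a$grid - mean(X[, 2]))
  expect_lt(max(abs(a$effects[interior] - expected[interior])), 1e-6)
  expect_equal(a$direction, "accelerated")

  neg <- compute_ale(species = X, pathways = NULL, view = "species",
                     feature = 4, predict_fn = function(sp, pw) -3 * sp[, 4])
  expect_equal(neg$direction, "mitigated")

  null_f <- compute_ale(species = X, pathways = NULL, view = "species",
                        feature = 3, predict_fn = pf)
  expect_true(all(abs(null_f$effects) < 1e-12))
  expect_true(all(abs(null_f$per_sample_effect) < 1e-12))
  expect_equal(null_f$direction, "null")
})

test_that("ALE reconstructs each additive component up to a constant", {
  set.seed(10)
  n <- 500
  X <- matrix(runif(n * 3), n, 3)
  g <- function(x) sin(3 * x)
  h <- function(x) x^2
  pf <- function(sp, pw) g(sp[, 1]) + h(sp[, 2])
  a1 <- compute_ale(species = X, pathways = NULL, view = "species",
                    feature = 1, n_intervals = 60, predict_fn = pf)
  dev <- a1$effects - g(a1$grid)
  expect_lt(diff(range(dev)), 1e-6)
  a2 <- compute_ale(species = X, pathways = NULL, view = "species",
                    feature = 2, n_intervals = 60, predict_fn = pf)
  dev2 <- a2$effects - h(a2$grid)
  expect_lt(diff(range(dev2)), 1e-6)
})

test_that("per-sample effects are centered and reproducible in batch mode", {
  sim <- simulate_profiles(simulation_config(n_paired = 120, n_species = 25,
                                             n_pathways = 12,
                                             n_markers_per_view = 5,
                                             seed = 6))
  m <- suppressWarnings(fit_ensemble(sim$profile, sim$metadata,
                                     zoo = c("lr", "lasso", "tree"),
                                     seed = 2))
  sp <- sim$profile$species
  pw <- sim$profile$pathways
  batch <- ale_all_features(m, sp, pw, view = "species", features = 1:6)
  for (a in batch) {
    expect_lt(abs(mean(a$per_sample_effect)), 1e-8)
    expect_true(all(diff(a$grid) > 0))
    expect_gte(a$prevalence, 0)
    expect_lte(a$prevalence, 1)
  }
  single <- compute_ale(m, species = sp, pathways = pw, view = "species",
                        feature = 3)
  expect_equal(single$effects, batch[[3]]$effects, tolerance = 1e-10)
  expect_equal(single$mean_abs_effect, batch[[3]]$mean_abs_effect,
               tolerance = 1e-10)
})

test_that("a zero-inflated feature keeps its zero mass in the first bin", {
  set.seed(11)
  x <- c(rep(0, 60), runif(40, 0.1, 0.5))
  X <- cbind(x, runif(100))
  colnames(X) <- c("zf", "other")
  a <- compute_ale(species = X, pathways = NULL, view = "species",
                   feature = "zf", predict_fn = function(sp, pw) 5 * sp[, 1])
  expect_equal(a$grid[1], 0)
  expect_gt(a$grid[2], 0)
  expect_equal(a$prevalence, 0.4)
})

test_that("direction classification separates monotone from reversing curves", {
  set.seed(12)
  x <- runif(400)
  X <- cbind(x, runif(400))
  tent <- function(sp, pw) 4 * pmin(sp[, 1], 1 - sp[, 1])
  a <- compute_ale(species = X, pathways = NULL, view = "species",
                   feature = 1, predict_fn = tent)
  expect_equal(a$direction, "nonmonotone")
})

test_that("marker thresholds follow the effect and prevalence rules", {
  mk <- function(effect, prev, view = "species", feature = "f") {
    structure(list(view = view, feature = feature,
                   mean_abs_effect = effect, prevalence = prev,
                   direction = "accelerated"), class = "ale_result")
  }
  res <- rank_and_select(list(mk(0.20, 0.10, feature = "in"),
                              mk(0.05, 0.50, feature = "weak"),
                              mk(0.20, 0.005, feature = "rare")))
  expect_equal(res$markers$feature, "in")
  expect_equal(nrow(res$all_features), 3)
  # ranked by effect, ties by feature name
  res2 <- rank_and_select(list(mk(0.3, 0.5, feature = "b"),
                               mk(0.3, 0.5, feature = "a"),
                               mk(0.9, 0.5, feature = "c")))
  expect_equal(res2$markers$feature, c("c", "a", "b"))
})

test_that("the default effect threshold is one month of predicted age", {
  expect_lt(abs(gage_defaults()$effect_threshold - 1 / 12), 0.0005)
  expect_identical(formals(rank_and_select)$effect_threshold, 0.083)
  expect_identical(formals(rank_and_select)$prevalence_threshold, 0.01)
})
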