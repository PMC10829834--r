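test_that("every registry learner fits and predicts on a toy problem", {
  set.seed(1)
  n <- 80
  x <- matrix(rnorm(n * 6), n, 6)
  y <- 2 * x[, 1] - x[, 2] + rnorm(n, 0, 0.3)
  xt <- matrix(rnorm(30 * 6), 30, 6)
  for (nm in zoo_registry()) {
    fit <- fit_base_learner(nm, x, y, seed = 3)
    p <- predict_base_learner(fit, xt)
    expect_length(p, 30)
    expect_true(all(is.finite(p)), info = nm)
  }
  # stochastic learners are reproducible under a fixed seed
  for (nm in c("rf", "gbt")) {
    p1 <- predict_base_learner(fit_base_learner(nm, x, y, seed = 7), xt)
    p2 <- predict_base_learner(fit_base_learner(nm, x, y, seed = 7), xt)
    expect_identical(p1, p2, info = nm)
  }
  # Bayesian ridge stays close to OLS when the signal is strong
  br <- predict_base_learner(fit_base_learner("bridge", x, y), xt)
  ols <- predict_base_learner(fit_base_learner("lr", x, y), xt)
  expect_lt(mean(abs(br - ols)), 0.2)
})

test_that("the meta layer has one weight per view-learner plus intercept", {
  op <- oracle_profile()
  m <- suppressWarnings(fit_ensemble(op$profile, op$ages,
                                     zoo = c("lr", "tree"), seed = 1))
  expect_length(m$meta$full$coef, 2 * 2 + 1)
  expect_equal(names(m$meta$full$coef)[1], "(Intercept)")
  expect_length(m$meta$per_view$species$coef, 3)
  expect_setequal(names(m$views), c("species", "pathways"))
})

test_that("a deterministic age feature yields a near-perfect held-out clock", {
  op <- oracle_profile(n = 150)
  test_ids <- names(op$ages)[1:30]
  train <- multiview_profile(
    species = op$profile$species[!rownames(op$profile$species) %in% test_ids, ],
    pathways = op$profile$pathways[!rownames(op$profile$pathways) %in% test_ids, ],
    normalize = FALSE)
  m <- suppressWarnings(fit_ensemble(train, op$ages, seed = 2))
  pred <- predict(m, species = op$profile$species[test_ids, ],
                  pathways = op$profile$pathways[test_ids, ])
  y <- op$ages[test_ids]
  expect_gte(1 - sum((y - pred)^2) / sum((y - mean(y))^2), 0.99)
  expect_lte(mean(abs(y - pred)), 1)
})

test_that("permuted ages destroy held-out performance", {
  op <- oracle_profile(n = 140, seed = 9)
  set.seed(5)
  shuffled <- stats::setNames(sample(op$ages), names(op$ages))
  cv <- suppressWarnings(evaluate_cv(op$profile, shuffled, repeats = 1,
                                     folds = 5, seed = 4,
                                     zoo = c("lr", "lasso", "tree")))
  expect_lte(mean(cv$records$r2), 0.05)
})

test_that("prediction enforces views and feature manifests", {
  op <- oracle_profile(n = 120, seed = 3)
  m <- suppressWarnings(fit_ensemble(op$profile, op$ages,
                                     zoo = c("lr", "lasso"), seed = 1))
  sp <- op$profile$species; pw <- op$profile$pathways
  expect_error(predict(m, species = sp), "pathway")
  expect_error(predict(m, species = sp[, -1], pathways = pw), "missing feature")
  # single-view fallback is explicit
  p1 <- predict(m, species = sp, view = "species")
  expect_length(p1, nrow(sp))
  # all-zero meta weights collapse to the intercept
  m0 <- m
  m0$meta$full$coef[] <- 0
  m0$meta$full$coef[["(Intercept)"]] <- 40
  expect_equal(unname(predict(m0, species = sp[1:3, ], pathways = pw[1:3, ])),
               rep(40, 3))
})

test_that("cross-validation bookkeeping and determinism hold", {
  op <- oracle_profile(n = 90, seed = 12)
  cv <- suppressWarnings(evaluate_cv(op$profile, op$ages, repeats = 2,
                                     folds = 3, seed = 6,
                                     zoo = c("lr", "tree")))
  expect_equal(nrow(cv$records), 6)
  expect_true(all(table(cv$records$repeat_id) == 3))
  expect_true(all(cv$records$mae >= 0))
  cv2 <- suppressWarnings(evaluate_cv(op$profile, op$ages, repeats = 2,
                                      folds = 3, seed = 6,
                                      zoo = c("lr", "tree")))
  expect_identical(cv$records, cv2$records)
  expect_error(evaluate_cv(op$profile, op$ages, repeats = 1, folds = 91),
               "folds")
})

test_that("standardization never sees the held-out fold", {
  # the training-view standardization must equal parameters recomputed
  # from the training samples alone
  op <- oracle_profile(n = 100, seed = 8)
  test_ids <- names(op$ages)[1:20]
  keep <- setdiff(names(op$ages), test_ids)
  train <- multiview_profile(species = op$profile$species[keep, ],
                             pathways = op$profile$pathways[keep, ],
                             normalize = FALSE)
  m <- suppressWarnings(fit_ensemble(train, op$ages, zoo = "lr", seed = 1))
  expect_equal(m$views$species$std$mean,
               colMeans(op$profile$species[keep, ]))
  expect_equal(m$views$species$std$sd,
               apply(op$profile$species[keep, ], 2, sd))
})

test_that("unpaired samples are used for base fitting, never for testing", {
  sim <- simulate_profiles(simulation_config(
    n_paired = 60, n_unpaired_pathway = 40, n_species = 20, n_pathways = 10,
    n_markers_per_view = 4, seed = 13))
  cv <- suppressWarnings(evaluate_cv(sim$profile, sim$metadata, repeats = 1,
                                     folds = 3, seed = 2, zoo = "lr"))
  expect_equal(sum(cv$records$n_test), 60)
  m <- suppressWarnings(fit_ensemble(sim$profile, sim$metadata, zoo = "lr",
                                     seed = 2))
  expect_equal(unname(m$manifest$n_view_train), c(60, 100))
  expect_equal(m$manifest$n_paired, 60)
})

test_that("a zero-paired profile cannot train the meta layer", {
  sp <- matrix(runif(20), 5, 4, dimnames = list(paste0("a", 1:5), NULL))
  pw <- matrix(runif(20), 5, 4, dimnames = list(paste0("b", 1:5), NULL))
  prof <- suppressWarnings(multiview_profile(species = sp, pathways = pw))
  ages <- stats::setNames(runif(10, 20, 80), c(paste0("a", 1:5),
                                               paste0("b", 1:5)))
  expect_error(suppressWarnings(fit_ensemble(prof, ages)),
               "meta-learning impossible")
})

test_that("feature selection recovers dominant markers and honours k", {
  set.seed(14)
  n <- 250
  age <- runif(n, 18, 90)
  x <- matrix(rnorm(n * 40), n, 40)
  true <- 1:10
  for (j in true) x[, j] <- x[, j] + 0.08 * age * c(1, -1)[j %% 2 + 1]
  idx <- feature_select(x, age, method = "spearman", k = 10)
  expect_gte(length(intersect(idx, true)), 8)
  expect_equal(sort(feature_select(x, age, method = "pearson", k = 40)),
               1:40)
  xc <- cbind(x, const = rep(1, n))
  for (m in c("f_regression", "mutual_information", "rf_importance",
              "gbt_importance")) {
    sel <- feature_select(xc, age, method = m, k = 15, seed = 2)
    expect_false(41 %in% sel)
    expect_length(sel, 15)
  }
  expect_warning(feature_select(x, age, method = "pearson", k = 99), "k exceeds")
})
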