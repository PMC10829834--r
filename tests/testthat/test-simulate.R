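test_that("invalid configurations are rejected with the offending field named", {
  expect_error(simulation_config(n_paired = 0), "n_paired")
  expect_error(simulation_config(n_markers_per_view = 80, n_species = 50,
                                 n_pathways = 40), "n_markers_per_view")
  expect_error(simulation_config(zero_inflation = 1.4), "zero_inflation")
  expect_error(simulation_config(age_range = c(90, 30)), "age_range")
  expect_error(simulation_config(n_confounded_cohorts = 9, n_cohorts = 5),
               "n_confounded_cohorts")
})

test_that("generated profiles honour the construction contract", {
  cfg <- simulation_config(n_paired = 200, n_unpaired_pathway = 30,
                           n_species = 150, n_pathways = 80,
                           n_markers_per_view = 10, seed = 7)
  sim <- simulate_profiles(cfg)
  expect_equal(dim(sim$profile$species), c(200, 150))
  expect_equal(dim(sim$profile$pathways), c(230, 80))
  expect_true(all(abs(rowSums(sim$profile$species) - 1) < 1e-9))
  expect_true(all(abs(rowSums(sim$profile$pathways) - 1) < 1e-9))
  expect_true(all(sim$profile$species >= 0))
  expect_equal(sum(sim$profile$pairing == "pathway_only"), 30)
  expect_length(sim$truth$marker_indices$species, 10)
  expect_length(sim$truth$marker_indices$pathways, 10)
  expect_false(anyDuplicated(sim$truth$marker_indices$species) > 0)
  expect_true(all(sim$truth$marker_directions$species %in% c(-1, 1)))
  expect_equal(nrow(sim$metadata), 230)
})

test_that("generation is bit-identical for a fixed config and seed", {
  cfg <- simulation_config(n_paired = 80, n_species = 40, n_pathways = 20,
                           n_markers_per_view = 5, seed = 31)
  a <- simulate_profiles(cfg)
  b <- simulate_profiles(cfg)
  expect_identical(a$profile$species, b$profile$species)
  expect_identical(a$profile$pathways, b$profile$pathways)
  expect_identical(a$metadata, b$metadata)
  expect_identical(a$truth, b$truth)
})

test_that("marker features track age with the planted direction", {
  hits <- 0L; total <- 0L
  for (s in 1:3) {
    sim <- simulate_profiles(simulation_config(
      n_paired = 300, n_species = 60, n_pathways = 30,
      n_markers_per_view = 8, effect_size = 0.02, seed = 200 + s))
    age <- sim$metadata$age[match(rownames(sim$profile$species),
                                  sim$metadata$sample_id)]
    for (m in seq_along(sim$truth$marker_indices$species)) {
      j <- sim$truth$marker_indices$species[m]
      rho <- suppressWarnings(
        cor(sim$profile$species[, j], age, method = "spearman"))
      hits <- hits + (sign(rho) == sim$truth$marker_directions$species[m])
      total <- total + 1L
    }
  }
  expect_gte(hits / total, 0.95)
})

test_that("a null effect size produces calibrated feature-age p-values", {
  pvals <- unlist(lapply(1:50, function(s) {
    sim <- simulate_profiles(simulation_config(
      n_paired = 60, n_species = 25, n_pathways = 12,
      n_markers_per_view = 2, effect_size = 0, seed = 900 + s))
    fc <- feature_age_correlation(
      sim$profile$species,
      sim$metadata$age[match(rownames(sim$profile$species),
                             sim$metadata$sample_id)])
    fc$p_value
  }))
  frac <- mean(pvals < 0.05, na.rm = TRUE)
  expect_gte(frac, 0.03)
  expect_lte(frac, 0.07)
})

test_that("the frailty latent increases with age by construction", {
  for (s in 1:3) {
    sim <- simulate_profiles(simulation_config(n_paired = 200,
                                               n_species = 40,
                                               n_pathways = 20, seed = s))
    rho <- cor(sim$metadata$age, sim$truth$frailty_latent,
               method = "spearman")
    expect_gt(rho, 0.3)
  }
})

test_that("the elderly preset restricts the age range", {
  sim <- simulate_profiles(elderly_config(n_paired = 100, n_species = 30,
                                          n_pathways = 15,
                                          n_markers_per_view = 5, seed = 2))
  expect_true(all(sim$metadata$age >= 60 & sim$metadata$age <= 100))
})
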