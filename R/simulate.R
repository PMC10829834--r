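#' Configuration for the synthetic two-view microbiome generator
#'
#' Defines the statistical conditions under which the aging-clock pipeline
#' is exercised: sparse compositional species and pathway profiles with a
#' planted subset of age-monotone marker features per view, cohort-level
#' offsets, optional cohort-level region-age confounding, a configurable
#' number of pathway-only (unpaired) samples, and frailty/disease latents
#' loaded on the marker features.
#'
#' @param n_paired samples carrying both views.
#' @param n_unpaired_pathway additional samples carrying only the pathway
#'   view.
#' @param n_species,n_pathways features per view.
#' @param n_markers_per_view planted age-marker features in each view.
#' @param effect_size log-abundance change per year of age for marker
#'   features (sign set per marker by its direction).
#' @param confound_strength cohort-level age-region dependence in \[0,1\];
#'   0 = ages independent of geography.
#' @param n_confounded_cohorts how many cohorts have their age distribution
#'   tied to their region (active only when `confound_strength > 0`).
#' @param n_cohorts,n_regions study cohorts and geographic regions; each
#'   cohort belongs to one country, countries are grouped into regions.
#' @param zero_inflation per-cell Bernoulli dropout rate in \[0,1\].
#' @param noise_sd per-cell log-scale noise standard deviation.
#' @param age_range sampling range of chronological age in years.
#' @param frailty_loading weight of the marker-deviation component in the
#'   frailty latent (the age component has weight 1).
#' @param disease_rate approximate marginal prevalence of each simulated
#'   disease label.
#' @param seed integer seed; generation is fully reproducible from it.
#' @return validated `simulation_config` list.
#' @seealso [simulate_profiles()], [elderly_config()]
#' @export
simulation_config <- function(n_paired = 400L,
                              n_unpaired_pathway = 0L,
                              n_species = 120L,
                              n_pathways = 60L,
                              n_markers_per_view = 20L,
                              effect_size = 0.03,
                              confound_strength = 0,
                              n_confounded_cohorts = 0L,
                              n_cohorts = 8L,
                              n_regions = 4L,
                              zero_inflation = 0.3,
                              noise_sd = 2,
                              age_range = c(18, 107),
                              frailty_loading = 0.5,
                              disease_rate = 0.15,
                              seed = 1L) {
  cfg <- list(n_paired = as.integer(n_paired),
              n_unpaired_pathway = as.integer(n_unpaired_pathway),
              n_species = as.integer(n_species),
              n_pathways = as.integer(n_pathways),
              n_markers_per_view = as.integer(n_markers_per_view),
              effect_size = effect_size,
              confound_strength = confound_strength,
              n_confounded_cohorts = as.integer(n_confounded_cohorts),
              n_cohorts = as.integer(n_cohorts),
              n_regions = as.integer(n_regions),
              zero_inflation = zero_inflation,
              noise_sd = noise_sd,
              age_range = as.numeric(age_range),
              frailty_loading = frailty_loading,
              disease_rate = disease_rate,
              seed = as.integer(seed))
  bad <- function(field, why) {
    stop("invalid simulation config: field '", field, "' ", why, call. = FALSE)
  }
  for (f in c("n_paired", "n_species", "n_pathways", "n_markers_per_view",
              "n_cohorts", "n_regions")) {
    if (length(cfg[[f]]) != 1 || is.na(cfg[[f]]) || cfg[[f]] < 1) {
      bad(f, "must be a positive count")
    }
  }
  if (cfg$n_unpaired_pathway < 0) bad("n_unpaired_pathway", "must be >= 0")
  if (cfg$n_markers_per_view > min(cfg$n_species, cfg$n_pathways)) {
    bad("n_markers_per_view", "exceeds a view dimension")
  }
  for (f in c("zero_inflation", "confound_strength", "disease_rate")) {
    if (cfg[[f]] < 0 || cfg[[f]] > 1) bad(f, "must lie in [0,1]")
  }
  if (cfg$noise_sd < 0) bad("noise_sd", "must be nonnegative")
  if (length(cfg$age_range) != 2 || diff(cfg$age_range) <= 0) {
    bad("age_range", "must be an ordered pair of years")
  }
  if (cfg$n_confounded_cohorts < 0 || cfg$n_confounded_cohorts > cfg$n_cohorts) {
    bad("n_confounded_cohorts", "must be between 0 and n_cohorts")
  }
  if (cfg$n_regions > cfg$n_cohorts) bad("n_regions", "exceeds n_cohorts")
  class(cfg) <- "simulation_config"
  cfg
}

#' Elderly-cohort preset
#'
#' Same generator restricted to ages 60-100 years, mirroring validation
#' cohorts of older adults.
#' @param ... overrides passed to [simulation_config()].
#' @export
elderly_config <- function(...) {
  args <- list(...)
  if (is.null(args$age_range)) args$age_range <- c(60, 100)
  do.call(simulation_config, args)
}

#' Simulate two-view compositional microbiome profiles with planted truth
#'
#' Generates log-normal latent abundances per feature with feature-specific
#' baselines, adds age effects on planted marker features (slope =
#' direction x `effect_size` per year), cohort-level log-abundance offsets,
#' and a sparse species-to-pathway coupling so the two views share signal.
#' Zeros are introduced by independent Bernoulli masking, then each row is
#' closed to sum 1. The last `n_unpaired_pathway` samples carry only the
#' pathway view. A frailty latent (age component plus marker-deviation
#' component) and thresholded-logistic disease labels give the downstream
#' association layer known ground truth.
#'
#' @param config a [simulation_config()].
#' @return list with elements
#'   \describe{
#'     \item{profile}{a [multiview_profile()]}
#'     \item{metadata}{data.frame of sample metadata (age, cohort, country,
#'       region, westernized, non-host covariates, disease flags, frailty
#'       indices)}
#'     \item{truth}{planted ground truth: marker indices and directions per
#'       view, cohort offsets, frailty latent, disease labels, confounded
#'       cohorts and the country-to-region map}
#'   }
#' @export
simulate_profiles <- function(config = simulation_config()) {
  if (!inherits(config, "simulation_config")) {
    config <- do.call(simulation_config, as.list(config))
  }
  restore <- rng_local(config$seed)
  on.exit(restore())

  n_total <- config$n_paired + config$n_unpaired_pathway
  ids <- sprintf("S%05d", seq_len(n_total))
  amin <- config$age_range[1]; amax <- config$age_range[2]
  amid <- mean(config$age_range)

  ## cohorts, countries, regions ------------------------------------------
  cohorts <- sort(rep_len(seq_len(config$n_cohorts), n_total))
  cohorts <- sample(cohorts)                       # random sizes stay equal
  cohort_names <- sprintf("cohort_%02d", seq_len(config$n_cohorts))
  country_names <- sprintf("country_%02d", seq_len(config$n_cohorts))
  n_conf <- if (config$confound_strength > 0) config$n_confounded_cohorts else 0L
  if (n_conf > 0 && n_conf < config$n_regions) {
    # each confounded cohort is its own region's only study - the typical
    # situation where one geography is sampled by a single age-restricted
    # cohort; the remaining cohorts share the remaining regions
    cohort_region <- integer(config$n_cohorts)
    cohort_region[seq_len(n_conf)] <- seq_len(n_conf)
    rest <- seq(n_conf + 1L, config$n_cohorts)
    cohort_region[rest] <- n_conf + 1L +
      (seq_along(rest) - 1L) %% (config$n_regions - n_conf)
  } else {
    cohort_region <- ((seq_len(config$n_cohorts) - 1L) %% config$n_regions) + 1L
  }
  region_names <- sprintf("region_%d", seq_len(config$n_regions))
  country_region_map <- stats::setNames(region_names[cohort_region],
                                        country_names)

  ## ages: uniform, except confounded cohorts tied to their region --------
  age <- stats::runif(n_total, amin, amax)
  confounded <- integer(0)
  if (config$confound_strength > 0 && config$n_confounded_cohorts > 0) {
    confounded <- seq_len(config$n_confounded_cohorts)
    # confounded cohorts get narrow age windows spread across the range,
    # so each one ties its region to a distinct age stratum
    centers <- amin + (confounded - 0.5) / length(confounded) * (amax - amin)
    half <- (amax - amin) / 2
    for (co in confounded) {
      idx <- which(cohorts == co)
      width <- half * (1 - config$confound_strength)
      age[idx] <- pmin(pmax(centers[co] +
                              stats::runif(length(idx), -1, 1) * width,
                            amin), amax)
    }
  }

  ## marker placement ------------------------------------------------------
  mk_s <- sort(sample.int(config$n_species, config$n_markers_per_view))
  mk_p <- sort(sample.int(config$n_pathways, config$n_markers_per_view))
  dir_s <- sample(c(-1, 1), config$n_markers_per_view, replace = TRUE)
  dir_p <- sample(c(-1, 1), config$n_markers_per_view, replace = TRUE)

  ## latent log-abundances -------------------------------------------------
  latent_view <- function(p, markers, dirs, coupling = NULL) {
    mu <- stats::rnorm(p, 0, 1.5)
    # markers sit at low baseline abundance, as reported aging-marker taxa
    # do; this also keeps the compositional closure from leaking marker
    # age signal into the bulk features
    mu[markers] <- mu[markers] - 2
    cohort_off <- matrix(stats::rnorm(config$n_cohorts * p, 0, 0.3),
                         config$n_cohorts, p)
    eps <- matrix(stats::rnorm(n_total * p, 0, config$noise_sd), n_total, p)
    L <- matrix(mu, n_total, p, byrow = TRUE) + cohort_off[cohorts, ] + eps
    if (!is.null(coupling)) L <- L + coupling
    for (m in seq_along(markers)) {
      j <- markers[m]
      L[, j] <- L[, j] + dirs[m] * config$effect_size * (age - amid)
    }
    list(L = L, eps = eps, cohort_off = cohort_off)
  }
  sp <- latent_view(config$n_species, mk_s, dir_s)

  # sparse species-to-pathway coupling: a random subset of species latents
  # loads onto pathway latents so both views carry shared signal
  n_src <- min(config$n_species, 40L)
  src <- sample.int(config$n_species, n_src)
  W <- matrix(stats::rnorm(n_src * config$n_pathways) *
                (stats::runif(n_src * config$n_pathways) < 0.15),
              n_src, config$n_pathways)
  coupling <- scale(sp$L[, src, drop = FALSE], scale = FALSE) %*% W
  csd <- apply(coupling, 2, stats::sd)
  csd[csd == 0] <- 1
  coupling <- sweep(coupling, 2, csd, "/") * 0.7
  pw <- latent_view(config$n_pathways, mk_p, dir_p, coupling = coupling)

  ## zero inflation + closure ---------------------------------------------
  close_view <- function(L) {
    A <- exp(L)
    if (config$zero_inflation > 0) {
      keep <- matrix(stats::runif(length(A)) >= config$zero_inflation,
                     nrow(A), ncol(A))
      # never let a sample lose every feature: keep its largest latent
      top <- max.col(L)
      keep[cbind(seq_len(nrow(A)), top)] <- TRUE
      A <- A * keep
    }
    A / rowSums(A)
  }
  species <- close_view(sp$L)
  pathways <- close_view(pw$L)
  rownames(species) <- rownames(pathways) <- ids
  colnames(species) <- sprintf(
    "k__Bacteria|p__Phylum|c__Class|o__Order|f__Family|g__Genus_%03d|s__Species_%03d",
    seq_len(config$n_species), seq_len(config$n_species))
  colnames(pathways) <- sprintf("PWY-%04d", seq_len(config$n_pathways))

  paired <- seq_len(config$n_paired)
  profile <- multiview_profile(species = species[paired, , drop = FALSE],
                               pathways = pathways,
                               normalize = FALSE)

  ## frailty latent and disease labels -------------------------------------
  dev <- rowMeans(sweep(sp$eps[, mk_s, drop = FALSE], 2, dir_s, "*"))
  zscore <- function(v) (v - mean(v)) / max(stats::sd(v), 1e-12)
  frailty_latent <- zscore(age) + config$frailty_loading * zscore(dev) +
    stats::rnorm(n_total, 0, 0.5)
  names(frailty_latent) <- ids

  disease_names <- c("IBD", "T2D", "CRC")
  disease <- sapply(disease_names, function(d) {
    w <- stats::rnorm(length(mk_s))
    score <- zscore(drop(sp$eps[, mk_s, drop = FALSE] %*% w)) +
      0.3 * zscore(age)
    stats::rbinom(n_total, 1, stats::plogis(stats::qlogis(config$disease_rate) +
                                              score))
  })
  rownames(disease) <- ids

  ## observed frailty indices: clinical scales decreasing with frailty -----
  fr <- frailty_latent
  metadata <- data.frame(
    sample_id = ids,
    age = age,
    cohort = cohort_names[cohorts],
    country = country_names[cohorts],
    region = unname(country_region_map[country_names[cohorts]]),
    westernized = TRUE,
    dna_kit = c("kitA", "kitB")[(cohorts %% 2L) + 1L],
    platform = c("HiSeq", "NovaSeq")[((cohorts %/% 2L) %% 2L) + 1L],
    FIM = 110 - 10 * fr + stats::rnorm(n_total, 0, 4),
    MMSE = 27 - 2.5 * fr + stats::rnorm(n_total, 0, 1.5),
    MNA = 24 - 3 * fr + stats::rnorm(n_total, 0, 2),
    ADL = 95 - 12 * fr + stats::rnorm(n_total, 0, 5),
    stringsAsFactors = FALSE
  )
  metadata <- cbind(metadata, as.data.frame(disease))

  truth <- list(marker_indices = list(species = mk_s, pathways = mk_p),
                marker_directions = list(species = dir_s, pathways = dir_p),
                cohort_offsets = list(species = sp$cohort_off,
                                      pathways = pw$cohort_off),
                frailty_latent = frailty_latent,
                marker_deviation = stats::setNames(dev, ids),
                disease_labels = disease,
                confounded_cohorts = cohort_names[confounded],
                country_region_map = country_region_map)

  list(profile = profile, metadata = metadata, truth = truth)
}
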