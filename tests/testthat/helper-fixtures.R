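# shared fixtures and a lazy cache for the expensive default-condition runs

.gc_cache <- new.env(parent = emptyenv())

cache_get <- function(key, compute) {
  if (!exists(key, envir = .gc_cache, inherits = FALSE)) {
    assign(key, compute(), envir = .gc_cache)
  }
  get(key, envir = .gc_cache, inherits = FALSE)
}

# one cross-validated run of the clock under default generator conditions;
# reused by the dominance and the residual-frailty checks
default_cv_run <- function(s) {
  cache_get(paste0("cv_default_", s), function() {
    sim <- simulate_profiles(simulation_config(seed = 100 + s))
    cv <- suppressWarnings(
      evaluate_cv(sim$profile, sim$metadata, repeats = 1, folds = 5,
                  seed = s))
    list(sim = sim, cv = cv)
  })
}

# small species table fixture in the merged MetaPhlAn percentage dialect
write_species_fixture <- function(path,
                                  clades = c(
                                    "k__Bacteria|p__Firmicutes|c__Clostridia|o__Eubacteriales|f__Oscillospiraceae|g__Faecalibacterium|s__Faecalibacterium_prausnitzii",
                                    "k__Bacteria|p__Firmicutes|c__Clostridia|o__Eubacteriales|f__Lachnospiraceae|g__Agathobacter|s__Eubacterium_rectale",
                                    "k__Bacteria|p__Firmicutes|c__Bacilli|o__Lactobacillales|f__Enterococcaceae|g__Enterococcus|s__Enterococcus_faecalis"),
                                  values = matrix(c(40, 35, 25), 3, 1),
                                  samples = "S1",
                                  extra_rows = NULL) {
  df <- data.frame(clade_name = clades, values, check.names = FALSE)
  colnames(df)[-1] <- samples
  if (!is.null(extra_rows)) df <- rbind(extra_rows, df)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

write_pathway_fixture <- function(path,
                                  rows = c("UNMAPPED", "LEU-DEG2-PWY",
                                           "ILEUDEG-PWY"),
                                  values = matrix(c(50, 30, 20), 3, 1),
                                  samples = "S1") {
  df <- data.frame(pathway = rows, values, check.names = FALSE)
  colnames(df) <- c("# Pathway", samples)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# a tiny profile with a deterministic age signal: one species feature IS
# the age (normalization off, so the signal stays exactly linear)
oracle_profile <- function(n = 150, seed = 42) {
  set.seed(seed)
  age <- runif(n, 20, 90)
  ids <- sprintf("O%03d", seq_len(n))
  sp <- cbind(age, matrix(runif(n * 5, 0, 0.2), n, 5))
  pw <- matrix(runif(n * 4), n, 4)
  pw <- pw / rowSums(pw)
  rownames(sp) <- rownames(pw) <- ids
  colnames(sp) <- paste0("sp", seq_len(ncol(sp)))
  colnames(pw) <- paste0("pw", seq_len(ncol(pw)))
  list(profile = multiview_profile(species = sp, pathways = pw,
                                   normalize = FALSE),
       ages = stats::setNames(age, ids))
}
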