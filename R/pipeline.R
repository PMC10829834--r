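#' Pipeline-level defaults
#'
#' The constants every stage falls back to: confounder-filter termination
#' threshold on cross-validated region-to-age R2 (0.001), the 10 x 5
#' cross-validation scheme, the ALE marker thresholds (0.083 years of
#' predicted-age deviation - about one month - and 1% prevalence) and the
#' PERMANOVA permutation count.
#'
#' @return named list of defaults.
#' @export
gage_defaults <- function() {
  list(filter_threshold = 0.001,
       cv_repeats = 10L,
       cv_folds = 5L,
       effect_threshold = 0.083,
       prevalence_threshold = 0.01,
       n_permutations = 999L,
       zoo = default_zoo())
}

#' Run the aging-clock pipeline end to end
#'
#' Stages, in order: simulate (or ingest TSV inputs) -> confounder filter
#' -> train -> evaluate -> interpret -> associate. Every run writes a
#' resolved-config snapshot (with a content hash) and a log to `out_dir`;
#' rerunning with the identical config reproduces all artifacts.
#'
#' @param config list with any of: `seed` (master seed; stage seeds are
#'   derived from it), `simulation` (list of [simulation_config()]
#'   overrides; if absent, `species_path`/`pathway_path`/`metadata_path`
#'   must point to TSV inputs), `stages` (character subset of
#'   filter/train/evaluate/interpret/associate), `cv_repeats`, `cv_folds`,
#'   `zoo`, `filter_threshold`, `effect_threshold`,
#'   `prevalence_threshold`.
#' @param out_dir output directory (created if needed).
#' @return invisible list of in-memory stage results; artifacts on disk.
#' @export
run_pipeline <- function(config = list(), out_dir) {
  defaults <- gage_defaults()
  cfg <- utils::modifyList(
    list(seed = 1L, simulation = list(), stages = c("filter", "train",
                                                    "evaluate", "interpret",
                                                    "associate"),
         cv_repeats = defaults$cv_repeats, cv_folds = defaults$cv_folds,
         zoo = defaults$zoo, filter_threshold = defaults$filter_threshold,
         effect_threshold = defaults$effect_threshold,
         prevalence_threshold = defaults$prevalence_threshold),
    config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "run.log")
  logf <- function(...) {
    cat(format(Sys.time(), "%H:%M:%S"), paste0(...), "\n",
        file = log_path, append = TRUE)
  }
  snapshot <- cfg
  snapshot$config_hash <- config_hash(cfg)
  jsonlite::write_json(snapshot, file.path(out_dir, "resolved_config.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  results <- list(config = snapshot)
  stage <- "ingest"
  run_stage <- function(name, expr) {
    stage <<- name
    tryCatch(expr, error = function(e) {
      logf("stage ", name, " FAILED: ", conditionMessage(e))
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  ## ingest or simulate ----------------------------------------------------
  if (length(cfg$simulation) || is.null(cfg$species_path)) {
    sim_cfg <- do.call(simulation_config,
                       utils::modifyList(list(seed = derive_seed(cfg$seed, 1L)),
                                         cfg$simulation))
    sim <- run_stage("simulate", simulate_profiles(sim_cfg))
    profile <- sim$profile
    metadata <- sim$metadata
    results$truth <- sim$truth
    if (!is.null(profile$species)) {
      write_species_table(profile$species,
                          file.path(out_dir, "species_profile.tsv"))
    }
    write_pathway_table(profile$pathways,
                        file.path(out_dir, "pathway_profile.tsv"))
    write_metadata(metadata, file.path(out_dir, "metadata.tsv"))
    logf("simulate: ", length(profile$sample_ids), " samples")
  } else {
    profile <- run_stage("ingest", assemble_multiview(
      species = read_species_table(cfg$species_path),
      pathways = read_pathway_table(cfg$pathway_path),
      metadata = read_metadata(cfg$metadata_path)))
    metadata <- attr(profile, "metadata")
    logf("ingest: ", length(profile$sample_ids), " samples")
  }
  results$profile <- profile
  results$metadata <- metadata

  ## confounder filter ------------------------------------------------------
  if ("filter" %in% cfg$stages) {
    trace <- run_stage("filter", {
      west <- drop_nonwesternized(metadata)
      md <- metadata[metadata$sample_id %in% west, , drop = FALSE]
      recursive_cohort_elimination(md, threshold = cfg$filter_threshold,
                                   min_cohorts = max(3L,
                                     length(unique(md$cohort)) %/% 3L),
                                   seed = derive_seed(cfg$seed, 2L))
    })
    results$filter_trace <- trace
    jsonlite::write_json(
      list(iterations = trace$iterations,
           retained = length(trace$retained_ids),
           final_r2 = as.list(trace$final_r2),
           terminated = trace$terminated, threshold = trace$threshold),
      file.path(out_dir, "filter_trace.json"), auto_unbox = TRUE,
      digits = NA, dataframe = "rows")
    utils::write.table(data.frame(sample_id = trace$retained_ids),
                       file.path(out_dir, "retained_samples.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    profile <- subset_profile(profile, trace$retained_ids)
    metadata <- metadata[metadata$sample_id %in% trace$retained_ids, ,
                         drop = FALSE]
    logf("filter: retained ", length(trace$retained_ids), " samples; ",
         nrow(trace$iterations), " cohort(s) removed")
  }

  model <- NULL
  if ("train" %in% cfg$stages) {
    model <- run_stage("train",
                       fit_ensemble(profile, metadata, zoo = cfg$zoo,
                                    seed = derive_seed(cfg$seed, 3L)))
    results$model <- model
    saveRDS(model, file.path(out_dir, "model.rds"))
    logf("train: ", length(model$meta$full$coef) - 1, " meta weights")
  }

  if ("evaluate" %in% cfg$stages) {
    cv <- run_stage("evaluate",
                    evaluate_cv(profile, metadata,
                                repeats = cfg$cv_repeats,
                                folds = cfg$cv_folds,
                                seed = derive_seed(cfg$seed, 4L),
                                zoo = cfg$zoo))
    results$cv <- cv
    utils::write.table(cv$records, file.path(out_dir, "cv_records.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(cv$summary, file.path(out_dir, "cv_summary.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    logf("evaluate: mean R2 ",
         round(cv$summary$mean[cv$summary$metric == "r2"], 3))
  }

  if ("interpret" %in% cfg$stages && !is.null(model)) {
    markers <- run_stage("interpret", {
      pids <- paired_ids(profile)
      sp <- profile$species[pids, , drop = FALSE]
      pw <- profile$pathways[pids, , drop = FALSE]
      ale <- c(ale_all_features(model, sp, pw, view = "species"),
               ale_all_features(model, sp, pw, view = "pathways"))
      rank_and_select(ale, effect_threshold = cfg$effect_threshold,
                      prevalence_threshold = cfg$prevalence_threshold)
    })
    results$markers <- markers
    utils::write.table(markers$markers, file.path(out_dir, "markers.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(markers$all_features,
                       file.path(out_dir, "ale_all_features.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    logf("interpret: ", nrow(markers$markers), " markers")
  }

  if ("associate" %in% cfg$stages && !is.null(results$cv)) {
    assoc <- run_stage("associate", {
      pids <- rownames(results$cv$predictions)
      gage <- rowMeans(results$cv$predictions)
      md <- metadata[match(pids, metadata$sample_id), , drop = FALSE]
      rr <- prediction_residuals(gage, md$age)
      frailty_cols <- intersect(c("FIM", "MMSE", "MNA", "ADL"), colnames(md))
      rep_frailty <- correlate_with_indices(rr$residuals,
                                            md[, frailty_cols, drop = FALSE])
      list(residuals = rr, frailty = rep_frailty)
    })
    results$association <- assoc
    utils::write.table(assoc$frailty,
                       file.path(out_dir, "residual_frailty_association.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    logf("associate: ", nrow(assoc$frailty), " indices tested")
  }

  logf("done")
  invisible(results)
}

config_hash <- function(cfg) {
  s <- jsonlite::toJSON(cfg[order(names(cfg))], auto_unbox = TRUE,
                        digits = NA)
  # small rolling hash; stable across sessions, no extra dependency
  sum(utf8ToInt(as.character(s)) *
        (seq_len(nchar(as.character(s))) %% 97 + 1)) %% 2147483647
}
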