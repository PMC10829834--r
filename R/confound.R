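#' Remove non-westernized samples
#'
#' Geography and diet dominate gut microbiome variation, so non-westernized
#' samples are removed before the region-age confounder filter. A missing
#' westernized flag is treated as westernized, with a warning counting the
#' affected samples.
#'
#' @param metadata data.frame with `sample_id` and (ideally) a logical or
#'   yes/no `westernized` column.
#' @return character vector of retained sample ids.
#' @export
drop_nonwesternized <- function(metadata) {
  if (!"westernized" %in% colnames(metadata)) {
    warning("no 'westernized' column; all ", nrow(metadata),
            " samples treated as westernized")
    return(metadata$sample_id)
  }
  w <- metadata$westernized
  if (is.character(w)) w <- tolower(w) %in% c("yes", "true", "1")
  miss <- is.na(w)
  if (any(miss)) {
    warning(sum(miss), " sample(s) with missing westernized flag retained")
    w[miss] <- TRUE
  }
  metadata$sample_id[w]
}

#' Map country labels to geographic regions
#'
#' @param metadata data.frame with a `country` column.
#' @param country_to_region named character vector mapping every country
#'   label to a region label.
#' @return character vector of per-sample region labels.
#' @export
cluster_regions <- function(metadata, country_to_region) {
  countries <- metadata$country
  unmapped <- setdiff(unique(countries), names(country_to_region))
  if (length(unmapped)) {
    stop("countries without a region mapping: ",
         paste(unmapped, collapse = ", "))
  }
  unname(country_to_region[countries])
}

#' Cross-validated region-to-age predictability
#'
#' Fits two heterogeneous models (linear regression and a random forest) of
#' age on one-hot-encoded region labels and reports each model's pooled
#' out-of-fold R-squared (1 - SSE/SST; may be negative). Used as the
#' stopping criterion of [recursive_cohort_elimination()]: when even the
#' better model explains less than 0.1% of age variance from geography,
#' region and age are considered unconfounded.
#'
#' @param regions character/factor region labels.
#' @param ages chronological ages, same length.
#' @param k_folds cross-validation folds (default 5).
#' @param seed integer seed for fold assignment and the forest.
#' @return named numeric `c(linear = , forest = )`; a single-level region
#'   vector returns `(0, 0)` with attribute `note`.
#' @export
region_age_r2 <- function(regions, ages, k_folds = 5, seed = 1L) {
  regions <- as.character(regions)
  stopifnot(length(regions) == length(ages))
  if (length(unique(regions)) < 2) {
    out <- c(linear = 0, forest = 0)
    attr(out, "note") <- "single region level: no variance exploitable"
    return(out)
  }
  n <- length(ages)
  if (n < 2 * k_folds) stop("need at least 2 samples per fold")
  X <- stats::model.matrix(~ region - 1,
                           data = data.frame(region = factor(regions)))
  folds <- fold_assignments(n, k_folds, seed = derive_seed(seed, 11L))
  pred_lin <- pred_rf <- numeric(n)
  for (k in seq_len(k_folds)) {
    test <- folds == k
    Xtr <- X[!test, , drop = FALSE]
    # levels absent from the training fold contribute the training mean
    fit <- stats::lm.fit(cbind(1, Xtr), ages[!test])
    co <- fit$coefficients
    co[is.na(co)] <- 0
    pred_lin[test] <- drop(cbind(1, X[test, , drop = FALSE]) %*% co)
    rf <- ranger::ranger(x = Xtr, y = ages[!test], num.trees = 150,
                         num.threads = 1, seed = derive_seed(seed, 13L + k))
    pred_rf[test] <- stats::predict(rf, data = X[test, , drop = FALSE],
                                    num.threads = 1)$predictions
  }
  sst <- sum((ages - mean(ages))^2)
  c(linear = 1 - sum((ages - pred_lin)^2) / sst,
    forest = 1 - sum((ages - pred_rf)^2) / sst)
}

#' Recursive single-cohort elimination of region-age confounding
#'
#' Greedy loop: while the larger of the two cross-validated region-to-age
#' R-squared values ([region_age_r2()]) is at or above `threshold`, evaluate
#' the criterion with each remaining cohort left out, and remove the cohort
#' whose exclusion minimizes it (ties broken by removing the smaller
#' cohort, retaining more data). Stops when the criterion drops below
#' `threshold`, or - with `terminated = FALSE` - when only `min_cohorts`
#' cohorts remain.
#'
#' @param metadata data.frame with `sample_id`, `cohort`, `region`, `age`.
#' @param threshold termination threshold on max(R2) (default 0.001).
#' @param min_cohorts stop guard: never remove below this many cohorts.
#' @param seed integer seed forwarded to the criterion models.
#' @return a `filter_trace` list: `iterations` (data.frame of removed
#'   cohort and resulting R2s), `retained_ids`, `final_r2`, `terminated`,
#'   `threshold`.
#' @export
recursive_cohort_elimination <- function(metadata, threshold = 0.001,
                                         min_cohorts = 3L, seed = 1L) {
  need <- c("sample_id", "cohort", "region", "age")
  if (!all(need %in% colnames(metadata))) {
    stop("metadata must contain columns: ", paste(need, collapse = ", "))
  }
  cohorts <- unique(metadata$cohort)
  if (min_cohorts >= length(cohorts)) {
    stop("min_cohorts (", min_cohorts, ") must be below the initial cohort",
         " count (", length(cohorts), ")")
  }
  current <- metadata
  iterations <- data.frame(removed_cohort = character(),
                           n_removed = integer(),
                           r2_linear = numeric(), r2_forest = numeric())
  crit <- function(md) region_age_r2(md$region, md$age, seed = seed)
  r2 <- crit(current)
  terminated <- max(r2) < threshold
  while (!terminated && length(unique(current$cohort)) > min_cohorts) {
    remaining <- unique(current$cohort)
    cand <- lapply(remaining, function(co) {
      crit(current[current$cohort != co, , drop = FALSE])
    })
    crit_max <- vapply(cand, max, numeric(1))
    sizes <- vapply(remaining, function(co) sum(current$cohort == co),
                    integer(1))
    best <- order(crit_max, sizes)[1]       # ties: remove smaller cohort
    removed <- remaining[best]
    current <- current[current$cohort != removed, , drop = FALSE]
    r2 <- cand[[best]]
    iterations <- rbind(iterations, data.frame(
      removed_cohort = removed, n_removed = sizes[best],
      r2_linear = r2[["linear"]], r2_forest = r2[["forest"]]))
    terminated <- max(r2) < threshold
  }
  structure(list(iterations = iterations,
                 retained_ids = current$sample_id,
                 removed_cohorts = iterations$removed_cohort,
                 final_r2 = r2,
                 terminated = terminated,
                 threshold = threshold),
            class = "filter_trace")
}

#' @export
print.filter_trace <- function(x, ...) {
  cat("confounder filter trace:", nrow(x$iterations), "cohort(s) removed,",
      length(x$retained_ids), "samples retained\n")
  cat(sprintf("  final R2: linear %.5f, forest %.5f (threshold %g, %s)\n",
              x$final_r2[["linear"]], x$final_r2[["forest"]], x$threshold,
              if (x$terminated) "terminated" else "guard reached"))
  if (nrow(x$iterations)) print(x$iterations)
  invisible(x)
}
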