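#' Prediction residuals of the aging clock
#'
#' Ordinary least squares of predicted on chronological age; the residual
#' (predicted minus fitted) is the age-independent component of the clock:
#' positive residuals suggest accelerated aging. By OLS identities the
#' residuals have exactly zero mean and zero Pearson correlation with
#' chronological age.
#'
#' @param predicted predicted ages (years).
#' @param chronological chronological ages (years), same length (>= 3).
#' @return a `residual_result`: `intercept`, `slope`, `residuals`.
#' @export
prediction_residuals <- function(predicted, chronological) {
  if (length(predicted) != length(chronological) || length(predicted) < 3) {
    stop("need equal-length vectors with at least 3 samples")
  }
  if (stats::sd(chronological) == 0) {
    stop("chronological ages are constant; residual fit undefined")
  }
  slope <- stats::cov(chronological, predicted) / stats::var(chronological)
  intercept <- mean(predicted) - slope * mean(chronological)
  res <- predicted - (intercept + slope * chronological)
  names(res) <- names(predicted)
  structure(list(intercept = intercept, slope = slope, residuals = res),
            class = "residual_result")
}

#' Spearman association of a score with named indices
#'
#' Correlates a per-sample value (gAge, residual, chronological age) with
#' each supplied index on complete cases, with Benjamini-Hochberg
#' adjustment across indices. Indices with fewer than 3 complete pairs are
#' skipped with a note.
#'
#' @param values named or aligned numeric vector.
#' @param indices data.frame of numeric columns (frailty scores, disease
#'   counts, biochemistry), aligned with `values`.
#' @param adjust multiple-testing method (default "BH").
#' @return data.frame with `index`, `n`, `rho`, `p_value`, `q_value`,
#'   `note`.
#' @export
correlate_with_indices <- function(values, indices, adjust = "BH") {
  stopifnot(nrow(indices) == length(values))
  rows <- lapply(colnames(indices), function(nm) {
    idx <- indices[[nm]]
    ok <- !is.na(idx) & !is.na(values)
    if (sum(ok) < 3) {
      return(data.frame(index = nm, n = sum(ok), rho = NA_real_,
                        p_value = NA_real_,
                        note = "skipped: fewer than 3 complete pairs"))
    }
    ct <- suppressWarnings(stats::cor.test(values[ok], idx[ok],
                                           method = "spearman"))
    data.frame(index = nm, n = sum(ok), rho = unname(ct$estimate),
               p_value = ct$p.value, note = "")
  })
  out <- do.call(rbind, rows)
  out$q_value <- stats::p.adjust(out$p_value, method = adjust)
  out[, c("index", "n", "rho", "p_value", "q_value", "note")]
}

#' Rank-based group comparison
#'
#' Two-sided Wilcoxon rank-sum for two groups, Kruskal-Wallis for more.
#' Groups with fewer than 2 members are dropped with a warning. The
#' significance stars follow the usual caption convention
#' (* p<.05, ** p<.01, *** p<.001).
#'
#' @param values numeric vector.
#' @param grouping factor/character of the same length.
#' @return data.frame row with `test`, `n_groups`, `statistic`, `p_value`,
#'   `stars`.
#' @export
group_compare <- function(values, grouping) {
  grouping <- as.character(grouping)
  ok <- !is.na(values) & !is.na(grouping)
  values <- values[ok]; grouping <- grouping[ok]
  sizes <- table(grouping)
  small <- names(sizes)[sizes < 2]
  if (length(small)) {
    warning("group(s) with fewer than 2 members dropped: ",
            paste(small, collapse = ", "))
    keep <- !(grouping %in% small)
    values <- values[keep]; grouping <- grouping[keep]
    sizes <- table(grouping)
  }
  if (length(sizes) < 2) stop("need at least 2 usable groups")
  if (length(sizes) == 2) {
    g <- names(sizes)
    ht <- stats::wilcox.test(values[grouping == g[1]],
                             values[grouping == g[2]], exact = FALSE)
    test <- "wilcoxon_rank_sum"
  } else {
    ht <- stats::kruskal.test(values, factor(grouping))
    test <- "kruskal_wallis"
  }
  p <- ht$p.value
  stars <- if (p < 0.001) "***" else if (p < 0.01) "**" else
    if (p < 0.05) "*" else "NS"
  data.frame(test = test, n_groups = length(sizes),
             statistic = unname(ht$statistic), p_value = p, stars = stars)
}

#' Disease discrimination from aging-clock markers
#'
#' Gradient-boosted classifier on the marker features only, with
#' stratified cross-validation; reports the pooled out-of-fold ROC/AUC and
#' the booster's own feature-importance ranking.
#'
#' @param x samples x marker-features matrix.
#' @param labels binary vector (0/1 or logical).
#' @param folds stratified CV folds (default 5).
#' @param seed integer seed.
#' @return a `classifier_result`: `auc`, `roc` (data.frame of points),
#'   `importance`, `oof_probability`.
#' @export
marker_discriminator <- function(x, labels, folds = 5L, seed = 1L) {
  x <- as.matrix(x)
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2) {
    stop("both classes must be present")
  }
  cn <- colnames(x) %||% paste0("f", seq_len(ncol(x)))
  colnames(x) <- cn
  fold_id <- stratified_folds(labels, folds, seed)
  prob <- numeric(length(labels))
  for (k in seq_len(folds)) {
    te <- fold_id == k
    m <- xgboost::xgboost(x[!te, , drop = FALSE],
                          factor(labels[!te], levels = c(0, 1)),
                          objective = "binary:logistic", nrounds = 80,
                          max_depth = 3, learning_rate = 0.1,
                          nthreads = 1, seed = seed, verbosity = 0)
    prob[te] <- stats::predict(m, x[te, , drop = FALSE],
                               type = "response")
  }
  roc <- pROC::roc(labels, prob, quiet = TRUE, direction = "<")
  final <- xgboost::xgboost(x, factor(labels, levels = c(0, 1)),
                            objective = "binary:logistic", nrounds = 80,
                            max_depth = 3, learning_rate = 0.1,
                            nthreads = 1, seed = seed, verbosity = 0)
  imp <- xgboost::xgb.importance(model = final)
  structure(list(auc = as.numeric(pROC::auc(roc)),
                 roc = data.frame(specificity = roc$specificities,
                                  sensitivity = roc$sensitivities),
                 importance = as.data.frame(imp),
                 oof_probability = prob,
                 folds = folds, seed = seed),
            class = "classifier_result")
}

#' @export
print.classifier_result <- function(x, ...) {
  cat(sprintf("classifier_result: CV AUC %.3f (%d-fold)\n", x$auc, x$folds))
  invisible(x)
}

stratified_folds <- function(labels, k, seed) {
  restore <- rng_local(seed)
  on.exit(restore())
  id <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    id[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  id
}

#' Overlap between two marker sets
#'
#' @param a,b marker sets: `marker_set` objects, data.frames with
#'   `view`/`feature` columns, or character vectors.
#' @return list with `only_a`, `shared`, `only_b` counts and the shared
#'   members.
#' @export
marker_overlap <- function(a, b) {
  key <- function(x) {
    if (inherits(x, "marker_set")) x <- x$markers
    if (is.data.frame(x)) paste(x$view, x$feature, sep = "/") else
      as.character(x)
  }
  ka <- unique(key(a)); kb <- unique(key(b))
  shared <- intersect(ka, kb)
  list(only_a = length(setdiff(ka, kb)), shared = length(shared),
       only_b = length(setdiff(kb, ka)), shared_members = shared)
}

#' Compare two marker sources as predictors of the same target
#'
#' Fits a gradient-boosted regressor per feature source with identical CV
#' folds, then a paired two-sided Wilcoxon test on the two out-of-fold
#' prediction vectors. Identical predictions make the paired test
#' degenerate; p = 1 is reported with a note.
#'
#' @param x samples x features matrix holding both sources' features.
#' @param target numeric score to predict.
#' @param features_a,features_b column names/indices of the two sources.
#' @param folds CV folds (default 5).
#' @param seed integer seed.
#' @return data.frame-backed list: per-source R2, out-of-fold predictions,
#'   `p_value`, `note`, and the fold assignment hash.
#' @export
compare_marker_sources <- function(x, target, features_a, features_b,
                                   folds = 5L, seed = 1L) {
  x <- as.matrix(x)
  if (length(features_a) == 0 || length(features_b) == 0) {
    stop("both feature sources must be non-empty")
  }
  fold_id <- fold_assignments(nrow(x), folds, seed = derive_seed(seed, 31L))
  run_source <- function(feats) {
    xs <- x[, feats, drop = FALSE]
    colnames(xs) <- colnames(xs) %||% paste0("f", seq_len(ncol(xs)))
    oof <- numeric(nrow(x))
    for (k in seq_len(folds)) {
      te <- fold_id == k
      m <- xgboost::xgboost(xs[!te, , drop = FALSE], target[!te],
                            nrounds = 80, max_depth = 3,
                            learning_rate = 0.1, nthreads = 1,
                            seed = seed, verbosity = 0)
      oof[te] <- stats::predict(m, xs[te, , drop = FALSE])
    }
    oof
  }
  pa <- run_source(features_a)
  pb <- run_source(features_b)
  if (isTRUE(all.equal(pa, pb))) {
    p <- 1; note <- "identical predictions: paired test degenerate"
  } else {
    p <- stats::wilcox.test(pa, pb, paired = TRUE, exact = FALSE)$p.value
    note <- ""
  }
  list(r2_a = r_squared(target, pa), r2_b = r_squared(target, pb),
       predictions_a = pa, predictions_b = pb,
       p_value = p, note = note,
       fold_hash = sum(fold_id * seq_along(fold_id)))
}

#' Multimorbidity count from binary disease flags
#'
#' @param metadata data.frame containing 0/1 disease columns.
#' @param disease_cols character vector of the disease column names.
#' @return integer per-sample disease count.
#' @export
disease_count <- function(metadata, disease_cols) {
  missing_cols <- setdiff(disease_cols, colnames(metadata))
  if (length(missing_cols)) {
    stop("disease columns absent: ", paste(missing_cols, collapse = ", "))
  }
  as.integer(rowSums(metadata[, disease_cols, drop = FALSE], na.rm = TRUE))
}
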