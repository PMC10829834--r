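#' Fit the two-view stacked ensemble aging clock
#'
#' Per view, features are Z-score standardized (parameters estimated from
#' that view's training samples, paired and unpaired alike) and every
#' requested base learner is fitted on ALL samples carrying the view -
#' unpaired single-view samples therefore strengthen their view's base
#' models. Out-of-fold predictions for the paired samples (internal 5-fold
#' split, shared across views) feed the meta layer: unregularized ordinary
#' least squares with intercept, one weight per (view, learner). Per-view
#' meta coefficients are fitted alongside, giving single-view clocks from
#' the same base predictions.
#'
#' @param profile a [multiview_profile()].
#' @param ages named numeric vector of chronological ages (years) covering
#'   all profile samples, or a metadata data.frame with `sample_id`, `age`.
#' @param zoo character vector of base-learner names (see [zoo_registry()]).
#' @param seed integer seed; the fit is deterministic given it.
#' @param internal_folds folds of the internal out-of-fold split.
#' @return an object of class `gage_model`.
#' @export
fit_ensemble <- function(profile, ages, zoo = default_zoo(), seed = 1L,
                         internal_folds = 5L) {
  stopifnot(inherits(profile, "multiview_profile"))
  zoo <- match.arg(zoo, zoo_registry(), several.ok = TRUE)
  ages <- resolve_ages(ages, profile$sample_ids)
  pids <- paired_ids(profile)
  if (length(pids) == 0) {
    stop("meta-learning impossible: the profile has no paired samples")
  }
  if (length(pids) < internal_folds) {
    stop("fewer paired samples than internal folds")
  }
  views <- c("species", "pathways")[!vapply(list(profile$species,
                                                 profile$pathways),
                                            is.null, logical(1))]
  folds <- fold_assignments(length(pids), internal_folds,
                            seed = derive_seed(seed, 1L))
  names(folds) <- pids
  y_paired <- ages[pids]

  fitted_views <- list()
  oof_cols <- list()
  dropped <- character()
  for (v in views) {
    X <- profile[[v]]
    ids_v <- rownames(X)
    y_v <- ages[ids_v]
    std <- standardize_params(X)
    Xz <- apply_standardize(X, std)
    learners <- list()
    for (nm in zoo) {
      res <- tryCatch({
        full <- fit_base_learner(nm, Xz, y_v,
                                 seed = derive_seed(seed, view_offset(v)))
        lambda <- if (nm %in% c("lasso", "ridge", "enet"))
          full$fit$lambda else NULL
        oof <- numeric(length(pids))
        for (k in seq_len(internal_folds)) {
          test_ids <- pids[folds == k]
          train_ids <- setdiff(ids_v, test_ids)
          Xtr <- X[train_ids, , drop = FALSE]
          std_k <- standardize_params(Xtr)
          mk <- fit_base_learner(nm, apply_standardize(Xtr, std_k),
                                 ages[train_ids],
                                 seed = derive_seed(seed,
                                                    view_offset(v) + k),
                                 lambda = lambda)
          oof[folds == k] <- predict_base_learner(
            mk, apply_standardize(X[test_ids, , drop = FALSE], std_k))
        }
        list(full = full, oof = oof)
      }, error = function(e) e)
      if (inherits(res, "error")) {
        warning("base learner '", nm, "' failed on view ", v,
                " and was dropped: ", conditionMessage(res))
        dropped <- c(dropped, paste0(v, ".", nm))
        next
      }
      learners[[nm]] <- res$full
      oof_cols[[paste0(v, ".", nm)]] <- res$oof
    }
    if (length(learners) == 0) stop("every base learner failed on view ", v)
    fitted_views[[v]] <- list(std = std, learners = learners,
                              feature_names = colnames(X),
                              n_train = nrow(X))
  }

  Z <- do.call(cbind, oof_cols)
  rownames(Z) <- pids
  meta_fit <- function(cols) {
    fit <- stats::lm.fit(cbind("(Intercept)" = 1, Z[, cols, drop = FALSE]),
                         y_paired)
    co <- fit$coefficients
    collinear <- names(co)[is.na(co)]
    co[is.na(co)] <- 0
    list(coef = co, collinear = collinear)
  }
  meta_full <- meta_fit(colnames(Z))
  meta_view <- lapply(views, function(v) {
    meta_fit(grep(paste0("^", v, "\\."), colnames(Z), value = TRUE))
  })
  names(meta_view) <- views

  structure(list(
    views = fitted_views,
    meta = list(full = meta_full, per_view = meta_view),
    oof = Z,
    zoo = zoo,
    seed = seed,
    internal_folds = internal_folds,
    paired_ids = pids,
    manifest = list(
      n_paired = length(pids),
      n_view_train = vapply(fitted_views, `[[`, numeric(1), "n_train"),
      dropped_learners = dropped,
      collinear_meta_columns = meta_full$collinear,
      fold_scheme = paste0("internal ", internal_folds, "-fold"),
      seed = seed)
  ), class = "gage_model")
}

view_offset <- function(v) if (v == "species") 1000L else 2000L

standardize_params <- function(X) {
  m <- colMeans(X)
  s <- apply(X, 2, stats::sd)
  constant <- s == 0
  s[constant] <- 1
  list(mean = m, sd = s, constant = constant)
}

apply_standardize <- function(X, std) {
  sweep(sweep(X, 2, std$mean), 2, std$sd, "/")
}

resolve_ages <- function(ages, ids) {
  if (is.data.frame(ages)) {
    if (!all(c("sample_id", "age") %in% colnames(ages))) {
      stop("metadata must contain 'sample_id' and 'age'")
    }
    ages <- stats::setNames(ages$age, ages$sample_id)
  }
  if (is.null(names(ages))) {
    if (length(ages) != length(ids)) stop("unnamed ages must match samples")
    names(ages) <- ids
  }
  miss <- setdiff(ids, names(ages))
  if (length(miss)) {
    stop("no age for sample(s): ", paste(utils::head(miss, 5), collapse = ", "))
  }
  av <- ages[ids]
  if (!all(is.finite(av))) stop("ages must be finite")
  av
}

#' Base-learner prediction matrix for one view
#'
#' Standardizes `newx` with the model's stored per-view parameters and
#' returns one column of predictions per fitted base learner. Exposed so
#' interpretation code can cache the unmodified view's predictions.
#'
#' @param model a `gage_model`.
#' @param view `"species"` or `"pathways"`.
#' @param newx samples x features matrix matching the view's manifest.
#' @return matrix n x n_learners with `view.learner` column names.
#' @export
base_predictions <- function(model, view, newx) {
  vf <- model$views[[view]]
  if (is.null(vf)) stop("model has no fitted view '", view, "'")
  newx <- as.matrix(newx)
  miss <- setdiff(vf$feature_names, colnames(newx))
  if (length(miss)) {
    stop("view ", view, " is missing feature(s): ",
         paste(utils::head(miss, 3), collapse = ", "),
         if (length(miss) > 3) sprintf(" (and %d more)", length(miss) - 3))
  }
  Xz <- apply_standardize(newx[, vf$feature_names, drop = FALSE], vf$std)
  out <- vapply(vf$learners, function(l) predict_base_learner(l, Xz),
                numeric(nrow(Xz)))
  if (is.null(dim(out))) out <- matrix(out, nrow = 1)
  colnames(out) <- paste0(view, ".", names(vf$learners))
  rownames(out) <- rownames(newx)
  out
}

#' Predict biological age (gAge)
#'
#' @param object a `gage_model` from [fit_ensemble()].
#' @param species,pathways matrices of new samples (rows aligned across
#'   views when both are given). With `view = "both"` (default) both views
#'   are required; `view = "species"`/`"pathways"` is the explicit
#'   single-view fallback using that view's meta weights.
#' @param view which meta layer to apply.
#' @param ... unused.
#' @return numeric vector of predicted ages in years.
#' @export
predict.gage_model <- function(object, species = NULL, pathways = NULL,
                               view = c("both", "species", "pathways"),
                               ...) {
  view <- match.arg(view)
  have <- list(species = species, pathways = pathways)
  if (view == "both") {
    need <- names(object$views)
    for (v in need) {
      if (is.null(have[[v]])) {
        stop("view '", v, "' is required for ensemble prediction; ",
             "pass view='", setdiff(need, v)[1] %||% v,
             "' for the single-view fallback")
      }
    }
    Z <- do.call(cbind, lapply(need, function(v) {
      base_predictions(object, v, have[[v]])
    }))
    co <- object$meta$full$coef
  } else {
    if (is.null(have[[view]])) stop("matrix for view '", view, "' missing")
    if (is.null(object$meta$per_view[[view]])) {
      stop("model has no fitted view '", view, "'")
    }
    Z <- base_predictions(object, view, have[[view]])
    co <- object$meta$per_view[[view]]$coef
  }
  pred <- drop(cbind(1, Z[, names(co)[-1], drop = FALSE]) %*% co)
  unname(pred)
}

#' @export
print.gage_model <- function(x, ...) {
  cat("gage_model: stacked ensemble aging clock\n")
  for (v in names(x$views)) {
    cat("  ", v, ": ", length(x$views[[v]]$learners), " base learners on ",
        x$views[[v]]$n_train, " samples x ",
        length(x$views[[v]]$feature_names), " features\n", sep = "")
  }
  cat("  meta: ", length(x$meta$full$coef) - 1, " weights + intercept (",
      x$manifest$n_paired, " paired samples)\n", sep = "")
  if (length(x$manifest$dropped_learners)) {
    cat("  dropped:", paste(x$manifest$dropped_learners, collapse = ", "),
        "\n")
  }
  invisible(x)
}

#' Repeated k-fold cross-validation of the aging clock
#'
#' Outer folds split the PAIRED samples only; unpaired single-view samples
#' remain in every training pool (they never appear in a test fold). Each
#' fold refits the full ensemble on the training portion and scores the
#' held-out portion. R-squared is 1 - SSE/SST on the held-out samples (can
#' be negative); MAE is in years. Single-view clock metrics (same base
#' predictions, per-view meta weights) are reported alongside.
#'
#' @param profile a [multiview_profile()].
#' @param ages as in [fit_ensemble()].
#' @param repeats,folds cross-validation scheme (default 10 x 5).
#' @param seed integer seed.
#' @param zoo base-learner selection.
#' @return a `cv_result`: `records` (one row per repeat x fold),
#'   `predictions` (paired samples x repeats out-of-fold gAge), `summary`.
#' @export
evaluate_cv <- function(profile, ages, repeats = 10L, folds = 5L,
                        seed = 1L, zoo = default_zoo()) {
  ages <- resolve_ages(ages, profile$sample_ids)
  pids <- paired_ids(profile)
  if (folds > length(pids)) stop("more folds than paired samples")
  views <- names(which(!vapply(list(species = profile$species,
                                    pathways = profile$pathways),
                               is.null, logical(1))))
  records <- list()
  preds <- matrix(NA_real_, length(pids), repeats,
                  dimnames = list(pids, NULL))
  for (r in seq_len(repeats)) {
    assign_r <- fold_assignments(length(pids), folds,
                                 seed = derive_seed(seed, 50L + r))
    for (k in seq_len(folds)) {
      test_ids <- pids[assign_r == k]
      train_prof <- subset_profile(profile, setdiff(profile$sample_ids,
                                                    test_ids))
      fit <- fit_ensemble(train_prof, ages, zoo = zoo,
                          seed = derive_seed(seed, 100L * r + k))
      sp_te <- if (!is.null(profile$species))
        profile$species[test_ids, , drop = FALSE]
      pw_te <- if (!is.null(profile$pathways))
        profile$pathways[test_ids, , drop = FALSE]
      y_te <- ages[test_ids]
      p_ens <- predict(fit, species = sp_te, pathways = pw_te)
      preds[test_ids, r] <- p_ens
      row <- data.frame(repeat_id = r, fold = k, n_test = length(test_ids),
                        r2 = r_squared(y_te, p_ens),
                        mae = mean(abs(y_te - p_ens)))
      for (v in views) {
        pv <- predict(fit, species = sp_te, pathways = pw_te, view = v)
        row[[paste0("r2_", v)]] <- r_squared(y_te, pv)
        row[[paste0("mae_", v)]] <- mean(abs(y_te - pv))
      }
      records[[length(records) + 1L]] <- row
    }
  }
  records <- do.call(rbind, records)
  metric_cols <- setdiff(colnames(records), c("repeat_id", "fold", "n_test"))
  summary <- data.frame(metric = metric_cols,
                        mean = vapply(records[metric_cols], mean, numeric(1)),
                        sd = vapply(records[metric_cols], stats::sd,
                                    numeric(1)),
                        row.names = NULL)
  structure(list(records = records, predictions = preds, summary = summary,
                 scheme = c(repeats = repeats, folds = folds), seed = seed),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat("cv_result:", x$scheme[["repeats"]], "x", x$scheme[["folds"]],
      "cross-validation,", nrow(x$records), "fold records\n")
  print(x$summary, digits = 3)
  invisible(x)
}

r_squared <- function(y, pred) {
  1 - sum((y - pred)^2) / sum((y - mean(y))^2)
}

subset_profile <- function(profile, keep_ids) {
  multiview_profile(
    species = if (!is.null(profile$species)) {
      ids <- intersect(rownames(profile$species), keep_ids)
      if (length(ids)) profile$species[ids, , drop = FALSE] else NULL
    },
    pathways = if (!is.null(profile$pathways)) {
      ids <- intersect(rownames(profile$pathways), keep_ids)
      if (length(ids)) profile$pathways[ids, , drop = FALSE] else NULL
    },
    normalize = FALSE)
}

#' Unpaired-sample benchmark
#'
#' Holds the paired sample count fixed and grows the number of
#' pathway-only training samples along a grid, recording the ensemble and
#' the single-pathway-view cross-validated R-squared at each point. The
#' grid point 0 is the paired-only baseline; for a given seed the fold
#' split is identical across grid points, so differences along the grid
#' are attributable to the added unpaired samples alone.
#'
#' @param config a [simulation_config()] used as the template (its
#'   `n_paired` and `n_unpaired_pathway` are overridden).
#' @param n_paired_fixed paired samples held fixed.
#' @param unpaired_grid nondecreasing grid of added pathway-only counts,
#'   starting at 0.
#' @param n_seeds replicate simulations (default 5).
#' @param folds cross-validation folds per point.
#' @param zoo base-learner selection.
#' @param seed master seed.
#' @return an `unpaired_curve`: `records` (seed x grid point) and `summary`
#'   (per grid point mean/sd of ensemble and single-pathway R-squared).
#' @export
unpaired_experiment <- function(config = simulation_config(),
                                n_paired_fixed = 300L,
                                unpaired_grid = c(0L, 300L, 900L),
                                n_seeds = 5L, folds = 5L,
                                zoo = default_zoo(), seed = 1L) {
  unpaired_grid <- as.integer(unpaired_grid)
  if (is.unsorted(unpaired_grid) || any(unpaired_grid < 0)) {
    stop("unpaired_grid must be nondecreasing and nonnegative")
  }
  if (unpaired_grid[1] != 0) stop("unpaired_grid must start at 0")
  records <- list()
  for (s in seq_len(n_seeds)) {
    cfg <- config
    cfg$n_paired <- as.integer(n_paired_fixed)
    cfg$n_unpaired_pathway <- max(unpaired_grid)
    cfg$seed <- derive_seed(seed, 7000L + s)
    sim <- simulate_profiles(cfg)
    prof <- sim$profile
    unpaired_ids <- names(prof$pairing)[prof$pairing == "pathway_only"]
    eval_seed <- derive_seed(seed, 8000L + s)
    for (g in unpaired_grid) {
      if (g > length(unpaired_ids)) {
        stop("grid point ", g, " exceeds available unpaired samples")
      }
      keep <- c(paired_ids(prof), utils::head(unpaired_ids, g))
      cv <- evaluate_cv(subset_profile(prof, keep), sim$metadata,
                        repeats = 1L, folds = folds, seed = eval_seed,
                        zoo = zoo)
      records[[length(records) + 1L]] <- data.frame(
        seed = s, n_unpaired = g,
        r2_ensemble = mean(cv$records$r2),
        r2_pathway_only = mean(cv$records$r2_pathways),
        r2_species_only = mean(cv$records$r2_species),
        mae_ensemble = mean(cv$records$mae))
    }
  }
  records <- do.call(rbind, records)
  summary <- do.call(rbind, lapply(split(records, records$n_unpaired),
    function(d) data.frame(n_unpaired = d$n_unpaired[1],
                           r2_ensemble_mean = mean(d$r2_ensemble),
                           r2_ensemble_sd = stats::sd(d$r2_ensemble),
                           r2_pathway_only_mean = mean(d$r2_pathway_only),
                           r2_species_only_mean = mean(d$r2_species_only))))
  rownames(summary) <- NULL
  structure(list(records = records, summary = summary,
                 n_paired = n_paired_fixed, seed = seed),
            class = "unpaired_curve")
}

#' @export
print.unpaired_curve <- function(x, ...) {
  cat("unpaired_curve:", x$n_paired, "fixed paired samples\n")
  print(x$summary, digits = 3)
  invisible(x)
}

#' Univariate and model-embedded feature selection
#'
#' @param x samples x features matrix.
#' @param y numeric response (age).
#' @param method scoring method: univariate linear-regression F statistic,
#'   plug-in mutual information on equal-frequency bins, absolute Pearson
#'   or Spearman correlation, or embedded importance from a random forest
#'   or gradient-boosted model.
#' @param k number of features to keep.
#' @param seed seed for the stochastic scorers.
#' @return integer indices of the top-k features (score-descending, ties
#'   by index); constant features score 0.
#' @export
feature_select <- function(x, y,
                           method = c("f_regression", "mutual_information",
                                      "pearson", "spearman",
                                      "rf_importance", "gbt_importance"),
                           k, seed = 1L) {
  method <- match.arg(method)
  x <- as.matrix(x)
  if (k < 1) stop("k must be >= 1")
  if (k > ncol(x)) {
    warning("k exceeds feature count; returning all features")
    k <- ncol(x)
  }
  constant <- apply(x, 2, function(col) stats::sd(col) == 0)
  score <- switch(method,
    f_regression = {
      r <- suppressWarnings(stats::cor(x, y))
      r[is.na(r)] <- 0
      n <- nrow(x)
      drop((n - 2) * r^2 / pmax(1 - r^2, 1e-12))
    },
    mutual_information = apply(x, 2, mutual_information_binned, y = y),
    pearson = {
      r <- suppressWarnings(stats::cor(x, y))
      r[is.na(r)] <- 0
      abs(drop(r))
    },
    spearman = {
      r <- suppressWarnings(stats::cor(x, y, method = "spearman"))
      r[is.na(r)] <- 0
      abs(drop(r))
    },
    rf_importance = {
      colnames(x) <- colnames(x) %||% paste0("f", seq_len(ncol(x)))
      rf <- ranger::ranger(x = x, y = y, num.trees = 300, num.threads = 1,
                           importance = "impurity", seed = seed)
      rf$variable.importance
    },
    gbt_importance = {
      cn <- colnames(x) %||% paste0("f", seq_len(ncol(x)))
      colnames(x) <- cn
      m <- xgboost::xgboost(x, y, nrounds = 80, max_depth = 3,
                            learning_rate = 0.1, nthreads = 1,
                            seed = seed, verbosity = 0)
      imp <- xgboost::xgb.importance(model = m)
      sc <- stats::setNames(rep(0, ncol(x)), cn)
      sc[imp$Feature] <- imp$Gain
      sc
    })
  score <- as.numeric(score)
  score[constant] <- 0
  order(-score, seq_along(score))[seq_len(k)]
}

# plug-in mutual information after equal-frequency discretization
mutual_information_binned <- function(col, y, bins = 8L) {
  if (stats::sd(col) == 0) return(0)
  bx <- cut(rank(col, ties.method = "first"), bins, labels = FALSE)
  by <- cut(rank(y, ties.method = "first"), bins, labels = FALSE)
  tab <- table(bx, by) / length(col)
  px <- rowSums(tab); py <- colSums(tab)
  nz <- tab > 0
  sum(tab[nz] * log(tab[nz] / outer(px, py)[nz]))
}
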