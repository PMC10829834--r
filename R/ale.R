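#' Accumulated local effects of one feature on predicted age
#'
#' First-order ALE on the ensemble's full prediction path: the feature's
#' empirical quantiles (duplicate edges collapsed, so a zero-inflated
#' feature's zero mass forms the first bin) define intervals; the local
#' effect of interval k is the mean, over the samples falling in it, of the
#' prediction difference when the feature is moved from the interval's
#' lower to its upper edge, everything else held at the sample's own
#' values. Local effects are accumulated by running sum and centered so
#' the sample-weighted mean effect is zero; each sample's effect is the
#' centered curve linearly interpolated at its own feature value.
#'
#' @param model a `gage_model`; ignored when `predict_fn` is supplied.
#' @param species,pathways matrices of the evaluation samples (paired
#'   samples of the training study, typically).
#' @param view `"species"` or `"pathways"`: the view holding the feature.
#' @param feature column name or index within the view.
#' @param n_intervals target number of quantile intervals (default 40,
#'   reduced automatically to the number of distinct values).
#' @param predict_fn optional prediction contract
#'   `function(species, pathways) -> years`, substituting for the model
#'   (used for closed-form oracle checks).
#' @return an `ale_result`: `grid` (interval edges), `effects` (centered
#'   accumulated effect in years at each edge), `per_sample_effect`
#'   (named, years), `mean_abs_effect`, `prevalence`, `direction`,
#'   `bin_counts`.
#' @export
compute_ale <- function(model = NULL, species = NULL, pathways = NULL,
                        view = c("species", "pathways"), feature,
                        n_intervals = 40L, predict_fn = NULL) {
  view <- match.arg(view)
  if (is.null(predict_fn)) {
    if (is.null(model)) stop("either a model or a predict_fn is required")
    predict_fn <- function(sp, pw) predict(model, species = sp, pathways = pw)
  }
  X <- if (view == "species") species else pathways
  if (is.null(X)) stop("matrix for view '", view, "' missing")
  X <- as.matrix(X)
  j <- if (is.character(feature)) match(feature, colnames(X)) else feature
  if (is.na(j) || j < 1 || j > ncol(X)) stop("unknown feature: ", feature)
  xj <- X[, j]
  pair_fn <- function(lo_vals, hi_vals) {
    mod <- function(vals) {
      Xm <- X
      Xm[, j] <- vals
      if (view == "species") predict_fn(Xm, pathways) else
        predict_fn(species, Xm)
    }
    list(lo = mod(lo_vals), hi = mod(hi_vals))
  }
  res <- ale_core(xj, pair_fn, n_intervals)
  finalize_ale(res, view = view,
               feature = colnames(X)[j] %||% as.character(j), xj = xj)
}

# shared ALE arithmetic: grid construction, local effects, accumulation,
# per-sample centering
ale_core <- function(xj, pair_fn, n_intervals) {
  grid <- unique(stats::quantile(xj, probs = seq(0, 1,
                                                 length.out = n_intervals + 1),
                                 names = FALSE, type = 7))
  n <- length(xj)
  if (length(grid) < 2) {
    return(list(grid = grid, acc = rep(0, length(grid)),
                raw = rep(0, n), bin_counts = n, degenerate = TRUE))
  }
  bin <- findInterval(xj, grid, rightmost.closed = TRUE, left.open = TRUE)
  bin[bin == 0] <- 1L
  k_max <- length(grid) - 1L
  pr <- pair_fn(grid[bin], grid[bin + 1L])
  diffs <- pr$hi - pr$lo
  local <- vapply(seq_len(k_max), function(k) {
    inb <- bin == k
    if (any(inb)) mean(diffs[inb]) else 0
  }, numeric(1))
  acc <- c(0, cumsum(local))
  raw <- stats::approx(grid, acc, xout = xj, rule = 2)$y
  list(grid = grid, acc = acc, raw = raw,
       bin_counts = tabulate(bin, k_max), degenerate = FALSE)
}

finalize_ale <- function(core, view, feature, xj) {
  center <- mean(core$raw)
  per_sample <- core$raw - center
  names(per_sample) <- names(xj)
  out <- list(view = view, feature = feature,
              grid = core$grid,
              effects = core$acc - center,
              per_sample_effect = per_sample,
              mean_abs_effect = mean(abs(per_sample)),
              prevalence = mean(xj > 0),
              bin_counts = core$bin_counts,
              feature_values = xj,
              degenerate = isTRUE(core$degenerate))
  class(out) <- "ale_result"
  out$direction <- classify_direction(out)
  out
}

#' @export
print.ale_result <- function(x, ...) {
  cat(sprintf("ale_result: %s / %s\n", x$view, x$feature))
  cat(sprintf("  mean |effect| %.4f years, prevalence %.3f, direction %s\n",
              x$mean_abs_effect, x$prevalence, x$direction))
  invisible(x)
}

#' Classify the direction of a feature's effect on the clock
#'
#' Fits the least-squares slope of the per-sample centered effect against
#' the feature value: positive slope = "accelerated" (more abundance, older
#' prediction), negative = "mitigated". A feature is "nonmonotone" when the
#' accumulated curve reverses - its local effects carry both signs and the
#' minority sign accounts for at least `reversal_fraction` of the total
#' (sample-weighted) absolute effect movement; this is the
#' rising-then-falling pattern reported for some branched-chain amino-acid
#' degradation pathways, where low abundance accelerates the clock and
#' high abundance mitigates it. All-zero effects give "null".
#'
#' @param ale an `ale_result`.
#' @param reversal_fraction minority-mass threshold (default 0.25).
#' @return one of "accelerated", "mitigated", "nonmonotone", "null".
#' @export
classify_direction <- function(ale, reversal_fraction = 0.25) {
  e <- ale$per_sample_effect
  x <- ale$feature_values
  if (all(abs(e) < 1e-12)) return("null")
  d <- diff(ale$effects)                 # local effect per interval
  w <- ale$bin_counts
  up_mass <- sum(w * pmax(d, 0))
  down_mass <- sum(w * pmax(-d, 0))
  total <- up_mass + down_mass
  if (total > 0 && min(up_mass, down_mass) / total >= reversal_fraction) {
    return("nonmonotone")
  }
  slope <- stats::cov(x, e) / max(stats::var(x), 1e-300)
  if (slope > 0) "accelerated" else if (slope < 0) "mitigated" else "nonmonotone"
}

#' ALE for every feature of a view, batched
#'
#' Computes [compute_ale()] for all (or selected) features of one view.
#' The other view's contribution to the ensemble prediction is cached once
#' - modifying a species feature never changes the pathway base-model
#' predictions - and modified-feature predictions are evaluated in stacked
#' chunks, so the cost is two ensemble passes per feature over the
#' evaluation samples.
#'
#' @param model a `gage_model`.
#' @param species,pathways evaluation-sample matrices (both views).
#' @param view the view to interpret.
#' @param features optional column names/indices (default: all).
#' @param n_intervals quantile intervals per feature.
#' @param chunk_size features per stacked prediction batch.
#' @return list of `ale_result`, named by feature.
#' @export
ale_all_features <- function(model, species, pathways,
                             view = c("species", "pathways"),
                             features = NULL, n_intervals = 40L,
                             chunk_size = 16L) {
  view <- match.arg(view)
  other <- setdiff(c("species", "pathways"), view)
  X <- as.matrix(if (view == "species") species else pathways)
  n <- nrow(X)
  co <- model$meta$full$coef
  # cached contribution of the unmodified view + intercept
  fixed <- rep(co[["(Intercept)"]], n)
  if (other %in% names(model$views)) {
    Zo <- base_predictions(model, other,
                           if (other == "species") species else pathways)
    cols <- intersect(colnames(Zo), names(co))
    fixed <- fixed + drop(Zo[, cols, drop = FALSE] %*% co[cols])
  }
  co_v <- co[grep(paste0("^", view, "\\."), names(co), value = TRUE)]
  predict_modified <- function(Xm) {
    Zv <- base_predictions(model, view, Xm)
    fixed_rep <- rep_len(fixed, nrow(Xm))
    drop(Zv[, names(co_v), drop = FALSE] %*% co_v) + fixed_rep
  }

  if (is.null(features)) features <- seq_len(ncol(X))
  if (is.character(features)) features <- match(features, colnames(X))
  out <- vector("list", length(features))
  names(out) <- colnames(X)[features] %||% as.character(features)
  for (start in seq(1, length(features), by = chunk_size)) {
    idx <- features[start:min(start + chunk_size - 1L, length(features))]
    # per-feature grids and bin assignments
    pre <- lapply(idx, function(j) {
      xj <- X[, j]
      grid <- unique(stats::quantile(xj,
                                     probs = seq(0, 1,
                                                 length.out = n_intervals + 1),
                                     names = FALSE, type = 7))
      if (length(grid) < 2) return(list(degenerate = TRUE, grid = grid))
      bin <- findInterval(xj, grid, rightmost.closed = TRUE,
                          left.open = TRUE)
      bin[bin == 0] <- 1L
      list(degenerate = FALSE, grid = grid, bin = bin)
    })
    live <- which(!vapply(pre, `[[`, logical(1), "degenerate"))
    if (length(live)) {
      stacked <- do.call(rbind, lapply(live, function(ii) {
        j <- idx[ii]; p <- pre[[ii]]
        Xlo <- X; Xlo[, j] <- p$grid[p$bin]
        Xhi <- X; Xhi[, j] <- p$grid[p$bin + 1L]
        rbind(Xlo, Xhi)
      }))
      preds <- predict_modified(stacked)
      offset <- 0L
      for (ii in live) {
        j <- idx[ii]; p <- pre[[ii]]
        lo <- preds[offset + seq_len(n)]
        hi <- preds[offset + n + seq_len(n)]
        offset <- offset + 2L * n
        k_max <- length(p$grid) - 1L
        diffs <- hi - lo
        local <- vapply(seq_len(k_max), function(k) {
          inb <- p$bin == k
          if (any(inb)) mean(diffs[inb]) else 0
        }, numeric(1))
        acc <- c(0, cumsum(local))
        raw <- stats::approx(p$grid, acc, xout = X[, j], rule = 2)$y
        core <- list(grid = p$grid, acc = acc, raw = raw,
                     bin_counts = tabulate(p$bin, k_max),
                     degenerate = FALSE)
        out[[which(features == j)]] <-
          finalize_ale(core, view, colnames(X)[j] %||% as.character(j),
                       X[, j])
      }
    }
    for (ii in setdiff(seq_along(idx), live)) {
      j <- idx[ii]
      core <- list(grid = pre[[ii]]$grid, acc = rep(0, length(pre[[ii]]$grid)),
                   raw = rep(0, n), bin_counts = n, degenerate = TRUE)
      out[[which(features == j)]] <-
        finalize_ale(core, view, colnames(X)[j] %||% as.character(j), X[, j])
    }
  }
  out
}

#' Threshold ALE results into a directional marker set
#'
#' A feature is a potential age-specific marker when its mean absolute
#' per-sample effect exceeds `effect_threshold` (default 0.083 years - a
#' predicted-age deviation of about one month) and it is present (nonzero)
#' in at least `prevalence_threshold` of the samples (default 1%).
#' Features with direction "null" are excluded.
#'
#' @param ale_results list of `ale_result` (e.g. from
#'   [ale_all_features()]), possibly spanning both views.
#' @param effect_threshold years (default 0.083).
#' @param prevalence_threshold fraction (default 0.01).
#' @return a `marker_set`: data.frame `markers` with columns `view`,
#'   `feature`, `mean_abs_effect`, `prevalence`, `direction` ranked by
#'   effect (ties by feature name), plus the thresholds used.
#' @export
rank_and_select <- function(ale_results, effect_threshold = 0.083,
                            prevalence_threshold = 0.01) {
  df <- do.call(rbind, lapply(ale_results, function(a) {
    data.frame(view = a$view, feature = a$feature,
               mean_abs_effect = a$mean_abs_effect,
               prevalence = a$prevalence,
               direction = a$direction, stringsAsFactors = FALSE)
  }))
  rownames(df) <- NULL
  keep <- df$mean_abs_effect > effect_threshold &
    df$prevalence >= prevalence_threshold & df$direction != "null"
  markers <- df[keep, , drop = FALSE]
  markers <- markers[order(-markers$mean_abs_effect, markers$feature), ,
                     drop = FALSE]
  rownames(markers) <- NULL
  structure(list(markers = markers, all_features = df,
                 effect_threshold = effect_threshold,
                 prevalence_threshold = prevalence_threshold),
            class = "marker_set")
}

#' @export
print.marker_set <- function(x, ...) {
  cat("marker_set:", nrow(x$markers), "markers (|effect| >",
      x$effect_threshold, "years, prevalence >=",
      x$prevalence_threshold, ")\n")
  tab <- table(x$markers$view, x$markers$direction)
  if (nrow(x$markers)) print(tab)
  invisible(x)
}

#' Per-sample effect matrix for exported beeswarm-style plots
#'
#' @param ale_results list of `ale_result` over one sample set.
#' @return samples x features matrix of centered per-sample effects
#'   (years).
#' @export
ale_effect_matrix <- function(ale_results) {
  m <- vapply(ale_results, `[[`, numeric(length(ale_results[[1]]$per_sample_effect)),
              "per_sample_effect")
  colnames(m) <- vapply(ale_results, `[[`, character(1), "feature")
  m
}
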