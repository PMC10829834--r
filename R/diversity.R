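#' Per-sample alpha diversity
#'
#' Richness is the count of strictly positive features; Shannon entropy is
#' computed on the row renormalized to sum 1, in natural-log units by
#' default. All-zero rows get richness 0 and Shannon 0 with a warning.
#'
#' @param x samples x features nonnegative abundance matrix.
#' @param base logarithm base for Shannon (default `exp(1)`, nats).
#' @return data.frame with `sample_id`, `richness`, `shannon`.
#' @export
alpha_diversity <- function(x, base = exp(1)) {
  x <- as.matrix(x)
  if (any(x < 0)) stop("abundances must be nonnegative")
  rs <- rowSums(x)
  if (any(rs == 0)) warning(sum(rs == 0), " all-zero sample row(s)")
  xn <- x / ifelse(rs == 0, 1, rs)
  data.frame(
    sample_id = rownames(x) %||% as.character(seq_len(nrow(x))),
    richness = as.integer(rowSums(x > 0)),
    shannon = vegan::diversity(xn, index = "shannon", base = base),
    row.names = NULL
  )
}

#' Spearman trend of a per-sample quantity against age
#'
#' @param values numeric per-sample values (e.g. Shannon index).
#' @param ages chronological ages, same length.
#' @return list with `rho` and `p_value`.
#' @export
age_trend <- function(values, ages) {
  ct <- suppressWarnings(stats::cor.test(values, ages, method = "spearman"))
  list(rho = unname(ct$estimate), p_value = ct$p.value)
}

#' Bray-Curtis distance matrix
#'
#' d(u, v) = sum |u - v| / sum (u + v); the distance between two all-zero
#' samples is defined as 0 (with a warning).
#'
#' @param x samples x features nonnegative abundance matrix.
#' @return symmetric matrix with zero diagonal, entries in \[0, 1\].
#' @export
bray_curtis <- function(x) {
  x <- as.matrix(x)
  if (any(x < 0)) stop("abundances must be nonnegative")
  zero_rows <- rowSums(x) == 0
  d <- as.matrix(suppressWarnings(vegan::vegdist(x, method = "bray")))
  if (any(zero_rows)) {
    warning("distance between all-zero samples set to 0")
    d[is.na(d)] <- 0
  }
  diag(d) <- 0
  d
}

#' Confounder-adjusted PERMANOVA (Adonis)
#'
#' Sequential (type-I) partitioning of a distance matrix over ordered
#' covariates with confounders entered first and the variable of interest
#' last, using free permutations of sample labels. Covariates observed in
#' fewer than `min_presence` of the samples are excluded before fitting;
#' the remaining samples are complete-case.
#'
#' @param d distance matrix (or `dist`) over samples.
#' @param metadata data.frame aligned with the rows of `d`.
#' @param confounders character vector of confounder column names, in entry
#'   order (may be empty).
#' @param variable character, the covariate of interest (entered last).
#' @param n_permutations permutation count (default 999).
#' @param seed integer RNG seed for the permutations.
#' @param min_presence minimum fraction of non-missing values a covariate
#'   needs to enter the model (default 0.5).
#' @return data.frame with columns `term`, `df`, `sum_of_squares`,
#'   `pseudo_F`, `R2`, `p_value`; attribute `n_permutations`.
#' @export
permanova_adjusted <- function(d, metadata, confounders = character(),
                               variable, n_permutations = 999, seed = 1L,
                               min_presence = 0.5) {
  d <- as.matrix(d)
  n <- nrow(d)
  if (n != nrow(metadata)) stop("distance matrix and metadata disagree on n")
  terms <- c(confounders, variable)
  missing_cols <- setdiff(terms, colnames(metadata))
  if (length(missing_cols)) {
    stop("covariates absent from metadata: ",
         paste(missing_cols, collapse = ", "))
  }
  presence <- vapply(terms, function(v) mean(!is.na(metadata[[v]])),
                     numeric(1))
  dropped <- terms[presence < min_presence]
  if (variable %in% dropped) {
    stop("variable of interest '", variable, "' observed in under ",
         round(min_presence * 100), "% of samples")
  }
  terms <- setdiff(terms, dropped)
  keep <- stats::complete.cases(metadata[, terms, drop = FALSE])
  if (sum(keep) < 3) stop("fewer than 3 complete-case samples")
  md <- metadata[keep, terms, drop = FALSE]
  v <- md[[variable]]
  if (length(unique(v[!is.na(v)])) < 2) {
    stop("variable of interest '", variable, "' is constant")
  }
  dd <- stats::as.dist(d[keep, keep])
  form <- stats::as.formula(paste("dd ~", paste(terms, collapse = " + ")))
  restore <- rng_local(seed)
  on.exit(restore())
  fit <- vegan::adonis2(form, data = md, permutations = n_permutations,
                        by = "terms")
  out <- data.frame(term = rownames(fit),
                    df = fit$Df,
                    sum_of_squares = fit$SumOfSqs,
                    pseudo_F = fit$F,
                    R2 = fit$R2,
                    p_value = fit$`Pr(>F)`,
                    row.names = NULL)
  attr(out, "n_permutations") <- n_permutations
  attr(out, "dropped_covariates") <- dropped
  out
}

#' Per-feature Spearman correlation with age
#'
#' @param x samples x features abundance matrix.
#' @param ages chronological ages aligned with rows.
#' @return data.frame with `feature`, `rho`, `p_value`, `q_value`
#'   (Benjamini-Hochberg across the view's features) and a `note` column;
#'   constant features get `NA` rho with a note.
#' @export
feature_age_correlation <- function(x, ages) {
  x <- as.matrix(x)
  if (nrow(x) < 3) stop("need at least 3 samples")
  res <- apply(x, 2, function(col) {
    if (stats::sd(col) == 0) return(c(NA_real_, NA_real_))
    ct <- suppressWarnings(stats::cor.test(col, ages, method = "spearman"))
    c(unname(ct$estimate), ct$p.value)
  })
  out <- data.frame(
    feature = colnames(x) %||% as.character(seq_len(ncol(x))),
    rho = res[1, ],
    p_value = res[2, ],
    row.names = NULL
  )
  out$q_value <- stats::p.adjust(out$p_value, method = "BH")
  out$note <- ifelse(is.na(out$rho), "constant feature", "")
  out
}

#' Two-dimensional embedding of samples (UMAP wiring)
#'
#' Thin wire to the umap-learn backend, invoked through the `python`
#' executable on the PATH; the embedding algorithm itself is external. The
#' input may be a precomputed symmetric distance matrix (e.g. from
#' [bray_curtis()]) or a raw samples x features matrix (embedded with the
#' Euclidean metric).
#'
#' @param x distance matrix or feature matrix.
#' @param method only "umap" is wired.
#' @param seed integer `random_state` for the backend; fixing it makes the
#'   embedding deterministic.
#' @param n_neighbors UMAP neighbourhood size (capped at n - 1).
#' @return samples x 2 coordinate matrix.
#' @export
embed_2d <- function(x, method = "umap", seed = 42L, n_neighbors = 15L) {
  method <- match.arg(method, "umap")
  x <- as.matrix(x)
  precomputed <- nrow(x) == ncol(x) && isTRUE(all.equal(x, t(x))) &&
    all(diag(x) == 0)
  n_neighbors <- min(as.integer(n_neighbors), nrow(x) - 1L)
  py <- Sys.which("python")
  if (py == "") {
    stop("embed_2d requires a 'python' executable with umap-learn on PATH")
  }
  fin <- tempfile(fileext = ".tsv"); fout <- tempfile(fileext = ".tsv")
  on.exit(unlink(c(fin, fout)), add = TRUE)
  utils::write.table(x, fin, sep = "\t", row.names = FALSE,
                     col.names = FALSE)
  script <- paste(
    "import sys, numpy as np",
    "try:",
    "    import umap",
    "except Exception as e:",
    "    sys.stderr.write('umap-learn unavailable: %s' % e); sys.exit(3)",
    "x = np.loadtxt(sys.argv[1])",
    "metric = 'precomputed' if sys.argv[4] == '1' else 'euclidean'",
    "emb = umap.UMAP(n_components=2, metric=metric,",
    "                random_state=int(sys.argv[2]),",
    "                n_neighbors=int(sys.argv[3])).fit_transform(x)",
    "np.savetxt(sys.argv[5], emb, delimiter='\\t')",
    sep = "\n")
  status <- system2(py, c("-c", shQuote(script), shQuote(fin), seed,
                          n_neighbors, as.integer(precomputed),
                          shQuote(fout)),
                    stdout = FALSE, stderr = tempfile())
  if (status != 0 || !file.exists(fout)) {
    stop("UMAP backend failed (is python with umap-learn available?)")
  }
  coords <- as.matrix(utils::read.delim(fout, header = FALSE))
  if (!all(is.finite(coords))) stop("UMAP backend returned non-finite coordinates")
  rownames(coords) <- rownames(x)
  colnames(coords) <- c("UMAP1", "UMAP2")
  coords
}

`%||%` <- function(a, b) if (is.null(a)) b else a
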