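#' Two-view microbiome profile container
#'
#' Holds species and metabolic-pathway relative-abundance matrices for a
#' (possibly partially overlapping) set of samples, together with a
#' per-sample pairing mask. Abundances are stored as fractions summing to 1
#' per sample row; readers convert from percentage tables.
#'
#' @param species samples x features matrix of species relative abundances,
#'   or `NULL`; rownames are sample ids.
#' @param pathways samples x features matrix of pathway relative abundances,
#'   or `NULL`; rownames are sample ids.
#' @param normalize renormalize rows to sum to 1 (default TRUE).
#' @return an object of class `multiview_profile` with elements
#'   `sample_ids`, `species`, `pathways`, `species_features`,
#'   `pathway_features` and `pairing` (named character vector with values
#'   `"paired"`, `"species_only"` or `"pathway_only"`).
#' @export
multiview_profile <- function(species = NULL, pathways = NULL,
                              normalize = TRUE) {
  if (is.null(species) && is.null(pathways)) {
    stop("at least one view must be supplied")
  }
  check_view <- function(m, what) {
    if (is.null(m)) return(NULL)
    m <- as.matrix(m)
    storage.mode(m) <- "double"
    if (is.null(rownames(m))) stop(what, " matrix must carry sample ids as rownames")
    if (any(m < 0)) stop(what, " abundances must be nonnegative")
    if (normalize) m <- renormalize_rows(m)
    m
  }
  species <- check_view(species, "species")
  pathways <- check_view(pathways, "pathways")
  sp_ids <- rownames(species)
  pw_ids <- rownames(pathways)
  ids <- union(sp_ids, pw_ids)
  pairing <- ifelse(ids %in% sp_ids & ids %in% pw_ids, "paired",
                    ifelse(ids %in% sp_ids, "species_only", "pathway_only"))
  names(pairing) <- ids
  structure(list(sample_ids = ids,
                 species = species,
                 pathways = pathways,
                 species_features = colnames(species),
                 pathway_features = colnames(pathways),
                 pairing = pairing),
            class = "multiview_profile")
}

#' @export
print.multiview_profile <- function(x, ...) {
  tab <- table(factor(x$pairing, c("paired", "species_only", "pathway_only")))
  cat("multiview_profile:", length(x$sample_ids), "samples\n")
  cat("  species view: ",
      if (is.null(x$species)) "absent" else
        paste0(nrow(x$species), " x ", ncol(x$species)), "\n", sep = "")
  cat("  pathway view: ",
      if (is.null(x$pathways)) "absent" else
        paste0(nrow(x$pathways), " x ", ncol(x$pathways)), "\n", sep = "")
  cat("  pairing: ", tab[["paired"]], " paired, ",
      tab[["species_only"]], " species-only, ",
      tab[["pathway_only"]], " pathway-only\n", sep = "")
  invisible(x)
}

#' Samples carrying both views
#' @param profile a [multiview_profile()].
#' @return character vector of paired sample ids, in profile order.
#' @export
paired_ids <- function(profile) {
  names(profile$pairing)[profile$pairing == "paired"]
}

renormalize_rows <- function(m, warn_zero = TRUE) {
  rs <- rowSums(m)
  zero <- rs <= 0
  if (any(zero) && warn_zero) {
    warning(sum(zero), " all-zero sample row(s) retained as zeros")
  }
  rs[zero] <- 1
  m / rs
}

#' Prevalence/abundance feature filter
#'
#' Keeps features that are nonzero in at least `min_prevalence` of samples
#' and whose mean relative abundance is at least `min_mean_abundance`.
#' Rows are deliberately NOT renormalized afterwards: the result is a
#' sub-composition of the original profile, so retained abundances remain
#' comparable across filter settings.
#'
#' @param x samples x features abundance matrix.
#' @param min_prevalence fraction in \[0,1\]; default 0 (keep all).
#' @param min_mean_abundance fraction in \[0,1\]; default 0.
#' @return list with `matrix` (filtered) and `kept` (integer indices).
#' @export
filter_features <- function(x, min_prevalence = 0, min_mean_abundance = 0) {
  stopifnot(min_prevalence >= 0, min_prevalence <= 1,
            min_mean_abundance >= 0, min_mean_abundance <= 1)
  x <- as.matrix(x)
  prev <- colMeans(x > 0)
  mab <- colMeans(x)
  kept <- which(prev >= min_prevalence & mab >= min_mean_abundance)
  if (length(kept) == 0) {
    stop("feature filter removed every feature (min_prevalence=",
         min_prevalence, ", min_mean_abundance=", min_mean_abundance, ")")
  }
  list(matrix = x[, kept, drop = FALSE], kept = unname(kept))
}
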