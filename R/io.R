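#' Read a merged MetaPhlAn-style species table
#'
#' Expects a tab-delimited table whose first column holds pipe-delimited
#' taxonomy clades (`k__...|p__...|...|s__...`) and whose remaining columns
#' are samples, with abundances in percent. Only rows at the requested
#' taxonomic rank are retained; percentages are divided by 100 and each
#' sample is renormalized to sum 1.
#'
#' @param path TSV file path.
#' @param taxonomic_rank one of kingdom, phylum, class, order, family,
#'   genus, species (default), strain.
#' @return list with `matrix` (samples x features, fractions),
#'   `feature_names` and `sample_ids`.
#' @export
read_species_table <- function(path, taxonomic_rank = "species") {
  prefixes <- c(kingdom = "k__", phylum = "p__", class = "c__",
                order = "o__", family = "f__", genus = "g__",
                species = "s__", strain = "t__")
  taxonomic_rank <- match.arg(taxonomic_rank, names(prefixes))
  raw <- read_profile_tsv(path, what = "species table")
  ids <- raw$sample_ids
  clades <- raw$feature_names
  last <- vapply(strsplit(clades, "|", fixed = TRUE),
                 function(p) p[[length(p)]], character(1))
  known <- substr(last, 1, 3) %in% unname(prefixes)
  if (any(!known)) {
    stop("unrecognized clade prefix in rows: ",
         paste(utils::head(clades[!known], 3), collapse = ", "))
  }
  keep <- startsWith(last, prefixes[[taxonomic_rank]])
  if (!any(keep)) stop("no rows at rank '", taxonomic_rank, "' in ", path)
  m <- raw$values[keep, , drop = FALSE] / 100
  out <- t(m)
  rownames(out) <- ids
  colnames(out) <- clades[keep]
  out <- renormalize_rows(out)
  list(matrix = out, feature_names = clades[keep], sample_ids = ids)
}

#' Read a merged HUMAnN-style pathway table
#'
#' Drops stratified rows (pathway|taxon, containing `|`) and optionally the
#' UNMAPPED/UNINTEGRATED rows, then renormalizes each sample to sum 1.
#' A sample left all-zero after filtering is retained as a zero row with a
#' warning.
#'
#' @param path TSV file path.
#' @param drop_unmapped drop UNMAPPED and UNINTEGRATED rows (default TRUE).
#' @return list with `matrix` (samples x features, fractions),
#'   `feature_names` and `sample_ids`.
#' @export
read_pathway_table <- function(path, drop_unmapped = TRUE) {
  raw <- read_profile_tsv(path, what = "pathway table")
  feats <- raw$feature_names
  keep <- !grepl("|", feats, fixed = TRUE)
  if (drop_unmapped) {
    base <- sub(":.*$", "", feats)
    keep <- keep & !(base %in% c("UNMAPPED", "UNINTEGRATED"))
  }
  if (!any(keep)) stop("no community-level pathway rows left in ", path)
  out <- t(raw$values[keep, , drop = FALSE])
  rownames(out) <- raw$sample_ids
  colnames(out) <- feats[keep]
  out <- renormalize_rows(out)
  list(matrix = out, feature_names = feats[keep], sample_ids = raw$sample_ids)
}

# shared TSV scaffold for the two merged-profile dialects
read_profile_tsv <- function(path, what) {
  if (!file.exists(path)) stop(what, " not found: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, comment.char = "",
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("malformed ", what, " header in ", path)
  ids <- colnames(df)[-1]
  dup <- ids[duplicated(ids)]
  if (length(dup)) {
    stop("duplicated sample column(s) in ", path, ": ",
         paste(unique(dup), collapse = ", "))
  }
  vals <- as.matrix(df[, -1, drop = FALSE])
  if (is.character(vals)) {
    num <- suppressWarnings(matrix(as.numeric(vals), nrow(vals), ncol(vals)))
    bad <- which(is.na(num) & !is.na(vals) & nzchar(vals), arr.ind = TRUE)
    if (nrow(bad)) {
      stop("non-numeric cell in ", path, " at line ", bad[1, 1] + 1L,
           " (sample ", ids[bad[1, 2]], ")")
    }
    vals <- num
  }
  if (anyNA(vals)) stop("missing abundance values in ", path)
  if (any(vals < 0)) stop("negative abundance values in ", path)
  list(values = vals, feature_names = as.character(df[[1]]), sample_ids = ids)
}

#' Read a sample metadata table
#'
#' Tab-delimited with a header row; must contain `sample_id` and `age`
#' columns. Empty strings and `NA` are treated as missing, never as zero.
#'
#' @param path TSV file path.
#' @return data.frame with one row per sample.
#' @export
read_metadata <- function(path) {
  md <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE,
                          na.strings = c("NA", ""))
  if (!all(c("sample_id", "age") %in% colnames(md))) {
    stop("metadata must contain 'sample_id' and 'age' columns")
  }
  if (anyDuplicated(md$sample_id)) {
    stop("duplicated sample_id in metadata: ",
         md$sample_id[duplicated(md$sample_id)][1])
  }
  if (any(md$age < 0 | md$age > 130, na.rm = TRUE)) {
    stop("ages outside [0, 130] in metadata")
  }
  md
}

#' Assemble a two-view profile and align it with metadata
#'
#' Samples present in both views are flagged paired; samples in exactly one
#' view are flagged species_only / pathway_only. Samples carrying a profile
#' but no metadata row are excluded and listed in the `rejects` attribute.
#'
#' @param species species reader result (list with `matrix`) or a matrix
#'   with sample rownames, or `NULL`.
#' @param pathways pathway reader result or matrix, or `NULL`.
#' @param metadata data.frame with a `sample_id` column, or `NULL` to skip
#'   the metadata join.
#' @return a [multiview_profile()]; when metadata is supplied the matched
#'   rows are attached as attribute `metadata` and excluded profile samples
#'   as attribute `rejects`.
#' @export
assemble_multiview <- function(species = NULL, pathways = NULL,
                               metadata = NULL) {
  as_mat <- function(x) {
    if (is.null(x)) return(NULL)
    if (is.list(x) && !is.null(x$matrix)) x$matrix else as.matrix(x)
  }
  sp <- as_mat(species)
  pw <- as_mat(pathways)
  prof <- multiview_profile(species = sp, pathways = pw)
  if (length(paired_ids(prof)) == 0 && !is.null(sp) && !is.null(pw)) {
    warning("no paired samples: the two views share no sample ids ",
            "(meta-learning will be impossible)")
  }
  if (!is.null(metadata)) {
    missing <- setdiff(prof$sample_ids, metadata$sample_id)
    if (length(missing)) {
      warning(length(missing),
              " profiled sample(s) without metadata excluded: ",
              paste(utils::head(missing, 5), collapse = ", "))
      keep <- setdiff(prof$sample_ids, missing)
      prof <- multiview_profile(
        species = if (!is.null(prof$species))
          prof$species[intersect(rownames(prof$species), keep), , drop = FALSE],
        pathways = if (!is.null(prof$pathways))
          prof$pathways[intersect(rownames(prof$pathways), keep), , drop = FALSE],
        normalize = FALSE)
    }
    md <- metadata[match(prof$sample_ids, metadata$sample_id), , drop = FALSE]
    rownames(md) <- NULL
    attr(prof, "metadata") <- md
    attr(prof, "rejects") <- missing
  }
  prof
}

#' Write merged profile tables in the dialects the readers accept
#'
#' `write_species_table()` emits a MetaPhlAn-style percentage table (clades
#' as rows); `write_pathway_table()` a HUMAnN-style percentage table;
#' `write_metadata()` a plain TSV.
#'
#' @param x samples x features fraction matrix (with sample rownames) or a
#'   metadata data.frame.
#' @param path output TSV path.
#' @return the path, invisibly.
#' @export
write_species_table <- function(x, path) {
  write_profile_tsv(x, path, first_col = "clade_name")
}

#' @rdname write_species_table
#' @export
write_pathway_table <- function(x, path) {
  write_profile_tsv(x, path, first_col = "# Pathway")
}

#' @rdname write_species_table
#' @export
write_metadata <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

write_profile_tsv <- function(x, path, first_col) {
  m <- t(as.matrix(x)) * 100
  df <- data.frame(feature = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1] <- first_col
  colnames(df)[-1] <- rownames(x)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
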