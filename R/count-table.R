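#' @useDynLib fecology, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

TAX_RANKS <- c("kingdom", "phylum", "class", "order", "family", "genus", "species")

#' Sentinel for missing taxonomic assignment
#'
#' Ranks that could not be assigned carry this sentinel rather than an empty
#' string, so rank-based filters are unambiguous.
#' @export
UNASSIGNED <- "UNASSIGNED"

#' Validate and construct a taxa-by-sample count table
#'
#' The count table is the central object of the package: a numeric matrix of
#' non-negative integer read counts with taxa as rows and samples as columns
#' (the usual amplicon feature-table orientation).
#'
#' @param counts numeric matrix, taxa x samples, with unique row and column
#'   names, all entries non-negative integers.
#' @return the validated matrix (storage mode double, integer-valued).
#' @export
count_table <- function(counts) {
  if (!is.matrix(counts) || !is.numeric(counts))
    stop("counts must be a numeric matrix")
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have taxon row names and sample column names")
  if (anyDuplicated(rownames(counts)))
    stop("duplicate taxon ids: ",
         paste(unique(rownames(counts)[duplicated(rownames(counts))]), collapse = ", "))
  if (anyDuplicated(colnames(counts)))
    stop("duplicate sample ids: ",
         paste(unique(colnames(counts)[duplicated(colnames(counts))]), collapse = ", "))
  if (anyNA(counts)) stop("counts contain NA")
  bad <- which(counts < 0 | counts != round(counts), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf("negative or non-integer count at taxon '%s', sample '%s'",
                 rownames(counts)[bad[1, 1]], colnames(counts)[bad[1, 2]]))
  storage.mode(counts) <- "double"
  counts
}

#' Read a taxa-by-sample count table
#'
#' TSV tables have taxon ids in the first column and sample ids in the header.
#' BIOM (v1/v2) files are read through the biomformat package.
#'
#' @param path file path.
#' @param format `"tsv"` or `"biom"`.
#' @return a validated count table matrix (taxa x samples).
#' @export
read_count_table <- function(path, format = c("tsv", "biom")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "biom") {
    if (!requireNamespace("biomformat", quietly = TRUE))
      stop("reading BIOM files requires the biomformat package")
    b <- biomformat::read_biom(path)
    m <- as(biomformat::biom_data(b), "matrix")
    return(count_table(m))
  }
  df <- utils::read.delim(path, check.names = FALSE, colClasses = "character")
  if (ncol(df) < 2) stop("count table needs a taxon id column plus >= 1 sample")
  taxa <- df[[1]]
  samples <- colnames(df)[-1]
  raw <- as.matrix(df[, -1, drop = FALSE])
  num <- suppressWarnings(array(as.numeric(raw), dim = dim(raw)))
  bad <- which(is.na(num) | num < 0 | num != round(num), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf("invalid count '%s' at taxon '%s', sample '%s'",
                 raw[bad[1, 1], bad[1, 2]], taxa[bad[1, 1]], samples[bad[1, 2]]))
  dimnames(num) <- list(taxa, samples)
  count_table(num)
}

#' Write a count table as TSV
#' @param ct count table matrix.
#' @param path output path.
#' @export
write_count_table <- function(ct, path) {
  ct <- count_table(ct)
  df <- data.frame(taxon_id = rownames(ct), ct, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read sample metadata (sample_id, host, site)
#'
#' Host and site jointly define a population (all plants of one host sampled
#' at one site).
#' @param path TSV with columns `sample_id`, `host`, `site`.
#' @return data.frame with those three character columns.
#' @export
read_sample_metadata <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, colClasses = "character")
  sample_metadata(df)
}

#' Validate sample metadata
#' @param df data.frame with columns `sample_id`, `host`, `site`.
#' @export
sample_metadata <- function(df) {
  need <- c("sample_id", "host", "site")
  miss <- setdiff(need, colnames(df))
  if (length(miss) > 0)
    stop("metadata is missing column(s): ", paste(miss, collapse = ", "))
  df <- as.data.frame(df)[, need]
  for (k in need) df[[k]] <- as.character(df[[k]])
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample ids in metadata")
  df
}

#' Population (host x site) labels for samples
#' @param meta sample metadata.
#' @return character vector named by sample id, `"host@site"`.
#' @export
population_labels <- function(meta) {
  meta <- sample_metadata(meta)
  stats::setNames(paste(meta$host, meta$site, sep = "@"), meta$sample_id)
}

#' Validate a taxonomy table
#'
#' Seven ranks kingdom..species; an unassigned rank carries the
#' [UNASSIGNED] sentinel, and everything below an unassigned rank must be
#' unassigned too.
#' @param df data.frame with columns `taxon_id` and the seven ranks.
#' @export
taxonomy_table <- function(df) {
  need <- c("taxon_id", TAX_RANKS)
  miss <- setdiff(need, colnames(df))
  if (length(miss) > 0)
    stop("taxonomy is missing column(s): ", paste(miss, collapse = ", "))
  df <- as.data.frame(df)[, need]
  for (k in need) df[[k]] <- as.character(df[[k]])
  if (anyDuplicated(df$taxon_id)) stop("duplicate taxon ids in taxonomy")
  if (any(df == "" | is.na(df)))
    stop("empty taxonomy entries; use the UNASSIGNED sentinel")
  for (i in seq_len(length(TAX_RANKS) - 1)) {
    hi <- df[[TAX_RANKS[i]]]; lo <- df[[TAX_RANKS[i + 1]]]
    bad <- hi == UNASSIGNED & lo != UNASSIGNED
    if (any(bad))
      stop("rank ", TAX_RANKS[i + 1], " assigned below unassigned ",
           TAX_RANKS[i], " for taxon ", df$taxon_id[which(bad)[1]])
  }
  df
}

#' Read a taxonomy TSV (taxon_id + 7 rank columns)
#' @param path file path.
#' @export
read_taxonomy <- function(path) {
  taxonomy_table(utils::read.delim(path, check.names = FALSE,
                                   colClasses = "character"))
}

#' Write a taxonomy TSV
#' @param tax taxonomy data.frame.
#' @param path output path.
#' @export
write_taxonomy <- function(tax, path) {
  utils::write.table(taxonomy_table(tax), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Hellinger transform of a count table
#'
#' Per sample j: value(i,j) = sqrt(count(i,j) / total(j)), so the squared
#' values of each sample sum to one. Down-weights dominant taxa ahead of
#' Bray-Curtis / ordination.
#'
#' @param ct count table.
#' @return matrix of the same shape with attribute `transform = "hellinger"`.
#' @export
hellinger_transform <- function(ct) {
  ct <- count_table(ct)
  tot <- colSums(ct)
  if (any(tot == 0))
    stop("zero-total sample(s): ", paste(colnames(ct)[tot == 0], collapse = ", "))
  out <- sqrt(sweep(ct, 2, tot, "/"))
  attr(out, "transform") <- "hellinger"
  out
}

#' Per-sample relative abundances
#' @param ct count table.
#' @export
relative_abundance <- function(ct) {
  ct <- count_table(ct)
  tot <- colSums(ct)
  if (any(tot == 0))
    stop("zero-total sample(s): ", paste(colnames(ct)[tot == 0], collapse = ", "))
  out <- sweep(ct, 2, tot, "/")
  attr(out, "transform") <- "relative"
  out
}

#' Presence/absence (incidence) matrix of a count table
#' @param ct count table.
#' @return 0/1 matrix of the same shape.
#' @export
to_incidence <- function(ct) {
  ct <- count_table(ct)
  out <- (ct > 0) * 1
  dimnames(out) <- dimnames(ct)
  out
}

#' Write a labelled square distance matrix as TSV
#' @param dm symmetric matrix with zero diagonal, values in \[0, 1\].
#' @param path output path.
#' @export
write_distance_matrix <- function(dm, path) {
  dm <- validate_distance_matrix(dm)
  df <- data.frame(id = rownames(dm),
                   format(dm, digits = 12, scientific = FALSE, trim = TRUE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a labelled square distance matrix from TSV
#' @param path file path.
#' @export
read_distance_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- as.character(df[[1]])
  validate_distance_matrix(m)
}

validate_distance_matrix <- function(dm, tol = 1e-12) {
  if (!is.matrix(dm) || nrow(dm) != ncol(dm))
    stop("distance matrix must be square")
  if (is.null(rownames(dm))) stop("distance matrix must be labelled")
  if (!identical(rownames(dm), colnames(dm)))
    stop("row and column labels disagree")
  if (anyNA(dm)) stop("distance matrix contains NA")
  if (max(abs(dm - t(dm))) > tol) stop("distance matrix is asymmetric")
  if (any(abs(diag(dm)) > tol)) stop("distance matrix has a nonzero diagonal")
  if (any(dm < -tol) || any(dm > 1 + 1e-9))
    stop("distances must lie in [0, 1]")
  dm <- (dm + t(dm)) / 2
  diag(dm) <- 0
  dm
}
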