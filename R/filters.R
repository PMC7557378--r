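#' Agglomerate taxa with identical species-level assignments
#'
#' All taxa sharing an identical full seven-rank assignment down to species
#' are summed into one taxon named after the species. Taxa unassigned at
#' species rank are kept as separate original taxa (their identity cannot be
#' established). Read totals are conserved.
#'
#' @param ct count table.
#' @param tax taxonomy covering every taxon in `ct`.
#' @return list with elements `counts` (agglomerated count table) and
#'   `taxonomy` (one row per surviving taxon).
#' @export
agglomerate_species <- function(ct, tax) {
  ct <- count_table(ct)
  tax <- taxonomy_table(tax)
  miss <- setdiff(rownames(ct), tax$taxon_id)
  if (length(miss) > 0)
    stop("taxonomy does not cover taxa: ", paste(utils::head(miss, 3), collapse = ", "))
  tax <- tax[match(rownames(ct), tax$taxon_id), ]
  assigned <- tax$species != UNASSIGNED
  lineage <- do.call(paste, c(tax[TAX_RANKS], sep = "|"))
  # unassigned-at-species taxa keep their own identity
  key <- ifelse(assigned, lineage, paste0("__asv__", tax$taxon_id))
  newct <- rowsum(ct, group = key, reorder = FALSE)
  first <- !duplicated(key)
  newtax <- tax[first, ]
  newid <- ifelse(assigned[first], newtax$species, newtax$taxon_id)
  # disambiguate homonymous species names from different lineages
  if (anyDuplicated(newid)) newid <- make.unique(newid, sep = " #")
  rownames(newct) <- newid
  newtax$taxon_id <- newid
  rownames(newtax) <- NULL
  list(counts = count_table(newct), taxonomy = newtax)
}

filter_report <- function(step, removed, remaining, reads_removed, reads_total) {
  data.frame(step = step,
             items_removed = removed,
             items_remaining = remaining,
             fraction_of_reads_removed = if (reads_total > 0) reads_removed / reads_total else 0,
             stringsAsFactors = FALSE)
}

#' Drop samples with sparse reads
#'
#' Removes samples whose total read count is strictly below `min_reads`
#' (default 1000, the usual sparse-library floor).
#'
#' @param ct count table.
#' @param min_reads minimum total reads a sample must reach to be kept.
#' @return list(counts, report) where report is a one-row data.frame.
#' @export
filter_samples_min_reads <- function(ct, min_reads = 1000) {
  ct <- count_table(ct)
  stopifnot(min_reads >= 0)
  tot <- colSums(ct)
  keep <- tot >= min_reads
  if (!any(keep)) stop("all samples fall below ", min_reads, " reads")
  rep <- filter_report("sample_min_reads", sum(!keep), sum(keep),
                       sum(tot[!keep]), sum(tot))
  list(counts = ct[, keep, drop = FALSE], report = rep)
}

#' Rarity filter presets
#'
#' * `singleton_doubleton`: drop taxa with < 3 total reads (whole-dataset
#'   singletons and doubletons).
#' * `core`: drop taxa present in < 5 samples (prevalence filter defining the
#'   core dataset).
#' * `beta`: drop taxa with < 3 reads or present in < 5 samples (input for
#'   dissimilarity-based analyses).
#' @export
rare_taxon_presets <- list(
  singleton_doubleton = c(min_total_reads = 3, min_incidence = 0),
  core                = c(min_total_reads = 0, min_incidence = 5),
  beta                = c(min_total_reads = 3, min_incidence = 5)
)

#' Drop rare taxa by total reads and/or incidence
#'
#' A taxon is removed when its total read count is below `min_total_reads`
#' or its incidence (number of samples with >= 1 read) is below
#' `min_incidence`. Idempotent at fixed thresholds.
#'
#' @param ct count table.
#' @param min_total_reads keep taxa with total reads >= this.
#' @param min_incidence keep taxa with incidence >= this.
#' @param preset optional name from [rare_taxon_presets] overriding the two
#'   thresholds.
#' @return list(counts, report).
#' @export
filter_rare_taxa <- function(ct, min_total_reads = 0, min_incidence = 0,
                             preset = NULL) {
  ct <- count_table(ct)
  if (!is.null(preset)) {
    preset <- match.arg(preset, names(rare_taxon_presets))
    p <- rare_taxon_presets[[preset]]
    min_total_reads <- p[["min_total_reads"]]
    min_incidence <- p[["min_incidence"]]
  }
  stopifnot(min_total_reads >= 0, min_incidence >= 0)
  tot <- rowSums(ct)
  inc <- rowSums(ct > 0)
  keep <- tot >= min_total_reads & inc >= min_incidence
  rep <- filter_report(
    if (is.null(preset)) "rare_taxa" else paste0("rare_taxa_", preset),
    sum(!keep), sum(keep), sum(tot[!keep]), sum(tot))
  list(counts = ct[keep, , drop = FALSE], report = rep)
}

#' Partition taxa by the set of groups they occur in
#'
#' Every taxon is assigned to the subset of groups (hosts by default) in
#' which it has at least one read; read shares are computed against the grand
#' total of `reference` (default: `ct` itself), so shares of a filtered core
#' table can be expressed relative to the full dataset.
#'
#' @param ct count table (e.g. the core dataset).
#' @param meta sample metadata.
#' @param by metadata column defining the groups.
#' @param reference count table whose grand total defines the read shares.
#' @return data.frame: subset label (group names joined by `+`), n_taxa,
#'   reads, read_share.
#' @export
venn_partition <- function(ct, meta, by = "host", reference = ct) {
  ct <- count_table(ct)
  meta <- sample_metadata(meta)
  if (!all(colnames(ct) %in% meta$sample_id))
    stop("metadata does not cover all samples")
  grp <- meta[[by]][match(colnames(ct), meta$sample_id)]
  groups <- sort(unique(grp))
  if (length(groups) < 2) stop("need >= 2 groups")
  pres <- sapply(groups, function(g)
    rowSums(ct[, grp == g, drop = FALSE] > 0) > 0)
  present_any <- rowSums(pres) > 0
  if (any(!present_any))
    warning(sum(!present_any), " taxa with zero reads excluded from partition")
  pres <- pres[present_any, , drop = FALSE]
  subset_lab <- apply(pres, 1, function(z) paste(groups[z], collapse = "+"))
  ref <- count_table(reference)
  ref_tot <- sum(ref)
  out <- do.call(rbind, lapply(split(rownames(pres), subset_lab), function(tx) {
    reads <- sum(ref[intersect(tx, rownames(ref)), , drop = FALSE])
    data.frame(subset = NA_character_, n_taxa = length(tx), reads = reads,
               read_share = reads / ref_tot, stringsAsFactors = FALSE)
  }))
  out$subset <- names(split(rownames(pres), subset_lab))
  rownames(out) <- NULL
  out[order(-nchar(out$subset), out$subset), c("subset", "n_taxa", "reads", "read_share")]
}

#' Rank taxa by median transformed abundance, with a per-taxon host ANOVA
#'
#' Orders taxa by decreasing median abundance across all samples (ties broken
#' by mean, then taxon id) and tests host differences per taxon with a
#' one-way ANOVA on the transformed abundances. Significance stars follow the
#' usual 0.05 / 0.01 / 0.001 coding.
#'
#' @param at abundance matrix (e.g. Hellinger-transformed), taxa x samples.
#' @param meta sample metadata.
#' @param top_n number of taxa to report.
#' @return list(summary, values): `summary` has one row per reported taxon
#'   (median, mean, anova_p, stars); `values` is long-format per-sample data
#'   for those taxa.
#' @export
rank_abundance_summary <- function(at, meta, top_n = 18) {
  meta <- sample_metadata(meta)
  if (top_n > nrow(at)) stop("top_n exceeds the number of taxa")
  host <- meta$host[match(colnames(at), meta$sample_id)]
  med <- apply(at, 1, stats::median)
  mn <- rowMeans(at)
  ord <- order(-med, -mn, rownames(at))
  top <- ord[seq_len(top_n)]
  pvals <- vapply(top, function(i) {
    v <- at[i, ]
    if (stats::var(v) < 1e-300 || length(unique(host)) < 2) return(1)
    stats::anova(stats::lm(v ~ factor(host)))[["Pr(>F)"]][1]
  }, numeric(1))
  stars <- ifelse(pvals < 0.001, "***",
           ifelse(pvals < 0.01, "**",
           ifelse(pvals < 0.05, "*", "")))
  summary <- data.frame(taxon_id = rownames(at)[top],
                        median_abundance = med[top],
                        mean_abundance = mn[top],
                        anova_p = pvals, stars = stars,
                        rank = seq_len(top_n),
                        stringsAsFactors = FALSE)
  rownames(summary) <- NULL
  values <- data.frame(
    taxon_id = rep(rownames(at)[top], each = ncol(at)),
    sample_id = rep(colnames(at), times = top_n),
    host = rep(host, times = top_n),
    abundance = as.vector(t(at[top, , drop = FALSE])),
    stringsAsFactors = FALSE)
  list(summary = summary, values = values)
}

#' Class-level relative abundance composition
#'
#' Relative read abundance summed by taxonomic class, per population
#' (host x site) and per host. Classes outside the overall top `top_k` are
#' pooled as `"Other"`; the UNASSIGNED class is always reported as its own
#' category.
#'
#' @param ct count table.
#' @param tax taxonomy.
#' @param meta sample metadata.
#' @param top_k number of named classes to keep.
#' @return data.frame: level ("host"|"population"), group, class, share.
#' @export
class_composition <- function(ct, tax, meta, top_k = 12) {
  ct <- count_table(ct)
  tax <- taxonomy_table(tax)
  meta <- sample_metadata(meta)
  cls <- tax$class[match(rownames(ct), tax$taxon_id)]
  if (anyNA(cls)) stop("taxonomy does not cover all taxa")
  bycls <- rowsum(ct, group = cls)
  tot <- rowSums(bycls)
  named <- setdiff(names(sort(tot, decreasing = TRUE)), UNASSIGNED)
  keep <- utils::head(named, top_k)
  lab <- rownames(bycls)
  lab[!(lab %in% c(keep, UNASSIGNED))] <- "Other"
  bycls <- rowsum(bycls, group = lab)

  share_of <- function(cols) {
    s <- rowSums(bycls[, cols, drop = FALSE])
    s / sum(s)
  }
  pop <- population_labels(meta)[colnames(ct)]
  host <- meta$host[match(colnames(ct), meta$sample_id)]
  rows <- list()
  for (h in sort(unique(host))) {
    sh <- share_of(host == h)
    rows[[length(rows) + 1]] <- data.frame(level = "host", group = h,
                                           class = names(sh), share = unname(sh))
  }
  for (p in sort(unique(pop))) {
    sh <- share_of(pop == p)
    rows[[length(rows) + 1]] <- data.frame(level = "population", group = p,
                                           class = names(sh), share = unname(sh))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
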