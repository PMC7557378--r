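#' Sampling design of the three-host wheat endophyte survey
#'
#' The field design the package's examples and synthetic preset emulate: a
#' bread-wheat crop (TA) and two wild wheat relatives (AS, TD) sampled across
#' nine named sites, with the number of plants collected per population and
#' the number of samples retained for analysis after quality control and the
#' 1000-read library floor.
#'
#' @return data.frame (site, host, samples_retained, plants_collected).
#' @export
fec_survey_design <- function() {
  d <- rbind(
    c("ArsufGaash",     "AS", 29, 44), c("Zikkim",         "AS", 41, 42),
    c("Palmachim",      "AS", 37, 40), c("Netanya",        "AS", 43, 44),
    c("Almagor",        "TD", 34, 42), c("Eliad",          "TD", 37, 42),
    c("RamotMenache",   "TD", 44, 44),
    c("ArsufGaash",     "TA", 37, 42), c("Palmachim",      "TA", 42, 43),
    c("Almagor",        "TA", 30, 43), c("Eliad",          "TA", 39, 44),
    c("RamotMenache",   "TA", 42, 42), c("Karmiya",        "TA", 34, 42),
    c("HaderaElyachin", "TA", 41, 42))
  out <- data.frame(site = d[, 1], host = d[, 2],
                    samples_retained = as.integer(d[, 3]),
                    plants_collected = as.integer(d[, 4]),
                    stringsAsFactors = FALSE)
  out
}

#' Taxon bookkeeping of the survey dataset
#'
#' Taxon counts after the successive preparation steps of the survey dataset:
#' species-level agglomeration (with the <1000-read sample filter), removal
#' of whole-dataset singletons and doubletons, and the incidence-below-5
#' rarity filter that defines the core dataset.
#'
#' @return named integer vector: `agglomerated`, `after_singleton_doubleton`,
#'   `rare_low_incidence` (taxa removed by the core prevalence filter).
#' @export
fec_survey_taxon_counts <- function() {
  c(agglomerated = 1687L, after_singleton_doubleton = 1666L,
    rare_low_incidence = 1001L)
}

#' Reported among-population differentiation of the survey
#'
#' The published differentiation summary of the survey dataset, per host and
#' data type: number of populations N, differentiation statistic D, effective
#' number of populations 1D(TM), and its normalised version 1nD(TM). Useful
#' as a worked example for [effective_number()], whose normalisation identity
#' links the last two columns.
#'
#' @return data.frame (host, data_type, N, D, effective, normalized).
#' @export
fec_survey_differentiation <- function() {
  data.frame(
    host = rep(c("AS", "TA", "TD"), 2),
    data_type = rep(c("incidence", "abundance"), each = 3),
    N = rep(c(4L, 7L, 3L), 2),
    D = c(0.125, 0.190, 0.151, 0.314, 0.367, 0.288),
    effective = c(2.637, 4.251, 2.093, 2.138, 3.200, 1.749),
    normalized = c(0.546, 0.542, 0.547, 0.379, 0.367, 0.375),
    stringsAsFactors = FALSE)
}

#' Pipeline configuration
#'
#' Bundles the stage parameters of [run_pipeline()]. Every stochastic stage
#' has an explicit seed derived from `seed`.
#'
#' @param synthetic a [synthetic_config()] used to generate the input data
#'   (alternatively supply `counts`/`metadata`/`taxonomy` paths).
#' @param counts,metadata,taxonomy input file paths (TSV), used when
#'   `synthetic` is NULL.
#' @param min_reads_sample sample read floor.
#' @param q Hill orders for the alpha stage.
#' @param bootstrap_reps bootstrap replicates for the Hill curves.
#' @param n_perm permutations for PERMANOVA/ANOSIM/differentiation.
#' @param alpha_edge significance threshold for co-occurrence edges.
#' @param min_sites minimum populations per combined-network edge.
#' @param d_variant differentiation variant, see [differentiation()].
#' @param seed master seed.
#' @export
pipeline_config <- function(synthetic = NULL, counts = NULL, metadata = NULL,
                            taxonomy = NULL, min_reads_sample = 1000,
                            q = c(0, 1, 2), bootstrap_reps = 50,
                            n_perm = 999, alpha_edge = 0.001, min_sites = 2,
                            d_variant = "partition", seed = 1) {
  if (is.null(synthetic) && (is.null(counts) || is.null(metadata) || is.null(taxonomy)))
    stop("supply either a synthetic config or counts+metadata+taxonomy paths")
  cfg <- list(synthetic = synthetic, counts = counts, metadata = metadata,
              taxonomy = taxonomy, min_reads_sample = min_reads_sample,
              q = q, bootstrap_reps = bootstrap_reps, n_perm = n_perm,
              alpha_edge = alpha_edge, min_sites = min_sites,
              d_variant = d_variant, seed = as.integer(seed))
  class(cfg) <- "pipeline_config"
  cfg
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full analysis pipeline
#'
#' Ingest (or simulate) -> agglomerate -> sample/rarity filters -> taxon
#' partition and composition -> alpha diversity -> beta diversity and group
#' tests -> Kosman dispersion/differentiation -> co-occurrence networks ->
#' manifest. All stage outputs are written as TSV (plus GraphML per host
#' network and a JSON manifest); a rerun with the same config is
#' byte-identical.
#'
#' @param cfg a [pipeline_config()].
#' @param out_dir output directory (created if needed).
#' @return invisible list of in-memory stage results.
#' @export
run_pipeline <- function(cfg, out_dir) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }

  dat <- stage("input", {
    if (!is.null(cfg$synthetic)) generate_community(cfg$synthetic)
    else list(counts = read_count_table(cfg$counts),
              metadata = read_sample_metadata(cfg$metadata),
              taxonomy = read_taxonomy(cfg$taxonomy), truth = NULL)
  })

  agg <- stage("agglomerate", agglomerate_species(dat$counts, dat$taxonomy))
  sf <- stage("sample_filter", filter_samples_min_reads(agg$counts, cfg$min_reads_sample))
  sd <- stage("singleton_doubleton",
              filter_rare_taxa(sf$counts, preset = "singleton_doubleton"))
  core <- stage("core_filter", filter_rare_taxa(sd$counts, preset = "core"))
  meta <- dat$metadata[dat$metadata$sample_id %in% colnames(core$counts), ]
  ledger <- rbind(
    data.frame(step = "agglomerate", items_removed = nrow(dat$counts) - nrow(agg$counts),
               items_remaining = nrow(agg$counts), fraction_of_reads_removed = 0),
    sf$report, sd$report, core$report)
  write_tsv(ledger, file.path(out_dir, "filter_ledger.tsv"))

  venn <- stage("venn", venn_partition(core$counts, meta, reference = sd$counts))
  write_tsv(venn, file.path(out_dir, "venn_partition.tsv"))
  comp <- stage("class_composition",
                class_composition(core$counts, agg$taxonomy, meta))
  write_tsv(comp, file.path(out_dir, "class_composition.tsv"))

  # alpha diversity on the unfiltered (post-sample-filter) table: rare taxa
  # carry the information the richness estimators need
  inc_alpha <- to_incidence(sf$counts)
  rich <- sample_richness(sf$counts, meta)
  write_tsv(rich$samples, file.path(out_dir, "richness_samples.tsv"))
  write_tsv(rich$group_means, file.path(out_dir, "richness_host_means.tsv"))
  div <- stage("alpha", diversity_table(inc_alpha, meta, q = cfg$q))
  write_tsv(div, file.path(out_dir, "diversity_asymptotes.tsv"))
  pops <- population_labels(meta)[colnames(inc_alpha)]
  knots <- list()
  for (p in sort(unique(pops))) for (qq in cfg$q) {
    cur <- hill_curve(inc_alpha, colnames(inc_alpha)[pops == p], q = qq,
                      bootstrap_reps = cfg$bootstrap_reps,
                      seed = cfg$seed + qq)
    cur$population <- p
    cur$q <- qq
    knots[[length(knots) + 1]] <- cur
  }
  knots <- do.call(rbind, knots)
  write_tsv(knots[, c("population", "q", "t", "estimate", "lower", "upper", "regime")],
            file.path(out_dir, "hill_curves.tsv"))

  # beta diversity on the beta-filtered table
  beta_tab <- stage("beta_filter", filter_rare_taxa(sf$counts, preset = "beta"))$counts
  hel <- hellinger_transform(beta_tab)
  bc <- stage("bray_curtis", bray_curtis(hel))
  dc <- stage("dice", dice(to_incidence(beta_tab)))
  write_distance_matrix(bc, file.path(out_dir, "bray_curtis.tsv"))
  write_distance_matrix(dc, file.path(out_dir, "dice.tsv"))
  ord <- stage("pcoa", pcoa(bc, n_axes = 2))
  write_tsv(data.frame(sample_id = rownames(ord$coordinates), ord$coordinates),
            file.path(out_dir, "pcoa_coordinates.tsv"))
  host_of <- meta$host[match(colnames(beta_tab), meta$sample_id)]
  site_of <- meta$site[match(colnames(beta_tab), meta$sample_id)]
  tests <- list()
  for (metric in c("bray", "dice")) {
    dmx <- if (metric == "bray") bc else dc
    for (fac in c("host", "site")) {
      lab <- if (fac == "host") host_of else site_of
      pt <- stage("permanova", permanova(dmx, lab, cfg$n_perm, seed = cfg$seed))
      at <- stage("anosim", anosim(dmx, lab, cfg$n_perm, seed = cfg$seed))
      tests[[length(tests) + 1]] <- data.frame(
        metric = metric, factor = fac,
        permanova_F = pt$statistic, permanova_R2 = pt$R_squared,
        permanova_p = pt$p_value, anosim_R = at$statistic,
        anosim_p = at$p_value, stringsAsFactors = FALSE)
    }
  }
  tests <- do.call(rbind, tests)
  write_tsv(tests, file.path(out_dir, "group_tests.tsv"))

  # Kosman statistics per host on the Dice (incidence) distances
  pops_beta <- population_labels(meta)[colnames(beta_tab)]
  kos_within <- list(); kos_diff <- list()
  for (h in sort(unique(host_of))) {
    idx <- which(host_of == h)
    dmh <- dc[idx, idx, drop = FALSE]
    wv <- stage("kosman_within",
                within_population_variation(dmh, pops_beta[idx]))
    wv$host <- h
    kos_within[[length(kos_within) + 1]] <- wv
    if (length(unique(pops_beta[idx])) >= 2) {
      df <- stage("differentiation",
                  differentiation(dmh, pops_beta[idx], n_perm = cfg$n_perm,
                                  seed = cfg$seed, variant = cfg$d_variant))
      kos_diff[[length(kos_diff) + 1]] <- data.frame(
        host = h, N = df$N, M = df$M, D = df$D, p_value = df$p_value,
        effective = df$effective, normalized = df$normalized,
        stringsAsFactors = FALSE)
    }
  }
  kos_within <- do.call(rbind, kos_within)
  kos_diff <- do.call(rbind, kos_diff)
  write_tsv(kos_within, file.path(out_dir, "kosman_within.tsv"))
  write_tsv(kos_diff, file.path(out_dir, "kosman_differentiation.tsv"))

  # co-occurrence networks per host
  gct <- stage("genus_table", genus_table(core$counts, agg$taxonomy))
  pops_gct <- population_labels(meta)[colnames(gct)]
  host_gct <- meta$host[match(colnames(gct), meta$sample_id)]
  net_summaries <- list(); hubs <- list()
  for (h in sort(unique(host_of))) {
    edges <- list()
    for (p in unique(pops_gct[host_gct == h])) {
      cols <- colnames(gct)[pops_gct == p]
      if (length(cols) >= 5)
        edges[[p]] <- spearman_edges(gct[, cols, drop = FALSE], site = p,
                                     alpha = cfg$alpha_edge)
    }
    if (length(edges) == 0) next
    net <- stage("combine_networks",
                 suppressWarnings(combine_networks(edges, min_sites = cfg$min_sites)))
    write_tsv(net$edges, file.path(out_dir, paste0("network_edges_", h, ".tsv")))
    if (igraph::ecount(net$graph) > 0) {
      igraph::write_graph(net$graph,
                          file.path(out_dir, paste0("network_", h, ".graphml")),
                          format = "graphml")
      ce <- centralities(net)
      write_tsv(ce, file.path(out_dir, paste0("network_vertices_", h, ".tsv")))
      hb <- hub_candidates(net, top_k = 10)
      hb$host <- h
      hubs[[length(hubs) + 1]] <- hb
      ns <- network_summary(net)
      net_summaries[[length(net_summaries) + 1]] <-
        data.frame(host = h, as.data.frame(ns), stringsAsFactors = FALSE)
    }
  }
  if (length(net_summaries) > 0)
    write_tsv(do.call(rbind, net_summaries), file.path(out_dir, "network_summary.tsv"))
  if (length(hubs) > 0)
    write_tsv(do.call(rbind, hubs), file.path(out_dir, "network_hubs.tsv"))

  manifest <- list(
    package = "fecology",
    seed = cfg$seed,
    parameters = cfg[c("min_reads_sample", "q", "bootstrap_reps", "n_perm",
                       "alpha_edge", "min_sites", "d_variant")],
    synthetic_seed = if (!is.null(cfg$synthetic)) cfg$synthetic$seed else NULL,
    n_samples = ncol(core$counts), n_core_taxa = nrow(core$counts),
    outputs = sort(list.files(out_dir)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  invisible(list(ledger = ledger, venn = venn, composition = comp,
                 richness = rich, diversity = div, hill_knots = knots,
                 group_tests = tests, kosman_within = kos_within,
                 kosman_differentiation = kos_diff))
}

#' Markdown summary of a pipeline run
#'
#' @param out_dir directory written by [run_pipeline()].
#' @return character scalar of markdown.
#' @export
pipeline_report <- function(out_dir) {
  rd <- function(f) {
    p <- file.path(out_dir, f)
    if (file.exists(p)) utils::read.delim(p, check.names = FALSE) else NULL
  }
  fmt <- function(df) paste(utils::capture.output(print(df, row.names = FALSE)),
                            collapse = "\n")
  ledger <- rd("filter_ledger.tsv")
  parts <- c("# Community analysis report", "",
             "## Filter ledger", fmt(ledger), "",
             "## Mean richness per host", fmt(rd("richness_host_means.tsv")), "",
             "## Diversity asymptotes", fmt(utils::head(rd("diversity_asymptotes.tsv"), 12)), "",
             "## Group tests", fmt(rd("group_tests.tsv")),
             "", sprintf("Permutation p-values have resolution 1/(n_perm+1)."), "",
             "## Differentiation among populations", fmt(rd("kosman_differentiation.tsv")), "")
  hubs <- rd("network_hubs.tsv")
  parts <- c(parts, "## Network hub candidates",
             if (is.null(hubs)) "No edge survived the minimum-site filter."
             else fmt(hubs), "")
  paste(parts, collapse = "\n")
}
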