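#' Configuration for the synthetic endophyte community generator
#'
#' The generator emulates a post-denoising amplicon dataset from several host
#' species sampled at several sites: a set of core taxa present in every
#' host with log-normal latent abundances shifted by host and site effects, a
#' long tail of sporadic low-abundance taxa occurring independently at low
#' probability, optional host-specific taxa, and optional taxon pairs whose
#' plant-to-plant abundance fluctuations are correlated through a Gaussian
#' copula (targets a Spearman coefficient). Counts are multinomial given a
#' log-normal library size.
#'
#' @param hosts character vector of host species names.
#' @param sites named list mapping each host to its site names; site names
#'   shared between hosts share their site effect (paired sampling).
#' @param plants_per_population plants sampled per host x site population.
#' @param n_core_taxa,n_sporadic_taxa,n_unique_per_host taxon pool sizes.
#' @param core_log_abundance_mean,core_log_abundance_sd latent log-abundance
#'   distribution of core taxa.
#' @param host_effect_sd,site_effect_sd sd of per-taxon log-scale shifts for
#'   host and site; 0 gives exchangeable populations (null model).
#' @param plant_noise_sd sd of the plant-level log-abundance noise.
#' @param sporadic_occurrence_prob per-plant occurrence probability of each
#'   sporadic taxon.
#' @param sporadic_log_abundance latent log abundance of sporadic taxa,
#'   relative to the core mean.
#' @param library_size_meanlog,library_size_sdlog log-normal library sizes.
#' @param n_genera number of genera the taxa are spread over.
#' @param class_mix named probabilities assigning genera to classes.
#' @param prop_species_unassigned,prop_genus_unassigned fractions of taxa
#'   left unassigned at species / genus rank.
#' @param correlated_pairs data.frame with columns `taxon_a`, `taxon_b`
#'   (indices into the core taxa), `rho` (target Spearman, |rho| <= 0.99) and
#'   `sites` (`"all"` or semicolon-separated `host@site` population labels
#'   where the pair is active).
#' @param seed mandatory integer seed.
#' @return a `synthetic_config` list.
#' @export
synthetic_config <- function(hosts = c("hostA", "hostB"),
                             sites = NULL,
                             plants_per_population = 40,
                             n_core_taxa = 60,
                             n_sporadic_taxa = 120,
                             n_unique_per_host = 0,
                             core_log_abundance_mean = 0,
                             core_log_abundance_sd = 1.5,
                             host_effect_sd = 0.4,
                             site_effect_sd = 0.25,
                             plant_noise_sd = 1.0,
                             sporadic_occurrence_prob = 0.05,
                             sporadic_log_abundance = -3,
                             library_size_meanlog = log(2e4),
                             library_size_sdlog = 0.5,
                             n_genera = NULL,
                             class_mix = c(Dothideomycetes = 0.45,
                                           Tremellomycetes = 0.2,
                                           Sordariomycetes = 0.15,
                                           Leotiomycetes = 0.1,
                                           Saccharomycetes = 0.1),
                             prop_species_unassigned = 0.3,
                             prop_genus_unassigned = 0.15,
                             correlated_pairs = NULL,
                             seed) {
  if (missing(seed)) stop("seed is mandatory")
  if (is.null(sites))
    sites <- stats::setNames(rep(list(c("site1", "site2")), length(hosts)), hosts)
  if (!all(hosts %in% names(sites))) stop("sites must name every host")
  if (is.null(n_genera)) n_genera <- max(2L, ceiling(n_core_taxa / 4))
  stopifnot(plants_per_population >= 1, n_core_taxa >= 1,
            sporadic_occurrence_prob >= 0, sporadic_occurrence_prob <= 1,
            prop_species_unassigned >= 0, prop_species_unassigned <= 1,
            prop_genus_unassigned >= 0, prop_genus_unassigned <= 1,
            abs(sum(class_mix) - 1) < 1e-8)
  if (!is.null(correlated_pairs)) {
    stopifnot(is.data.frame(correlated_pairs),
              all(c("taxon_a", "taxon_b", "rho") %in% colnames(correlated_pairs)))
    if (any(abs(correlated_pairs$rho) > 0.99))
      stop("infeasible target rho (|rho| > 0.99)")
    if (is.null(correlated_pairs$sites)) correlated_pairs$sites <- "all"
  }
  cfg <- list(hosts = hosts, sites = sites,
              plants_per_population = plants_per_population,
              n_core_taxa = n_core_taxa, n_sporadic_taxa = n_sporadic_taxa,
              n_unique_per_host = n_unique_per_host,
              core_log_abundance_mean = core_log_abundance_mean,
              core_log_abundance_sd = core_log_abundance_sd,
              host_effect_sd = host_effect_sd, site_effect_sd = site_effect_sd,
              plant_noise_sd = plant_noise_sd,
              sporadic_occurrence_prob = sporadic_occurrence_prob,
              sporadic_log_abundance = sporadic_log_abundance,
              library_size_meanlog = library_size_meanlog,
              library_size_sdlog = library_size_sdlog,
              n_genera = n_genera, class_mix = class_mix,
              prop_species_unassigned = prop_species_unassigned,
              prop_genus_unassigned = prop_genus_unassigned,
              correlated_pairs = correlated_pairs, seed = as.integer(seed))
  class(cfg) <- "synthetic_config"
  cfg
}

#' Configuration mimicking the scale of a three-host wheat endophyte survey
#'
#' Three host species; seven, four and three sites respectively, with the
#' wild hosts paired to a subset of the crop's sites; ~38 plants per
#' population (14 populations, 532 samples); ~1760 taxa of which 400 are
#' core. Defaults include five planted correlated pairs active everywhere.
#'
#' @param seed integer seed.
#' @param plants_per_population plants per population (default 38).
#' @param ... further overrides passed to [synthetic_config()].
#' @export
preset_paper_shape <- function(seed = 1, plants_per_population = 38, ...) {
  sites <- list(
    TA = c("Almagor", "Eliad", "RamotMenache", "ArsufGaash", "Palmachim",
           "Karmiya", "HaderaElyachin"),
    AS = c("ArsufGaash", "Palmachim", "Netanya", "Zikkim"),
    TD = c("Almagor", "Eliad", "RamotMenache"))
  pairs <- data.frame(taxon_a = c(1, 3, 5, 7, 9),
                      taxon_b = c(2, 4, 6, 8, 10),
                      rho = 0.9, sites = "all",
                      stringsAsFactors = FALSE)
  args <- list(hosts = c("TA", "AS", "TD"), sites = sites,
               plants_per_population = plants_per_population,
               n_core_taxa = 400, n_sporadic_taxa = 1300,
               n_unique_per_host = 20,
               core_log_abundance_sd = 4, plant_noise_sd = 3,
               library_size_meanlog = log(8000),
               sporadic_occurrence_prob = 0.05, sporadic_log_abundance = 0,
               correlated_pairs = pairs, seed = seed)
  override <- list(...)
  args[names(override)] <- override
  do.call(synthetic_config, args)
}

# Pearson correlation of the latent Gaussians that yields a target Spearman
# coefficient for a bivariate normal copula.
spearman_to_pearson <- function(rho) 2 * sin(pi * rho / 6)

#' Generate a synthetic community with known ground truth
#'
#' Deterministic under a fixed config seed. Returns the four canonical
#' artifacts plus the ground truth used to plant them.
#'
#' @param cfg a [synthetic_config()].
#' @return list(counts, metadata, taxonomy, truth).
#' @export
generate_community <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  set.seed(cfg$seed)
  hosts <- cfg$hosts
  n_core <- cfg$n_core_taxa
  n_spor <- cfg$n_sporadic_taxa
  n_uniq <- cfg$n_unique_per_host * length(hosts)
  n_taxa <- n_core + n_spor + n_uniq
  taxa <- sprintf("t%05d", seq_len(n_taxa))
  role <- c(rep("core", n_core), rep("sporadic", n_spor),
            rep(paste0("unique:", hosts), each = cfg$n_unique_per_host))
  uniq_host <- ifelse(startsWith(role, "unique:"), sub("^unique:", "", role), NA)

  # latent base abundances (log scale)
  base <- stats::rnorm(n_taxa, cfg$core_log_abundance_mean, cfg$core_log_abundance_sd)
  base[role == "sporadic"] <- cfg$core_log_abundance_mean + cfg$sporadic_log_abundance
  pairs <- cfg$correlated_pairs
  if (!is.null(pairs)) {
    idx <- unique(c(pairs$taxon_a, pairs$taxon_b))
    if (any(idx > n_core)) stop("correlated pairs must index core taxa")
    # make correlated taxa reasonably abundant so count noise does not drown
    # the planted rank correlation
    base[idx] <- cfg$core_log_abundance_mean + 1.5 * cfg$core_log_abundance_sd
  }

  # taxonomy: genera nested in classes, two phyla
  genera <- sprintf("Genus%03d", seq_len(cfg$n_genera))
  classes <- sample(names(cfg$class_mix), cfg$n_genera, replace = TRUE,
                    prob = cfg$class_mix)
  phyla <- ifelse(seq_len(cfg$n_genera) %% 2 == 0, "Ascomycota", "Basidiomycota")
  gidx <- sample.int(cfg$n_genera, n_taxa, replace = TRUE)
  genus <- genera[gidx]
  species <- paste0(genus, " sp", seq_len(n_taxa))
  sp_un <- stats::runif(n_taxa) < cfg$prop_species_unassigned
  gn_un <- stats::runif(n_taxa) < cfg$prop_genus_unassigned
  species[sp_un | gn_un] <- UNASSIGNED
  genus[gn_un] <- UNASSIGNED
  taxonomy <- data.frame(
    taxon_id = taxa, kingdom = "Fungi",
    phylum = phyla[gidx], class = classes[gidx],
    order = paste0(classes[gidx], "ales"),
    family = paste0(genera[gidx], "aceae"),
    genus = genus, species = species, stringsAsFactors = FALSE)
  taxonomy <- taxonomy_table(taxonomy)

  # host and site effects
  host_eff <- matrix(stats::rnorm(n_taxa * length(hosts), 0, cfg$host_effect_sd),
                     n_taxa, length(hosts), dimnames = list(taxa, hosts))
  all_sites <- sort(unique(unlist(cfg$sites)))
  site_eff <- matrix(stats::rnorm(n_taxa * length(all_sites), 0, cfg$site_effect_sd),
                     n_taxa, length(all_sites), dimnames = list(taxa, all_sites))

  pops <- do.call(rbind, lapply(hosts, function(h)
    data.frame(host = h, site = cfg$sites[[h]], stringsAsFactors = FALSE)))
  pops$label <- paste(pops$host, pops$site, sep = "@")

  pair_active <- function(pair_sites, pop_label) {
    pair_sites == "all" || pop_label %in% strsplit(pair_sites, ";")[[1]]
  }

  n_plants <- cfg$plants_per_population
  counts <- matrix(0, n_taxa, nrow(pops) * n_plants)
  sample_ids <- character(nrow(pops) * n_plants)
  meta_rows <- vector("list", nrow(pops))
  col <- 0
  for (pi in seq_len(nrow(pops))) {
    h <- pops$host[pi]; s <- pops$site[pi]
    mu <- base + host_eff[, h] + site_eff[, s]
    active_pairs <- if (is.null(pairs)) NULL else
      pairs[vapply(pairs$sites, pair_active, logical(1), pop_label = pops$label[pi]), ,
            drop = FALSE]
    ids <- sprintf("%s_%s_p%02d", h, s, seq_len(n_plants))
    for (k in seq_len(n_plants)) {
      eps <- stats::rnorm(n_taxa, 0, cfg$plant_noise_sd)
      if (!is.null(active_pairs) && nrow(active_pairs) > 0) {
        for (r in seq_len(nrow(active_pairs))) {
          a <- active_pairs$taxon_a[r]; b <- active_pairs$taxon_b[r]
          rr <- spearman_to_pearson(active_pairs$rho[r])
          z1 <- stats::rnorm(1); z2 <- rr * z1 + sqrt(1 - rr^2) * stats::rnorm(1)
          eps[a] <- z1 * cfg$plant_noise_sd
          eps[b] <- z2 * cfg$plant_noise_sd
        }
      }
      lat <- mu + eps
      w <- exp(lat)
      if (n_spor > 0) {
        occ <- stats::rbinom(n_spor, 1, cfg$sporadic_occurrence_prob)
        w[n_core + seq_len(n_spor)] <- w[n_core + seq_len(n_spor)] * occ
      }
      if (n_uniq > 0) {
        off <- !is.na(uniq_host) & uniq_host != h
        w[off] <- 0
      }
      libsize <- max(1, round(stats::rlnorm(1, cfg$library_size_meanlog,
                                            cfg$library_size_sdlog)))
      col <- col + 1
      counts[, col] <- stats::rmultinom(1, libsize, w / sum(w))
      sample_ids[col] <- ids[k]
    }
    meta_rows[[pi]] <- data.frame(sample_id = ids, host = h, site = s,
                                  stringsAsFactors = FALSE)
  }
  dimnames(counts) <- list(taxa, sample_ids)
  meta <- sample_metadata(do.call(rbind, meta_rows))
  truth <- list(role = stats::setNames(role, taxa),
                base_log_abundance = stats::setNames(base, taxa),
                host_effects = host_eff, site_effects = site_eff,
                correlated_pairs = if (is.null(pairs)) NULL else
                  transform(pairs, id_a = taxa[pairs$taxon_a],
                            id_b = taxa[pairs$taxon_b]),
                genus = stats::setNames(taxonomy$genus, taxa),
                class = stats::setNames(taxonomy$class, taxa),
                config = cfg)
  list(counts = count_table(counts), metadata = meta,
       taxonomy = taxonomy, truth = truth)
}
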