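#' Collapse a count table to genus level
#'
#' Counts are summed within each assigned genus; taxa unassigned at genus
#' rank are dropped entirely.
#'
#' @param ct count table.
#' @param tax taxonomy covering every taxon.
#' @return genus x sample count table.
#' @export
genus_table <- function(ct, tax) {
  ct <- count_table(ct)
  tax <- taxonomy_table(tax)
  gen <- tax$genus[match(rownames(ct), tax$taxon_id)]
  if (anyNA(gen)) stop("taxonomy does not cover all taxa")
  keep <- gen != UNASSIGNED
  if (!any(keep)) stop("no genus-assigned taxa remain")
  count_table(rowsum(ct[keep, , drop = FALSE], group = gen[keep]))
}

#' Spearman co-occurrence edges within one population
#'
#' For every genus pair passing the prevalence floor, the Spearman rank
#' correlation (midranks for ties) across the plants of the population, with
#' a two-sided p-value from the t approximation; records with p < alpha are
#' kept with the sign of rho retained. Genera with zero variance are skipped.
#'
#' @param gct genus-level count table restricted to one population's plants
#'   (>= 5 plants).
#' @param site population label stored on each edge record.
#' @param alpha significance threshold on the raw p-value.
#' @param min_prevalence keep genera present in at least this many plants.
#' @param scale value scale for the correlation: within-sample relative
#'   abundance (default), raw counts, or Hellinger.
#' @return data.frame (genus_a, genus_b, site, rho, p_value), genus_a <
#'   genus_b.
#' @export
spearman_edges <- function(gct, site = "site", alpha = 0.001,
                           min_prevalence = 5,
                           scale = c("relative", "raw", "hellinger")) {
  scale <- match.arg(scale)
  n <- ncol(gct)
  if (n < 5) stop("population needs >= 5 plants")
  x <- switch(scale,
              relative = relative_abundance(gct),
              hellinger = hellinger_transform(gct),
              raw = gct)
  prev <- rowSums(gct > 0)
  x <- x[prev >= min_prevalence, , drop = FALSE]
  keep <- apply(x, 1, function(v) stats::var(v) > 0)
  if (any(!keep))
    message(sum(!keep), " constant gener(a) skipped in ", site)
  x <- x[keep, , drop = FALSE]
  if (nrow(x) < 2)
    return(data.frame(genus_a = character(), genus_b = character(),
                      site = character(), rho = numeric(),
                      p_value = numeric(), stringsAsFactors = FALSE))
  rho <- stats::cor(t(x), method = "spearman")
  ut <- which(upper.tri(rho), arr.ind = TRUE)
  r <- rho[ut]
  r2 <- pmin(r^2, 1 - 1e-15)
  tstat <- r * sqrt((n - 2) / (1 - r2))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  sig <- which(p < alpha)
  out <- data.frame(genus_a = rownames(x)[ut[sig, 1]],
                    genus_b = rownames(x)[ut[sig, 2]],
                    site = rep(site, length(sig)), rho = r[sig],
                    p_value = p[sig], stringsAsFactors = FALSE)
  swap <- out$genus_a > out$genus_b
  tmp <- out$genus_a[swap]
  out$genus_a[swap] <- out$genus_b[swap]
  out$genus_b[swap] <- tmp
  out[order(out$genus_a, out$genus_b), , drop = FALSE]
}

#' Combine per-site edge sets into a per-host network
#'
#' Groups edge records by unordered genus pair, drops pairs detected in
#' fewer than `min_sites` populations (single-site associations are treated
#' as random), and accumulates the significant rho values separately by
#' sign.
#'
#' @param edges data.frame of [spearman_edges()] records from >= 2 sites
#'   (rbind them), or a list of such data.frames.
#' @param min_sites minimum number of populations an association must appear
#'   in.
#' @return object of class `fec_network`: list(edges, graph) where `edges`
#'   has site_count, acc_rho_pos, acc_rho_neg per pair and `graph` is an
#'   igraph graph.
#' @export
combine_networks <- function(edges, min_sites = 2) {
  if (is.list(edges) && !is.data.frame(edges))
    edges <- do.call(rbind, edges)
  if (length(unique(edges$site)) < 2 && nrow(edges) > 0 && min_sites > 1)
    warning("edge records from fewer than 2 sites supplied")
  if (nrow(edges) == 0) {
    comb <- data.frame(genus_a = character(), genus_b = character(),
                       site_count = integer(), acc_rho_pos = numeric(),
                       acc_rho_neg = numeric(), stringsAsFactors = FALSE)
  } else {
    key <- paste(edges$genus_a, edges$genus_b, sep = "\r")
    comb <- do.call(rbind, lapply(split(edges, key), function(e) {
      data.frame(genus_a = e$genus_a[1], genus_b = e$genus_b[1],
                 site_count = length(unique(e$site)),
                 acc_rho_pos = sum(e$rho[e$rho > 0]),
                 acc_rho_neg = sum(e$rho[e$rho < 0]),
                 stringsAsFactors = FALSE)
    }))
    comb <- comb[comb$site_count >= min_sites, , drop = FALSE]
    comb <- comb[order(comb$genus_a, comb$genus_b), , drop = FALSE]
    rownames(comb) <- NULL
  }
  g <- igraph::graph_from_data_frame(comb[, c("genus_a", "genus_b")],
                                     directed = FALSE)
  igraph::E(g)$site_count <- comb$site_count
  igraph::E(g)$acc_rho_pos <- comb$acc_rho_pos
  igraph::E(g)$acc_rho_neg <- comb$acc_rho_neg
  igraph::E(g)$weight_abs <- pmax(comb$acc_rho_pos, abs(comb$acc_rho_neg))
  structure(list(edges = comb, graph = g), class = "fec_network")
}

#' @export
print.fec_network <- function(x, ...) {
  cat("Combined co-occurrence network: ", igraph::vcount(x$graph),
      " genera, ", igraph::ecount(x$graph), " edges\n", sep = "")
  invisible(x)
}

#' Vertex centralities of a combined network
#'
#' Degree, harmonic closeness (well-defined on disconnected graphs),
#' normalised betweenness, and eigenvector centrality computed per connected
#' component (scores of each component scaled by its share of the vertex
#' set). Paths are unweighted.
#'
#' @param net an `fec_network`.
#' @return data.frame (genus, degree, closeness, betweenness, eigenvector).
#' @export
centralities <- function(net) {
  g <- net$graph
  if (igraph::vcount(g) == 0) stop("empty network")
  deg <- igraph::degree(g)
  clo <- igraph::harmonic_centrality(g, normalized = TRUE)
  btw <- igraph::betweenness(g, normalized = TRUE, weights = NA)
  comp <- igraph::components(g)
  eig <- numeric(igraph::vcount(g))
  for (k in seq_len(comp$no)) {
    vs <- which(comp$membership == k)
    sub <- igraph::induced_subgraph(g, vs)
    sc <- if (igraph::vcount(sub) == 1) 1
          else igraph::eigen_centrality(sub, weights = NA)$vector
    eig[vs] <- sc * (comp$csize[k] / igraph::vcount(g))
  }
  data.frame(genus = igraph::V(g)$name, degree = unname(deg),
             closeness = unname(clo), betweenness = unname(btw),
             eigenvector = unname(eig), stringsAsFactors = FALSE)
}

#' Hub (keystone) genus candidates
#'
#' Composite centrality rule: genera are ranked by the sum of their rank by
#' descending degree, rank by descending closeness, and rank by ascending
#' betweenness (low betweenness favoured); ties broken by genus id.
#'
#' @param net an `fec_network`.
#' @param top_k number of candidates to report.
#' @return data.frame of the top_k genera with raw metrics and composite
#'   rank score.
#' @export
hub_candidates <- function(net, top_k = 10) {
  ce <- centralities(net)
  score <- rank(-ce$degree, ties.method = "min") +
    rank(-ce$closeness, ties.method = "min") +
    rank(ce$betweenness, ties.method = "min")
  ce$rank_score <- score
  ce <- ce[order(score, ce$genus), , drop = FALSE]
  utils::head(ce, top_k)
}

#' Whole-network summary statistics
#'
#' Diameter and mean shortest-path distance are computed on the largest
#' connected component; edge density |E| / (|V| (|V|-1) / 2) uses the full
#' vertex set.
#'
#' @param net an `fec_network`.
#' @return list(n_vertices, n_edges, diameter, mean_distance, edge_density).
#' @export
network_summary <- function(net) {
  g <- net$graph
  if (igraph::vcount(g) == 0) stop("empty network")
  comp <- igraph::components(g)
  big <- igraph::induced_subgraph(g, which(comp$membership == which.max(comp$csize)))
  nv <- igraph::vcount(g)
  list(n_vertices = nv,
       n_edges = igraph::ecount(g),
       diameter = igraph::diameter(big, weights = NA),
       mean_distance = igraph::mean_distance(big, weights = NA),
       edge_density = if (nv > 1) igraph::ecount(g) / (nv * (nv - 1) / 2) else 0)
}
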