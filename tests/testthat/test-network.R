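pop_counts <- function(n_genera = 6, n_plants = 10, seed = 1) {
  set.seed(seed)
  m <- matrix(rpois(n_genera * n_plants, 20), n_genera, n_plants,
              dimnames = list(paste0("g", seq_len(n_genera)),
                              paste0("p", seq_len(n_plants))))
  m
}

test_that("genus table sums by genus and drops unassigned genera", {
  m <- matrix(c(3, 5, 2, 0, 1, 1), nrow = 3, byrow = TRUE,
              dimnames = list(c("a1", "a2", "a3"), c("s1", "s2")))
  tax <- tiny_taxonomy(c("a1", "a2", "a3"),
                       species = c("Alternaria infectoria",
                                   "Alternaria alternata", UNASSIGNED))
  gt <- genus_table(m, tax)
  expect_equal(as.vector(gt["Alternaria", ]), c(6, 6))

  tax$genus[3] <- UNASSIGNED; tax$species[3] <- UNASSIGNED
  gt2 <- genus_table(m, tax)
  expect_equal(sum(gt2), sum(m) - sum(m["a3", ]))
  tax$genus <- UNASSIGNED; tax$species <- UNASSIGNED
  expect_error(genus_table(m, tax), "no genus-assigned")
})

test_that("spearman edges keep significant monotone pairs with sign", {
  m <- pop_counts(4, 12, seed = 2)
  m["g1", ] <- 10 * (1:12)          # perfectly increasing
  m["g2", ] <- 5 * (1:12) + 3       # monotone with g1
  e <- spearman_edges(m, site = "sA", alpha = 0.001, scale = "raw")
  hit <- e[e$genus_a == "g1" & e$genus_b == "g2", ]
  expect_equal(nrow(hit), 1)
  expect_equal(hit$rho, 1)
  m["g2", ] <- -m["g2", ] + 100     # perfectly decreasing
  e2 <- spearman_edges(m, site = "sA", alpha = 0.001, scale = "raw")
  expect_equal(e2$rho[e2$genus_a == "g1" & e2$genus_b == "g2"], -1)
  expect_error(spearman_edges(m[, 1:4], site = "x"), ">= 5 plants")
})

test_that("spearman rho equals the midrank formula on a tied example", {
  x <- c(1, 2, 2, 4, 5, 5)
  y <- c(2, 1, 3, 3, 6, 5)
  m <- rbind(g1 = x, g2 = y, g3 = c(9, 1, 4, 7, 2, 8))
  colnames(m) <- paste0("p", 1:6)
  e <- spearman_edges(m, site = "s", alpha = 1.1, min_prevalence = 0,
                      scale = "raw")
  oracle <- stats::cor(rank(x), rank(y))  # midranks by default
  expect_equal(e$rho[e$genus_a == "g1" & e$genus_b == "g2"], oracle,
               tolerance = 1e-12)
})

test_that("constant genera are skipped rather than propagating NA", {
  m <- pop_counts(3, 8, seed = 3)
  m["g3", ] <- 7
  expect_message(e <- spearman_edges(m, site = "s", alpha = 1.1,
                                     min_prevalence = 0, scale = "raw"),
                 "constant")
  expect_false(any(c(e$genus_a, e$genus_b) == "g3"))
  expect_false(anyNA(e$rho))
})

test_that("combined networks enforce the multi-site rule and per-sign accumulation", {
  ed <- data.frame(
    genus_a = c("a", "a", "a", "b", "a"),
    genus_b = c("b", "b", "b", "c", "d"),
    site = c("s1", "s2", "s3", "s1", "s1"),
    rho = c(0.8, 0.9, 0.7, 0.95, 0.9),
    p_value = 1e-5, stringsAsFactors = FALSE)
  net <- suppressWarnings(combine_networks(ed, min_sites = 2))
  expect_equal(nrow(net$edges), 1)           # b-c and a-d are single-site
  expect_equal(net$edges$site_count, 3)
  expect_equal(net$edges$acc_rho_pos, 2.4)
  expect_equal(net$edges$acc_rho_neg, 0)

  mixed <- data.frame(genus_a = "a", genus_b = "b", site = c("s1", "s2"),
                      rho = c(0.8, -0.75), p_value = 1e-5,
                      stringsAsFactors = FALSE)
  nm <- combine_networks(mixed, min_sites = 2)
  expect_equal(nm$edges$acc_rho_pos, 0.8)
  expect_equal(nm$edges$acc_rho_neg, -0.75)
  expect_equal(nm$edges$site_count, 2)
})

test_that("combining is invariant to site order and idempotent", {
  set.seed(5)
  ed <- data.frame(
    genus_a = sample(letters[1:4], 12, replace = TRUE),
    genus_b = sample(letters[5:8], 12, replace = TRUE),
    site = sample(paste0("s", 1:3), 12, replace = TRUE),
    rho = runif(12, -1, 1), p_value = 1e-4, stringsAsFactors = FALSE)
  n1 <- combine_networks(ed, min_sites = 2)
  n2 <- combine_networks(ed[sample(nrow(ed)), ], min_sites = 2)
  expect_equal(n1$edges, n2$edges)
})

test_that("centralities match closed forms on canonical graphs", {
  path <- data.frame(genus_a = c("a", "b"), genus_b = c("b", "c"),
                     site = "s1", rho = 0.9, p_value = 1e-5)
  path2 <- path; path2$site <- "s2"
  net <- combine_networks(rbind(path, path2), min_sites = 2)
  ce <- centralities(net)
  ce <- ce[order(ce$genus), ]
  expect_equal(ce$degree, c(1, 2, 1))
  expect_equal(ce$betweenness, c(0, 1, 0))
  expect_gt(ce$closeness[2], ce$closeness[1])

  star <- data.frame(genus_a = "hub", genus_b = c("l1", "l2", "l3", "l4"),
                     site = "s1", rho = 0.9, p_value = 1e-5)
  star2 <- star; star2$site <- "s2"
  nst <- combine_networks(rbind(star, star2), min_sites = 2)
  cs <- centralities(nst)
  expect_equal(cs$degree[cs$genus == "hub"], 4)
  expect_true(all(cs$degree[cs$genus != "hub"] == 1))
  expect_equal(which.max(cs$closeness), which(cs$genus == "hub"))

  tri <- data.frame(genus_a = c("x", "y", "x"), genus_b = c("y", "z", "z"),
                    site = "s1", rho = 0.9, p_value = 1e-5)
  tri2 <- tri; tri2$site <- "s2"
  ctr <- centralities(combine_networks(rbind(tri, tri2), min_sites = 2))
  for (col in c("degree", "closeness", "betweenness", "eigenvector"))
    expect_equal(length(unique(round(ctr[[col]], 10))), 1)
})

test_that("hub ranking penalises high betweenness and breaks ties by id", {
  star <- data.frame(genus_a = "hub", genus_b = c("l1", "l2", "l3", "l4"),
                     site = "s1", rho = 0.9, p_value = 1e-5)
  star2 <- star; star2$site <- "s2"
  net <- combine_networks(rbind(star, star2), min_sites = 2)
  hc <- hub_candidates(net, top_k = 5)
  # the centre has max degree/closeness but also max betweenness; under the
  # composite rule the leaves tie ahead of it, ordered by id
  expect_equal(hc$genus[1:2], c("l1", "l2"))
  expect_false(hc$genus[1] == "hub")
})

test_that("network summaries follow the documented conventions", {
  tri <- data.frame(genus_a = c("x", "y", "x"), genus_b = c("y", "z", "z"),
                    site = c("s1"), rho = 0.9, p_value = 1e-5)
  tri2 <- tri; tri2$site <- "s2"
  ns <- network_summary(combine_networks(rbind(tri, tri2), min_sites = 2))
  expect_equal(ns$diameter, 1)
  expect_equal(ns$mean_distance, 1)
  expect_equal(ns$edge_density, 1)

  p3 <- data.frame(genus_a = c("a", "b"), genus_b = c("b", "c"),
                   site = "s1", rho = 0.9, p_value = 1e-5)
  p3b <- p3; p3b$site <- "s2"
  np <- network_summary(combine_networks(rbind(p3, p3b), min_sites = 2))
  expect_equal(np$diameter, 2)
  expect_equal(np$mean_distance, 4 / 3)
  expect_equal(np$edge_density, 2 / 3)

  two <- data.frame(genus_a = c("a", "c"), genus_b = c("b", "d"),
                    site = "s1", rho = 0.9, p_value = 1e-5)
  two2 <- two; two2$site <- "s2"
  nt <- network_summary(combine_networks(rbind(two, two2), min_sites = 2))
  expect_equal(nt$edge_density, 2 / 6)
  expect_equal(nt$diameter, 1)   # largest component is a single edge
})
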