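test_that("species agglomeration sums identical assignments and keeps unassigned apart", {
  m <- matrix(c(3, 5, 2, 0, 1, 1), nrow = 3, byrow = TRUE,
              dimnames = list(c("asv1", "asv2", "asv3"), c("s1", "s2")))
  tax <- tiny_taxonomy(c("asv1", "asv2", "asv3"))
  agg <- agglomerate_species(m, tax)
  expect_equal(nrow(agg$counts), 1)
  expect_equal(as.vector(agg$counts["Alternaria infectoria", ]), c(6, 6))
  expect_equal(sum(agg$counts), sum(m))

  tax2 <- tax
  tax2$species <- UNASSIGNED
  agg2 <- agglomerate_species(m, tax2)
  expect_equal(nrow(agg2$counts), 3)
  expect_setequal(rownames(agg2$counts), c("asv1", "asv2", "asv3"))
  expect_equal(sum(agg2$counts), sum(m))
})

test_that("agglomeration conserves reads on generated communities", {
  g <- generate_community(synthetic_config(seed = 3, n_core_taxa = 25,
                                           n_sporadic_taxa = 25,
                                           plants_per_population = 6))
  agg <- agglomerate_species(g$counts, g$taxonomy)
  expect_equal(sum(agg$counts), sum(g$counts))
  expect_lte(nrow(agg$counts), nrow(g$counts))
})

test_that("sample read floor uses a strict inequality", {
  m <- matrix(c(999, 1000, 5000), 1, 3,
              dimnames = list("t1", c("a", "b", "c")))
  out <- filter_samples_min_reads(m, 1000)
  expect_equal(colnames(out$counts), c("b", "c"))
  expect_equal(out$report$items_removed, 1)
  expect_equal(out$report$fraction_of_reads_removed, 999 / 6999)
  expect_equal(colnames(filter_samples_min_reads(m, 0)$counts),
               colnames(m))
  expect_error(filter_samples_min_reads(m, 1e7), "all samples")
})

test_that("rarity filter presets drop the right taxa and are idempotent", {
  m <- matrix(0, 4, 6, dimnames = list(paste0("t", 1:4), paste0("s", 1:6)))
  m[1, 1] <- 2                 # doubleton (total 2)
  m[2, 1:4] <- 1               # incidence 4
  m[3, 1:5] <- 2               # incidence 5
  m[4, ] <- 10
  sd <- filter_rare_taxa(m, preset = "singleton_doubleton")
  expect_false("t1" %in% rownames(sd$counts))
  expect_true(all(c("t2", "t3", "t4") %in% rownames(sd$counts)))

  core <- filter_rare_taxa(m, preset = "core")
  expect_false("t2" %in% rownames(core$counts))   # incidence 4 < 5 removed
  expect_true("t3" %in% rownames(core$counts))    # incidence 5 kept

  expect_identical(filter_rare_taxa(m, 0, 0)$counts, count_table(m))
  twice <- filter_rare_taxa(filter_rare_taxa(m, 3, 5)$counts, 3, 5)
  expect_identical(twice$counts, filter_rare_taxa(m, 3, 5)$counts)
  expect_equal(twice$report$items_removed, 0)
})

test_that("preset chain yields non-increasing taxon counts", {
  g <- generate_community(synthetic_config(seed = 9, n_core_taxa = 40,
                                           n_sporadic_taxa = 80,
                                           plants_per_population = 8))
  agg <- agglomerate_species(g$counts, g$taxonomy)
  s1 <- filter_samples_min_reads(agg$counts, 1000)$counts
  s2 <- filter_rare_taxa(s1, preset = "singleton_doubleton")$counts
  s3 <- filter_rare_taxa(s2, preset = "core")$counts
  n <- c(nrow(g$counts), nrow(agg$counts), nrow(s1), nrow(s2), nrow(s3))
  expect_true(all(diff(n) <= 0))
})

test_that("venn partition recovers planted shared and host-unique taxa", {
  # hand fixture: taxon in host A only
  m <- matrix(c(3, 0, 0, 2, 1, 4), 3, 2, byrow = TRUE,
              dimnames = list(c("uA", "uB", "sh"), c("a1", "b1")))
  meta <- data.frame(sample_id = c("a1", "b1"), host = c("A", "B"),
                     site = "s")
  v <- venn_partition(m, meta)
  expect_equal(sum(v$n_taxa), 3)
  expect_equal(v$n_taxa[v$subset == "A"], 1)
  expect_equal(sum(v$reads), sum(m))
  expect_equal(sum(v$read_share), 1)

  # generator-planted: 10 shared core + 2 unique per host, no sporadics
  cfg <- synthetic_config(hosts = c("A", "B"),
                          sites = list(A = "s", B = "s"),
                          plants_per_population = 15, n_core_taxa = 10,
                          n_sporadic_taxa = 0, n_unique_per_host = 2,
                          sporadic_occurrence_prob = 0,
                          core_log_abundance_sd = 0.5, plant_noise_sd = 0.3,
                          seed = 21)
  g <- generate_community(cfg)
  v2 <- venn_partition(g$counts, g$metadata)
  expect_equal(v2$n_taxa[v2$subset == "A+B"], 10)
  expect_equal(v2$n_taxa[v2$subset == "A"], 2)
  expect_equal(v2$n_taxa[v2$subset == "B"], 2)
})

test_that("rank-abundance summary orders by median with documented tie-breaks", {
  at <- rbind(
    mostly_zero = c(0, 0, 0, 0, 0, 1),
    steady      = c(.2, .2, .2, .2, .2, .2),
    tied_hi     = c(.3, .3, .3, .3, .3, .9),
    tied_lo     = c(.3, .3, .3, .3, .3, .3))
  colnames(at) <- paste0("s", 1:6)
  meta <- data.frame(sample_id = colnames(at),
                     host = rep(c("h1", "h2"), each = 3), site = "x")
  res <- rank_abundance_summary(at, meta, top_n = 4)
  expect_equal(res$summary$taxon_id,
               c("tied_hi", "tied_lo", "steady", "mostly_zero"))
  # identical distributions across hosts -> no significance
  expect_equal(res$summary$anova_p[res$summary$taxon_id == "tied_lo"], 1)
  expect_equal(res$summary$stars[res$summary$taxon_id == "tied_lo"], "")
  expect_error(rank_abundance_summary(at, meta, top_n = 10), "top_n")
})

test_that("class composition shares sum to one and recover a planted mix", {
  ct <- tiny_counts()[1:3, ]
  tax <- tiny_taxonomy(rownames(ct))
  meta <- data.frame(sample_id = colnames(ct), host = "h", site = "s")
  cc <- class_composition(ct, tax, meta)
  expect_true(all(abs(vapply(split(cc$share, paste(cc$level, cc$group)),
                             sum, numeric(1)) - 1) < 1e-12))
  expect_equal(unique(cc$class), "Dothideomycetes")

  cfg <- synthetic_config(seed = 31, n_core_taxa = 150, n_sporadic_taxa = 0,
                          plants_per_population = 15,
                          class_mix = c(ClassA = 0.6, ClassB = 0.3, ClassC = 0.1),
                          n_genera = 120, host_effect_sd = 0, site_effect_sd = 0,
                          core_log_abundance_sd = 0.8)
  g <- generate_community(cfg)
  cc2 <- class_composition(g$counts, g$taxonomy, g$metadata, top_k = 3)
  hostA <- cc2[cc2$level == "host" & cc2$group == "hostA", ]
  got <- stats::setNames(hostA$share, hostA$class)[c("ClassA", "ClassB", "ClassC")]
  expect_equal(unname(got), c(0.6, 0.3, 0.1), tolerance = 0.35)
  expect_equal(order(-got), 1:3)  # planted ordering recovered
})
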