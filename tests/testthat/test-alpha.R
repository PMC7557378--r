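make_inc <- function(Y, T) {
  # incidence matrix with given per-taxon frequencies over T units
  m <- matrix(0, length(Y), T,
              dimnames = list(paste0("t", seq_along(Y)), paste0("u", seq_len(T))))
  for (i in seq_along(Y)) m[i, seq_len(Y[i])] <- 1
  m
}

test_that("per-sample richness counts positive taxa", {
  m <- matrix(c(0, 3, 0, 1, 0, 0, 0, 0), 4, 2,
              dimnames = list(paste0("t", 1:4), c("s1", "s2")))
  r <- sample_richness(m)
  expect_equal(r$richness, c(2, 0))
  meta <- data.frame(sample_id = c("s1", "s2"), host = c("a", "b"), site = "x")
  rl <- sample_richness(m, meta)
  expect_equal(rl$group_means$mean_richness, c(2, 0))
})

test_that("incidence frequency summaries match their definitions", {
  inc <- make_inc(c(2, 1, 1), 3)
  f <- incidence_frequencies(inc)
  expect_equal(f$S_obs, 3)
  expect_equal(f$Q1, 2)
  expect_equal(f$Q2, 1)
  expect_equal(f$U, 4)
  f2 <- incidence_frequencies(make_inc(c(2), 2))
  expect_equal(f2$Q2, 1)
  expect_error(incidence_frequencies(inc, character(0)), "empty")
})

test_that("hill estimates reproduce closed-form worked examples", {
  f <- incidence_frequencies(make_inc(c(4, 4, 1), 4))
  expect_equal(hill_estimate(f, 0, 2), 2.5)          # 2 + (1 - C(3,2)/C(4,2))
  expect_equal(hill_estimate(f, 0, 4), f$S_obs)

  f2 <- incidence_frequencies(make_inc(c(4, 3, 2, 1, 1), 4))  # Q1=2, Q2=1
  expect_equal(hill_asymptote(f2, 0), 5 + (3 / 4) * (4 / 2))  # Chao2 = 6.5

  expect_error(hill_estimate(f, 3, 2), "q must be")
  expect_error(hill_estimate(f, 0, 0), "t must be")
})

test_that("all orders return observed diversity at t = T", {
  set.seed(8)
  for (rep in 1:5) {
    T <- sample(3:9, 1)
    inc <- matrix(rbinom(25 * T, 1, 0.4), 25, T,
                  dimnames = list(paste0("t", 1:25), paste0("u", seq_len(T))))
    if (sum(inc) == 0) next
    f <- incidence_frequencies(inc)
    p <- f$Y / f$U
    expect_equal(hill_estimate(f, 0, T), f$S_obs, tolerance = 1e-9)
    expect_equal(hill_estimate(f, 1, T), exp(-sum(p * log(p))), tolerance = 1e-9)
    expect_equal(hill_estimate(f, 2, T), 1 / sum(p^2), tolerance = 1e-9)
  }
})

test_that("q = 0 interpolation equals the exhaustive subset-average oracle", {
  set.seed(13)
  for (rep in 1:4) {
    T <- sample(4:8, 1)
    inc <- matrix(rbinom(15 * T, 1, 0.5), 15, T,
                  dimnames = list(paste0("t", 1:15), paste0("u", seq_len(T))))
    if (sum(inc) == 0) next
    f <- incidence_frequencies(inc)
    for (t in 1:T)
      expect_equal(hill_estimate(f, 0, t), subset_richness_oracle(inc, t),
                   tolerance = 1e-9)
  }
})

test_that("diversity ordering and q = 0 monotonicity hold along the curve", {
  set.seed(19)
  inc <- matrix(rbinom(60 * 10, 1, 0.35), 60, 10,
                dimnames = list(paste0("t", 1:60), paste0("u", 1:10)))
  f <- incidence_frequencies(inc)
  tg <- 1:20
  d0 <- hill_estimate(f, 0, tg)
  d1 <- hill_estimate(f, 1, tg)
  d2 <- hill_estimate(f, 2, tg)
  expect_true(all(d0 - d1 >= -1e-9))
  expect_true(all(d1 - d2 >= -1e-9))
  expect_true(all(diff(d0) >= -1e-9))
  expect_gte(hill_asymptote(f, 0), d0[length(d0)])
})

test_that("hill curves label regimes and give honest intervals", {
  set.seed(23)
  inc <- matrix(rbinom(40 * 8, 1, 0.4), 40, 8,
                dimnames = list(paste0("t", 1:40), paste0("u", 1:8)))
  cur <- hill_curve(inc, q = 0, bootstrap_reps = 50, seed = 1)
  expect_equal(cur$regime[cur$t == 8], "observed")
  expect_true(all(cur$regime[cur$t < 8] == "interpolated"))
  expect_true(all(cur$regime[cur$t > 8] == "extrapolated"))
  expect_true(all(cur$lower <= cur$estimate + 1e-12))
  expect_true(all(cur$upper >= cur$estimate - 1e-12))
  expect_equal(max(cur$t), 16)  # default extrapolation cap 2T

  # degenerate population: identical plants -> zero-width intervals at t <= T
  deg <- matrix(rep(c(1, 1, 0, 1, 0), 4), 5, 4,
                dimnames = list(paste0("t", 1:5), paste0("u", 1:4)))
  cd <- hill_curve(deg, q = 0, bootstrap_reps = 30, seed = 2)
  at <- cd[cd$t <= 4, ]
  expect_true(all(abs(at$upper - at$lower) < 1e-12))
})

test_that("populations with more planted richness give higher q = 0 curves", {
  gr <- generate_community(synthetic_config(
    hosts = "h", sites = list(h = "s1"), plants_per_population = 15,
    n_core_taxa = 80, n_sporadic_taxa = 150, sporadic_occurrence_prob = 0.15,
    seed = 7))
  gp <- generate_community(synthetic_config(
    hosts = "h", sites = list(h = "s1"), plants_per_population = 15,
    n_core_taxa = 20, n_sporadic_taxa = 150, sporadic_occurrence_prob = 0.02,
    seed = 7))
  fr <- incidence_frequencies(to_incidence(gr$counts))
  fp <- incidence_frequencies(to_incidence(gp$counts))
  for (t in c(5, 10, 15, 25))
    expect_gt(hill_estimate(fr, 0, t), hill_estimate(fp, 0, t))
})

test_that("diversity table reports one row per population and order", {
  g <- generate_community(synthetic_config(seed = 2, n_core_taxa = 25,
                                           n_sporadic_taxa = 25,
                                           plants_per_population = 6))
  div <- diversity_table(to_incidence(g$counts), g$metadata)
  expect_equal(nrow(div), length(unique(population_labels(g$metadata))) * 3)
  expect_true(all(div$asymptote >= div$observed - 1e-9))
})
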