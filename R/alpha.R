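#' Per-sample taxon richness
#'
#' Number of taxa with at least one read in each sample; with metadata, also
#' the mean richness per host.
#'
#' @param ct count table (or incidence matrix).
#' @param meta optional sample metadata.
#' @return data.frame (sample_id, richness); if `meta` is given, a list with
#'   elements `samples` and `group_means` (host, mean_richness).
#' @export
sample_richness <- function(ct, meta = NULL) {
  rich <- colSums(ct > 0)
  samples <- data.frame(sample_id = colnames(ct), richness = unname(rich),
                        stringsAsFactors = FALSE)
  if (is.null(meta)) return(samples)
  meta <- sample_metadata(meta)
  samples$host <- meta$host[match(samples$sample_id, meta$sample_id)]
  gm <- stats::aggregate(richness ~ host, data = samples, FUN = mean)
  colnames(gm) <- c("host", "mean_richness")
  list(samples = samples, group_means = gm)
}

#' Incidence frequency counts of one population
#'
#' Summarises a set of sampling units (plants) into the sufficient statistics
#' of incidence-based diversity estimation: the number of units `T`, the
#' per-taxon incidence frequencies `Y` (units containing the taxon), the
#' observed richness `S_obs`, the frequency counts `Q1` (uniques) and `Q2`
#' (duplicates), and the total incidence `U`.
#'
#' @param inc incidence (or count) matrix, taxa x samples.
#' @param samples sampling-unit ids to use (default: all columns).
#' @return object of class `incidence_freq`.
#' @export
incidence_frequencies <- function(inc, samples = colnames(inc)) {
  if (length(samples) < 1) stop("population is empty")
  if (!all(samples %in% colnames(inc))) stop("unknown sample ids")
  sub <- inc[, samples, drop = FALSE] > 0
  Y <- rowSums(sub)
  Y <- Y[Y >= 1]
  f <- list(T = length(samples), Y = Y, S_obs = length(Y),
            Q1 = sum(Y == 1), Q2 = sum(Y == 2), U = sum(Y))
  class(f) <- "incidence_freq"
  f
}

chao2_unseen <- function(f) {
  if (f$Q2 > 0) (f$T - 1) / f$T * f$Q1^2 / (2 * f$Q2)
  else (f$T - 1) / f$T * f$Q1 * (f$Q1 - 1) / 2
}

# Asymptotic incidence entropy (Shannon, natural log) estimator.
incidence_entropy_asym <- function(f) {
  T <- f$T; Y <- f$Y; U <- f$U; Q1 <- f$Q1; Q2 <- f$Q2
  A <- if (Q2 > 0) 2 * Q2 / ((T - 1) * Q1 + 2 * Q2)
       else if (Q1 > 0) 2 / ((T - 1) * (Q1 - 1) + 2)
       else 1
  h1 <- sum(Y / T * (digamma(T) - digamma(Y)))
  h2 <- if (Q1 > 0 && A < 1) {
    r <- seq_len(T - 1)
    Q1 / T * (1 - A)^(1 - T) * (-log(A) - sum((1 - A)^r / r))
  } else 0
  (T / U) * (h1 + h2) + log(U / T)
}

observed_hill <- function(f, q) {
  p <- f$Y / f$U
  switch(as.character(q),
         "0" = f$S_obs,
         "1" = exp(-sum(p * log(p))),
         "2" = 1 / sum(p^2))
}

#' Asymptotic Hill-number estimate for incidence data
#'
#' q = 0 uses the Chao2 unseen-taxa correction; q = 1 exponentiates the
#' asymptotic incidence entropy estimator; q = 2 uses the unbiased
#' inverse-concentration estimator. Never below the observed diversity.
#'
#' @param f an [incidence_frequencies()] object.
#' @param q diversity order, 0, 1 or 2.
#' @export
hill_asymptote <- function(f, q) {
  stopifnot(inherits(f, "incidence_freq"))
  if (!q %in% c(0, 1, 2)) stop("q must be 0, 1 or 2")
  obs <- observed_hill(f, q)
  if (f$T < 2) return(obs)
  est <- switch(as.character(q),
    "0" = f$S_obs + chao2_unseen(f),
    "1" = exp(incidence_entropy_asym(f)),
    "2" = {
      ss <- sum(f$Y * (f$Y - 1))
      if (ss > 0) (f$T - 1) / f$T * f$U^2 / ss else obs
    })
  max(est, obs)
}

#' Rarefied / extrapolated Hill number of order q at t sampling units
#'
#' Sample-size-based interpolation (t <= T) and extrapolation (t > T) of the
#' incidence-data Hill numbers. For q = 0 the interpolated value is the exact
#' expected richness of a random subset of t units; extrapolation uses the
#' Chao2 unseen-taxa term. q = 1 interpolates through the expected incidence
#' frequency counts and extrapolates by blending the observed and asymptotic
#' entropies in proportion T/t; q = 2 uses one closed-form estimator valid on
#' both sides. At t = T all orders return the observed diversity.
#'
#' @param f an [incidence_frequencies()] object.
#' @param q diversity order, 0, 1 or 2.
#' @param t number of sampling units (vectorised); must be >= 1.
#' @export
hill_estimate <- function(f, q, t) {
  stopifnot(inherits(f, "incidence_freq"))
  if (!q %in% c(0, 1, 2)) stop("q must be 0, 1 or 2")
  if (any(t < 1)) stop("t must be >= 1")
  if (f$S_obs == 0) return(rep(0, length(t)))
  vapply(t, function(tt) hill_estimate1(f, q, tt), numeric(1))
}

hill_estimate1 <- function(f, q, t) {
  T <- f$T; Y <- f$Y; U <- f$U
  if (q == 0) {
    if (t <= T) {
      miss <- ifelse(T - Y >= t, exp(lchoose(T - Y, t) - lchoose(T, t)), 0)
      return(f$S_obs - sum(miss))
    }
    q0hat <- chao2_unseen(f)
    if (f$Q1 == 0 || q0hat == 0) return(f$S_obs)
    return(f$S_obs + q0hat * (1 - (1 - f$Q1 / (f$Q1 + T * q0hat))^(t - T)))
  }
  if (q == 1) {
    if (t == T) return(observed_hill(f, 1))
    if (t < T) {
      Ut <- t * U / T
      k <- seq_len(t)
      # expected number of taxa with incidence k in a subset of t units
      Qk <- vapply(k, function(kk) {
        ok <- Y >= kk & (T - Y) >= (t - kk)
        sum(exp(lchoose(Y[ok], kk) + lchoose(T - Y[ok], t - kk) - lchoose(T, t)))
      }, numeric(1))
      H <- sum(ifelse(Qk > 0, -(k / Ut) * log(k / Ut) * Qk, 0))
      return(exp(H))
    }
    H_obs <- log(observed_hill(f, 1))
    H_inf <- if (T >= 2) max(incidence_entropy_asym(f), H_obs) else H_obs
    return(exp(T / t * H_obs + (t - T) / t * H_inf))
  }
  # q == 2: one unbiased closed form on both sides of T
  if (T == 1) return(observed_hill(f, 2))
  Ut <- t * U / T
  denom <- sum(t / T * Y + t * (t - 1) / (T * (T - 1)) * Y * (Y - 1))
  Ut^2 / denom
}

#' Rarefaction/extrapolation curve with bootstrap intervals
#'
#' Point estimates from [hill_estimate()] on a grid of sampling-unit numbers
#' spanning interpolation and extrapolation (default endpoint 2T), with
#' percentile bootstrap intervals obtained by resampling sampling units
#' (plants) with replacement, and the asymptotic estimate attached.
#'
#' @param inc incidence (or count) matrix, taxa x samples.
#' @param samples sampling-unit ids forming the population.
#' @param q diversity order, 0, 1 or 2.
#' @param t_grid integer grid of unit numbers; default ~30 knots on 1..2T.
#' @param bootstrap_reps bootstrap replicates (>= 1); 0 disables intervals.
#' @param conf interval coverage.
#' @param seed optional seed for the bootstrap.
#' @param extrap_factor extrapolation endpoint as a multiple of T.
#' @return data.frame (t, estimate, lower, upper, regime) with attributes
#'   `q`, `T` and `asymptote`.
#' @export
hill_curve <- function(inc, samples = colnames(inc), q = 0, t_grid = NULL,
                       bootstrap_reps = 200, conf = 0.95, seed = NULL,
                       extrap_factor = 2) {
  f <- incidence_frequencies(inc, samples)
  T <- f$T
  if (is.null(t_grid))
    t_grid <- sort(unique(c(round(seq(1, max(2, extrap_factor * T),
                                      length.out = 30)), T)))
  t_grid <- sort(unique(pmax(1, round(t_grid))))
  est <- hill_estimate(f, q, t_grid)
  lower <- upper <- rep(NA_real_, length(t_grid))
  if (bootstrap_reps >= 1) {
    if (!is.null(seed)) set.seed(seed)
    sub <- inc[, samples, drop = FALSE]
    boot <- matrix(NA_real_, bootstrap_reps, length(t_grid))
    for (b in seq_len(bootstrap_reps)) {
      bs <- sample.int(T, T, replace = TRUE)
      bm <- sub[, bs, drop = FALSE]
      colnames(bm) <- paste0("u", seq_len(T))
      boot[b, ] <- hill_estimate(incidence_frequencies(bm), q, t_grid)
    }
    alpha2 <- (1 - conf) / 2
    lower <- apply(boot, 2, stats::quantile, probs = alpha2, na.rm = TRUE)
    upper <- apply(boot, 2, stats::quantile, probs = 1 - alpha2, na.rm = TRUE)
    lower <- pmin(lower, est)
    upper <- pmax(upper, est)
  }
  out <- data.frame(t = t_grid, estimate = est, lower = lower, upper = upper,
                    regime = ifelse(t_grid < T, "interpolated",
                             ifelse(t_grid == T, "observed", "extrapolated")),
                    stringsAsFactors = FALSE)
  attr(out, "q") <- q
  attr(out, "T") <- T
  attr(out, "asymptote") <- hill_asymptote(f, q)
  out
}

#' Observed and asymptotic diversity per population
#'
#' One row per population (host x site) and order q: sample size, observed
#' diversity, asymptotic estimate.
#'
#' @param inc incidence (or count) matrix.
#' @param meta sample metadata.
#' @param q diversity orders.
#' @param by `"population"` (host x site) or `"host"` (pooled sites).
#' @export
diversity_table <- function(inc, meta, q = c(0, 1, 2),
                            by = c("population", "host")) {
  by <- match.arg(by)
  meta <- sample_metadata(meta)
  grp <- if (by == "population") population_labels(meta)[colnames(inc)]
         else meta$host[match(colnames(inc), meta$sample_id)]
  rows <- list()
  for (g in sort(unique(grp))) {
    f <- incidence_frequencies(inc, colnames(inc)[grp == g])
    for (qq in q)
      rows[[length(rows) + 1]] <- data.frame(
        group = g, q = qq, sample_size = f$T,
        observed = observed_hill(f, qq),
        asymptote = hill_asymptote(f, qq), stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
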