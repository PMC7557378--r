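#' Minimum-cost linear assignment
#'
#' Exact solver (successive shortest augmenting paths, compiled) for the
#' rectangular assignment problem: match every row of the cost matrix to a
#' distinct column minimising the total cost. Used by the assignment-based
#' dispersion and distance statistics.
#'
#' @param cost numeric cost matrix; if nrow > ncol it is solved transposed.
#' @return list(rows, cols, total): matched row/column indices and the
#'   minimal total cost.
#' @export
solve_assignment <- function(cost) {
  if (!is.matrix(cost) || !is.numeric(cost)) stop("cost must be a numeric matrix")
  flip <- nrow(cost) > ncol(cost)
  m <- if (flip) t(cost) else cost
  cols <- .lsap_cpp(m)
  rows <- seq_len(nrow(m))
  total <- sum(m[cbind(rows, cols)])
  if (flip) list(rows = cols, cols = rows, total = total)
  else list(rows = rows, cols = cols, total = total)
}

#' Assignment-based dispersion KW of one population
#'
#' Solves the assignment problem on the within-population distance matrix
#' with self-assignment forbidden (the optimum is a fixed-point-free
#' permutation; mutual pairings are allowed) and returns the minimal average
#' cost KW = (1/n) * minimal total cost.
#'
#' @param dm symmetric within-population distance matrix, n >= 2.
#' @export
kw_dispersion <- function(dm) {
  dm <- validate_distance_matrix(dm)
  n <- nrow(dm)
  if (n < 2) stop("KW needs at least 2 individuals")
  big <- n * (max(dm) + 1) + 1
  cost <- dm
  diag(cost) <- big
  sol <- solve_assignment(cost)
  if (any(sol$rows == sol$cols)) stop("internal error: fixed point in KW assignment")
  sol$total / n
}

#' Average-based dispersion (mean pairwise distance)
#' @param dm symmetric distance matrix, n >= 2.
#' @export
mean_dispersion <- function(dm) {
  n <- nrow(dm)
  if (n < 2) stop("dispersion needs at least 2 individuals")
  sum(dm[upper.tri(dm)]) / (n * (n - 1) / 2)
}

#' Kosman distance between two populations
#'
#' Minimal average cost of a one-to-one assignment matching every member of
#' the smaller population to a distinct member of the larger, averaged over
#' the min(n_a, n_b) matched pairs.
#'
#' @param block rectangular matrix of distances between members of
#'   population a (rows) and population b (columns).
#' @export
kosman_distance <- function(block) {
  if (!is.matrix(block) || nrow(block) < 1 || ncol(block) < 1)
    stop("empty population")
  solve_assignment(block)$total / min(dim(block))
}

#' Effective number of communities from a mean distance
#'
#' effective = 1 + (N - 1) * M and its normalisation
#' (effective - 1) / (N - 1) = M, the number of completely distinct
#' communities that would produce mean inter-community distance M.
#'
#' @param M mean distance in \[0, 1\].
#' @param N number of communities, >= 2.
#' @return list(effective, normalized).
#' @export
effective_number <- function(M, N) {
  if (M < 0 || M > 1) stop("M must lie in [0, 1]")
  if (N < 2) stop("N must be >= 2")
  eff <- 1 + (N - 1) * M
  list(effective = eff, normalized = (eff - 1) / (N - 1))
}

#' Within-population variation (KW and effective plant numbers)
#'
#' Per population, and optionally for the pooled set of all individuals, the
#' assignment-based dispersion KW, the mean pairwise distance, and the
#' effective / normalised effective number of distinct individuals computed
#' from KW.
#'
#' @param dm distance matrix over all individuals.
#' @param populations population label per individual (in `rownames(dm)`
#'   order).
#' @param pooled also report the pooled set as population `"all"`.
#' @return data.frame (population, n, KW, mean_dispersion, effective,
#'   normalized). Populations of size 1 are skipped with a warning.
#' @export
within_population_variation <- function(dm, populations, pooled = TRUE) {
  dm <- validate_distance_matrix(dm)
  if (length(populations) != nrow(dm))
    stop("populations must match the distance matrix")
  labs <- as.character(populations)
  groups <- split(seq_len(nrow(dm)), labs)
  small <- names(groups)[lengths(groups) < 2]
  if (length(small) > 0) {
    warning("skipping size-1 population(s): ", paste(small, collapse = ", "))
    groups <- groups[lengths(groups) >= 2]
  }
  if (pooled && nrow(dm) >= 2) groups <- c(groups, list(all = seq_len(nrow(dm))))
  rows <- lapply(names(groups), function(g) {
    idx <- groups[[g]]
    sub <- dm[idx, idx, drop = FALSE]
    kw <- kw_dispersion(sub)
    en <- effective_number(min(kw, 1), length(idx))
    data.frame(population = g, n = length(idx), KW = kw,
               mean_dispersion = mean_dispersion(sub),
               effective = en$effective, normalized = en$normalized,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

kb_matrix <- function(dm, groups) {
  nms <- names(groups)
  N <- length(nms)
  KB <- matrix(0, N, N, dimnames = list(nms, nms))
  for (i in seq_len(N - 1)) for (j in seq(i + 1, N)) {
    KB[i, j] <- KB[j, i] <-
      kosman_distance(dm[groups[[i]], groups[[j]], drop = FALSE])
  }
  KB
}

d_statistic <- function(dm, groups, variant) {
  w <- lengths(groups) / sum(lengths(groups))
  within_avg <- vapply(groups, function(idx)
    mean_dispersion(dm[idx, idx, drop = FALSE]), numeric(1))
  if (variant == "partition") {
    mean_dispersion(dm) - sum(w * within_avg)
  } else {
    KB <- kb_matrix(dm, groups)
    within_kw <- vapply(groups, function(idx)
      kw_dispersion(dm[idx, idx, drop = FALSE]), numeric(1))
    mean(KB[upper.tri(KB)]) - sum(w * within_kw)
  }
}

#' Differentiation among populations with permutation significance
#'
#' Pairwise Kosman distances KB between the populations, their mean M, the
#' differentiation statistic D, a permutation p-value, and the effective /
#' normalised effective number of populations computed from M.
#'
#' Two variants of D are available (the additive-partition definition is the
#' default): `"partition"` takes D = (mean pairwise distance of the pooled
#' individual set) - (size-weighted mean within-population average
#' dispersion), i.e. the among-population component of total = within +
#' among; `"assignment"` takes D = mean pairwise KB - size-weighted mean
#' within-population KW. The permutation test reshuffles individuals among
#' the populations preserving population sizes.
#'
#' @param dm distance matrix over all individuals of one host.
#' @param populations population label per individual.
#' @param n_perm permutations (>= 1).
#' @param seed optional seed.
#' @param variant `"partition"` (default) or `"assignment"`.
#' @return list of class `differentiation`: N, sizes, KB, M, D, p_value,
#'   effective, normalized, variant, n_permutations.
#' @export
differentiation <- function(dm, populations, n_perm = 1000, seed = NULL,
                            variant = c("partition", "assignment")) {
  variant <- match.arg(variant)
  dm <- validate_distance_matrix(dm)
  if (n_perm < 1) stop("n_perm must be >= 1")
  labs <- as.character(populations)
  if (length(labs) != nrow(dm)) stop("populations must match the distance matrix")
  groups <- split(seq_len(nrow(dm)), labs)
  if (length(groups) < 2) stop("need >= 2 populations")
  if (any(lengths(groups) < 2)) stop("every population needs >= 2 individuals")

  KB <- kb_matrix(dm, groups)
  M <- mean(KB[upper.tri(KB)])
  D_obs <- d_statistic(dm, groups, variant)

  if (!is.null(seed)) set.seed(seed)
  n <- nrow(dm)
  sizes <- lengths(groups)
  hits <- 0
  for (b in seq_len(n_perm)) {
    perm <- sample.int(n)
    pg <- split(perm, rep(names(groups), times = sizes))
    if (d_statistic(dm, pg, variant) >= D_obs) hits <- hits + 1
  }
  en <- effective_number(min(max(M, 0), 1), length(groups))
  structure(list(N = length(groups), sizes = sizes, KB = KB, M = M, D = D_obs,
                 p_value = (1 + hits) / (1 + n_perm),
                 effective = en$effective, normalized = en$normalized,
                 variant = variant, n_permutations = n_perm),
            class = "differentiation")
}

#' @export
print.differentiation <- function(x, ...) {
  cat("Differentiation among ", x$N, " populations (", x$variant, " variant)\n",
      "  D = ", signif(x$D, 4), ", p = ", signif(x$p_value, 4),
      " (", x$n_permutations, " permutations)\n",
      "  mean Kosman distance M = ", signif(x$M, 4),
      ", 1D(TM) = ", signif(x$effective, 4),
      ", 1nD(TM) = ", signif(x$normalized, 4), "\n", sep = "")
  invisible(x)
}
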