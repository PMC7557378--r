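check_zero_samples <- function(m) {
  zs <- colnames(m)[colSums(m) == 0]
  if (length(zs) >= 2)
    stop("dissimilarity undefined between all-zero samples: ",
         paste(zs, collapse = ", "))
}

#' Bray-Curtis dissimilarity between samples
#'
#' d(x, y) = sum|x_i - y_i| / sum(x_i + y_i), on non-negative abundances
#' (typically Hellinger-transformed). Computed through vegan.
#'
#' @param at abundance matrix, taxa x samples.
#' @return labelled symmetric matrix with zero diagonal, values in \[0, 1\].
#' @export
bray_curtis <- function(at) {
  if (any(at < 0)) stop("abundances must be non-negative")
  check_zero_samples(at)
  d <- vegan::vegdist(t(at), method = "bray")
  validate_distance_matrix(as.matrix(d))
}

#' Dice (Sorensen) dissimilarity between samples on incidence data
#'
#' d = 1 - 2a / (2a + b + c), with a shared presences and b, c unilateral
#' presences. Computed through vegan (binary Bray-Curtis).
#'
#' @param inc 0/1 incidence matrix, taxa x samples.
#' @export
dice <- function(inc) {
  if (!all(inc %in% c(0, 1))) stop("incidence matrix must be binary")
  check_zero_samples(inc)
  d <- vegan::vegdist(t(inc), method = "bray", binary = TRUE)
  validate_distance_matrix(as.matrix(d))
}

#' Principal coordinate analysis (classical metric scaling)
#'
#' Double-centering of -d^2/2, eigendecomposition, coordinates scaled by the
#' square roots of the positive eigenvalues. Axes with non-positive
#' eigenvalues are dropped; negative eigenvalues are reported.
#'
#' @param dm distance matrix.
#' @param n_axes axes to return (truncated with a warning if fewer positive
#'   eigenvalues exist).
#' @return list(coordinates, eigenvalues, proportion_explained,
#'   negative_eigenvalues).
#' @export
pcoa <- function(dm, n_axes = 2) {
  dm <- validate_distance_matrix(dm)
  n <- nrow(dm)
  # cmdscale warns whenever fewer than k axes are positive; rank deficiency
  # is expected here and reported through the eigenvalues instead
  sc <- suppressWarnings(stats::cmdscale(stats::as.dist(dm), k = n - 1, eig = TRUE))
  eig <- sc$eig
  pos <- which(eig > 1e-9 * max(abs(eig)))
  if (n_axes > length(pos)) {
    warning("only ", length(pos), " positive-eigenvalue axes available")
    n_axes <- length(pos)
  }
  coords <- sc$points[, seq_len(n_axes), drop = FALSE]
  colnames(coords) <- paste0("PCo", seq_len(n_axes))
  list(coordinates = coords,
       eigenvalues = eig[pos],
       proportion_explained = eig[pos] / sum(eig[pos]),
       negative_eigenvalues = eig[eig < 0])
}

group_test_result <- function(method, statistic, R2, p, n_perm, seed) {
  structure(list(method = method, statistic = statistic, R_squared = R2,
                 p_value = p, n_permutations = n_perm, seed = seed),
            class = "group_test")
}

#' @export
print.group_test <- function(x, ...) {
  cat(x$method, ": statistic = ", signif(x$statistic, 5),
      if (!is.na(x$R_squared)) paste0(", R2 = ", signif(x$R_squared, 4)),
      ", p = ", signif(x$p_value, 4),
      " (", x$n_permutations, " permutations)\n", sep = "")
  invisible(x)
}

check_groups <- function(dm, labels) {
  if (length(labels) != nrow(dm)) stop("labels must match the distance matrix")
  tab <- table(labels)
  if (length(tab) < 2) stop("need >= 2 groups")
  if (any(tab < 1)) stop("empty group")
  factor(labels)
}

#' One-factor PERMANOVA (through vegan::adonis2)
#'
#' Pseudo-F from the partition of squared inter-point distances by a single
#' grouping factor; p-value (1 + hits) / (1 + permutations) under label
#' reshuffling.
#'
#' @param dm distance matrix.
#' @param labels group label per item.
#' @param n_perm number of permutations.
#' @param seed optional seed.
#' @export
permanova <- function(dm, labels, n_perm = 999, seed = NULL) {
  dm <- validate_distance_matrix(dm)
  grp <- check_groups(dm, labels)
  if (!is.null(seed)) set.seed(seed)
  fit <- vegan::adonis2(stats::as.dist(dm) ~ grp, permutations = n_perm)
  group_test_result("PERMANOVA", fit$F[1], fit$R2[1], fit$`Pr(>F)`[1],
                    n_perm, seed)
}

#' ANOSIM (through vegan::anosim)
#'
#' R = (mean between-group rank - mean within-group rank) / (M/2) on the
#' midranked dissimilarities; permutation p-value as in [permanova()].
#'
#' @inheritParams permanova
#' @export
anosim <- function(dm, labels, n_perm = 999, seed = NULL) {
  dm <- validate_distance_matrix(dm)
  grp <- check_groups(dm, labels)
  if (!is.null(seed)) set.seed(seed)
  fit <- vegan::anosim(stats::as.dist(dm), grp, permutations = n_perm)
  group_test_result("ANOSIM", fit$statistic, NA_real_, fit$signif, n_perm, seed)
}
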