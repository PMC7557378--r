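# Brute-force oracles and small fixture builders shared across tests.

# All permutations of 1..n (rows), recursive construction.
all_perms <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_perms(n - 1)
  out <- NULL
  for (k in seq_len(n)) {
    block <- cbind(k, sub + (sub >= k))
    out <- rbind(out, block)
  }
  unname(out)
}

# Minimal average derangement cost: oracle for kw_dispersion.
kw_oracle <- function(dm) {
  n <- nrow(dm)
  P <- all_perms(n)
  P <- P[rowSums(P == matrix(seq_len(n), nrow(P), n, byrow = TRUE)) == 0, ,
         drop = FALSE]
  totals <- apply(P, 1, function(p) sum(dm[cbind(seq_len(n), p)]))
  min(totals) / n
}

# Minimal average injection cost: oracle for kosman_distance.
kb_oracle <- function(block) {
  if (nrow(block) > ncol(block)) return(kb_oracle(t(block)))
  n <- nrow(block); m <- ncol(block)
  P <- all_perms(m)[, seq_len(n), drop = FALSE]
  totals <- apply(P, 1, function(p) sum(block[cbind(seq_len(n), p)]))
  min(totals) / n
}

# Random symmetric distance-like matrix in [0,1] with zero diagonal.
random_dm <- function(n, labels = paste0("i", seq_len(n))) {
  m <- matrix(stats::runif(n * n), n, n)
  m <- (m + t(m)) / 2
  diag(m) <- 0
  dimnames(m) <- list(labels, labels)
  m
}

# Exhaustive subset-expectation oracle for rarefied richness.
subset_richness_oracle <- function(inc, t) {
  subs <- utils::combn(ncol(inc), t)
  mean(apply(subs, 2, function(s) sum(rowSums(inc[, s, drop = FALSE]) > 0)))
}

# One-factor PERMANOVA pseudo-F computed directly from sums of squared
# distances (independent of vegan).
pseudo_f_oracle <- function(dm, labels) {
  n <- nrow(dm)
  labels <- as.character(labels)
  ss <- function(idx) {
    sub <- dm[idx, idx, drop = FALSE]
    sum(sub[upper.tri(sub)]^2) / length(idx)
  }
  ss_tot <- ss(seq_len(n))
  ss_within <- sum(vapply(split(seq_len(n), labels), ss, numeric(1)))
  k <- length(unique(labels))
  ((ss_tot - ss_within) / (k - 1)) / (ss_within / (n - k))
}

# Tiny labelled count fixture: 4 taxa x 3 samples.
tiny_counts <- function() {
  m <- matrix(c(4, 1, 0, 4,
                0, 2, 3, 1,
                5, 0, 0, 0), nrow = 4,
              dimnames = list(c("tx1", "tx2", "tx3", "tx4"),
                              c("s1", "s2", "s3")))
  m
}

tiny_taxonomy <- function(ids, genus = "Alternaria",
                          species = "Alternaria infectoria") {
  data.frame(taxon_id = ids, kingdom = "Fungi", phylum = "Ascomycota",
             class = "Dothideomycetes", order = "Pleosporales",
             family = "Pleosporaceae",
             genus = rep_len(genus, length(ids)),
             species = rep_len(species, length(ids)),
             stringsAsFactors = FALSE)
}
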