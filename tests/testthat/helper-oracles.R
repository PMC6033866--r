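# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: direct summation, exhaustive enumeration, and a
# from-scratch affine-gap dynamic program.

# Shannon entropy of a count vector, direct summation
oracle_shannon <- function(counts, base = 2) {
  p <- counts[counts > 0] / sum(counts)
  -sum(p * log(p) / log(base))
}

# Bray-Curtis between two count vectors, direct formula
oracle_bray_curtis <- function(u, v) {
  1 - 2 * sum(pmin(u, v)) / (sum(u) + sum(v))
}

# Expected number of distinct patterns after rarefying a count row to
# `depth`, hypergeometric closed form
oracle_expected_richness <- function(row, depth) {
  total <- sum(row)
  sum(1 - choose(total - row, depth) / choose(total, depth))
}

# ANOSIM R by definition: ranked dissimilarities, mean between-group rank
# minus mean within-group rank over M/2
oracle_anosim_R <- function(dmat, groups) {
  n <- nrow(dmat)
  pairs <- t(combn(n, 2))
  dv <- dmat[pairs]
  r <- rank(dv)
  between <- groups[pairs[, 1]] != groups[pairs[, 2]]
  M <- length(dv)
  (mean(r[between]) - mean(r[!between])) / (M / 2)
}

# Exact ANOSIM p over all distinct labelings (small n): proportion of
# labelings whose R is >= the observed R (observed labeling included)
oracle_anosim_exact_p <- function(dmat, groups) {
  n <- nrow(dmat)
  r_obs <- oracle_anosim_R(dmat, groups)
  perms <- .all_permutations(n)
  r_all <- apply(perms, 1, function(ix) oracle_anosim_R(dmat, groups[ix]))
  mean(r_all >= r_obs - 1e-12)
}

.all_permutations <- function(n) {
  if (n == 1) return(matrix(1, 1, 1))
  sub <- .all_permutations(n - 1)
  do.call(rbind, lapply(seq_len(n), function(k)
    cbind(k, sub + (sub >= k))))
}

# Cramer T by direct double summation
oracle_cramer_T <- function(x, y, phi = function(z) z / 2) {
  if (is.vector(x)) x <- matrix(x, ncol = 1)
  if (is.vector(y)) y <- matrix(y, ncol = 1)
  m <- nrow(x); n <- nrow(y)
  ed <- function(a, b) sqrt(sum((a - b)^2))
  sxy <- sxx <- syy <- 0
  for (i in seq_len(m)) for (j in seq_len(n)) sxy <- sxy + phi(ed(x[i, ], y[j, ]))
  for (i in seq_len(m)) for (j in seq_len(m)) sxx <- sxx + phi(ed(x[i, ], x[j, ]))
  for (i in seq_len(n)) for (j in seq_len(n)) syy <- syy + phi(ed(y[i, ], y[j, ]))
  (m * n / (m + n)) * (2 * sxy / (m * n) - sxx / m^2 - syy / n^2)
}

# Exact Cramer p over all choose(m+n, m) splits of the pooled sample
oracle_cramer_exact_p <- function(x, y, phi = function(z) z / 2) {
  if (is.vector(x)) x <- matrix(x, ncol = 1)
  if (is.vector(y)) y <- matrix(y, ncol = 1)
  pool <- rbind(x, y)
  m <- nrow(x); n <- nrow(y)
  t_obs <- oracle_cramer_T(x, y, phi)
  splits <- combn(m + n, m)
  t_all <- apply(splits, 2, function(ix)
    oracle_cramer_T(pool[ix, , drop = FALSE],
                    pool[-ix, , drop = FALSE], phi))
  mean(t_all >= t_obs - 1e-12)
}

# Affine-gap global-local alignment score (Gotoh): the pattern aligns
# globally against a consecutive subsequence of the subject. Penalty for a
# gap of length L is open + ext * L. `score_fun(a, b)` scores one column.
oracle_fitting_score <- function(pattern, subject, score_fun,
                                 open = 5, ext = 2) {
  p <- strsplit(pattern, "")[[1]]; s <- strsplit(subject, "")[[1]]
  m <- length(p); n <- length(s)
  NEG <- -1e9
  M <- matrix(NEG, m + 1, n + 1)   # p_i aligned to s_j
  X <- matrix(NEG, m + 1, n + 1)   # gap in subject (pattern base unmatched)
  Y <- matrix(NEG, m + 1, n + 1)   # gap in pattern (subject base skipped)
  M[1, ] <- 0                      # free leading subject
  for (i in 2:(m + 1)) {
    X[i, 1] <- -(open + ext * (i - 1))
    for (j in 2:(n + 1)) {
      best_prev <- max(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1])
      M[i, j] <- best_prev + score_fun(p[i - 1], s[j - 1])
      X[i, j] <- max(max(M[i - 1, j], Y[i - 1, j]) - (open + ext), X[i - 1, j] - ext)
      Y[i, j] <- max(max(M[i, j - 1], X[i, j - 1]) - (open + ext), Y[i, j - 1] - ext)
    }
  }
  max(M[m + 1, ], X[m + 1, ], Y[m + 1, ])  # free trailing subject
}

# column score matching the package's bisulfite-aware scheme (read C
# matches collapsed-reference T)
bisulfite_score_fun <- function(match = 2, mismatch = -3) {
  function(a, b) {
    if (a == b || (a == "C" && b == "T")) match else mismatch
  }
}

revcomp_chr <- function(x) {
  chartr("ACGT", "TGCA", paste(rev(strsplit(x, "")[[1]]), collapse = ""))
}

# small shared fixture: a 60 bp reference with 4 CpGs and plenty of CpHs
tiny_reference <- function(seed = 11) {
  make_synthetic_reference(60, 4, n_cph_min = 8, seed = seed,
                           locus_name = "tiny")
}
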