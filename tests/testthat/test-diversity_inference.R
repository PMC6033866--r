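test_that("alpha diversity matches direct-summation Shannon on small tables", {
  pats <- c("0011", "0101", "1100", "1111")
  tab <- epiallele_count_table(matrix(c(4L, 0L, 0L, 0L), 1,
                                      dimnames = list("s", pats)),
                               rarefaction_depth = 4L)
  a <- alpha_diversity(tab)
  expect_identical(a$observed_epialleles, 1L)
  expect_equal(a$shannon, 0)
  uni <- epiallele_count_table(matrix(rep(3L, 4), 1, dimnames = list("s", pats)),
                               rarefaction_depth = 12L)
  expect_equal(alpha_diversity(uni)$shannon, 2)
  tri <- epiallele_count_table(matrix(c(2L, 1L, 1L, 0L), 1,
                                      dimnames = list("s", pats)),
                               rarefaction_depth = 4L)
  expect_equal(alpha_diversity(tri)$shannon, 1.5)
  # random tables vs the oracle, to 1e-12
  set.seed(8)
  for (i in 1:20) {
    counts <- matrix(rpois(12, 4), 3, 4, dimnames = list(NULL, pats))
    counts[rowSums(counts) == 0, 1] <- 1L
    t2 <- epiallele_count_table(counts, rarefaction_depth = 1L)
    a2 <- alpha_diversity(t2)
    for (r in 1:3)
      expect_equal(a2$shannon[r], oracle_shannon(counts[r, ]), tolerance = 1e-12)
  }
  # unrarefied input computes but warns
  expect_warning(alpha_diversity(epiallele_count_table(
    matrix(c(1L, 2L), 1, dimnames = list("s", pats[1:2])))), "rarefied")
  # Shannon bounded by log2 observed, equality iff uniform
  expect_lte(alpha_diversity(tri)$shannon,
             log2(alpha_diversity(tri)$observed_epialleles))
})

test_that("Bray-Curtis matches its formula, bounds, and flags empty samples", {
  pats <- c("01", "10")
  m <- matrix(c(1L, 1L, 1L, 3L), 2, byrow = TRUE, dimnames = list(c("a", "b"), pats))
  d <- bray_curtis(epiallele_count_table(m, rarefaction_depth = 2L))
  expect_equal(d["a", "b"], 1 / 3)                       # 1 - 2*2/6
  expect_equal(d["a", "a"], 0)
  ident <- matrix(c(2L, 3L, 2L, 3L), 2, byrow = TRUE,
                  dimnames = list(c("a", "b"), pats))
  expect_equal(bray_curtis(ident)["a", "b"], 0)
  disj <- matrix(c(5L, 0L, 0L, 7L), 2, byrow = TRUE,
                 dimnames = list(c("a", "b"), pats))
  expect_equal(bray_curtis(disj)["a", "b"], 1)
  set.seed(9)
  x <- matrix(rpois(40, 5), 4, 10)
  d2 <- bray_curtis(x)
  expect_true(isSymmetric(unclass(d2)))
  expect_true(all(d2 >= 0 & d2 <= 1))
  for (i in 1:3) for (j in (i + 1):4)
    expect_equal(d2[i, j], oracle_bray_curtis(x[i, ], x[j, ]), tolerance = 1e-12)
  empty <- matrix(c(0L, 0L, 1L, 2L), 2, byrow = TRUE,
                  dimnames = list(c("z", "b"), pats))
  expect_warning(de <- bray_curtis(empty), "zero-sum")
  expect_true(is.na(de["z", "b"]))
})

test_that("PCoA reproduces known configurations and reports negative eigenvalues", {
  # two samples at distance d: one axis, separation d, 100% variance
  d2 <- matrix(c(0, 0.4, 0.4, 0), 2, dimnames = list(c("a", "b"), c("a", "b")))
  p2 <- pcoa(d2)
  expect_identical(ncol(p2$points), 1L)
  expect_equal(abs(p2$points[1, 1] - p2$points[2, 1]), 0.4)
  expect_equal(p2$variance_fraction[1], 1)
  # three equidistant samples: two equal positive eigenvalues, 50%/50%
  d3 <- matrix(0.6, 3, 3); diag(d3) <- 0
  p3 <- pcoa(d3)
  expect_equal(p3$eigenvalues[1], p3$eigenvalues[2], tolerance = 1e-9)
  expect_equal(unname(p3$variance_fraction[1:2]), c(0.5, 0.5), tolerance = 1e-9)
  # Euclidean-embeddable input: embedding distances reproduce the input
  set.seed(10)
  pts <- matrix(rnorm(5 * 3), 5, 3)
  din <- as.matrix(dist(pts))
  pe <- pcoa(din)
  expect_equal(as.matrix(dist(pe$points)), din, ignore_attr = TRUE,
               tolerance = 1e-8)
  expect_length(pe$negative_eigenvalues[abs(pe$negative_eigenvalues) > 1e-8], 0)
  expect_error(pcoa(matrix(c(0, 1, 2, 0), 2)), "symmetric")
})

test_that("ANOSIM attains R = 1 on perfectly separated groups", {
  # between-group distances all exceed within-group distances
  pts <- rbind(matrix(rnorm(8, 0, 0.01), 4), matrix(rnorm(8, 10, 0.01), 4))
  d <- as.matrix(dist(pts))
  g <- rep(c("A", "B"), each = 4)
  res <- anosim(d, g, n_permutations = 199, seed = 1)
  expect_equal(res$statistic, 1)
  expect_lte(res$p_value, 0.05)
  expect_gte(res$p_value, 1 / 200)
  expect_error(anosim(d, c("A", rep("B", 7))), "at least two samples")
})

test_that("ANOSIM agrees with the definitional oracle and exhaustive p", {
  set.seed(12)
  x <- matrix(rpois(6 * 8, 6), 6, 8)
  d <- bray_curtis(x)
  g <- rep(c("A", "B"), each = 3)
  res <- anosim(d, g, n_permutations = 999, seed = 3)
  expect_equal(res$statistic, oracle_anosim_R(unclass(d), g), tolerance = 1e-12)
  p_exact <- oracle_anosim_exact_p(unclass(d), g)
  expect_lt(abs(res$p_value - p_exact), 0.06)
  # rank invariance under monotone transformation of the dissimilarities
  res_sq <- anosim(unclass(d)^2, g, n_permutations = 99, seed = 3)
  expect_equal(res_sq$statistic, res$statistic, tolerance = 1e-12)
})

test_that("ANOSIM p-values are seed-reproducible with the +1 convention", {
  set.seed(21)
  x <- matrix(rpois(60, 5), 6, 10)
  d <- bray_curtis(x)
  g <- rep(c("A", "B"), 3)
  r1 <- anosim(d, g, n_permutations = 199, seed = 9)
  r2 <- anosim(d, g, n_permutations = 199, seed = 9)
  expect_identical(r1$p_value, r2$p_value)
  expect_gte(r1$p_value, 1 / 200)
})

test_that("the Cramer statistic follows its closed form and invariances", {
  # identical multisets: T = 0
  x <- matrix(c(0, 1, 2), ncol = 1)
  expect_equal(cramer_test(x, x, n_resamples = 10, seed = 1)$statistic, 0)
  # x = {0}, y = {1}: T = 0.5 with the z/2 kernel
  expect_equal(cramer_test(0, 1, n_resamples = 10, seed = 1)$statistic, 0.5)
  set.seed(31)
  a <- matrix(rnorm(12), 4); b <- matrix(rnorm(15, 1), 5)
  t0 <- cramer_test(a, b, n_resamples = 5, seed = 1)$statistic
  expect_equal(t0, oracle_cramer_T(a, b), tolerance = 1e-12)
  # invariant under common translation
  shift <- matrix(rep(c(3, -2, 7), each = 1), 1)
  t_shift <- cramer_test(a + rep(shift, each = 4),
                         b + rep(shift, each = 5),
                         n_resamples = 5, seed = 1)$statistic
  expect_equal(t_shift, t0, tolerance = 1e-9)
  # scales as the kernel under common scaling (phi(z) = z/2 is linear)
  t_scaled <- cramer_test(2 * a, 2 * b, n_resamples = 5, seed = 1)$statistic
  expect_equal(t_scaled, 2 * t0, tolerance = 1e-9)
})

test_that("Cramer permutation p matches exhaustive enumeration at m = n = 3", {
  set.seed(41)
  x <- c(0.1, 0.5, 0.9); y <- c(1.4, 1.9, 2.6)
  p_exact <- oracle_cramer_exact_p(x, y)
  res <- cramer_test(x, y, n_resamples = 2000, seed = 2)
  expect_lt(abs(res$p_value - p_exact), 0.05)
  expect_gte(res$p_value, 1 / 2001)
  # bootstrap mode also runs and is seeded
  rb <- cramer_test(x, y, n_resamples = 200, seed = 2, method = "bootstrap")
  expect_identical(rb$p_value,
                   cramer_test(x, y, n_resamples = 200, seed = 2,
                               method = "bootstrap")$p_value)
  expect_error(cramer_test(numeric(0), 1), "at least one")
})

test_that("group comparisons: t tests, Bonferroni, ANOVA and Tukey", {
  set.seed(51)
  # identical groups -> t = 0, p = 1
  m <- matrix(rep(c(50, 60, 70), each = 6), 6, 3)
  g <- rep(c("CTRL", "SCZ"), each = 3)
  m_jit <- m + rnorm(18, 0, 2)
  m_ident <- rbind(m_jit[1:3, ], m_jit[1:3, ])
  res <- group_comparisons(m_ident, g)
  expect_true(all(abs(res$t_table$t) < 1e-12))
  expect_true(all(res$t_table$p_raw > 1 - 1e-12))
  # Bonferroni: adjusted = min(1, m * raw)
  res2 <- group_comparisons(m_jit, g)
  expect_equal(res2$t_table$p_bonferroni,
               pmin(1, 3 * res2$t_table$p_raw))
  # degenerate site (zero variance in both groups) flagged, not crashed
  m_deg <- m_jit; m_deg[, 2] <- 55
  res3 <- group_comparisons(m_deg, g)
  expect_true(res3$t_table$degenerate[2])
  expect_true(is.na(res3$t_table$p_raw[2]))
  # ANOVA + Tukey layer over areas
  areas <- rep(c("HIPP", "DLPFC", "CB"), each = 6)
  alpha <- c(rnorm(6, 10), rnorm(6, 10.5), rnorm(6, 6))
  res4 <- group_comparisons(m_jit[rep(1:6, 3), ], rep(g, 3),
                            alpha_metric = alpha, areas = areas)
  expect_lt(res4$anova$p_value, 0.05)
  expect_identical(nrow(res4$tukey), 3L)
  # Tukey agrees with direct TukeyHSD on the same fit
  direct <- stats::TukeyHSD(stats::aov(alpha ~ as.factor(areas)))[[1]]
  expect_equal(sort(res4$tukey$p_adjusted), sort(unname(direct[, "p adj"])),
               tolerance = 1e-9)
})

test_that("null data give a uniform family-wise error under Bonferroni", {
  set.seed(61)
  n_rep <- 300; m_sites <- 8
  fwe <- 0L
  g <- rep(c("A", "B"), each = 5)
  for (r in seq_len(n_rep)) {
    m <- matrix(rnorm(10 * m_sites, 50, 5), 10, m_sites)
    res <- group_comparisons(m, g)
    if (any(res$t_table$p_bonferroni < 0.05, na.rm = TRUE)) fwe <- fwe + 1L
  }
  # family-wise error at most ~alpha (3 SD slack above 0.05)
  expect_lte(fwe / n_rep, 0.05 + 3 * sqrt(0.05 * 0.95 / n_rep))
})
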