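# minimal profile data.frame builder (call strings only)
make_profiles <- function(calls, locus = "toy") {
  n_amb <- vapply(strsplit(calls, ""), function(x) sum(x == "2"), integer(1))
  out <- data.frame(read_id = sprintf("r%03d", seq_along(calls)),
                    locus = locus, calls = calls, n_ambiguous = n_amb,
                    bisulfite_efficiency = 1,
                    aligned_fraction = 1, read_length = 10L,
                    mcph_count = 0L, total_cph_aligned = 10L,
                    stringsAsFactors = FALSE)
  class(out) <- c("methylation_profiles", "data.frame")
  out
}
toy_ref <- function(n_cpg = 2)
  make_synthetic_reference(20 + 4 * n_cpg, n_cpg, seed = 40 + n_cpg,
                           locus_name = "toy")

test_that("count tables count unambiguous patterns and tally ambiguity", {
  ref <- toy_ref(2)
  tab <- build_count_table(make_profiles(c("11", "00", "10", "11")), ref)
  expect_identical(tab$counts[1, c("00", "10", "11")], c(`00` = 1L, `10` = 1L, `11` = 2L))
  # ambiguous-containing molecules are excluded but tallied
  tab2 <- build_count_table(make_profiles(c("12", "11")), ref)
  expect_identical(colnames(tab2$counts), "11")
  expect_identical(unname(tab2$ambiguous_tally), 1L)
  # conservation: counts + ambiguous = retained profiles
  expect_identical(sum(tab2$counts) + sum(tab2$ambiguous_tally), 2L)
  # mixed loci rejected
  bad <- make_profiles("11", locus = "other")
  expect_error(build_count_table(bad, ref), "locus")
})

test_that("a noise-free synthetic sample reproduces its multinomial draw", {
  ref <- make_synthetic_reference(150, 4, n_cph_min = 20, seed = 19)
  spec <- epiallele_mixture_spec(ref$locus_name,
                                 c("1111" = 0.5, "0000" = 0.3, "1001" = 0.2),
                                 3000, seed = 23)
  mol <- sample_epialleles(spec, ref)
  rd <- emit_bisulfite_reads(mol, ref, seed = 24)
  prof <- call_profiles(align_bisulfite(rd, ref), ref)
  tab <- build_count_table(prof, ref)
  truth <- table(mol$patterns)
  expect_identical(tab$counts[1, names(truth)],
                   stats::setNames(as.integer(truth), names(truth)))
})

test_that("rarefaction is exact at full depth, at zero, and errors past depth", {
  counts <- matrix(c(5L, 5L), 1, dimnames = list("s1", c("01", "10")))
  tab <- epiallele_count_table(counts)
  expect_identical(rarefy(tab, 10, seed = 1)$counts, counts)
  r0 <- rarefy(tab, 0, seed = 1)
  expect_identical(sum(r0$counts), 0L)
  expect_identical(alpha_diversity(r0)$observed_epialleles, 0L)
  expect_error(rarefy(tab, 11), "s1")
  # every row sums to depth; deterministic under seed
  set.seed(14)
  pats4 <- vapply(1:10, function(i) paste0(strrep("0", i - 1), "1",
                                           strrep("0", 10 - i)), "")
  big <- epiallele_count_table(matrix(rpois(40, 10) + 1L, 4, 10,
                                      dimnames = list(NULL, pats4)))
  r <- rarefy(big, 20, seed = 3)
  expect_true(all(rowSums(r$counts) == 20L))
  expect_identical(r$counts, rarefy(big, 20, seed = 3)$counts)
})

test_that("rarefied richness matches the hypergeometric closed form", {
  counts <- matrix(c(5L, 5L), 1, dimnames = list("s1", c("01", "10")))
  tab <- epiallele_count_table(counts)
  expected <- oracle_expected_richness(c(5, 5), 4)
  expect_equal(expected, 2 * (1 - choose(5, 4) / choose(10, 4))) # 1.95238...
  draws <- vapply(1:2000, function(s)
    alpha_diversity(rarefy(tab, 4, seed = s))$observed_epialleles, integer(1))
  se <- stats::sd(draws) / sqrt(length(draws))
  expect_lt(abs(mean(draws) - expected), 3 * se)
})

test_that("rarefaction never increases observed richness", {
  set.seed(55)
  pats <- vapply(1:10, function(i)
    paste0(strrep("0", i - 1), "1", strrep("0", 10 - i)), "")
  counts <- matrix(rpois(30, 3), 3, 10, dimnames = list(NULL, pats))
  tab <- epiallele_count_table(counts)
  # unrarefied on purpose: richness of the full table is the reference point
  full <- suppressWarnings(alpha_diversity(tab))$observed_epialleles
  for (s in 1:10) {
    r <- rarefy(tab, min(rowSums(counts)) %/% 2L, seed = s)
    expect_true(all(alpha_diversity(r)$observed_epialleles <= full))
  }
})

test_that("class distributions depend only on the methyl count per molecule", {
  ref <- toy_ref(2)
  tab <- build_count_table(make_profiles(c("11", "00", "10", "01")), ref)
  cd <- class_distribution(tab)
  expect_equal(unname(cd$frequencies[1, ]), c(0.25, 0.5, 0.25))
  expect_equal(sum(cd$frequencies), 1)
  # single fully methylated pattern -> all mass at the top class
  d10 <- matrix(7L, 1, 1, dimnames = list("s", strrep("1", 10)))
  cd10 <- class_distribution(epiallele_count_table(d10))
  expect_equal(unname(cd10$frequencies[1, 11]), 1)
  # invariance under popcount-preserving relabeling
  a <- epiallele_count_table(matrix(c(3L, 2L), 1,
                                    dimnames = list("s", c("1100", "0001"))))
  b <- epiallele_count_table(matrix(c(3L, 2L), 1,
                                    dimnames = list("s", c("0011", "0100"))))
  expect_identical(class_distribution(a)$frequencies,
                   class_distribution(b)$frequencies)
})

test_that("per-site percentages exclude ambiguous calls sitewise", {
  ref <- toy_ref(1)
  p <- make_profiles(c("1", "1", "0"), locus = "toy")
  expect_equal(unname(per_site_methylation(p, ref)), 100 * 2 / 3,
               tolerance = 1e-12)
  p2 <- make_profiles(c("0", "0", "2"), locus = "toy")
  expect_equal(unname(per_site_methylation(p2, ref)), 0)
  # a site with no unambiguous call is missing, not zero
  p3 <- make_profiles(c("2", "2"), locus = "toy")
  expect_true(is.na(per_site_methylation(p3, ref)))
  # names carry TSS-relative labels
  expect_identical(names(per_site_methylation(p, ref)),
                   sprintf("%+d", ref$cpg_labels))
})

test_that("regional average pools calls and matches site means at equal depth", {
  expect_equal(region_average_methylation(make_profiles(c("11", "11"))), 100)
  expect_equal(region_average_methylation(make_profiles(c("10", "01"))), 50)
  # pooled average equals depth-weighted site mean when depths are equal
  set.seed(66)
  ref <- toy_ref(4)
  calls <- vapply(1:50, function(i)
    paste(sample(0:1, 4, TRUE), collapse = ""), "")
  p <- make_profiles(calls)
  expect_equal(region_average_methylation(p),
               mean(per_site_methylation(p, ref)), tolerance = 1e-12)
})

test_that("synthetic per-site rates are recovered within binomial error", {
  ref <- make_synthetic_reference(150, 3, n_cph_min = 20, seed = 29)
  freqs <- c("111" = 0.3, "110" = 0.3, "010" = 0.2, "000" = 0.2)
  spec <- epiallele_mixture_spec(ref$locus_name, freqs, 10000, seed = 31)
  mol <- sample_epialleles(spec, ref)
  rd <- emit_bisulfite_reads(mol, ref, seed = 32)
  prof <- call_profiles(align_bisulfite(rd, ref), ref)
  pct <- per_site_methylation(prof, ref)
  truth <- mol$expected_site_freq   # 0.6, 0.8, 0.5
  tol <- 4 * 100 * sqrt(truth * (1 - truth) / 10000)
  expect_true(all(abs(pct - 100 * truth) < tol))
})

test_that("mCpH summaries follow the stated formulas and corrections", {
  p <- make_profiles(rep("1", 100))
  p$mcph_count <- c(rep(1L, 50), rep(0L, 50))   # 50 mCpH total
  p$total_cph_aligned <- rep(5L, 100)           # 500 CpH total
  conv <- structure(list(sample_id = "s", n_spike_reads = 10,
                         conversion_efficiency = 0.98,
                         residual_c_fraction = 0.02),
                    class = "conversion_report")
  s <- mch_summary(p, conv)
  expect_equal(s$mcph_percent, 100 * 50 / 500)            # 10%
  expect_equal(s$mcph_per_molecule_raw, 0.5)
  expect_equal(s$mcph_percent_corrected, 100 * (0.1 - 0.02))
  expect_equal(s$mcph_per_molecule_corrected, (0.1 - 0.02) * 5)
  expect_equal(s$mcph_percent_calibrated, 100 * (0.1 - 0.02) / 0.98)
  expect_equal(s$mcpg_per_molecule, 1)
  # correction clamps at zero rather than reporting negative methylation
  conv$residual_c_fraction <- 0.5
  s2 <- mch_summary(p, conv)
  expect_identical(s2$mcph_percent_corrected, 0)
  expect_identical(s2$mcph_per_molecule_corrected, 0)
  # missing report: corrected equals raw, with a warning
  expect_warning(s3 <- mch_summary(p, NULL), "conversion report")
  expect_equal(s3$mcph_percent_corrected, s3$mcph_percent)
})

test_that("the spike-in analysed as a locus shows ~100 * failure-rate methylation", {
  ref <- make_synthetic_reference(150, 4, n_cph_min = 20, seed = 37)
  spec <- epiallele_mixture_spec(ref$locus_name, c("0000" = 1), 5000,
                                 conversion_failure_rate = 0.02, seed = 41)
  rd <- emit_bisulfite_reads(sample_epialleles(spec, ref), ref,
                             conversion_failure_rate = 0.02, seed = 42)
  prof <- call_profiles(align_bisulfite(rd, ref), ref)
  avg <- region_average_methylation(prof)
  expect_lt(abs(avg - 2), 4 * 100 * sqrt(0.02 * 0.98 / (5000 * 4)))
})
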