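#' Build a sample-by-epiallele count table
#'
#' Each retained molecule's 0/1 call string is an epiallele; molecules
#' carrying any ambiguous call (2) have no defined pattern and are
#' excluded from the table (tallied separately). The result is the
#' BIOM-style object all diversity analyses run on.
#'
#' @param profiles A `methylation_profiles` data.frame (one sample) or a
#'   named list of them (one element per sample).
#' @param reference The [amplicon_reference()] the profiles were called
#'   against; all profiles must come from its locus.
#' @return An object of class `epiallele_count_table`: `counts` (integer
#'   matrix, samples x patterns, patterns sorted lexicographically),
#'   `locus_name`, `n_cpg`, `ambiguous_tally` (per sample),
#'   `rarefaction_depth` and `seed` (NULL until [rarefy()]).
#' @export
build_count_table <- function(profiles, reference) {
  stopifnot(inherits(reference, "amplicon_reference"))
  if (inherits(profiles, "methylation_profiles")) profiles <- list(sample = profiles)
  stopifnot(is.list(profiles), length(profiles) >= 1L, !is.null(names(profiles)))
  amb <- integer(length(profiles)); names(amb) <- names(profiles)
  per_sample <- vector("list", length(profiles))
  for (i in seq_along(profiles)) {
    p <- profiles[[i]]
    if (!all(p$locus == reference$locus_name))
      stop("profiles from locus '", unique(p$locus)[1],
           "' do not match reference '", reference$locus_name, "'")
    if (any(nchar(p$calls) != reference$n_cpg))
      stop("call-string length does not match the reference CpG count")
    is_amb <- p$n_ambiguous > 0L
    amb[i] <- sum(is_amb)
    per_sample[[i]] <- table(p$calls[!is_amb])
  }
  patterns <- sort(unique(unlist(lapply(per_sample, names))))
  counts <- matrix(0L, length(profiles), length(patterns),
                   dimnames = list(names(profiles), patterns))
  for (i in seq_along(per_sample))
    counts[i, names(per_sample[[i]])] <- as.integer(per_sample[[i]])
  structure(list(counts = counts, locus_name = reference$locus_name,
                 n_cpg = reference$n_cpg, ambiguous_tally = amb,
                 rarefaction_depth = NULL, seed = NULL),
            class = "epiallele_count_table")
}

#' Construct a count table directly from counts
#'
#' Used for tables read back from disk or built in simulations that skip
#' the read level.
#'
#' @param counts Integer matrix, samples x patterns; column names are the
#'   binary pattern strings, row names the sample ids.
#' @param locus_name Locus label.
#' @param rarefaction_depth,seed Optional rarefaction provenance.
#' @param n_cpg CpG count; required only for the degenerate zero-pattern
#'   table, otherwise inferred from the pattern strings.
#' @export
epiallele_count_table <- function(counts, locus_name = "locus",
                                  rarefaction_depth = NULL, seed = NULL,
                                  n_cpg = NULL) {
  stopifnot(is.matrix(counts), all(counts >= 0))
  if (ncol(counts) > 0L) {
    stopifnot(!is.null(colnames(counts)),
              all(grepl("^[01]+$", colnames(counts))))
    if (anyDuplicated(colnames(counts))) stop("patterns must be unique")
    n_cpg <- unique(nchar(colnames(counts)))
    if (length(n_cpg) != 1L) stop("patterns must share one length")
  } else if (is.null(n_cpg)) n_cpg <- 0L
  if (is.null(rownames(counts)))
    rownames(counts) <- sprintf("S%02d", seq_len(nrow(counts)))
  storage.mode(counts) <- "integer"
  structure(list(counts = counts, locus_name = locus_name, n_cpg = n_cpg,
                 ambiguous_tally = NULL,
                 rarefaction_depth = rarefaction_depth, seed = seed),
            class = "epiallele_count_table")
}

#' @export
print.epiallele_count_table <- function(x, ...) {
  cat(sprintf("epiallele_count_table '%s': %d samples x %d patterns (N = %d CpG)%s\n",
              x$locus_name, nrow(x$counts), ncol(x$counts), x$n_cpg,
              if (!is.null(x$rarefaction_depth))
                sprintf(", rarefied to %d (seed %s)", x$rarefaction_depth,
                        format(x$seed)) else ""))
  invisible(x)
}

#' Rarefy a count table to a common depth
#'
#' Each sample's molecules are subsampled without replacement to exactly
#' `depth`, removing depth differences before diversity comparisons. A
#' single seeded draw is taken (the seed is recorded in the result); use
#' repeated calls with different seeds for variance estimation.
#'
#' @param table An [epiallele_count_table()].
#' @param depth Target depth; default is the minimum sample depth.
#' @param seed Integer seed for the draw.
#' @return The rarefied table (patterns with all-zero columns retained,
#'   so pattern order is stable across draws).
#' @export
rarefy <- function(table, depth = NULL, seed = 1L) {
  stopifnot(inherits(table, "epiallele_count_table"))
  rs <- rowSums(table$counts)
  if (is.null(depth)) depth <- min(rs)
  depth <- as.integer(depth)
  if (any(rs < depth)) {
    bad <- rownames(table$counts)[which(rs < depth)[1]]
    stop(sprintf("sample '%s' has only %d molecules (< depth %d)",
                 bad, rs[bad], depth))
  }
  out <- table$counts
  with_seed(seed, {
    for (i in seq_len(nrow(out))) {
      row <- table$counts[i, ]
      if (sum(row) == depth) next
      if (depth == 0L) { out[i, ] <- 0L; next }
      drawn <- sample(rep.int(seq_along(row), row), depth)
      out[i, ] <- tabulate(drawn, nbins = length(row))
    }
  })
  structure(list(counts = out, locus_name = table$locus_name,
                 n_cpg = table$n_cpg, ambiguous_tally = table$ambiguous_tally,
                 rarefaction_depth = depth, seed = as.integer(seed)),
            class = "epiallele_count_table")
}

#' Per-sample epiallele class distribution
#'
#' The class of a molecule is its number of methylated CpGs, ignoring
#' positions; class frequencies over 0..N are the heatmap rows of the
#' class analysis.
#'
#' @param table An [epiallele_count_table()] (conventionally rarefied).
#' @return Object of class `class_distribution`: `frequencies` (matrix,
#'   samples x classes 0..N, rows summing to 1) and `n_molecules` per
#'   sample.
#' @export
class_distribution <- function(table) {
  stopifnot(inherits(table, "epiallele_count_table"))
  N <- table$n_cpg
  cls <- pattern_class(colnames(table$counts))
  freq <- matrix(0, nrow(table$counts), N + 1L,
                 dimnames = list(rownames(table$counts), as.character(0:N)))
  for (k in 0:N) {
    sel <- which(cls == k)
    if (length(sel)) freq[, k + 1L] <- rowSums(table$counts[, sel, drop = FALSE])
  }
  n_mol <- rowSums(freq)
  if (any(n_mol == 0)) stop("sample with zero molecules has no class distribution")
  structure(list(frequencies = freq / n_mol, n_molecules = n_mol,
                 locus_name = table$locus_name),
            class = "class_distribution")
}

#' Per-CpG-site percent methylation
#'
#' Site percent is 100 * methylated / (methylated + unmethylated) calls;
#' ambiguous calls are excluded sitewise, so a read with one ambiguous
#' site still contributes at its other sites. A site with no unambiguous
#' call is reported as NA (missing), not 0.
#'
#' @param profiles A `methylation_profiles` data.frame.
#' @param reference The [amplicon_reference()]; supplies the TSS-relative
#'   site labels used as names.
#' @return Named numeric vector of length N (percent), names like "+11".
#' @export
per_site_methylation <- function(profiles, reference) {
  stopifnot(inherits(profiles, "methylation_profiles"),
            inherits(reference, "amplicon_reference"))
  cm <- .calls_matrix(profiles)
  meth <- colSums(cm == 1L)
  unmeth <- colSums(cm == 0L)
  pct <- ifelse(meth + unmeth > 0L, 100 * meth / (meth + unmeth), NA_real_)
  names(pct) <- sprintf("%+d", reference$cpg_labels)
  pct
}

#' Regional average percent methylation
#'
#' Pooled over all unambiguous calls of all reads and sites (each call
#' weighted equally, not a mean of site means). Equals the depth-weighted
#' mean of per-site percents; when some sites have more missing calls
#' than others the two differ, and [per_site_methylation()] plus an
#' unweighted mean gives the site-mean variant.
#'
#' @inheritParams per_site_methylation
#' @return Percent methylation (scalar).
#' @export
region_average_methylation <- function(profiles) {
  stopifnot(inherits(profiles, "methylation_profiles"))
  cm <- .calls_matrix(profiles)
  meth <- sum(cm == 1L); unmeth <- sum(cm == 0L)
  if (meth + unmeth == 0L) stop("no unambiguous calls")
  100 * meth / (meth + unmeth)
}

#' Non-CpG (CpH) and CpG methylation summary with spike-in correction
#'
#' Computes the aggregate CpH methylation statistics of one sample:
#' \itemize{
#'   \item `mcph_percent` = 100 * (total mCpH) / (total aligned CpH);
#'   \item `mcph_per_molecule_raw` = total mCpH / number of reads;
#'   \item `mcph_per_molecule_corrected` and `mcph_percent_corrected`:
#'     the residual-C fraction measured on the unmethylated spike-in is
#'     subtracted from the observed CpH-methylation fraction (clamped at
#'     zero) before scaling -- the conventional spike-in subtraction;
#'   \item `mcph_percent_calibrated` = 100 * (p - f) / (1 - f) with p the
#'     observed fraction and f the spike-in residual: the estimator that
#'     is unbiased for the true CpH methylation rate when conversion
#'     failure acts independently per site (subtraction alone
#'     under-corrects by f * p_true);
#'   \item `mcpg_per_molecule` = methylated CpG calls / number of reads.
#' }
#'
#' @param profiles A `methylation_profiles` data.frame (one sample).
#' @param conversion_report A `conversion_report` from
#'   [estimate_conversion_efficiency()], or NULL -- corrected values then
#'   equal the raw ones and a warning is issued.
#' @return List of class `methylation_summary`.
#' @export
mch_summary <- function(profiles, conversion_report = NULL) {
  stopifnot(inherits(profiles, "methylation_profiles"))
  n_reads <- nrow(profiles)
  if (n_reads == 0L) stop("no profiles")
  total_mcph <- sum(profiles$mcph_count)
  total_cph <- sum(profiles$total_cph_aligned)
  if (total_cph == 0L) stop("no aligned CpH positions")
  p <- total_mcph / total_cph
  if (is.null(conversion_report)) {
    warning("no conversion report: corrected mCpH values equal raw values")
    f <- 0
  } else {
    stopifnot(inherits(conversion_report, "conversion_report"))
    f <- conversion_report$residual_c_fraction
  }
  cph_per_mol <- total_cph / n_reads
  cm <- .calls_matrix(profiles)
  structure(list(
    n_reads = n_reads,
    mcph_percent = 100 * p,
    mcph_per_molecule_raw = total_mcph / n_reads,
    mcph_per_molecule_corrected = max(0, p - f) * cph_per_mol,
    mcph_percent_corrected = 100 * max(0, p - f),
    mcph_percent_calibrated = if (f < 1) 100 * max(0, (p - f) / (1 - f)) else NA_real_,
    mcpg_per_molecule = sum(cm == 1L) / n_reads,
    residual_c_fraction = f
  ), class = "methylation_summary")
}

# call strings -> integer matrix reads x sites
.calls_matrix <- function(profiles) {
  m <- do.call(rbind, strsplit(profiles$calls, "", fixed = TRUE))
  storage.mode(m) <- "integer"
  m
}
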