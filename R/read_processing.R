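#' Filtering thresholds for per-read QC
#'
#' Defaults are package choices exposed in full (the upstream pipeline the
#' field uses applies the same four read-level criteria but does not
#' publish its values): reads must be within 10% of the reference length,
#' show >= 98% CpH conversion (bisulfite efficiency), have at most 10%
#' ambiguous CpG calls, and align over at least 60% of the reference.
#' The mean-quality cutoff of 33 is the conventional value for this assay.
#'
#' @param min_mean_phred Minimum arithmetic mean per-base PHRED score.
#' @param length_tolerance Allowed relative deviation of read length from
#'   the reference length.
#' @param min_bisulfite_efficiency Minimum fraction of aligned CpH
#'   cytosines read as T.
#' @param max_ambiguous_cpg_fraction Maximum fraction of CpG calls equal
#'   to 2 (ambiguous).
#' @param min_aligned_fraction Minimum fraction of reference positions
#'   covered by the alignment.
#' @return A list of class `filter_thresholds`.
#' @export
filter_thresholds <- function(min_mean_phred = 33,
                              length_tolerance = 0.10,
                              min_bisulfite_efficiency = 0.98,
                              max_ambiguous_cpg_fraction = 0.10,
                              min_aligned_fraction = 0.60) {
  stopifnot(length_tolerance >= 0,
            min_bisulfite_efficiency >= 0, min_bisulfite_efficiency <= 1,
            max_ambiguous_cpg_fraction >= 0, max_ambiguous_cpg_fraction <= 1,
            min_aligned_fraction >= 0, min_aligned_fraction <= 1)
  structure(list(min_mean_phred = min_mean_phred,
                 length_tolerance = length_tolerance,
                 min_bisulfite_efficiency = min_bisulfite_efficiency,
                 max_ambiguous_cpg_fraction = max_ambiguous_cpg_fraction,
                 min_aligned_fraction = min_aligned_fraction),
            class = "filter_thresholds")
}

#' Read a FASTQ file of merged amplicon reads
#'
#' @param path FASTQ path (PHRED+33 qualities).
#' @return A `Biostrings::QualityScaledDNAStringSet`.
#' @export
read_sample_fastq <- function(path) {
  quiet_mcols(Biostrings::readQualityScaledDNAStringSet(path))
}

#' Mean-PHRED quality filter
#'
#' A read passes iff the arithmetic mean of its per-base PHRED scores is
#' at least `min_mean_phred`.
#'
#' @param reads A `QualityScaledDNAStringSet` (from [read_sample_fastq()])
#'   or a `synthetic_reads` object.
#' @param min_mean_phred Threshold (default 33).
#' @return List: `pass` (the passing reads, same class as input),
#'   `n_pass`, `n_fail`, `mean_phred` (per input read).
#' @export
quality_filter <- function(reads, min_mean_phred = 33) {
  if (inherits(reads, "synthetic_reads")) {
    mq <- reads$truth$mean_phred
    keep <- mq >= min_mean_phred
    pass <- reads
    pass$sequences <- reads$sequences[keep]
    pass$qualities <- reads$qualities[keep]
    pass$truth <- reads$truth[keep, , drop = FALSE]
  } else {
    stopifnot(methods::is(reads, "QualityScaledDNAStringSet"))
    qm <- methods::as(Biostrings::quality(reads), "IntegerList")
    mq <- vapply(qm, mean, numeric(1))
    keep <- mq >= min_mean_phred
    pass <- quiet_mcols(reads[keep])
  }
  list(pass = pass, n_pass = sum(keep), n_fail = sum(!keep), mean_phred = mq)
}

#' Bisulfite-aware alignment of reads to an amplicon reference
#'
#' Aligns each read, in the bisulfite-insensitive collapsed space, against
#' the fully converted (all C to T) reference with an affine-gap
#' global-local alignment (the read global, the reference local). Rather
#' than collapsing the read's own Cs, the substitution matrix scores a
#' read C against a reference (collapsed) T as a match, which is
#' score-identical to collapsing both strings but keeps the original read
#' bases available at each aligned reference position -- those bases are
#' what methylation calling consumes. Both the read and its reverse
#' complement are aligned and the higher-scoring orientation kept.
#'
#' Default scores: match +2, mismatch -3, gap open -5, gap extend -2.
#'
#' @param reads A `DNAStringSet`, `QualityScaledDNAStringSet`, character
#'   vector, or `synthetic_reads` object.
#' @param reference An [amplicon_reference()].
#' @param match,mismatch,gap_opening,gap_extension Scoring parameters
#'   (penalties given as positive numbers).
#' @param chunk_size Reads aligned per batch (memory control).
#' @return List of class `bisulfite_alignment`: `base_matrix` (character
#'   matrix, one row per read and one column per reference position; "-"
#'   where the alignment has a gap or does not cover the position),
#'   `score`, `orientation` ("fwd"/"rev"), `aligned_fraction`,
#'   `read_length`, `read_id`.
#' @export
align_bisulfite <- function(reads, reference,
                            match = 2, mismatch = -3,
                            gap_opening = 5, gap_extension = 2,
                            chunk_size = 2000L) {
  stopifnot(inherits(reference, "amplicon_reference"))
  if (inherits(reads, "synthetic_reads")) reads <- reads$sequences
  if (is.character(reads)) reads <- Biostrings::DNAStringSet(reads)
  reads <- quiet_mcols(methods::as(reads, "DNAStringSet"))
  n <- length(reads)
  if (n == 0L) stop("no reads to align")
  ids <- names(reads)
  if (is.null(ids)) ids <- sprintf("read%06d", seq_len(n))
  subj <- Biostrings::DNAString(bisulfite_convert(reference$sequence))
  submat <- .bisulfite_submat(match, mismatch)
  L <- reference$length

  base_matrix <- matrix("-", n, L)
  score <- numeric(n); orient <- character(n)
  for (start in seq(1L, n, by = chunk_size)) {
    sel <- start:min(start + chunk_size - 1L, n)
    fw <- reads[sel]
    rv <- Biostrings::reverseComplement(fw)
    a_f <- Biostrings::pairwiseAlignment(fw, subj, type = "global-local",
                                         substitutionMatrix = submat,
                                         gapOpening = gap_opening,
                                         gapExtension = gap_extension)
    a_r <- Biostrings::pairwiseAlignment(rv, subj, type = "global-local",
                                         substitutionMatrix = submat,
                                         gapOpening = gap_opening,
                                         gapExtension = gap_extension)
    use_rev <- Biostrings::score(a_r) > Biostrings::score(a_f)
    for (w in c(FALSE, TRUE)) {
      pick <- which(use_rev == w)
      if (!length(pick)) next
      aln <- if (w) a_r[pick] else a_f[pick]
      # aligned() = read bases in reference coordinates, gaps as "-",
      # insertions relative to the reference removed, padded to full length
      am <- as.matrix(Biostrings::aligned(aln))
      base_matrix[sel[pick], ] <- am
      score[sel[pick]] <- Biostrings::score(aln)
      orient[sel[pick]] <- if (w) "rev" else "fwd"
    }
  }
  structure(list(
    base_matrix = base_matrix,
    score = score,
    orientation = orient,
    aligned_fraction = rowSums(base_matrix != "-") / L,
    read_length = Biostrings::width(reads),
    read_id = ids,
    locus_name = reference$locus_name
  ), class = "bisulfite_alignment")
}

.bisulfite_submat <- function(match = 2, mismatch = -3) {
  bases <- c("A", "C", "G", "T")
  m <- matrix(mismatch, 4, 4, dimnames = list(bases, bases))
  diag(m) <- match
  m["C", "T"] <- match   # read C vs converted-reference T: bisulfite match
  m
}

#' Call per-molecule methylation profiles from an alignment
#'
#' Applies the 0/1/2 coding per CpG site: the read base at the site is C
#' (methylated, 1), T (unmethylated, 0), or anything else -- a mismatching
#' base or an alignment gap -- gives the ambiguous code 2. CpH positions
#' accumulate the per-read conversion evidence: a C increments
#' `mcph_count`, a T increments the converted count, other bases and gaps
#' are excluded; `bisulfite_efficiency` is converted / (converted +
#' retained). Reads with zero aligned CpH get `NA` efficiency and are
#' treated as failing the efficiency filter downstream.
#'
#' @param alignment A `bisulfite_alignment` from [align_bisulfite()].
#' @param reference The matching [amplicon_reference()].
#' @return A data.frame of class `methylation_profiles`: read_id, locus,
#'   calls (string over 0/1/2, one char per CpG), n_ambiguous,
#'   bisulfite_efficiency, aligned_fraction, read_length, mcph_count,
#'   total_cph_aligned.
#' @export
call_profiles <- function(alignment, reference) {
  stopifnot(inherits(alignment, "bisulfite_alignment"),
            inherits(reference, "amplicon_reference"))
  bm <- alignment$base_matrix
  n <- nrow(bm)
  N <- reference$n_cpg
  if (N == 0L) stop("reference has no CpG sites")
  sub <- bm[, reference$cpg_positions, drop = FALSE]
  calls <- matrix(2L, n, N)
  calls[sub == "C"] <- 1L
  calls[sub == "T"] <- 0L
  if (reference$n_cph > 0L) {
    hsub <- bm[, reference$cph_positions, drop = FALSE]
    mcph <- rowSums(hsub == "C")
    conv <- rowSums(hsub == "T")
  } else {
    mcph <- conv <- integer(n)
  }
  total <- mcph + conv
  eff <- ifelse(total > 0L, conv / total, NA_real_)
  out <- data.frame(
    read_id = alignment$read_id,
    locus = reference$locus_name,
    calls = apply(calls, 1L, paste, collapse = ""),
    n_ambiguous = rowSums(calls == 2L),
    bisulfite_efficiency = eff,
    aligned_fraction = alignment$aligned_fraction,
    read_length = alignment$read_length,
    mcph_count = as.integer(mcph),
    total_cph_aligned = as.integer(total),
    stringsAsFactors = FALSE
  )
  class(out) <- c("methylation_profiles", "data.frame")
  out
}

#' Apply the per-read QC filters
#'
#' A profile is retained iff it satisfies all four criteria: read length
#' within `length_tolerance` of the reference length, bisulfite
#' efficiency at least the minimum (reads with undefined efficiency --
#' zero aligned CpH -- fail rather than pass vacuously), fraction of
#' ambiguous CpG calls at most the maximum, and aligned fraction at least
#' the minimum. Each read is tested against every criterion, so the
#' per-criterion rejection tallies can sum to more than the number of
#' rejected reads.
#'
#' @param profiles A `methylation_profiles` data.frame.
#' @param reference The [amplicon_reference()].
#' @param thresholds A [filter_thresholds()].
#' @return List: `retained` (profiles subset), `n_input`, `n_retained`,
#'   `rejections` (named integer vector per criterion).
#' @export
filter_profiles <- function(profiles, reference,
                            thresholds = filter_thresholds()) {
  stopifnot(inherits(profiles, "methylation_profiles"),
            inherits(reference, "amplicon_reference"),
            inherits(thresholds, "filter_thresholds"))
  L <- reference$length
  N <- reference$n_cpg
  ok_len <- abs(profiles$read_length - L) <= thresholds$length_tolerance * L
  eff <- profiles$bisulfite_efficiency
  ok_eff <- !is.na(eff) & eff >= thresholds$min_bisulfite_efficiency
  ok_amb <- profiles$n_ambiguous / N <= thresholds$max_ambiguous_cpg_fraction
  ok_aln <- profiles$aligned_fraction >= thresholds$min_aligned_fraction
  keep <- ok_len & ok_eff & ok_amb & ok_aln
  retained <- profiles[keep, , drop = FALSE]
  class(retained) <- class(profiles)
  list(retained = retained,
       n_input = nrow(profiles),
       n_retained = sum(keep),
       rejections = c(read_length = sum(!ok_len),
                      bisulfite_efficiency = sum(!ok_eff),
                      ambiguous_cpg = sum(!ok_amb),
                      aligned_fraction = sum(!ok_aln)))
}

#' Estimate bisulfite conversion efficiency from spike-in reads
#'
#' The spike-in is a fully unmethylated control, so every cytosine of its
#' reference should read as T; efficiency is the pooled fraction of
#' aligned reference-cytosine positions (all contexts) read as T among
#' those read as C or T, across all spike reads.
#'
#' @param spike_reads Reads from the spike-in amplicon (any input
#'   [align_bisulfite()] accepts).
#' @param spike_reference The spike-in [amplicon_reference()].
#' @param sample_id Identifier carried into the report.
#' @return List of class `conversion_report`: sample_id, n_spike_reads,
#'   conversion_efficiency, residual_c_fraction. `NULL` (with a warning)
#'   when no spike read aligns over any cytosine; downstream mCpH
#'   correction then falls back to zero-subtraction.
#' @export
estimate_conversion_efficiency <- function(spike_reads, spike_reference,
                                           sample_id = "pooled") {
  aln <- align_bisulfite(spike_reads, spike_reference)
  c_pos <- which(strsplit(spike_reference$sequence, "", fixed = TRUE)[[1]] == "C")
  bm <- aln$base_matrix[, c_pos, drop = FALSE]
  n_c <- sum(bm == "C")
  n_t <- sum(bm == "T")
  if (n_c + n_t == 0L) {
    warning("no aligned spike-in cytosines; conversion efficiency unavailable")
    return(NULL)
  }
  structure(list(sample_id = sample_id,
                 n_spike_reads = nrow(aln$base_matrix),
                 conversion_efficiency = n_t / (n_c + n_t),
                 residual_c_fraction = n_c / (n_c + n_t)),
            class = "conversion_report")
}

#' FASTQ to filtered methylation profiles for one sample
#'
#' Convenience wrapper running the full read-level stage: quality filter,
#' bisulfite alignment, profile calling and QC filtering.
#'
#' @param fastq Path to the sample's merged-read FASTQ, or any reads
#'   object accepted by [quality_filter()]/[align_bisulfite()].
#' @param reference The locus [amplicon_reference()].
#' @param thresholds A [filter_thresholds()].
#' @return List: `profiles` (retained `methylation_profiles`), `report`
#'   (read counts in/out of each filter).
#' @export
process_sample <- function(fastq, reference, thresholds = filter_thresholds()) {
  reads <- if (is.character(fastq) && length(fastq) == 1L && file.exists(fastq))
    read_sample_fastq(fastq) else fastq
  qf <- quality_filter(reads, thresholds$min_mean_phred)
  if (qf$n_pass == 0L) stop("no reads pass the quality filter")
  aln <- align_bisulfite(qf$pass, reference)
  prof <- call_profiles(aln, reference)
  fl <- filter_profiles(prof, reference, thresholds)
  list(profiles = fl$retained,
       report = list(n_raw = qf$n_pass + qf$n_fail,
                     n_quality_pass = qf$n_pass,
                     n_retained = fl$n_retained,
                     rejections = fl$rejections))
}
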