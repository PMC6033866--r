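#' Generate a synthetic amplicon reference with planted CpG sites
#'
#' Builds a random top-strand amplicon with an exact number of CpG
#' dinucleotides and at least a requested number of CpH cytosines,
#' structurally emulating targeted bisulfite amplicons (300-450 bp,
#' 3-30 CpGs, many CpHs). The background alphabet is A/C/T with G used
#' only in planted CpGs, so no CpG can arise or vanish by adjacency
#' accident; the construction is verified with [classify_cytosines()].
#'
#' @param length Amplicon length in bp.
#' @param n_cpg Exact number of CpG sites to plant.
#' @param n_cph_min Minimum number of CpH cytosines.
#' @param tss_offset 1-based index of the +1 base (default: mid-amplicon).
#' @param locus_name Name for the reference.
#' @param seed Integer seed; the construction is deterministic given it.
#' @return An [amplicon_reference()] with attribute `planted_cpg`
#'   (the planted C indices, equal to its `cpg_positions`).
#' @export
make_synthetic_reference <- function(length, n_cpg, n_cph_min = 0,
                                     tss_offset = NULL,
                                     locus_name = "synthetic",
                                     seed = 1L) {
  length <- as.integer(length); n_cpg <- as.integer(n_cpg)
  if (length < 2L * n_cpg)
    stop(sprintf("infeasible: %d CpGs cannot fit in %d bp", n_cpg, length))
  if (n_cph_min > length - 2L * n_cpg)
    stop(sprintf("infeasible: %d CpHs cannot fit beside %d CpGs in %d bp",
                 n_cph_min, n_cpg, length))
  if (is.null(tss_offset)) tss_offset <- length %/% 2L
  with_seed(seed, {
    chars <- sample(c("A", "C", "T"), length, replace = TRUE,
                    prob = c(0.40, 0.25, 0.35))
    if (n_cpg > 0L) {
      # distinct positions with pairwise gap >= 2 so the CG pairs never overlap
      c_pos <- sort(sample.int(length - n_cpg, n_cpg)) + seq_len(n_cpg) - 1L
      chars[c_pos] <- "C"
      chars[c_pos + 1L] <- "G"
    } else c_pos <- integer(0)
    # top up CpH count if the random background fell short
    free <- setdiff(which(chars %in% c("A", "T")), c(c_pos, c_pos + 1L, length))
    n_cph_now <- sum(chars == "C") - n_cpg - (chars[length] == "C")
    if (n_cph_now < n_cph_min) {
      need <- n_cph_min - n_cph_now
      if (need > base::length(free)) stop("infeasible: not enough free positions for CpHs")
      chars[sample(free, need)] <- "C"
    }
    ref <- amplicon_reference(locus_name, paste(chars, collapse = ""), tss_offset)
  })
  if (!identical(ref$cpg_positions, c_pos))
    stop("internal error: planted CpG sites not recovered")  # defensive
  attr(ref, "planted_cpg") <- c_pos
  ref
}

#' Specification of a per-sample epiallele mixture
#'
#' Describes one sample's molecule population at one locus: a discrete
#' mixture of epiallele patterns, the per-site CpH methylation rate, and
#' the chemistry/sequencing noise applied when reads are emitted.
#'
#' @param locus_name Locus the patterns belong to.
#' @param patterns Named numeric vector: names are binary strings of
#'   length N (the locus's CpG count), values are mixture frequencies
#'   summing to 1 (tolerance 1e-9).
#' @param n_reads Number of molecules/reads to draw.
#' @param cph_methylation_rate Per-site, per-molecule probability that a
#'   CpH cytosine is methylated (i.i.d.).
#' @param conversion_failure_rate Probability an unmethylated C survives
#'   bisulfite conversion and is read as C (study chemistry: ~0.5-2%).
#' @param sequencing_error_rate Per-base substitution probability.
#' @param seed Integer seed for all draws derived from this spec.
#' @return An object of class `epiallele_mixture_spec`.
#' @export
epiallele_mixture_spec <- function(locus_name, patterns, n_reads,
                                   cph_methylation_rate = 0,
                                   conversion_failure_rate = 0,
                                   sequencing_error_rate = 0,
                                   seed = 1L) {
  stopifnot(is.numeric(patterns), !is.null(names(patterns)), n_reads >= 0)
  if (any(patterns < 0)) stop("pattern frequencies must be >= 0")
  if (abs(sum(patterns) - 1) > 1e-9) stop("pattern frequencies must sum to 1")
  nlen <- unique(nchar(names(patterns)))
  if (length(nlen) != 1L || !all(grepl("^[01]+$", names(patterns))))
    stop("patterns must be binary strings of one common length")
  for (r in c(cph_methylation_rate, conversion_failure_rate, sequencing_error_rate))
    if (r < 0 || r > 1) stop("rates must lie in [0, 1]")
  structure(list(locus_name = locus_name, patterns = patterns,
                 n_cpg = nlen, n_reads = as.integer(n_reads),
                 cph_methylation_rate = cph_methylation_rate,
                 conversion_failure_rate = conversion_failure_rate,
                 sequencing_error_rate = sequencing_error_rate,
                 seed = as.integer(seed)),
            class = "epiallele_mixture_spec")
}

#' Draw true molecules from an epiallele mixture
#'
#' Multinomial draw of epiallele patterns plus i.i.d. Bernoulli CpH
#' methylation states per molecule; the returned truth record is exactly
#' reproducible from (spec, seed) and joins 1:1 to emitted reads.
#'
#' @param spec An [epiallele_mixture_spec()].
#' @param reference The [amplicon_reference()] the molecules belong to;
#'   its CpG count must equal the spec's pattern length.
#' @return List of class `synthetic_molecules`: `patterns` (character,
#'   one binary string per molecule), `cph_states` (n x n_cph 0/1 integer
#'   matrix), `truth` (data.frame with molecule_id, pattern, n_meth_cpg,
#'   n_meth_cph), plus `expected_class_freq` and `expected_site_freq`
#'   implied by the mixture.
#' @export
sample_epialleles <- function(spec, reference) {
  stopifnot(inherits(spec, "epiallele_mixture_spec"),
            inherits(reference, "amplicon_reference"))
  if (spec$n_cpg != reference$n_cpg)
    stop(sprintf("pattern length %d != locus CpG count %d",
                 spec$n_cpg, reference$n_cpg))
  n <- spec$n_reads
  pat_names <- names(spec$patterns)
  with_seed(spec$seed, {
    idx <- sample.int(length(pat_names), n, replace = TRUE, prob = spec$patterns)
    cph_states <- matrix(0L, nrow = n, ncol = reference$n_cph)
    if (spec$cph_methylation_rate > 0 && reference$n_cph > 0L)
      cph_states[] <- rbinom(n * reference$n_cph, 1L, spec$cph_methylation_rate)
  })
  patterns <- pat_names[idx]
  bits <- .pattern_bits(pat_names)            # one row per distinct pattern
  pop <- rowSums(bits)
  cls <- numeric(spec$n_cpg + 1L)
  for (k in seq_along(pop)) cls[pop[k] + 1L] <- cls[pop[k] + 1L] + spec$patterns[k]
  structure(list(
    patterns = patterns,
    cph_states = cph_states,
    truth = data.frame(
      molecule_id = seq_len(n),
      pattern = patterns,
      n_meth_cpg = pop[idx],
      n_meth_cph = if (reference$n_cph > 0L) rowSums(cph_states) else integer(n),
      stringsAsFactors = FALSE),
    expected_class_freq = stats::setNames(cls, 0:spec$n_cpg),
    expected_site_freq = as.numeric(spec$patterns %*% bits),
    locus_name = spec$locus_name,
    seed = spec$seed
  ), class = "synthetic_molecules")
}

#' Emit bisulfite-converted reads for drawn molecules
#'
#' Applies the bisulfite chemistry model to each molecule of the
#' reference: methylated cytosines are read as C; unmethylated cytosines
#' are read as T except that each survives unconverted (read as C) with
#' probability `conversion_failure_rate`. Independent substitution errors
#' are then added at `sequencing_error_rate`, and per-base qualities are
#' drawn from `phred_model`. Deterministic under `seed`.
#'
#' @param molecules A `synthetic_molecules` object from
#'   [sample_epialleles()] (or NULL for an all-unmethylated spike-in with
#'   `n_reads` molecules).
#' @param reference The [amplicon_reference()].
#' @param conversion_failure_rate,sequencing_error_rate See
#'   [epiallele_mixture_spec()].
#' @param phred_model Quality model: `list(type = "constant", q = 38)` or
#'   `list(type = "two_state", q = c(q1, q2), prob = c(p1, p2))`, the
#'   latter assigning each read a single quality drawn between two levels
#'   (useful for testing mean-quality filters against known truth).
#' @param seed Integer seed.
#' @param sample_id Prefix used in read identifiers; IDs are
#'   `sample|locus|mol<index>` so truth joins are unambiguous.
#' @param n_reads Only used when `molecules` is NULL.
#' @return List of class `synthetic_reads`: `sequences`
#'   (`Biostrings::DNAStringSet`, named by read ID), `qualities`
#'   (character, PHRED+33), `truth` (the molecule truth joined with
#'   per-read mean quality and error count).
#' @export
emit_bisulfite_reads <- function(molecules, reference,
                                 conversion_failure_rate = 0,
                                 sequencing_error_rate = 0,
                                 phred_model = list(type = "constant", q = 38),
                                 seed = 1L,
                                 sample_id = "S1",
                                 n_reads = NULL) {
  stopifnot(inherits(reference, "amplicon_reference"))
  if (is.null(molecules)) {
    stopifnot(!is.null(n_reads))
    n <- as.integer(n_reads)
    patterns_bits <- matrix(0L, n, reference$n_cpg)
    cph_states <- matrix(0L, n, reference$n_cph)
    truth <- data.frame(molecule_id = seq_len(n),
                        pattern = strrep("0", reference$n_cpg),
                        n_meth_cpg = 0L, n_meth_cph = 0L,
                        stringsAsFactors = FALSE)
  } else {
    stopifnot(inherits(molecules, "synthetic_molecules"))
    n <- length(molecules$patterns)
    patterns_bits <- .pattern_bits(molecules$patterns)
    cph_states <- molecules$cph_states
    truth <- molecules$truth
  }
  L <- reference$length
  refchars <- strsplit(reference$sequence, "", fixed = TRUE)[[1]]
  # base matrix: n reads x L positions, filled with the reference
  mat <- matrix(rep(refchars, each = n), nrow = n)
  with_seed(seed, {
    # cytosines: CpG per pattern, CpH per drawn state, any terminal C unmethylated
    emit_c <- function(cols, meth) {
      # meth: n x length(cols) 0/1; unmethylated read as T unless conversion fails
      if (!length(cols)) return()
      fail <- matrix(stats::runif(n * length(cols)) < conversion_failure_rate,
                     nrow = n)
      mat[, cols] <<- ifelse(meth == 1L | fail, "C", "T")
    }
    if (reference$n_cpg > 0L) emit_c(reference$cpg_positions, patterns_bits)
    if (reference$n_cph > 0L) emit_c(reference$cph_positions, cph_states)
    term_c <- which(refchars == "C")
    term_c <- setdiff(term_c, c(reference$cpg_positions, reference$cph_positions))
    if (length(term_c)) emit_c(term_c, matrix(0L, n, length(term_c)))
    # substitution sequencing errors
    n_err <- 0L
    err_per_read <- integer(n)
    if (sequencing_error_rate > 0) {
      hit <- which(stats::runif(n * L) < sequencing_error_rate)
      n_err <- length(hit)
      if (n_err) {
        cur <- mat[hit]
        alt <- vapply(cur, function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1L), "")
        mat[hit] <- alt
        err_per_read <- tabulate((hit - 1L) %% n + 1L, nbins = n)
      }
    }
    quals <- .draw_qualities(phred_model, n, L)
  })
  ids <- sprintf("%s|%s|mol%06d", sample_id, reference$locus_name, seq_len(n))
  seqs <- Biostrings::DNAStringSet(apply(mat, 1L, paste, collapse = ""))
  names(seqs) <- ids
  truth$read_id <- ids
  truth$mean_phred <- quals$mean
  truth$n_errors <- err_per_read
  structure(list(sequences = seqs, qualities = quals$strings, truth = truth,
                 locus_name = reference$locus_name, sample_id = sample_id,
                 seed = as.integer(seed)),
            class = "synthetic_reads")
}

#' Emit reads from a fully unmethylated spike-in control
#'
#' Convenience wrapper over [emit_bisulfite_reads()] with an
#' all-unmethylated truth: every cytosine of the spike-in reference is
#' expected to convert, so the fraction of residual Cs in these reads
#' estimates the conversion failure rate.
#'
#' @inheritParams emit_bisulfite_reads
#' @param spike_reference An [amplicon_reference()] flagged
#'   `is_unmethylated_control`.
#' @export
emit_spike_in <- function(n_reads, spike_reference,
                          conversion_failure_rate = 0,
                          sequencing_error_rate = 0,
                          phred_model = list(type = "constant", q = 38),
                          seed = 1L, sample_id = "S1") {
  if (!isTRUE(spike_reference$is_unmethylated_control))
    warning("spike reference is not flagged as an unmethylated control")
  emit_bisulfite_reads(NULL, spike_reference,
                       conversion_failure_rate = conversion_failure_rate,
                       sequencing_error_rate = sequencing_error_rate,
                       phred_model = phred_model, seed = seed,
                       sample_id = sample_id, n_reads = n_reads)
}

#' Write synthetic reads as a 4-line FASTQ (PHRED+33)
#'
#' @param reads A `synthetic_reads` object.
#' @param path Output FASTQ path.
#' @return `path`, invisibly.
#' @export
write_reads_fastq <- function(reads, path) {
  stopifnot(inherits(reads, "synthetic_reads"))
  Biostrings::writeXStringSet(reads$sequences, path, format = "fastq",
                              qualities = Biostrings::BStringSet(reads$qualities))
  invisible(path)
}

#' Simulate a multi-region, two-group cohort on disk
#'
#' Emulates the study-shaped design: three brain areas (default HIPP,
#' DLPFC, CB), two diagnosis groups (CTRL, SCZ) with `n_per_group`
#' samples each per area, area-specific epiallele mixtures, and an
#' unmethylated spike-in per sample. Writes one FASTQ per sample, one for
#' its spike-in, a truth table and a manifest TSV.
#'
#' @param out_dir Output directory (created).
#' @param reference Locus [amplicon_reference()].
#' @param spike_reference Spike-in [amplicon_reference()].
#' @param area_mixtures Named list (one element per area) of named
#'   frequency vectors over epiallele patterns, as in
#'   [epiallele_mixture_spec()]. Groups within an area share the mixture
#'   (the study detected area effects, not diagnosis effects).
#' @param n_per_group Samples per diagnosis group per area.
#' @param reads_per_sample Reads per sample (study depth is ~200,000;
#'   simulations typically use a scaled-down depth).
#' @param spike_reads_per_sample Spike-in reads per sample.
#' @param cph_methylation_rate,conversion_failure_rate,sequencing_error_rate,phred_model
#'   Passed to the generator; defaults emulate the study chemistry
#'   (conversion failure 1%, low substitution error).
#' @param groups Diagnosis group labels.
#' @param seed Master seed; every sample derives its own sub-seed from it.
#' @return The manifest as a data.frame (sample_id, group, area, locus,
#'   fastq, spike_fastq, truth, seed), also written to
#'   `<out_dir>/manifest.tsv`.
#' @export
simulate_cohort <- function(out_dir, reference, spike_reference,
                            area_mixtures,
                            n_per_group = 6L,
                            reads_per_sample = 5000L,
                            spike_reads_per_sample = 2000L,
                            cph_methylation_rate = 0.01,
                            conversion_failure_rate = 0.01,
                            sequencing_error_rate = 0.002,
                            phred_model = list(type = "two_state",
                                               q = c(20, 40), prob = c(0.05, 0.95)),
                            groups = c("CTRL", "SCZ"),
                            seed = 1L) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  areas <- names(area_mixtures)
  stopifnot(length(areas) >= 1L, !is.null(areas))
  rows <- list()
  i <- 0L
  for (area in areas) for (grp in groups) for (k in seq_len(n_per_group)) {
    i <- i + 1L
    sid <- sprintf("%s_%s_%02d", area, grp, k)
    sseed <- (seed * 10000L + i) %% .Machine$integer.max
    spec <- epiallele_mixture_spec(reference$locus_name, area_mixtures[[area]],
                                   n_reads = reads_per_sample,
                                   cph_methylation_rate = cph_methylation_rate,
                                   conversion_failure_rate = conversion_failure_rate,
                                   sequencing_error_rate = sequencing_error_rate,
                                   seed = sseed)
    mol <- sample_epialleles(spec, reference)
    rd <- emit_bisulfite_reads(mol, reference,
                               conversion_failure_rate = conversion_failure_rate,
                               sequencing_error_rate = sequencing_error_rate,
                               phred_model = phred_model,
                               seed = sseed + 1L, sample_id = sid)
    sp <- emit_spike_in(spike_reads_per_sample, spike_reference,
                        conversion_failure_rate = conversion_failure_rate,
                        sequencing_error_rate = sequencing_error_rate,
                        phred_model = phred_model,
                        seed = sseed + 2L, sample_id = sid)
    fq <- file.path(out_dir, paste0(sid, ".fastq"))
    sfq <- file.path(out_dir, paste0(sid, ".spike.fastq"))
    tr <- file.path(out_dir, paste0(sid, ".truth.tsv"))
    write_reads_fastq(rd, fq)
    write_reads_fastq(sp, sfq)
    utils::write.table(rd$truth, tr, sep = "\t", quote = FALSE, row.names = FALSE)
    rows[[i]] <- data.frame(sample_id = sid, group = grp, area = area,
                            locus = reference$locus_name,
                            fastq = fq, spike_fastq = sfq, truth = tr,
                            seed = sseed, stringsAsFactors = FALSE)
  }
  manifest <- do.call(rbind, rows)
  utils::write.table(manifest, file.path(out_dir, "manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  manifest
}

#' Built-in area-specific epiallele mixtures
#'
#' Three mixtures over 10-CpG epiallele patterns emulating the qualitative
#' brain-area contrast the assay is designed to detect: two cortical-like
#' populations (HIPP, DLPFC) with many epiallele species spread across
#' intermediate classes, and a cerebellum-like population (CB) dominated
#' by the fully methylated molecule plus an unmethylated fraction -- fewer
#' species, lower diversity, a distinct class profile. HIPP and DLPFC
#' differ only in weights, giving a subtler second contrast.
#'
#' @param n_cpg Number of CpG sites (only 10 is provided).
#' @return Named list of pattern-frequency vectors (HIPP, DLPFC, CB)
#'   suitable for [epiallele_mixture_spec()] / [simulate_cohort()].
#' @export
example_area_mixtures <- function(n_cpg = 10) {
  stopifnot(n_cpg == 10)
  list(
    HIPP = c("1111111111" = 0.16, "1111100000" = 0.12, "0000011111" = 0.12,
             "1010101010" = 0.10, "0101010101" = 0.10, "1100110011" = 0.10,
             "0011001100" = 0.09, "1110001110" = 0.08, "0001110001" = 0.08,
             "0000000000" = 0.05),
    DLPFC = c("1111111111" = 0.20, "1111100000" = 0.10, "0000011111" = 0.10,
              "1010101010" = 0.12, "0101010101" = 0.08, "1100110011" = 0.08,
              "0011001100" = 0.11, "1110001110" = 0.09, "0001110001" = 0.07,
              "0000000000" = 0.05),
    CB = c("1111111111" = 0.55, "1111111110" = 0.20, "1111101111" = 0.10,
           "0000000000" = 0.15)
  )
}

# binary pattern strings -> 0/1 integer matrix (one row per string)
.pattern_bits <- function(patterns) {
  if (!length(patterns)) return(matrix(0L, 0, 0))
  m <- do.call(rbind, strsplit(patterns, "", fixed = TRUE))
  storage.mode(m) <- "integer"
  m
}

.draw_qualities <- function(phred_model, n, L) {
  type <- phred_model$type %||% "constant"
  if (type == "constant") {
    q <- rep(as.integer(phred_model$q), n)
  } else if (type == "two_state") {
    q <- sample(as.integer(phred_model$q), n, replace = TRUE,
                prob = phred_model$prob)
  } else stop("unknown phred_model type: ", type)
  strings <- vapply(q, function(qq) strrep(rawToChar(as.raw(qq + 33L)), L), "")
  list(strings = strings, mean = as.numeric(q))
}
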